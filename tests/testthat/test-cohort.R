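specs3 <- list(
  sepsis = variable_spec("sepsis", "outcome", "categorical", c("0", "1")),
  scr = variable_spec("scr", "putative_risk", "continuous",
                      c("<=116", ">116"), cutpoints = 116, sides = "left",
                      reference = "<=116", min = 0),
  smoking = variable_spec("smoking", "confounder", "categorical",
                          c("No", "Yes"), reference = "No"))

write_tmp <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

test_that("load_cohort reads delimited text, preserves order, flags missing", {
  f <- write_tmp(c("sepsis,scr,smoking", "0,100,No", "1,130,Yes", "0,80,No"))
  raw <- load_cohort(f, specs3)
  expect_equal(nrow(raw), 3)
  expect_equal(raw$scr, c(100, 130, 80))
  expect_equal(attr(raw, "n_missing"), 0L)

  # tab-separated autodetection
  ftab <- write_tmp(c("sepsis\tscr\tsmoking", "0\t100\tNo"))
  expect_equal(nrow(load_cohort(ftab, specs3)), 1)

  # one empty cell -> flagged, not dropped
  fm <- write_tmp(c("sepsis,scr,smoking", "0,,No", "1,130,Yes"))
  rawm <- load_cohort(fm, specs3)
  expect_equal(nrow(rawm), 2)
  expect_equal(attr(rawm, "n_missing"), 1L)
  expect_true(is.na(rawm$scr[1]))
})

test_that("load_cohort errors name the offending column or line", {
  f <- write_tmp(c("sepsis,smoking", "0,No"))
  expect_error(load_cohort(f, specs3), "scr")
  fbad <- write_tmp(c("sepsis,scr,smoking", "0,100,No", "0,abc,No"))
  expect_error(load_cohort(fbad, specs3), "line 2")
})

test_that("impute_missing uses means, modes and the lexicographic tie rule", {
  raw <- data.frame(sepsis = c(0, 1, 0), scr = c(1, 2, NA),
                    smoking = c("No", "No", "Yes"), stringsAsFactors = FALSE)
  imp <- impute_missing(raw, specs3)
  expect_equal(imp$scr, c(1, 2, 1.5))

  raw2 <- data.frame(sepsis = 0:1, scr = c(1, 1),
                     smoking = c(NA, "Yes"), stringsAsFactors = FALSE)
  # tie between No (0) and Yes (1)? only Yes observed -> Yes
  expect_equal(impute_missing(raw2, specs3)$smoking, c("Yes", "Yes"))

  raw3 <- data.frame(sepsis = c(0, 0, 1, 1), scr = rep(1, 4),
                     smoking = c("Yes", "No", NA, NA),
                     stringsAsFactors = FALSE)
  # Yes/No tie -> lexicographically smallest ("No")
  expect_equal(impute_missing(raw3, specs3)$smoking[3:4], c("No", "No"))

  # identity on a complete table
  expect_identical(impute_missing(raw3[1:2, ], specs3), raw3[1:2, ])
  # fully-missing column refused
  raw4 <- data.frame(sepsis = 0:1, scr = c(NA_real_, NA_real_),
                     smoking = c("No", "No"), stringsAsFactors = FALSE)
  expect_error(impute_missing(raw4, specs3), "fully missing")
})

test_that("discretize honours published boundary sides exactly", {
  specs <- default_variable_specs()
  grab <- function(nm, vals) {
    s <- specs[[nm]]
    cut_fun <- septree:::cut_value
    cut_fun(vals, s$cutpoints, s$sides, s$levels)
  }
  expect_equal(grab("scr", c(116, 116.01)), c("<=116", ">116"))
  expect_equal(grab("car", c(0.277, 0.278)), c("<0.278", ">=0.278"))
  expect_equal(grab("glu", c(10, 10.01)), c("<=10", ">10"))
  expect_equal(grab("bmi", c(18.49, 18.5, 24, 25)),
               c("<18.5", "18.5-24", ">=24", ">=24"))
  expect_equal(grab("alb", c(35.9, 36)), c("<36", ">=36"))
  expect_equal(grab("age", c(74.9, 75)), c("65-74", ">=75"))
  expect_equal(grab("surgery_duration", c(120, 121)), c("<=120", ">120"))
})

test_that("discretize validates domain and labels", {
  raw <- data.frame(sepsis = c(0, 1), scr = c(-5, 100),
                    smoking = c("No", "No"), stringsAsFactors = FALSE)
  expect_error(discretize(raw, specs3), "below domain minimum")
  raw2 <- data.frame(sepsis = c(0, 1), scr = c(50, 100),
                     smoking = c("No", "Sometimes"), stringsAsFactors = FALSE)
  expect_error(discretize(raw2, specs3), "Sometimes")
})

test_that("level counts partition the cohort and round-trips are exact", {
  set.seed(11)
  raw <- data.frame(sepsis = rbinom(50, 1, 0.3),
                    scr = runif(50, 50, 200),
                    smoking = sample(c("No", "Yes"), 50, TRUE),
                    stringsAsFactors = FALSE)
  co <- discretize(raw, specs3)
  for (nm in c("scr", "smoking"))
    expect_equal(sum(table(co[[nm]])), nrow(co))

  # discretize . impute is idempotent on an already-clean categorical table
  clean <- as.data.frame(lapply(co, as.character), stringsAsFactors = FALSE)
  clean$sepsis <- as.numeric(clean$sepsis)
  cat_specs <- specs3
  cat_specs$scr <- variable_spec("scr", "putative_risk", "categorical",
                                 c("<=116", ">116"), reference = "<=116")
  again <- discretize(impute_missing(clean, cat_specs), cat_specs)
  expect_equal(as.character(again$scr), as.character(co$scr))

  # write -> load -> discretize reproduces the cohort cell-for-cell
  f <- tempfile(fileext = ".tsv")
  write_cohort(co, f)
  back <- discretize(impute_missing(load_cohort(f, cat_specs), cat_specs),
                     cat_specs)
  expect_equal(as.data.frame(lapply(back, as.character)),
               as.data.frame(lapply(co, as.character)))
})

test_that("comorbidity count is derived from the seven flags when absent", {
  gen <- generate_cohort(default_config(n = 400, seed = 5))
  co <- gen$cohort
  raw <- as.data.frame(lapply(co, as.character), stringsAsFactors = FALSE)
  raw$sepsis <- as.numeric(raw$sepsis)
  raw$n_comorbidities <- NULL
  specs <- attr(co, "specs")
  co2 <- discretize(raw, specs)
  flags <- c("diabetes", "coronary_disease", "cerebrovascular_disease",
             "malignant_tumor", "hepatic_failure", "pneumonia",
             "acute_kidney_injury")
  cnt <- rowSums(sapply(flags, function(f) raw[[f]] == "Yes"))
  expect_equal(as.character(co2$n_comorbidities),
               ifelse(cnt == 0, "0", ifelse(cnt <= 2, "1-2", ">=3")))
})

test_that("spec invariants are enforced at construction", {
  expect_error(variable_spec("x", "outcome", "categorical", c("A", "B")),
               "0, 1")
  expect_error(variable_spec("x", "confounder", "continuous",
                             c("a", "b"), cutpoints = c(2, 1)),
               "strictly increasing")
  expect_error(variable_spec("x", "confounder", "categorical", c("A", "B"),
                             reference = "C"), "reference")
  expect_error(validate_specs <- septree:::validate_specs(list(
    variable_spec("a", "confounder", "categorical", c("A", "B")))),
    "outcome")
})
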