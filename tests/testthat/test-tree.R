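test_that("encode_confounders uses K-1 one-vs-rest coding", {
  gen <- generate_cohort(default_config(n = 200, seed = 2))
  co <- gen$cohort
  x <- encode_confounders(co, c("diabetes", "bmi", "n_comorbidities"))
  expect_equal(colnames(x),
               c("diabetes=Yes", "bmi=<18.5", "bmi=>=24",
                 "n_comorbidities=1-2", "n_comorbidities=>=3"))
  expect_true(all(x %in% 0:1))
  expect_equal(unname(x[, "diabetes=Yes"]),
               as.integer(co$diabetes == "Yes"))
})

test_that("grow_tree picks the exhaustive-search split and obeys stopping rules", {
  set.seed(21)
  d <- random_indicator_cohort(300, 6, p_hi = 0.30, p_lo = 0.05,
                               signal_col = 3)
  tree <- strat_tree(d$x, d$y)
  expect_equal(tree$frame$var[1], "v3")
  expect_equal(septree:::best_split(d$x, d$y, seq_along(d$y), 7)$j,
               oracle_best_split(d$x, d$y, 7)$j)

  # n below min_split -> single leaf
  small <- strat_tree(d$x[1:19, ], d$y[1:19], min_split = 20)
  expect_equal(nrow(small$frame), 1L)

  # constant outcome -> single-leaf tree, not an error
  pure <- strat_tree(d$x, rep(0, 300))
  expect_equal(nrow(pure$frame), 1L)
  expect_equal(pure$frame$yval, 0)
})

test_that("chosen splits match exhaustive search on random cohorts", {
  set.seed(22)
  for (i in 1:40) {
    n <- sample(50:200, 1)
    p <- sample(2:8, 1)
    x <- matrix(rbinom(n * p, 1, runif(1, 0.2, 0.6)), n, p)
    colnames(x) <- paste0("v", seq_len(p))
    y <- rbinom(n, 1, plogis(-1 + x %*% rnorm(p, 0, 0.7)))
    if (sum(y) %in% c(0, n)) next
    mine <- septree:::best_split(x, y, seq_len(n), 7)
    orac <- oracle_best_split(x, y, 7)
    if (is.null(mine)) {
      expect_lte(orac$gain, 1e-12)
    } else {
      expect_equal(mine$j, orac$j)
      expect_equal(mine$gain, orac$gain, tolerance = 1e-9)
    }
  }
})

test_that("root split agrees with rpart's anova fit on a planted cohort", {
  set.seed(23)
  d <- random_indicator_cohort(400, 5, p_hi = 0.35, p_lo = 0.08,
                               signal_col = 2)
  df <- data.frame(y = d$y, d$x)
  rp <- rpart::rpart(y ~ ., df, method = "anova",
                     control = rpart::rpart.control(minsplit = 20,
                                                    minbucket = 7, cp = 0))
  mine <- strat_tree(d$x, d$y)
  expect_equal(mine$frame$var[1],
               as.character(rp$frame$var[1]))
})

test_that("cost-complexity path is nested with non-decreasing alphas", {
  # degenerate cases
  single <- strat_tree(matrix(0L, 10, 1, dimnames = list(NULL, "v1")),
                       rep(c(0, 1), 5))
  p1 <- cost_complexity_path(single)
  expect_length(p1, 1)
  expect_equal(p1[[1]]$alpha, 0)

  x2 <- matrix(rep(0:1, each = 20), ncol = 1,
               dimnames = list(NULL, "v1"))
  y2 <- c(rbinom(20, 1, 0.1), rbinom(20, 1, 0.8))
  t2 <- strat_tree(x2, y2)
  p2 <- cost_complexity_path(t2)
  expect_length(p2, 2)
  expect_equal(nrow(p2[[2]]$tree$frame), 1L)

  set.seed(24)
  d <- random_indicator_cohort(500, 6)
  full <- strat_tree(d$x, d$y)
  path <- cost_complexity_path(full)
  alphas <- vapply(path, `[[`, 0, "alpha")
  expect_false(is.unsorted(alphas))
  sig <- function(tr) {
    fr <- tr$frame
    paste(fr$var[!is.na(fr$var)], fr$n[!is.na(fr$var)],
          fr$events[!is.na(fr$var)], sep = ":")
  }
  full_sig <- sig(full)
  for (k in seq_along(path)) {
    # every subtree's splits are a subset of the full tree's splits
    expect_true(all(sig(path[[k]]$tree) %in% full_sig))
    if (k > 1)
      expect_true(all(sig(path[[k]]$tree) %in% sig(path[[k - 1]]$tree)))
    # leaves always partition the cohort
    fr <- path[[k]]$tree$frame
    expect_equal(sum(fr$n[is.na(fr$var)]), 500)
  }
  expect_equal(nrow(path[[length(path)]]$tree$frame), 1L)
})

test_that("cv_prune keeps a dominant planted split and is reproducible", {
  set.seed(25)
  d <- random_indicator_cohort(800, 5, p_hi = 0.4, p_lo = 0.05,
                               signal_col = 1)
  tree <- cv_prune(d$x, d$y, folds = 10, seed = 99)
  expect_true("v1" %in% tree$frame$var)
  tree2 <- cv_prune(d$x, d$y, folds = 10, seed = 99)
  expect_identical(tree$frame, tree2$frame)
  expect_identical(tree$alpha, tree2$alpha)

  # leaves partition even with tiny cohorts and 2 folds
  d2 <- random_indicator_cohort(40, 3, p_hi = 0.6, p_lo = 0.4)
  t40 <- cv_prune(d2$x, d2$y, folds = 2, seed = 1)
  expect_equal(sum(t40$frame$n[is.na(t40$frame$var)]), 40)
})

test_that("cv_prune prunes hard under pure noise", {
  set.seed(26)
  leaves <- integer(20)
  full_leaves <- integer(20)
  for (s in 1:20) {
    x <- matrix(rbinom(500 * 4, 1, 0.5), 500,
                dimnames = list(NULL, paste0("v", 1:4)))
    y <- rbinom(500, 1, 0.3)
    full_leaves[s] <- sum(is.na(strat_tree(x, y)$frame$var))
    tree <- cv_prune(x, y, folds = 10, seed = s)
    leaves[s] <- sum(is.na(tree$frame$var))
  }
  # root-only in the majority of seeds, and far smaller than the full tree
  expect_gte(mean(leaves == 1), 0.5)
  expect_lte(stats::median(leaves), 2)
  expect_lt(mean(leaves), mean(full_leaves) / 3)
})

test_that("stratified folds refuse degenerate outcomes", {
  x <- matrix(rbinom(60, 1, 0.5), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- c(rep(1, 3), rep(0, 27))
  expect_error(cv_prune(x, y, folds = 10, seed = 1), "fewer folds")
})

test_that("tree AIC matches the closed form and the +2-per-leaf identity", {
  # root-only closed form
  n <- 200; e <- 30; p <- e / n
  root <- tree_from_list(list(n = n, min_split = 20, min_leaf = 7,
                              root = list(n = n, events = e)))
  expect_equal(tree_aic(root),
               -2 * (e * log(p) + (n - e) * log(1 - p)) + 2)

  # a split leaving both leaf incidences equal adds exactly 2
  split_even <- tree_from_list(list(
    n = n, min_split = 20, min_leaf = 7,
    root = list(n = n, events = e, var = "v1",
                left = list(n = 100, events = 15),
                right = list(n = 100, events = 15))))
  expect_equal(tree_aic(split_even), tree_aic(root) + 2)

  # an informative planted split lowers the AIC below root-only
  set.seed(27)
  d <- random_indicator_cohort(600, 4, p_hi = 0.35, p_lo = 0.05)
  full <- strat_tree(d$x, d$y)
  path <- cost_complexity_path(full)
  rt <- path[[length(path)]]$tree
  expect_lt(tree_aic(full), tree_aic(rt))

  # AIC agrees with stats::AIC via the logLik method
  expect_equal(tree_aic(full), AIC(full))
})

test_that("degenerate leaf incidences are clamped for the AIC likelihood", {
  t0 <- tree_from_list(list(n = 30, min_split = 20, min_leaf = 7,
                            root = list(n = 30, events = 0)))
  expect_true(is.finite(tree_aic(t0)))
})

test_that("select_model minimizes AIC with the smaller-set tie rule", {
  cand <- function(id, aic, k) structure(
    list(id = id, confounders = paste0("c", seq_len(k)), aic = aic),
    class = "candidate_model")
  picked <- select_model(list(cand("model1", 3056.8, 5),
                              cand("model2", 2943.7, 13),
                              cand("model3", 2907.4, 16)))
  expect_equal(picked$id, "model3")
  expect_equal(select_model(list(cand("only", 10, 2)))$id, "only")
  tie <- select_model(list(cand("big", 100, 9), cand("small", 100, 3)))
  expect_equal(tie$id, "small")
})

test_that("assign_strata partitions the cohort and sibling leaves are disjoint", {
  set.seed(28)
  d <- random_indicator_cohort(300, 4, p_hi = 0.4, p_lo = 0.05)
  tree <- strat_tree(d$x, d$y)
  strata <- assign_strata(tree, d$x)
  fr <- tree$frame
  leaf_ids <- fr$id[is.na(fr$var)]
  expect_setequal(unique(strata), leaf_ids)
  expect_equal(as.vector(table(factor(strata, leaf_ids))),
               fr$n[is.na(fr$var)])
  # sibling subject sets are disjoint and union to the parent
  for (i in fr$id[!is.na(fr$var)]) {
    under <- function(j) {
      ids <- j; k <- 1
      while (k <= length(ids)) {
        jj <- ids[k]
        if (!is.na(fr$var[jj])) ids <- c(ids, fr$left[jj], fr$right[jj])
        k <- k + 1
      }
      which(strata %in% intersect(ids, leaf_ids))
    }
    l <- under(fr$left[i]); r <- under(fr$right[i])
    expect_length(intersect(l, r), 0)
    expect_equal(length(l) + length(r), fr$n[i])
  }
  # root-only tree puts everyone in one stratum
  rt <- cost_complexity_path(tree)
  rt <- rt[[length(rt)]]$tree
  expect_equal(unique(assign_strata(rt, d$x)), 1L)
})

test_that("pairwise node effects divide child incidences with Katz CIs", {
  tr <- tree_from_list(list(
    n = 20, min_split = 20, min_leaf = 7,
    root = list(n = 20, events = 3, var = "v1",
                left = list(n = 10, events = 1),
                right = list(n = 10, events = 2))))
  pe <- pairwise_node_effects(tr)
  expect_equal(pe$rr, 2)
  expect_true(pe$lo < 2 && pe$hi > 2)

  # identical incidences -> ratio 1
  tr1 <- tree_from_list(list(
    n = 40, min_split = 20, min_leaf = 7,
    root = list(n = 40, events = 8, var = "v1",
                left = list(n = 20, events = 4),
                right = list(n = 20, events = 4))))
  expect_equal(pairwise_node_effects(tr1)$rr, 1)

  # zero-cell continuity affects only the interval
  tr0 <- tree_from_list(list(
    n = 30, min_split = 20, min_leaf = 7,
    root = list(n = 30, events = 5, var = "v1",
                left = list(n = 15, events = 5),
                right = list(n = 15, events = 0))))
  pe0 <- pairwise_node_effects(tr0)
  expect_equal(pe0$rr, 0)
  expect_true(is.finite(pe0$lo) && is.finite(pe0$hi))
})

test_that("serialization round-trips and renderings expose every node", {
  set.seed(29)
  d <- random_indicator_cohort(200, 4, p_hi = 0.5, p_lo = 0.1)
  tree <- strat_tree(d$x, d$y)
  back <- tree_from_list(tree_to_list(tree))
  expect_equal(back$frame$var, tree$frame$var)
  expect_equal(back$frame$n, tree$frame$n)
  expect_equal(back$frame$events, tree$frame$events)
  expect_equal(predict(back, d$x), predict(tree, d$x))

  lines <- render_tree(tree)
  expect_length(lines, nrow(tree$frame))
  expect_match(lines[1], "root")
  dot <- tree_to_dot(tree)
  expect_match(dot, "digraph")
  # yaml round-trip of the nested form
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(tree_to_list(tree), f)
  back2 <- tree_from_list(yaml::read_yaml(f))
  expect_equal(back2$frame$var, tree$frame$var)
})

test_that("candidate model sets are nested and two_stage selects by AIC", {
  gen <- generate_cohort(default_config(n = 1500, seed = 31))
  specs <- attr(gen$cohort, "specs")
  sets <- confounder_sets(specs)
  expect_true(all(sets$model1 %in% sets$model2))
  expect_true(all(sets$model2 %in% sets$model3))
  expect_length(sets$model3, 16)

  fit <- suppressWarnings(two_stage(gen$cohort, folds = 5, seed = 7,
                                    lr = FALSE))
  aics <- vapply(fit$candidates, `[[`, 0, "aic")
  expect_equal(fit$selected$aic, min(aics))
  expect_s3_class(fit, "two_stage")
})
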