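# independent oracles and fixture builders used across the suite

# exhaustive single-split search: best between-group sum of squares computed
# from first principles (explicit residual sums), independent of best_split()
oracle_best_split <- function(x, y, min_leaf = 1) {
  sse <- function(v) sum((v - mean(v))^2)
  best <- list(j = NA_integer_, gain = -Inf)
  for (j in seq_len(ncol(x))) {
    g1 <- y[x[, j] == 1]
    g0 <- y[x[, j] == 0]
    if (length(g1) < min_leaf || length(g0) < min_leaf) next
    gain <- sse(y) - sse(g1) - sse(g0)
    if (gain > best$gain + 1e-12) best <- list(j = j, gain = gain)
  }
  best
}

# direct-summation Pearson statistic, no correction
oracle_chi2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# brute-force MH odds ratio over a list of (a,b,c,d) tables
oracle_mh_or <- function(tabs) {
  num <- 0; den <- 0
  for (t in tabs) {
    n <- t$a + t$b + t$c + t$d
    num <- num + t$a * t$d / n
    den <- den + t$b * t$c / n
  }
  num / den
}

oracle_mh_rr <- function(tabs) {
  num <- 0; den <- 0
  for (t in tabs) {
    n <- t$a + t$b + t$c + t$d
    num <- num + t$a * (t$c + t$d) / n
    den <- den + t$c * (t$a + t$b) / n
  }
  num / den
}

# build a categorical cohort from a data.frame (character columns + 0/1 y),
# inferring levels from the data; roles: every non-outcome column defaults
# to putative_risk unless listed in `confounders`
make_cohort <- function(df, outcome = "y", confounders = character(0),
                        references = list()) {
  specs <- list()
  specs[[outcome]] <- variable_spec(outcome, "outcome", "categorical",
                                    c("0", "1"), reference = "0")
  for (nm in setdiff(names(df), outcome)) {
    lv <- sort(unique(as.character(df[[nm]])))
    ref <- if (!is.null(references[[nm]])) references[[nm]] else lv[1]
    specs[[nm]] <- variable_spec(
      nm, if (nm %in% confounders) "confounder" else "putative_risk",
      "categorical", lv, reference = ref)
  }
  raw <- df
  raw[[outcome]] <- as.numeric(df[[outcome]])
  for (nm in setdiff(names(df), outcome))
    raw[[nm]] <- as.character(df[[nm]])
  discretize(raw, specs)
}

# random planted-split indicator cohort for tree tests
random_indicator_cohort <- function(n, p, p_hi = 0.3, p_lo = 0.05,
                                    signal_col = 1) {
  x <- matrix(rbinom(n * p, 1, 0.4), n, p)
  colnames(x) <- paste0("v", seq_len(p))
  pr <- ifelse(x[, signal_col] == 1, p_hi, p_lo)
  list(x = x, y = rbinom(n, 1, pr))
}

# spec'd variables file and published counts, loaded once per test run
t1_counts <- table1_counts()

t1_table <- function(variable, level, reference) {
  d <- t1_counts[t1_counts$variable == variable, ]
  e <- d[d$level == level, ]
  r <- d[d$level == reference, ]
  two_by_two(a = e$sepsis, b = e$nonsepsis, c = r$sepsis, d = r$nonsepsis)
}
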