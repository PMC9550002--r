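Z95 <- 1.959964

#' 2 x 2 outcome-by-exposure table
#'
#' @param a exposed subjects with the outcome.
#' @param b exposed subjects without the outcome.
#' @param c unexposed subjects with the outcome.
#' @param d unexposed subjects without the outcome.
#' @return an object of class `"two_by_two"`.
#' @export
two_by_two <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b + c + d > 0)
  structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("exposed", "unexposed"),
                              c("outcome", "no outcome")))
  print(m)
  invisible(x)
}

effect_estimate <- function(exposure, level, reference, estimate, lo, hi,
                            measure, method, model = NA_character_,
                            continuity = FALSE) {
  stopifnot(estimate > 0 || continuity, lo <= estimate + 1e-12,
            estimate <= hi + 1e-12)
  structure(data.frame(exposure = exposure, level = level,
                       reference = reference, measure = measure,
                       method = method, model = model,
                       estimate = estimate, lo = lo, hi = hi,
                       continuity = continuity, stringsAsFactors = FALSE),
            class = c("effect_estimate", "data.frame"))
}

#' Marginal 2 x 2 table for one exposure contrast
#'
#' Builds the exposed-versus-reference outcome table for one level of a
#' discretized exposure; subjects at other levels of a multi-level exposure
#' are excluded (pairwise contrasts against the reference level).
#'
#' @param cohort a `"cohort"` data.frame.
#' @param exposure exposure variable name.
#' @param level exposed level; default the first non-reference level.
#' @param reference reference level; default the spec's reference.
#' @return a [two_by_two()] table.
#' @export
marginal_table <- function(cohort, exposure, level = NULL, reference = NULL) {
  specs <- attr(cohort, "specs")
  s <- specs[[exposure]]
  if (is.null(s)) stop("unknown exposure '", exposure, "'")
  if (is.null(reference)) reference <- s$reference
  if (is.null(level)) level <- setdiff(s$levels, reference)[1]
  if (identical(level, reference))
    stop("exposed level equals the reference level")
  v <- cohort[[exposure]]
  y <- cohort[[outcome_name(specs)]]
  ex <- v == level
  rf <- v == reference
  if (!any(ex)) stop("empty exposed level '", level, "'")
  if (!any(rf)) stop("empty reference level '", reference, "'")
  two_by_two(a = sum(y[ex]), b = sum(ex) - sum(y[ex]),
             c = sum(y[rf]), d = sum(rf) - sum(y[rf]))
}

#' Crude odds ratio (cross-product ratio)
#'
#' \eqn{(a d)/(b c)} with the Woolf log-scale confidence interval
#' \eqn{\exp(\ln OR \pm z \sqrt{1/a + 1/b + 1/c + 1/d})}. Any zero cell
#' triggers the Haldane-Anscombe continuity correction (0.5 added to all
#' four cells), flagged in the output.
#'
#' @param t a [two_by_two()] table.
#' @param exposure,level,reference labels carried into the output.
#' @return an `"effect_estimate"` row with `measure = "odds-ratio"`,
#'   `method = "crude"`.
#' @export
crude_or <- function(t, exposure = "exposure", level = "exposed",
                     reference = "reference") {
  cc <- if (t$a == 0 || t$b == 0 || t$c == 0 || t$d == 0) 0.5 else 0
  a <- t$a + cc; b <- t$b + cc; c <- t$c + cc; d <- t$d + cc
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  effect_estimate(exposure, level, reference, or,
                  exp(log(or) - Z95 * se), exp(log(or) + Z95 * se),
                  "odds-ratio", "crude", continuity = cc > 0)
}

#' Crude risk ratio
#'
#' \eqn{[a/(a+b)] / [c/(c+d)]} with the Katz log-scale confidence interval.
#' A zero cell adds 0.5 to all four counts for the interval (and for the
#' point estimate when the numerator incidence is zero is left at zero).
#'
#' @inheritParams crude_or
#' @return an `"effect_estimate"` row with `measure = "risk-ratio"`.
#' @export
crude_rr <- function(t, exposure = "exposure", level = "exposed",
                     reference = "reference") {
  if (t$c + t$d == 0 || t$a + t$b == 0) stop("empty exposure group")
  if (t$c == 0) stop("zero incidence in the reference group")
  cc <- if (t$a == 0 || t$b == 0 || t$d == 0) 0.5 else 0
  a <- t$a + cc; c <- t$c + cc
  n1 <- t$a + t$b + 2 * cc; n0 <- t$c + t$d + 2 * cc
  se <- sqrt(1 / a - 1 / n1 + 1 / c - 1 / n0)
  lrr <- log((a / n1) / (c / n0))
  effect_estimate(exposure, level, reference, exp(lrr),
                  exp(lrr - Z95 * se), exp(lrr + Z95 * se),
                  "risk-ratio", "crude", continuity = cc > 0)
}

#' Per-stratum 2 x 2 series for one exposure
#'
#' @param cohort a `"cohort"` data.frame.
#' @param exposure exposure name.
#' @param strata stratum label per subject (e.g. from [assign_strata()]).
#' @param level,reference exposed and reference levels (defaults as in
#'   [marginal_table()]).
#' @return list of [two_by_two()] tables, named by stratum, whose cells sum
#'   to the marginal table.
#' @export
stratum_series <- function(cohort, exposure, strata, level = NULL,
                           reference = NULL) {
  specs <- attr(cohort, "specs")
  s <- specs[[exposure]]
  if (is.null(reference)) reference <- s$reference
  if (is.null(level)) level <- setdiff(s$levels, reference)[1]
  stopifnot(length(strata) == nrow(cohort))
  v <- cohort[[exposure]]
  y <- cohort[[outcome_name(specs)]]
  out <- lapply(split(seq_len(nrow(cohort)), strata), function(idx) {
    ex <- v[idx] == level
    rf <- v[idx] == reference
    if (!any(ex) && !any(rf)) return(NULL)  # stratum empty at both levels
    two_by_two(a = sum(y[idx][ex]), b = sum(ex) - sum(y[idx][ex]),
               c = sum(y[idx][rf]), d = sum(rf) - sum(y[idx][rf]))
  })
  Filter(Negate(is.null), out)
}

#' Mantel-Haenszel common odds ratio
#'
#' \eqn{\hat{OR}_{MH} = \sum_i a_i d_i / n_i \; / \; \sum_i b_i c_i / n_i}
#' across the strata, with the Robins-Breslow-Greenland variance for the
#' log-scale confidence interval. Strata with \eqn{a_i d_i = b_i c_i = 0}
#' contribute nothing; if every stratum is uninformative an error is raised.
#'
#' @param series list of [two_by_two()] tables (one per stratum).
#' @param exposure,level,reference labels carried into the output.
#' @param model stratification model id recorded in the output.
#' @return an `"effect_estimate"` row with `method = "MH"`.
#' @export
mh_common_or <- function(series, exposure = "exposure", level = "exposed",
                         reference = "reference", model = NA_character_) {
  series <- Filter(function(t) t$n > 0, series)
  a <- vapply(series, `[[`, 0, "a"); b <- vapply(series, `[[`, 0, "b")
  c <- vapply(series, `[[`, 0, "c"); d <- vapply(series, `[[`, 0, "d")
  n <- a + b + c + d
  R <- a * d / n
  S <- b * c / n
  if (sum(R) == 0 && sum(S) == 0)
    stop("all strata uninformative for the MH odds ratio")
  cc <- FALSE
  if (sum(R) == 0 || sum(S) == 0) {
    # a one-sided zero margin leaves the estimator at 0 or infinity;
    # fall back to continuity-corrected cells and flag the row
    cc <- TRUE
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    n <- a + b + c + d
    R <- a * d / n
    S <- b * c / n
  }
  or <- sum(R) / sum(S)
  P <- (a + d) / n
  Q <- (b + c) / n
  v <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)
  se <- sqrt(v)
  effect_estimate(exposure, level, reference, or,
                  exp(log(or) - Z95 * se), exp(log(or) + Z95 * se),
                  "odds-ratio", "MH", model, continuity = cc)
}

#' Mantel-Haenszel common risk ratio
#'
#' \eqn{\hat{RR}_{MH} = \sum_i a_i (c_i + d_i)/n_i \; / \;
#' \sum_i c_i (a_i + b_i)/n_i}, with the Greenland-Robins variance for the
#' log-scale confidence interval.
#'
#' @inheritParams mh_common_or
#' @return an `"effect_estimate"` row with `measure = "risk-ratio"`,
#'   `method = "MH"`.
#' @export
mh_common_rr <- function(series, exposure = "exposure", level = "exposed",
                         reference = "reference", model = NA_character_) {
  series <- Filter(function(t) t$n > 0, series)
  a <- vapply(series, `[[`, 0, "a"); b <- vapply(series, `[[`, 0, "b")
  c <- vapply(series, `[[`, 0, "c"); d <- vapply(series, `[[`, 0, "d")
  n <- a + b + c + d
  R <- a * (c + d) / n
  S <- c * (a + b) / n
  if (sum(R) == 0 && sum(S) == 0)
    stop("all strata uninformative for the MH risk ratio")
  cc <- FALSE
  if (sum(R) == 0 || sum(S) == 0) {
    cc <- TRUE
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    n <- a + b + c + d
    R <- a * (c + d) / n
    S <- c * (a + b) / n
  }
  rr <- sum(R) / sum(S)
  num <- sum(((a + c) * (a + b) * (c + d) / n - a * c) / n)
  se <- sqrt(num / (sum(R) * sum(S)))
  effect_estimate(exposure, level, reference, rr,
                  exp(log(rr) - Z95 * se), exp(log(rr) + Z95 * se),
                  "risk-ratio", "MH", model, continuity = cc)
}

#' Crude and stratum-adjusted effects for every putative risk factor
#'
#' For every putative risk factor (and every non-reference level of a
#' multi-level factor) computes the crude estimate from the marginal 2 x 2
#' table plus one Mantel-Haenszel estimate per supplied stratification, in
#' spec order. The default measure is the odds ratio (the cross-product
#' ratio reproduces the published crude column); risk ratios are available
#' via `measure = "rr"`.
#'
#' A warning is raised when the reference level of an exposure shows a
#' higher outcome incidence than an exposed level while the estimate is
#' below 1 — the situation produced by inverted level labels.
#'
#' @param cohort a `"cohort"` data.frame.
#' @param strata named list of stratum-assignment vectors, one per
#'   stratification model (may be empty for crude-only output).
#' @param exposures exposure names; default all `putative_risk` variables.
#' @param measure `"or"` (default) or `"rr"`.
#' @param warn_inverted warn on reference-incidence inversions (default
#'   TRUE).
#' @return data.frame of `"effect_estimate"` rows.
#' @export
effect_table <- function(cohort, strata = list(), exposures = NULL,
                         measure = c("or", "rr"), warn_inverted = TRUE) {
  measure <- match.arg(measure)
  specs <- attr(cohort, "specs")
  if (is.null(exposures)) exposures <- vars_by_role(specs, "putative_risk")
  crude_fun <- if (measure == "or") crude_or else crude_rr
  mh_fun <- if (measure == "or") mh_common_or else mh_common_rr
  rows <- list()
  for (ex in exposures) {
    s <- specs[[ex]]
    for (lv in setdiff(s$levels, s$reference)) {
      t <- marginal_table(cohort, ex, lv, s$reference)
      cr <- crude_fun(t, ex, lv, s$reference)
      if (warn_inverted &&
          t$c / (t$c + t$d) > t$a / (t$a + t$b) && cr$estimate < 1)
        warning("exposure '", ex, "': reference level '", s$reference,
                "' has higher outcome incidence than level '", lv,
                "'; check level labels", call. = FALSE)
      rows[[length(rows) + 1L]] <- cr
      for (mid in names(strata)) {
        ser <- stratum_series(cohort, ex, strata[[mid]], lv, s$reference)
        rows[[length(rows) + 1L]] <- mh_fun(ser, ex, lv, s$reference, mid)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an effect table to delimited text
#'
#' One row per exposure contrast; crude, per-model MH and (if present) LR
#' columns rendered as \dQuote{estimate (lo, hi)} with two decimals.
#'
#' @param tab data.frame of `"effect_estimate"` rows.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_effects <- function(tab, path) {
  fmt <- sprintf("%.2f (%.2f, %.2f)", tab$estimate, tab$lo, tab$hi)
  key <- paste(tab$exposure, tab$level, sep = ":")
  cols <- ifelse(tab$method == "crude", "crude",
                 ifelse(tab$method == "MH", paste0("MH_", tab$model), "LR"))
  wide <- stats::reshape(
    data.frame(key = key, col = cols, val = fmt, stringsAsFactors = FALSE),
    idvar = "key", timevar = "col", direction = "wide")
  names(wide) <- sub("^val\\.", "", names(wide))
  wide <- wide[match(unique(key), wide$key), , drop = FALSE]
  parts <- strsplit(wide$key, ":", fixed = TRUE)
  out <- cbind(data.frame(exposure = vapply(parts, `[`, "", 1),
                          level = vapply(parts, `[`, "", 2),
                          measure = tab$measure[match(wide$key, key)],
                          stringsAsFactors = FALSE),
               wide[, -1, drop = FALSE])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
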