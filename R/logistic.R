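#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit of a 0/1 outcome on a design matrix.
#' Iteration stops when the largest absolute coefficient change falls below
#' `tol` or after `maxit` iterations; the log-likelihood at every iteration
#' is recorded so monotone convergence can be verified. Apparent separation
#' (non-convergence or runaway coefficients) is flagged rather than raised.
#'
#' @param x numeric design matrix (should include an intercept column, see
#'   [build_design()]); must have full column rank.
#' @param y 0/1 outcome vector.
#' @param tol convergence tolerance on coefficient changes (default 1e-8).
#' @param maxit maximum iterations (default 100).
#' @return an object of class `"logit_fit"`: `coefficients`, `se`, `vcov`,
#'   `loglik`, `loglik_trace`, `iterations`, `converged`, `diagnostic`.
#' @export
fit_logistic <- function(x, y, tol = 1e-8, maxit = 100) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(x), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) stop("outcome has a single class")
  if (qr(x)$rank < ncol(x))
    stop("design matrix is rank deficient; drop aliased terms")
  beta <- numeric(ncol(x))
  trace <- numeric(0)
  converged <- FALSE
  xtwx <- NULL
  for (it in seq_len(maxit)) {
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    trace[it] <- sum(y * log(pmax(mu, 1e-300)) +
                     (1 - y) * log(pmax(1 - mu, 1e-300)))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    xtwx <- crossprod(x, x * w)
    delta <- solve(xtwx, crossprod(x, w * z)) - beta
    beta <- beta + drop(delta)
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  diagnostic <- NULL
  if (!converged || max(abs(beta)) > 15) {
    converged <- FALSE
    diagnostic <- "possible separation: coefficients diverging or IRLS not converged"
  }
  vc <- solve(xtwx)
  structure(list(coefficients = stats::setNames(beta, colnames(x)),
                 se = stats::setNames(sqrt(diag(vc)), colnames(x)),
                 vcov = vc, loglik = trace[length(trace)],
                 loglik_trace = trace, iterations = length(trace),
                 converged = converged, diagnostic = diagnostic,
                 n = length(y), rank = ncol(x)),
            class = "logit_fit")
}

#' @export
coef.logit_fit <- function(object, ...) object$coefficients

#' @export
vcov.logit_fit <- function(object, ...) object$vcov

#' @export
logLik.logit_fit <- function(object, ...) {
  structure(object$loglik, df = object$rank, nobs = object$n,
            class = "logLik")
}

#' @export
print.logit_fit <- function(x, ...) {
  cat(sprintf("<logit_fit> %d obs, %d terms, logLik %.3f (%s, %d iterations)\n",
              x$n, x$rank, x$loglik,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  est <- cbind(coef = x$coefficients, se = x$se,
               OR = exp(x$coefficients))
  print(round(est, 4))
  if (!is.null(x$diagnostic)) cat("  !", x$diagnostic, "\n")
  invisible(x)
}

#' Build a treatment-coded design matrix from a cohort
#'
#' Releveled so that each variable's spec'd reference level is the baseline,
#' with optional pairwise interaction terms.
#'
#' @param cohort a `"cohort"` data.frame.
#' @param terms main-effect variable names.
#' @param interactions list of character pairs to interact.
#' @return numeric design matrix with an `(Intercept)` column.
#' @export
build_design <- function(cohort, terms, interactions = NULL) {
  specs <- attr(cohort, "specs")
  df <- as.data.frame(cohort)[, terms, drop = FALSE]
  for (nm in terms)
    df[[nm]] <- stats::relevel(droplevels(df[[nm]]),
                               ref = specs[[nm]]$reference)
  rhs <- c(terms, vapply(interactions, paste, "", collapse = ":"))
  f <- stats::as.formula(paste("~", paste(rhs, collapse = " + ")))
  stats::model.matrix(f, df)
}

#' Screen first-order confounder interactions
#'
#' For every unordered pair of confounders, a likelihood-ratio test of the
#' all-main-effects model against the model with that pairwise interaction
#' added. Pairs whose interaction is inestimable (empty level combinations
#' making the design rank deficient) are reported as untestable.
#'
#' @param cohort a `"cohort"` data.frame.
#' @param confounders confounder names (typically the tree-selected set).
#' @param alpha flagging threshold on the LRT p-value (default 0.05).
#' @return data.frame with columns `var1`, `var2`, `statistic`, `df`,
#'   `p.value`, `flagged`, `testable`.
#' @export
screen_interactions <- function(cohort, confounders, alpha = 0.05) {
  specs <- attr(cohort, "specs")
  y <- cohort[[outcome_name(specs)]]
  if (length(confounders) < 2)
    return(data.frame(var1 = character(0), var2 = character(0),
                      statistic = numeric(0), df = numeric(0),
                      p.value = numeric(0), flagged = logical(0),
                      testable = logical(0)))
  base <- fit_logistic(build_design(cohort, confounders), y)
  pairs <- utils::combn(confounders, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    pr <- pairs[, k]
    res <- tryCatch({
      xi <- build_design(cohort, confounders, interactions = list(pr))
      fit <- fit_logistic(xi, y)
      stat <- 2 * (fit$loglik - base$loglik)
      df <- fit$rank - base$rank
      p <- stats::pchisq(stat, df, lower.tail = FALSE)
      data.frame(var1 = pr[1], var2 = pr[2], statistic = stat, df = df,
                 p.value = p, flagged = p < alpha, testable = TRUE,
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(var1 = pr[1], var2 = pr[2], statistic = NA_real_,
                 df = NA_real_, p.value = NA_real_, flagged = FALSE,
                 testable = FALSE, stringsAsFactors = FALSE))
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Confounder-adjusted odds ratio by logistic regression
#'
#' Fits outcome ~ exposure + confounder main effects + any flagged
#' confounder interactions, and returns the exponentiated exposure
#' coefficient(s) with Wald confidence intervals — one estimate per
#' non-reference exposure level.
#'
#' @param cohort a `"cohort"` data.frame.
#' @param exposure exposure name (must not be among the confounders).
#' @param confounders confounder names (may be empty: crude logistic fit).
#' @param interactions list of flagged confounder pairs (default none).
#' @return data.frame of `"effect_estimate"` rows with `method = "LR"`.
#' @export
adjusted_or_lr <- function(cohort, exposure, confounders = character(0),
                           interactions = NULL) {
  specs <- attr(cohort, "specs")
  if (exposure %in% confounders)
    stop("exposure '", exposure, "' is in the confounder set")
  y <- cohort[[outcome_name(specs)]]
  x <- build_design(cohort, c(exposure, confounders), interactions)
  fit <- fit_logistic(x, y)
  s <- specs[[exposure]]
  lvs <- setdiff(levels(droplevels(cohort[[exposure]])), s$reference)
  rows <- lapply(lvs, function(lv) {
    term <- paste0(exposure, lv)
    b <- fit$coefficients[term]
    se <- fit$se[term]
    effect_estimate(exposure, lv, s$reference, exp(b),
                    exp(b - Z95 * se), exp(b + Z95 * se),
                    "odds-ratio", "LR", "LR")
  })
  out <- do.call(rbind, rows)
  attr(out, "fit") <- fit
  out
}

#' Forward-stepwise exposure selection by AIC
#'
#' Starting from the confounder-only logistic model, repeatedly adds the
#' candidate exposure giving the largest AIC decrease, stopping when no
#' addition lowers the AIC. The trace records every step's added term and
#' AIC.
#'
#' @param cohort a `"cohort"` data.frame.
#' @param candidates candidate exposure names.
#' @param confounders confounder main effects always kept in the model.
#' @param interactions optional confounder interaction pairs kept in the
#'   model.
#' @return list with `selected` (ordered character vector) and `trace`
#'   (data.frame of step, term, AIC).
#' @export
forward_stepwise <- function(cohort, candidates, confounders = character(0),
                             interactions = NULL) {
  specs <- attr(cohort, "specs")
  y <- cohort[[outcome_name(specs)]]
  fit_aic <- function(terms) {
    x <- if (length(terms)) build_design(cohort, terms, interactions)
         else matrix(1, nrow(cohort), 1, dimnames = list(NULL, "(Intercept)"))
    fit <- fit_logistic(x, y)
    -2 * fit$loglik + 2 * fit$rank
  }
  current <- confounders
  cur_aic <- fit_aic(current)
  selected <- character(0)
  trace <- data.frame(step = 0L, term = "<confounders only>",
                      aic = cur_aic, stringsAsFactors = FALSE)
  pool <- candidates
  step <- 0L
  while (length(pool)) {
    aics <- vapply(pool, function(tm)
      tryCatch(fit_aic(c(current, tm)), error = function(e) Inf), 0)
    best <- which.min(aics)
    if (aics[best] >= cur_aic) break
    step <- step + 1L
    current <- c(current, pool[best])
    selected <- c(selected, pool[best])
    cur_aic <- aics[best]
    trace <- rbind(trace, data.frame(step = step, term = pool[best],
                                     aic = cur_aic))
    pool <- pool[-best]
  }
  list(selected = selected, trace = trace)
}
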