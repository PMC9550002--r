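risk_leaf <- function(p) list(p = p)
risk_node <- function(var, level, yes, no) list(var = var, level = level,
                                                yes = yes, no = no)

#' Default synthetic-cohort configuration
#'
#' Emulates the statistical structure of the 7,302-subject elderly surgical
#' cohort: confounder and exposure level prevalences set to the published
#' marginals, a tree-structured baseline risk whose first splitter is
#' cerebrovascular disease (30.3% incidence when present versus 5.0%
#' overall when absent), further splits on red-blood-cell infusion,
#' pneumonia, age >= 75, malignant tumor and diabetes giving seven risk
#' strata and an implied overall incidence near 5.4%, and exposure effects
#' defaulting to the published crude log odds ratios. Exposure draws are
#' tilted towards high-risk strata (`weight`), which plants genuine
#' confounding of crude estimates.
#'
#' Only the cerebrovascular leaf risk (0.303) and the relative risk of the
#' age split (1.92) are pinned by published stratum incidences; the
#' remaining leaf risks are free parameters chosen to respect those two
#' anchors and the 5.4% overall incidence.
#'
#' @param n cohort size (default 7302).
#' @param seed generator seed (default 20150901).
#' @param weight exposure-confounding tilt on the baseline log-odds scale
#'   (default 0.6; 0 removes exposure-confounder dependence).
#' @param null_effects if TRUE, all exposure effects are set to zero
#'   (log-odds scale) while prevalences are kept.
#' @return a `"generator_config"` list: `n`, `seed`, `confounders`,
#'   `risk_tree`, `exposures`, `weight`.
#' @export
default_config <- function(n = 7302, seed = 20150901, weight = 0.6,
                           null_effects = FALSE) {
  counts <- table1_counts()
  specs <- default_variable_specs()
  marg <- function(nm) {
    d <- counts[counts$variable == nm, ]
    stats::setNames(d$total / sum(d$total), d$level)
  }
  confounders <- lapply(vars_by_role(specs, "confounder"), function(nm)
    list(levels = specs[[nm]]$levels, probs = unname(marg(nm)[specs[[nm]]$levels]),
         reference = specs[[nm]]$reference))
  names(confounders) <- vars_by_role(specs, "confounder")
  # crude cross-product ratios from the published counts, as planted effects
  exposures <- lapply(vars_by_role(specs, "putative_risk"), function(nm) {
    s <- specs[[nm]]
    d <- counts[counts$variable == nm, ]
    ref <- d[d$level == s$reference, ]
    lor <- vapply(setdiff(s$levels, s$reference), function(lv) {
      e <- d[d$level == lv, ]
      log((e$sepsis * ref$nonsepsis) / (e$nonsepsis * ref$sepsis))
    }, 0)
    if (null_effects) lor[] <- 0
    list(levels = s$levels, probs = unname(marg(nm)[s$levels]),
         reference = s$reference, log_or = lor)
  })
  names(exposures) <- vars_by_role(specs, "putative_risk")
  # seven-leaf baseline risk tree; leaf risks give ~5.44% overall incidence
  tree <- risk_node("cerebrovascular_disease", "Yes",
    yes = risk_leaf(0.303),
    no = risk_node("rbc_infusion", "Yes",
      yes = risk_leaf(0.16),
      no = risk_node("pneumonia", "Yes",
        yes = risk_leaf(0.13),
        no = risk_node("age", ">=75",
          yes = risk_leaf(0.0652),
          no = risk_node("malignant_tumor", "Yes",
            yes = risk_node("diabetes", "Yes",
              yes = risk_leaf(0.07),
              no = risk_leaf(0.042)),
            no = risk_leaf(0.0237))))))
  validate_config(structure(list(n = n, seed = seed,
                                 confounders = confounders,
                                 risk_tree = tree, exposures = exposures,
                                 weight = weight),
                            class = "generator_config"))
}

validate_config <- function(config) {
  stopifnot(config$n >= 1)
  for (nm in names(config$confounders)) {
    cf <- config$confounders[[nm]]
    stopifnot(length(cf$levels) == length(cf$probs),
              all(cf$probs >= 0), abs(sum(cf$probs) - 1) < 1e-8)
  }
  for (nm in names(config$exposures)) {
    ex <- config$exposures[[nm]]
    stopifnot(length(ex$levels) == length(ex$probs),
              all(ex$probs >= 0), abs(sum(ex$probs) - 1) < 1e-8,
              all(names(ex$log_or) %in% ex$levels) ||
                length(ex$log_or) == length(ex$levels) - 1)
  }
  walk <- function(node) {
    if (!is.null(node$p)) stopifnot(node$p > 0, node$p < 1)
    else { walk(node$yes); walk(node$no) }
  }
  walk(config$risk_tree)
  config
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> n=%d, seed=%d, %d confounders, %d exposures, %d risk strata\n",
              x$n, x$seed, length(x$confounders), length(x$exposures),
              length(leaf_probs(x)$p)))
  cat(sprintf("  implied overall incidence: %.4f; confounding weight %.2f\n",
              implied_incidence(x), x$weight))
  invisible(x)
}

# leaf reach probabilities and risks under independent confounder draws
leaf_probs <- function(config) {
  marg <- function(var, level) {
    cf <- config$confounders[[var]]
    cf$probs[match(level, cf$levels)]
  }
  reach <- numeric(0)
  p <- numeric(0)
  walk <- function(node, pr) {
    if (!is.null(node$p)) {
      reach <<- c(reach, pr)
      p <<- c(p, node$p)
    } else {
      q <- marg(node$var, node$level)
      walk(node$yes, pr * q)
      walk(node$no, pr * (1 - q))
    }
  }
  walk(config$risk_tree, 1)
  list(reach = reach, p = p)
}

#' Implied overall outcome incidence of a configuration
#'
#' The mixture of leaf risks weighted by leaf reach probabilities under
#' independent confounder draws.
#'
#' @param config a `"generator_config"`.
#' @return scalar incidence.
#' @export
implied_incidence <- function(config) {
  lp <- leaf_probs(config)
  sum(lp$reach * lp$p)
}

#' Ground truth planted by a configuration
#'
#' @param config a `"generator_config"`.
#' @return list with `effects` (per exposure, the exponentiated conditional
#'   log odds ratio per non-reference level), `n_strata` (risk-tree leaf
#'   count), `leaf_risks` and `leaf_reach`.
#' @export
planted_truth <- function(config) {
  lp <- leaf_probs(config)
  effects <- lapply(config$exposures, function(ex) {
    lv <- setdiff(ex$levels, ex$reference)
    lor <- ex$log_or
    if (is.null(names(lor))) names(lor) <- lv
    exp(lor[lv])
  })
  list(effects = effects, n_strata = length(lp$p),
       leaf_risks = lp$p, leaf_reach = lp$reach)
}

route_risk_tree <- function(config, data) {
  n <- nrow(data)
  leaf <- integer(n)
  prob <- numeric(n)
  counter <- 0L
  walk <- function(node, idx) {
    if (!is.null(node$p)) {
      counter <<- counter + 1L
      leaf[idx] <<- counter
      prob[idx] <<- node$p
    } else {
      go <- data[[node$var]][idx] == node$level
      walk(node$yes, idx[go])
      walk(node$no, idx[!go])
    }
  }
  walk(config$risk_tree, seq_len(n))
  list(leaf = leaf, p = prob)
}

#' Generate a synthetic cohort
#'
#' Confounders are drawn independently from their configured level
#' probabilities; each subject is routed down the risk tree to a baseline
#' risk; exposure levels are drawn with their probabilities tilted on the
#' log scale by `weight` times the subject's centred baseline log-odds
#' (planting exposure-confounder dependence); and the outcome is Bernoulli
#' with log-odds equal to a per-stratum intercept plus the subject's summed
#' exposure effects. The per-stratum intercept is calibrated so that the
#' expected incidence in each risk stratum equals its configured leaf risk,
#' which keeps the planted log odds ratios exactly conditional effects
#' while preserving the stratum incidences the tree declares.
#'
#' The same `config` and `seed` always reproduce the identical cohort.
#'
#' @param config a `"generator_config"` (see [default_config()]).
#' @param seed optional override of `config$seed`.
#' @return list with `cohort` (a `"cohort"` data.frame whose specs mirror
#'   the configuration) and `truth` (stratum id, baseline risk and linear
#'   predictor per subject, per-stratum intercepts, and the
#'   [planted_truth()] record).
#' @export
generate_cohort <- function(config, seed = NULL) {
  config <- validate_config(config)
  if (is.null(seed)) seed <- config$seed
  with_seed(seed, {
    n <- config$n
    data <- data.frame(row.names = seq_len(n))
    for (nm in names(config$confounders)) {
      cf <- config$confounders[[nm]]
      data[[nm]] <- sample(cf$levels, n, replace = TRUE, prob = cf$probs)
    }
    rt <- route_risk_tree(config, data)
    b <- stats::qlogis(rt$p)
    lp <- leaf_probs(config)
    b_centered <- b - sum(lp$reach * stats::qlogis(lp$p))
    eta <- numeric(n)
    for (nm in names(config$exposures)) {
      ex <- config$exposures[[nm]]
      lor <- ex$log_or
      if (is.null(names(lor))) names(lor) <- setdiff(ex$levels, ex$reference)
      logp <- matrix(log(ex$probs), n, length(ex$levels), byrow = TRUE)
      tilt <- config$weight * b_centered
      nonref <- ex$levels != ex$reference
      logp[, nonref] <- logp[, nonref] + tilt
      pr <- exp(logp - apply(logp, 1, max))
      pr <- pr / rowSums(pr)
      u <- stats::runif(n)
      cum <- t(apply(pr, 1, cumsum))
      lev_idx <- rowSums(u > cum) + 1L
      data[[nm]] <- ex$levels[lev_idx]
      eff <- stats::setNames(numeric(length(ex$levels)), ex$levels)
      eff[names(lor)] <- lor
      eta <- eta + eff[data[[nm]]]
    }
    # per-stratum intercept so that mean expected incidence matches the leaf
    intercepts <- numeric(max(rt$leaf))
    pout <- numeric(n)
    for (lf in sort(unique(rt$leaf))) {
      idx <- which(rt$leaf == lf)
      target <- rt$p[idx[1]]
      e <- eta[idx]
      if (all(e == 0)) cl <- stats::qlogis(target)
      else {
        f <- function(cc) mean(stats::plogis(cc + e)) - target
        span <- max(abs(e)) + 10
        cl <- stats::uniroot(f, stats::qlogis(target) + c(-span, span),
                             tol = 1e-10)$root
      }
      intercepts[lf] <- cl
      pout[idx] <- stats::plogis(cl + e)
    }
    y <- stats::rbinom(n, 1, pout)
    specs <- config_specs(config)
    data[[outcome_name(specs)]] <- y
    cohort <- discretize(data, specs)
    list(cohort = cohort,
         truth = list(stratum = rt$leaf, baseline_risk = rt$p,
                      eta = unname(eta), intercepts = intercepts,
                      expected_p = pout, seed = seed,
                      planted = planted_truth(config)))
  })
}

# variable specs mirroring a generator configuration (all categorical:
# generation happens at the grouped level, not on raw laboratory values)
config_specs <- function(config) {
  specs <- list(sepsis = variable_spec("sepsis", "outcome", "categorical",
                                       c("0", "1"), reference = "0"))
  for (nm in names(config$confounders)) {
    cf <- config$confounders[[nm]]
    specs[[nm]] <- variable_spec(nm, "confounder", "categorical",
                                 cf$levels, reference = cf$reference)
  }
  for (nm in names(config$exposures)) {
    ex <- config$exposures[[nm]]
    specs[[nm]] <- variable_spec(nm, "putative_risk", "categorical",
                                 ex$levels, reference = ex$reference)
  }
  validate_specs(specs)
}

#' Minimal configuration with one planted confounded exposure
#'
#' A compact generator for parameter-recovery studies: one binary
#' confounder driving a two-leaf baseline risk (5% versus 25%), and one
#' binary exposure with a planted conditional odds ratio whose draws are
#' strongly tilted towards the high-risk stratum, so the crude odds ratio
#' is biased upwards by well over 30%.
#'
#' @param n cohort size (default 3000).
#' @param seed generator seed.
#' @param log_or planted conditional log odds ratio (default `log(2)`).
#' @param weight confounding tilt (default 1.5).
#' @return a `"generator_config"`.
#' @export
confounding_demo_config <- function(n = 3000, seed = 20150901,
                                    log_or = log(2), weight = 1.5) {
  validate_config(structure(list(
    n = n, seed = seed,
    confounders = list(
      z = list(levels = c("No", "Yes"), probs = c(0.6, 0.4),
               reference = "No")),
    risk_tree = risk_node("z", "Yes",
                          yes = risk_leaf(0.25), no = risk_leaf(0.05)),
    exposures = list(
      x = list(levels = c("No", "Yes"), probs = c(0.7, 0.3),
               reference = "No",
               log_or = stats::setNames(log_or, "Yes"))),
    weight = weight), class = "generator_config"))
}
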