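#' Confounders used by a fitted tree
#'
#' Maps the indicator names at the tree's splits (`var=level`) back to
#' variable names.
#'
#' @param tree a `"strat_tree"`.
#' @return character vector of confounder names (empty for a root-only
#'   tree).
#' @export
selected_confounders <- function(tree) {
  v <- stats::na.omit(unique(tree$frame$var))
  unique(sub("=.*$", "", v))
}

#' Two-stage risk-factor analysis
#'
#' The full analysis on a discretized cohort: grows and
#' cross-validation-prunes one stratification tree per nested confounder
#' set, selects the best tree by AIC, stratifies the cohort by the tree
#' leaves, and estimates crude plus Mantel-Haenszel stratum-adjusted
#' effects for every putative risk factor under each candidate
#' stratification. A logistic-regression sensitivity analysis adjusts each
#' exposure for the selected tree's confounders (with first-order
#' interaction screening among them) and runs a forward-stepwise search
#' over the exposures.
#'
#' @param cohort a `"cohort"` data.frame from [discretize()] or
#'   [generate_cohort()].
#' @param folds cross-validation folds for tree pruning (default 10).
#' @param seed fold-assignment seed (default 20150901).
#' @param measure effect measure for the crude/MH columns: `"or"` (default)
#'   or `"rr"`.
#' @param lr run the logistic sensitivity analysis (default TRUE).
#' @param ... further arguments to [cv_prune()] (e.g. `metric`,
#'   `min_split`, `se_rule`).
#' @return an object of class `"two_stage"`: candidate models, the selected
#'   model, stratum assignments, the effect table, pairwise node effects of
#'   the selected tree, interaction screen, LR estimates and stepwise
#'   trace.
#' @export
two_stage <- function(cohort, folds = 10, seed = 20150901,
                      measure = c("or", "rr"), lr = TRUE, ...) {
  measure <- match.arg(measure)
  specs <- attr(cohort, "specs")
  candidates <- candidate_models(cohort, folds = folds, seed = seed, ...)
  names(candidates) <- vapply(candidates, `[[`, "", "id")
  best <- select_model(candidates)
  strata <- lapply(candidates, function(cm)
    assign_strata(cm$tree, encode_confounders(cohort, cm$confounders)))
  effects <- effect_table(cohort, strata, measure = measure)
  pairwise <- pairwise_node_effects(best$tree)
  interactions <- NULL
  lr_effects <- NULL
  stepwise <- NULL
  if (lr) {
    conf <- selected_confounders(best$tree)
    interactions <- screen_interactions(cohort, conf)
    flagged <- interactions[interactions$flagged & interactions$testable, ,
                            drop = FALSE]
    pairs <- if (nrow(flagged))
      lapply(seq_len(nrow(flagged)), function(i)
        c(flagged$var1[i], flagged$var2[i])) else NULL
    exposures <- vars_by_role(specs, "putative_risk")
    lr_effects <- do.call(rbind, lapply(exposures, function(ex)
      adjusted_or_lr(cohort, ex, conf, pairs)))
    stepwise <- forward_stepwise(cohort, exposures, conf, pairs)
    effects <- rbind(effects, lr_effects)
  }
  structure(list(cohort_n = nrow(cohort), specs = specs,
                 candidates = candidates, selected = best,
                 strata = strata, effects = effects, pairwise = pairwise,
                 interactions = interactions, lr = lr_effects,
                 stepwise = stepwise, measure = measure,
                 folds = folds, seed = seed),
            class = "two_stage")
}

#' @export
print.two_stage <- function(x, ...) {
  cat(sprintf("Two-stage risk-factor analysis (%d subjects)\n", x$cohort_n))
  for (cm in x$candidates)
    cat(sprintf("  %s: AIC %.1f, %d strata (%s)\n", cm$id, cm$aic,
                n_leaves(cm$tree),
                if (identical(cm$id, x$selected$id)) "selected" else " "))
  cat(sprintf("  selected confounders: %s\n",
              paste(selected_confounders(x$selected$tree), collapse = ", ")))
  cat(sprintf("  %d effect estimates (%s); use coef() or summary()\n",
              nrow(x$effects), x$measure))
  invisible(x)
}

#' @export
coef.two_stage <- function(object, ...) object$effects

#' @export
summary.two_stage <- function(object, ...) {
  print(object)
  cat("\nCrude and adjusted estimates (selected model):\n")
  sel <- object$effects[object$effects$method == "crude" |
                          (object$effects$method == "MH" &
                             object$effects$model == object$selected$id) |
                          object$effects$method == "LR", ]
  out <- sel[order(match(sel$exposure, unique(sel$exposure))), ]
  print(data.frame(exposure = out$exposure, level = out$level,
                   method = out$method,
                   estimate = sprintf("%.2f (%.2f, %.2f)", out$estimate,
                                      out$lo, out$hi)),
        row.names = FALSE)
  invisible(object)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage: %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full pipeline and write every report
#'
#' Orchestrates load/impute/discretize (or synthetic generation), the
#' characteristics table, tree fitting/selection, the effect table, the
#' logistic sensitivity analysis, and tree renderings, writing each
#' artifact under `out_dir` and a manifest listing every file with the
#' seeds and configuration used. Reruns with the same inputs and seeds
#' produce identical numeric output.
#'
#' @param input path to a delimited cohort file, or NULL to simulate.
#' @param simulate if TRUE (exclusive with `input`), generate the cohort
#'   from [default_config()].
#' @param spec_path YAML variable specification; default the packaged one.
#' @param out_dir output directory (created if absent).
#' @param folds,seed,measure passed to [two_stage()].
#' @param sim_n cohort size when simulating (default 7302).
#' @param ... further arguments to [two_stage()].
#' @return the run manifest (named list), invisibly; written as
#'   `manifest.yaml`.
#' @export
run_pipeline <- function(input = NULL, simulate = is.null(input),
                         spec_path = NULL, out_dir = "septree-run",
                         folds = 10, seed = 20150901,
                         measure = "or", sim_n = 7302, ...) {
  if (is.null(input) == !simulate)
    stop("[stage: config] exactly one of 'input' or 'simulate' must be set")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    files <<- c(files, name)
    path
  }
  if (simulate) {
    cohort <- stage("simulate", {
      gen <- generate_cohort(default_config(n = sim_n, seed = seed))
      gen$cohort
    })
    emit("cohort.tsv", function(p) write_cohort(cohort, p))
  } else {
    cohort <- stage("schema", {
      specs <- if (is.null(spec_path)) default_variable_specs()
               else read_variable_specs(spec_path)
      discretize(impute_missing(load_cohort(input, specs), specs), specs)
    })
  }
  chars <- stage("describe", characteristics_table(cohort))
  emit("characteristics.tsv", function(p) write_characteristics(chars, p))
  fit <- stage("analyse", two_stage(cohort, folds = folds, seed = seed,
                                    measure = measure, ...))
  emit("effects.tsv", function(p) write_effects(fit$effects, p))
  for (cm in fit$candidates) {
    emit(paste0("tree_", cm$id, ".txt"), function(p)
      writeLines(render_tree(cm$tree), p))
    emit(paste0("tree_", cm$id, ".yaml"), function(p)
      yaml::write_yaml(tree_to_list(cm$tree), p))
  }
  emit("tree_selected.dot", function(p)
    writeLines(tree_to_dot(fit$selected$tree), p))
  emit("pairwise_nodes.tsv", function(p)
    utils::write.table(fit$pairwise, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  if (!is.null(fit$stepwise))
    emit("stepwise_trace.tsv", function(p)
      utils::write.table(fit$stepwise$trace, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  manifest <- list(
    input = if (simulate) "simulated" else input,
    n_subjects = nrow(cohort),
    seed = seed, folds = folds, measure = measure,
    cv_metric = fit$selected$tree$cv_metric,
    selected_model = fit$selected$id,
    candidate_aic = stats::setNames(
      lapply(fit$candidates, function(cm) cm$aic),
      names(fit$candidates)),
    files = as.list(files),
    checksums = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$checksums) <- files
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
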