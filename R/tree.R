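#' Encode confounders as binary indicators
#'
#' Turns each discretized confounder into one-versus-rest 0/1 indicators for
#' its non-reference levels (a K-level confounder yields K-1 columns named
#' `var=level`), the splittable features of the stratification tree.
#'
#' @param cohort a `"cohort"` data.frame from [discretize()].
#' @param confounders confounder names to encode; default every variable
#'   with role `"confounder"`.
#' @return integer 0/1 matrix, one row per subject.
#' @export
encode_confounders <- function(cohort, confounders = NULL) {
  specs <- attr(cohort, "specs")
  if (is.null(confounders)) confounders <- vars_by_role(specs, "confounder")
  cols <- list()
  for (nm in confounders) {
    s <- specs[[nm]]
    for (lv in setdiff(s$levels, s$reference))
      cols[[paste0(nm, "=", lv)]] <-
        as.integer(cohort[[nm]] == lv)
  }
  do.call(cbind, cols)
}

node_sse <- function(e, n) e - e * e / n   # sum (y - ybar)^2 for 0/1 y

best_split <- function(x, y, idx, min_leaf) {
  n <- length(idx)
  e <- sum(y[idx])
  xm <- x[idx, , drop = FALSE]
  n1 <- colSums(xm)
  e1 <- colSums(xm * y[idx])
  n0 <- n - n1
  e0 <- e - e1
  ok <- n1 >= min_leaf & n0 >= min_leaf
  if (!any(ok)) return(NULL)
  p1 <- e1 / n1
  p0 <- e0 / n0
  gain <- ifelse(ok, n1 * n0 / n * (p1 - p0)^2, -Inf)
  j <- unname(which.max(gain))    # ties: smallest column index
  if (gain[j] <= 1e-12) return(NULL)
  list(j = j, gain = unname(gain[j]))
}

#' Grow a confounder stratification tree
#'
#' Greedy top-down recursive partitioning of a binary outcome on binary
#' indicator features. At every node the split maximizing the between-group
#' sum of squares of the 0/1 outcome (equivalently, minimizing the
#' within-group error sum of squares) is chosen. Recursion stops when a node
#' holds fewer than `min_split` subjects, when no split yields a positive
#' between-group sum of squares, or when a split would create a child
#' smaller than `min_leaf`. A constant outcome yields a single-leaf tree.
#'
#' Ties between equally good splits go to the leftmost indicator column, so
#' growth is deterministic. The convention throughout the package is that
#' the right child carries the indicator value 1 (\dQuote{present}).
#'
#' @param x 0/1 indicator matrix (from [encode_confounders()]).
#' @param y 0/1 outcome vector.
#' @param min_split minimum node size eligible for splitting (default 20).
#' @param min_leaf minimum size of a child node (default 7).
#' @return an object of class `"strat_tree"`: a node frame (preorder) plus
#'   fitting metadata. Leaves partition the subjects.
#' @seealso [cv_prune()], [cost_complexity_path()], [tree_aic()],
#'   [assign_strata()]
#' @export
strat_tree <- function(x, y, min_split = 20, min_leaf = 7) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(x), all(y %in% c(0, 1)),
            all(x %in% c(0, 1)), min_split >= 2, min_leaf >= 1)
  rows <- list()
  grow <- function(idx, depth) {
    id <- length(rows) + 1L
    n <- length(idx)
    e <- sum(y[idx])
    rows[[id]] <<- list(id = id, var = NA_character_, n = n, events = e,
                        yval = e / n, left = NA_integer_, right = NA_integer_,
                        depth = depth)
    if (n < min_split || e == 0 || e == n) return(id)
    sp <- best_split(x, y, idx, min_leaf)
    if (is.null(sp)) return(id)
    go_right <- x[idx, sp$j] == 1
    lid <- grow(idx[!go_right], depth + 1L)
    rid <- grow(idx[go_right], depth + 1L)
    rows[[id]]$var <<- colnames(x)[sp$j]
    rows[[id]]$left <<- lid
    rows[[id]]$right <<- rid
    id
  }
  grow(seq_along(y), 0L)
  frame <- make_frame(rows)
  structure(list(frame = frame, features = colnames(x),
                 min_split = min_split, min_leaf = min_leaf,
                 n = length(y)),
            class = "strat_tree")
}

make_frame <- function(rows) {
  data.frame(id = vapply(rows, `[[`, 0L, "id"),
             var = vapply(rows, `[[`, "", "var"),
             n = vapply(rows, `[[`, 0, "n"),
             events = vapply(rows, `[[`, 0, "events"),
             yval = vapply(rows, `[[`, 0, "yval"),
             left = vapply(rows, `[[`, 0L, "left"),
             right = vapply(rows, `[[`, 0L, "right"),
             depth = vapply(rows, `[[`, 0L, "depth"),
             stringsAsFactors = FALSE)
}

n_leaves <- function(tree) sum(is.na(tree$frame$var))

is_leaf <- function(frame) is.na(frame$var)

#' Route subjects to tree nodes
#'
#' @param object a `"strat_tree"`.
#' @param x indicator matrix with the columns used at the tree's splits.
#' @param type `"leaf"` for the terminal node id per subject, `"prob"` for
#'   the leaf outcome incidence.
#' @param ... unused.
#' @return integer leaf ids or numeric incidences, one per subject.
#' @export
predict.strat_tree <- function(object, x, type = c("leaf", "prob"), ...) {
  type <- match.arg(type)
  fr <- object$frame
  x <- as.matrix(x)
  need <- stats::na.omit(unique(fr$var))
  miss <- setdiff(need, colnames(x))
  if (length(miss))
    stop("indicator matrix lacks split feature(s): ",
         paste(miss, collapse = ", "))
  vvar <- fr$var; vleft <- fr$left; vright <- fr$right
  node <- rep.int(1L, nrow(x))
  for (i in seq_along(vvar)) {          # preorder: parents precede children
    if (is.na(vvar[i])) next
    here <- which(node == i)
    if (!length(here)) next
    right <- x[here, vvar[i]] == 1
    node[here[right]] <- vright[i]
    node[here[!right]] <- vleft[i]
  }
  if (type == "leaf") node else fr$yval[node]
}

#' Cost-complexity pruning path
#'
#' Weakest-link pruning: repeatedly collapses the internal node(s) with the
#' smallest per-leaf error-reduction rate, producing the nested sequence of
#' optimally pruned subtrees with their critical complexity parameters.
#' Alphas are non-decreasing; the first element is the full tree at alpha 0
#' and the last is the root-only tree.
#'
#' @param tree a `"strat_tree"` (typically the full grown tree).
#' @return list of `list(alpha =, tree =)` elements.
#' @export
cost_complexity_path <- function(tree) {
  fr <- tree$frame
  var <- fr$var; left <- fr$left; right <- fr$right
  nn <- fr$n; ee <- fr$events; yv <- fr$yval; dp <- fr$depth
  nr <- length(var)
  r_node <- node_sse(ee, nn)
  alive <- rep.int(TRUE, nr)
  isleaf <- is.na(var)
  materialize <- function() {
    keep <- which(alive)                 # ascending = preorder preserved
    remap <- integer(nr); remap[keep] <- seq_along(keep)
    v <- var[keep]; l <- left[keep]; r <- right[keep]
    lf <- isleaf[keep]
    v[lf] <- NA_character_
    l[lf] <- NA_integer_; r[lf] <- NA_integer_
    l[!lf] <- remap[l[!lf]]; r[!lf] <- remap[r[!lf]]
    out <- tree
    out$frame <- data.frame(id = seq_along(keep), var = v, n = nn[keep],
                            events = ee[keep], yval = yv[keep],
                            left = l, right = r, depth = dp[keep],
                            stringsAsFactors = FALSE)
    out
  }
  path <- list(list(alpha = 0, tree = tree))
  alpha <- 0
  while (sum(isleaf & alive) > 1L) {
    act <- which(alive)
    leaves_under <- numeric(nr)
    r_sub <- numeric(nr)
    g <- rep.int(Inf, nr)
    for (i in rev(act)) {               # children precede parents in reverse
      if (isleaf[i]) {
        leaves_under[i] <- 1
        r_sub[i] <- r_node[i]
      } else {
        leaves_under[i] <- leaves_under[left[i]] + leaves_under[right[i]]
        r_sub[i] <- r_sub[left[i]] + r_sub[right[i]]
        g[i] <- (r_node[i] - r_sub[i]) / (leaves_under[i] - 1)
      }
    }
    m <- min(g[act])
    alpha <- max(alpha, m)
    weak <- act[!isleaf[act] & g[act] <= m + 1e-12]
    for (w in weak) {
      if (!alive[w]) next
      isleaf[w] <- TRUE
      stack <- c(left[w], right[w])
      while (length(stack)) {
        i <- stack[length(stack)]; stack <- stack[-length(stack)]
        if (!alive[i]) next
        alive[i] <- FALSE
        if (!isleaf[i]) stack <- c(stack, left[i], right[i])
      }
    }
    path[[length(path) + 1L]] <- list(alpha = alpha, tree = materialize())
  }
  path
}

#' Select the path element for a complexity value
#'
#' @param path result of [cost_complexity_path()].
#' @param alpha complexity parameter.
#' @return the `"strat_tree"` optimal at `alpha` (largest path alpha not
#'   exceeding `alpha`).
#' @export
prune_at <- function(path, alpha) {
  alphas <- vapply(path, `[[`, 0, "alpha")
  path[[max(which(alphas <= alpha + 1e-12))]]$tree
}

clamp_prob <- function(p, n) pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))

holdout_score <- function(tree, x, y, metric) {
  leaf <- predict(tree, x, type = "leaf")
  p <- clamp_prob(tree$frame$yval[leaf], tree$frame$n[leaf])
  if (metric == "deviance")
    -2 * sum(y * log(p) + (1 - y) * log(1 - p))
  else
    mean((p > 0.5) == (y == 1))
}

stratified_folds <- function(y, folds) {
  if (min(table(factor(y, levels = 0:1))) < folds)
    stop("a fold would lack both outcome classes; use fewer folds")
  fold <- integer(length(y))
  for (cls in c(0, 1)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Grow and cross-validation-prune a stratification tree
#'
#' Grows the full tree, computes its cost-complexity path, and selects the
#' complexity parameter by stratified k-fold cross-validation (folds
#' preserve the outcome prevalence). For every candidate alpha (geometric
#' midpoints of successive path alphas) the mean held-out score is computed;
#' the best alpha wins, ties going to the largest alpha (simplest tree), and
#' the returned tree is the full-data tree pruned at that alpha.
#'
#' The default score is the held-out binomial deviance. Classification
#' accuracy is available but degenerate for rare outcomes: when every leaf
#' incidence is below one half, all subtrees predict the majority class,
#' accuracy is constant along the path, and the largest-alpha tie-break
#' always returns the root-only tree.
#'
#' By default the one-standard-error rule is applied: the simplest tree
#' whose mean held-out score is within one standard error (across folds) of
#' the best score is selected, which guards against keeping spurious splits
#' whose apparent gain is within cross-validation noise. Set
#' `se_rule = FALSE` to select the score optimum itself.
#'
#' @param x 0/1 indicator matrix.
#' @param y 0/1 outcome vector.
#' @param folds number of folds (default 10).
#' @param seed integer seed for the fold assignment (default 20150901).
#' @param min_split,min_leaf growth controls, see [strat_tree()].
#' @param metric `"deviance"` (default) or `"accuracy"`.
#' @param se_rule apply the one-standard-error selection rule (default
#'   TRUE).
#' @return the selected `"strat_tree"`, with components `cv` (a data.frame
#'   of alpha, leaves and mean held-out score), `alpha` (the winning value),
#'   `cv_metric` and `cv_seed` recorded.
#' @export
cv_prune <- function(x, y, folds = 10, seed = 20150901,
                     min_split = 20, min_leaf = 7,
                     metric = c("deviance", "accuracy"), se_rule = TRUE) {
  metric <- match.arg(metric)
  stopifnot(folds >= 2)
  x <- as.matrix(x)
  y <- as.numeric(y)
  full <- strat_tree(x, y, min_split, min_leaf)
  path <- cost_complexity_path(full)
  alphas <- vapply(path, `[[`, 0, "alpha")
  m <- length(alphas)
  eval_alpha <- if (m == 1L) alphas else
    c(sqrt(alphas[-m] * alphas[-1]), alphas[m])
  fold <- with_seed(seed, stratified_folds(y, folds))
  scores <- matrix(NA_real_, folds, m)
  for (f in seq_len(folds)) {
    tr <- fold != f
    ft <- strat_tree(x[tr, , drop = FALSE], y[tr], min_split, min_leaf)
    fpath <- cost_complexity_path(ft)
    falphas <- vapply(fpath, `[[`, 0, "alpha")
    # master alphas mapping to the same fold subtree share one evaluation
    pick <- vapply(eval_alpha, function(a)
      max(which(falphas <= a + 1e-12)), 0L)
    sc <- rep(NA_real_, length(fpath))
    for (k in unique(pick))
      sc[k] <- holdout_score(fpath[[k]]$tree, x[!tr, , drop = FALSE],
                             y[!tr], metric)
    scores[f, ] <- sc[pick]
  }
  mean_score <- colMeans(scores)
  se_score <- apply(scores, 2, stats::sd) / sqrt(folds)
  kbest <- if (metric == "deviance") which.min(mean_score) else
    which.max(mean_score)
  slack <- if (se_rule) se_score[kbest] else 1e-9
  ok <- if (metric == "deviance")
    mean_score <= mean_score[kbest] + slack
  else mean_score >= mean_score[kbest] - slack
  k <- max(which(ok))                   # largest qualifying alpha
  out <- prune_at(path, eval_alpha[k])
  out$cv <- data.frame(alpha = eval_alpha,
                       leaves = vapply(path, function(p) n_leaves(p$tree), 0L),
                       score = mean_score, se = se_score)
  out$alpha <- eval_alpha[k]
  out$cv_metric <- metric
  out$cv_seed <- seed
  out
}

# run code under a fixed RNG state, restoring the caller's state after
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' @export
logLik.strat_tree <- function(object, ...) {
  fr <- object$frame
  lf <- fr[is_leaf(fr), , drop = FALSE]
  p <- clamp_prob(lf$yval, lf$n)
  ll <- sum(lf$events * log(p) + (lf$n - lf$events) * log(1 - p))
  structure(ll, df = nrow(lf), nobs = object$n, class = "logLik")
}

#' Tree AIC
#'
#' Binomial-deviance AIC of a stratification tree:
#' \eqn{-2 \sum_i [y_i \ln p_{leaf(i)} + (1-y_i)\ln(1-p_{leaf(i)})] + 2 L}
#' with one parameter per leaf. Leaf incidences of exactly 0 or 1 are
#' clamped to \eqn{1/(2 n_{leaf})} from the boundary.
#'
#' @param tree a `"strat_tree"`.
#' @return the AIC value.
#' @export
tree_aic <- function(tree) {
  ll <- logLik(tree)
  -2 * as.numeric(ll) + 2 * attr(ll, "df")
}

#' Assign subjects to tree strata
#'
#' @param tree a fitted `"strat_tree"`.
#' @param x indicator matrix over the same confounder encoding.
#' @return integer vector of stratum (leaf) ids; the strata partition the
#'   subjects.
#' @export
assign_strata <- function(tree, x) predict(tree, x, type = "leaf")

#' Crude risk ratios at every split of a tree
#'
#' For each internal node, the ratio of outcome incidences between its two
#' children, the child with the splitting indicator present (the right
#' child) being the exposed group. Confidence intervals use the Katz
#' log-scale method; when any of the four implied counts is zero, 0.5 is
#' added to all four for the interval only.
#'
#' @param tree a `"strat_tree"`.
#' @param conf_level confidence level (default 0.95).
#' @return data.frame with one row per internal node: split variable, child
#'   counts/events/incidences, risk ratio and CI bounds.
#' @export
pairwise_node_effects <- function(tree, conf_level = 0.95) {
  fr <- tree$frame
  internal <- which(!is_leaf(fr))
  if (!length(internal))
    return(data.frame(node = integer(0), var = character(0)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- lapply(internal, function(i) {
    L <- fr[fr$left[i], ]
    R <- fr[fr$right[i], ]
    a <- R$events; n1 <- R$n; c0 <- L$events; n0 <- L$n
    rr <- (a / n1) / (c0 / n0)
    cc <- if (a == 0 || c0 == 0 || a == n1 || c0 == n0) 0.5 else 0
    ac <- a + cc; cc0 <- c0 + cc; n1c <- n1 + 2 * cc; n0c <- n0 + 2 * cc
    se <- sqrt(1 / ac - 1 / n1c + 1 / cc0 - 1 / n0c)
    lrr <- log((ac / n1c) / (cc0 / n0c))
    data.frame(node = i, var = fr$var[i],
               n_exposed = n1, events_exposed = a, inc_exposed = a / n1,
               n_ref = n0, events_ref = c0, inc_ref = c0 / n0,
               rr = rr, lo = exp(lrr - z * se), hi = exp(lrr + z * se),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the candidate stratification models
#'
#' Fits one cross-validation-pruned tree per nested confounder set: model 1
#' on demographics, model 2 adding preoperative comorbidities, model 3
#' adding preoperative management. Each candidate records its confounders,
#' fitted tree and AIC.
#'
#' @param cohort a `"cohort"` data.frame.
#' @param sets named list of confounder-name vectors; default
#'   [confounder_sets()] on the cohort's specs.
#' @param ... passed to [cv_prune()].
#' @return list of `"candidate_model"` objects.
#' @export
candidate_models <- function(cohort, sets = NULL, ...) {
  specs <- attr(cohort, "specs")
  if (is.null(sets)) sets <- confounder_sets(specs)
  y <- cohort[[outcome_name(specs)]]
  lapply(names(sets), function(id) {
    x <- encode_confounders(cohort, sets[[id]])
    tree <- cv_prune(x, y, ...)
    structure(list(id = id, confounders = sets[[id]], tree = tree,
                   aic = tree_aic(tree)),
              class = "candidate_model")
  })
}

#' Nested confounder sets
#'
#' The default three nested confounder groupings: demographics (model 1),
#' plus preoperative comorbidities (model 2), plus preoperative management
#' related to acquired immunosuppression (model 3, all confounders).
#'
#' @param specs named list of [variable_spec()] objects.
#' @return named list `model1`, `model2`, `model3` of confounder names.
#' @export
confounder_sets <- function(specs) {
  conf <- vars_by_role(specs, "confounder")
  demo <- intersect(c("age", "sex", "bmi", "smoking", "drinking"), conf)
  como <- intersect(c("diabetes", "coronary_disease",
                      "cerebrovascular_disease", "malignant_tumor",
                      "hepatic_failure", "pneumonia", "acute_kidney_injury",
                      "n_comorbidities"), conf)
  list(model1 = demo, model2 = c(demo, como), model3 = conf)
}

#' Select the best candidate model by AIC
#'
#' @param candidates list of `"candidate_model"` objects (or any objects
#'   with `aic` and `confounders` components).
#' @return the candidate with the smallest AIC; ties go to the smaller
#'   confounder set.
#' @export
select_model <- function(candidates) {
  stopifnot(length(candidates) >= 1)
  aic <- vapply(candidates, `[[`, 0, "aic")
  nconf <- vapply(candidates, function(c) length(c$confounders), 0)
  ok <- aic <= min(aic) + 1e-9
  idx <- which(ok)[which.min(nconf[ok])]
  candidates[[idx]]
}

#' @export
print.candidate_model <- function(x, ...) {
  cat(sprintf("<candidate_model> %s: %d confounders, %d strata, AIC %.1f\n",
              x$id, length(x$confounders), n_leaves(x$tree), x$aic))
  invisible(x)
}

#' @export
print.strat_tree <- function(x, ...) {
  cat(sprintf("Confounder stratification tree: %d subjects, %d strata\n",
              x$n, n_leaves(x)))
  if (!is.null(x$alpha))
    cat(sprintf("  pruned at alpha %.4g (%s CV, seed %d)\n",
                x$alpha, x$cv_metric, x$cv_seed))
  cat(render_tree(x), sep = "\n")
  invisible(x)
}

#' @export
summary.strat_tree <- function(object, ...) {
  fr <- object$frame
  lf <- fr[is_leaf(fr), ]
  cat(sprintf("Stratification tree on %d subjects\n", object$n))
  cat(sprintf("  strata: %d   AIC: %.1f\n", nrow(lf), tree_aic(object)))
  cat("  leaf incidences:",
      paste(sprintf("%d/%d (%.1f%%)", lf$events, lf$n, 100 * lf$yval),
            collapse = ", "), "\n")
  invisible(object)
}

#' Render a tree as indented text
#'
#' One line per node: the split condition (indicator present/absent),
#' subject count, outcome count and incidence.
#'
#' @param tree a `"strat_tree"`.
#' @return character vector of lines.
#' @export
render_tree <- function(tree) {
  fr <- tree$frame
  lines <- character(0)
  walk <- function(i, label, depth) {
    tag <- if (is.na(fr$var[i])) sprintf("* stratum %d", i) else
      sprintf("split on [%s]", fr$var[i])
    lines <<- c(lines, sprintf("%s%s %s: n=%d, events=%d, incidence=%.3f",
                               strrep("  ", depth), label, tag,
                               fr$n[i], fr$events[i], fr$yval[i]))
    if (!is.na(fr$var[i])) {
      walk(fr$left[i], sprintf("[%s absent]", fr$var[i]), depth + 1)
      walk(fr$right[i], sprintf("[%s present]", fr$var[i]), depth + 1)
    }
  }
  walk(1L, "root", 0)
  lines
}

#' Serialize a tree to a nested list
#'
#' The nested form round-trips through [tree_from_list()] and serializes
#' cleanly to YAML/JSON.
#'
#' @param tree a `"strat_tree"`.
#' @return nested list of nodes (`var`, `n`, `events`, `incidence`,
#'   `left`/`right` sub-lists for internal nodes).
#' @export
tree_to_list <- function(tree) {
  fr <- tree$frame
  build <- function(i) {
    node <- list(n = fr$n[i], events = fr$events[i], incidence = fr$yval[i])
    if (!is.na(fr$var[i])) {
      node$var <- fr$var[i]
      node$left <- build(fr$left[i])
      node$right <- build(fr$right[i])
    }
    node
  }
  list(n = tree$n, min_split = tree$min_split, min_leaf = tree$min_leaf,
       root = build(1L))
}

#' Rebuild a tree from its nested-list serialization
#'
#' @param x nested list from [tree_to_list()].
#' @return a `"strat_tree"`.
#' @export
tree_from_list <- function(x) {
  rows <- list()
  build <- function(node, depth) {
    id <- length(rows) + 1L
    rows[[id]] <<- list(id = id, var = NA_character_, n = node$n,
                        events = node$events, yval = node$events / node$n,
                        left = NA_integer_, right = NA_integer_,
                        depth = depth)
    if (!is.null(node$var)) {
      lid <- build(node$left, depth + 1L)
      rid <- build(node$right, depth + 1L)
      rows[[id]]$var <<- node$var
      rows[[id]]$left <<- lid
      rows[[id]]$right <<- rid
    }
    id
  }
  build(x$root, 0L)
  frame <- do.call(rbind, lapply(rows, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
  structure(list(frame = frame,
                 features = stats::na.omit(unique(frame$var)),
                 min_split = x$min_split, min_leaf = x$min_leaf, n = x$n),
            class = "strat_tree")
}

#' Export a tree as a DOT graph
#'
#' @param tree a `"strat_tree"`.
#' @return character scalar with a Graphviz DOT document.
#' @export
tree_to_dot <- function(tree) {
  fr <- tree$frame
  nodes <- vapply(seq_len(nrow(fr)), function(i) {
    lab <- if (is.na(fr$var[i]))
      sprintf("stratum %d\\n%d/%d (%.1f%%)", i, fr$events[i], fr$n[i],
              100 * fr$yval[i])
    else
      sprintf("%s\\n%d/%d (%.1f%%)", fr$var[i], fr$events[i], fr$n[i],
              100 * fr$yval[i])
    sprintf("  n%d [shape=%s, label=\"%s\"];", i,
            if (is.na(fr$var[i])) "box" else "ellipse", lab)
  }, "")
  edges <- unlist(lapply(which(!is_leaf(fr)), function(i) c(
    sprintf("  n%d -> n%d [label=\"absent\"];", i, fr$left[i]),
    sprintf("  n%d -> n%d [label=\"present\"];", i, fr$right[i]))))
  paste(c("digraph strat_tree {", nodes, edges, "}"), collapse = "\n")
}

#' Plot a stratification tree
#'
#' A simple base-graphics rendering: splits as internal labels, strata as
#' boxes with counts and incidences.
#'
#' @param x a `"strat_tree"`.
#' @param ... unused.
#' @return invisibly, `x`.
#' @export
plot.strat_tree <- function(x, ...) {
  fr <- x$frame
  pos <- matrix(NA_real_, nrow(fr), 2)
  leaf_x <- 0
  place <- function(i, depth) {
    if (is.na(fr$var[i])) {
      leaf_x <<- leaf_x + 1
      pos[i, ] <<- c(leaf_x, -depth)
    } else {
      place(fr$left[i], depth + 1)
      place(fr$right[i], depth + 1)
      pos[i, ] <<- c(mean(pos[c(fr$left[i], fr$right[i]), 1]), -depth)
    }
  }
  place(1L, 0)
  graphics::plot(pos, type = "n", axes = FALSE, xlab = "", ylab = "",
                 ylim = range(pos[, 2]) + c(-0.5, 0.5))
  for (i in which(!is_leaf(fr))) {
    graphics::segments(pos[i, 1], pos[i, 2], pos[fr$left[i], 1],
                       pos[fr$left[i], 2])
    graphics::segments(pos[i, 1], pos[i, 2], pos[fr$right[i], 1],
                       pos[fr$right[i], 2])
  }
  lab <- ifelse(is.na(fr$var),
                sprintf("%d/%d\n%.1f%%", fr$events, fr$n, 100 * fr$yval),
                fr$var)
  graphics::text(pos[, 1], pos[, 2], lab, cex = 0.8)
  invisible(x)
}
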