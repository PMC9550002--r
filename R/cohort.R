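#' Variable specification
#'
#' Declares how one cohort variable is read, imputed and discretized.
#' Continuous variables carry ordered cutpoints; each cutpoint's `side`
#' states which neighbouring interval owns the boundary value
#' (`"left"` for a \dQuote{<= c vs > c} split, `"right"` for
#' \dQuote{< c vs >= c}).
#'
#' @param name variable (column) name.
#' @param role one of `"outcome"`, `"putative_risk"`, `"confounder"`.
#' @param vtype `"continuous"` or `"categorical"`.
#' @param levels ordered character vector of level labels. For a continuous
#'   variable there must be `length(cutpoints) + 1` labels, ordered by
#'   interval. The outcome must have exactly the levels `c("0", "1")`.
#' @param reference reference level label (must be one of `levels`).
#' @param cutpoints strictly increasing numeric thresholds (continuous only).
#' @param sides character vector, one of `"left"`/`"right"` per cutpoint;
#'   recycled if length 1. Default `"left"`.
#' @param min optional lower domain bound for a continuous variable; values
#'   below it are rejected at discretization.
#'
#' @return an object of class `"variable_spec"`.
#' @export
variable_spec <- function(name, role, vtype, levels, reference = levels[1],
                          cutpoints = numeric(0), sides = "left", min = NULL) {
  role <- match.arg(role, c("outcome", "putative_risk", "confounder"))
  vtype <- match.arg(vtype, c("continuous", "categorical"))
  levels <- as.character(levels)
  if (!reference %in% levels)
    stop("reference level '", reference, "' not among levels of '", name, "'")
  if (vtype == "continuous") {
    cutpoints <- as.numeric(cutpoints)
    if (length(cutpoints) < 1L)
      stop("continuous variable '", name, "' needs at least one cutpoint")
    if (is.unsorted(cutpoints, strictly = TRUE))
      stop("cutpoints of '", name, "' must be strictly increasing")
    if (length(levels) != length(cutpoints) + 1L)
      stop("'", name, "': need ", length(cutpoints) + 1L, " level labels")
    sides <- rep_len(match.arg(sides, c("left", "right"), several.ok = TRUE),
                     length(cutpoints))
  } else {
    cutpoints <- numeric(0)
    sides <- character(0)
  }
  if (role == "outcome" && !identical(sort(levels), c("0", "1")))
    stop("outcome levels must be exactly {0, 1}")
  structure(list(name = name, role = role, vtype = vtype, levels = levels,
                 reference = reference, cutpoints = cutpoints, sides = sides,
                 min = min),
            class = "variable_spec")
}

#' @export
print.variable_spec <- function(x, ...) {
  cat(sprintf("<variable_spec> %s (%s, %s)\n", x$name, x$role, x$vtype))
  cat("  levels:", paste(x$levels, collapse = " | "),
      " reference:", x$reference, "\n")
  if (length(x$cutpoints))
    cat("  cutpoints:", paste(x$cutpoints, collapse = ", "),
        " sides:", paste(x$sides, collapse = ", "), "\n")
  invisible(x)
}

validate_specs <- function(specs) {
  if (is.null(names(specs)) || any(names(specs) == ""))
    names(specs) <- vapply(specs, `[[`, "", "name")
  roles <- vapply(specs, `[[`, "", "role")
  if (sum(roles == "outcome") != 1L)
    stop("exactly one variable must have role 'outcome'")
  specs
}

#' Read variable specifications from a YAML document
#'
#' The document is a mapping from variable name to a block with keys
#' `role`, `vtype`, `levels`, `reference`, and (continuous only)
#' `cutpoints`, `sides`, `min`.
#'
#' @param path path to the YAML file.
#' @return named list of [variable_spec()] objects.
#' @export
read_variable_specs <- function(path) {
  doc <- yaml::read_yaml(path)
  specs <- lapply(names(doc), function(nm) {
    b <- doc[[nm]]
    variable_spec(name = nm, role = b$role, vtype = b$vtype,
                  levels = as.character(b$levels),
                  reference = if (is.null(b$reference)) as.character(b$levels)[1]
                              else as.character(b$reference),
                  cutpoints = if (is.null(b$cutpoints)) numeric(0) else b$cutpoints,
                  sides = if (is.null(b$sides)) "left" else b$sides,
                  min = b$min)
  })
  names(specs) <- names(doc)
  validate_specs(specs)
}

#' Default variable specifications for the elderly surgical cohort
#'
#' The packaged specification covering the binary sepsis outcome, 16
#' potential confounders (demographics, preoperative comorbidities,
#' preoperative management) and 17 putative risk factors (intraoperative and
#' preoperative laboratory variables), with the published grouping cutpoints
#' (e.g. serum creatinine <=116 vs >116 umol/L, CAR <0.278 vs >=0.278, age
#' 65-74 vs >=75, BMI <18.5 / 18.5-24 / >=24 kg/m2).
#'
#' @return named list of [variable_spec()] objects (34 variables).
#' @export
default_variable_specs <- function() {
  read_variable_specs(system.file("extdata", "table1_variables.yaml",
                                  package = "septree", mustWork = TRUE))
}

#' Load a raw cohort table
#'
#' Reads a delimited text file (comma or tab, autodetected from the header
#' line), checks that every specified variable is present, parses continuous
#' columns as numeric, and flags — but does not drop — missing cells.
#'
#' @param path path to the delimited file.
#' @param specs named list of [variable_spec()] objects.
#' @return a data.frame in file order; continuous columns numeric,
#'   categorical columns character, `NA` marking missing cells. Attribute
#'   `"n_missing"` records the count of missing cells in spec'd columns.
#' @export
load_cohort <- function(path, specs) {
  specs <- validate_specs(specs)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", na.strings = c("", "NA"),
                           fileEncoding = "UTF-8")
  need <- names(specs)
  # the comorbidity-count confounder may be derived later from the flags
  derivable <- need[vapply(specs, function(s)
    isTRUE(attr(s, "derived")) || s$name == "n_comorbidities", TRUE)]
  missing_cols <- setdiff(need, c(colnames(raw), derivable))
  if (length(missing_cols))
    stop("cohort file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  for (nm in intersect(need, colnames(raw))) {
    s <- specs[[nm]]
    if (s$vtype == "continuous" || s$role == "outcome") {
      v <- raw[[nm]]
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad))
        stop("column '", nm, "': unparseable numeric value '", v[bad[1]],
             "' at data line ", bad[1])
      raw[[nm]] <- num
    }
  }
  attr(raw, "n_missing") <- sum(is.na(raw[, intersect(need, colnames(raw)),
                                         drop = FALSE]))
  raw
}

#' Impute missing cells
#'
#' Continuous columns are filled with the arithmetic mean of the observed
#' values; categorical columns with the most frequent observed level (ties
#' broken by the lexicographically smallest label). Imputation happens
#' before discretization.
#'
#' @param raw data.frame from [load_cohort()].
#' @param specs named list of [variable_spec()] objects.
#' @return the data.frame with no missing cells in spec'd columns.
#' @export
impute_missing <- function(raw, specs) {
  specs <- validate_specs(specs)
  for (nm in intersect(names(specs), colnames(raw))) {
    v <- raw[[nm]]
    if (!anyNA(v)) next
    if (all(is.na(v)))
      stop("column '", nm, "' is fully missing; cannot impute")
    if (specs[[nm]]$vtype == "continuous" || specs[[nm]]$role == "outcome") {
      v[is.na(v)] <- mean(v, na.rm = TRUE)
    } else {
      tab <- table(v[!is.na(v)])
      top <- names(tab)[tab == max(tab)]
      v[is.na(v)] <- sort(top)[1]
    }
    raw[[nm]] <- v
  }
  raw
}

cut_value <- function(x, cutpoints, sides, labels) {
  # interval index per value honouring per-cutpoint boundary ownership
  idx <- rep.int(1L, length(x))
  for (k in seq_along(cutpoints)) {
    above <- if (sides[k] == "left") x > cutpoints[k] else x >= cutpoints[k]
    idx[above] <- k + 1L
  }
  labels[idx]
}

#' Discretize an imputed cohort
#'
#' Maps every continuous value to its interval label (honouring the
#' open/closed boundary side of each cutpoint), turns categorical columns
#' into factors over their declared levels, codes the outcome as integer
#' 0/1, and derives the comorbidity-count confounder from the seven
#' comorbidity flags when it is specified but absent from the input.
#'
#' @param raw imputed data.frame.
#' @param specs named list of [variable_spec()] objects.
#' @return a `"cohort"` data.frame: factor columns plus an integer outcome,
#'   with the specs stored in attribute `"specs"`.
#' @export
discretize <- function(raw, specs) {
  specs <- validate_specs(specs)
  if (anyNA(raw[, intersect(names(specs), colnames(raw)), drop = FALSE]))
    stop("missing cells remain; run impute_missing() first")
  if ("n_comorbidities" %in% names(specs) &&
      !"n_comorbidities" %in% colnames(raw)) {
    flags <- c("diabetes", "coronary_disease", "cerebrovascular_disease",
               "malignant_tumor", "hepatic_failure", "pneumonia",
               "acute_kidney_injury")
    have <- intersect(flags, colnames(raw))
    if (length(have) < length(flags))
      stop("cannot derive n_comorbidities: missing flag(s) ",
           paste(setdiff(flags, have), collapse = ", "))
    cnt <- Reduce(`+`, lapply(raw[have], function(v) as.integer(v == "Yes")))
    raw$n_comorbidities <- cut_value(cnt, c(1, 3), c("right", "right"),
                                     specs$n_comorbidities$levels)
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (nm in names(specs)) {
    s <- specs[[nm]]
    v <- raw[[nm]]
    if (s$role == "outcome") {
      y <- as.integer(v)
      if (!all(y %in% c(0L, 1L))) stop("outcome must be coded 0/1")
      out[[nm]] <- y
    } else if (s$vtype == "continuous" && is.numeric(v)) {
      if (!is.null(s$min) && any(v < s$min))
        stop("column '", nm, "': value ", min(v), " below domain minimum ",
             s$min)
      out[[nm]] <- factor(cut_value(v, s$cutpoints, s$sides, s$levels),
                          levels = s$levels)
    } else {
      v <- as.character(v)
      bad <- setdiff(unique(v), s$levels)
      if (length(bad))
        stop("column '", nm, "': label(s) not in spec: ",
             paste(bad, collapse = ", "))
      out[[nm]] <- factor(v, levels = s$levels)
    }
  }
  structure(out, specs = specs, class = c("cohort", "data.frame"))
}

#' @export
print.cohort <- function(x, ...) {
  specs <- attr(x, "specs")
  ynm <- outcome_name(specs)
  cat(sprintf("<cohort> %d subjects, %d variables, outcome '%s' (%d events, %.2f%%)\n",
              nrow(x), ncol(x) - 1L, ynm, sum(x[[ynm]]),
              100 * mean(x[[ynm]])))
  invisible(x)
}

outcome_name <- function(specs) {
  names(specs)[vapply(specs, function(s) s$role == "outcome", TRUE)]
}

vars_by_role <- function(specs, role) {
  names(specs)[vapply(specs, function(s) s$role == role, TRUE)]
}

#' Write a cohort to delimited text
#'
#' Writes the discretized level labels (and 0/1 outcome) as a tab-separated
#' file that [load_cohort()] followed by [discretize()] reproduces
#' cell-for-cell.
#'
#' @param cohort a `"cohort"` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(lapply(cohort, as.character),
                      check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
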