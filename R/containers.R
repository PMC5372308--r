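#' Single-cohort expression container
#'
#' A `study_matrix` holds one cohort's log2 expression values (features in
#' rows, samples in columns) together with the two-class sample annotation.
#' Values must be finite, feature IDs unique, and both classes need at least
#' two samples.
#'
#' @param values Numeric matrix, features x samples, with rownames (feature
#'   IDs) and colnames (sample IDs); log2 scale.
#' @param classes Character vector, one class token per sample (exactly two
#'   distinct tokens).
#' @param study_id Identifier string for the cohort.
#' @param case_class Token naming the case (tumor) class.  Defaults to the
#'   lexicographically larger token with a message, because the case class
#'   should normally be declared, not inferred.
#' @param pair_id Optional per-sample pairing identifier (tumor/normal from
#'   the same patient); carried along but unused by the default analysis.
#'
#' @return An object of class `study_matrix`.
#' @export
study_matrix <- function(values, classes, study_id = "study",
                         case_class = NULL, pair_id = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (features x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` needs feature rownames and sample colnames")
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite (no NA/Inf)")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicated feature ID(s): ", paste(unique(dup), collapse = ", "))
  classes <- as.character(classes)
  if (length(classes) != ncol(values))
    stop("`classes` must have one entry per sample")
  tab <- table(classes)
  if (length(tab) != 2L)
    stop("exactly two classes required, got: ",
         paste(names(tab), collapse = ", "))
  if (any(tab < 2L))
    stop("each class needs >= 2 samples; counts: ",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  if (is.null(case_class)) {
    case_class <- max(names(tab))
    message("case class not declared; using '", case_class, "'")
  }
  if (!case_class %in% names(tab))
    stop("case_class '", case_class, "' not among class tokens")
  if (!is.null(pair_id) && length(pair_id) != ncol(values))
    stop("`pair_id` must have one entry per sample")
  structure(list(
    study_id = as.character(study_id),
    values = values,
    classes = classes,
    case_class = case_class,
    pair_id = pair_id
  ), class = "study_matrix")
}

#' @export
print.study_matrix <- function(x, ...) {
  tab <- table(x$classes)
  cat(sprintf("study_matrix '%s': %d features x %d samples (%s; case = %s)\n",
              x$study_id, nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              x$case_class))
  invisible(x)
}

#' @export
dim.study_matrix <- function(x) dim(x$values)

# case/control column indices
case_idx <- function(study) which(study$classes == study$case_class)
control_idx <- function(study) which(study$classes != study$case_class)

#' Multi-study container on a shared feature namespace
#'
#' A `meta_dataset` is an ordered list of [study_matrix()] objects whose
#' feature IDs are identical and identically ordered, the unit of work for
#' the integrated analysis.
#'
#' @param studies List of `study_matrix` objects sharing one canonical
#'   feature list (see [intersect_features()] for harmonization).
#' @return An object of class `meta_dataset`.
#' @export
meta_dataset <- function(studies) {
  if (!length(studies) || !all(vapply(studies, inherits, TRUE, "study_matrix")))
    stop("`studies` must be a non-empty list of study_matrix objects")
  ids <- rownames(studies[[1L]]$values)
  for (s in studies[-1L]) {
    if (!identical(rownames(s$values), ids))
      stop("studies do not share an identical, identically ordered feature list; ",
           "run intersect_features() first")
  }
  names(studies) <- vapply(studies, `[[`, "", "study_id")
  structure(list(studies = studies, feature_ids = ids),
            class = "meta_dataset")
}

#' @export
print.meta_dataset <- function(x, ...) {
  cat(sprintf("meta_dataset: %d studies, %d shared features\n",
              length(x$studies), length(x$feature_ids)))
  for (s in x$studies) {
    tab <- table(s$classes)
    cat(sprintf("  %-12s %4d samples (%s)\n", s$study_id, ncol(s$values),
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  }
  invisible(x)
}

#' @export
length.meta_dataset <- function(x) length(x$studies)

#' Named gene-set database
#'
#' Holds named gene sets (pathways, or one set per target-prediction source)
#' over a declared universe.  Every set must be a non-empty subset of the
#' universe; members are deduplicated.
#'
#' @param sets Named list of character vectors.
#' @param universe Character vector containing every set member; defaults to
#'   the union of all sets (enrichment p-values depend strongly on this
#'   choice, so an explicit universe is recommended when available).
#' @return An object of class `gene_set_db`.
#' @export
gene_set_db <- function(sets, universe = NULL) {
  if (!length(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("`sets` must be a non-empty named list")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0L)) {
    bad <- names(sets)[lengths(sets) == 0L]
    stop("empty gene set(s): ", paste(bad, collapse = ", "))
  }
  memb <- unique(unlist(sets, use.names = FALSE))
  if (is.null(universe)) {
    universe <- sort(memb)
  } else {
    universe <- unique(as.character(universe))
    missing <- setdiff(memb, universe)
    if (length(missing))
      stop("set member(s) outside the declared universe: ",
           paste(utils::head(missing, 5L), collapse = ", "))
  }
  structure(list(sets = sets, universe = universe), class = "gene_set_db")
}

#' @export
print.gene_set_db <- function(x, ...) {
  cat(sprintf("gene_set_db: %d sets over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  cat(sprintf("  set sizes: min %d, median %g, max %d\n",
              min(lengths(x$sets)), stats::median(lengths(x$sets)),
              max(lengths(x$sets))))
  invisible(x)
}

#' Per-subject survival table
#'
#' Validates a data frame of right-censored follow-up data: `time`
#' (nonnegative, in months by convention), `event` (0 censored / 1 event),
#' plus any number of named covariate columns and optionally a `marker`
#' expression column.
#'
#' @param data A data.frame with at least columns `time` and `event`.
#' @return The validated data.frame with class `survival_table` prepended.
#' @export
survival_table <- function(data) {
  stopifnot(is.data.frame(data))
  if (!all(c("time", "event") %in% names(data)))
    stop("survival data needs `time` and `event` columns")
  if (any(!is.finite(data$time)) || any(data$time < 0))
    stop("`time` must be finite and >= 0")
  if (!all(data$event %in% c(0, 1)))
    stop("`event` must be 0 (censored) or 1 (event)")
  class(data) <- unique(c("survival_table", class(data)))
  data
}
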