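#' Pipeline configuration
#'
#' Bundles every tunable setting of the integrated analysis in one validated
#' object.  The defaults reproduce the published analysis settings: mean and
#' SD filter fractions of 0.10, 300 permutations, and a 0.05 significance
#' level.
#'
#' @param mean_filter_frac Fraction in `[0, 1)` of features dropped by the
#'   cross-study mean-rank filter.
#' @param sd_filter_frac Fraction in `[0, 1)` dropped by the SD-rank filter
#'   (applied after the mean filter).
#' @param n_permutations Positive integer; permutation rounds for the null
#'   distribution of the moderated t and the combined statistic.
#' @param fudge_quantile Fraction in `[0, 1]`; quantile of the per-feature
#'   standard errors used as the fudge constant `s0` (default median).
#' @param alpha Significance level in `(0, 1)` for direction calls and the
#'   raw-p significance flag.
#' @param fdr_method Multiple-testing correction across features; only
#'   `"bh"` (Benjamini-Hochberg) is supported.
#' @param min_consensus_sources Positive integer; number of target-prediction
#'   sources a gene must appear in to enter the consensus set.  `NA` means
#'   "all sources" (strict intersection).
#' @param random_seed Integer seed governing every stochastic step.
#' @param tie_method Tie handling for the Cox partial likelihood; only
#'   `"breslow"` is supported.
#' @param case_class Optional string naming the case (tumor) class token;
#'   when `NULL` the case class must be declared on each study matrix.
#'
#' @return An object of class `pipeline_config` (a named list).
#' @seealso [write_config()], [read_config()]
#' @examples
#' cfg <- pipeline_config()
#' cfg$n_permutations
#' @export
pipeline_config <- function(mean_filter_frac = 0.10,
                            sd_filter_frac = 0.10,
                            n_permutations = 300L,
                            fudge_quantile = 0.5,
                            alpha = 0.05,
                            fdr_method = "bh",
                            min_consensus_sources = NA_integer_,
                            random_seed = 1L,
                            tie_method = "breslow",
                            case_class = NULL) {
  stopifnot(
    is.numeric(mean_filter_frac), length(mean_filter_frac) == 1L,
    mean_filter_frac >= 0, mean_filter_frac < 1,
    is.numeric(sd_filter_frac), length(sd_filter_frac) == 1L,
    sd_filter_frac >= 0, sd_filter_frac < 1,
    is.numeric(n_permutations), length(n_permutations) == 1L,
    n_permutations >= 1, n_permutations == round(n_permutations),
    is.numeric(fudge_quantile), fudge_quantile >= 0, fudge_quantile <= 1,
    is.numeric(alpha), alpha > 0, alpha < 1,
    is.numeric(random_seed), length(random_seed) == 1L
  )
  fdr_method <- match.arg(fdr_method, "bh")
  tie_method <- match.arg(tie_method, "breslow")
  if (!is.na(min_consensus_sources)) {
    stopifnot(min_consensus_sources >= 1,
              min_consensus_sources == round(min_consensus_sources))
    min_consensus_sources <- as.integer(min_consensus_sources)
  }
  structure(list(
    mean_filter_frac = as.numeric(mean_filter_frac),
    sd_filter_frac = as.numeric(sd_filter_frac),
    n_permutations = as.integer(n_permutations),
    fudge_quantile = as.numeric(fudge_quantile),
    alpha = as.numeric(alpha),
    fdr_method = fdr_method,
    min_consensus_sources = min_consensus_sources,
    random_seed = as.integer(random_seed),
    tie_method = tie_method,
    case_class = case_class
  ), class = "pipeline_config")
}

#' Write / read a pipeline configuration
#'
#' Configurations serialize to plain-text YAML and round-trip losslessly.
#'
#' @param config A [pipeline_config()] object.
#' @param path File path.
#' @return `read_config()` returns a `pipeline_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$min_consensus_sources <-
    if (is.na(x$min_consensus_sources)) "all" else x$min_consensus_sources
  if (is.null(x$case_class)) x$case_class <- ""
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  mcs <- x$min_consensus_sources
  if (identical(mcs, "all")) mcs <- NA_integer_
  cc <- x$case_class
  if (is.null(cc) || identical(cc, "")) cc <- NULL
  pipeline_config(
    mean_filter_frac = x$mean_filter_frac,
    sd_filter_frac = x$sd_filter_frac,
    n_permutations = x$n_permutations,
    fudge_quantile = x$fudge_quantile,
    alpha = x$alpha,
    fdr_method = x$fdr_method,
    min_consensus_sources = mcs,
    random_seed = x$random_seed,
    tie_method = x$tie_method,
    case_class = cc
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.null(v)) v <- "<unset>"
    if (is.na(v)[1L] && nm == "min_consensus_sources") v <- "all"
    cat(sprintf("  %-22s %s\n", nm, paste(v, collapse = ", ")))
  }
  invisible(x)
}
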