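# Feature-namespace harmonization across studies and the mean/SD fraction
# filters applied before the integrated analysis.

#' Rename probe-level features to canonical IDs
#'
#' Features are renamed through the map; unmapped features are dropped (and
#' counted in a message, mirroring probe-annotation cleanup where probes
#' that map to no recognized miRNA are removed).  When several source
#' features map to one canonical ID their per-sample values are collapsed
#' to a single row.
#'
#' @param study A [study_matrix()].
#' @param id_map Named character vector (`map[source_id] == canonical_id`),
#'   e.g. from [read_id_map()].
#' @param collapse Collapse rule for multi-probe features: `"mean"`
#'   (default) averages the probe rows; `"maxvar"` keeps the row with the
#'   largest variance.
#' @return A [study_matrix()] on the canonical namespace, with attribute
#'   `n_unmapped`.
#' @export
standardize_ids <- function(study, id_map, collapse = c("mean", "maxvar")) {
  stopifnot(inherits(study, "study_matrix"))
  collapse <- match.arg(collapse)
  src <- rownames(study$values)
  mapped <- src %in% names(id_map)
  n_unmapped <- sum(!mapped)
  if (!any(mapped))
    stop("all features unmapped in study '", study$study_id, "'")
  if (n_unmapped)
    message(study$study_id, ": dropped ", n_unmapped, " unmapped feature(s)")
  m <- study$values[mapped, , drop = FALSE]
  canon <- unname(id_map[rownames(m)])
  if (anyDuplicated(canon)) {
    groups <- split(seq_len(nrow(m)), canon)
    collapsed <- t(vapply(groups, function(rows) {
      if (length(rows) == 1L) return(m[rows, ])
      if (collapse == "mean") return(colMeans(m[rows, , drop = FALSE]))
      vars <- apply(m[rows, , drop = FALSE], 1L, stats::var)
      m[rows[which.max(vars)], ]
    }, numeric(ncol(m))))
    rownames(collapsed) <- names(groups)
    m <- collapsed
  } else {
    rownames(m) <- canon
  }
  out <- study_matrix(m, study$classes, study_id = study$study_id,
                      case_class = study$case_class, pair_id = study$pair_id)
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Restrict studies to their shared features
#'
#' Intersects the canonical feature lists of two or more studies and
#' returns a [meta_dataset()] on the common, sorted feature order.
#'
#' @param studies List of [study_matrix()] objects (>= 2).
#' @return A [meta_dataset()].
#' @export
intersect_features <- function(studies) {
  if (length(studies) < 2L) stop("need >= 2 studies to intersect")
  shared <- Reduce(intersect, lapply(studies, function(s) rownames(s$values)))
  if (!length(shared)) stop("empty feature intersection across studies")
  shared <- sort(shared)
  meta_dataset(lapply(studies, function(s) {
    study_matrix(s$values[shared, , drop = FALSE], s$classes,
                 study_id = s$study_id, case_class = s$case_class,
                 pair_id = s$pair_id)
  }))
}

# drop the `n_drop` features with the lowest cross-study average rank of
# `stat_fun` (per-study row statistic); boundary ties broken by feature ID
.rank_filter <- function(meta, frac, stat_fun) {
  J <- length(meta$feature_ids)
  n_keep <- ceiling((1 - frac) * J)
  n_drop <- J - n_keep
  if (n_keep < 1L) stop("filter would leave zero features")
  if (n_drop == 0L) return(meta)
  stat <- vapply(meta$studies, function(s) stat_fun(s$values), numeric(J))
  avg_rank <- rowMeans(apply(stat, 2L, rank))  # ties -> average rank
  ord <- order(avg_rank, meta$feature_ids)     # deterministic boundary
  keep <- sort(meta$feature_ids[ord[(n_drop + 1L):J]])
  meta_dataset(lapply(meta$studies, function(s) {
    study_matrix(s$values[keep, , drop = FALSE], s$classes,
                 study_id = s$study_id, case_class = s$case_class,
                 pair_id = s$pair_id)
  }))
}

#' Filter low-intensity and low-variation features
#'
#' Two-step fraction filter: (1) rank features within each study by mean
#' expression, average the ranks across studies, and drop the lowest
#' `mean_frac` fraction; (2) repeat on the survivors with per-study SDs and
#' `sd_frac`.  The retained count after each step is
#' `ceiling((1 - frac) * n)`.  Boundary ties are resolved by feature-ID
#' lexicographic order for determinism.
#'
#' @param meta A [meta_dataset()].
#' @param mean_frac,sd_frac Fractions in `[0, 1)` to drop at each step
#'   (default 0.10 each, the published setting).
#' @return The reduced [meta_dataset()] with attribute `funnel`, a
#'   data.frame (`stage`, `n_features`) reporting the filtering funnel.
#' @export
filter_mean_sd <- function(meta, mean_frac = 0.10, sd_frac = 0.10) {
  stopifnot(inherits(meta, "meta_dataset"),
            mean_frac >= 0, mean_frac < 1, sd_frac >= 0, sd_frac < 1)
  n0 <- length(meta$feature_ids)
  out <- .rank_filter(meta, mean_frac, function(v) rowMeans(v))
  n1 <- length(out$feature_ids)
  out <- .rank_filter(out, sd_frac, function(v) apply(v, 1L, stats::sd))
  n2 <- length(out$feature_ids)
  attr(out, "funnel") <- data.frame(
    stage = c("input", "mean_filter", "sd_filter"),
    n_features = c(n0, n1, n2), stringsAsFactors = FALSE)
  out
}
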