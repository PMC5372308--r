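# Consensus target-set intersection across prediction sources and
# hypergeometric over-representation of gene sets.

#' Consensus targets across prediction sources
#'
#' Returns the genes present in at least `min_sources` of the source sets
#' (default: all sources, i.e. the strict intersection), together with the
#' Venn-region counts for every source combination.
#'
#' @param sources A [gene_set_db()] with one set per prediction source.
#' @param min_sources Integer in `[1, n_sources]`; `NA` means all sources.
#' @return An object of class `consensus_targets`: list with `genes`
#'   (sorted consensus list), `membership` (data.frame gene x source
#'   logical matrix plus `n_sources` count) and `venn` (data.frame
#'   `region`, `count` for every non-empty source combination).
#' @export
consensus_targets <- function(sources, min_sources = NA_integer_) {
  stopifnot(inherits(sources, "gene_set_db"))
  ns <- length(sources$sets)
  if (is.na(min_sources)) min_sources <- ns
  if (min_sources < 1 || min_sources > ns)
    stop("`min_sources` must be in [1, ", ns, "]")
  genes <- sort(unique(unlist(sources$sets, use.names = FALSE)))
  memb <- vapply(sources$sets, function(s) genes %in% s, logical(length(genes)))
  if (is.null(dim(memb))) memb <- matrix(memb, nrow = length(genes))
  counts <- rowSums(memb)
  consensus <- genes[counts >= min_sources]

  region <- apply(memb, 1L, function(row)
    paste(names(sources$sets)[row], collapse = "&"))
  venn <- as.data.frame(table(region), stringsAsFactors = FALSE)
  names(venn) <- c("region", "count")
  venn <- venn[order(venn$region), , drop = FALSE]
  rownames(venn) <- NULL

  membership <- data.frame(gene = genes, memb, n_sources = counts,
                           check.names = FALSE, stringsAsFactors = FALSE)
  structure(list(genes = consensus, membership = membership, venn = venn,
                 min_sources = as.integer(min_sources)),
            class = "consensus_targets")
}

#' @export
print.consensus_targets <- function(x, ...) {
  cat(sprintf("consensus_targets: %d gene(s) in >= %d source(s)\n",
              length(x$genes), x$min_sources))
  print.data.frame(x$venn, row.names = FALSE)
  invisible(x)
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided over-representation: for each set of size `K` in a universe of
#' `N` genes, with a query of size `n` overlapping in `k` genes,
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.  The table is sorted
#' by ascending p; the `significant` flag uses the raw-p cutoff (BH q is
#' reported alongside but does not drive the flag).
#'
#' @param query Character vector of query genes.  Genes outside the DB
#'   universe are dropped with a warning.
#' @param db A [gene_set_db()].
#' @param cutoff Raw-p significance cutoff (default 0.05).
#' @param ease Use the conservative EASE variant (`P(X >= k)` computed with
#'   `k - 1` overlapping genes); default off.
#' @return An object of class `enrichment_table`: data.frame with one row
#'   per set (`set`, `k`, `K`, `n`, `N`, `p_hyper`, `q_bh`, `significant`).
#' @export
hypergeometric_enrichment <- function(query, db, cutoff = 0.05,
                                      ease = FALSE) {
  stopifnot(inherits(db, "gene_set_db"))
  query <- unique(as.character(query))
  outside <- setdiff(query, db$universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped",
            call. = FALSE)
    query <- intersect(query, db$universe)
  }
  if (!length(query)) stop("empty query after universe restriction")
  N <- length(db$universe)
  n <- length(query)
  k <- vapply(db$sets, function(s) length(intersect(s, query)), 0L)
  K <- lengths(db$sets)
  kk <- if (ease) pmax(k - 1L, 0L) else k
  # P(X >= kk) = upper tail of Hypergeometric(N, K, n)
  p <- stats::phyper(kk - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(set = names(db$sets), k = k, K = K, n = n, N = N,
                    p_hyper = p, q_bh = stats::p.adjust(p, method = "BH"),
                    significant = p < cutoff,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_hyper, out$set), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  attr(out, "cutoff") <- cutoff
  out
}

#' @export
print.enrichment_table <- function(x, max_rows = 10L, ...) {
  cat(sprintf("enrichment_table: %d sets, %d significant at raw p < %g\n",
              nrow(x), sum(x$significant), attr(x, "cutoff")))
  print.data.frame(utils::head(as.data.frame(x), max_rows),
                   row.names = FALSE, digits = 4)
  invisible(x)
}
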