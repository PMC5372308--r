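# Readers/writers for the plain-text formats the pipeline touches.
# All tabular output is TSV (never CSV) to avoid locale decimal ambiguity.

#' Read a study expression matrix with its class labels
#'
#' @param path Tab-delimited matrix file: first column feature IDs, first row
#'   sample IDs, log2 values (plain or scientific notation).
#' @param labels_path Two-column TSV (`sample_id`, `class`) mapping every
#'   sample to one of exactly two class tokens.
#' @param study_id Cohort identifier; defaults to the matrix file name.
#' @param case_class Token of the case (tumor) class; see [study_matrix()].
#' @param transpose Set `TRUE` when the file is samples x features.
#' @return A [study_matrix()].
#' @export
read_expression_matrix <- function(path, labels_path,
                                   study_id = NULL, case_class = NULL,
                                   transpose = FALSE) {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("matrix file needs >= 1 sample column: ", path)
  ids <- as.character(raw[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated feature ID(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (transpose) m <- t(m)
  if (anyNA(m)) stop("non-numeric or missing values in ", path)

  lab <- utils::read.delim(labels_path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(lab) < 2L) stop("labels file needs two columns: ", labels_path)
  cls <- as.character(lab[[2L]])
  names(cls) <- as.character(lab[[1L]])
  missing <- setdiff(colnames(m), names(cls))
  if (length(missing))
    stop("sample(s) in matrix missing from labels: ",
         paste(missing, collapse = ", "))
  if (is.null(study_id))
    study_id <- sub("\\.[^.]*$", "", basename(path))
  study_matrix(m, cls[colnames(m)], study_id = study_id,
               case_class = case_class)
}

#' Read / write gene sets in GMT format
#'
#' Each GMT line is `set_name<TAB>description<TAB>gene1<TAB>...`; members are
#' deduplicated, empty sets rejected.
#'
#' @param path File path.
#' @param universe Optional explicit universe (default: union of all sets).
#' @return `read_gmt()` returns a [gene_set_db()]; `write_gmt()` returns
#'   `path` invisibly.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("GMT line ", bad[1L], " has fewer than 3 fields in ", path)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  gene_set_db(sets, universe = universe)
}

#' @rdname read_gmt
#' @param db A [gene_set_db()].
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gmt <- function(db, path, descriptions = NULL) {
  stopifnot(inherits(db, "gene_set_db"))
  if (is.null(descriptions)) descriptions <- rep("na", length(db$sets))
  lines <- mapply(function(nm, desc, genes)
    paste(c(nm, desc, genes), collapse = "\t"),
    names(db$sets), descriptions, db$sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read a probe-to-canonical ID mapping table
#'
#' Two-column TSV (`source_id`, `canonical_id`), one row per source ID.
#' @param path File path.
#' @return Named character vector: `map[source_id] == canonical_id`.
#' @export
read_id_map <- function(path) {
  x <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(x) < 2L) stop("ID map needs two columns: ", path)
  src <- as.character(x[[1L]])
  if (anyDuplicated(src))
    stop("duplicated source ID(s) in map: ",
         paste(unique(src[duplicated(src)]), collapse = ", "))
  stats::setNames(as.character(x[[2L]]), src)
}

#' Read a survival table
#'
#' TSV with columns `time`, `event` (0/1) plus named covariate columns and
#' optionally `marker`.
#' @param path File path.
#' @return A [survival_table()].
#' @export
read_survival_table <- function(path) {
  survival_table(utils::read.delim(path, header = TRUE, check.names = FALSE,
                                   stringsAsFactors = FALSE))
}

# ---- results tables ---------------------------------------------------------

# column used for "descending significance" ordering, per result flavor
.sig_column <- function(df) {
  for (cand in c("p_perm", "p_hyper", "wald_p", "p"))
    if (cand %in% names(df)) return(cand)
  NULL
}

#' Write a results table to TSV
#'
#' Writes any of the pipeline's result objects (integrated-analysis table,
#' enrichment table, Cox fit table, or a plain data.frame) as tab-delimited
#' text: a `#`-prefixed header comment documenting the columns, one header
#' row, then one row per feature/set/covariate.  Numbers carry six
#' significant digits; rows are ordered by ascending p-value with the ID
#' column as tie-break, so repeated runs from the same seed are
#' byte-identical.
#'
#' @param result A `meta_de`, `enrichment_table`, `cox_fit` object or
#'   data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(result, path) {
  df <- as.data.frame(result)
  if (anyNA(df))
    stop("result is incomplete (missing values); refusing to write")
  sig <- .sig_column(df)
  idcol <- names(df)[1L]
  if (!is.null(sig) && nrow(df))
    df <- df[order(df[[sig]], df[[idcol]]), , drop = FALSE]
  num <- vapply(df, is.numeric, TRUE)
  out <- df
  out[num] <- lapply(df[num], function(v) sprintf("%.6g", v))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("# %s: %d row(s)", class(result)[1L], nrow(df)),
    paste0("# columns: ", paste(names(df), collapse = ", "))
  ), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#' @param path File path.
#' @return A data.frame.
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, header = TRUE, comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}
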