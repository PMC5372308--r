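# Diagnostic-marker evaluation: empirical ROC/AUC, the linear-regression
# panel risk score, Pearson correlation, and small quantification formulas
# (relative qPCR expression, xenograft tumor volume).

#' Empirical ROC curve and AUC
#'
#' AUC is the Mann-Whitney probability that a case scores above a control,
#' with ties counted 1/2; the curve is the empirical threshold sweep over
#' the distinct scores.
#'
#' @param scores Numeric per-sample scores.
#' @param labels Two-class tokens, one per sample.
#' @param case_class Token of the positive (case) class; defaults to the
#'   lexicographically larger token.
#' @return An object of class `roc_curve`: list with `thresholds`
#'   (decreasing), `tpr`, `fpr` (both nondecreasing along the sweep, with
#'   the (0,0) and (1,1) endpoints) and `auc`.
#' @export
roc_auc <- function(scores, labels, case_class = NULL) {
  scores <- as.numeric(scores)
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  cls <- sort(unique(labels))
  if (length(cls) != 2L)
    stop("both classes must be present (got ", length(cls), ")")
  if (is.null(case_class)) case_class <- cls[2L]
  pos <- labels == case_class
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("one class absent")
  # midrank form of the Mann-Whitney statistic: exact tie handling
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores[pos] >= t) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores[!pos] >= t) / n0, 0)
  structure(list(thresholds = c(Inf, thr), tpr = c(0, tpr),
                 fpr = c(0, fpr), auc = auc,
                 n_case = n1, n_control = n0),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: AUC = %.4f (%d case vs %d control, %d thresholds)\n",
              x$auc, x$n_case, x$n_control, length(x$thresholds)))
  invisible(x)
}

#' Fit a linear-regression panel risk score
#'
#' Ordinary least squares of a 0/1 class indicator on the log2 marker
#' matrix with intercept, following the published panel construction
#' `risk score = b0 + sum_j b_j E_j` with `E_j` the log2 expression of
#' marker `j`.  Fitted scores are the linear predictor; the apparent
#' (in-sample) AUC is computed via [roc_auc()].
#'
#' @param expression Numeric matrix or data.frame, samples x markers
#'   (log2 values), with marker column names.
#' @param labels Two-class tokens, one per sample.
#' @param case_class Token coded 1 in the indicator; defaults to the
#'   lexicographically larger token.
#' @return An object of class `risk_score_model`: `marker_ids`,
#'   `coefficients` (per marker), `intercept`, `fitted_scores`, `auc`,
#'   `case_class`.  Methods: `print`, `coef`, `predict`.
#' @export
fit_linear_risk_score <- function(expression, labels, case_class = NULL) {
  X <- as.matrix(expression)
  if (is.null(colnames(X))) colnames(X) <- sprintf("marker%d", seq_len(ncol(X)))
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  cls <- sort(unique(labels))
  if (length(cls) != 2L) stop("exactly two classes required")
  if (is.null(case_class)) case_class <- cls[2L]
  y <- as.numeric(labels == case_class)
  if (nrow(X) < ncol(X) + 2L)
    stop("need more samples than markers + 1")
  D <- cbind(`(Intercept)` = 1, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    keep <- qrD$pivot[seq_len(qrD$rank)]
    bad <- setdiff(colnames(D), colnames(D)[keep])
    stop("singular design matrix; collinear marker(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrD, y)
  scores <- drop(D %*% beta)
  structure(list(
    marker_ids = colnames(X),
    coefficients = beta[-1L],
    intercept = unname(beta[1L]),
    fitted_scores = scores,
    auc = roc_auc(scores, labels, case_class = case_class)$auc,
    case_class = case_class
  ), class = "risk_score_model")
}

#' @export
print.risk_score_model <- function(x, digits = 4, ...) {
  terms <- sprintf("%+.*f E_%s", digits, x$coefficients, x$marker_ids)
  cat("risk score =", paste(terms, collapse = " "),
      sprintf("%+.*f", digits, x$intercept), "\n")
  cat(sprintf("  (E_m = log2 expression; apparent AUC = %.4f, case = %s)\n",
              x$auc, x$case_class))
  invisible(x)
}

#' @export
coef.risk_score_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
#' @param newdata Samples x markers matrix with the model's marker columns.
#' @rdname fit_linear_risk_score
predict.risk_score_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$marker_ids, drop = FALSE]
  drop(object$intercept + X %*% object$coefficients)
}

#' Pearson correlation with t-based significance
#'
#' `r` is the sample Pearson coefficient; the two-sided p-value uses
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with nonzero
#'   variance.
#' @return List with `r`, `r2`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  n <- length(x)
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, r2 = r^2, p = p, n = n)
}

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_target,sample - Ct_reference,sample) -
#'         (Ct_target,calibrator - Ct_reference,calibrator)`;
#' the returned fold change is `2^-ddCt`.
#'
#' @param ct_target_sample,ct_reference_sample Ct values in the sample of
#'   interest for the target and the endogenous reference gene.
#' @param ct_target_calibrator,ct_reference_calibrator Ct values in the
#'   calibrator condition.
#' @return Fold change (a single positive number).
#' @export
ddct_relative_expression <- function(ct_target_sample, ct_reference_sample,
                                     ct_target_calibrator,
                                     ct_reference_calibrator) {
  cts <- c(ct_target_sample, ct_reference_sample,
           ct_target_calibrator, ct_reference_calibrator)
  if (any(!is.finite(cts))) stop("Ct values must be finite")
  ddct <- (ct_target_sample - ct_reference_sample) -
    (ct_target_calibrator - ct_reference_calibrator)
  2^(-ddct)
}

#' Xenograft tumor volume
#'
#' `volume = length * width^2 / 2` (mm^3), the standard caliper formula.
#'
#' @param length,width Tumor dimensions in mm (`length >= width` expected;
#'   a warning is issued otherwise and the volume computed anyway).
#' @return Volume in mm^3.
#' @export
tumor_volume <- function(length, width) {
  if (any(length <= 0) || any(width <= 0))
    stop("dimensions must be positive")
  if (any(width > length))
    warning("width exceeds length; computing anyway")
  length * width^2 / 2
}
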