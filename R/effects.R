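# Standardized-mean-difference effect sizes and their fixed-/random-effects
# pooling (inverse-variance, DerSimonian-Laird between-study variance).

#' Hedges' g standardized mean difference
#'
#' `d = (mean(case) - mean(control)) / s_pooled`, corrected by
#' `J = 1 - 3 / (4 (n1 + n2) - 9)` for small-sample bias; the sampling
#' variance is `v = (n1 + n2) / (n1 n2) + g^2 / (2 (n1 + n2))`.
#'
#' @param case,control Numeric vectors (>= 2 values each).
#' @return List with `g` and `v`.
#' @export
hedges_g <- function(case, control) {
  n1 <- length(case); n2 <- length(control)
  stopifnot(n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * stats::var(case) + (n2 - 1) * stats::var(control)) /
    (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled SD: standardized effect undefined")
  d <- (mean(case) - mean(control)) / sqrt(sp2)
  J <- 1 - 3 / (4 * (n1 + n2) - 9)
  g <- J * d
  v <- (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2))
  list(g = g, v = v)
}

#' Pool per-study standardized effects
#'
#' Fixed effect: inverse-variance weighted mean with `w_k = 1/v_k`,
#' `se = 1/sqrt(sum w)`.  Heterogeneity: Cochran's
#' `Q = sum w_k (g_k - mu_fixed)^2` and the DerSimonian-Laird estimator
#' `tau2 = max(0, (Q - (K-1)) / (sum w - sum w^2 / sum w))`.  The random
#' effect re-weights with `w*_k = 1/(v_k + tau2)`;
#' `I2 = max(0, (Q - (K-1))/Q) * 100`.  95% CIs are `estimate +/- 1.96 se`.
#'
#' @param g_list Numeric vector of per-study Hedges' g values.
#' @param v_list Their sampling variances (all > 0).
#' @return List with `mu_fixed`, `se_fixed`, `mu_random`, `se_random`,
#'   `tau2`, `Q`, `I2`, `ci95_low`, `ci95_high` (random-effects CI), `k`.
#' @export
combine_effects <- function(g_list, v_list) {
  g <- as.numeric(g_list); v <- as.numeric(v_list)
  stopifnot(length(g) >= 1, length(g) == length(v))
  if (any(v <= 0)) stop("all effect variances must be > 0")
  r <- .combine_effects_mat(matrix(g, 1L), matrix(v, 1L))
  lapply(r, function(col) col[1L])
}

# vectorized pooling: g, v are features x studies matrices
.combine_effects_mat <- function(g, v) {
  K <- ncol(g)
  w <- 1 / v
  sw <- rowSums(w)
  mu_f <- rowSums(w * g) / sw
  se_f <- 1 / sqrt(sw)
  Q <- rowSums(w * (g - mu_f)^2)
  if (K > 1L) {
    cc <- sw - rowSums(w^2) / sw
    tau2 <- pmax(0, (Q - (K - 1)) / cc)
    I2 <- ifelse(Q > 0, pmax(0, (Q - (K - 1)) / Q) * 100, 0)
  } else {
    tau2 <- rep(0, nrow(g))
    I2 <- rep(0, nrow(g))
  }
  ws <- 1 / (v + tau2)
  sws <- rowSums(ws)
  mu_r <- rowSums(ws * g) / sws
  se_r <- 1 / sqrt(sws)
  list(mu_fixed = mu_f, se_fixed = se_f,
       mu_random = mu_r, se_random = se_r,
       tau2 = tau2, Q = Q, I2 = I2,
       ci95_low = mu_r - 1.96 * se_r,
       ci95_high = mu_r + 1.96 * se_r,
       k = rep(K, nrow(g)))
}

# per-study Hedges g/v for every feature of a study matrix
.hedges_study <- function(study) {
  ci <- case_idx(study); ni <- control_idx(study)
  n1 <- length(ci); n2 <- length(ni)
  X1 <- study$values[, ci, drop = FALSE]
  X0 <- study$values[, ni, drop = FALSE]
  m1 <- rowMeans(X1); m0 <- rowMeans(X0)
  ss1 <- rowSums((X1 - m1)^2); ss0 <- rowSums((X0 - m0)^2)
  sp2 <- (ss1 + ss0) / (n1 + n2 - 2)
  d <- (m1 - m0) / sqrt(sp2)
  J <- 1 - 3 / (4 * (n1 + n2) - 9)
  g <- J * d
  v <- (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2))
  list(g = g, v = v)
}
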