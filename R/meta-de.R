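# Integrated differential-expression core: per-study moderated t with a
# fudge constant, permutation null, Fisher combination of per-study
# p-values, one-sided direction classification, and effect-size pooling.

#' Moderated two-sample t-statistic
#'
#' `t_mod = (mean(case) - mean(control)) / (s_pooled sqrt(1/n1 + 1/n2) + s0)`
#' where `s_pooled` is the pooled within-group SD and `s0 >= 0` the fudge
#' constant stabilizing low-variance features.  At `s0 = 0` this is exactly
#' the pooled-variance Student t.
#'
#' @param case,control Numeric vectors (>= 2 values each).
#' @param s0 Nonnegative fudge constant (log2 units).
#' @return List with `t_mod` and `mean_diff`.
#' @export
moderated_t <- function(case, control, s0 = 0) {
  n1 <- length(case); n2 <- length(control)
  stopifnot(n1 >= 2, n2 >= 2, s0 >= 0)
  sp2 <- ((n1 - 1) * stats::var(case) + (n2 - 1) * stats::var(control)) /
    (n1 + n2 - 2)
  se <- sqrt(sp2) * sqrt(1 / n1 + 1 / n2)
  if (se + s0 == 0)
    stop("zero denominator (constant data and s0 = 0): statistic undefined")
  d <- mean(case) - mean(control)
  list(t_mod = d / (se + s0), mean_diff = d)
}

#' Estimate the fudge constant for one study
#'
#' Returns the given quantile (default: median) of the per-feature
#' standard-error terms `s_pooled sqrt(1/n1 + 1/n2)` across all features of
#' the study.
#'
#' @param study A [study_matrix()].
#' @param quantile Fraction in `[0, 1]`.
#' @return The fudge constant `s0` (a single number, log2 units).
#' @export
estimate_fudge <- function(study, quantile = 0.5) {
  stopifnot(inherits(study, "study_matrix"),
            quantile >= 0, quantile <= 1)
  se <- .study_se(study)
  stats::quantile(se, probs = quantile, names = FALSE)
}

# observed per-feature SE terms of one study
.study_se <- function(study) {
  ci <- case_idx(study); ni <- control_idx(study)
  n1 <- length(ci); n2 <- length(ni)
  X1 <- study$values[, ci, drop = FALSE]
  X0 <- study$values[, ni, drop = FALSE]
  ss <- rowSums((X1 - rowMeans(X1))^2) + rowSums((X0 - rowMeans(X0))^2)
  sqrt(ss / (n1 + n2 - 2)) * sqrt(1 / n1 + 1 / n2)
}

# moderated t for J features under B label assignments
# X: J x n values; ind: n x B 0/1 case-membership indicator (columns share
# the same case count); returns t (J x B), diff, se
.mod_t_mat <- function(X, ind, s0) {
  n <- ncol(X); n1 <- sum(ind[, 1L]); n2 <- n - n1
  S1 <- X %*% ind
  S2 <- rowSums(X) - S1
  Q1 <- (X * X) %*% ind
  Q2 <- rowSums(X * X) - Q1
  ss <- pmax(0, (Q1 - S1^2 / n1) + (Q2 - S2^2 / n2))
  se <- sqrt(ss / (n - 2)) * sqrt(1 / n1 + 1 / n2)
  d <- S1 / n1 - S2 / n2
  list(t = d / (se + s0), diff = d, se = se)
}

# p[j, i] = #{i': A[j, i'] >= A[j, i]} / ncol(A)  (larger value = smaller p).
# Statistics are rounded to 12 significant digits first so that label
# assignments whose statistics are equal in exact arithmetic (e.g. an
# assignment and its mirror under |t|) tie despite last-ulp differences in
# floating-point summation order.
.rank_p_rows <- function(A) {
  A <- signif(A, 12)
  B1 <- ncol(A)
  out <- matrix(0, nrow(A), B1)
  for (j in seq_len(nrow(A)))
    out[j, ] <- (B1 - rank(A[j, ], ties.method = "min") + 1) / B1
  out
}

# all distinct case-label assignments as an n x C indicator matrix,
# plus the column index of the observed assignment
.enumerate_assignments <- function(n, case_cols) {
  combs <- utils::combn(n, length(case_cols))
  ind <- matrix(0, n, ncol(combs))
  ind[cbind(as.vector(combs),
            rep(seq_len(ncol(combs)), each = nrow(combs)))] <- 1
  obs <- which(colSums(ind[case_cols, , drop = FALSE]) == length(case_cols) &
                 colSums(ind) == length(case_cols))
  list(ind = ind, obs_col = obs[1L])
}

# permutation machinery for one study; returns observed and per-round
# p-values in all three tails.  Exact enumeration replaces sampling when
# the number of distinct assignments C <= B (with a warning); the sampled
# stream then draws rounds from the enumerated assignments so observed and
# permuted statistics are measured against the same exact null.
.study_null <- function(study, B, s0) {
  X <- study$values
  n <- ncol(X)
  cc <- case_idx(study)
  C <- choose(n, length(cc))
  if (C <= B) {
    warning("study '", study$study_id, "': ", B,
            " permutations exceed the ", C,
            " distinct label assignments; using exact enumeration",
            call. = FALSE)
    en <- .enumerate_assignments(n, cc)
    st <- .mod_t_mat(X, en$ind, s0)
    P2 <- .rank_p_rows(abs(st$t))
    Pu <- .rank_p_rows(st$t)
    Pd <- .rank_p_rows(-st$t)
    draw <- sample.int(C, B, replace = TRUE)
    list(method = "exact", C = C, s0 = s0,
         t_obs = st$t[, en$obs_col],
         diff_obs = st$diff[, en$obs_col],
         p_two = P2[, en$obs_col], p_up = Pu[, en$obs_col],
         p_down = Pd[, en$obs_col],
         P2_star = P2[, draw, drop = FALSE],
         Pu_star = Pu[, draw, drop = FALSE],
         Pd_star = Pd[, draw, drop = FALSE])
  } else {
    ind_obs <- matrix(0, n, 1L); ind_obs[cc, 1L] <- 1
    obs <- .mod_t_mat(X, ind_obs, s0)
    ind <- matrix(0, n, B)
    for (b in seq_len(B)) ind[sample.int(n, length(cc)), b] <- 1
    st <- .mod_t_mat(X, ind, s0)
    A <- cbind(obs$t[, 1L], st$t)
    P2 <- .rank_p_rows(abs(A))
    Pu <- .rank_p_rows(A)
    Pd <- .rank_p_rows(-A)
    list(method = "sampled", C = C, s0 = s0,
         t_obs = obs$t[, 1L], diff_obs = obs$diff[, 1L],
         p_two = P2[, 1L], p_up = Pu[, 1L], p_down = Pd[, 1L],
         P2_star = P2[, -1L, drop = FALSE],
         Pu_star = Pu[, -1L, drop = FALSE],
         Pd_star = Pd[, -1L, drop = FALSE])
  }
}

#' Permutation null of the per-study moderated t
#'
#' Permutes class labels independently within each study `B` times (the
#' same permutation stream per study is reused across that study's
#' features), recomputes the moderated t, and estimates per-study
#' per-feature p-values as `(1 + #{b: |t*| >= |t_obs|}) / (B + 1)`
#' (one-sided tails use the signed comparison).  When `B` exceeds the
#' number of distinct label assignments of a study, exact enumeration is
#' used instead (with a warning) and p-values lie on the grid
#' `{1/C, ..., 1}`.
#'
#' @param meta A [meta_dataset()].
#' @param B Number of permutation rounds (default 300, the published
#'   setting).
#' @param s0 Optional numeric vector of per-study fudge constants; by
#'   default [estimate_fudge()] at the median.
#' @param seed Integer seed for the permutation streams.
#' @param fudge_quantile Quantile passed to [estimate_fudge()] when `s0` is
#'   not supplied.
#' @return An object of class `permutation_null`: a list with one element
#'   per study carrying `p_two`, `p_up`, `p_down`, `t_obs`, `mean_diff`,
#'   `s0`, `method` (`"sampled"` or `"exact"`) and the per-round p-value
#'   store used for combining.
#' @export
permutation_null <- function(meta, B = 300L, s0 = NULL, seed = 1L,
                             fudge_quantile = 0.5) {
  stopifnot(inherits(meta, "meta_dataset"), B >= 1)
  K <- length(meta$studies)
  if (is.null(s0))
    s0 <- vapply(meta$studies, estimate_fudge, 0, quantile = fudge_quantile)
  s0 <- rep_len(s0, K)
  set.seed(seed)
  out <- vector("list", K)
  for (k in seq_len(K)) {
    nk <- .study_null(meta$studies[[k]], B, s0[k])
    nk$study_id <- meta$studies[[k]]$study_id
    nk$mean_diff <- nk$diff_obs
    out[[k]] <- nk
  }
  names(out) <- names(meta$studies)
  structure(list(studies = out, B = as.integer(B),
                 feature_ids = meta$feature_ids, seed = as.integer(seed)),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("permutation_null: %d studies x %d features, B = %d\n",
              length(x$studies), length(x$feature_ids), x$B))
  for (s in x$studies)
    cat(sprintf("  %-12s method = %-7s s0 = %.4g\n",
                s$study_id, s$method, s$s0))
  invisible(x)
}

#' Fisher's combined statistic
#'
#' `S = sum_k -2 ln(p_k)` over per-study p-values of one feature.  Larger
#' `S` means stronger combined evidence; decreasing any `p_k` strictly
#' increases `S`.
#'
#' @param p_values Per-study probabilities in `(0, 1]`.
#' @return The combined statistic `S` (a single nonnegative number).
#' @export
fisher_combine <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  sum(-2 * log(p))
}

#' Integrated differential-expression analysis
#'
#' The central fit of the pipeline.  For each study, class labels are
#' permuted `B` times and moderated t-statistics recomputed; per-study
#' p-values come from the permutation ranks.  Per feature, the two-sided
#' per-study p-values are combined into Fisher's `S = sum -2 ln p`, whose
#' significance is referenced to the permutation null of `S` pooled across
#' all features (the standard permutation device for genomic integration:
#' pooling gives the p-value granularity `1 / (B * n_features + 1)` that a
#' per-feature count over `B` rounds cannot).  One-sided up- and
#' down-combinations classify direction; a feature significant at `alpha`
#' in exactly one direction, with the sign of the pooled effect agreeing,
#' is called `up` or `down`, and `inconsistent` otherwise.  Per-study
#' Hedges' g effects are pooled under fixed- and random-effects
#' (DerSimonian-Laird) models.
#'
#' @param meta A preprocessed [meta_dataset()].
#' @param config A [pipeline_config()]; supplies `B`, `alpha`, the fudge
#'   quantile and the seed unless overridden.
#' @param B,alpha,seed Optional overrides of the config values.
#' @return An object of class `meta_de` with components `table` (one row
#'   per feature: `feature_id`, `S_obs`, `p_perm`, `q_bh`, `p_up`,
#'   `p_down`, `direction`, `mu_fixed`, `se_fixed`, `mu_random`,
#'   `se_random`, `tau2`, `Q`, `I2`, `ci95_low`, `ci95_high`, `es_p`,
#'   `es_q`), `study_p` (per-study p-value/statistic data frames), `g` and
#'   `v` (features x studies effect matrices), `s0`, `B`, `alpha`, `seed`.
#'   Methods: `print`, `summary`, `coef` (pooled random-effects estimates),
#'   `as.data.frame`.
#' @export
meta_de <- function(meta, config = pipeline_config(),
                    B = config$n_permutations, alpha = config$alpha,
                    seed = config$random_seed) {
  stopifnot(inherits(meta, "meta_dataset"))
  J <- length(meta$feature_ids)
  K <- length(meta$studies)
  if (K < 2L) stop("integrated analysis needs >= 2 studies")

  null <- permutation_null(meta, B = B, seed = seed,
                           fudge_quantile = config$fudge_quantile)
  P2 <- vapply(null$studies, `[[`, numeric(J), "p_two")
  Pu <- vapply(null$studies, `[[`, numeric(J), "p_up")
  Pd <- vapply(null$studies, `[[`, numeric(J), "p_down")

  S_obs <- rowSums(-2 * log(P2))
  S_up <- rowSums(-2 * log(Pu))
  S_down <- rowSums(-2 * log(Pd))
  S2_star <- Reduce(`+`, lapply(null$studies,
                                function(s) -2 * log(s$P2_star)))
  Su_star <- Reduce(`+`, lapply(null$studies,
                                function(s) -2 * log(s$Pu_star)))
  Sd_star <- Reduce(`+`, lapply(null$studies,
                                function(s) -2 * log(s$Pd_star)))

  p_perm <- .pooled_perm_p(S_obs, S2_star)
  p_up <- .pooled_perm_p(S_up, Su_star)
  p_down <- .pooled_perm_p(S_down, Sd_star)
  q_bh <- stats::p.adjust(p_perm, method = "BH")

  g <- vapply(meta$studies, function(s) .hedges_study(s)$g, numeric(J))
  v <- vapply(meta$studies, function(s) .hedges_study(s)$v, numeric(J))
  pool <- .combine_effects_mat(g, v)
  es_z <- pool$mu_random / pool$se_random
  es_p <- 2 * stats::pnorm(-abs(es_z))
  es_q <- stats::p.adjust(es_p, method = "BH")

  sig2 <- p_perm < alpha
  sigu <- p_up < alpha
  sigd <- p_down < alpha
  direction <- rep("ns", J)
  direction[sig2] <- "inconsistent"
  direction[sig2 & sigu & !sigd & pool$mu_fixed > 0] <- "up"
  direction[sig2 & sigd & !sigu & pool$mu_fixed < 0] <- "down"

  tab <- data.frame(
    feature_id = meta$feature_ids,
    S_obs = S_obs, p_perm = p_perm, q_bh = q_bh,
    p_up = p_up, p_down = p_down, direction = direction,
    mu_fixed = pool$mu_fixed, se_fixed = pool$se_fixed,
    mu_random = pool$mu_random, se_random = pool$se_random,
    tau2 = pool$tau2, Q = pool$Q, I2 = pool$I2,
    ci95_low = pool$ci95_low, ci95_high = pool$ci95_high,
    es_p = es_p, es_q = es_q,
    stringsAsFactors = FALSE)

  study_p <- lapply(null$studies, function(s)
    data.frame(feature_id = meta$feature_ids,
               t_mod = s$t_obs, mean_diff = s$mean_diff,
               p_two = s$p_two, p_up = s$p_up, p_down = s$p_down,
               stringsAsFactors = FALSE))

  structure(list(
    table = tab, study_p = study_p, g = g, v = v,
    s0 = vapply(null$studies, `[[`, 0, "s0"),
    method = vapply(null$studies, `[[`, "", "method"),
    B = null$B, alpha = alpha, seed = as.integer(seed),
    n_features = J, n_studies = K
  ), class = "meta_de")
}

# pooled permutation p: rank each observed S among ALL permuted S values
# (every feature, every round); (1 + #{>= S_obs}) / (N + 1)
.pooled_perm_p <- function(S_obs, S_star) {
  nullv <- sort(as.numeric(S_star))
  N <- length(nullv)
  cnt_lt <- findInterval(S_obs, nullv, left.open = TRUE)  # #{null < S_obs}
  (1 + (N - cnt_lt)) / (N + 1)
}

#' @export
print.meta_de <- function(x, ...) {
  cat(sprintf("Integrated DE analysis: %d features, %d studies, B = %d\n",
              x$n_features, x$n_studies, x$B))
  tb <- table(factor(x$table$direction,
                     levels = c("up", "down", "inconsistent", "ns")))
  cat(sprintf("  direction calls at alpha = %g: up %d, down %d, inconsistent %d, ns %d\n",
              x$alpha, tb[["up"]], tb[["down"]], tb[["inconsistent"]],
              tb[["ns"]]))
  cat(sprintf("  features with BH q < %g: %d\n",
              x$alpha, sum(x$table$q_bh < x$alpha)))
  invisible(x)
}

#' @export
summary.meta_de <- function(object, alpha = object$alpha, ...) {
  tab <- object$table
  fisher_sig <- tab$feature_id[tab$p_perm < alpha]
  es_sig <- tab$feature_id[tab$es_p < alpha]
  out <- list(
    alpha = alpha, B = object$B,
    n_features = object$n_features, n_studies = object$n_studies,
    fisher_significant = fisher_sig,
    effect_significant = es_sig,
    both = intersect(fisher_sig, es_sig),
    up = tab$feature_id[tab$direction == "up"],
    down = tab$feature_id[tab$direction == "down"],
    inconsistent = tab$feature_id[tab$direction == "inconsistent"])
  class(out) <- "summary.meta_de"
  out
}

#' @export
print.summary.meta_de <- function(x, ...) {
  cat(sprintf("Integrated DE summary (alpha = %g, B = %d)\n", x$alpha, x$B))
  cat(sprintf("  combined-p significant: %d\n", length(x$fisher_significant)))
  cat(sprintf("  effect-size significant: %d\n", length(x$effect_significant)))
  cat(sprintf("  intersection of the two routes: %d\n", length(x$both)))
  cat(sprintf("  direction: %d up, %d down, %d inconsistent\n",
              length(x$up), length(x$down), length(x$inconsistent)))
  invisible(x)
}

#' @export
coef.meta_de <- function(object, ...) {
  stats::setNames(object$table$mu_random, object$table$feature_id)
}

#' @export
as.data.frame.meta_de <- function(x, ...) x$table

#' Per-study effect table for one feature (forest-plot content)
#'
#' @param fit A [meta_de()] result.
#' @param feature_id A feature present in the fit.
#' @return Data frame with one row per study (`study`, `g`, `ci_low`,
#'   `ci_high`, `weight`) followed by the pooled fixed- and random-effects
#'   rows; weights are normalized random-effects weights (percent).
#' @export
forest_table <- function(fit, feature_id) {
  stopifnot(inherits(fit, "meta_de"))
  j <- match(feature_id, fit$table$feature_id)
  if (is.na(j)) stop("feature '", feature_id, "' not in fit")
  g <- fit$g[j, ]; v <- fit$v[j, ]
  tau2 <- fit$table$tau2[j]
  w <- 1 / (v + tau2)
  rows <- data.frame(
    study = colnames(fit$g),
    g = g, ci_low = g - 1.96 * sqrt(v), ci_high = g + 1.96 * sqrt(v),
    weight = 100 * w / sum(w), stringsAsFactors = FALSE)
  pooled <- data.frame(
    study = c("pooled_fixed", "pooled_random"),
    g = c(fit$table$mu_fixed[j], fit$table$mu_random[j]),
    ci_low = c(fit$table$mu_fixed[j] - 1.96 * fit$table$se_fixed[j],
               fit$table$ci95_low[j]),
    ci_high = c(fit$table$mu_fixed[j] + 1.96 * fit$table$se_fixed[j],
                fit$table$ci95_high[j]),
    weight = c(100, 100), stringsAsFactors = FALSE)
  rbind(rows, pooled)
}
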