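# Synthetic multi-study expression, survival and target-database generators.
# These emulate the statistical structure the integrated analysis assumes
# (study-specific baseline shifts, heterogeneous feature variances, a
# minority of planted directional DE features, censored survival with a
# marker-dependent hazard) so that every downstream stage is testable
# without any cohort download.  All generators are pure functions of
# (spec, seed) and always return the ground truth alongside the data.

#' Specification of a simulated multi-study expression dataset
#'
#' Defaults are desk-scale stand-ins for the seven curated cohorts
#' (roughly 55 tumor + 55 normal samples each, totalling close to the
#' 387/386 tumor/normal samples of the real corpus).
#'
#' @param n_studies Number of cohorts.
#' @param n_features Number of features (miRNAs) per cohort.
#' @param n_case,n_control Per-study sample counts.
#' @param n_de Number of planted differentially expressed features
#'   (`n_de <= n_features`; all other features have effect exactly 0).
#' @param effect_g Target standardized mean difference of planted features
#'   (unitless; signed per feature).
#' @param frac_up Fraction of planted features upregulated in cases.
#' @param study_shift_sd SD of per-study additive baseline shifts
#'   (log2 units).
#' @param feature_sd_range Length-2 range for the per-feature noise SD
#'   (log2 units).
#' @param tau Between-study SD of true standardized effects (unitless),
#'   entering additively on the standardized scale to match the
#'   random-effects pooling model.
#' @param baseline_range Length-2 range of per-feature baseline means
#'   (log2 units; typical microarray intensities).
#' @param seed Integer seed.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_studies = 7L, n_features = 1000L,
                            n_case = 55L, n_control = 55L,
                            n_de = 50L, effect_g = 1.5, frac_up = 0.5,
                            study_shift_sd = 0.5,
                            feature_sd_range = c(0.3, 1.2),
                            tau = 0.2, baseline_range = c(6, 12),
                            seed = 1L) {
  n_case <- rep_len(as.integer(n_case), n_studies)
  n_control <- rep_len(as.integer(n_control), n_studies)
  stopifnot(
    n_studies >= 1, n_features >= 1,
    all(n_case >= 2), all(n_control >= 2),
    n_de >= 0, n_de <= n_features,
    frac_up >= 0, frac_up <= 1,
    study_shift_sd >= 0, tau >= 0,
    length(feature_sd_range) == 2L, feature_sd_range[1L] > 0,
    feature_sd_range[2L] >= feature_sd_range[1L]
  )
  structure(list(
    n_studies = as.integer(n_studies), n_features = as.integer(n_features),
    n_case = n_case, n_control = n_control, n_de = as.integer(n_de),
    effect_g = effect_g, frac_up = frac_up,
    study_shift_sd = study_shift_sd,
    feature_sd_range = as.numeric(feature_sd_range),
    tau = tau, baseline_range = as.numeric(baseline_range),
    seed = as.integer(seed)
  ), class = "simulation_spec")
}

#' Simulate a multi-study two-class expression dataset
#'
#' For study `k` and feature `j`, control values are
#' `Normal(mu_j + b_k, sigma_j^2)` and case values
#' `Normal(mu_j + b_k + delta_jk * sigma_j, sigma_j^2)` with
#' `delta_jk = g_j + Normal(0, tau^2)` for planted features and 0 otherwise;
#' `g_j = +/- effect_g` with signs assigned by `frac_up`.  Effects are
#' planted in units of `sigma_j`, so the realized Hedges' g is comparable
#' across features.  All values are on the log2 scale.
#'
#' @param spec A [simulation_spec()].
#' @return List with components `dataset` (a [meta_dataset()]; classes
#'   `"tumor"`/`"normal"`, case = `"tumor"`) and `truth` (data.frame with
#'   one row per planted feature: `feature_id`, `sign`, `g`, and one
#'   `delta_<study>` column of realized per-study true effects).
#' @export
simulate_meta_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  J <- spec$n_features; K <- spec$n_studies
  feat <- sprintf("miR-%04d", seq_len(J))
  mu <- stats::runif(J, spec$baseline_range[1L], spec$baseline_range[2L])
  sigma <- stats::runif(J, spec$feature_sd_range[1L],
                        spec$feature_sd_range[2L])
  b <- stats::rnorm(K, 0, spec$study_shift_sd)

  de_idx <- if (spec$n_de > 0) sort(sample.int(J, spec$n_de)) else integer(0)
  n_up <- round(spec$frac_up * spec$n_de)
  sgn <- rep(-1, spec$n_de)
  if (n_up > 0) sgn[seq_len(n_up)] <- 1
  g <- numeric(J)
  g[de_idx] <- sgn * spec$effect_g

  # realized per-study standardized effects (0 for null features)
  delta <- matrix(0, J, K)
  if (length(de_idx))
    delta[de_idx, ] <- g[de_idx] +
      matrix(stats::rnorm(length(de_idx) * K, 0, spec$tau),
             length(de_idx), K)

  studies <- vector("list", K)
  for (k in seq_len(K)) {
    n1 <- spec$n_case[k]; n0 <- spec$n_control[k]
    ctrl <- matrix(stats::rnorm(J * n0, mu + b[k], sigma), J, n0)
    case <- matrix(stats::rnorm(J * n1, mu + b[k] + delta[, k] * sigma,
                                sigma), J, n1)
    vals <- cbind(case, ctrl)
    rownames(vals) <- feat
    colnames(vals) <- sprintf("s%02d_%s%03d", k,
                              rep(c("T", "N"), c(n1, n0)),
                              c(seq_len(n1), seq_len(n0)))
    studies[[k]] <- study_matrix(
      vals, rep(c("tumor", "normal"), c(n1, n0)),
      study_id = sprintf("study%02d", k), case_class = "tumor")
  }

  truth <- data.frame(feature_id = feat[de_idx],
                      sign = sgn, g = g[de_idx],
                      stringsAsFactors = FALSE)
  if (length(de_idx)) {
    dd <- as.data.frame(delta[de_idx, , drop = FALSE])
    names(dd) <- sprintf("delta_study%02d", seq_len(K))
    truth <- cbind(truth, dd)
  }
  list(dataset = meta_dataset(studies), truth = truth)
}

#' Specification of a simulated survival cohort
#'
#' @param n_subjects Number of subjects.
#' @param beta Numeric vector of log-hazard coefficients, one per covariate
#'   column.
#' @param baseline_rate Baseline event rate (events per time unit; > 0).
#' @param censor_rate Rate of independent exponential censoring (>= 0;
#'   0 means no random censoring).
#' @param admin_cutoff Optional administrative censoring time (subjects
#'   still at risk at this time are censored there); `Inf` disables it.
#' @param seed Integer seed.
#' @return An object of class `survival_sim_spec`.
#' @export
survival_sim_spec <- function(n_subjects, beta, baseline_rate = 0.05,
                              censor_rate = 0.02, admin_cutoff = Inf,
                              seed = 1L) {
  stopifnot(n_subjects >= 1, is.numeric(beta), length(beta) >= 1)
  if (baseline_rate <= 0) stop("`baseline_rate` must be > 0")
  if (censor_rate < 0) stop("`censor_rate` must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects), beta = as.numeric(beta),
                 baseline_rate = baseline_rate, censor_rate = censor_rate,
                 admin_cutoff = admin_cutoff, seed = as.integer(seed)),
            class = "survival_sim_spec")
}

#' Simulate a right-censored survival cohort
#'
#' Event times are exponential with hazard
#' `baseline_rate * exp(x %*% beta)`; censoring is independent exponential
#' at `censor_rate` (plus an optional administrative cutoff).  The observed
#' time is the minimum, and `event = 1` iff the event time came first.
#'
#' @param spec A [survival_sim_spec()].
#' @param covariates Numeric matrix or data.frame with `n_subjects` rows and
#'   one column per element of `spec$beta`.
#' @return A [survival_table()] with `time`, `event` and the covariate
#'   columns.
#' @export
simulate_survival_cohort <- function(spec, covariates) {
  stopifnot(inherits(spec, "survival_sim_spec"))
  x <- as.matrix(covariates)
  if (nrow(x) != spec$n_subjects)
    stop("`covariates` must have n_subjects (", spec$n_subjects, ") rows")
  if (ncol(x) != length(spec$beta))
    stop("`covariates` must have one column per beta coefficient")
  if (is.null(colnames(x))) colnames(x) <- sprintf("x%d", seq_len(ncol(x)))
  set.seed(spec$seed)
  rate <- spec$baseline_rate * exp(drop(x %*% spec$beta))
  t_event <- stats::rexp(spec$n_subjects, rate)
  t_cens <- if (spec$censor_rate > 0)
    stats::rexp(spec$n_subjects, spec$censor_rate) else rep(Inf, spec$n_subjects)
  t_cens <- pmin(t_cens, spec$admin_cutoff)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  survival_table(data.frame(time = time, event = event,
                            as.data.frame(x), check.names = FALSE))
}

#' Simulate a multi-source target-prediction database
#'
#' Builds one gene set per prediction source as the planted `core_set` with
#' a `jitter` fraction of random swaps (core members removed, non-core
#' universe members added), so all sources share the core by construction
#' at `jitter = 0`.
#'
#' @param n_sources Number of prediction sources (e.g. 4).
#' @param core_set Character vector of planted consensus target genes
#'   (subset of the universe).
#' @param jitter Fraction in `[0, 1)` of core genes swapped out per source.
#' @param universe_size Size of the gene universe (`gene0001`, ...); ignored
#'   if `universe` is given.
#' @param seed Integer seed.
#' @param universe Optional explicit universe containing `core_set`.
#' @return A [gene_set_db()] with sources named `source1..n` and attribute
#'   `core_set`.
#' @export
simulate_target_db <- function(n_sources, core_set, jitter = 0.2,
                               universe_size = 1000L, seed = 1L,
                               universe = NULL) {
  stopifnot(n_sources >= 1)
  if (jitter < 0 || jitter >= 1) stop("`jitter` must be in [0, 1)")
  if (is.null(universe))
    universe <- sprintf("gene%04d", seq_len(universe_size))
  core_set <- unique(as.character(core_set))
  if (length(core_set) > length(universe))
    stop("core_set larger than the universe")
  if (!all(core_set %in% universe))
    stop("core_set must be a subset of the universe")
  set.seed(seed)
  pool <- setdiff(universe, core_set)
  n_swap <- floor(jitter * length(core_set))
  sets <- lapply(seq_len(n_sources), function(k) {
    if (n_swap == 0L) return(core_set)
    drop <- sample(core_set, n_swap)
    add <- sample(pool, min(n_swap, length(pool)))
    sort(union(setdiff(core_set, drop), add))
  })
  names(sets) <- sprintf("source%d", seq_len(n_sources))
  db <- gene_set_db(sets, universe = universe)
  attr(db, "core_set") <- sort(core_set)
  db
}
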