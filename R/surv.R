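# Prognosis stage: median dichotomization, Kaplan-Meier product-limit
# estimation with Greenwood variance, the two-group log-rank test, and Cox
# proportional-hazards fitting (Newton-Raphson on the Breslow partial
# likelihood) with univariate screening and stepwise selection.

#' Split subjects at the marker median
#'
#' Subjects with marker value `>= median` are labeled `"high"`, the rest
#' `"low"` (the ">= median vs. < median" convention of clinical tables).
#'
#' @param marker Numeric per-subject values (`n >= 2`, not all identical).
#' @return Character vector of `"high"`/`"low"` labels.
#' @export
median_dichotomize <- function(marker) {
  marker <- as.numeric(marker)
  stopifnot(length(marker) >= 2)
  if (length(unique(marker)) == 1L)
    stop("all marker values identical: degenerate split")
  m <- stats::median(marker)
  ifelse(marker >= m, "high", "low")
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times, with
#' censored subjects leaving the risk set after their recorded time;
#' Greenwood standard error `S(t) sqrt(sum d_i / (n_i (n_i - d_i)))`
#' (reported as 0 once the curve reaches 0).
#'
#' @param table A [survival_table()] (or data.frame with `time`, `event`).
#' @return An object of class `km_curve`: data.frame with one row per
#'   distinct event time (`time`, `n_risk`, `n_event`, `survival`,
#'   `greenwood_se`), plus attributes `n` and `n_events`.
#' @export
km_estimate <- function(table) {
  table <- survival_table(as.data.frame(table))
  time <- table$time; event <- table$event
  et <- sort(unique(time[event == 1]))
  n_risk <- vapply(et, function(t) sum(time >= t), 0L)
  n_event <- vapply(et, function(t) sum(time == t & event == 1), 0L)
  surv <- cumprod(1 - n_event / n_risk)
  gw_term <- ifelse(n_risk > n_event,
                    n_event / (n_risk * (n_risk - n_event)), Inf)
  se <- surv * sqrt(cumsum(gw_term))
  se[surv == 0] <- 0
  out <- data.frame(time = et, n_risk = n_risk, n_event = n_event,
                    survival = surv, greenwood_se = se)
  attr(out, "n") <- nrow(table)
  attr(out, "n_events") <- sum(event)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d events, %d event times\n",
              attr(x, "n"), attr(x, "n_events"), nrow(x)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Two-group log-rank test
#'
#' At each distinct event time, observed minus hypergeometric-expected
#' events in group A are summed; the squared sum over the summed
#' hypergeometric variance is referenced to chi-square with 1 df.
#'
#' @param groupA,groupB [survival_table()]s (or data.frames with `time`,
#'   `event`).
#' @return List with `chi2`, `p`, `observed` and `expected` (events in
#'   group A).
#' @export
logrank_test <- function(groupA, groupB) {
  a <- survival_table(as.data.frame(groupA))
  b <- survival_table(as.data.frame(groupB))
  time <- c(a$time, b$time)
  event <- c(a$event, b$event)
  grp <- rep(c(1L, 0L), c(nrow(a), nrow(b)))
  if (sum(event) < 1) stop("no events in either group")
  et <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == 1L)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1L)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V <= 0) stop("zero log-rank variance: no comparable risk sets")
  chi2 <- (O - E)^2 / V
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       observed = O, expected = E)
}

# Breslow partial loglik, score vector and observed information at beta.
# X must already be column-centered by the caller for numerical stability.
.cox_lik <- function(beta, X, time, event) {
  ord <- order(time, decreasing = TRUE)
  Xs <- X[ord, , drop = FALSE]
  ts <- time[ord]; ev <- event[ord]
  p <- ncol(X)
  eta <- drop(Xs %*% beta)
  w <- exp(eta)
  # risk set at an event time = all subjects with time >= t; with the
  # descending sort, that is the cumulative sum up to the END of the tie
  # group containing t
  grp <- cumsum(!duplicated(ts))
  pos_last <- ave(seq_along(ts), grp, FUN = max)
  R0 <- cumsum(w)[pos_last]
  S1 <- apply(Xs * w, 2L, cumsum)
  if (is.null(dim(S1))) S1 <- matrix(S1, nrow = 1L)
  S1r <- S1[pos_last, , drop = FALSE]
  evi <- which(ev == 1L)
  loglik <- sum(eta[evi]) - sum(log(R0[evi]))
  xbar <- S1r / R0
  U <- colSums(Xs[evi, , drop = FALSE] - xbar[evi, , drop = FALSE])
  I <- matrix(0, p, p)
  for (a in seq_len(p)) for (b in a:p) {
    S2ab <- cumsum(Xs[, a] * Xs[, b] * w)[pos_last]
    val <- sum(S2ab[evi] / R0[evi] - xbar[evi, a] * xbar[evi, b])
    I[a, b] <- I[b, a] <- val
  }
  list(loglik = loglik, U = U, I = I)
}

#' Cox proportional-hazards fit
#'
#' Maximizes the Breslow partial likelihood by Newton-Raphson from
#' `beta = 0`; convergence when `max |score| < 1e-8` or the relative
#' log-likelihood change drops below `1e-10`.  Standard errors come from
#' the inverse observed information; per-covariate Wald p-values and the
#' score test at `beta = 0` (which for a single tie-free binary covariate
#' equals the log-rank statistic) are reported.  Monotone likelihood
#' (perfect separation) is flagged when any `|beta| > 20`.
#'
#' @param table A [survival_table()] (or data.frame with `time`, `event`
#'   and covariate columns).
#' @param covariate_names Character vector of covariate columns to fit; an
#'   empty vector returns the null model.
#' @param max_iter Newton-Raphson iteration cap (error beyond it).
#' @return An object of class `cox_fit`: `coefficients` data.frame
#'   (`covariate`, `beta`, `se`, `hr`, `ci_low`, `ci_high`, `wald_p`),
#'   `loglik`, `loglik_null`, `score_chi2`, `score_p`, `n`, `n_events`,
#'   `iter`, `flagged` (separation).  Methods: `print`, `coef`, `confint`.
#' @export
cox_fit <- function(table, covariate_names, max_iter = 50L) {
  table <- survival_table(as.data.frame(table))
  if (sum(table$event) < 1) stop("need >= 1 event")
  covariate_names <- as.character(covariate_names)
  missing <- setdiff(covariate_names, names(table))
  if (length(missing))
    stop("covariate(s) not in table: ", paste(missing, collapse = ", "))
  p <- length(covariate_names)
  n <- nrow(table)

  if (p == 0L) {
    nul <- .cox_lik(0, matrix(0, n, 1L), table$time, table$event)
    return(structure(list(
      coefficients = data.frame(covariate = character(0), beta = numeric(0),
                                se = numeric(0), hr = numeric(0),
                                ci_low = numeric(0), ci_high = numeric(0),
                                wald_p = numeric(0)),
      loglik = nul$loglik, loglik_null = nul$loglik,
      score_chi2 = NA_real_, score_p = NA_real_,
      n = n, n_events = sum(table$event), iter = 0L, flagged = FALSE
    ), class = "cox_fit"))
  }

  X <- as.matrix(table[covariate_names])
  storage.mode(X) <- "double"
  degen <- covariate_names[apply(X, 2L, stats::sd) == 0]
  if (length(degen))
    stop("degenerate (constant) covariate(s): ",
         paste(degen, collapse = ", "))
  X <- sweep(X, 2L, colMeans(X))  # centering leaves beta unchanged

  beta <- rep(0, p)
  fit0 <- .cox_lik(beta, X, table$time, table$event)
  score_chi2 <- drop(t(fit0$U) %*% solve(fit0$I, fit0$U))
  ll_old <- fit0$loglik
  cur <- fit0
  iter <- 0L
  repeat {
    if (max(abs(cur$U)) < 1e-8) break
    iter <- iter + 1L
    if (iter > max_iter)
      stop("Cox fit did not converge in ", max_iter,
           " iterations; last beta = ",
           paste(sprintf("%.4g", beta), collapse = ", "))
    step <- solve(cur$I, cur$U)
    beta <- beta + step
    cur <- .cox_lik(beta, X, table$time, table$event)
    if (abs(cur$loglik - ll_old) <
        1e-10 * (abs(ll_old) + 1e-10)) break
    ll_old <- cur$loglik
  }
  flagged <- any(abs(beta) > 20)
  if (flagged)
    warning("|beta| > 20: monotone likelihood (perfect separation) suspected",
            call. = FALSE)
  se <- sqrt(diag(solve(cur$I)))
  z <- beta / se
  coefs <- data.frame(
    covariate = covariate_names, beta = beta, se = se,
    hr = exp(beta), ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se),
    wald_p = 2 * stats::pnorm(-abs(z)),
    stringsAsFactors = FALSE)
  structure(list(
    coefficients = coefs, loglik = cur$loglik, loglik_null = fit0$loglik,
    score_chi2 = score_chi2,
    score_p = stats::pchisq(score_chi2, df = p, lower.tail = FALSE),
    n = n, n_events = sum(table$event), iter = iter, flagged = flagged
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (Breslow ties): n = %d, events = %d\n",
              x$n, x$n_events))
  if (!nrow(x$coefficients)) {
    cat("  null model (no covariates); loglik =",
        format(x$loglik, digits = 6), "\n")
    return(invisible(x))
  }
  df <- x$coefficients
  df$`HR (95% CI)` <- sprintf("%.3f (%.3f-%.3f)", df$hr, df$ci_low,
                              df$ci_high)
  print.data.frame(df[c("covariate", "beta", "se", "HR (95% CI)", "wald_p")],
                   row.names = FALSE, digits = 4)
  if (x$flagged) cat("  WARNING: possible monotone likelihood (separation)\n")
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) {
  stats::setNames(object$coefficients$beta, object$coefficients$covariate)
}

#' @export
confint.cox_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  cf <- object$coefficients
  out <- cbind(cf$beta - z * cf$se, cf$beta + z * cf$se)
  dimnames(out) <- list(cf$covariate,
                        sprintf("%.1f %%", c((1 - level) / 2,
                                             1 - (1 - level) / 2) * 100))
  out
}

#' @export
as.data.frame.cox_fit <- function(x, ...) x$coefficients

#' Univariate Cox screening
#'
#' Fits one single-covariate Cox model per candidate and returns those with
#' Wald `p < alpha`, alongside the full per-covariate HR/CI/p table.
#'
#' @param table A [survival_table()].
#' @param covariates Character vector of candidate covariate columns.
#' @param alpha Screening level (default 0.05).
#' @return List with `selected` (character vector) and `table` (data.frame
#'   in the covariate/HR/CI/p layout of clinical reports).
#' @export
univariate_screen <- function(table, covariates, alpha = 0.05) {
  covariates <- as.character(covariates)
  if (!length(covariates))
    return(list(selected = character(0),
                table = data.frame(covariate = character(0),
                                   hr = numeric(0), ci_low = numeric(0),
                                   ci_high = numeric(0),
                                   wald_p = numeric(0))))
  rows <- lapply(covariates, function(cv) {
    f <- cox_fit(table, cv)
    f$coefficients[, c("covariate", "hr", "ci_low", "ci_high", "wald_p")]
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(selected = tab$covariate[tab$wald_p < alpha], table = tab)
}

#' Stepwise Cox model selection
#'
#' Forward step: among candidates not yet included, add the one with the
#' smallest Wald `p < p_enter` in the model extended by it.  Backward step:
#' remove the included covariate with the largest Wald `p > p_remove`.
#' Iterate to a fixed point; ties are broken by covariate name for
#' determinism, and a candidate whose addition makes the design singular is
#' skipped.  Follows the clinical-table convention of stepwise addition and
#' removal with Wald-statistic entry/stay rules.
#'
#' @param table A [survival_table()].
#' @param candidate_covariates Character vector (normally pre-screened by
#'   [univariate_screen()]).
#' @param p_enter,p_remove Wald-p entry and removal thresholds (default
#'   0.05 each).
#' @return The final [cox_fit()]; the null model if nothing enters.
#' @export
stepwise_cox <- function(table, candidate_covariates,
                         p_enter = 0.05, p_remove = 0.05) {
  cand <- sort(unique(as.character(candidate_covariates)))
  included <- character(0)
  max_steps <- max(2L * length(cand), 2L)
  for (step in seq_len(max_steps + 1L)) {
    if (step > max_steps)
      stop("stepwise selection oscillated beyond ", max_steps, " iterations")
    changed <- FALSE
    # forward
    pool <- setdiff(cand, included)
    best_p <- Inf; best_cv <- NULL
    for (cv in pool) {
      f <- tryCatch(suppressWarnings(cox_fit(table, c(included, cv))),
                    error = function(e) NULL)
      if (is.null(f)) next
      pv <- f$coefficients$wald_p[f$coefficients$covariate == cv]
      if (is.finite(pv) && pv < p_enter && pv < best_p) {
        best_p <- pv; best_cv <- cv  # pool is sorted: ties keep first name
      }
    }
    if (!is.null(best_cv)) {
      included <- sort(c(included, best_cv))
      changed <- TRUE
    }
    # backward
    repeat {
      if (!length(included)) break
      f <- cox_fit(table, included)
      pv <- f$coefficients$wald_p
      worst <- which(pv > p_remove)
      if (!length(worst)) break
      drop_cv <- f$coefficients$covariate[worst][
        order(-pv[worst], f$coefficients$covariate[worst])][1L]
      included <- setdiff(included, drop_cv)
      changed <- TRUE
    }
    if (!changed) break
  }
  cox_fit(table, included)
}
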