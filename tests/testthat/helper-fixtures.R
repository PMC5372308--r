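# in-code fixtures shared across test files

# tiny deterministic study: J features, n1 cases + n2 controls
toy_study <- function(J = 6, n1 = 4, n2 = 4, seed = 1, study_id = "toy",
                      delta = 0) {
  set.seed(seed)
  vals <- matrix(rnorm(J * (n1 + n2), 8, 1), J, n1 + n2)
  vals[, seq_len(n1)] <- vals[, seq_len(n1)] + delta
  rownames(vals) <- sprintf("f%02d", seq_len(J))
  colnames(vals) <- sprintf("s%02d", seq_len(n1 + n2))
  study_matrix(vals, rep(c("T", "N"), c(n1, n2)), study_id = study_id,
               case_class = "T")
}

# write a study matrix + labels to TSV files; returns the two paths
write_study_files <- function(study, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  m <- file.path(dir, paste0("expr_", study$study_id, ".tsv"))
  l <- file.path(dir, paste0("labels_", study$study_id, ".tsv"))
  df <- data.frame(feature_id = rownames(study$values), study$values,
                   check.names = FALSE)
  write.table(df, m, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = colnames(study$values),
                         class = study$classes),
              l, sep = "\t", quote = FALSE, row.names = FALSE)
  c(matrix = m, labels = l)
}

# brute-force AUC: all case-control pairs, ties counted 1/2
auc_bruteforce <- function(scores, labels, case_class) {
  s1 <- scores[labels == case_class]
  s0 <- scores[labels != case_class]
  tot <- 0
  for (a in s1) for (b in s0)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# hypergeometric upper tail by explicit combinatorial enumeration
hyper_tail_enum <- function(N, K, n, k) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# exhaustive-permutation p-values of the moderated t for one small study:
# plain-formula reimplementation independent of the package internals
perm_p_bruteforce <- function(study, s0) {
  X <- study$values
  n <- ncol(X)
  n1 <- sum(study$classes == study$case_class)
  obs_cases <- which(study$classes == study$case_class)
  combs <- combn(n, n1)
  tstat <- function(cases) {
    apply(X, 1, function(v) {
      a <- v[cases]; b <- v[-cases]
      sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                   (length(a) + length(b) - 2))
      (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)) + s0)
    })
  }
  Tm <- apply(combs, 2, tstat)
  obs_col <- which(apply(combs, 2, function(cc) setequal(cc, obs_cases)))
  t_obs <- Tm[, obs_col]
  list(
    p_two = rowMeans(abs(Tm) >= abs(t_obs)),
    p_up = rowMeans(Tm >= t_obs),
    p_down = rowMeans(Tm <= t_obs),
    C = ncol(combs))
}
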