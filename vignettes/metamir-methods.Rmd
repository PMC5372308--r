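---
title: "Methods: integrated miRNA meta-analysis in metamir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated miRNA meta-analysis in metamir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`metamir` integrates several two-class (tumor vs. paired-normal) miRNA
expression cohorts into one differential-expression call set, then carries
the candidates through diagnostic, prognostic and functional stages. This
vignette is the package's own account of the statistics: the models and
their assumptions, the tunable parameters, what the synthetic-data
generator does and does not emulate, and the numerical choices that an
auditor or maintainer would want written down.

## Input model and preprocessing

Each cohort is a `study_matrix`: a features × samples grid of log2
intensities with a two-class sample annotation. The pipeline assumes the
matrices are already summarized and log2-scaled (no background correction,
quantile normalization or batch correction is attempted — inputs are
expected to have been normalized per cohort upstream). The case class is
declared, never inferred from token names.

Probe-level features are renamed to canonical miRNA identifiers through an
explicit two-column map (`standardize_ids()`); unmapped probes are dropped
and counted. When several probes map to one miRNA the rows are collapsed
by their per-sample **mean** — the package's documented choice where
conventions differ; keeping the maximum-variance row is available via
`collapse = "maxvar"`. Studies are then restricted to their common feature
namespace (`intersect_features()`), intersection **before** filtering.
The order is a design choice: filtering first would let a feature's fate
depend on cohorts that are later dropped from the namespace.

**Mean/SD fraction filter.** `filter_mean_sd()` removes low-intensity and
low-variation features in two steps: features are ranked within each study
by mean expression, ranks are averaged across studies, and the lowest
`mean_frac` fraction is dropped; the procedure repeats on the survivors
with per-study SDs and `sd_frac`. Defaults are 0.10/0.10. The retained
count after each step is `ceiling((1 - frac) * n)`, so the funnel report
is exactly reproducible; boundary ties in the averaged ranks are resolved
by feature-ID lexicographic order so filtering is deterministic. Note that
with the ceiling rule any fraction below 1 retains at least one feature.

## The integrated test

### Moderated t with a fudge constant

Per study and feature,

$$t_{mod} = \frac{\bar x_1 - \bar x_0}
  {s_p \sqrt{1/n_1 + 1/n_0} + s_0},$$

with $s_p$ the pooled within-group SD. The fudge constant $s_0 \ge 0$
(log2 units) prevents features with accidentally tiny variance from
dominating the ranking; `estimate_fudge()` sets it per study to the
**median** of the per-feature standard-error terms, the usual convention
for this family of statistics. The quantile is tunable
(`fudge_quantile`, in [0, 1]); $s_0 = 0$ recovers the Student t exactly.
A feature with constant values in both groups and $s_0 = 0$ has an
undefined statistic and is reported as an error rather than silently
scored.

### Permutation null

Class labels are permuted independently **within each study** — this
preserves study-level baseline shifts, which must not leak into the null —
and one permutation stream per study, governed by the seed, is reused
across all of that study's features. Per-study two-sided p-values use the
rank estimator

$$p = \frac{1 + \#\{b: |t^*_b| \ge |t_{obs}|\}}{B + 1},$$

which counts the observed point, guarantees $p > 0$, and is valid (not
anti-conservative) at any $B$. One-sided tails use the signed comparison.
When a study has at most $B$ distinct label assignments
($\binom{n}{n_1} \le B$), sampling is replaced by exact enumeration (with
a warning) and p-values lie on the grid $\{1/C, \dots, 1\}$.

Two numerical details matter here. First, observed and permuted
statistics are treated **exchangeably**: each permuted statistic receives
a p-value by the same rank rule as the observed one, so the combined
statistics below are identically distributed under the null. Second,
statistics are rounded to 12 significant digits before rank comparison:
a label assignment and its mirror give $|t|$ values equal in exact
arithmetic but differing in the final ulp under floating-point summation
order, and without the rounding such ties are miscounted.

### Fisher combination, pooled null, direction calls

Per feature the per-study two-sided p-values combine into
$S = \sum_k -2 \ln p_k$. The permutation p-value of $S$ is computed
against the null distribution of $S^*$ pooled **across all features**:

$$p_{perm}(j) = \frac{1 + \#\{(b, j'): S^*_{b j'} \ge S_{obs,j}\}}
  {B \cdot J + 1}.$$

Pooling across features is the standard permutation device in genomic
integration and is the reason the default $B = 300$ suffices: a
per-feature count over $B$ rounds cannot produce p-values below
$1/(B+1) \approx 0.003$, which makes FDR control at 0.05 across a
thousand features impossible no matter how strong the signal; the pooled
null has granularity $1/(BJ+1)$. The trade-off is the usual one: all
features share a null, so the estimator assumes permuted statistics are
comparable across features — which the rank-based per-study p-values
guarantee by construction, since each feature's statistics are reduced to
ranks within its own permutation distribution before pooling.

Benjamini–Hochberg q-values over $p_{perm}$ are reported alongside the
raw-α significance rule; both columns are emitted because integrated
studies commonly report raw-α thresholds.

**Direction.** One-sided p-value sets are combined separately for up and
for down. A feature that is two-sided significant at α and one-sided
significant in exactly one direction, with the sign of the fixed-effect
pooled standardized difference agreeing, is called `up` or `down`;
a two-sided-significant feature failing that test (including "both tails
significant", which happens when studies disagree strongly) is
`inconsistent`; everything else is `ns`. Requiring sign agreement is the
package's resolution of an otherwise ambiguous classification rule.

### Effect-size pooling

Per study, Hedges' g:
$d = (\bar x_1 - \bar x_0)/s_p$, $J = 1 - 3/(4(n_1+n_0) - 9)$,
$g = Jd$, $v = (n_1+n_0)/(n_1 n_0) + g^2/(2(n_1+n_0))$. Pooled:
inverse-variance fixed effect; DerSimonian–Laird
$\tau^2 = \max(0, (Q - (K-1))/(\sum w - \sum w^2/\sum w))$; random-effects
re-weighting with $w^*_k = 1/(v_k + \tau^2)$; $I^2 = \max(0, (Q -
(K-1))/Q) \cdot 100$; CIs at $\pm 1.96\,se$. With homogeneous inputs
($Q \le K-1$), $\tau^2 = 0$ and the random-effects estimate equals the
fixed-effects one by construction. `meta_de()` reports both routes —
combined p-values and pooled effects — and their intersection, rather
than committing to one reconciliation rule.

## The synthetic-data generator

`simulate_meta_dataset()` emulates the statistical structure the analysis
assumes, at desk scale: for study $k$ and feature $j$, controls are
$N(\mu_j + b_k, \sigma_j^2)$ and cases
$N(\mu_j + b_k + \delta_{jk}\sigma_j, \sigma_j^2)$, with
$\delta_{jk} = g_j + N(0, \tau^2)$ for planted features and 0 otherwise.
Effects are planted **in units of $\sigma_j$** so the realized Hedges' g
is comparable across features, and between-study heterogeneity enters
additively on the standardized scale — deliberately the same model the
random-effects pooling stage fits, so parameter recovery is well-posed.
Ground truth (which features, which signs, the realized per-study
effects) is always returned, never hidden.

Defaults emulate the integrated corpus: 7 studies of 55 + 55 samples
(the real corpus totals just under 400 per class over seven cohorts),
baseline means uniform on [6, 12] log2 units (typical microarray
intensities), study shifts $b_k \sim N(0, 0.5^2)$ log2 units, feature
SDs uniform on [0.3, 1.2] log2 units, $\tau = 0.2$. The shift and SD
magnitudes are declared constants — no per-study variance estimates are
available to calibrate them against — and are tunable in
`simulation_spec()`.

What the generator does **not** emulate: platform-specific probe
chemistry, intensity-dependent variance, correlated features, miRNA
isoforms, or non-normal heavy tails. Passing tests therefore demonstrate
correctness of the statistical machinery under its stated model, not
robustness to every artifact of real microarray data.

`simulate_survival_cohort()` draws exponential event times with hazard
$\lambda_0 e^{x\beta}$ and independent exponential censoring (an
administrative cutoff is available); `simulate_target_db()` builds one
gene set per prediction source as a planted core plus a jitter fraction
of random swaps, so the all-sources consensus equals the core exactly at
jitter 0.

## Downstream stages

**ROC/AUC** (`roc_auc()`): AUC is the Mann–Whitney probability
$P(\text{case} > \text{control}) + \tfrac12 P(\text{tie})$, computed by
midranks — exact under ties, no smoothing. **Risk score**
(`fit_linear_risk_score()`): ordinary least squares of a 0/1 class
indicator on the log2 marker matrix — a linear, not logistic, model,
matching the published construction; the reported AUC is apparent
(in-sample). Under label permutation the *fixed* score is uninformative
(AUC centers on 1/2); refitting on permuted labels would not be, since
in-sample fitting aligns scores with labels by construction.

**Survival**: the Kaplan–Meier estimator with Greenwood SEs, the
two-group log-rank test, and Cox regression maximizing the **Breslow**
partial likelihood by Newton–Raphson from $\beta = 0$ (convergence at
max |score| < 1e-8 or relative log-likelihood change < 1e-10, 50
iterations at most; covariates are centered internally, which leaves
$\beta$ unchanged but avoids overflow in $e^{x\beta}$). Breslow ties are
the package's choice because they preserve the classical identity that
the score test at $\beta = 0$ for a tie-free binary covariate *is* the
log-rank statistic — an identity the test suite checks to 1e-6 against
the independently implemented log-rank routine. Monotone likelihood
(separation) is flagged at $|\beta| > 20$. Marker dichotomization is
"≥ median → high". Stepwise selection (`stepwise_cox()`) uses Wald-p
entry/removal at 0.05 on candidates pre-screened univariately at 0.05,
ties broken by covariate name, with a singularity guard that skips
candidates making the design degenerate. The pre-screen is not
decorative: it is what keeps noise covariates out of the final model
often enough for selection to be reliable.

**Enrichment**: consensus targets are "present in ≥ `min_sources`
sources", default all sources (strict intersection) — the rule is
explicit and configurable because published consensus counts rarely state
one. Over-representation uses the hypergeometric upper tail
$P(X \ge k)$ via `stats::phyper` (one-sided; the conservative EASE
variant with $k-1$ is a flag, default off). The universe defaults to the
union of the database's sets; enrichment p-values depend strongly on this
choice, so an explicit universe overrides it. The raw-p cutoff (default
0.05) drives the `significant` flag; BH q is reported but not used for
flagging.

## Validation design and problem sizes

The acceptance layer of the test suite validates the pipeline at fixed
study conditions chosen to mirror the integrated design at desk scale:
five cohorts of 20 + 20 samples, 1000 features, 200 permutation rounds
for the error-control and recall checks; effect pooling at
$\tau = 0.2$, $g = 1$ over five cohorts of 30 + 30 (the corpus's minimum
cohort size) with 200 replicates; Cox recovery at $n = 2000$; stepwise
selection over 100 replicates of $n = 500$. These sizes keep the full
suite under a minute on one CPU while leaving Monte-Carlo error well
inside the asserted bands for all but one check (below). Exact
components — enumeration-mode permutation p-values, the all-pairs AUC,
hypergeometric tails up to a universe of 25, the closed-form pooling
identities — are asserted exactly or at 1e-12, against independent
brute-force oracles implemented in the tests themselves, and the
hand-implemented KM/log-rank/Cox routines are additionally cross-checked
against the `survival` package (as `metafor` cross-checks the pooling and
`pROC` the AUC).

## Known limitations

- **DerSimonian–Laird coverage.** With few studies (K = 5) the DL 95% CI
  covers the true pooled effect slightly below nominal — a well-known
  property of the estimator (no Knapp–Hartung adjustment is applied,
  keeping the classical formulation). `scripts/acceptance.R` measures
  the realized coverage at the recovery conditions above; note that a
  200-replicate estimate carries roughly ±1.7 points of Monte-Carlo
  error, so individual runs land a point or two either side of the
  long-run value.
- **Apparent AUC.** Panel AUCs are in-sample and optimistic; the package
  reports them as such and makes no cross-validation claim by default.
- **Permutation granularity.** Per-study p-values cannot go below
  $1/(B+1)$; inference-quality FDR control relies on the pooled combined
  null, not on per-study p-values alone.
- **Independence assumptions.** Studies are treated as independent, and
  the default analysis treats classes as independent groups even when a
  `pair_id` is carried (paired designs are not exploited).
- **Model scope.** No time-dependent covariates, competing risks or
  proportional-hazards diagnostics; no probe-level preprocessing; no live
  target-prediction or pathway-database queries.
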