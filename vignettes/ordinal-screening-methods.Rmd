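---
title: "Methods: screening genes against an ordinal severity scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening genes against an ordinal severity scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pagscreen)
```

## The problem

Clinical severity is often recorded on an ordinal scale — Vonsattel grades
of striatal neurodegeneration in Huntington's disease, tumour stages,
dementia ratings.  Binary disease-vs-control comparisons discard that
structure, and correlation-style analyses over-interpret it by treating a
grade of four as "twice" a grade of two.  `pagscreen` links expression to
severity through a model that uses only the *ordering* of the categories:
per-gene proportional-odds cumulative-link regression.  Genes whose
expression must shift consistently — already at the earliest disease stage
and monotonically through the scale — are called phenotype-associated
genes (PAGs) and ranked by the magnitude of the fitted slope.

## The model

For `k + 1` ordered categories with grades `y ∈ {0, …, k}` and a single
covariate `x` (one gene's log expression),

```
P(Y ≤ i | x) = F(α_i − βx),   i = 1, …, k,
```

with `α_1 < … < α_k` and one shared slope `β` (the proportional-odds
assumption).  The default link `F` is the standard Gaussian CDF, which is
the latent-variable formulation `z* = βx + ε`, `ε ~ N(0, 1)`, with `Y = i`
when `z*` lands between consecutive cut points.  A logistic link is
available through `link = "logit"`.

Two conventions deserve a note:

* **Sign.**  We write the linear predictor as `α_i − βx`, so `β > 0` means
  expression *rises* with severity ("upregulated").  The equivalent
  `α_i + βx` parameterization differs only by the sign of `β`; the
  latent-variable form above is the one most cumulative-link software
  (e.g. `MASS::polr`) uses, and it keeps the up/down vocabulary aligned
  with the slope sign.
* **"Odds".**  Cumulative models are often introduced through
  `odds(Y ≤ i)`, but with a probit link the transform applied to the
  cumulative probability is `Φ⁻¹`, not a log-odds.  We implement the
  standard cumulative-link model with a selectable link and treat the
  odds wording as informal.

## Estimation and inference

The per-gene fit (`ordreg_fit()`) maximizes the multinomial likelihood
directly.  Numerical choices:

* **Ordering constraint.**  Parameters are optimized as the first
  intercept plus log-gaps, which makes the intercept ordering
  unconditional.  Gap underflow (tied intercepts) yields an infinite
  negative log-likelihood rather than an invalid state.
* **Optimizer.**  BFGS with an analytic gradient, followed by Newton
  polishing until the gradient norm falls below `tol = 1e-8` (at most 200
  quasi-Newton iterations).  Initialization is deterministic — link
  quantiles of the marginal category frequencies with `β = 0` — so a
  screen is exactly reproducible.
* **Conditioning.**  The covariate is centred internally (microarray
  log-intensities sit around 6–12, far from zero); estimates and standard
  errors are mapped back to the original scale through the exact Jacobian.
* **Inference.**  Standard errors come from the inverse observed
  information (finite differences of the analytic gradient at the MLE);
  `z = estimate/SE` with two-tailed normal p-values.
* **Degenerate fits.**  Constant-expression genes are refused; separation
  (estimates drifting beyond ±25 on the latent scale, or a non-invertible
  information matrix) is flagged and all p-values for that gene are set to
  1, so such genes can never be called significant.

## Calling, orienting and ranking PAGs

`screen_genes()` fits every row of the matrix and calls a gene a PAG when
the Wald p-values of **all** `k + 1` parameters fall below the threshold
(default `1e-6`).  Reading "all fitted parameters" literally is the strict
interpretation; because a balanced intercept sits near zero on
*standardized* covariates, the rule is only meaningful on natural
expression scales, where intercepts absorb `β·mean(x)` and are far from
zero.  Since it is debatable whether intercept tests belong in the rule,
`all_params = FALSE` restricts it to the slope.  The raw threshold is used
deliberately — no multiplicity correction enters the call — but
BH-adjusted slope p-values are emitted alongside for transparency.

PAGs are split by slope sign into up- and downregulated lists and ranked
by `|β|` within each direction (`split_and_rank()`); ties break by smaller
slope p-value, then lexicographic gene id.  The default clinical mapping
(`default_hd_mapping()`) collapses controls and Vonsattel grades 0–4 into
four ordered levels — controls, grades 0–1, grade 2, grades 3–4.  The
exact collapse used for any given cohort is a documented assumption, not
a fact of the method, which is why it ships as an editable mapping whose
*name order* declares the clinical order (order-violating maps are
rejected).

## The binary comparator and enrichment scores

To contrast the ordinal screen with the conventional two-group analysis,
`moderated_two_group_test()` implements the empirical-Bayes moderated
t-test: per-gene pooled variances are shrunk toward a prior variance
`s0²` with prior df `d0` estimated by a method-of-moments fit on log
variances (`d0` solves `trigamma(d0/2) = var(e) − trigamma(d/2)`), and
the moderated statistic is referred to `d0 + d` df.  With `d0 = 0` it is
exactly the pooled t-test; the implementation reproduces the standard
`limma` prior fit to machine precision on shared inputs (this is verified
in the test suite, where `limma::eBayes` serves as an independent
cross-check, not as the implementation).  DEGs are called on BH-adjusted
p-values (default 0.001).

Over-representation (`enrich()`) is the hypergeometric upper tail over a
user-supplied GMT collection, with the enrichment score defined as the
frequency ratio `(k/n)/(K/N)` — target-list frequency of a term's genes
over background frequency.  Score distributions of two gene lists are
compared with a Welch two-tailed t-test (`compare_score_distributions()`),
reporting means and SDs.  The background defaults to all genes fitted in
the screen; GO-hierarchy propagation is out of scope — sets are taken as
given.

## Epigenome integration

`assign_peaks()` attaches ChIP-seq peaks (BED-like, 0-based half-open,
with MAnorm-style M-values) to genes whose promoter window they overlap.
The window is `[tss − w, tss + w)` with `w = 10000` bp by default —
"within 10 kb of the promoter" is read symmetrically; both the width and
the symmetry are parameters, and strand is recorded but does not alter a
symmetric window.  The H3K9ac score `X1` of a gene is the sum of assigned
M-values; genes without a peak are not candidates.  The orientation of
the M-values (treated minus untreated or the reverse) is asserted by the
data provider.

For candidate genes (upregulated, `X2 > 0`, with at least one promoter
peak) the interaction effect is

```
IE = γ0 + γ1·X1 + γ2·X2 + γ3·X1·X2,
```

standardized across candidates to `IE_Z` and thresholded strictly at
`IE_Z > 0`.  Defaults are `γ0 = 0` (it cannot change the ranking) and
`γ1 = γ2 = γ3 = 1`.  The z-score uses the population SD (divisor `n`); a
sample-SD option exists.  `IE_Z` — and therefore the selected set — is
invariant under any positive affine map of IE, hence under common
positive rescaling of `(γ1, γ2, γ3)` and any `γ0`.  `gamma_robustness()`
quantifies sensitivity beyond that invariance by redrawing
`(γ1, γ2, γ3)` (default independent U(0.5, 2), seedable) 100 times and
reporting the fraction of iterations whose selected set is identical to
the default-γ set.

## What the generators emulate — and what they do not

`simulate_ordinal_cohort()` produces data *exactly* from the cumulative
probit model: a latent severity `s ~ N(0, 1)` is drawn once per sample and
cut at thresholds `τ` to give the shared grade vector; an associated gene
with slope `β` gets expression `x = μ + ρs + √(1 − ρ²)·ε` with
`ρ = β/√(1 + β²)`, which is algebraically the latent relation
`z* = β(x − μ) + ε'` cut at `α_i = τ_i·√(1 + β²)`.  Because the grades are
drawn from their marginal distribution and expression is then drawn
conditionally, the sample is i.i.d. from the joint model and the
prospective MLE estimates exactly the recorded `β`.  (The alternative of
fixing stratum counts — a true case-control design — makes the prospective
probit MLE an approximation whose quality depends on how closely the
stratum fractions match the marginal probabilities; we chose the drawn
design so that parameter-recovery checks are exact statements.  The
conditional-given-grade view is equivalent here: conditioning on a grade
is conditioning on `s` lying between two thresholds.)

Defaults mirror the study design the screen targets: 70 samples with
level probabilities `(0.457, 0.181, 0.181, 0.181)` (32 controls and 38
patients spread over three disease strata), four ordered levels, 4.5%
associated genes, slope magnitudes 1.5–3 with random signs, and gene
means uniform on log2-scale 6–12.  The slope range was chosen so that
truly associated genes are comfortably detectable at `n = 70` under the
strict `p < 1e-6` rule (the suite verifies recall ≥ 0.9 there), while
null calibration is checked independently.

What the generators do **not** emulate: probe-level structure and
normalization artefacts, correlated gene modules (genes are conditionally
independent given the severity factor), heavy-tailed noise, batch
effects, cell-type composition shifts across severity, and missing
grades.  Passing tests therefore certify the statistical machinery under
the model's own assumptions, not robustness to the full messiness of
public microarray compendia.

`simulate_two_groups()` (Gaussian, mean-shifted DE genes) and
`simulate_peak_landscape()` (TSSs spaced far apart, in-window signal
peaks plus out-of-window decoys, truth recorded) play the same role for
the comparator and the integration stages.

## Verification at a glance

The test suite pins every stage to an independent oracle: hand-summed
Gaussian-CDF likelihoods, a dense grid search around the optimum, the
binary-probit reduction at `k = 1`, `MASS::polr` as a cross-check fit,
brute-force definitions of quantile normalization, BH and the
hypergeometric tail, an all-pairs interval scan for peak assignment, and
simulation-based calibration (type-I error, PAG null rate, Wald
coverage).  `scripts/acceptance.R` recomputes the headline numbers from
scratch at fixed problem sizes — 500 cohorts of `n = 1000` for recovery
and coverage, 10⁴ null genes at `n = 70` for calibration — chosen to make
Monte-Carlo noise small relative to the tolerances while keeping a run in
the low minutes on one core.

## Known limitations

* A single covariate per fit: no age/sex adjustment, no multi-gene
  models — deliberately outside scope.
* The strict all-parameters rule depends on the expression scale through
  the intercepts; on mean-centred data use `all_params = FALSE`.
* Wald p-values are asymptotic; at very small `n` or extreme separation
  they are conservative by construction (separated fits report p = 1).
* The moderated test assumes exchangeable gene variances under its
  inverse-χ² prior; strongly clustered variances violate the moments fit.
* Enrichment treats gene sets as flat lists; no ontology structure.
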