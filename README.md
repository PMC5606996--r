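# pagscreen

Screening genes whose expression tracks an **ordinal clinical severity
scale** — not just disease vs. control.

Many clinical measurements are ordered categories: Vonsattel grades of
striatal neurodegeneration in Huntington's disease, tumour stages, dementia
ratings.  Standard differential-expression analysis collapses them to a
binary contrast and loses the progression signal; correlation analysis
over-interprets them as numbers.  `pagscreen` fits, for every gene, a
proportional-odds cumulative-link regression with a probit link

    P(Y ≤ i | x) = Φ(α_i − βx),   i = 1, …, k

where `Y` is the severity category of a sample, `x` the gene's (log)
expression, `α_1 < … < α_k` the category cut points and `β` a single slope
shared across all boundaries (the proportional-odds assumption; the
latent-variable reading is `z* = βx + ε`, `ε ~ N(0,1)`).  Genes whose
fitted parameters are all significant by two-tailed Wald z-tests
(`p < 1e-6` by default) are called **phenotype-associated genes (PAGs)**,
oriented by the sign of `β` (up/down with progression) and ranked by
`|β|` — the rate at which expression changes per severity step.

Around this core the package implements the full analysis pipeline:

* `quantile_normalize()`, `collapse_probes()`, `map_homologs()` — matrix
  preprocessing and cross-species mapping;
* `moderated_two_group_test()` — the empirical-Bayes moderated t-test used
  as the binary disease-vs-control comparator, with `bh_adjust()` and
  `overlap_stats()` for PAG-vs-DEG contrasts;
* `enrich()`, `compare_score_distributions()` — hypergeometric gene-set
  over-representation with enrichment scores `(k/n)/(K/N)`;
* `assign_peaks()`, `h3k9ac_score()`, `interaction_effect()`,
  `gamma_robustness()` — integration of promoter H3K9ac ChIP-seq M-values
  with expression fold-changes through the interaction-effect statistic
  `IE = γ0 + γ1X1 + γ2X2 + γ3X1X2`, z-scored to `IE_Z` with `IE_Z > 0`
  selection;
* `simulate_ordinal_cohort()` and friends — seedable generators that
  produce data exactly from the model, with recorded truth, so every stage
  is testable without downloads;
* a command-line interface (`system.file("cli", "pagscreen.R")`) with
  `simulate`, `screen`, `deg`, `enrich`, `integrate` and `robustness`
  subcommands over TSV/GMT/YAML files.

## Worked example

```r
library(pagscreen)

sim <- simulate_ordinal_cohort(n_genes = 500, n_samples = 70, seed = 42)
pag <- screen_genes(sim$expr, sim$phenotype)
#> screened 500 genes: 500 fitted, 0 constant skipped, 0 non-finite skipped,
#> 0 not converged, 0 separated, 22 PAGs

ranked <- split_and_rank(pag)
head(ranked$up[, c("gene_id", "beta", "se_beta", "p_slope", "p_max", "rank")], 3)
#>      gene_id     beta   se_beta      p_slope        p_max rank
#> 1 gene_00042 2.964845 0.4405341 1.695291e-11 3.805545e-11    1
#> 2 gene_00389 2.744155 0.4650925 3.629829e-09 7.030284e-09    4
#> 3 gene_00032 2.699131 0.4108642 5.051816e-11 9.551189e-11    5
```

The cohort has 70 samples in four ordered severity levels.  Of 500
simulated genes, 22 pass the all-parameters `p < 1e-6` rule — every one a
true simulated association (the generator planted ~22).  `gene_00042`
ranks first among upregulated PAGs: its expression rises by an estimated
`β ≈ 2.96` latent-SD units per unit of log-expression, and `rank` is the
global position by `|β|` across both directions.

A single gene can be examined (or plotted) through the model object:

```r
fit <- ordreg_fit(sim$expr["gene_00005", ], sim$phenotype$grades)
summary(fit)
#> Cumulative-link (proportional-odds) regression, probit link
#> 70 observations, 4 ordered categories
#>          Estimate Std. Error z value Pr(>|z|)
#> alpha1 -0.2672259  1.4095768 -0.1896   0.8496
#> alpha2  0.1661109  1.4117623  0.1177   0.9063
#> alpha3  0.7777782  1.4096178  0.5518   0.5811
#> beta   -0.0014779  0.1492322 -0.0099   0.9921
#> log-likelihood: -93.0325  converged: TRUE
```

This is a null gene: the slope is indistinguishable from zero.  `coef()`,
`vcov()`, `logLik()`, `predict()` (category probabilities), `simulate()`
and `plot()` methods are available on the fit.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "pagscreen",
                               load_package = "installed")'
```
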