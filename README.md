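# lonelybrain

Multimodal population-scale association analysis between trait loneliness —
the binary self-report of often feeling lonely — and three brain-imaging
feature sets: regional gray-matter volumes, resting-state functional-coupling
edges, and white-matter tract microstructure. The package is aimed at
population-neuroscience analysts who work with imaging-derived phenotypes
(already-extracted tabular features, not images) and want the three analysis
arms, the nuisance deconfounding, and a ground-truth simulator in one tested
toolbox.

## What it computes

**Gray matter — hierarchical variance components.** A Bayesian hierarchical
logistic model relates the outcome to 100 atlas regions nested in seven
canonical cortical networks:

    y ~ Bernoulli(p)
    logit(p) = Σ_r x_r β_r + α_men + α_women + α_men_age·age + α_women_age·age
    β_r ~ N(0, σ²_network(r)),   σ_k ~ half-normal(1),   α ~ N(0, 1)

The seven network scales σ_k quantify how much each network, as a coherent
set of regions, explains loneliness; regions are flagged when their 5–95%
highest-density interval excludes zero. Fitting uses the package's built-in
No-U-Turn sampler (C++, analytic gradients, non-centered parameterization);
convergence is reported as split-R̂ with the working criterion R̂ ≤ 1.02. A
sex-stratified variant estimates men's and women's region parameters jointly.

**Functional connectome — dominant PLS mode.** The 4,950 lower-triangle
coupling edges are linked to the ±1-coded label by partial least squares;
with a univariate target the first component's edge weights are exactly the
normalized cross-covariance `normalize(Xᵀy)`. Significance comes from a
1,000-iteration label-permutation null with the add-one p-value
`(1 + #{null ≥ obs}) / (1 + B)`; edge weights are summarized into a 7×7
network-block matrix.

**White matter — tract associations.** Per-tract Pearson (point-biserial) and
Spearman correlations with two-sided p-values, Bonferroni correction at
m = 48 within each family, percentile 5–95% bootstrap intervals (B = 100
resamples), and ranking from strongest to weakest |rho|.

**Synthetic cohorts.** `generate_cohort()` simulates all of the above with
known ground truth: calibrated 13.1% prevalence at n = 38,701, network effect
scales largest for the default network, a planted default-network-dominant
connectivity mode, exact planted fornix-tract correlations, and optional
confound contamination. Every analysis arm is validated against these planted
truths; see `vignettes/methods.Rmd` for the generative details and what they
do and do not emulate.

## Worked example

```r
library(lonelybrain)

# a cohort with one amplified network so the signal is visible at n = 4000
sig <- setNames(rep(0.02, 7), canonical_networks()); sig["Default"] <- 0.3
co <- generate_cohort(generator_config(n = 4000, seed = 101,
                                       sigma_per_network = sig,
                                       fc_mode_strength = 4))
co
#> <lb_cohort> n = 4000 | prevalence = 0.131 | blocks: volumes, fc_edges, fa

# clean each block on the standard nuisance set, then fit the three arms
vol <- deconfound(co$volumes, co$cohort, default_confounds())
fit <- fit_volume_model(vol, co$cohort, chains = 4, tune = 500, draws = 500,
                        seed = 1)
network_ranking(fit)
#> # A tibble: 7 x 5
#>   network    sigma_mean    hpd_low hpd_high  rank
#>   <chr>           <dbl>      <dbl>    <dbl> <int>
#> 1 Default        0.311  0.217        0.395      1
#> 2 Limbic         0.0525 0.00944      0.0908     2
#> 3 Salience       0.0431 0.0000328    0.0734     3
#> 4 SomMot         0.0318 0.00000925   0.0627     4
#> 5 Visual         0.0275 0.0000125    0.0528     5
#> 6 Control        0.0267 0.000258     0.0544     6
#> 7 DorsalAttn     0.0232 0.0000900    0.0472     7

cor(co$truth$beta_region, tidy(fit)$mean[1:100])   # parameter recovery
#> [1] 0.9794

fc <- deconfound(co$fc_edges, co$cohort, default_confounds())
perm <- permutation_test(fc, co$cohort$loneliness, B = 1000, seed = 2)
perm
#> <lb_permutation> observed rho = 0.9431 | B = 1000 | p = 0.000999

fa <- deconfound(co$fa, co$cohort, default_confounds())
ta <- tract_associations(fa, co$cohort$loneliness, bootstrap = 100, seed = 3)
head(tidy(ta)[, c("tract", "pearson_rho", "ci_low", "ci_high", "p_bonferroni")], 3)
#> # A tibble: 3 x 5
#>   tract                              pearson_rho ci_low ci_high p_bonferroni
#>   <chr>                                    <dbl>  <dbl>   <dbl>        <dbl>
#> 1 Fornix (column and body)                0.0741 0.0488  0.0958     0.000130
#> 2 Fornix (cres) / Stria terminalis R      0.0477 0.0235  0.0778     0.123
#> 3 Fornix (cres) / Stria terminalis L      0.0475 0.0252  0.0688     0.128
```

Reading the output: the amplified default network is ranked first by its
posterior variance component (σ ≈ 0.31 against the planted 0.30), region
coefficients correlate 0.98 with the planted truth, the planted connectivity
mode is significant at the add-one floor p = 1/1001, and the three
fornix-system tracts head the tract ranking with their planted effect sizes
(0.06 / 0.05 / 0.05) inside the bootstrap intervals. `autoplot()` methods draw each result
(network sigma intervals, network-block heatmap, permutation null, ranked
tract bars); `run_pipeline(pipeline_config(...))` chains all stages and
writes a results bundle with a manifest.

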