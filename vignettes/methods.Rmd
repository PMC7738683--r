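---
title: "Models and methods behind lonelybrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lonelybrain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

lonelybrain asks one scientific question three ways: how does trait
loneliness — the binary self-report of often feeling lonely — express itself
in gray-matter morphology, in resting-state functional coupling, and in
white-matter microstructure, at population-cohort scale? Each imaging
modality gets the statistical treatment suited to its structure, and a
synthetic-cohort generator with known ground truth makes the whole pipeline
testable without access to restricted population data.

```{r setup, eval = FALSE}
library(lonelybrain)
```

## The hierarchical volume model

Gray matter enters as 100 regional volumes per participant, parcellated by a
100-parcel cortical atlas whose regions group into seven canonical networks
(Visual, SomMot, DorsalAttn, Salience, Limbic, Control, Default). The outcome
model is Bayesian hierarchical logistic regression:

$$y_i \sim \mathrm{Bernoulli}(p_i)$$
$$\mathrm{logit}(p_i) = \textstyle\sum_{r=1}^{100} x_{ir}\,\beta_r
  + \alpha_{men} + \alpha_{women}
  + \alpha_{men\_age}\,\mathrm{age}_i + \alpha_{women\_age}\,\mathrm{age}_i$$

with sex-specific intercepts and age slopes as nuisance terms (each
$\mathcal N(0,1)$; the two intercepts are indexed by sex, i.e. each
participant receives exactly one of them, and age is z-scored). Volumes are
deconfounded and z-scored before entry, so the $\beta_r$ are comparable
log-odds per standard deviation of regional volume.

The region coefficients are partially pooled. In the **network-level** form,
all regions of network $k$ share one scale,
$\beta_r \sim \mathcal N(0, \sigma^2_{k(r)})$: the seven $\sigma_k$ are
variance components that directly quantify how much each network, as a
coherent collection of regions, explains loneliness — in rough analogy to
ANOVA with networks as factors. In the **region-level** form every region has
its own scale $\sigma_r$. In both forms the network covariance is diagonal:
we deliberately model no within-network correlation of coefficients, because
the effect-correlation structure between regions is not something the
variance-component question needs, it is weakly identified at realistic
effect sizes, and the diagonal form is exactly the displayed generative model
the package's synthetic cohorts follow. Users who need correlated-effect
priors should treat that as out of scope here.

Priors: each scale gets a half-normal(1) prior (sampled on the log scale with
the Jacobian included), weakly informative on the logit scale where plausible
per-region effects are well below 1. A prior-predictive check in the test
suite confirms the implied prevalence spans (0, 1) rather than concentrating
at the extremes. The `stratify_sex` variant duplicates the $\beta$ block (and
its scales) per sex and estimates both jointly, as `beta[region,men]` /
`beta[region,women]`.

### Sampling and diagnostics

Posteriors are approximated with the package's own No-U-Turn sampler
(dynamic Hamiltonian Monte Carlo, implemented in C++): slice-based tree
doubling with a generalized U-turn criterion, dual-averaging step-size
adaptation targeting 0.8 acceptance, and a diagonal metric estimated from the
middle half of warmup. The model is parameterized non-centrally
($\beta = \sigma z$, $z \sim \mathcal N(0,1)$), which removes the funnel
geometry that otherwise appears when scales shrink toward zero. Gradients are
analytic and verified against central finite differences to 1e-9 in the test
suite; the posterior itself is cross-checked against an independent Gibbs
implementation (JAGS) on a 10-region toy model.

Defaults are 4 chains x (1,000 warmup + 1,000 retained draws), run
sequentially under R's RNG so one seed fixes the whole fit;
`long_warmup = TRUE` switches to the heavier 4,000-step warmup preset.
Convergence is judged by classic split-$\hat R$ (each chain halved, between-
over within-half variance), with the working criterion $\hat R \le 1.02$;
divergent transitions and maximum-treedepth hits are reported per chain.
Constant chains define $\hat R = 1$ with a warning.

Summaries report the posterior mean and the "5–95% HPD", interpreted as the
90%-mass highest-density interval: the narrowest window of the sorted draws
containing 90% of them. For the symmetric unimodal posteriors this model
produces, it coincides with the 5th–95th percentile interval
(`central_interval()` is available for the literal-percentile reading).
Networks are ranked by posterior mean $\sigma$, descending, with ties broken
by canonical network order so output is deterministic. Regions are flagged
when their interval excludes zero (`threshold_regions()`). Whether a
published scale estimate is a posterior mean or median is generally
ambiguous; the package reports means.

## The connectivity mode

Functional coupling enters as the lower triangle of each participant's
100 x 100 coupling matrix — 4,950 edges, enumerated row-major with $i > j$.
Edges are standardized across participants and deconfounded, so an edge value
of 0 means "average coupling in this cohort", and mode weights read as
deviations from that average. A hierarchical model over edges is unattractive
here (edges do not nest into single networks, and the features are strongly
collinear), so the dominant population mode is extracted with partial least
squares against the label coded +1 (lonely) / −1 (non-lonely), then centered.

With a univariate target, the first PLS component has a closed form: the
x-weights are the normalized feature-by-label cross-covariance
$w \propto X^\top y$. The implementation computes exactly that (and the test
suite enforces it against the formula and against an independent PLS
implementation); the sign is fixed so participant scores correlate
positively with loneliness. Only mode 1 is validated and reported — later
components (via deflation) exist but are unsupported. Edge weights are
back-projected to a 7 x 7 network-block matrix by averaging within each
network-pair cell.

Significance uses a label-permutation null: the connectome is held fixed, the
labels are shuffled B = 1,000 times, the full PLS is refit per shuffle, and
the positively oriented Pearson correlation between scores and shuffled
labels is recorded. The p-value is the add-one formula
$(1 + \#\{\text{null} \ge \text{observed}\})/(1 + B)$ — one-sided, never
exactly zero. Only the single leading mode is tested, so no multiplicity
correction is applied. Deconfounding happens once, before permutation;
re-residualizing per shuffle would not change what the null destroys (the
label-feature link) and would multiply cost by B. Edges are not re-z-scored
after residualization by default (`standardize_after` controls this).

## Tract associations

White matter enters as 48 tract-averaged fractional-anisotropy values (the
ICBM-DTI-81 tract set, which includes the fornix column/body and the
bilateral fornix cres / stria terminalis). No hierarchy suggests itself and
collinearity is mild, so the simplest defensible approach is used: per tract,
the Pearson correlation with the binary label (equal to the point-biserial
correlation) and the Spearman rank correlation, each with two-sided analytic
p-values, Bonferroni-corrected at m = 48 within each statistic family
(linear and rank families are reported side by side, not pooled into m = 96).
Tracts are ranked by |Pearson rho| descending, ties broken by catalog order.

Uncertainty in the effect sizes comes from a percentile bootstrap: B = 100
participant resamples with replacement, Pearson recomputed per tract, and the
5th/95th percentiles of the resampled estimates reported as the 5–95%
interval. Percentile (rather than BCa) matches the interval's plain
definition and is the stable choice at B = 100. A resample that loses an
outcome class is redrawn (logged, with a retry cap). Note a percentile
interval is not guaranteed to contain the point estimate, though in practice
it almost always does here.

## The synthetic cohort generator

`generate_cohort()` produces cohorts from the same generative story the
volume model assumes, with ground truth recorded. Defaults describe the
population conditions the package targets:

* n = 38,701; 47.5% men; age uniform on [40, 69] then z-scored.
* Loneliness prevalence 13.1%: the logistic intercept is calibrated by
  bisection (to 1e-6) so the *expected* prevalence hits the target; the
  realized rate is binomial around it (sd about 0.17 percentage points at
  full n).
* Network effect scales (Default 0.07, Limbic 0.06, DorsalAttn 0.05,
  SomMot 0.04, Visual 0.04, Control 0.03, Salience 0.02): the published
  population posterior means, used as *planted truth*. At these scales the
  signal is weak by construction — recovery tests therefore amplify one
  network (e.g. sigma = 0.3, the "strong-signal" configuration) rather than
  pretending the desk-scale fits could re-estimate 0.07 at small n.
* Volumes are unit-variance with exchangeable within-network correlation 0.3,
  induced by one shared factor per network (feasible for any correlation
  below 1); between-network correlation defaults to zero and is not
  separately configurable.
* The connectivity block is unit Gaussian edge noise plus
  `fc_mode_strength * centered(label) * mode`, where the unit-norm planted
  mode is default-network-dominant (positive within-Default, positive
  within-Visual, negative Visual-to-other, mildly positive Default couplings
  to Limbic/DorsalAttn/SomMot). The default strength 1 is deliberately weak
  (detectable at full cohort size, not at n = 2,000); the planted-mode
  recovery tests use strength 4, chosen by a signal-to-noise calculation:
  the weight estimate $X^\top y$ has signal norm $s\,n\,\mathrm{var}(y_c)$
  against orthogonal noise norm $\sqrt{E\,n\,\mathrm{var}(y_c)}$, and cosine
  similarity 0.8 at n = 2,000 with E = 4,950 edges requires s just above 3.
* Tract FA columns are built as
  $\rho\,\mathrm{std}(y) + \sqrt{1-\rho^2}\,\varepsilon$, which makes the
  population point-biserial correlation exactly $\rho$ (defaults: fornix
  0.06, fornix-cres L/R 0.05, all other tracts 0).
* Optional confound contamination adds `loading * z(confound)` to every
  column of a feature block, giving a known, detectable violation for the
  deconfounding stage to remove.

Per-block sub-seeds are derived from the master seed by stable string
hashing, so the phenotype and volume arms are bit-identical whether or not
the (large) connectivity block is materialized.

What the generator does **not** emulate: spatial autocorrelation of volumes
beyond the network factor, realistic edge-weight distributions (real coupling
matrices are correlation-valued and heavy-tailed, not unit Gaussian),
site-by-feature interactions, non-linear confound effects, missingness, or
any genetic structure. Passing tests therefore demonstrate that the
estimators recover the effects they model, under the model's own assumptions
— not that those assumptions hold in any real cohort.

## Deconfounding

All three feature blocks are cleaned identically: each column is replaced by
its least-squares residual against a design of intercept + z-scored
continuous confounds + one-hot site (first level dropped), then z-scored
(n − 1 denominator). The package residualizes first and standardizes second —
cleaning precedes model entry, and this order leaves columns exactly
unit-variance for the models; `standardize_after = FALSE` gives the other
convention. Residualization is a projection, hence idempotent (tested to
1e-10) and exactly orthogonal to the design (tested to 1e-8 per column).
Rank-deficient designs error out naming the collinear columns. Higher-order
age adjustment is available as polynomial age columns (`age_degree`).

## Problem sizes and numerical choices

The validation suite runs at sizes chosen to make each statistical property
sharp while staying desk-friendly: parameter recovery on ten strong-signal
cohorts at n = 4,000 (4 chains x 500 + 500 per fit); null shrinkage at
n = 2,000 with the full 4 x (1,000 + 1,000) settings; HPD oracle on 1e5
draws; permutation calibration over 200 null replicates at B = 199; bootstrap
coverage over 500 replicates at n = 1,000, B = 100. The full-size n = 38,701
generator default is exercised for prevalence and planted-tract recovery.

Other numerical decisions: bisection bracket for the intercept is
$\mathrm{logit}(t) \pm (\max|\eta| + 1)$, guaranteeing a sign change;
zero-variance feature columns are errors, not silent drops; NUTS maximum
tree depth is 10; the permutation null statistic uses |cor| because the
refitted mode's orientation is arbitrary; JSON/TSV outputs are written in
full double precision so reruns are bit-comparable.

## Known limitations

* The region-level model estimates per-region scales but no within-network
  effect correlations (diagonal covariance by design, see above).
* Split-$\hat R$ is the classic, not rank-normalized, variant; for the
  near-Gaussian posteriors here the difference is immaterial.
* The bundled atlas is a structurally faithful synthetic stand-in (correct
  counts, hemispheres and network assignment scheme), not the public atlas
  release's label table; analyses of real data should load the genuine
  lookup file via `load_atlas(path)`.
* Percentile bootstrap at B = 100 gives interval endpoints with appreciable
  Monte-Carlo noise; increase B for publication-grade intervals.
* PLS components beyond the first are unvalidated; the permutation test
  covers mode 1 only.
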