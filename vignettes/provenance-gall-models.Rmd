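---
title: "Modelling provenance effects on gall abundance with population nonindependence"
author: "provgall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling provenance effects on gall abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(provgall)
```

## The problem

A common-garden provenance trial grows trees from many seed-source
populations (provenances) under identical conditions, so that differences in
the herbivore load carried by each provenance can be attributed to the trees'
genetic origin rather than to their environment. `provgall` implements the
full analysis chain for such a trial: per-shoot counts of cynipid gallwasp
galls are modelled as a function of tree provenance and of provenance-level
phenotypes (spring budburst phenology, diameter growth, stem form), while
explicitly accounting for the fact that provenances are **not statistically
independent replicates** — they share ancestry and exchange migrants, so
their effects on herbivores are expected to covary.

The package covers five stages:

1. a synthetic provenance-trial generator with known ground truth;
2. population-genetic structure: pairwise Weir–Cockerham $F_{ST}$ from
   microsatellites, a Mantel test of isolation by distance, and a
   distance-predicted pseudo-$F_{ST}$ (*GeoF~ST~*) for provenances without
   genotypes;
3. provenance covariance construction (identity, $1-F_{ST}$,
   $1-GeoF_{ST}$);
4. a Bayesian Poisson/Gaussian mixed model sampler supporting
   covariance-structured random effects, a nugget term and an
   observation-level (UNIT) overdispersion term;
5. reporting: variance components, marginal $R^2$, pMCMC, VIF, FDR control,
   prediction curves and survey summaries.

## The count model

For one gall type, the count $y_i$ on shoot record $i$ is modelled as

$$y_i \sim \mathrm{Poisson}(e^{\eta_i}), \qquad
\eta_i = \mathbf{x}_i^\top\beta + u_{\mathrm{prov}[i]} + w_{\mathrm{prov}[i]}
 + z_{\mathrm{zone}[i]} + p_{\mathrm{plot}[i]} + t_{\mathrm{tree}[i]} + e_i,$$

where the fixed effects $\beta$ contain an intercept, a two-level survey-year
factor (treatment contrasts, first year as reference) and optionally the
tree phenotypes; $u \sim N(0, \sigma^2_{\mathrm{prov}} C)$ is the structured
provenance effect with $C$ one of the covariance structures above;
$w$ is the identity-structured provenance *nugget* absorbing provenance
variation beyond that implied by the correlation structure; $z, p, t$ are
iid random intercepts for soil zone, plot and tree; and $e_i$ is the
observation-level UNIT effect capturing overdispersion. For Gaussian
responses (e.g. DBH) the UNIT term is the residual and the link is the
identity.

**Priors.** Fixed effects get $N(0, 10^8)$. Every random-effect variance
gets a scaled $F_{1,1}$ prior with scale 1000 — equivalently a half-Cauchy
with scale $\sqrt{1000}$ on the standard deviation, the heavy-tailed half-t
family recommended for variance components. The UNIT/residual variance gets
an inverse-gamma prior with shape and scale 0.001.

**Sampler.** `fit_glmm()` runs a Metropolis-within-Gibbs scheme written in
C++: (a) the latent log-rates $\eta_i$ are updated one observation at a time
by adaptive random-walk Metropolis (step size tuned towards ~35% acceptance
during burn-in, then frozen for reproducibility); (b) given $\eta$, the fixed
and random location effects are conjugate Gaussian updates, with structured
terms entering through the inverse and Cholesky factor of $C$; (c) the
UNIT/residual variance is a conjugate inverse-gamma update; (d) each
scaled-$F$ variance is updated through the exact inverse-gamma mixture
representation of the half-Cauchy
($\sigma^2 \mid a \sim \mathrm{IG}(\tfrac12, 1/a)$,
$a \sim \mathrm{IG}(\tfrac12, 1/1000)$), which is fully conjugate and
equivalent in distribution to the usual parameter-expansion construction.
The prior implementation is validated by a prior-only sampling mode whose
variance draws are checked against the theoretical $1000 \cdot F_{1,1}$
quantiles.

**Schedules.** The `paper` preset (500 000 iterations, 50 000 burn-in,
thinning 450) is the production schedule; the `desk` preset
(20 000 / 5 000 / 15) gives the same 1000 retained draws and is what the
test-suite calibration runs use. Chains are checked with `glmm_diagnostics()`
(AR-spectral effective sample size and Geweke z).

## Variance partitioning

`variance_components()` computes, per retained draw,

$$\mathrm{comp}_k = \frac{\sigma^2_k}{\sum_j \sigma^2_j}\,(1 - R^2_M),$$

where the sum runs over every random-effect variance including UNIT, and
$R^2_M$ is the marginal $R^2$: the share of latent-scale variance explained
by the fixed effects,
$R^2_M = \sigma^2_f / (\sigma^2_f + \sum_j \sigma^2_j + \sigma^2_d)$ with
$\sigma^2_f$ the variance of the fixed-effect linear predictor over the
observations and $\sigma^2_d$ the distribution-specific variance. For the
log-link Poisson we use the lognormal approximation
$\sigma^2_d = \ln(1/\lambda + 1)$, $\lambda = \exp(\beta_0 + \tfrac12\sum_j
\sigma^2_j)$, the standard choice for this family; for Gaussian models
$\sigma^2_d = 0$. By construction the components of each draw sum to
$1 - R^2_M$ exactly, which the tests assert to $10^{-6}$.

For structured provenance models the provenance signal is reported three
ways: the structured component, the nugget component, and their pooled sum
(`provenance_pooled`), since a single "provenance" value is what the
identity model reports and what structure comparisons need.

## Identifiability of the structured provenance variance

Empirical $F_{ST}$ between tree provenances is small (a few percent), so
$1-F_{ST}$ and $1-GeoF_{ST}$ matrices are close to an all-ones matrix —
nearly rank one, with the constant vector as the dominant eigendirection. A
structured provenance effect along that direction is a common shift of all
provenances and is therefore almost indistinguishable from the intercept.
Two practical consequences, both visible in the package's tests:

- under *zero* true provenance signal the structured variance is only weakly
  identified, and its heavy-tailed prior keeps the posterior mean of the
  structured component well above zero (the identity-model component and
  the nugget, which are identified, do shrink to zero, and the credible
  interval of the structured component reaches down to zero);
- structured models systematically attribute *more* variance to provenance
  than identity models fitted to the same data — the qualitative pattern the
  structure comparison (`compare_structures()`) is designed to expose.

Interpreting the absolute size of a structured provenance component
therefore requires confidence in the covariance model itself; the package
deliberately reports both the identity and structured versions side by side.

## The synthetic trial generator

`generate_origins()`, `simulate_genotypes()`, `simulate_phenotypes()` and
`simulate_gall_counts()` emulate the study conditions of a large oak
provenance trial:

- **Design**: 20 provenances spanning 15° latitude and 34° longitude around
  a trial site at (48.086°N, 0.168°W); 5 soil zones; 2 plots per zone per
  provenance (24 trees planted, 12 surveyed per plot); 10 terminal shoots
  per surveyed tree; surveys in spring (sexual generation galls) and autumn
  (asexual generation) of 2008 and 2009. This yields 200 plots, 4800 planted
  and 2400 surveyed trees, and 24 000 shoot records per survey.
- **Genotypes**: 10 microsatellite loci (6 alleles by default), 30
  individuals per provenance. Provenance allele frequencies are a Gaussian
  process on the log (softmax) scale with an exponential distance-decay
  kernel $\sigma^2 e^{-\rho d}$ ($\rho$ = `ibd_decay`, default 0.002 per km,
  $\sigma = 0.6$), chosen so that pairwise $F_{ST}$ is small (of order
  0.01–0.1) yet detectably increases with distance — a Mantel test at 999
  permutations is significant in nearly all replicates. With `ibd_decay = 0`
  all provenances share one frequency vector and expected $F_{ST}$ is 0.
- **Phenotypes**: budburst is an ordinal 0–5 score generated from a latent
  Gaussian around a provenance mean with a latitudinal cline (default −0.3
  score/degree; southern origins flush earlier), anchored at 1.6 for the
  local provenance; DBH declines with genetic distance from the local
  provenance (default 35 units per unit genetic distance from a baseline of
  115); form is an ordinal 1–10 score around 4.3. Ordinal traits are rounded
  and clipped to their scales, matching how field scores are recorded.
- **Counts**: the generative inverse of the analysis model above, with the
  realised random effects and the generating parameters attached to the
  output for recovery tests, and a YAML sidecar writer for on-disk runs.

What the generator does *not* emulate: parasitoid pressure, multi-year
gallwasp lifecycle feedbacks, spatial autocorrelation *within* the
plantation, and the unbalanced shoot counts present in parts of the real
survey data (synthetic surveys are fully balanced). Passing recovery tests
on this generator therefore demonstrates correctness of the estimation
machinery under the stated model, not robustness to every feature of field
data.

## Numerical choices

- $F_{ST}$ uses the Weir–Cockerham (1984) $\theta$, combining the a, b, c
  variance components as a ratio of sums across alleles and loci (the fstat
  convention). Negative pairwise estimates are retained for the Mantel and
  regression stages (the estimator is unbiased around zero) and clamped to
  $[0, 0.999]$ only when building covariances, so covariances stay in
  $(0, 1]$.
- The $GeoF_{ST}$ regression defaults to raw $F_{ST}$ on raw great-circle km
  (haversine, 6371 km sphere); log-distance and Rousset-linearised
  ($F/(1-F)$) forms are available via `transform`. By default predictions
  replace observed values for genotyped provenances so the matrix is a
  single smooth function of distance; `replace_observed = FALSE` keeps
  observed pairs and only fills the missing provenances.
- The Mantel test is one-sided (greater), matching the isolation-by-distance
  hypothesis, with $p = (1 + \#\{r^\ast \ge r\})/(n_{\mathrm{perm}} + 1)$.
- Covariance matrices failing positive semidefiniteness are repaired by
  clipping negative eigenvalues to zero; the repair is flagged on the
  object, never silent. Repair can push individual entries slightly outside
  $(0, 1]$; the PSD guarantee is what the model requires.
- pMCMC is $\max(2\min(\Pr(>0), \Pr(<0)),\, 2/n_{\mathrm{draws}})$.
- FDR control wraps the BH and BY step-up procedures; in the pipeline the
  adjustment family is each fixed-effect term across the retained gall
  types. Between-year abundance ratios are rendered larger:smaller with the
  larger side rounded to the nearest integer ("16:1"), and "–" when a year's
  mean is zero.
- The prediction curve for a phenotype effect evaluates, per draw,
  $y(x) = \exp(\beta_0 + x\beta_x [+ x^2\beta_{x^2}] + \tfrac12\sum_j
  \sigma^2_j)$ — the last term is the lognormal mean correction for the
  latent random effects. A flag exposes the literal alternative
  $\tfrac12 x \sum_j \sigma^2_j$ for sensitivity only.
- All generators and fits take explicit integer seeds and restore the
  caller's RNG state; a fixed seed reproduces outputs byte-for-byte, which
  the pipeline exploits to make report CSVs bit-identical across reruns
  (their headers carry the tool version, a config hash and the seed).

## Problem sizes used in validation

The calibration suite fits the full 24 000-record single-survey design with
the `desk` schedule: ten replicate seeds for variance-component recovery
(posterior means within ±0.10 of generating proportions and ~95% interval
coverage), and ten replicate seeds for the identity-vs-structured comparison
(structured component at least as large as the identity component in at
least 80% of replicates). Sampler correctness is pinned by exact oracles at
smaller sizes: conjugate closed forms (Gaussian), an independent ML Poisson
fit (log-link, no UNIT term), exhaustive permutation enumeration (Mantel),
and a step-by-step variance-component oracle ($F_{ST}$).

## Known limitations

- The sampler updates latent log-rates one observation at a time; for data
  far larger than this trial a blocked or gradient-based sampler would mix
  faster per second.
- Only Poisson (log) and Gaussian families are provided — no negative
  binomial or zero inflation.
- $GeoF_{ST}$ inherits all the uncertainty of the $F_{ST}$–distance
  regression; with weak isolation by distance the structured covariance is
  close to exchangeable and the caveats above apply with full force.
- No confidence intervals on $\theta$ (e.g. locus bootstrap) are provided.
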