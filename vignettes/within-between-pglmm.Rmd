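---
title: "Separating within- from between-species trait trends with Bayesian phylogenetic mixed models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating within- from between-species trait trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The inference problem

Fossil specimen compilations mix two levels of variation: specimens differ
within a species (through that species' own duration), and species differ
from one another (across the clade's history). A specimen-level regression
of a trait on age or body size pools the two levels into a single
coefficient, and the pooled slope can disagree in size — and even in sign —
with both of the level-specific slopes. For a trait like relative brain size
this matters scientifically: a within-species trend indicates anagenetic
change inside lineages, while a between-species trend indicates change
concentrated at or between speciation events.

`withinphylo` resolves the two levels by within-group centering: each
predictor $x_{ij}$ (specimen $i$, species $j$) is decomposed into the
species mean $\bar{x}_j$ and the deviation $\Delta x_{ij} = x_{ij} -
\bar{x}_j$, and both enter the model as separate regressors. The
decomposition is exact ($\bar{x}_j + \Delta x_{ij} = x_{ij}$), deviations
sum to zero within every species, and the species means are recomputed for
every replicate dataset because resampled ages change them.

## Model and sampler

The canonical model (M1) for log10 cranial capacity is a Gaussian mixed
model with four centered fixed effects (between/within body mass,
between/within time), a phylogenetically structured species intercept
$a \sim N(0, \sigma^2_a A)$, species-specific random slopes for within-time
$u_j \sim N(0, \sigma^2_u)$, and residual $\varepsilon \sim N(0,
\sigma^2_e)$. $A$ is the shared-path covariance of a time-calibrated tree:
entry $(j,k)$ is the root-to-MRCA path length, which is well defined for
non-ultrametric (fossil-tip) trees and needs no resolution of polytomies.
Before fitting, $A$ is divided by the mean of its diagonal and the factor is
retained; this puts $\sigma^2_a$ on the scale of the other variance
components whatever the tree's depth, and makes the heritability below
comparable across trees. If pruning a tree relocates its root, the discarded
root-to-MRCA stem is retained as a root edge and added to every entry of
$A$, so pruning commutes exactly with computing the covariance.

Priors are the standard diffuse choices for this model family: $N(0, 10^8)$
per fixed effect and inverse-gamma with shape and scale $0.01$ on every
variance component, the residual treated like the rest. Fitting is by a
blocked conjugate Gibbs sampler written in C++ (RcppArmadillo): each
iteration draws all location effects jointly from the multivariate-normal
full conditional given the current variances (the mixed-model equations; a
joint block avoids the slow mixing of scalar updates, and no single-site
update path is provided because the joint draw is exact), then each variance
from its inverse-gamma full conditional, using $u^\top A^{-1} u$ for the
phylogenetic block and the residual sum of squares for $\sigma^2_e$. All
randomness flows through R's RNG, so a seed fixes the chain exactly.
Retained draws are the post-burn-in iterations at the thinning interval;
the draw count is exactly `floor((iterations - burn_in)/thinning)`. Two
presets are shipped: `"paper"` (10^6 iterations, 10^4 burn-in, thinning 500)
for full-scale runs and `"desk"` (5×10^4 / 5×10^3 / 10) for interactive
work; all test and acceptance runs use desk-scale or smaller chains
(problem sizes: 25-replicate ensembles of n = 285, and 60-specimen designs
for calibration studies), which effective-sample-size checks show are ample
for this conjugate sampler.

The sampler was validated three ways: against `lme4` REML estimates on
well-identified random-intercept and random-slope designs, against the
closed-form GLS estimator when the variances are held fixed, and against a
brute-force grid integration of the exact posterior on a four-species
problem. The last check matters because it certifies the phylogenetic
variance update — the one component no standard package reproduces exactly.

## Derived statistics

* **pMCMC** — twice the smaller of the posterior probabilities that a
  coefficient is positive or negative; draws equal to zero split evenly;
  floored at $2/N$ so a chain can never report an exact zero.
* **HPD intervals** — shortest interval containing 95% of the sorted draws.
* **Heritability** — $h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_b +
  \sigma^2_e)$ per draw, averaged. Random-slope variances are excluded
  because they contribute nothing at the reference covariate value zero
  (the species mean). The mean-diagonal rescaling of $A$ is what makes this
  quantity meaningful for non-ultrametric trees.
* **Marginal / conditional R²** — per draw, the variance of the fixed-effect
  predictor over (that plus random-effect contributions plus residual);
  random slopes contribute their variance times the mean squared covariate,
  the phylogenetic block its variance times the mean diagonal of $A$ over
  specimens.
* **DIC** — $2\bar{D} - D(\hat\theta)$ with the Gaussian deviance
  conditional on the location effects, evaluated at posterior means of the
  location effects and the residual variance. The conditional (not marginal)
  deviance is used and documented as such; for a single retained draw DIC
  collapses to that draw's deviance.
* **Species slopes** — posterior mean of (fixed within-time coefficient +
  species slope deviation), in log10 units per Myr on the age axis; a
  sign-flip option reports "through time" slopes for display.

## Replicate ensemble and significance rule

One replicate dataset per tree: ages drawn uniformly from each specimen's
chronometric range, controversial specimens assigned uniformly among their
candidate species, missing body masses imputed from the assigned species'
pool. For pools under 20 estimates the default reads "sampled from within
the observed range" literally as a continuous uniform on [min, max]; a
`resample` mode draws the observed values instead, since the wording admits
both. Pools of 20+ are stratified: entries matching the specimen's rock unit
(mapped from its sampled age via ICS stage boundaries, user-overridable) and
biogeographic realm, relaxing to same-unit, then same-realm, then the whole
pool. Replicate seeds derive deterministically from a master seed.

An effect is significant when its pMCMC is at or below 0.05 in at least 95%
of replicate fits, the boundary inclusive on both comparisons. Failed fits
reduce the denominator and are reported; more than 5% failures warns. The
slope–age correlation (per-species slope magnitude against the 95% quantile
of sampled specimen ages, averaged over replicates) excludes species with
ten or fewer specimens by default, mirroring how sparsely sampled species
are usually treated in such displays; magnitudes and the time-directed sign
convention are defaults with signed/age-directed alternatives exposed, since
either convention is defensible.

## The synthetic-data generator

The generator runs the fitted model forward under a scenario grid: time
scenarios A–E (between-only trend, common within trend, both, heterogeneous
within slopes with no between-time effect, heterogeneous slopes around
zero), crossed with body-mass scenarios F–J (the analogous grid). Scenario
"D" is the geometry inferred for hominins — no between-species time effect,
species-specific within-species increase, between-species allometry — and in
that scenario the *apparent* between-species increase emerges from the
phylogenetic effect plus body-mass allometry, which is the point the
centered model has to recover. (In the scenario-letter grid the label "D"
follows the acceptance fixture definition with `beta_time_between = 0`;
a between-trend-plus-heterogeneous-slopes variant is available by overriding
`beta_time_between`.)

Defaults are chosen to emulate the study conditions and to make every effect
comfortably detectable at fixture scale, which the generative parameters of
real data need not be: 18 species, 285 specimens with strongly skewed
per-species counts, 7 Myr clade depth, species durations 0.6–1.8 Myr,
recorded age uncertainty ±0.15 Ma, 65% body-mass missingness (at least one
observed mass per species, as in real compilations), within-time slope
−0.12 log10/Myr with across-species standard deviation ~0.035
(a hominin-like magnitude: order 0.15 log10 units across a long-lived
species), allometric slope 1.0 with species mean masses spread by a recency
trend plus independent scatter (contemporaneous species differ widely in
size), residual 0.05 log10 units, and $h^2 = 0.9$ via $\sigma^2_a = h^2/(1 -
h^2)\,\sigma^2_e$. Replicate trees are branch-length-jittered copies of the
data tree, emulating successive posterior samples; independent random
topologies would destroy the phylogenetic effect they are meant to carry.
Taxonomic ambiguity is assigned only between phylogenetically close species
of similar age and size — specimens are confused between taxa that are
related and look alike — and only when such a candidate exists. The truth
record written next to every fixture includes the realized heritability
computed in the $A$-metric ($a^\top A^{-1} a / S$), since the naive sample
variance of correlated effects is biased downward.

What the generator does **not** emulate: measurement error in cranial
capacity itself, non-uniform age posteriors, correlated taxonomic and
body-mass errors, body-mass estimation error structure (all masses are
treated as exact), and real topological uncertainty (jitter moves node ages,
not clades). Passing tests therefore show the estimator recovers the truth
under the stated generative model, not that any particular empirical
dataset satisfies that model.

## Design choices that were genuinely open

* **Species random intercept.** The model description "(phylogeny) +
  (species : within-time)" can be read with or without an additional iid
  species intercept. Both readings are implemented
  (`pglmm_model(..., species_intercept = TRUE)`), but the default omits it:
  at 18 species the iid intercept and the phylogenetic intercept are only
  weakly identified against each other, the exact posterior moves a
  substantial share of phylogenetic variance into the iid component, and
  heritability is biased downward by ~0.2 as a consequence — behavior
  incompatible with the near-unity heritability this model family reports on
  clade-level fossil data. With the slope-only reading, heritability
  recovery is accurate (verified at generative 0.9 and 0.5).
* **Node-count convention.** Counts include the root and exclude the tip;
  any fixed convention only shifts the log10 covariate by a constant that
  the intercept absorbs.
* **No-time node-count variant.** `M3-notime` keeps the body-mass terms and
  the node count with the phylogenetic effect only, since without a
  within-time term there is no slope block to attach.
* **Predictor treatment.** Centering is applied to log10 body mass and to
  raw age in Ma; predictors are not standardized, and coefficients are
  reported in those units.
* **DIC variant.** Conditional-deviance DIC (see above), documented rather
  than assumed comparable with other software's marginal variants.
* **Uncertainty of the pooled contrast.** The `PGLS-naive` model keeps the
  phylogenetic effect but uses uncentered specimen-level predictors; its
  single time coefficient cannot represent a between-species trend that
  differs from the within-species one, which is the conflation it exists to
  demonstrate.

## Numerical notes and degenerate inputs

The phylogenetic covariance is inverted by Cholesky; if a tree makes it
numerically singular a jitter of $10^{-10}$ times the mean diagonal is added
(and recorded on the fit). The location-update precision matrix gets a tiny
ridge only if its Cholesky fails, which does not occur with positive
variance draws. Degenerate cases behave exactly: a zero-width age range
returns its value; a single-candidate specimen is assigned
deterministically; a single-member species centers to deviation zero; a
single retained draw collapses DIC to that draw's deviance; an empty species
pool is an error naming the species, as is a species absent from the tree.

Two caveats follow from the inverse-gamma(0.01, 0.01) prior. First, it sets
an *absolute* variance scale: for components whose true value is of order
0.001–0.01 (log10 trait units) the prior scale 0.01 is not negligible and
inflates small variance components; heritability recovery is therefore
assessed on unit-order trait variance where the prior is diffuse relative to
the likelihood, and mid-range heritability on the raw log10 scale should be
interpreted knowing this prior pushes it upward. Second, exact invariance of
$h^2$ and $R^2$ under rescaling time holds only in the likelihood-dominated
regime, because rescaling time rescales the slope variance across the
prior's fixed scale; the invariance checks therefore use a modest rescaling
toward larger variances.

## Limitations

Inference at realistic clade sizes (≈18 species) is realization-sensitive:
a single draw of phylogenetic effects can align with time by chance and
produce a between-time signal that is "real" for that clade though absent
from the generative parameters; the replicate-wise significance rule
averages over dating/taxonomic/imputation uncertainty but cannot average
over the clade's single evolutionary history. The sampler covers Gaussian
responses only, and the species random intercept/slope pairs use independent
variances (an unstructured 2×2 covariance is not implemented). Effective
sample sizes are estimated by initial-positive-sequence autocorrelation
sums and fits with any fixed-effect ESS under 200 are flagged.
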