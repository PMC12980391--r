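---
title: "Models and methods behind acutephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind acutephys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The design and the primary model

`acutephys` targets randomized acute-exercise studies with three arms
(endurance exercise EE, resistance exercise RE, non-exercise control
CON) and repeated blood sampling around a single bout: a pre-exercise
draw in everyone, during-exercise draws only where safely possible (EE
and CON), an immediate post draw in all arms, and later draws assigned
by temporal randomization — each participant is randomized to an
*early*, *middle*, *late*, or *all* schedule so the full recovery window
is covered without every participant being sampled at every time. That
randomization produces planned, design-driven missingness that any
analysis must respect.

Every molecular feature is modelled separately as

$$y_{ij} = \mu_{g(i),\,t(j)} + x_{ij}^\top\gamma + u_i + \varepsilon_{ij},
\qquad u_i \sim N(0, \sigma_u^2),\quad
\varepsilon_{ij} \sim N(0, \sigma_e^2 / w_{ij}),$$

a **cell-means** parameterization: one coefficient per observed
group-by-timepoint cell and no intercept, so every scientific hypothesis
is a linear contrast of cell means. The participant random intercept
$u_i$ carries the within-person correlation of repeated draws;
$x_{ij}$ are optional fixed covariates (age, sex, BMI, clinical site,
technical covariates), with continuous covariates mean-centered so the
cell means keep their interpretation; $w_{ij}$ are fixed precision
weights, used for transcript counts only (below).

Three contrast families are built on the cells:

* **difference-in-changes (delta-delta)** — the primary endpoint:
  $(\mu_{EX,t}-\mu_{EX,pre}) - (\mu_{CON,t}-\mu_{CON,pre})$, with
  weights $(+1,-1,-1,+1)$. Whatever is shared with control — circadian
  drift, fasting, venipuncture stress — cancels.
* **group-specific** — $\mu_{g,t}-\mu_{g,pre}$, a descriptive
  within-arm effect size, deliberately not the primary endpoint because
  it confounds exercise with time-of-day.
* **resistance vs endurance** — the difference of the two exercise
  deltas; the control terms cancel algebraically. A `direct = TRUE`
  switch compares the two modes' timepoint means instead, since the
  algebra of this comparison admits both readings.

Inference per contrast uses the REML estimate of
$(\beta, \sigma_u^2, \sigma_e^2)$ and a t reference with
**Satterthwaite** denominator degrees of freedom: the delta method on
$\mathrm{Var}(L\hat\beta)$ over the variance components, with the
component covariance taken as twice the inverse finite-difference
Hessian of the $-2$ restricted log-likelihood. With subgroups as small
as four participants, a normal (Wald z) reference is visibly
anti-conservative; the benchmark below quantifies exactly that.

The REML fit is implemented directly in the package: the ratio
$\theta = \sigma_u^2/\sigma_e^2$ is profiled, every
$V^{-1}$-quantity is computed per participant by Sherman–Morrison
(the random-intercept covariance is block diagonal), and $\theta$ is
optimised on a fixed log-scale grid refined by golden-section search,
which keeps a single fit in the low milliseconds and makes
20,000-replicate operating-characteristic runs practical. The engine is
validated in the test suite against `lmerTest` (coefficients, standard
errors, Satterthwaite df, and p-values agree to at least four decimals
on randomized cases, with and without weights).

**Eligibility.** A feature enters a contrast only if every group in the
contrast has at least three participants with observed values at both
pre-exercise and the contrast timepoint. Ineligible feature-contrast
pairs are excluded both from fitting and from the multiplicity
adjustment.

**Multiplicity.** Benjamini–Hochberg is applied *within* each
contrast-group-tissue-ome-timepoint stratum
(`"contrast|group|tissue|ome|timepoint"` strings make the rule
auditable), never pooled across strata. Missing p-values propagate and
do not count toward a stratum's test number.

**Count data.** Transcript counts get voom-style precision weights: a
first-pass unweighted fit on log-CPM, per-gene square-root residual
standard deviations smoothed against mean log count (lowess, span 0.5),
and each observation weighted by the predicted trend value to the
inverse fourth power at its fitted log-count, clamped to the trend's
support. Weights correlate with `limma::voom`'s above 0.95 on simulated
count tables.

# The synthetic-data generator

The simulator exists so every downstream stage can be tested without
any cohort data. It matches, within each sex-by-group subgroup, exactly
the summaries a repeated-measures analysis is sensitive to: the mean
vector over timepoints, the timepoint covariance, and the marginal
skewness and excess kurtosis.

Margins are generated by **Fleishman polynomials**
$Y = a + bZ + cZ^2 + dZ^3$ ($Z$ standard normal, $a = -c$), whose three
moment equations are solved by damped Newton iteration from a fixed
starting point (deterministic; residual tolerance $10^{-8}$;
infeasible pairs — excess kurtosis below $\gamma_1^2 - 2$ — error out).
Margins are coupled by **Vale–Maurelli intermediate correlations**: the
latent normal correlation solving the cubic that maps latent to
post-transform correlation, found by root bracketing; the resulting
latent correlation matrix is eigenvalue-floored back to positive
definiteness when the mapping pushes it marginally outside. Correctness
is pinned by closed-form moment checks and Monte-Carlo oracles at
$n = 10^5$–$10^6$ in the test suite.

Collection masks follow the blood-draw schedule: everyone has `pre` and
`post10`; the early/middle/late profiles add `post30` / `post3.5h` /
`post24h` respectively and the `all` profile adds all three. Profile
allocation is balanced within subgroup (uniform quarters by default),
and an extra 5% completely-at-random dropout is applied on top. Under
the null every cell expectation is constant over time within subgroup;
alternatives add a standardized shift to the exercise arm's affected
cells.

Three presets (`adipose`, `blood`, `muscle`) span the design space the
analysis must tolerate — subgroup sizes from 4 to 50, skewness up to
|1.5|, excess kurtosis up to 6, within-participant correlation 0.3–0.8,
sex-dependent baseline means. They are configuration, not estimates of
any real cohort. Preset covariances are **compound symmetric**
(exchangeable): the simulator's job is to generate data with the
statistical structure the primary analysis assumes, and the
random-intercept model implies exchangeable within-person correlation;
an AR(1) builder (`ar1_cov()`) is exported for stress-testing the
model's robustness to decaying correlation, where the random-intercept
test becomes conservative for short-lag contrasts (we measured ~2.6%
type-I at nominal 5% under lag-1 testing of an AR-decay preset — a
useful robustness fact, but not the reference condition).

What the generator does *not* emulate: between-feature correlation
(features are iid given the design), assay-level missingness mechanisms
beyond left-censoring and MCAR, batch structure in continuous omes, and
any real cohort's actual moment values (not public). Passing tests
therefore demonstrate correct behaviour *under the stated statistical
structure*, not agreement with any particular dataset.

Two auxiliary generators feed the preprocessing stages:
negative-binomial counts with a decreasing dispersion trend
($\phi = \phi_0 + s/\mu$), log-normal library sizes and an optional
batch fold-change; and multi-platform metabolite tables with shared
RefMet identities, per-platform internal standards at nominal CVs
(log-normal, $\sigma = \sqrt{\log(1 + \mathrm{CV}^2)}$), left-censoring
below a quantile (MNAR) plus MCAR, and a truth record naming the
lower-CV platform per shared identity.

# The strategy benchmark

Six analytic strategies are compared on simulated replicates, each
producing one p-value for the same difference-in-changes hypothesis:

1. `paired_t` — Welch two-sample t on per-participant change scores
   (exercise vs control). "Pairwise t-tests between timepoints" is
   under-specified for a between-group hypothesis; the change-score
   two-sample test is the only version testing the same null.
2. `ols` — cell-means least squares ignoring clustering.
3. `lmm_ri_weighted` — the package's REML random-intercept engine with
   Satterthwaite df, carrying precision weights when the scenario is
   count-valued (for continuous scenarios it coincides with 4).
4. `lmm_ri` — the same without weights.
5. `mmrm_unstructured` — multivariate-normal fit with a fully
   unstructured timepoint covariance: the mean profiled out by GLS and
   the covariance estimated by Fisher scoring on its distinct elements
   with step-halving (warm-started from the pairwise-complete residual
   covariance), **REML by default**. We first implemented plain ML and
   measured its null rejection at ~6.0%: with ~31 participants carrying
   10 cell-mean parameters, ML's downward variance bias is material,
   and the spurious power it buys would scramble any power comparison.
   REML — the standard in repeated-measures practice — measures 5.0%
   under the same null. `reml = FALSE` restores ML. Wald t with
   between-within df (participants minus fixed-effect rank), chosen
   a priori as the reference distribution.
6. `gee_ar1` — Gaussian identity-link GEE with working correlation
   $\alpha^{|t_s - t_t|}$ on the timepoint grid ($\alpha$ by the lag-1
   moment estimator), robust Liang–Zeger sandwich covariance, Wald z.
   **No small-sample correction is applied by default** — deliberately,
   because the small-cluster anti-conservatism of the uncorrected
   sandwich is precisely the phenomenon the benchmark documents; a
   Mancl–DeRouen corrected variant is available.

`run_benchmark()` streams replicates (memory constant in the replicate
count), reports rejection rates with binomial Monte-Carlo standard
errors and the bias of the delta-delta estimate against the planted
truth, counts non-convergent fits without resampling them, and is
deterministic per seed. On the small-subgroup null preset at 20,000
replicates the weighted random-intercept LMM sits near 5% while the
uncorrected AR(1) GEE inflates to roughly 7%; under the default
alternative (0.6 SD at the immediate post-exercise draw in EE) the
ordering is GEE above the weighted LMM above paired t, REML-MMRM, and
far above OLS — the inflation-vs-stability trade-off that motivates a
random-intercept primary analysis. Replicate counts are configurable;
the shipped acceptance runs use 20,000, which one CPU completes in
minutes with the engines above.

`power_two_sample_t()` provides the exact noncentral-t power of the
two-sided two-sample t-test (both rejection tails; `power.t.test`
drops the opposite tail, so the package's value is marginally larger at
small n).

# Preprocessing chains

**Metabolomics / lipidomics** (fixed order, every step logged with
feature counts): average duplicate identifiers (missing-aware
entrywise means) → convert non-positive intensities to missing →
remove features with **more than** 20% missing (exactly 20% survives)
→ impute (feature-space KNN for panels above 12 features: Pearson
similarity over pairwise-complete profiles with at least 3 shared
samples, distance-weighted mean of up to 10 donors observed in the
target sample; half-minimum for panels of 12 or fewer — the boundary
panel of exactly 12 takes the conservative small-panel branch) →
$\log_2(x+1)$ (so intensities in (0,1) keep positive logs) → gated
per-sample median-MAD normalization → PC outlier flags. The
normalization gate runs four Kruskal–Wallis tests (per-sample medians
and upper quartiles, against sex and against sex-by-group); if any has
p < 0.01 the normalization is skipped and the reason recorded, since
sample-level location differences might then be biology. Outlier
detection fences the first PCs of the complete table at multiplier
times the IQR — 5×IQR on 5 PCs for metabolomics, 3×IQR on 3 PCs for
proteomics (the PC count for the metabolomics rule is not pinned by
convention, so it is configurable with 5 as default).

**Platform redundancy**: per platform, the CV of each internal
standard on the raw intensity scale is averaged; a RefMet identity
measured on several platforms keeps the lowest-CV platform's
measurement, with losing platforms recorded. Computing CVs on raw
(pre-log) intensities across all samples follows the reference-standard
reading of the rule.

**RNA-seq**: samples with RIN strictly below 5 are excluded (5.0
survives; missing RIN excludes with a warning); low-expression
filtering defaults to `keep_expressed` — keep genes with CPM above 0.5
in at least 10% of samples — because the verbatim form of the rule
("0.5 or fewer CPM in at least 10% of samples" marking *removal*)
would discard nearly every gene; that literal form ships as
`mode = "literal"` for auditability and both modes log their removals.
TMM factors come from `edgeR::calcNormFactors` (the canonical
implementation); log-CPM uses the explicit closed form
$\log_2((c + 0.5) / (f \cdot \mathrm{lib} + 1) \cdot 10^6)$. Batch
regression jointly fits the protected design (age, sex, and the
group-by-timepoint cells) with the batch columns and subtracts only the
fitted batch component (via `limma::removeBatchEffect`), after a rank
check that refuses batch covariates collinear with the protected
design — the adipose-style failure where assay batch coincides with
exercise modality and "correction" would delete the biology.

# Enrichment

Differential results become a genes-by-contrasts z-score matrix
(estimate/SE when the SE is available — avoiding p-value underflow — or
the signed normal quantile of the two-sided p otherwise, clipped at
$10^{-300}$); where several features map to one gene only the most
extreme z survives, ties keeping the first feature id. Collections are
filtered to sets with at least 5 members in the measured universe *and*
at least 70% of their original membership (both boundaries inclusive).
The competitive test is the parametric correlation-adjusted mean-rank
test: a two-sample comparison of in-set vs out-of-set z with the in-set
variance inflated by $\mathrm{VIF} = 1 + (m-1)\rho$ ($\rho = 0.01$ by
default, configurable) and a t reference on $G - 2$ df; at $\rho = 0$
it reduces exactly to the equal-variance two-sample t-test, and it
matches `limma::cameraPR` to nine decimals in the tests.
Over-representation uses the upper-tail hypergeometric. Both adjust by
BH within each tissue-ome-contrast-collection combination.

# Temporal clustering

Feature trajectories are group-wise per-timepoint means of the
normalized data, z-scored per feature (constant profiles dropped);
mean profiles, rather than subject-level curves, are clustered because
the object of interest is each analyte's shape. Fuzzy c-means uses the
standard Bezdek updates with k-means++ seeding on a deterministic RNG
stream; the objective is asserted non-increasing on every run, and the
near-crisp limit (m → 1) reproduces k-means. The fuzzifier defaults to
the Schwämmle–Jensen dimension-based estimate with m = 2 as fallback.
Cluster number selection computes the minimum pairwise centroid
distance over a candidate range (best of five restarts per candidate)
and proposes the elbow as the last c before the curve's largest
proportional drop — the second-difference corner of the log-scale
curve, which, unlike the linear-scale second difference, also detects a
corner at the first candidate; the full curve is returned and a manual
override is honoured, mirroring inspection-based practice. Class
enrichment within clusters reuses the competitive test with the
cluster's membership column as the ranking statistic (ORA on
membership cores as fallback), BH within cluster.

# Sparse canonical correlation

Baseline metabolite profiles and exercise traits (both column
standardized; missing trait values mean-imputed with a flagged count;
constant columns dropped) are related by rank-1 penalized matrix
decomposition of the cross-product: alternating soft-thresholded power
iterations with each L1 budget enforced by 100-step bisection on the
threshold, initialized from the leading singular vector. At the
no-sparsity limit the solution equals the leading singular pair of
$X^\top Z$ (tested); the objective is non-decreasing and all
constraints are asserted on return. Penalties are tuned by
permutations: per grid point, the Fisher-z of the real canonical
correlation is standardized against its row-permutation null (minimum
50 permutations enforced; zero-variance grid points skipped with a
log), and the largest standardized gap wins. Successive variates
deflate the cross-product by the fitted rank-1 term (the PMD
convention, rather than residualizing the data), three variates by
default; signs follow a largest-|trait-loading|-positive convention.
Trait standardization is global rather than per-sex — the sex effect
on traits is part of the variation the analysis is meant to span.

# Numerical choices and degenerate inputs

* Fleishman solver: damped Newton, fixed start, tolerance $10^{-8}$;
  attainability checked before solving.
* REML profile: log-ratio grid $[-14, 8]$ step 2, golden-section
  refinement, boundary fits reported as $\sigma_u^2 = 0$; rank-deficient
  designs error before fitting.
* Satterthwaite: relative finite-difference steps ($10^{-4}$ gradient,
  $10^{-3}$ Hessian), df floored at 1, fallback to residual df if the
  Hessian is singular.
* MMRM: scoring capped at 30 iterations, step-halving to PD; the
  pairwise warm start is eigenvalue-floored. Non-convergence is
  flagged and counted, never silently dropped.
* GEE: $\alpha$ clamped to $\pm 0.99$; clusters sharing an observation
  pattern and design rows are processed as one matrix block.
* FCM: coincident feature/centroid distances floored; crisp assignment
  in that limit.
* Imputation never alters observed entries and is idempotent; features
  with zero observed values error (they should have been filtered).
* All simulation entry points are deterministic given their seed.

# Problem sizes in the shipped checks

The test suite validates engines on small randomized instances against
independent oracles (`lmerTest`, `nlme::gls`, `limma`, `e1071`,
closed-form and brute-force references) and runs the two
operating-characteristic experiments at 20,000 replicates each — the
size at which a rate near 5% carries a Monte-Carlo standard error of
about 0.15 percentage points, tight enough to separate 5% calibration
from 7% inflation many times over. Moment-recovery checks run at
$10^5$–$10^6$ draws. These sizes are the package's own choice of
statistical resolution; all are plain arguments and scale freely.

# Known limitations

* Features are simulated independently; FDR behaviour under strong
  between-feature correlation is not benchmarked.
* The GEE strategy is Gaussian identity-link only — adequate for the
  benchmark's continuous outcomes, not a general GEE.
* The MMRM Wald test uses between-within df, not a Satterthwaite or
  Kenward–Roger adjustment (deliberately out of scope).
* Covariate selection is not automated: covariates come from the
  caller, and the BIC-style search some studies report is not
  reimplemented.
* The enrichment layer ships no gene-set content; collections are
  user-supplied GMT files.
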