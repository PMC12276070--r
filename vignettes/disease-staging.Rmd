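---
title: "Event-based staging of preclinical Alzheimer's disease in Down syndrome: models and methods"
author: "dsebm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-based staging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the models it fits,
the assumptions behind them, the parameters that matter, and the places
where the design was genuinely open and a choice had to be made.

# The scientific setting

Adults with Down syndrome (DS) overexpress the amyloid precursor protein
and develop Alzheimer's disease (AD) neuropathology from their mid-30s,
with clinical dementia diagnosed around age 53–54 on average. Before any
dementia diagnosis, plasma biomarkers and cognitive scores drift from a
"normal" (pre-decline) distribution to an "abnormal" one — but in what
order, and fastest at what age? The package answers both questions from a
single cross-sectional cohort split into younger adults (YA, ages 20–35,
treated as pre-decline controls) and older adults (OA, ages 36–59, the
preclinical at-risk group).

The nine-marker panel combines five plasma measures — the Aβ42/40 ratio
(falls as brain amyloid accumulates), p-tau181 and p-tau231 (tauopathy),
NfL (axonal injury) and GFAP (astrocytic activation), all in pg/mL except
the unitless ratio — with four cognitive scores (paired-associates
first-trial memory, Tower of London, NEPSY-II visuomotor precision, IED
stages completed), all of which fall with decline. Each marker declares its
direction of pathological change; that declaration orients the abnormal
mixture component and the sign conventions of composite scores.

# The event-based model

An *event* is a marker crossing from its normal to its abnormal
distribution. The event-based model (EBM) assumes a single event ordering
$S = (s_1, \dots, s_K)$ shared by the cohort, and an unknown per-participant
stage $k \in \{0,\dots,K\}$: events at positions $\le k$ have occurred.
With per-marker normal/abnormal densities and a uniform stage prior, a
participant's likelihood marginalizes the stage:

$$P(\mathbf{x}_i \mid S) = \frac{1}{K+1}\sum_{k=0}^{K}
  \prod_{j \le k} p\!\left(x_{i,s_j} \mid E\right)
  \prod_{j > k} p\!\left(x_{i,s_j} \mid \neg E\right).$$

Missing cells contribute a factor of one (the model marginalizes them), so
cell-wise exclusions and incomplete cognitive batteries reduce information
without dropping participants. Participants missing every marker are
excluded from the product, with a warning and a count.

## Mixture densities: why they are constrained

The two densities per marker come from a two-component Gaussian mixture on
the pooled sample. Fitting that mixture freely is *not* viable at cohort
scale: for a late event only 10–20% of the sample is abnormal, and a free
(or even control-initialized) EM can reach a degenerate solution — the
"abnormal" component sliding into the bulk of the data — that equals or
marginally beats the truthful fit in likelihood. Once a marker's abnormal
density covers the normal bulk, declaring that event "occurred" becomes
cheap for everyone and the event migrates to the front of the sequence,
corrupting the whole ordering. The fitter therefore imposes three
constraints:

* **Control anchoring.** The normal component's mean and SD are the YA
  moments. The design gives us a group that is overwhelmingly pre-event;
  using it is the analogue of fitting controls first.
* **Minimum separation.** The abnormal mean must sit on the pathological
  side of the normal mean, at least 1.5 control SDs away — mirroring the
  common convention of calling a measurement abnormal at $|z| \ge 1.5$.
  This floor is what prevents the bulk-collapse degeneracy; a fit pinned at
  the floor is a legitimate, conservative estimate for a weak component.
  The floor's value was calibrated by simulating ordering recovery on
  held-out synthetic cohorts and is configurable (`min_separation`).
* **Equal variances** by default: the abnormal SD is tied to the normal SD
  (`equal_variances = FALSE` frees it, bounded above by the normal SD).
  The homoscedastic fit estimates one displacement and one weight per
  marker and proved markedly more stable than the heteroscedastic variant.

Displacement and mixing weight are then estimated by direct maximum
likelihood with multi-start Nelder–Mead (deterministic; no RNG). If the
abnormal weight collapses — the zero-separation limit where the groups are
indistinguishable — the fit falls back to group-label plug-in moments and
is flagged; the two components then nearly coincide and the event carries
essentially no ordering information. The mixing weight is reported but
deliberately unused by the sequence likelihood: stage prevalence is carried
by the uniform stage prior, the standard EBM choice.

## Sequence inference

The permutation space is explored two ways. `greedy_ascent()` runs
best-improvement pairwise-swap hill climbing from random restarts (default
10) and is both the initializer and a maximum-likelihood estimate.
`mcmc_sequences()` runs Metropolis–Hastings with symmetric two-event-swap
proposals and a uniform prior over permutations (acceptance probability
$\min(1, e^{\Delta \log L})$), defaulting to 100,000 iterations with
50,000 burn-in, a single chain, and a fixed seed; the acceptance rate is
reported. Post-burn-in draws yield the positional-variance matrix
$P(\text{event } i \text{ at position } j)$, which is doubly stochastic by
construction; its diagonal concentration visualizes ordering certainty.
The likelihood evaluation inside the sampler is compiled (Rcpp) and uses
R's RNG, so runs are reproducible via `set.seed()`-style seeding; the
vectorized R evaluator `sequence_loglik()` is the reference implementation
and the two are tested against an independent brute-force oracle.

A density floor of $10^{-300}$ keeps logs finite for extreme values. Stage
assignment (`stage_participants()`) uses the posterior over $k$ under the
ML sequence; ties break toward the *smallest* stage, conservative toward
"earlier disease".

## What ordering recovery can and cannot achieve

With nine events staggered over 18 years, two-SD effects and roughly 120
participants, adjacent events are separated by only a handful of
participants whose stage falls between the two onsets. Simulation with the
*true* generative densities shows the likelihood's global argmax still
transposes an adjacent pair in roughly half of cohorts, while Kendall
agreement with the planted ordering stays high. Exact recovery of a full
nine-event permutation at this sample size is therefore not a property any
estimator can promise; the positional-variance diagram, not the point
estimate, is the honest summary of ordering certainty. The test suite
measures both the exact-recovery rate and the mean Kendall tau across 20
simulated cohorts.

# Preprocessing

* **Outliers.** Values beyond $Q_1 - 1.5\,\mathrm{IQR}$ or
  $Q_3 + 1.5\,\mathrm{IQR}$ are excluded cell-wise (set to missing), not
  participant-wise, and only for plasma markers by default — gross assay
  artifacts are a plasma phenomenon, and the EBM marginalizes the holes.
  Quartiles use linear interpolation between order statistics
  (`stats::quantile` type 7); the convention is configurable because
  flagged counts can shift for values at the fence. Exclusion runs before
  the control-group regression below, so that gross values cannot corrupt
  it.
* **Intellectual-disability adjustment.** DS cohorts span mild and
  moderate intellectual disability (ID), which shifts cognitive baselines
  independently of AD. Each marker is regressed on the ID-level indicator
  *in the YA group only*, and the YA-fitted coefficients residualize
  everyone — so OA residuals retain disease-related shifts. With only one
  ID level present the model degrades to intercept-only with a warning.
* **Marker screen.** A Kruskal–Wallis rank test (tie-corrected, chi-square
  with 1 df) compares YA vs OA per marker, by default on the
  ID-residualized values ("controlling for ID level" has no standard
  rank-test construct; residualization reuses the machinery above, and the
  raw-value path is available via `residualize = FALSE`). Markers with
  $p < 0.05$ are selected as EBM inputs; no multiplicity adjustment is
  applied, and the pipeline accepts an explicit include-list override
  because marginal markers (a late event like GFAP in some cohorts, or an
  amyloid ratio near the threshold) can be scientifically mandatory
  regardless of the screen.

# The age-trajectory arm

* **Imputation.** Chained-equations predictive mean matching, written in
  the package: each incomplete plasma marker is regressed on the other
  markers plus age, group and ID level; each missing cell copies the
  observed value of one of 5 nearest-prediction donors chosen at random;
  10 sweeps, 10 independent imputations, deterministic given the seed.
  PMM keeps imputed values on the observed support and assumes data are
  missing at random.
* **Pooled PCA.** Within each imputed dataset the plasma markers are
  log-transformed (when all observed values are positive — the `"auto"`
  default; the synthetic generator is additive-Gaussian, so logging is
  skipped there), standardized, and decomposed. Eigenvectors are defined
  only up to sign, so each dataset's components are flipped to align with
  the first dataset's before averaging; pooled loading columns are
  renormalized to unit norm, and explained-variance fractions are averaged.
  Simple sign-aligned averaging is used for loadings because Rubin's rules
  apply cleanly only to scalar estimands. Note the panel carries the
  Aβ42/40 ratio as a single marker, so imputation operates on the ratio
  itself rather than on separately imputed numerator and denominator.
* **Smooths.** `fit_gam()` is a penalized cubic-regression-spline smooth
  (basis dimension 8, second-derivative penalty, smoothing parameter by
  GCV via `mgcv`), returning a 100-point age-grid curve, a pointwise band
  from the smoother's covariance, and a finite-difference derivative in
  units per year. Per-imputation fits are combined on the common grid by
  Rubin's rules in `pool_smooths()` (total variance = within + (1 + 1/m) ×
  between). `fit_loess()` is local *linear* regression with tricube
  weights, span 0.75 by default, with the band built from the residual
  variance and local weight vector. Pointwise 95% bands are honest where
  smoothing bias is small relative to noise; near sharp bends an
  over-smoothed span biases both the curve and the location of derivative
  peaks, which is why the LOESS span is exposed rather than fixed.
* **Composite z-score.** Per-marker z-scores summed with the Aβ42/40 ratio
  inverted so every term points toward pathology. Participants with some
  missing plasma values contribute the mean of their available z-scores
  rescaled to the full marker count (configurable to strict exclusion);
  participants with none are flagged `NA`.
* **Change window.** From any smooth's derivative, the peak age and the
  maximal contiguous grid interval containing it where the rate stays at
  or above half the peak (criterion configurable). A non-positive peak
  yields an empty window with a warning rather than a spurious interval.

# The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, with known ground truth: two age groups (uniform ages 20–35 and
36–59 — group-internal age distributions are otherwise unspecified in this
design, and uniform is the neutral choice); a planted event ordering with
strictly increasing onset ages (default: amyloid ratio first, memory early,
GFAP last, staggered evenly over 36–54, the window in which DS pathology
emerges); a latent stage obtained by thresholding age plus a 2-year
Gaussian jitter against the onset schedule (stage is monotone in age but
not a deterministic function of it — the groups are age-defined, not
stage-defined); marker values equal to a baseline mean, shifted by
`effect_size × noise_sd` (default 2 SD) in the marker's pathological
direction once its event has occurred, plus an additive moderate-ID effect
(defaults: half an SD on cognitive scores, zero on plasma) and Gaussian
noise. Baseline means and SDs default to values on the scale reported for
pre-decline DS adults (ratio ≈ 0.06, NfL ≈ 9 pg/mL, memory score ≈ 11).
Missingness is then applied completely at random (default 5%, matching
per-marker sample sizes a little below the cohort size), and gross ×5
multiplicative outliers hit observed plasma cells (default 4%, a handful
of cells per marker at cohort scale). The latent stage is recorded before
corruption.

What the generator does **not** emulate: assay-specific error structure,
longitudinal visits, dementia conversion, correlated missingness, or
skewed concentration distributions (values are additive-Gaussian, which is
why the PCA arm's log-transform is auto-detected off). Passing tests
therefore demonstrate correctness of the machinery under the model's own
assumptions — monotone staged progression with MCAR missingness — not
robustness to every pathology of real plasma data.

# Numerical choices and degenerate inputs

* Density floor $10^{-300}$; SD floors at $10^{-6}$ of the sample SD;
  degenerate variance raises an error naming the marker.
* Greedy ascent breaks likelihood ties (improvement $\le 10^{-12}$) by
  stopping, so flat landscapes terminate; staging ties break to the
  smallest stage; quantile and PCA sign conventions as above.
* All stochastic steps (generator, greedy restarts, MCMC, PMM) are
  deterministic given their seed; the pipeline threads one master seed
  through every stage, and two runs with the same configuration produce
  byte-identical artifacts (the manifest's timestamps aside).
* Problem sizes used by the test suite — 20 cohorts of n = 120 for
  ordering/staging properties, 1,000 replicates for screen calibration,
  200 for band coverage — were chosen as the smallest sizes at which the
  measured properties are stable.

# Known limitations

* Exact recovery of a full event permutation at n ≈ 120 is
  information-limited (see above); consumers should read the
  positional-variance diagram, not just the ML sequence.
* The Gaussian mixture family is a modeling choice; kernel-density
  mixtures are a possible extension and are out of scope here.
* The KW screen's "controlling for ID level" via residualization is one of
  several defensible readings (a stratified van Elteren test is another);
  the raw-value path is exposed for sensitivity analyses.
* PMM assumes at least MAR; the generator's MCAR missingness cannot probe
  violations of that assumption.
* No formal inference is attached to the change-window endpoints; the
  window is a descriptive summary of the smoothed derivative.
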