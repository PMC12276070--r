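# dsebm

Data-driven staging of preclinical Alzheimer's disease (AD) in adults with
Down syndrome (DS), from cross-sectional plasma biomarker and cognitive
data.

Adults with DS carry a third copy of the *APP* gene and face a near-certain
accumulation of AD neuropathology decades before the general population,
with dementia diagnosed around age 53–54 on average. Characterizing the
*order* in which plasma biomarkers (the Aβ42/40 ratio, p-tau181, p-tau231,
NfL, GFAP) and cognitive abilities (memory, planning, set-shifting,
visuomotor skill) become abnormal — and the age window in which change is
fastest — matters for early diagnosis and for timing preventive trials.
`dsebm` implements that analysis as a tested, reusable pipeline, together
with a synthetic cohort generator so every stage can be validated against a
known ground truth without access to participant-level data.

## The model

The core is an **event-based model (EBM)**. Each marker's transition from
its normal to its abnormal distribution is an *event*; disease progression
is a fixed sequence *S* = (s₁, …, s_K) of the K events, and each
participant sits at an unknown stage *k* ∈ {0, …, K}: events at positions
≤ *k* have occurred, later events have not. With per-marker normal and
abnormal densities p(x | ¬E) and p(x | E) and a uniform prior over stages,
the likelihood of participant *i*'s data **x**ᵢ is

    P(x_i | S) = 1/(K+1) · Σ_{k=0}^{K} Π_{j≤k} p(x_{i,s_j} | E_{s_j}) · Π_{j>k} p(x_{i,s_j} | ¬E_{s_j})

and the sequence likelihood is the product over participants. The
densities come from constrained two-component Gaussian mixtures (younger
pre-decline adults anchor the normal component); the sequence posterior is
explored by Metropolis–Hastings over permutations with two-event-swap
proposals, summarized as a positional-variance matrix, and each participant
receives a disease stage (the posterior mode of *k* under the
maximum-likelihood sequence).

A companion **age-trajectory arm** handles missing data by chained-equations
predictive mean matching (10 imputations), pools a PCA of the standardized
log plasma biomarkers across imputations by Rubin's rules, smooths principal
components and the pathology-aligned composite z-score against age with GAMs
and LOESS, and locates the age window of maximal rate of change.

## Worked example

```r
library(dsebm)

cfg    <- synthetic_config(seed = 42)       # planted 9-event ordering
cohort <- generate_cohort(cfg)
clean  <- apply_iqr_exclusion(cohort)$cohort
resid  <- residualize_cohort(clean)

kruskal_wallis_screen(clean)
#>       marker      H  p_value   n selected
#> 1 abeta42_40 63.068 2.00e-15 112     TRUE
#> 2    ptau181 25.668 4.05e-07 111     TRUE
#> ...
#> 5       gfap  0.392 5.31e-01 111    FALSE

mix  <- fit_cohort_mixtures(resid)
post <- mcmc_sequences(resid, mix, seed = 1)
post
#> Event sequence posterior (50000 draws, acceptance 0.03)
#> ML sequence (log-lik -2337.22):
#>   abeta42_40 -> pal -> nfl -> ptau231 -> ptau181 -> tol -> ied -> nepsy -> gfap

stages <- stage_participants(resid, post$ml_sequence, mix)
staging_histogram(stages, clean)
#>      stage
#> group  0  1  2  3  4  5  6  7  8  9
#>    YA 48  9  1  1  0  0  1  0  0  0
#>    OA  2  3 11  4  6  4  5  6 10  9

comp <- composite_z(clean)
max_change_window(fit_loess(clean$age, comp))
#> change window: ages 34.1-58.6 (peak 38.4, rate 0.317/yr, >= 50% of peak)
```

The recovered maximum-likelihood sequence equals the planted ordering
(amyloid ratio first, memory early, GFAP last); younger adults concentrate
at stage 0 while the older at-risk group spreads across later stages; and
the composite z-score's fastest rise brackets the planted onset window.

The whole pipeline can also be driven by one call —
`run_pipeline(run_config(seed = 1, out_dir = "results"))` — which writes
every artifact (cohort, screen report, ML sequence, positional variance,
stages, pooled loadings, smooth curves, change window) as CSV/JSON plus a
run manifest, or from a shell via `inst/cli/dsebm.R`.

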