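---
title: "Quantification and modelling methods in splquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification and modelling methods in splquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splquant)
```

splquant implements the quantitative chain used in multiparametric
^18^F-FDG PET/MRI assessment of solitary pulmonary lesions (SPLs) — diffusion
model fitting, CEST asymmetry mapping, PET threshold volumetry — and the
statistical workflow that turns per-lesion parameters into a validated
benign-versus-malignant prediction model.  Because no patient data ship with
the package, every stage is paired with a synthetic generator whose ground
truth is known exactly; this vignette records the models, the defaults, and
the design decisions behind both.

## Diffusion models

Two signal models are fitted per voxel over the ten-b-value chest protocol
(`protocol_bvalues()`: 0–1000 s/mm²):

* mono-exponential: $S_b = S_0 \exp(-b \cdot \mathrm{ADC})$, and
* stretched-exponential: $S_b = S_0 \exp\left[-(b \cdot \mathrm{DDC})^\alpha\right]$,

with ADC and DDC in mm²/s and the heterogeneity index $\alpha \in (0, 1]$;
$\alpha = 1$ collapses the stretched model onto the mono-exponential one.
The ADC fit is weighted least squares on the log signal with weights equal
to the squared signal — the standard variance-stabilising choice, exact on
noiseless data.  Non-positive signals (possible after noise) are floored at
machine epsilon times the series maximum and given zero weight.

The stretched fit is a bounded Levenberg–Marquardt minimisation with
analytic Jacobian, DDC constrained to $[10^{-6}, 10^{-2}]$ mm²/s and
$\alpha$ to $[0.01, 1]$ (the upper bound inclusive: super-exponential decay
is outside the model's definition).  The DDC–$\alpha$ objective has a long
shallow valley, so the fit starts from the ADC solution with three
$\alpha$ starts (0.7, 0.35, 1.0) and keeps the best optimum; tests verify
that the result is never worse than a 200×200 profiled-S0 grid search.  The
engine is vectorised across voxels (all voxels iterate simultaneously with
per-voxel damping), which is why a 32³ volume fits in seconds; the
single-voxel and whole-volume paths share the same code, so they agree
exactly.  Non-convergence is reported with a flag and the best iterate —
never an exception.  Parameter maps are plain voxelwise fits (no spatial
regularisation) and per-lesion values are VOI means of the maps, fitting
per-voxel first and averaging after.  Per-b-value excitation averages of
the protocol are assumed already applied by acquisition averaging and are
not used as weights.

## CEST processing

The amide proton transfer contrast is the magnetisation transfer ratio
asymmetry at 3.5 ppm downfield of water,

$$\mathrm{MTRasym}(3.5\,\mathrm{ppm}) =
  \left[S_\mathrm{sat}(-3.5) - S_\mathrm{sat}(+3.5)\right] / S_0,$$

reported in percent (matching the clinical reporting convention) and
positive when the downfield side is more saturated.  The chain is: estimate
the static-field (B0) offset from the low-power series as the
spline-interpolated minimum of the water dip on a 0.001 ppm grid
(WASSR-style); recentre the main spectrum by cubic-spline resampling on the
shifted axis with flat extrapolation at the sweep edges; evaluate the
asymmetry by spline interpolation at ±3.5 ppm.  The B0 spline uses
Forsythe–Malcolm–Moler end conditions rather than natural ones: a natural
spline forces zero curvature at the sweep ends and pins a dip lying between
the outermost samples to the edge, whereas FMM end conditions recover it
(tested at a −0.95 ppm dip under a ±1 ppm sweep).  Estimates at the sweep
edge are clamped to the half-width and flagged `near_edge`.  Plateau minima
are resolved to the plateau midpoint.

The z-spectrum phantom is a sum of Lorentzian pools — direct-saturation
water and a broad semisolid MT pool at 0 ppm, an amide pool at +3.5 ppm —
on the 31-point ±4.5 ppm offset grid, with an 11-point ±1 ppm low-power
companion series.  The low-power water dip defaults to a 1.0 ppm FWHM,
much narrower than the main-series water line, reflecting how direct
saturation narrows at low saturation power; at that width the 0.2 ppm
sampling supports ±0.005 ppm B0 recovery.  The phantom's analytic
MTRasym is linear in the amide amplitude, so
`amide_amplitude_for_mtrasym()` builds spectra with any prescribed
asymmetry exactly.  The phantom does not model exchange dynamics, B1
inhomogeneity, or asymmetric nuclear Overhauser contributions — it is a
geometry for testing the estimator chain, not a physics simulator.

## PET volumetry

Lesions are segmented at the 40% SUVmax isocontour inside the VOI:
threshold inclusive ($\ge 0.4 \cdot \mathrm{SUV_{max}}$), restricted to the
26-connected component containing the SUVmax voxel so that disconnected hot
noise is excluded (the threshold rule alone does not specify connectivity;
anchoring at the maximum is the deterministic choice).  MTV is the member
count times the voxel volume (ml, on the 2.6 × 2.6 × 2.0 mm reconstruction
grid); TLG = SUVmean × MTV in grams assuming unit tissue density.  SUVmax
ties resolve to the lowest linear index.  The sphere phantom assigns uptake
by voxel-centre membership, so the discretised volume converges to
$\tfrac{4}{3}\pi r^3$ under voxel refinement; no partial-volume or
reconstruction physics is simulated.

## Inter-rater agreement

Agreement between two raters uses the two-way random-effects,
absolute-agreement, single-measurement intraclass correlation (ICC(A,1)),
the standard model when two raters from a larger population each measure
every lesion and agreement in magnitude matters, with the F-based 95%
confidence interval.  Bands follow the conventional thresholds (poor
< 0.40, fair 0.40–0.60, good 0.60–0.75, excellent ≥ 0.75; left-closed).
Zero total variance is reported as ICC 1 with a degenerate-data flag.  The
averaged rater table feeds the downstream analysis.

## Cohort simulation

`generate_cohort_table()` draws two-group per-lesion records through a
Gaussian copula: a latent multivariate normal with the configured
correlation matrix, transformed through per-group marginals.  Defaults
reproduce the training-cohort group statistics of the study the package
emulates: normal marginals for ADC (reported mean ± SD), log-normal for
SUVmax, MTV, TLG, DDC and MTRasym (reported median with quartiles,
right-skewed), and a truncated normal on (0, 1] for $\alpha$.  Log-normal
parameters come from the median (meanlog) and the quartile ratio (sdlog =
log(q3/q1) / (2 z₀.₇₅)).

The inter-parameter correlations are not identifiable from published group
summaries, so they are a design choice.  The default uses two physiologic
blocks — metabolic (MTV–TLG 0.85, SUVmax–TLG 0.65, SUVmax–MTV 0.45;
TLG is SUVmean × MTV by construction) and diffusion (ADC–DDC 0.75, with
$\alpha$ coupled negatively at −0.35/−0.30) — plus moderate negative
ADC–SUVmax and ADC–MTRasym couplings (−0.3) tying the blocks together.
This redundancy is what makes multivariable selection non-trivial and lets
a three-predictor model subsume the remaining parameters, the qualitative
outcome the emulated study reports; a minimal alternative (identity plus
the two −0.3 couplings) was considered and rejected because it leaves DDC
an independently strong marker, contradicting that outcome.  Clinical
covariates (age, sex, smoking, diameter) are drawn independently per group.

`generate_trio_cohort()` is a separate instrument for selection-consistency
experiments: SUVmax, ADC and MTRasym carry group signal independently,
while MTV, TLG, DDC and $\alpha$ are derived as the *same* linear function
of their raw parent plus independent additive Gaussian noise in both
groups.  Two details matter and were arrived at deliberately.  First,
additive noise around a linear parent makes the derived variable exactly
null in the score test once its parent is in the model (the projection
residual is independent noise); log-linked or multiplicative derivations
leave residual dependence that the misspecified linear logistic model can
exploit, silently inflating false selection.  Second, the parent–child
correlation is kept moderate (≈ 0.6): with very tight coupling the child
becomes a near-clone of the parent and wins the entry race about half the
time.  Simulating the trio through the within-group copula was rejected for
a subtler reason: group-standardised latents make the "noise" parameters
conditionally informative about the label, so selection correctly keeps
them and the experiment cannot measure what it is meant to.

All randomness flows from one integer master seed, split per named
sub-generator by a deterministic hash (`derive_seed()`), so a stage's draw
is invariant to reordering or adding stages.

## Statistical workflow

* **Split**: stratified 70/30 within each class, rounded to the nearest
  integer per class.  (No single rounding convention reproduces a 41→28 and
  79→56 split simultaneously; round-to-nearest is used and tests accept ±1.)
* **Group comparison**: chi-square (Pearson, uncorrected) for categorical
  variables; independent-samples pooled-variance t-test with mean ± SD
  summaries when both groups pass Shapiro–Wilk normality at 0.05; otherwise
  Mann–Whitney U with median [IQR] summaries.  The normality gate is a
  design choice — the reporting convention implies one but does not name
  it.  A degenerate-variance t path falls back to the rank test.  No
  multiple-testing adjustment is applied (raw p-values are reported, as is
  conventional in this literature).
* **Forward-LR selection**: entry by the smallest Rao score-test p-value
  below 0.05; after each entry, members with likelihood-ratio p above 0.10
  are removed; the loop stops at a fixed point and the final model is refit
  by maximum likelihood.  These entry/removal defaults are the classical
  ones for the procedure.  Continuous candidates are z-scored on the
  training set (so odds ratios are per 1 SD) and those statistics are
  frozen for test-set scoring.  Perfect separation is detected (pinned
  fitted probabilities or runaway coefficients) and the final fit falls
  back to a lightly ridge-penalised logistic regression, flagged in the
  result.
* **ROC**: empirical curve over all distinct thresholds; trapezoidal AUC
  (equal to the tie-corrected Mann–Whitney statistic); DeLong
  structural-components variance for the AUC confidence interval and for
  paired AUC comparisons (identical orderings give Z = 0, p = 1 by
  convention); cutoffs maximise Youden's J with ties resolved towards the
  higher specificity.  Markers that run low in disease are handled by an
  automatic orientation that is recorded in the result.
* **Calibration**: deciles of predicted probability against observed event
  rates, a logistic recalibration (slope/intercept on the linear
  predictor), and an optional bootstrap-averaged lowess curve.  The
  in-sample recalibration slope of a maximum-likelihood logistic model is 1
  by construction; the slope is informative on resampled or external data.
* **Decision curves**: net benefit $TP/N - (FP/N)\,p_t/(1-p_t)$ over a
  0.01–0.99 threshold grid, with treat-all and treat-none references.

One evaluation-design point deserves record: when checking that the
combined model outperforms every single parameter across simulated
replicates, each replicate runs the full workflow (forward-LR over the
complete candidate roster on that replicate's training set) and compares
*that* model — mirroring how the original comparison arose.  Fixing the
three predictors a priori instead leaves the comparison exposed to sampling
noise in whichever strong single marker (typically DDC) the fixed model
happens not to contain, and fails in roughly an eighth of replicates at
n = 84 even though the population-level ordering holds.

## Problem sizes and numerical tolerances

The test suite exercises: exact inversion on 32³ noiseless volumes
(ADC to 1e-9 relative, DDC/α to 1e-6); optimizer-versus-grid checks on 50
series; noisy recovery on 500 voxels at SNR 50 (median bias < 5%); CEST
recovery across B0 shifts in ±0.5 ppm (0.05 pp on built-in asymmetries,
0.1 pp null drift); sphere volumetry within 5% of analytic; AUC pair-count
identity to 1e-12 on 100 random samples and DeLong-versus-bootstrap
variance within 10% at n = 30 (10,000 replicates); coefficient CI coverage
at n = 2000 over 100 seeds; selection consistency and headline-ordering
experiments over 100 replicates each at the emulated study's sample sizes.
These sizes were chosen to make Monte-Carlo error small relative to each
tolerance while keeping the default suite quick.

## Known limitations

Phantoms are geometric, not anatomical: no respiratory motion, no
partial-volume effects, no PET reconstruction physics, no CEST exchange
dynamics or B1 dependence.  The cohort simulator matches published
location/scale per group and a chosen correlation structure — not any
patient-level joint distribution — so passing tests demonstrate the
correctness of the estimators and workflow, not clinical performance on
real data.  The emulated study's fitted model coefficients were never
published, so only its qualitative outcomes (which predictors survive,
the ordering of AUCs, calibration/decision-curve behaviour) can be
mirrored, and its exact probability formula cannot.  The forward-LR
"exactly the signal trio" event has, under the procedure's own 0.05/0.10
thresholds with four conditionally-null candidates, a success probability
of about 0.75–0.80 per cohort — an intrinsic familywise property of
stepwise selection worth remembering when interpreting any single
selection run.
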