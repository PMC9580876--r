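---
title: "Comparing single-target and multitarget ctDNA detection: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing single-target and multitarget ctDNA detection: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrdcompare)
```

This vignette is the package's account of the science it implements: the
measurement models for the two circulating tumour DNA (ctDNA) detection
strategies, the statistical calling machinery, what the synthetic cohort
generator does and does not emulate, and the design decisions taken where
the underlying protocols leave room.

## The measurement problem

Postoperative minimal-residual-disease (MRD) detection asks whether any
tumour-derived DNA fragments are present in a blood draw. The relevant
concentrations are tiny — often below one mutant genome equivalent (GE)
per mL of plasma — so an 8 mL aliquot may contain a literal handful of
informative molecules, or none. Two strategies are compared on paired
aliquots of the same draws:

* **ST**: droplet digital PCR (ddPCR) against one patient-specific clonal
  mutation;
* **MT**: multiplex PCR and deep sequencing of 16 patient-specific clonal
  mutations, with an input cap of ~66 ng (~20,000 GE at 3.3 pg per haploid
  GE).

## ddPCR partition model

A reaction converts ~20 µL of mix into droplets of ~0.834 nL (about 16,948
droplets per well, SD 1852, in the emulated instrument). Molecules land in
droplets essentially independently, so the number of copies per droplet is
Poisson with mean λ and the positive-droplet count k among n droplets
satisfies

$$\hat\lambda = -\ln(1 - k/n), \qquad
  \text{copies/µL} = \hat\lambda / v,\; v = 0.834\,\text{nL}.$$

`simulate_ddpcr_reaction()` draws molecule totals Poisson from
concentration × volume and assigns them uniformly to droplets. Because the
totals are Poisson, the occupied-droplet count is *exactly*
Binomial(n, 1 − e^{−λ}); the counts-only path samples that marginal law
directly, and per-droplet occupancy with amplitudes (three Gaussian
clusters: empty, wild-type-positive, mutant-positive) is materialised only
on request. Saturated wells (k = n) are rejected as errors rather than
mapped to an infinite estimate.

Amplitude thresholds follow the positive-control rule: the threshold sits
a predetermined assay-specific number of standard deviations (default
`threshold_sd_k = 3`; the per-assay values of the emulated protocol are
not public) below the mean amplitude of the positive droplets in the
positive control, and droplets at or above it are positive. QC requires a
clean no-template control, signal in the positive control, amplitudes
within the expected interval, and at least 8000 droplets; all QC-passing
wells of a sample are merged by summing counts before any calling.

Wild-type genome equivalents screened are recovered from the wild-type
channel's own partition estimate (`λ_wt × n`), not from pre-PCR
quantification, because the callers normalise noise by the DNA actually
analysed. One haploid GE carries one copy of the locus, so wild-type
copies and GE coincide.

## Noise profiles and the four-caller consensus

Each assay's false-positive behaviour is characterised on a panel of 94
tumour-free (buffy coat) blanks spanning a ladder of DNA inputs
(`simulate_blank_panel()` uses 500–20,000 GE). Four callers with distinct
noise models test a merged sample against the profile; their published
internals are proprietary or described elsewhere, so this package declares
simple stand-ins that preserve each caller's documented character:

* **Poisson**: expected noise µ = pooled blank rate × GE screened;
  positive when P(X ≥ k | Poisson(µ)) < α.
* **Error-corrected (CASTLE-style)**: negative-binomial fit to the blank
  counts with log link and exposure = GE screened (`MASS::glm.nb`),
  falling back to Poisson when the dispersion is unidentifiable (flagged
  in the profile); also reports `max(0, k − µ̂)`, the error-corrected
  molecule count used for quantification.
* **Beta-binomial (ALPACA-style)**: models the mutant droplet fraction
  k/(k_mut + k_wt); parameters come from the blank fractions by the method
  of moments, reducing to an exact binomial tail when the blanks show no
  excess-binomial variance.
* **Dynamic limit of blank**: each blank's count is rescaled to the
  sample's DNA input; the LOB is the 0.95 empirical quantile and the
  sample must *strictly* exceed it (an exactly-LOB count is negative —
  the conservative reading of a tie).

The consensus is positive when at least 3 of 4 agree; on a 2–2 split the
error-corrected caller decides, and it always supplies the reported level
via `mutant_per_ml()` (corrected copies / (plasma volume × fraction of
eluate analysed), clamped at zero). Per-caller α defaults to 0.05:
consensus, not α, is the primary specificity mechanism. Noise correction
is applied after merging reactions (where in the workflow the original
protocol corrects is unstated; correcting the pooled counts is the
variance-minimising choice).

The two-step eluate strategy is modelled as a calling wrapper
(`st_measure_cohort()`): 18 µL of the 60 µL eluate is analysed first;
positives stop there, negatives have the remaining 36 µL analysed and all
wells merged. `fraction_eluate_analyzed` (18/60 or 54/60) rescales the
level so quantification is comparable across routes. The emulated protocol
nominally reserves 54 µL of a 60 µL eluate for ctDNA analysis and 4 µL
for quantification (54 + 4 ≠ 60); both volumes are exposed as
configuration and deliberately not reconciled.

## Multitarget model

Extraction yields `cfdna_ge_per_ml × plasma_ml` GE; the library consumes
at most 20,000 GE, so in high-cfDNA samples only a fraction
`input/extracted` of the aliquot's tumour molecules can contribute.
Per-target tumour molecules are Poisson with mean
`ctdna × plasma × input_fraction × detectability`, plus Poisson background
at a per-GE rate. Read-level simulation (the real assay sequences at
>100,000× coverage) is deliberately collapsed to molecule level: molecules
are the information-bearing unit, and per-target detection operates on
them through a Poisson tail test at `per_target_alpha = 1e-3` — the
declared stand-in for the assay's proprietary confidence threshold. A
sample is positive when ≥ 2 of 16 targets are detected; the analytic
blank-sample false-positive rate is
$1 - (1-p)^{16} - 16p(1-p)^{15}$ for per-target false-detection
probability p, which keeps 16-target blank specificity far above 99% at
the defaults.

The level is the mean of molecules per mL plasma over **all 16 targets**,
zeros included, on raw (uncorrected) counts. Normalising by plasma volume
before or after averaging commutes, so the choice is cosmetic; the mean
over targets is not. Conditional on detection at very low ctDNA levels,
the ST estimator (≥ 1 molecule over one target) is bounded below by
1/(plasma × eluate fraction) ≈ 0.14 GE/mL, while the MT mean spreads a few
molecules over 16 targets (≈ 0.02–0.05 GE/mL) — the package's tests
reproduce this deliberately asymmetric behaviour, which is the mechanism
behind ST-only-positive samples showing higher estimated levels.

## The synthetic cohort

`simulate_cohort()` emulates the study conditions: 112 patients, stage II
fraction 0.232, recurrence fraction 0.24 with log-normal recurrence times
(median 12.2 months, sdlog 0.24), ~35.8-month follow-up, 70.5% adjuvant
treatment, preoperative draws for 82% of patients, early-postoperative
draws (1 month, inside the 60-day window and before adjuvant start at 2
months) for 50%, and 3-monthly surveillance draws for 58% starting one
month after end of definitive treatment (surgery, plus 6 months of
adjuvant where given). Cell-free DNA is log-normal with median 1625 GE/mL
(≈ 13,000 GE per 8 mL draw, matching the study's reported input medians)
and a 1.5× preoperative multiplier.

ctDNA kinetics are the minimal model consistent with observed behaviour:
a preoperative level (log-normal, median 0.7 GE/mL, sdlog 2), then
exponential regrowth `residual × 2^(t / doubling_time)` after surgery for
recurrence patients (doubling time ~1.5 months, chosen so detection leads
radiological recurrence by a few months at the default draw schedule).
The postoperative residual is a 50/50 mixture of a shedding component
(median 1 GE/mL) and a not-yet-shedding component (median 0.003 GE/mL,
far below both assays' floors) so that roughly half of recurrence
patients are detectable immediately after surgery — by either method —
while the rest become detectable during surveillance through growth. Six
percent of non-recurrence patients shed postoperatively and are cleared
at adjuvant start, mirroring the observed sporadic postoperative
positives among non-recurrence patients. Noise rates are free parameters
of the emulated assays: 1e-6 false mutant events per GE for the ddPCR
assay (an optimised, clonality-vetted assay; yields serial sample-level
specificity near the study's) and 2e-8 per GE per target for the MT
background (deep-coverage mPCR-NGS with near-noiseless per-target
calling).

Each draw realises one cfDNA and one true ctDNA concentration with
log-normal biological noise; the paired ST and MT aliquots consume the
same row, which is the shared-draw invariant the study design depends on.
Radiological recurrence times are drawn directly rather than derived from
the trajectory crossing an imaging threshold — simpler, and sufficient
for lead-time logic.

What the generator does **not** emulate: clonal haematopoiesis and
germline contamination, assay dropout and failed extractions, FFPE
artefacts, per-trinucleotide sequencing error profiles, imaging schedules
beyond a recurrence date, and any correlation between cfDNA burden and
tumour stage. Passing tests on synthetic cohorts therefore demonstrate
that the pipeline's machinery reproduces the study's *qualitative*
structure under its stated conditions — not that it would reproduce the
study's patient-level numbers, which depend on its actual plasma samples.
Two known departures at the defaults: the synthetic MT arm tends to turn
positive one surveillance draw earlier than ST in marginal recurrence
patients (the study observed identical first-detection times), and the
synthetic MT surveillance specificity is essentially 100%, which makes
the serial time-dependent Cox model for MT separate (monotone partial
likelihood, unbounded hazard ratio). The pipeline flags such fits rather
than reporting a pseudo-finite estimate, and the acceptance script
reports the postoperative (time-fixed) Cox hazard ratios, which are
well-behaved in both arms.

## Statistics layer

Cohen's κ and the raw agreement fraction summarise the paired 2×2 call
table; Wilson score intervals accompany every detection fraction; Fisher's
exact test uses the sum-of-small-point-probabilities two-sided convention
(the convention of `stats::fisher.test`, and the one that reproduces the
study's discordance p-value); Wilcoxon tests use midranks with exact
small-sample p-values where defined. The log–log level regression is
ordinary least squares on log10 levels over both-positive samples
(nonpositive levels are an error by construction of the filter), with
Pearson's r on the logged values. Specificity is reported at sample level
(1 − positive fraction) and patient level (a patient is false-positive if
*any* serial sample is); when every patient contributes at least one
sample, patient-level specificity can only be at or below sample level.

Lead time is recurrence time minus first positive surveillance draw
(months; convert day-scale data at 30.44 days/month — the source protocol
states no convention). Survival association uses Cox partial likelihood
with Efron tie handling (no tie method is named in the emulated analysis;
Efron is the least biased common default): `cox_time_dependent()`
episode-splits follow-up at the first positive sample (start–stop
representation), and `cox_postoperative()` is the time-fixed companion on
the early-postoperative call.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: saturated wells are errors;
empty amplitude vectors classify to (0, 0); all-zero blank panels give a
zero-noise profile whose callers treat any molecule as decisive;
degenerate margins make κ an error and constant levels flag the
regression as degenerate rather than returning a spurious r. The
negative-binomial fit falls back to Poisson on degenerate blank panels,
flagged in the profile. Ties at the dynamic LOB are negative.

The test-suite problem sizes are chosen to make Monte-Carlo bounds sharp
while keeping the default run fast: 10⁴ simulated wells for estimator
consistency, 2000 simulated blanks per caller for false-positive control,
10⁴ blank samples for the two-of-sixteen formula, complete enumeration
for Fisher/Wilcoxon oracles up to size 8, 200 replicates for Cox CI
coverage, and 50 replicate cohorts at the default 112-patient
configuration for the qualitative study-level findings; the acceptance
script uses 25 replicate cohorts and reports medians.
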