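# mrdcompare

Head-to-head comparison of single-target (ST) droplet digital PCR and
multitarget (MT) 16-plex mPCR-NGS strategies for circulating tumour DNA
(ctDNA) detection in postoperative minimal-residual-disease (MRD)
monitoring of resected stage II–III colorectal cancer.

After curative-intent surgery, residual disease sheds ctDNA at extremely
low concentrations (often well below 1 mutant genome equivalent (GE) per mL
plasma), so detection is dominated by sampling stochasticity: whether any
informative tumour fragment at all ends up in the analysed aliquot.
Multitarget panels track many patient-specific variants in the hope of
sampling at least some of them; single-target ddPCR assays are cheaper and
simpler but stake everything on one locus. This package provides the full
measurement and statistics machinery needed to compare the two strategies
on paired aliquots of the same blood draws, for methodologists who want to
study when the extra targets actually help.

## What is implemented

**ddPCR partition model** (`ddpcr_assay()`, `simulate_ddpcr_reaction()`,
`amplitude_threshold()`, `classify_droplets()`, `ddpcr_lambda()`,
`ddpcr_concentration()`, `qc_reactions()`, `merge_reactions()`,
`mutant_per_ml()`). A reaction partitions ~20 µL into droplets of ~0.834 nL;
with *k* of *n* droplets positive, the mean copies per droplet is the
Poisson occupancy estimate

&nbsp;&nbsp;&nbsp;&nbsp;λ = −ln(1 − k/n),&nbsp;&nbsp;
concentration = λ/v droplets,

with four QC rules per well (clean no-template control, signal in the
positive control, amplitudes in bounds, ≥ 8000 droplets) and merging of
QC-passing wells before sample-level calling.

**Blank-derived calling** (`noise_profile()`, `call_poisson()`,
`call_castle()`, `call_alpaca()`, `call_dynamic_lob()`, `call_st()`). Each
assay carries a noise profile built from 94 tumour-free blanks at varying
DNA inputs. Four callers test a merged sample against it — a pooled-rate
Poisson tail test, a negative-binomial error model with error-corrected
molecule counts, a beta-binomial test on the mutant droplet fraction, and
an input-scaled empirical limit of blank. The consensus is positive when
≥ 3 of 4 agree; 2–2 ties defer to the error-corrected caller, which also
supplies the reported level in mutant GE/mL plasma.

**Multitarget model** (`mt_panel()`, `simulate_mt_sample()`,
`detect_targets()`, `call_mt()`, `mt_level()`). Library input is capped at
~20,000 GE (66 ng); per-target molecule counts are Poisson; a sample is
positive when ≥ 2 of 16 targets pass a per-target Poisson confidence test;
the level is the mean over **all** 16 targets of molecules per mL plasma,
zeros included — which is exactly why MT level estimates sit below ST
estimates at very low ctDNA levels.

**Synthetic cohort generator** (`mrd_config()`, `simulate_cohort()`,
`tumor_trajectory()`, `draw_sample()`) emulating the study design: 112
patients (23% stage II), 24% recurrence with ~12.2-month median time to
recurrence, ~36-month follow-up, preoperative / early-postoperative /
surveillance draws, paired ST and MT aliquots sharing each draw's true
concentrations, and exponential post-surgical regrowth.

**Statistics layer** (`cohens_kappa()`, `agreement_fraction()`,
`wilson_interval()`, `fisher_exact()`, `wilcoxon_rank_sum()`,
`wilcoxon_signed_rank()`, `pearson_loglog()`, `sample_specificity()`,
`patient_specificity()`, `lead_times()`, `cox_time_dependent()`,
`cox_postoperative()`), the end-to-end pipeline (`compare_cohort()`), CSV
ingestion with schema validation (`read_reactions()`, `read_blanks()`,
`read_manifest()`), ggplot2 views (`autoplot()`, `plot_detection_rates()`)
and broom-style `tidy()`/`glance()` methods.

## Worked example

`worked_examples()` recomputes the study's headline statistics from their
published input counts:

```
> worked_examples()
# A tibble: 7 x 4
  quantity                   computed published ok
  <chr>                         <dbl>     <dbl> <lgl>
1 cohens_kappa                0.792      0.79   TRUE
2 agreement_pct              90.0       90      TRUE
3 fisher_preop_split_p        0.00366    0.0036 TRUE
4 st_sample_specificity_pct  97.6       97.6    TRUE
5 mt_sample_specificity_pct  99.2       99.2    TRUE
6 st_patient_specificity_pct 93.9       94      TRUE
7 mt_patient_specificity_pct 98.0       98      TRUE
```

Row 1 is Cohen's kappa for the 2×2 table of 379 paired calls (134 both
positive, 11 ST-only, 27 MT-only, 207 both negative); row 3 is the
two-sided Fisher test showing MT-only discordant samples are concentrated
preoperatively; rows 4–7 are serial surveillance specificities at sample
and patient level.

A full synthetic comparison runs in a couple of seconds:

```
> cmp <- compare_cohort(mrd_config(), seed = 7)
> cmp
<mrd_comparison> 669 samples from 112 patients (seed 7)
  concordance: 95.2% agreement, Cohen's kappa 0.84
  level correlation (both positive, n=107): Pearson r = 0.975
> glance(cmp)[, c("preop_sens_st", "preop_sens_mt")]
# A tibble: 1 x 2
  preop_sens_st preop_sens_mt
          <dbl>         <dbl>
1         0.791         0.989
> tidy(cmp$cox$postop_st)
# A tibble: 1 x 6
  term              estimate hazard_ratio conf_low conf_high   p_value
1 ST ctDNA positive     2.37         10.7     3.55      32.5 0.0000265
```

The preoperative MT advantage (here 98.9% vs 79.1%), the near-equal
postoperative sensitivities, the high serial specificities and the
positive ctDNA lead times mirror the qualitative findings of the study
design the generator emulates; `autoplot(cmp)` shows the detection rates
with Wilson intervals.

## Data formats

CSV throughout: per-well reaction counts (`sample_id, assay_id, role,
n_droplets, k_mutant, k_wildtype`), blank panels (`assay_id, blank_id,
ge_screened, fp_count`) and sample manifests (`sample_id, patient_id,
time_months, timing_class`). Configuration is YAML via `read_mrd_config()`;
every protocol constant (plasma volume, eluate volumes, droplet volume,
QC floor, input cap, alphas, cohort parameters) is a named field with a
validated default.
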