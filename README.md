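# p50gate

Auditory sensory gating is the brain's attenuation of its response to the
second of two identical stimuli presented in close succession. In the
paired-click (conditioning–testing) paradigm, two identical tones S1 and S2
are played 500 ms apart; the P50 — a positive event-related potential (ERP)
deflection about 50 ms post-stimulus, scored at electrode Cz as the P50 peak
minus the preceding N40 trough — is measured for each stimulus, and gating is
quantified by the ratio

```
gating ratio = 100 · A(S2) / A(S1),   A = P50 peak − N40 trough (µV)
```

with smaller ratios indicating stronger gating. `p50gate` implements, as a
tested and reusable R pipeline, the full analysis used in individual-differences
studies that relate this ratio to behavioural inhibition: raw multichannel
EEG → per-subject gating ratios, trial-level task logs → nine inhibition
indices (Stroop, Simon, flanker, alerting, orienting, latent inhibition,
novel pop-out, negative priming, go/no-go, switch, antisaccade, continuous
performance), and a correlation battery over the resulting score table
(bivariate and partial Pearson correlations controlling fluid intelligence
and working memory, Williams's *t* for dependent correlations, paired *t*
tests, standardized-residual outlier screening). Because raw participant
data for such studies are typically unavailable, a first-class synthetic-data
module generates cohorts with known ground truth: planted S1/S2 amplitudes,
planted task effects, and a planted cross-measure correlation structure.

It is intended for EEG/ERP researchers studying sensory gating, and for
methodologists who need a fully simulated test bed for paired-click
pipelines.

## What the pipeline does

1. **Simulate** (`generate_cohort`, `generate_raw_eeg`,
   `generate_trial_log`, `generate_ospan_items`): Gaussian-copula cohort
   with a target correlation matrix over {gating ratio, task indices, IQ,
   OSPAN}; per subject, continuous EEG at 2000 Hz (Cz, mastoids TP9/TP10,
   bipolar VEOG/HEOG) with 135 paired-beep trials plus 15 click trials,
   N40/P50 Gabor-atom components on 1/f noise, line noise, blinks and
   saccades; ex-Gaussian trial logs per task.
2. **Preprocess** (`preprocess_recording`): re-reference to average
   mastoids → 50 Hz notch + 10–50 Hz Butterworth band-pass (24 dB/octave
   per edge, zero-phase) → Gratton–Coles-style ocular regression →
   segmentation (−100…+200 ms) → ±50 µV amplitude and 50 µV/ms gradient
   rejection → baseline correction (−100…0 ms) → averaging.
3. **Score** (`score_p50`, `compute_gating`): P50 = most positive local
   peak at Cz in 40–80 ms; N40 = most negative preceding local trough in
   20–50 ms; subjects without an S1 P50 are excluded; an absent S2 P50 is
   full suppression, imputed at 0.01 µV; ratios above 200 are truncated.
4. **Correlate** (`correlation_battery`): the statistics listed above, with
   pairwise deletion for bivariate correlations and listwise deletion for
   partial correlations and Williams comparisons.

`run_pipeline()` chains all four stages, logs per-subject exclusions in a
manifest, and writes CSV/JSON artifacts. Recordings can be written/read in
BrainVision Core format (`write_brainvision` / `read_brainvision`).

## Worked example

```r
library(p50gate)

# a subject with planted S1 = 1.33 uV, S2 = 0.97 uV (ratio 72.93)
prof <- subject_profile("S001", s1_p50_amp = 1.33, s2_p50_amp = 0.97,
                        n40_amp = -0.45, p50_latency = 55, n40_latency = 38,
                        task_effects = list(), iq_raw = 35L, ospan_abs = 39L)
rec <- generate_raw_eeg(prof, seed = 1)     # 135 paired trials, snr 0.75
ev  <- preprocess_recording(rec)
score_gating(ev$S1, ev$S2)
#> <gating_result> S1 1.335 uV, S2 1.030 uV -> ratio 77.21
```

The recovered ratio (77.2) sits a few points from the planted 72.9: at the
default signal-to-noise ratio the residual background left after filtering
and 135-trial averaging perturbs the two amplitude estimates slightly. With
`snr = Inf` the chain returns the planted amplitudes to within 2%.

The gating rules themselves:

```r
compute_gating(peak_score(0.4), peak_score(1.0))$ratio          # 200 (truncated)
compute_gating(peak_score(1.0), peak_score(NA, found = FALSE))  # S2 imputed
#> <gating_result> S1 1.000 uV, S2 0.010 uV (imputed, full suppression) -> ratio 1.00
```

A full synthetic study:

```r
res <- run_pipeline(cohort_spec(n_subjects = 30, seed = 2024),
                    out_dir = "run", n_paired_trials = 25)
res$paired_t_s1_s2$t       # 2.68 — group-level gating effect (S1 > S2)
subset(res$report$bivariate, measure == "latent_inhibition")
#>             measure          r  n          p
#> latent_inhibition -0.4051587 30 0.02634568
```

(At n = 30 with only 25 paired trials per subject the planted r = −.63 is
attenuated by EEG measurement noise and estimated with a wide CI; the
structure-recovery tests use larger cohorts.)

## Documentation

The methods vignette (`vignettes/p50-gating-methods.Rmd`) documents the
signal model, every numeric constant and its origin, the design decisions
taken where the procedure is underdetermined, and known limitations.
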