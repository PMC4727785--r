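---
title: "Models and methods behind p50gate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind p50gate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p50gate)
```

`p50gate` turns the paired-click sensory-gating analysis — raw EEG to P50
gating ratios, trial logs to inhibition indices, score table to a
correlation battery — into a reproducible pipeline with a synthetic-data
module that provides known ground truth at every stage. This vignette
explains the models, the constants and where each one comes from, the
decisions taken where the procedure is genuinely underdetermined, and what
passing the package's tests does and does not establish about real data.

## The signal model behind the simulator

Each simulated subject carries a ground-truth profile: S1 and S2 P50
peak-to-trough amplitudes (µV), an N40 trough value, component latencies,
one true effect per behavioural task, and integer IQ/OSPAN scores. A
recording is built as

* **ERP components.** N40 and P50 are single-cycle Gaussian-windowed
  cosines (Gabor atoms, envelope SD 8 ms, carrier 35 Hz) centred at the
  planted latencies. Nothing in the gating literature prescribes a
  waveform shape; Gabor atoms are analytically simple and, with their
  energy near the middle of the 10–50 Hz analysis band, survive the filter
  chain with little distortion. The remaining distortion is removed by
  calibration: each subject's template is passed through the exact filter
  chain and scored once, and the template is rescaled so that the planted
  peak-to-trough amplitude is what the scoring rule recovers in the
  noise-free limit (every stage involved is linear, so a single scale
  factor suffices). This is why the end-to-end chain reproduces planted
  amplitudes to within 2% at `snr = Inf`.
* **Background.** Every electrode receives 1/f ("pink") Gaussian noise —
  the canonical first-order spectrum of resting EEG — generated by
  frequency-domain shaping with a 0.5 Hz flattening floor. The `snr`
  parameter is the planted S1 amplitude divided by this broadband noise
  SD. The default is `snr = 0.75` (noise SD ≈ 1.8 µV for a typical
  1.33 µV component): raw background an order of magnitude larger than
  the component, which is then beaten down by 135-trial averaging and
  band-pass filtering, as in real recordings. At this default the
  pipeline recovers planted gating ratios across a 40-subject cohort with
  correlation ≈ 0.97; recovery degrades to ≈ 0.91 at `snr = 0.5` and
  fails the package's 0.9 recovery requirement near `snr = 0.3`.
* **Artifacts.** Blinks are Poisson-timed (0.15/s) raised-cosine pulses
  (~150 µV, 250 ms) on the vertical EOG pair, propagated to Cz with
  coefficient 0.1; horizontal saccade steps appear on the HEOG pair at
  0.1/s; 50 Hz line noise (default 1 µV) is added to all channels.
* **Timing.** 135 paired trials (S1, then S2 after a 500 ms ISI) and 15
  interleaved click trials. The acquisition protocol used a 10 s
  inter-trial interval so that brain activity returns to baseline; the
  simulator defaults to 1 s because the ITI does not interact with
  scoring windows, and a 10× shorter recording keeps simulation-heavy
  tests fast. It is configurable (`iti = 10` reproduces protocol timing).
  Click-trial behavioural responses are not simulated; in the protocol
  the click task existed only to keep participants engaged.

### The planted correlation structure

Cohorts are drawn from a Gaussian copula: a latent multivariate normal
vector per subject with a target correlation matrix over the 16 measures
(gating ratio, 12 task indices, IQ, OSPAN), mapped to each measure's mean
and SD by a location–scale transform. Because all margins are normal up to
location and scale, planted correlations are exact in expectation. The
planted per-subject measure values are kept on this continuous scale in
`cohort$measures`; physical clipping — gating ratio to [2, 200] before
deriving S2 = ratio × S1 / 100, error counts to [0, 12], accuracy to
[0, 1], integer rounding of IQ/OSPAN — is applied only to the derived
profile fields used for waveform and trial simulation, so tail clipping
never silently distorts the planted correlation structure.

The default target matrix is calibrated to the published study this
pipeline is designed around:

* the gating-ratio column holds the published bivariate correlations
  (latent inhibition −.63, novel pop-out −.47, orienting −.38, CPT
  accuracy −.38, IQ −.42, OSPAN −.23, and the small non-significant
  entries);
* the task–covariate entries for the four partial-correlation tasks are
  *solved* from the published partial correlations — e.g. r(LI, IQ) = .18
  is the value that maps the bivariate −.63 to the reported −.62 given
  r(gating, IQ) = −.42. Notably the reported strengthening of the CPT
  correlation under covariate control (−.38 → −.58) is representable: it
  implies r(CPT, IQ) ≈ −.29 and r(CPT, OSPAN) ≈ −.47;
* the remaining cross-measure entries are invented weak within-family
  couplings (.15–.35). They are not published values; they are needed
  because a matrix with the published gating column and zeros elsewhere is
  *not* positive semi-definite (the squared gating correlations sum to
  1.25), so some positive coupling among the gating-correlated measures is
  a mathematical necessity, not just realism. The default matrix has
  minimum eigenvalue 0.06.

`cohort_spec(empirical = TRUE)` plants the matrix exactly (the latent
draws are rescaled so the sample correlation equals the target). The
structure-recovery test uses this mode at n = 5000 to verify that the
margin transforms plus the battery introduce less than 0.03 distortion in
any gating correlation, isolated from Monte-Carlo sampling error; random
sampling convergence is verified separately.

Marginal means and SDs default to the published descriptive table. Where
only a group mean and a paired *t* are printed, the between-subject SD of
the effect is recovered as `mean × sqrt(n) / t` (e.g. Stroop:
75 × √49 / 5.32 = 98.7 ms). The printed CPT-RT dispersion of 14 ms is used
as given, though it is plausibly a standard error; it only affects the
realism of that one margin.

### Behavioural trial logs

Reaction times are ex-Gaussian, RT = N(µ, σ) + Exp(τ), the standard
descriptive RT model; the planted condition effect shifts µ only, so the
scored mean-difference index is unbiased for the planted effect (verified
by a simulation oracle). Trial counts and condition splits follow the
acquisition protocols: 30 Stroop trials, 150 Simon, 290 ANT, 15 per search
condition (PE/NPE/NOV), 75 priming trials, 60 go/no-go trials with an
80/20 go/no-go split, 100 switch trials, 180 saccade trials, 273 CPT
trials with 30% targets. Go/no-go commission errors are Bernoulli per
no-go trial with probability planted-errors/12; CPT hits are Bernoulli
with the planted accuracy. Operation-span items use set sizes 2–7 in three
blocks (maximum absolute score 81), with perfect-recall probability
matched to the planted span; imperfect recall corrupts order or drops a
letter so the set scores zero under the absolute rule.

## Preprocessing: constants and realization

The chain is fixed: re-reference → filter → ocular correction → segment →
artifact rejection → baseline → average.

* **Re-referencing** to the average of TP9/TP10 is placed first. The
  protocol lists it only as "offline"; it must precede the ocular
  regression because the reference changes the regression coefficients,
  and a fixed position makes runs comparable. EOG channels are bipolar
  derivations and are not re-referenced.
* **Filters.** The "10–50 Hz band-pass, 24 dB/octave" is realized as a
  4th-order Butterworth high-pass at 10 Hz cascaded with a 4th-order
  low-pass at 50 Hz (24 dB/octave per edge; a single 8-pole narrow
  band-pass in transfer-function form is numerically marginal at a
  normalized band of 0.01–0.05). The 50 Hz notch is a 2nd-order biquad
  with quality factor 35 (−3 dB width ≈ 1.4 Hz; no width is prescribed
  anywhere). All stages run forward–backward (zero-phase) so peak
  latencies are unshifted; this doubles the effective roll-off, which is
  accepted and documented rather than compensated. Filtering uses
  reflection padding at the record ends to suppress edge transients.
  Measured response: −100 dB at 50 Hz, −111 dB at 2 Hz, −0.15 dB at
  30 Hz.
* **Ocular correction** is a regression (Gratton–Coles family):
  propagation coefficients of each scalp channel on the bipolar VEOG and
  HEOG derivations are estimated by least squares after subtracting
  per-condition event-related averages (so evoked activity common to EEG
  and EOG does not inflate the coefficients), then the raw bipolar EOG
  scaled by the coefficients is subtracted. A single combined regression
  is used; the original algorithm's blink/saccade distinction is not
  implemented, and a constant (degenerate) EOG yields zero coefficients
  with a warning. EOG channels are never modified.
* **Epochs** span −100 to +200 ms inclusive around the marker sample
  (601 samples at 2000 Hz); markers whose window exceeds the recording
  are dropped with a logged reason.
* **Artifact rejection** flags an epoch when any scalp-channel sample
  leaves ±50 µV or when the absolute one-sample difference scaled to
  µV/ms exceeds 50 (at 2000 Hz a one-sample step of s µV is 2s µV/ms).
  The protocol's "semi-automatic inspection" is implemented as fully
  automatic thresholding with a per-epoch report — reproducibility over
  operator judgment. Screening covers scalp channels only: raw EOG
  traces legitimately carry 100+ µV blinks, and rejecting on them would
  discard precisely the epochs the ocular regression exists to save.
* **Baseline** is the half-open interval [−100, 0) ms — the onset sample
  belongs to the post-stimulus side — subtracted per epoch and channel.
  The operation is idempotent.

## P50 scoring rules

P50 is the most positive *local* peak at Cz between 40 and 80 ms; N40 the
most negative local trough between 20 and 50 ms, constrained to precede
the P50. "Local" means the discrete first difference changes sign: a
window-edge extremum of a monotone segment is not a peak, so a flat or
ramping evoked yields "no P50" rather than a spurious score. Ties break
toward the earlier latency; latencies are reported on the 0.5 ms sample
grid without interpolation. Window endpoints are inclusive. Where the
protocol text gives both "a 40 ms period" and the bounds 40–80 ms, the
bounds are taken as authoritative.

Two fallbacks handle underdetermined cases. If no local trough precedes
the P50 inside 20–50 ms, the minimum value over the pre-P50 part of that
window serves as the trough (the amplitude definition requires *some*
preceding trough value). "No obvious P50" — a visual judgment in the
original procedure — is operationalized as: no positive local maximum in
the window, or a resulting amplitude at or below a configurable floor
(default 0.05 µV, logged in the configuration).

Gating arithmetic: ratio = 100 × A(S2)/A(S1). No S1 P50 → subject
excluded (an S1 scored "found" with non-positive amplitude is demoted to
not-found with a warning). No S2 P50 → full suppression, S2 amplitude
imputed as 0.01 µV. Ratios above 200 are truncated to 200 — applied to
the per-subject ratio only, after imputation. Subjects with S2 > S1
(ratio between 100 and 200) receive no special handling beyond the
ceiling.

## Behavioural indices

All RT indices are mean differences over correct responded trials only;
incorrect or withheld trials never contribute RTs (property-tested by
poisoning incorrect-trial RTs). An empty condition cell yields a missing
value, not zero. Specifics:

* Stroop, Simon, flanker: incongruent − congruent. Switch: switch −
  repetition. Antisaccade: anti − pro. Negative priming: ignored
  repetition − control. Latent inhibition: PE − NPE; novel pop-out:
  NPE − NOV.
* ANT cue contrasts: the source text's formulas (alerting = no cue −
  centre cue; orienting = no cue − spatial cue) are the default
  (`ant_convention = "paper_text"`), because fidelity to the analysed
  procedure comes first; the standard convention (alerting = no cue −
  double cue; orienting = centre cue − spatial cue) is available as
  `"fan2002"`. The source's own descriptive table is internally
  inconsistent for these two rows (its orienting row calls 584 ms
  "faster" than 511 ms); the generator plants effect means of 50 and
  73 ms taken from the printed row differences, and the inconsistency is
  flagged here rather than resolved.
* Go/no-go: count of responded no-go trials. CPT: accuracy = hits /
  targets (false alarms are not folded in) and mean RT over hits. OSPAN
  absolute score: sum of set sizes over sets recalled perfectly in
  order.
* No RT outlier trimming is applied anywhere (none is prescribed); a
  winsorization hook exists in principle through the configuration but
  is off by default.

## The correlation battery

* **Bivariate**: Pearson r on pairwise-complete cases (each pair keeps
  its own n, matching designs where different tasks lose different
  subjects), p two-tailed from t with n − 2 df.
* **Partial** (controlling IQ, OSPAN, or both): correlation of
  least-squares residuals on the covariate set, listwise-complete across
  the involved variables, df = n − 2 − k. The residual route is tested
  to 1e-12 against the recursive first/second-order formulas.
* **Williams's t** for two dependent correlations sharing the gating
  variable, in Steiger's T2 form with df = n − 3, computed for every
  pair of measures significantly correlated with gating. Because the
  design's source literature reports Z statistics under the name
  "Williams's t", Steiger's Z on Fisher-transformed correlations (pooled
  mean-correlation covariance term) is reported alongside. Under the
  null at n = 40 the t's simulated rejection rate is 4.4% at nominal 5%.
* **Paired t** for the group-level S1-vs-S2 amplitude comparison;
  constant nonzero differences return an infinite statistic with p = 0
  rather than erroring.
* **Outlier screen**: residuals of the simple regression of index on
  gating ratio, standardized by √MSE (the ZRESID convention of the
  typical point-and-click statistics package behind ±1.96 screens, not
  the leverage-adjusted studentized form), flagged beyond ±1.96.
* Significance is fixed at two-tailed 0.05 with no multiplicity
  correction, matching the analysed procedure; `p_adjust = "holm"` is
  available but off by default. The gating ratio enters all correlations
  as the truncated percentage.

## Orchestration

`run_pipeline()` runs simulate → preprocess → score → correlate for a
cohort. Per-subject failures and exclusions are logged into the manifest
(with reasons) and never abort the cohort; if fewer than 4 usable
subjects remain the battery refuses with "no usable subjects". The
manifest records package version, seed, simulation parameters and the
full configuration, so a run is reproducible from the manifest alone.
All stage outputs are plain CSV/JSON; recordings can round-trip through
BrainVision Core files (`.vhdr`/`.vmrk`/`.eeg`, IEEE float 32,
multiplexed). Identical spec + seed gives byte-identical outputs.

## Problem sizes used in the test suite

Simulation scales were chosen to make the checks sharp but quick: the
recovery test uses 40 subjects at the full 135 paired trials; the
pipeline smoke test 30 subjects at 25 trials; structure recovery plants
at n = 5000; stochastic calibration targets average 50–200 seeds; the
scored-effect dispersion oracle uses 4000 brute-force replicates. The
paired-t calibrations reproduce the published group statistics: S1/S2
amplitude pairs with means 1.33/0.97 µV, SD 0.99 µV and r = .87 at
n = 50 give mean t ≈ 5.1, and Stroop effects N(75, 98.7) ms at n = 49
give mean t ≈ 5.4 against the published 5.32 (the t statistic's expected
value slightly exceeds its noncentrality parameter at finite df).

## What the synthetic cohort does *not* emulate

No drowsiness or impedance drift, no bad channels or channel-count
variation, no alpha rhythms or other structured oscillations beyond 1/f,
no eye-tracking sample streams (antisaccade logs arrive pre-classified
with saccade RTs), no item-level IQ simulation (the test is
paper-and-pencil; the score is planted directly), and no S2 dependence
on attention or arousal within a session — the planted ratio is
stationary. Passing the recovery tests therefore shows the pipeline is
correct and well-calibrated under this model, not that it is robust to
every pathology of real recordings; the artifact-handling stages are
exercised only by the blink/saccade/line-noise model described above.
Acoustic stimulus parameters (4100 Hz tone, 70–75 dB, 10 ms bursts) do
not influence any computation and are carried only as documentation.
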