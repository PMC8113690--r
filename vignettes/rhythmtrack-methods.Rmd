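---
title: "Methods: neural tracking of auditory rhythms in disorders of consciousness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neural tracking of auditory rhythms in disorders of consciousness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmtrack)
library(dplyr)
```

## The problem

Patients with prolonged disorders of consciousness (DOC) — the unresponsive
wakefulness syndrome (UWS) and the minimally conscious state (MCS) — are
hard to assess behaviourally, and misdiagnosis rates with purely clinical
scales are high. A passive EEG paradigm sidesteps the need for voluntary
responses: the patient simply listens. When a sound carries a temporal
rhythm, auditory cortex (and, near 40 Hz, thalamocortical circuits) locks
its activity to that rhythm; the strength of this locking indexes the
integrity of the underlying circuitry. `rhythmtrack` implements the full
analysis chain for two such paradigms:

* a tone sinusoidally amplitude modulated at 41 Hz and frequency modulated
  at 2 Hz, which evokes steady-state responses at 2 and 4 Hz (FM fundamental
  and harmonic), at 41 Hz (AM), and at the 39/43 Hz intermodulation
  sidebands ("41 ± 2 Hz");
* narrated natural speech, whose slow envelope (delta and theta bands) is
  tracked by cortex.

## The statistic

Both paradigms reduce to one statistic. EEG and the stimulus modulation are
cut into non-overlapping 2-s bins and transformed by DFT, giving a response
phase $\alpha_{ft}$ and stimulus phase $\beta_{ft}$ per 0.5 Hz frequency
bin $f$ and segment $t$. The resultant of the phase differences over the
$T$ segments,

$$R_f = \left|\sum_{t=1}^{T} e^{i(\alpha_{ft}-\beta_{ft})}\right|,$$

measures how consistently the response phase follows the stimulus. The
package stores three normalizations side by side, because they serve
different purposes:

* `coherence_norm` $= R_f/T \in [0,1]$ — comparable across recordings of
  different length; this is the quantity that is averaged over channels and
  participants, correlated with clinical scores, and fed to classifiers;
* `rayleigh_z` $= R_f^2/T$ — the Rayleigh test statistic for circular
  uniformity, with large-sample $p = e^{-z}$, so $z > 3$ rejects uniform
  phase at $P < 0.05$ (`rayleigh_p(3)` = `r round(rayleigh_p(3), 4)`); a
  finite-sample refinement is applied when $T$ is supplied;
* the raw `resultant`.

For the modulated tone the stimulus period (0.5 s) divides the analysis bin,
so $\beta_{ft}$ is constant over $t$ and the computation reduces — exactly,
by rotation invariance of the resultant — to the inter-trial phase
coherence of the response phases alone (`itpc()`). For speech, $\beta$ is
the segmented DFT phase of the broadband envelope over the same bins.

Statistical analysis concentrates on a 14-channel centro-frontal region of
interest (Fz, F1–F4, FC1–FC4, Cz, C1–C4), where these responses are
largest. Topographies use a *signed* coherence: an electrode whose mean
response phase differs from Fz by more than 90° has its coherence negated
(at exactly 90° the positive sign is kept — the rule only prescribes the
strict inequalities, and the boundary case is measure-zero). For display,
topographies are normalized by the 95th percentile of the absolute values
across electrodes.

## Inference

**Chance level.** The tone evokes responses only at integer frequencies, so
coherence at the 50 non-integer frequencies 0.5, 1.5, …, 49.5 Hz is
chance. Because significance is assessed on group means, the null is built
at the group level: draw $N$ of the 47 participants, average their ROI
coherence at each chance frequency, repeat 1,000 times, and pool — 50,000
chance values. The one-sided empirical p of an observed group mean is its
exceedance fraction in the pool, floored at 1/50,000 (an exact zero would
break FDR correction and log-scale reporting). Benjamini–Hochberg FDR at
$\alpha = 0.01$ is applied across the integer frequencies of one spectrum;
each reported table or figure is corrected as its own family, since no
global family is defined anywhere.

**Group contrasts.** Unpaired comparisons use a bootstrap: resample each
group 5,000 times with replacement and count the $N$ iterations whose mean
difference contradicts the tested direction; $p = (N+1)/5001$. The tested
direction is stated a priori (HC ≥ DOC-P ≥ DOC-N); choosing the direction
from the observed means would make the one-sided p anti-conservative under
the null (it would be uniform on $[0, 0.5]$). A bias-corrected and
accelerated interval for the mean difference is computed alongside as a
diagnostic; the counting rule is the primary p-value because it is the only
rule fully specified for this procedure.

**Correlations.** Pearson correlations between band coherence and clinical
scores (CRS-R, GOS-E) are two-tailed, with at most one gross outlier
removed. The removal rule — drop the single point with the largest absolute
externally studentized residual if it exceeds 3 — was left open by the
procedure it implements; the studentized-residual rule was chosen because
it is deterministic, scale-free, and removes at most one point. The 6
features × 2 scores table is corrected as one 12-test BH family.

**Classification.** RBF-kernel SVMs discriminate MCS from UWS (diagnosis)
and positive from negative outcome (prognosis), where a positive outcome is
any advance in the ordered categories UWS < MCS− < MCS+ < EMCS between
baseline and follow-up. Feature sets: `hi` (41, 41±2 Hz), `lo` (2, 4 Hz),
`speech` (delta, theta), `combo` (lo + speech); participants with
incomplete speech data are excluded from `speech`/`combo`. The protocol is
a stratified 70/30 split (per-class training count
$\lfloor 0.7 n + 0.5\rfloor$, ties toward training), a grid search over
cost $\in 2^{-5..15}$ and $\gamma \in 2^{-15..3}$ by stratified 5-fold CV
accuracy (ties broken toward smaller cost, then smaller $\gamma$), and
test-set evaluation: confusion matrix, sensitivity, specificity, accuracy,
AUC from the continuous decision values, and a Pearson chi-square on the
confusion table (without continuity correction; the Yates value is kept
alongside). Features are z-scored with training-set statistics only — RBF
kernels are scale-sensitive, so standardization is applied even though the
protocol description leaves it implicit. Because a single split of ~30
patients is strongly seed-dependent, the primary output of
`run_protocol()` is the distribution of metrics over repeated splits with
its median; `n_repeats = 1` reproduces a single split exactly.

## The synthetic cohort generator

No patient EEG is distributed with this package, so `simulate_cohort()`
generates cohorts with the statistical structure the analysis assumes: by
default 16 HC, 15 patients with positive outcome (DOC_P), and 16 with
negative outcome (DOC_N), two sessions for the speech condition and one for
the tones.

**Signal model.** Each EEG channel is a sum of phase-locked sinusoids at
the response frequencies, $1/f$ background noise, and a leaked ocular
trace; an EOG channel carries the ocular trace itself. Within each 2-s
segment the response phase equals the stimulus reference phase plus a von
Mises jitter whose concentration $\kappa$ is obtained by inverting the mean
resultant length $A(\kappa) = I_1(\kappa)/I_0(\kappa)$ at the target
coherence. This gives an exact analytic link between the generator's knob
and the measured statistic: realized normalized coherence converges to the
target as $T$ grows (a target of 1 with no noise yields exactly 1). The
39/43 Hz sidebands are injected directly rather than arising from a
nonlinear interaction model, since downstream they are simply response
frequencies. The two speech sessions share their response phases (the
response to a repeated stimulus is assumed reproducible) with independent
noise, so session averaging raises SNR without changing the coherence
target.

**Between-participant structure.** DOC cohorts are extremely heterogeneous,
and that heterogeneity is what makes group contrasts hard. The generator
draws one latent "responsiveness" factor per participant, shared across
bands with weight 0.97, and gives each band target multiplicative Gaussian
dispersion with coefficient of variation $2 \times$ `target_jitter_sd`
(default 0.5, i.e. CV 1.0), clipped to $[0, 1]$. Two properties of this
choice matter. First, dispersion scaling with the mean puts the
poorly-responding group near the floor with a tight distribution while
strong responders spread widely — the only dispersion family under which
"HC ≈ DOC-P, both ≫ DOC-N at 41 Hz" can hold simultaneously at these
group sizes (homoscedastic jitter provably cannot satisfy both, since the
two effects differ only fourfold while sharing one noise scale). Second,
the shared latent factor makes a participant's band features co-vary, as
responses of one brain do.

**Clinical scores.** CRS-R is an affine map of the 41 Hz target
($3 + 25\,t$, rounded, clipped to 0–23, plus Gaussian noise), GOS-E
likewise ($1 + 9\,t$, clipped to 1–8); the baseline category (UWS/MCS−/MCS+)
follows from CRS-R, the follow-up category advances for DOC_P and stays or
regresses for DOC_N, and the outcome label is recomputed from the category
transition, so the labelling invariant holds by construction.
`score_noise_sd_for_rho()` inverts the affine-plus-noise model to hit a
prescribed coherence–score correlation in recovery studies.

**Two modes.** `mode = "waveform"` renders full multi-channel EEG and is
used by the end-to-end pipeline and calibration runs. `mode = "features"`
draws the same von Mises segment phases and reduces them directly to band
coherences, skipping waveform rendering; it is the identical generative
model one level up, and is used for many-replicate power and recovery
studies where rendering hundreds of full cohorts would be wasteful.

**What the generator does not emulate:** real electrode geometry beyond a
coarse centro-frontal gain profile, non-stationary artifacts (movement,
electrode pops), etiology heterogeneity, latency differences between
groups, or genuine nonlinear generation of the sidebands. Tests passing on
these cohorts therefore validate the analysis machinery — estimator
correctness, calibration of the nulls, recovery of built-in effects — not
clinical performance on real patients.

## Numerical and design choices

* **Filtering:** zero-phase FIR low-pass before decimation to 100 Hz,
  Kaiser window spanning 200 ms of the input rate (201 taps at 1 kHz),
  −6 dB cutoff 47.5 Hz, β = 3. This keeps the 43 Hz sideband in the
  passband while attenuating above the 50 Hz Nyquist of the target rate;
  the kernel is normalized to exact unity DC gain. Edge effects are handled
  by reflection padding.
* **Pipeline order:** filter/downsample → EOG regression → common-average
  re-reference → session averaging. EOG regression precedes re-referencing
  so ocular signal is not smeared across channels by the average; the EOG
  channel is excluded from the average and left untouched. Sessions of
  unequal length are trimmed to the shorter.
* **Stimulus defaults:** carrier 500 Hz, AM depth 1, FM deviation 20 Hz,
  waveform rate 4 kHz (the carrier must stay below Nyquist; only the
  modulation phases matter downstream). Reference phases use the cosine
  convention of the DFT; sine modulators therefore have phase $-\pi/2$,
  harmonics and sidebands get multiples and sums of the component phases.
  An unmodulated component (zero AM depth or FM deviation) has no
  reference phase: the generator refuses to emit one rather than invent it.
* **Degenerate inputs** are refused with diagnostics rather than silently
  patched: constant EOG (singular regression), zero topography normalizer,
  single-class training data, empty nulls. A zero-resultant channel has no
  mean phase; its topography sign is forced positive with a warning.
* **Chance-frequency grid:** the chance null uses the 50 frequencies
  0.5, 1.5, …, 49.5 Hz (odd multiples of 0.5 Hz), not all 99 half-integer
  bins — 2nd-order intermodulation products of the 2/41 Hz modulators land
  only on integer frequencies, and the x.5 grid is what yields a pool of
  exactly 50,000.
* **Spectrum averaging:** group spectra average `coherence_norm` across
  electrodes and participants (not the raw resultant or $z$), since it is
  the only one of the three normalizations on a common scale.

## Problem sizes

The shipped tests and the acceptance script use cohorts of 16/15/16
participants with $T = 450$ two-second segments (15 min) per recording for
calibration runs, $T = 60$ for bookkeeping checks, and feature-mode cohorts
for 50-seed recovery studies; these sizes were chosen so a full run
completes comfortably on a single CPU while leaving the Monte-Carlo margins
of the checks intact. The generator's defaults (cohort composition, targets,
dispersion) are independent of these sizes and are documented above.

## Known limitations

* The chi-square reported for a confusion matrix is a coarse association
  measure on a small table; at test-set sizes near 10 its asymptotic
  p-value is approximate at best. It is reported for completeness, with
  AUC as the primary discrimination measure.
* The empirical-p floor (1/50,000) makes extremely significant frequencies
  indistinguishable from one another.
* BCa intervals accompany, but do not replace, the counting-rule bootstrap
  p; with ≤ 16 observations per group the acceleration estimate is itself
  noisy.
* Real DOC EEG contains artifact structure and nonstationarity the
  generator does not model; performance numbers on synthetic cohorts
  measure the pipeline, not the clinic.
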