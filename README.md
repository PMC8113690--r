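# rhythmtrack

Quantifying how strongly the brain tracks auditory rhythms, and what that
tracking says about disorders of consciousness (DOC).

Patients in an unresponsive wakefulness syndrome (UWS) or a minimally
conscious state (MCS) cannot cooperate with behavioural testing, and
misdiagnosis is common. A passive EEG paradigm needs nothing from the
patient but listening: when a sound is rhythmically modulated — a tone
amplitude-modulated at 41 Hz and frequency-modulated at 2 Hz, or the slow
envelope of narrated speech — neural activity phase-locks to the rhythm,
and the strength of that locking indexes the integrity of thalamocortical
and cortical circuits. `rhythmtrack` implements the complete analysis for
clinical neurophysiologists and methods researchers: the coherence
statistic, its resampling-based inference, clinical-score correlations, and
SVM-based diagnosis/prognosis classification, plus a synthetic-cohort
generator with known ground truth so every stage is testable without
patient data.

## The statistic

EEG and stimulus modulation are segmented into non-overlapping 2-s bins and
DFT-transformed, giving response and stimulus phases α_ft, β_ft per 0.5 Hz
bin. The resultant of the phase differences over T segments,

    R_f = | Σ_t exp(i(α_ft − β_ft)) |,

is reported as the normalized coherence R_f/T ∈ [0, 1] (the primary
quantity), and as the Rayleigh statistic z = R_f²/T, where z > 3 rejects
phase uniformity at P < 0.05. For the periodic tone the stimulus phase is
constant within every bin and the statistic reduces exactly to the
inter-trial phase coherence. Analyses aggregate a 14-channel centro-frontal
region of interest; group-level significance is assessed against a pooled
chance distribution built from the 50 non-integer frequencies (1,000
group-average resamples × 50 frequencies = 50,000 chance values), with
Benjamini–Hochberg FDR across frequencies; group contrasts use a 5,000-fold
bootstrap with p = (N+1)/5001.

## Worked example

Simulate a small cohort (6 healthy controls, 6 patients with positive
outcome, 6 with negative outcome), compare the 41 Hz-band coherence across
groups, and train the diagnostic classifier:

```r
library(rhythmtrack)

spec <- cohort_spec(n_per_group = c(HC = 6, DOC_P = 6, DOC_N = 6),
                    n_segments = 150, seed = 42)
coh <- simulate_cohort(spec, mode = "features")

dplyr::select(coh$features[1:4, ], id, group, outcome, crsr_baseline,
              coh_41, coh_2)
#> # A tibble: 4 × 6
#>   id    group outcome crsr_baseline coh_41  coh_2
#>   <chr> <chr> <chr>           <dbl>  <dbl>  <dbl>
#> 1 P001  HC    <NA>                5 0.105  0.0916
#> 2 P002  HC    <NA>               23 1      0.741
#> 3 P003  HC    <NA>                3 0.0887 0.125
#> 4 P004  HC    <NA>               23 1      0.663

compare_groups(coh$features, feature_cols = c("coh_41", "coh_41pm2"),
               seed = 1)
#>     feature group_a group_b mean_a mean_b p_value  p_adj significant
#> 1    coh_41      HC   DOC_P  0.582  0.315  0.0618 0.0741       FALSE
#> 2    coh_41      HC   DOC_N  0.582  0.148  0.0014 0.0028        TRUE
#> 3    coh_41   DOC_P   DOC_N  0.315  0.148  0.0154 0.0231       FALSE
#> 4 coh_41pm2      HC   DOC_P  0.468  0.322  0.1624 0.1624       FALSE
#> 5 coh_41pm2      HC   DOC_N  0.468  0.118  0.0002 0.0012        TRUE
#> 6 coh_41pm2   DOC_P   DOC_N  0.322  0.118  0.0012 0.0028        TRUE
```

Each row is a one-sided bootstrap comparison of the ROI-mean normalized
coherence (the `mean_a`/`mean_b` columns); at this small size only the
contrasts against the negative-outcome group survive FDR at α = 0.01 —
patients with a negative outcome lock far more weakly to the 41 Hz rhythm.

```r
run_protocol(coh$features, "hi", "diagnosis", n_repeats = 10, seed = 2)
#> <protocol_result: hi features, diagnosis task, 10 repeats>
#> # A tibble: 1 × 4
#>   median_sensitivity median_specificity median_accuracy median_auc
#> 1                  1                  1               1          1
```

The RBF-SVM protocol (stratified 70/30 split, 5-fold-CV grid search over
cost and γ, repeated over 10 split seeds) separates MCS from UWS perfectly
here because in this synthetic cohort the diagnosis is driven by the same
latent responsiveness that sets the 41 Hz coherence.

The full chain — waveform synthesis, EDF export, preprocessing (zero-phase
anti-alias FIR + downsampling to 100 Hz, least-squares EOG regression,
common-average re-reference, cross-session averaging), coherence spectra,
chance nulls, correlation tables, classifiers, and a hashed output
manifest — runs from one call:

```r
res <- run_pipeline(default_run_config(seed = 1), out_dir = "run1")
```

or from the shell via `Rscript inst/cli/rhythmtrack.R --config config.yaml
--out run1`. Result objects have `tidy()`/`glance()` methods and
`autoplot()` displays (coherence spectra, signed topographies, confusion
matrices).

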