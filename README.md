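# painlfp

Analysis pipeline for **bilateral anterior-cingulate-cortex (ACC) local
field potentials (LFPs) during mechanical nociceptive stimulation**, for
electrophysiologists studying how pain intensity is encoded in cortical
population activity. The package covers the full analysis chain for
paradigms in which calibrated von Frey filaments deliver high-intensity
noxious (HN) and non-noxious (NN) stimuli to a rat's hind paw while LFPs
are recorded from both hemispheres at 1 kHz:

- **Preprocessing** — zero-phase 4th-order Butterworth band-pass
  (3–350 Hz), mains notch, iterative two-sided Grubbs trial rejection
  (trials with > 10% outlier samples are dropped), and per-session
  z-score normalization `z(t) = (x(t) − x̄)/σ`.
- **Evoked potentials** — onset-aligned trial averages with SEM;
  parametrization of the first positive peak (P1), first negative trough
  (N1) and P2 by smoothed-detection / parabolic-vertex measurement;
  samplewise Wilcoxon statistics; bilateral (ipsi vs contra) comparisons.
- **Spectral analysis** — analytic Morlet scalograms (6 cycles, 3–120 Hz
  log grid), baseline z-normalization against [−1, 0] s, and per-band
  (theta/alpha/beta/low-gamma/high-gamma) interval statistics over
  [0, 0.5] s and [0.5, 5] s.
- **Decoding** — band-limited mean-absolute-value features in 30-ms
  windows (2 hemispheres × 5 bands × 100 windows = 1,000 features per
  trial), greedy mRMR ranking
  `max_j [ I(x_j; y) − |S|⁻¹ Σ_{i∈S} I(x_j; x_i) ]`, and an RBF-kernel
  SVM validated by stratified 10-fold or leave-one-subject-out schemes
  (selection and normalization refitted inside every fold), reporting
  accuracy, Cohen's kappa, AUC, confusion matrices and feature maps.
- **Connectivity** — time–frequency phase-locking value
  `PLV = |N⁻¹ Σ_k exp(i(φ_x(ω,k) − φ_y(ω,k)))|` in sliding windows,
  sliding-window Pearson correlation (500 ms window, 1 ms step), and
  biased-estimator cross-correlation `r_xy(k) = C_xy(k)/(S_x S_y)` for
  interhemispheric lag estimation.
- **Synthetic data** — a seedable generator of bilateral LFP trial sets
  (1/f background, calibrated EP templates, band-specific post-stimulus
  gain envelopes, a post-stimulus interhemispheric coupling dip, session
  drift, withdrawal latencies, motion artifacts) with ground truth
  attached, so every stage is testable as a recovery problem.

See the methods vignette (`vignettes/painlfp-methods.Rmd`) for the models,
parameter defaults and design rationale.

## Worked example

Simulate a study-like data set, preprocess it, and read back evoked
potentials and interhemispheric dynamics:

```r
library(painlfp)

cfg <- sim_config(n_trials = c(HN = 120, NN = 120, NS = 120),
                  epoch_s = c(pre = 1, post = 5), seed = 7)
ts <- generate_trial_set(cfg)
print(ts)
#> <lfp_trial_set> 360 trials x 2 hemispheres x 6000 samples @ 1000 Hz
#>  HN  NN  NS
#> 120 120 120
#> epoch window: [-1.000, 4.999] s; 24 session(s), 4 subject(s)

pp <- preprocess_trials(ts)
sum(pp$report$rejected)
#> 0                         # clean simulation: nothing to reject

round(extract_ep_params(compute_ep(pp$trials, "HN")), 3)
#>   p1_latency_ms p1_amp n1_latency_ms n1_amp p2_present p2_latency_ms p2_amp
#> 1        92.091  1.122       155.303 -1.362          1        229.99  0.311

tr  <- sliding_correlation(pp$trials, "HN", step_ms = 5, sig_step_ms = NULL)
rec <- coupling_recovery_time(tr)
#> interhemispheric correlation: baseline 0.85, dip 0.27 at 0.80 s, recovered 3.83 s

estimate_interhemispheric_lag(pp$trials, "HN", max_lag_ms = 50)$lag_ms
#> 0                         # the two hemispheres respond synchronously
```

The noxious EP is recovered with its P1 near 92 ms (~1.1 z-units) and N1
near 157 ms (~−1.2 z-units, single-run noise included); the
interhemispheric correlation drops sharply after the stimulus and returns
to its baseline close to 4 s — the programmed persistence of the pain
effect. At 120 trials a single run carries visible estimation noise;
multi-replicate averages (below) tighten these to within a few percent.

For an end-to-end run that writes all result tables to disk:

```r
run_pipeline(pipeline_config(sim = cfg, out_dir = "out", seed = 7))
```

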