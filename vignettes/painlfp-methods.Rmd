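---
title: "Methods: bilateral ACC LFP analysis of mechanical pain intensity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bilateral ACC LFP analysis of mechanical pain intensity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

`painlfp` analyses bilateral local field potentials (LFPs) recorded from the
anterior cingulate cortex (ACC) of freely moving rats while calibrated von
Frey filaments deliver mechanical stimuli to the left hind paw at two
intensities: high-intensity noxious (HN, 30 g) and non-noxious (NN, 8 g),
alongside no-stimulation (NS) reference epochs. The pipeline covers five
analysis stages — preprocessing, evoked-potential (EP) parametrization,
Morlet time-frequency power, pain-intensity decoding, and interhemispheric
connectivity — plus a synthetic bilateral-LFP generator that makes every
stage testable as a *recovery problem*: each analysis must read back the
parameters the generator injected.

# The synthetic generator

Because raw in vivo recordings of this kind are rarely shareable, the
generator is a first-class module, not a test fixture. Each trial is built
as

$$x_h(t) = \frac{c(t)\,s(t) + (1-c(t))\,n_h(t)}{\sqrt{c(t)^2 + (1-c(t))^2}}
  + \mathrm{EP}_h(t), \qquad h \in \{\text{ipsi}, \text{contra}\},$$

where $s$ is a background source shared by both hemispheres, $n_h$ are
independent sources, and $c(t)$ is the amplitude-mixing (coupling) fraction.
The denominator keeps the background variance at exactly `noise_sd`^2 for
every coupling level; without it, session z-scoring downstream would
rescale the evoked amplitudes by a coupling-dependent factor and the
tabulated-amplitude recovery would fail by construction, not by analysis
error.

**Background.** Gaussian $1/f^\alpha$ noise (default $\alpha = 1$),
synthesized by spectral shaping between 3 and 350 Hz with raised-cosine
edges. Spectral synthesis is cheap, exactly seedable, and matches generic
LFP spectra well enough for a recovery benchmark; it makes no claim to
biophysical realism (no spikes, no cross-frequency coupling, no
non-Gaussian bursts).

**Evoked potentials.** Sums of Gaussian-windowed monophasic lobes. The
defaults follow the tabulated EP parameters for this preparation: HN P1 at
92 ms with amplitude 1.15 (z-units), N1 at 157 ms with −1.17, plus a weaker
P2 lobe (230 ms, 0.35 — observed for noxious stimulation but not
tabulated, so its parameters are package choices); NN P1 at 61 ms (0.21)
and N1 at 157 ms (−0.18). Because neighbouring lobes overlap, the lobe
centres and heights are *calibrated* by a fixed-point iteration until the
realized extrema of the summed waveform land exactly on the specified
latencies and amplitudes; a spec whose extrema cannot be kept within one
sample raises an infeasibility error. The `width_ms` field (default 25 ms)
is the full width at half maximum, i.e. a Gaussian $\sigma \approx
10.6$ ms. This convention was chosen deliberately: with $\sigma = 25$ ms
the lobes carry substantial energy below the 3-Hz high-pass edge and the
zero-phase band-pass of the preprocessing stage attenuates P1 by 12–21%,
which would contradict the amplitude conventions the templates are defined
in; at FWHM 25 ms the attenuation is below ~5% for HN and ~10% for NN.

**Filter-chain compensation.** Template amplitudes are defined in z-units
of the *preprocessed* signal — the scale EP parameters are tabulated on —
so by default the generator pre-compensates the deterministic linear gain
of the standard chain: lobe centres and heights are calibrated (an outer
fixed-point around the template calibration) until the extrema of the
band-pass-filtered template, divided by the chain's baseline-SD gain
(computed analytically from the synthesis mask and the squared Butterworth
response), land exactly on the spec values. `compensate_filter = FALSE`
injects the raw calibrated template instead; the raw-template extrema
always satisfy the spec values by construction.

**Ipsilateral dominance.** For HN the ipsilateral EP is larger than the
contralateral (`ipsi_gain`, default 1.3). The scaling is mean-preserving
(ipsi $\times 2g/(1+g)$, contra $\times 2/(1+g)$) so that the
hemisphere-pooled EP — which is what the tabulated amplitudes describe —
retains the template amplitude while the ipsi/contra ratio equals $g$.

**Band modulation.** Post-stimulus power changes are injected by
multiplying the band-restricted part of each background source by a gain
envelope: amplitude gain `early_gain` on [0, 0.5] s, `late_gain` from
0.5 s, then a linear relaxation to 1 reached at `recovery_s` (default 4 s,
with a plateau until 1.5 s). Defaults for HN follow the reported
directions: all bands up early; theta/alpha/beta down (×0.6–0.7) and the
gamma bands up (×1.3–1.4) late; NN uses milder gains. Modulating the
band-restricted decomposition of the *same* noise (rather than adding
independent band-passed noise) keeps the pre-stimulus variance exactly at
`noise_sd`^2, so baseline z-units stay meaningful. Gains are amplitude
multipliers; power scales with their square.

**Coupling dip.** After HN stimulation $c(t)$ drops by
`post_stim_dip_depth` (default 0.5) at 0.5 s and relaxes linearly over
`dip_duration_s` (default 3.5 s, i.e. recovered at 4 s) — the programmed
version of the few-second interhemispheric desynchronization this
preparation shows. The dip applies to HN trials only; for NN the reported
variations were not significant, so NN and NS trials keep constant
coupling.

**Behaviour, sessions, subjects.** HN trials carry paw-withdrawal latencies
drawn from N(225, 10²) ms. Trials are distributed over subjects (default
4) and sessions (2 per subject and class) with multiplicative session gain
drift, which the session z-scoring stage must undo. Sessions are
intensity-specific — each session holds one stimulation class, as in the
experimental protocol — so session normalization never mixes classes. Per-trial RNG substreams are
derived by counter from the master seed, so enlarging a trial count leaves
earlier trials byte-identical.

**SNR.** The source study reports no single-trial SNR, so it is a free
parameter: `noise_sd = 1` means template amplitudes *are* single-trial
SNRs (HN P1 ≈ 1.15, NN P1 ≈ 0.21). All stated recovery tolerances hold at
this default.

# Preprocessing

Zero-phase (forward–backward) 4th-order Butterworth band-pass, 3–350 Hz,
with explicit odd-reflection padding; causal filtering would bias P1/N1
latencies. The signal mean is removed before filtering so DC is nulled
exactly. Mains interference, when present, is removed by cascaded biquad
notches (Q = 30) at the mains frequency (default 50 Hz) and its harmonics
up to 350 Hz. Motion-distorted trials are detected per trial and
hemisphere by *iterative two-sided Grubbs* outlier testing (α = 0.05 per
iteration; implemented on a sorted copy with incremental moment updates, so
a 4,000-sample trial costs O(n log n)); trials with more than 10% flagged
samples on either hemisphere are rejected, as are behaviourally flagged
trials. Finally each channel is z-scored per session (sample SD, n−1
denominator; the normalization equation does not fix the denominator and
the sample convention is standard), which cancels session gain drift. For
epoched data the session statistics are estimated from the *pre-onset*
samples by default: continuous recording sessions are dominated by
inter-trial rest (a ~5-s stimulus effect per ~60-s inter-stimulus
interval), so the pre-onset interval is the unbiased proxy for
whole-session statistics, whereas whole-epoch statistics would let the
transient post-stimulus power set the units and make amplitudes depend on
the epoch length (`norm = "all"` restores the whole-epoch convention).
Sample indexing is 0-based half-open with time 0 at stimulus onset; a
stimulus epoch of [0, 3) s at 1 kHz has exactly 3,000 samples.

# Evoked potentials

EPs are plain onset-aligned trial averages with SEM. Parametrization: P1 is
the earliest qualifying positive local maximum in [20, 130] ms, N1 the
earliest qualifying negative local minimum in [80, 260] ms after P1, P2 a
positive local maximum after N1 exceeding 3× the baseline SEM. The search
windows are package choices bracketing both classes' latencies with margin.
Detection runs on a 20-ms moving-average smoothed copy with two
qualifications — the candidate must exceed 3× the baseline SD of the
smoothed trace *and* half the window's extreme value — so smoothed noise
bumps are not mistaken for small components (the NN P1, at 0.21 z-units,
sits only a few noise SDs above a 200-trial average). Measurement is
refined on the raw trace: when the trace is noiseless the raw extremum is
reported exactly; otherwise a least-squares parabolic vertex fitted over
±10 ms gives latency and amplitude. A raw maximum would be biased upward
by the noise (order +0.1–0.2 z-units at desk scale), which distorts class
amplitude ratios; the parabola's shape bias on these lobes is under 1%.

Per-trial parameters (needed for across-trial SEMs and rank tests) are
measured in windows *anchored at the class-average peaks*: the amplitude is
the trial's mean over ±10 ms around the anchored latency (unbiased at
single-trial SNR), the latency the trial's smoothed extremum within
±25 ms. A free per-trial peak search would be max-biased at this SNR and
inflate the small NN amplitudes, wrecking the HN/NN ratio identities.
Dispersion is reported across trials (the dispersion basis is not
determinable from the source; "across trials" is stated in all outputs).

Samplewise statistics use the Wilcoxon signed-rank test against per-trial
baseline means (or rank-sum between classes) at each sample, uncorrected by
default to mirror the figure-style display, with Benjamini–Hochberg behind
a flag; zero-variance differences are reported as p = 1 by convention.

# Spectral analysis

Analytic Morlet continuous wavelet transform, 6 cycles (the conventional
compromise between time and frequency resolution; configurable), on a
60-point log-spaced grid over 3–120 Hz, amplitude-normalized so a unit
sinusoid yields unit power. Epochs are reflection-padded by one wavelet
support; the per-frequency cone-of-influence half-width is recorded on
every scalogram. Power is averaged across trials *after* the per-trial
transform so induced (non-phase-locked) modulation survives. Baseline
normalization z-scores each frequency row against its own [−1, 0] s
baseline. Band statistics use theta 4–8, alpha 8–12, beta 12–30, low-gamma
30–80 and high-gamma 80–120 Hz over the evoked interval [0, 0.5] s and the
post-evoked interval [0.5, 5] s, with rank-sum (between classes) or
signed-rank (between hemispheres) tests and the conventional star encoding
(0.05/0.01/0.001/0.0001). Figure-style pooled analyses use the
hemisphere-averaged signal; bilateral comparisons keep hemispheres
separate.

# Decoding

Features: per hemisphere and band (zero-phase 4th-order Butterworth), the
mean absolute value in non-overlapping 30-ms windows over [0, 3] s — 2 × 5
× 100 = 1,000 features per trial — then column z-scoring. Ranking:
greedy mRMR maximizing $I(x_j; y) - |S|^{-1}\sum_{i \in S} I(x_j; x_i)$,
with plug-in mutual information on equal-frequency 8-bin discretized
features (the classical mRMR practice; the bin count is configurable).
Classifier: RBF-kernel SVM with inverse-frequency class weights.
Normalization, ranking and fitting are all refitted inside every
validation fold — selection before splitting is the canonical leakage bug,
and the test suite guards it by requiring chance-level accuracy under
label shuffling. The selected-feature count is scanned over a grid and
chosen by pooled validation accuracy. Ranking within folds is statistically
correct but differs from pipelines that rank once on all data; small
accuracy differences against such pipelines are expected. Validation:
stratified 10-fold, or leave-one-subject-out with per-subject rows and
mean ± SD. Default SVM cost is 1 with the library default kernel width; an
inner 3-fold cost grid is available (`cost_grid`) and off by default to
keep the default run at desk scale. AUC comes from decision values of the
positive class.

# Connectivity

**PLV.** Morlet phases per trial and hemisphere; the phase-locking value is
the modulus of the windowed mean of $e^{i(\phi_x - \phi_y)}$ — the window
length $N$ runs over *time* within a 500-ms sliding window (matching the
correlation window), averaged across trials afterwards. An
across-trials-at-fixed-time estimator is not provided, as every analysis
here is windowed-in-time. Raw PLV is bounded in [0, 1] and asserted so.
Baseline normalization subtracts the per-frequency baseline mean
(subtraction rather than z-scoring; a z mode is switchable since the
source description is ambiguous). For independent phases the estimator's
small-sample bias follows the Rayleigh-walk law
$\mathbb{E}|\bar z| \approx \sqrt{\pi/(4N)}$, verified by Monte-Carlo.

**Sliding correlation.** Windowed Pearson correlation (500 ms window, 1-ms
step, cumulative-sum implementation), averaged across trials with SEM;
zero-variance windows are excluded and counted. Significance against the
per-trial baseline mean is evaluated on a decimated grid (default 25 ms)
by signed-rank, uncorrected.

**Cross-correlation.** The biased estimator — normalization by the full
length T at every lag, scaled by the population SDs — over a symmetric lag
range, so $r_{xx}(0) = 1$ exactly and the estimate tapers toward large
lags. The interhemispheric lag is the argmax of the trial-averaged
cross-correlation (ties toward the earliest lag, flagged), with an
optional trial re-pairing permutation test that flags peaks inside the
null band as unreliable.

**Recovery-time readout.** `coupling_recovery_time()` smooths a trace
(100 ms), finds the post-stimulus minimum, and reports the first time the
trace rises back to the baseline mean minus a margin (the larger of twice
the mean SEM and 5% of the dip depth). The margin makes the crossing time
robust to trace noise at the cost of a small early bias (~0.1–0.2 s at
default conditions), well inside the ±0.5 s acceptance band around the
programmed 4-s recovery.

# Orchestration and containers

`run_pipeline()` executes simulate/ingest → preprocess → EP → spectral →
decode → connectivity per stage toggles, writes result CSVs and a JSON run
report with per-stage trial counts, and is reproducible for a fixed seed.
Configurations round-trip through YAML with unknown-key rejection. The
on-disk trial container is a single RDS file (`write_trial_set()` /
`read_trial_set()`), schema-checked on read by `validate_trial_set()`;
events travel as CSV with columns trial_id, subject, session, label,
onset_s, withdrawal_ms. The installed R stack offers no HDF5 or EDF
bindings, so RDS is the package's container format; the container API is
format-agnostic and a future HDF5 writer would slot behind the same
functions.

# What passing tests do and do not show

The generator emulates stimulus-locked EPs, band-specific induced power
changes, interhemispheric coupling with a post-stimulus dip, session drift,
behavioural latencies and motion artifacts. It does *not* emulate spike
leakage, cross-frequency coupling, non-stationary 1/f slopes, electrode
drift within a session, or correlated artifact topographies. Passing
recovery tests therefore demonstrates that the analysis code is correct
and unbiased under the stated statistical structure — not that the same
numerical results would be obtained on any particular real recording.

# Problem sizes and numerical choices

The test suite runs the recovery checks at desk scale: EP parameter
recovery uses 4 replicates of 300 HN + 400 NN trials (the acceptance
script uses 20 replicates of 400 + 500; the NN evoked response at 0.21
z-units needs a few hundred trials for a stable average-EP anchor, and the
study itself pooled 657/533 trials). Earliest-qualifying-peak detection on
a weak component retains a small positive selection bias (a few percent at
these trial counts, since detection and measurement share the averaging
noise); `ep_params_splithalf()` removes it by cross-fitting at the cost of
noisier anchors. Decoding sanity uses ten 120-trial
replicates with 1.5-s feature epochs; connectivity persistence uses six
60-trial replicates. Tie-breaks are always toward the earliest sample;
epoch boundaries use half-open 0-based ranges; degenerate inputs (constant
signals, zero-variance windows, single-class folds) raise typed errors or
documented conventions (p = 1, excluded-and-counted) rather than
propagating NaN.
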