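#' Evoked-potential template specification
#'
#' A per-class description of the stimulus-locked evoked potential as a sum of
#' Gaussian-windowed monophasic lobes. Component latencies/amplitudes are the
#' *realized* extrema of the summed waveform (overlapping lobes are
#' compensated by calibration in [make_ep_template()]); amplitudes are in
#' normalized z-units, i.e. units of the session-z-scored signal. `width_ms`
#' is the full width at half maximum of a lobe.
#'
#' @param components data.frame with columns `polarity` (+1/-1), `latency_ms`,
#'   `amplitude` (positive magnitude), `width_ms`. Zero rows = no evoked
#'   response (the NS class).
#' @param ipsi_gain ipsilateral/contralateral amplitude ratio (>= 1). The
#'   scaling is mean-preserving: ipsi x 2g/(1+g), contra x 2/(1+g), so the
#'   hemisphere-pooled average keeps the template amplitude.
#' @return an `ep_template_spec`
#' @export
ep_template_spec <- function(components, ipsi_gain = 1) {
  if (is.null(components) || nrow(components) == 0L) {
    components <- data.frame(polarity = numeric(), latency_ms = numeric(),
                             amplitude = numeric(), width_ms = numeric())
  } else {
    need <- c("polarity", "latency_ms", "amplitude", "width_ms")
    if (!all(need %in% names(components)))
      stop_invalid("components must have columns %s", paste(need, collapse = ", "))
    if (!all(components$polarity %in% c(-1, 1)))
      stop_invalid("polarity must be +1 or -1")
    if (is.unsorted(components$latency_ms, strictly = TRUE))
      stop_invalid("latencies must be strictly increasing")
    if (any(components$width_ms <= 0)) stop_invalid("widths must be > 0")
    if (any(components$amplitude <= 0)) stop_invalid("amplitudes must be > 0")
  }
  assert_scalar_num(ipsi_gain, "ipsi_gain", lo = 1)
  structure(list(components = components, ipsi_gain = ipsi_gain),
            class = "ep_template_spec")
}

#' Default evoked-potential templates for the HN / NN / NS classes
#'
#' HN: P1 at 92 ms (amplitude 1.15), N1 at 157 ms (-1.17), plus a weaker P2
#' lobe at 230 ms (0.35; observed for noxious stimulation but not tabulated,
#' so its parameters are package defaults). NN: P1 at 61 ms (0.21), N1 at
#' 157 ms (-0.18). NS: no evoked response.
#'
#' @param hn_ipsi_gain ipsilateral/contralateral amplitude ratio for HN
#'   (noxious stimulation drives the ipsilateral ACC harder); NN uses 1.
#' @return named list of `ep_template_spec` objects
#' @export
default_ep_specs <- function(hn_ipsi_gain = 1.3) {
  list(
    HN = ep_template_spec(data.frame(
      polarity = c(1, -1, 1),
      latency_ms = c(92, 157, 230),
      amplitude = c(1.15, 1.17, 0.35),
      width_ms = c(25, 25, 30)), ipsi_gain = hn_ipsi_gain),
    NN = ep_template_spec(data.frame(
      polarity = c(1, -1),
      latency_ms = c(61, 157),
      amplitude = c(0.21, 0.18),
      width_ms = c(25, 25)), ipsi_gain = 1),
    NS = ep_template_spec(NULL)
  )
}

#' Canonical LFP frequency bands
#'
#' theta 4-8, alpha 8-12, beta 12-30, low-gamma 30-80, high-gamma 80-120 Hz.
#' @return data.frame with columns `band`, `f_lo`, `f_hi`
#' @export
default_bands <- function() {
  data.frame(band = c("theta", "alpha", "beta", "low_gamma", "high_gamma"),
             f_lo = c(4, 8, 12, 30, 80),
             f_hi = c(8, 12, 30, 80, 120),
             stringsAsFactors = FALSE)
}

#' Post-stimulus band-power modulation specification
#'
#' Per band: an early amplitude gain on [0, 0.5] s, a late gain from 0.5 s
#' onwards, and a linear relaxation back to 1 reached at `recovery_s`. Gains
#' are amplitude multipliers (power scales with gain squared). The default
#' gain set follows the reported directions for noxious stimulation: all
#' bands up early; theta/alpha/beta down and gamma up late.
#'
#' @param bands data.frame from [default_bands()] (or same shape)
#' @param early_gain,late_gain,recovery_s per-band vectors (recycled)
#' @export
band_modulation_spec <- function(bands = default_bands(),
                                 early_gain = c(1.5, 1.5, 1.5, 1.8, 2.0),
                                 late_gain  = c(0.6, 0.7, 0.6, 1.3, 1.4),
                                 recovery_s = 4) {
  spec <- bands
  spec$early_gain <- rep_len(early_gain, nrow(bands))
  spec$late_gain  <- rep_len(late_gain, nrow(bands))
  spec$recovery_s <- rep_len(recovery_s, nrow(bands))
  if (any(spec$early_gain <= 0) || any(spec$late_gain <= 0))
    stop_invalid("gains must be > 0")
  if (any(spec$f_lo >= spec$f_hi)) stop_invalid("f_lo < f_hi required")
  if (is.unsorted(spec$f_lo) || any(spec$f_hi[-nrow(spec)] > spec$f_lo[-1]))
    stop_invalid("bands must be ordered and non-overlapping")
  structure(spec, class = c("band_modulation_spec", "data.frame"))
}

#' Milder modulation used for the non-noxious class
#' @rdname band_modulation_spec
#' @export
nn_band_modulation <- function() {
  band_modulation_spec(early_gain = c(1.2, 1.2, 1.2, 1.25, 1.3),
                       late_gain  = c(0.85, 0.9, 0.85, 1.1, 1.15),
                       recovery_s = 2.5)
}

#' Interhemispheric coupling specification
#'
#' The two hemispheres share a common background source with amplitude-mixing
#' fraction `shared_fraction`; after noxious stimulation the mixing drops by
#' `post_stim_dip_depth` at 0.5 s and relaxes linearly back over
#' `dip_duration_s` (default 3.5 s, i.e. recovered at 4 s after onset). The
#' dip is applied to HN trials only; for NN the reported interhemispheric
#' variations were not significant.
#'
#' @param shared_fraction amplitude mixing c in [0, 1]
#' @param baseline_plv_target nominal pre-stimulus PLV the mixing is meant to
#'   produce (metadata; the operative dial is `shared_fraction`)
#' @param post_stim_dip_depth fractional drop of c at 0.5 s, in [0, 1]
#' @param dip_duration_s linear recovery time of the dip, seconds
#' @export
coupling_spec <- function(shared_fraction = 0.7, baseline_plv_target = 0.6,
                          post_stim_dip_depth = 0.5, dip_duration_s = 3.5) {
  assert_scalar_num(shared_fraction, "shared_fraction", 0, 1)
  assert_scalar_num(baseline_plv_target, "baseline_plv_target", 0, 1)
  assert_scalar_num(post_stim_dip_depth, "post_stim_dip_depth", 0, 1)
  assert_scalar_num(dip_duration_s, "dip_duration_s", 0)
  structure(list(shared_fraction = shared_fraction,
                 baseline_plv_target = baseline_plv_target,
                 post_stim_dip_depth = post_stim_dip_depth,
                 dip_duration_s = dip_duration_s),
            class = "coupling_spec")
}

#' Simulation configuration
#'
#' @param fs sampling rate (Hz); must exceed twice the highest band edge.
#' @param n_trials named vector of trials per class, e.g. `c(HN=200, NN=200,
#'   NS=400)`. The full study-scale preset is `c(HN=657, NN=533, NS=1190)`.
#' @param epoch_s `c(pre=..., post=...)` epoch extent around onset, seconds.
#' @param noise_exponent spectral exponent alpha of the 1/f^alpha background.
#' @param noise_sd background standard deviation (z-units; 1 = unit-variance
#'   background so template amplitudes are single-trial SNRs).
#' @param artifact_rate,artifact_magnitude defaults for [inject_artifacts()]
#'   when run through the pipeline (rate 0 = clean data).
#' @param withdrawal_ms `c(mean=225, sd=10)`: paw-withdrawal latency
#'   distribution for HN trials.
#' @param session_gains multiplicative per-session amplitude drifts emulating
#'   non-stationary recording gain; undone by session z-scoring.
#' @param n_subjects number of simulated rats (trials split evenly).
#' @param sessions_per_subject sessions within each subject.
#' @param seed integer seed; fixes the output exactly.
#' @export
sim_config <- function(fs = 1000,
                       n_trials = c(HN = 200, NN = 200, NS = 400),
                       epoch_s = c(pre = 1, post = 5),
                       noise_exponent = 1,
                       noise_sd = 1,
                       artifact_rate = 0,
                       artifact_magnitude = 20,
                       withdrawal_ms = c(mean = 225, sd = 10),
                       session_gains = c(1, 1.08, 0.95, 1.05),
                       n_subjects = 4,
                       sessions_per_subject = 2,
                       seed = 1) {
  assert_scalar_num(fs, "fs", lo = 2 * 120 + 1e-9)
  if (any(n_trials < 1)) stop_invalid("n_trials must be >= 1 per class")
  if (length(epoch_s) != 2L || any(epoch_s < 0))
    stop_invalid("epoch_s must be c(pre, post) with nonnegative entries")
  names(epoch_s) <- c("pre", "post")
  if (length(withdrawal_ms) != 2L) stop_invalid("withdrawal_ms must be c(mean, sd)")
  names(withdrawal_ms) <- c("mean", "sd")
  assert_scalar_num(noise_exponent, "noise_exponent", lo = 0)
  assert_scalar_num(noise_sd, "noise_sd", lo = 0)
  assert_scalar_num(artifact_rate, "artifact_rate", 0, 1)
  structure(list(fs = fs, n_trials = n_trials, epoch_s = epoch_s,
                 noise_exponent = noise_exponent, noise_sd = noise_sd,
                 artifact_rate = artifact_rate,
                 artifact_magnitude = artifact_magnitude,
                 withdrawal_ms = withdrawal_ms,
                 session_gains = session_gains,
                 n_subjects = n_subjects,
                 sessions_per_subject = sessions_per_subject,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# ---- background synthesis ----------------------------------------------

# two-sided spectral amplitude mask: 1/f^(alpha/2) over [lo, hi] with
# raised-cosine edges; zero outside. npad-point FFT grid at rate fs.
spectral_mask <- function(npad, fs, alpha, lo = 3, hi = 350) {
  f <- (0:(npad - 1)) * fs / npad
  f <- pmin(f, fs - f)                      # fold to two-sided frequency
  hi <- min(hi, fs / 2)
  m <- numeric(npad)
  inside <- f >= lo & f <= hi
  m[inside] <- pmax(f[inside], lo)^(-alpha / 2)
  ramp_w <- lo / 3
  lo_ramp <- f >= lo - ramp_w & f < lo
  m[lo_ramp] <- lo^(-alpha / 2) * 0.5 * (1 - cos(pi * (f[lo_ramp] - lo + ramp_w) / ramp_w))
  m
}

band_mask <- function(npad, fs, f_lo, f_hi, ramp = 1) {
  f <- (0:(npad - 1)) * fs / npad
  f <- pmin(f, fs - f)
  m <- numeric(npad)
  m[f >= f_lo & f <= f_hi] <- 1
  lo_r <- f >= f_lo - ramp & f < f_lo
  m[lo_r] <- 0.5 * (1 - cos(pi * (f[lo_r] - f_lo + ramp) / ramp))
  hi_r <- f > f_hi & f <= f_hi + ramp
  m[hi_r] <- 0.5 * (1 + cos(pi * (f[hi_r] - f_hi) / ramp))
  m
}

# filter white noise `w` with a two-sided amplitude mask (units preserved:
# for unit-variance w the output variance is mean(mask^2))
mask_filter <- function(W, mask, n) {
  Re(stats::fft(W * mask, inverse = TRUE))[seq_len(n)] / length(W)
}

#' Generate 1/f^alpha background activity
#'
#' Zero-mean Gaussian noise whose power spectral density is proportional to
#' 1/f^alpha over the LFP range (3-350 Hz by default), synthesized by
#' spectral shaping of white noise. Variance is `sd^2`. Uses the current R
#' RNG stream.
#'
#' @param n_samples signal length
#' @param fs sampling rate (Hz)
#' @param alpha spectral exponent (>= 0; 0 = flat)
#' @param sd target standard deviation
#' @param lo,hi shaping band edges (Hz)
#' @return numeric vector of length `n_samples`
#' @export
generate_background <- function(n_samples, fs, alpha = 1, sd = 1,
                                lo = 3, hi = 350) {
  if (!is.numeric(n_samples) || n_samples <= 0)
    stop_invalid("n_samples must be positive")
  if (alpha < 0) stop_invalid("alpha must be >= 0")
  if (sd < 0) stop_invalid("sd must be >= 0")
  if (sd == 0) return(numeric(n_samples))
  npad <- stats::nextn(n_samples, 2)
  mask <- spectral_mask(npad, fs, alpha, lo, hi)
  scale <- sd / sqrt(mean(mask^2))
  w <- stats::rnorm(npad)
  mask_filter(stats::fft(w), mask, n_samples) * scale
}

# ---- EP template --------------------------------------------------------

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

eval_lobes <- function(t, mu, a, sigma) {
  y <- numeric(length(t))
  for (i in seq_along(mu)) y <- y + a[i] * exp(-(t - mu[i])^2 / (2 * sigma[i]^2))
  y
}

# fixed-point calibration: adjust lobe centres/amplitudes until the realized
# extrema of the summed waveform sit exactly at the spec targets
calibrate_lobes <- function(comp, max_iter = 100, tol = 1e-7) {
  mu <- comp$latency_ms / 1000
  a <- comp$polarity * comp$amplitude
  sigma <- comp$width_ms / 1000 * FWHM_TO_SIGMA
  target_mu <- mu; target_a <- a
  fine <- seq(min(mu) - 5 * max(sigma), max(mu) + 5 * max(sigma), by = 1e-4)
  for (it in seq_len(max_iter)) {
    y <- eval_lobes(fine, mu, a, sigma)
    err <- 0
    for (i in seq_along(mu)) {
      s <- sign(target_a[i])
      win <- which(abs(fine - target_mu[i]) < 2.5 * sigma[i])
      if (!length(win)) return(NULL)
      j <- win[which.max(s * y[win])]
      found_mu <- fine[j]; found_a <- y[j]
      if (s * found_a <= 0) return(NULL)       # extremum of wrong polarity lost
      err <- max(err, abs(found_mu - target_mu[i]), abs(found_a - target_a[i]))
      mu[i] <- mu[i] - (found_mu - target_mu[i])
      a[i] <- a[i] * (target_a[i] / found_a)
    }
    if (err < tol) break
  }
  if (err >= 1e-4) return(NULL)
  list(mu = mu, a = a, sigma = sigma)
}

#' Build a sampled evoked-potential template from a spec
#'
#' Sums Gaussian lobes calibrated so that the first positive extremum of the
#' waveform lands at the spec's P1 latency with the spec's amplitude (to the
#' nearest sample at `fs`), and likewise for every further component.
#'
#' @param spec an [ep_template_spec()]
#' @param fs sampling rate (Hz)
#' @param t optional time axis (seconds, relative to onset); defaults to a
#'   minimal support covering all components
#' @return numeric waveform on `t`
#' @export
make_ep_template <- function(spec, fs, t = NULL) {
  stopifnot(inherits(spec, "ep_template_spec"))
  comp <- spec$components
  if (is.null(t)) {
    tmax <- if (nrow(comp)) max(comp$latency_ms / 1000 + 5 * comp$width_ms / 1000) else 1
    t <- seq(0, tmax, by = 1 / fs)
  }
  if (nrow(comp) == 0L) return(numeric(length(t)))
  cal <- calibrate_lobes(comp)
  if (is.null(cal))
    stop_invalid("spec-infeasible: overlapping components shift extrema beyond tolerance")
  y <- eval_lobes(t, cal$mu, cal$a, cal$sigma)
  # verify the sampled extrema stay within one sample of the targets
  # (components whose support falls outside the axis are simply truncated)
  for (i in seq_len(nrow(comp))) {
    s <- comp$polarity[i]
    lat <- comp$latency_ms[i] / 1000
    if (lat - cal$sigma[i] < min(t) || lat + cal$sigma[i] > max(t)) next
    win <- which(abs(t - lat) <= 2.5 * cal$sigma[i])
    if (!length(win)) next
    j <- win[which.max(s * y[win])]
    if (abs(t[j] - comp$latency_ms[i] / 1000) > 1 / fs + 1e-12)
      stop_invalid("spec-infeasible: overlapping components shift extrema by > 1 sample")
  }
  y
}

# deterministic amplitude gain of the preprocessing chain on the background:
# zero-phase filtering (|H|^2 amplitude response) shrinks the baseline SD of
# the band-limited background below 1, and session z-scoring divides by that
# SD; the ratio is computable from the synthesis mask and the filter response
chain_gain <- function(npad, fs, mask, lo = 3, hi = 350, order = 4) {
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  f <- (0:(npad - 1)) * fs / npad
  f <- pmin(f, fs - f)
  w <- 2 * pi * f / fs
  ew <- exp(-1i * w)
  H <- Mod(vapply(seq_along(w), function(k)
    sum(bf$b * ew[k]^(0:(length(bf$b) - 1))) /
      sum(bf$a * ew[k]^(0:(length(bf$a) - 1))), complex(1)))
  sqrt(sum(mask^2 * H^4) / sum(mask^2))   # filtfilt applies |H|^2
}

# Outer calibration: scale/shift the spec so that the template's extrema hit
# the spec values *after* the standard zero-phase band-pass and session
# z-scoring. Template amplitudes are defined in z-units of the preprocessed
# signal (that is the scale on which EP parameters are tabulated for this
# preparation), so the generator pre-compensates the known linear
# attenuation of the chain: the filter's shape distortion of the lobes and
# the deterministic baseline-SD gain `k`. Falls back to the uncompensated
# template when a component's support is truncated by the time axis.
make_ep_template_filtcomp <- function(spec, fs, t, k = 1, lo = 3, hi = 350,
                                      order = 4, max_iter = 8) {
  comp <- spec$components
  if (nrow(comp) == 0L) return(numeric(length(t)))
  adj <- comp
  sigma <- comp$width_ms / 1000 * FWHM_TO_SIGMA
  w <- make_ep_template(spec, fs, t)
  for (it in seq_len(max_iter)) {
    filt <- lfp_bandpass(w, fs, lo, hi, order) / k
    err <- 0
    for (i in seq_len(nrow(comp))) {
      lat <- comp$latency_ms[i] / 1000
      if (lat - sigma[i] < min(t) || lat + sigma[i] > max(t)) next
      win <- which(abs(t - lat) <= 2.5 * sigma[i])
      s <- comp$polarity[i]
      j <- win[which.max(s * filt[win])]
      realized_amp <- s * filt[j]
      if (realized_amp <= 0) return(w)        # compensation infeasible here
      err <- max(err, abs(realized_amp - comp$amplitude[i]) / comp$amplitude[i],
                 abs(t[j] - lat) * 1000)
      adj$amplitude[i] <- adj$amplitude[i] * comp$amplitude[i] / realized_amp
      adj$latency_ms[i] <- adj$latency_ms[i] + (comp$latency_ms[i] - t[j] * 1000)
    }
    if (err < 1e-3) break
    if (is.unsorted(adj$latency_ms, strictly = TRUE)) return(w)
    w <- make_ep_template(ep_template_spec(adj, spec$ipsi_gain), fs, t)
  }
  w
}

# ---- trial synthesis ----------------------------------------------------

# time-varying coupling fraction; dip at 0.5 s, linear recovery
coupling_trace <- function(t, coupling, dipped) {
  c0 <- coupling$shared_fraction
  ct <- rep(c0, length(t))
  if (dipped && coupling$post_stim_dip_depth > 0) {
    t0 <- 0.5; t1 <- 0.5 + coupling$dip_duration_s
    drop <- c0 * coupling$post_stim_dip_depth
    seg <- t >= t0 & t < t1
    ct[seg] <- c0 - drop * (1 - (t[seg] - t0) / (t1 - t0))
  }
  ct
}

# per-band amplitude-gain envelope over the epoch time axis
gain_envelope <- function(t, early_gain, late_gain, recovery_s,
                          early_end = 0.5, plateau_end = 1.5) {
  g <- rep(1, length(t))
  g[t >= 0 & t < early_end] <- early_gain
  if (recovery_s > plateau_end) {
    late <- t >= early_end & t < plateau_end
    g[late] <- late_gain
    ramp <- t >= plateau_end & t < recovery_s
    g[ramp] <- late_gain + (1 - late_gain) * (t[ramp] - plateau_end) / (recovery_s - plateau_end)
  } else {
    g[t >= early_end & t < recovery_s] <- late_gain
  }
  g
}

# one band-modulated background source on the epoch grid
modulated_source <- function(npad, n, masks, gains_t, scale) {
  W <- stats::fft(stats::rnorm(npad))
  x <- mask_filter(W, masks$base, n) * scale
  for (b in seq_along(masks$bands)) {
    gb <- gains_t[[b]]
    if (is.null(gb)) next
    u <- mask_filter(W, masks$bands[[b]], n) * scale
    x <- x + (gb - 1) * u
  }
  x
}

#' Generate a synthetic bilateral LFP trial set
#'
#' Every trial is built as a coupled pair of band-modulated 1/f backgrounds
#' plus the class evoked-potential template:
#' `x_h(t) = [c(t) s(t) + (1 - c(t)) n_h(t)] / sqrt(c(t)^2 + (1-c(t))^2) + EP_h(t)`,
#' where `s` is a source shared by both hemispheres, `n_h` are independent
#' sources, and the normalization keeps the background variance at
#' `noise_sd^2` for every coupling level. Band modulation multiplies the
#' band-restricted part of each source by a gain envelope (all bands up in
#' the first 500 ms; theta/alpha/beta down and gamma up afterwards, for the
#' noxious class). The coupling fraction dips after noxious stimulation and
#' recovers linearly by `0.5 + dip_duration_s` seconds. HN trials carry
#' paw-withdrawal latencies; session gain drift and subject ids are attached
#' for the session-normalization and leave-one-subject-out stages.
#'
#' Ground truth (templates, coupling traces, band gains, withdrawal
#' parameters) is recorded in `$truth` so downstream stages can be tested as
#' recovery problems. Per-trial RNG substreams are derived by counter from
#' the config seed, so extending the trial count leaves earlier trials
#' untouched.
#'
#' @param config a [sim_config()]
#' @param ep named list of [ep_template_spec()] per class
#'   (default [default_ep_specs()])
#' @param bands [band_modulation_spec()] applied to HN trials
#' @param nn_bands modulation applied to NN trials (default
#'   [nn_band_modulation()]); NS trials are unmodulated
#' @param coupling a [coupling_spec()]
#' @param compensate_filter pre-compensate the linear attenuation of the
#'   standard 3-350 Hz zero-phase band-pass so that the *preprocessed* EP
#'   extrema land on the spec values (template amplitudes are defined in
#'   z-units of the preprocessed signal, which is the scale EP parameters
#'   are tabulated on). Set FALSE to inject the raw calibrated template.
#' @return an [trial_set()] with `$truth` filled
#' @export
generate_trial_set <- function(config = sim_config(),
                               ep = default_ep_specs(),
                               bands = band_modulation_spec(),
                               nn_bands = nn_band_modulation(),
                               coupling = coupling_spec(),
                               compensate_filter = TRUE) {
  stopifnot(inherits(config, "sim_config"), inherits(coupling, "coupling_spec"))
  fs <- config$fs
  n <- as.integer(round(sum(config$epoch_s) * fs))
  onset <- as.integer(round(config$epoch_s[["pre"]] * fs)) + 1L
  t <- (seq_len(n) - onset) / fs
  npad <- stats::nextn(n, 2)

  masks <- list(base = spectral_mask(npad, fs, config$noise_exponent),
                bands = lapply(seq_len(nrow(bands)), function(b)
                  spectral_mask(npad, fs, config$noise_exponent) *
                    band_mask(npad, fs, bands$f_lo[b], bands$f_hi[b])))
  scale <- if (config$noise_sd > 0)
    config$noise_sd / sqrt(mean(masks$base^2)) else 0
  zgain <- if (config$noise_sd > 0) chain_gain(npad, fs, masks$base) else 1

  classes <- names(config$n_trials)
  labels <- rep(classes, config$n_trials)
  ntot <- length(labels)

  # templates per class and hemisphere (mean-preserving ipsi/contra split)
  templates <- lapply(classes, function(cl) {
    spec <- ep[[cl]] %||% ep_template_spec(NULL)
    w <- if (compensate_filter) make_ep_template_filtcomp(spec, fs, t, k = zgain)
         else make_ep_template(spec, fs, t)
    g <- spec$ipsi_gain
    list(ipsi = w * 2 * g / (1 + g), contra = w * 2 / (1 + g), pooled = w)
  })
  names(templates) <- classes

  gains_by_class <- lapply(classes, function(cl) {
    if (cl == "NS") return(vector("list", nrow(bands)))
    bm <- if (cl == "HN") bands else nn_bands
    lapply(seq_len(nrow(bm)), function(b)
      gain_envelope(t, bm$early_gain[b], bm$late_gain[b], bm$recovery_s[b]))
  })
  names(gains_by_class) <- classes

  ct_by_class <- lapply(classes, function(cl)
    coupling_trace(t, coupling, dipped = (cl == "HN")))
  names(ct_by_class) <- classes

  # recording sessions are intensity-specific (stimulation class fixed per
  # session), so z-normalization never mixes classes within a session
  subject <- integer(ntot)
  session <- integer(ntot)
  sess_counter <- 0L
  for (cl in classes) {
    ii <- which(labels == cl)
    subject[ii] <- rep_len(seq_len(config$n_subjects), length(ii))
    for (sb in seq_len(config$n_subjects)) {
      jj <- ii[subject[ii] == sb]
      session[jj] <- sess_counter +
        rep_len(seq_len(config$sessions_per_subject), length(jj))
      sess_counter <- sess_counter + config$sessions_per_subject
    }
  }
  gains <- rep_len(config$session_gains, sess_counter)

  signals <- array(0, dim = c(ntot, 2L, n))
  withdrawal <- rep(NA_real_, ntot)

  for (i in seq_len(ntot)) {
    cl <- labels[i]
    set.seed(derive_seed(config$seed, i))
    if (cl == "HN")
      withdrawal[i] <- stats::rnorm(1, config$withdrawal_ms[["mean"]],
                                    config$withdrawal_ms[["sd"]])
    ct <- ct_by_class[[cl]]
    norm <- sqrt(ct^2 + (1 - ct)^2)
    if (scale > 0) {
      gt <- gains_by_class[[cl]]
      s  <- modulated_source(npad, n, masks, gt, scale)
      n1 <- modulated_source(npad, n, masks, gt, scale)
      n2 <- modulated_source(npad, n, masks, gt, scale)
      bg1 <- (ct * s + (1 - ct) * n1) / norm
      bg2 <- (ct * s + (1 - ct) * n2) / norm
    } else {
      bg1 <- bg2 <- numeric(n)
    }
    g <- gains[session[i]]
    signals[i, 1L, ] <- g * (bg1 + templates[[cl]]$ipsi)
    signals[i, 2L, ] <- g * (bg2 + templates[[cl]]$contra)
  }

  truth <- list(templates = templates, ep_specs = ep,
                coupling = coupling, coupling_traces = ct_by_class,
                band_modulation = list(HN = bands, NN = nn_bands),
                withdrawal_ms = config$withdrawal_ms,
                session_gains = gains, config = config,
                artifact_trials = integer())
  trial_set(signals, labels, fs, rep(onset, ntot), withdrawal,
            session, subject, truth = truth)
}

#' Inject motion-artifact excursions into a trial set
#'
#' Selects `floor(rate * n_trials)` trials without replacement and adds a
#' contiguous high-amplitude noise burst (Gaussian with SD `magnitude` times
#' the trial's background SD, covering `span` of the epoch) to both
#' hemispheres — the test load for Grubbs-based trial rejection. A noise
#' burst rather than a constant offset: iterative Grubbs starts from the
#' most extreme single sample, and a heavy-tailed burst guarantees one,
#' whereas uniform-offset contamination of >10% of samples would mask
#' itself.
#'
#' @param ts an `lfp_trial_set`
#' @param rate fraction of trials to contaminate, in [0, 1]
#' @param magnitude excursion SD in units of the trial's background SD
#' @param span fraction of samples covered (comfortably above the 10%
#'   rejection rule so flagged fractions exceed it even after the Grubbs
#'   stopping criterion leaves the mildest burst samples unflagged)
#' @param seed RNG seed for trial/onset selection
#' @return list with `trials` (modified set) and `affected` (trial ids)
#' @export
inject_artifacts <- function(ts, rate, magnitude = 20, span = 0.15, seed = 1) {
  stopifnot(inherits(ts, "lfp_trial_set"))
  assert_scalar_num(rate, "rate", 0, 1)
  nt <- n_trials(ts); ns <- n_samples(ts)
  k <- floor(rate * nt)
  if (k == 0L) return(list(trials = ts, affected = integer()))
  set.seed(derive_seed(seed, 777))
  affected <- sort(sample.int(nt, k))
  len <- ceiling(span * ns)
  for (i in affected) {
    start <- sample.int(ns - len + 1L, 1L)
    sd0 <- stats::sd(ts$signals[i, 1L, ])
    if (!is.finite(sd0) || sd0 == 0) sd0 <- 1
    exc <- stats::rnorm(len, 0, magnitude * sd0)
    idx <- start:(start + len - 1L)
    ts$signals[i, 1L, idx] <- ts$signals[i, 1L, idx] + exc
    ts$signals[i, 2L, idx] <- ts$signals[i, 2L, idx] + exc
  }
  if (!is.null(ts$truth)) ts$truth$artifact_trials <- affected
  list(trials = ts, affected = affected)
}
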