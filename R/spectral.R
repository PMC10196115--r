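# Time-frequency analysis: complex Morlet continuous wavelet transform,
# baseline-z normalized scalograms and five-band interval power statistics.

#' Default log-spaced frequency grid (3-120 Hz, 60 points)
#' @param n number of grid points
#' @param lo,hi grid limits in Hz
#' @export
default_freqs <- function(n = 60, lo = 3, hi = 120) {
  exp(seq(log(lo), log(hi), length.out = n))
}

# complex Morlet kernels; amplitude-normalized so that a unit-amplitude
# sinusoid at the kernel frequency yields |W| = 1
morlet_kernels <- function(freqs, fs, n_cycles = 6) {
  lapply(freqs, function(f) {
    sigma_t <- n_cycles / (2 * pi * f)
    h <- ceiling(4 * sigma_t * fs)
    tt <- (-h:h) / fs
    g <- exp(-tt^2 / (2 * sigma_t^2))
    k <- g * exp(2i * pi * f * tt)
    list(k = k / (sum(g) / 2), h = h)
  })
}

#' Complex Morlet continuous wavelet transform
#'
#' Convolves the signal with analytic Morlet wavelets (default 6 cycles) at
#' each requested frequency, via FFT with reflection padding of one wavelet
#' support. Amplitude-normalized: a unit sinusoid at a grid frequency gives
#' coefficients of magnitude ~1 (power 1).
#'
#' @param x numeric signal
#' @param fs sampling rate (Hz)
#' @param freqs frequency grid (Hz), within (0, fs/2)
#' @param n_cycles Morlet cycles (time/frequency resolution trade-off)
#' @return complex matrix, frequencies x time; attribute `coi_halfwidth`
#'   gives the per-frequency cone-of-influence half-width in samples
#' @export
morlet_cwt <- function(x, fs, freqs = default_freqs(), n_cycles = 6) {
  if (!length(freqs)) stop_invalid("empty frequency grid")
  if (any(freqs <= 0 | freqs >= fs / 2))
    stop_invalid("frequencies must lie in (0, fs/2)")
  kernels <- morlet_kernels(freqs, fs, n_cycles)
  n <- length(x)
  hmax <- max(vapply(kernels, function(k) k$h, 1))
  pad <- min(hmax, n - 1L)
  xp <- c(2 * x[1] - x[(pad + 1L):2], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  nfft <- stats::nextn(length(xp) + 2 * hmax, 2)
  X <- stats::fft(c(xp, numeric(nfft - length(xp))))
  out <- matrix(0i, length(freqs), n)
  for (i in seq_along(freqs)) {
    k <- kernels[[i]]
    kk <- complex(length.out = nfft)
    idx <- ((-k$h):(k$h)) %% nfft + 1L
    kk[idx] <- k$k
    y <- stats::fft(X * stats::fft(kk), inverse = TRUE) / nfft
    out[i, ] <- y[(pad + 1L):(pad + n)]
  }
  attr(out, "coi_halfwidth") <- vapply(kernels, function(k) k$h, 1)
  out
}

#' Morlet scalogram (time-frequency power)
#'
#' Squared magnitude of the Morlet transform of one signal, or the
#' trial-averaged power of a trial set (power is averaged across trials
#' after the per-trial transform, so induced, non-phase-locked activity is
#' retained).
#'
#' @param x numeric signal, or an `lfp_trial_set`
#' @param fs sampling rate (ignored for trial sets)
#' @param freqs frequency grid (Hz)
#' @param n_cycles Morlet cycles
#' @param class,hemisphere trial selection (trial-set input only)
#' @param time optional time axis for plain-vector input
#' @return `lfp_scalogram`: list with `freq`, `time`, `power`,
#'   `normalization` ("raw"), `n_trials`, `coi_halfwidth`
#' @export
cwt_power <- function(x, fs = NULL, freqs = default_freqs(), n_cycles = 6,
                      class = NULL, hemisphere = "pooled", time = NULL) {
  if (inherits(x, "lfp_trial_set")) {
    idx <- class_idx(x, class)
    m <- hemi_mat2(x, hemisphere, idx)
    tvec <- time_axis(x)
    pow <- matrix(0, length(freqs), ncol(m))
    for (i in seq_len(nrow(m))) {
      W <- morlet_cwt(m[i, ], x$fs, freqs, n_cycles)
      pow <- pow + Mod(W)^2
      if (i == 1L) coi <- attr(W, "coi_halfwidth")
    }
    pow <- pow / nrow(m)
    nt <- nrow(m)
  } else {
    stopifnot(is.numeric(x), !is.null(fs))
    W <- morlet_cwt(x, fs, freqs, n_cycles)
    pow <- Mod(W)^2
    coi <- attr(W, "coi_halfwidth")
    tvec <- time %||% (seq_along(x) - 1) / fs
    nt <- 1L
  }
  structure(list(freq = freqs, time = tvec, power = pow,
                 normalization = "raw", n_trials = nt,
                 coi_halfwidth = coi),
            class = "lfp_scalogram")
}

#' Baseline z-normalization of a scalogram
#'
#' Each frequency row is z-scored against its own baseline interval:
#' `(power - baseline mean) / baseline sd`.
#'
#' @param sc an `lfp_scalogram`
#' @param baseline interval in seconds on the scalogram's time axis
#' @return normalized `lfp_scalogram` (`normalization = "baseline_z"`)
#' @export
baseline_normalize <- function(sc, baseline = c(-1, 0)) {
  stopifnot(inherits(sc, "lfp_scalogram"))
  idx <- which(sc$time >= baseline[1] & sc$time < baseline[2])
  if (length(idx) < 2L) stop_invalid("baseline interval outside time axis")
  bm <- rowMeans(sc$power[, idx, drop = FALSE])
  bs <- apply(sc$power[, idx, drop = FALSE], 1, stats::sd)
  if (any(bs == 0)) stop_invalid("degenerate input: zero baseline sd at a frequency")
  sc$power <- (sc$power - bm) / bs
  sc$normalization <- "baseline_z"
  sc
}

# per-band log-spaced frequency sub-grid
band_freqs <- function(f_lo, f_hi, n = 6) exp(seq(log(f_lo), log(f_hi), length.out = n))

#' Per-trial band power in time intervals
#'
#' For every trial: Morlet power on a log-spaced grid inside each band,
#' optionally z-normalized per frequency against the trial's own baseline,
#' then averaged over band x interval. The intervals default to the evoked
#' interval [0, 0.5] s and the post-evoked interval [0.5, 5] s (clipped to
#' the epoch), with the baseline [-1, 0] s reported alongside.
#'
#' @param ts an `lfp_trial_set`
#' @param bands data.frame of bands ([default_bands()])
#' @param intervals named list of `c(start, stop)` intervals in seconds
#' @param class,hemisphere trial selection
#' @param normalize "baseline_z" (default) or "raw"
#' @param baseline baseline interval (s)
#' @param freqs_per_band frequencies per band
#' @param n_cycles Morlet cycles
#' @return long data.frame: trial, label, band, interval, value
#' @export
band_power <- function(ts, bands = default_bands(),
                       intervals = list(early = c(0, 0.5), late = c(0.5, 5)),
                       class = NULL, hemisphere = "pooled",
                       normalize = c("baseline_z", "raw"),
                       baseline = c(-1, 0), freqs_per_band = 6, n_cycles = 6) {
  stopifnot(inherits(ts, "lfp_trial_set"))
  normalize <- match.arg(normalize)
  idx <- class_idx(ts, class)
  m <- hemi_mat2(ts, hemisphere, idx)
  t <- time_axis(ts)
  t_end <- max(t)
  iv_idx <- lapply(intervals, function(iv) {
    if (iv[1] > t_end) stop_invalid("interval outside epoch")
    which(t >= iv[1] & t < min(iv[2], t_end + 1e-9))
  })
  base_idx <- which(t >= baseline[1] & t < baseline[2])
  if (normalize == "baseline_z" && length(base_idx) < 2L)
    stop_invalid("baseline interval outside epoch")
  freqs <- unlist(lapply(seq_len(nrow(bands)), function(b)
    band_freqs(bands$f_lo[b], bands$f_hi[b], freqs_per_band)))
  band_of <- rep(bands$band, each = freqs_per_band)
  out <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    pow <- Mod(morlet_cwt(m[i, ], ts$fs, freqs, n_cycles))^2
    if (normalize == "baseline_z") {
      bm <- rowMeans(pow[, base_idx, drop = FALSE])
      bs <- apply(pow[, base_idx, drop = FALSE], 1, stats::sd)
      bs[bs == 0] <- NA_real_
      pow <- (pow - bm) / bs
    }
    vals <- lapply(names(iv_idx), function(nm)
      tapply(rowMeans(pow[, iv_idx[[nm]], drop = FALSE]), band_of, mean))
    out[[i]] <- data.frame(
      trial = idx[i], label = as.character(ts$labels[idx[i]]),
      band = rep(bands$band, times = length(iv_idx)),
      interval = rep(names(iv_idx), each = nrow(bands)),
      value = unlist(lapply(vals, function(v) as.numeric(v[bands$band]))))
  }
  do.call(rbind, out)
}

#' Time-resolved normalized band power
#'
#' The continuous per-band power trace: per trial, baseline-z power averaged
#' over the band's frequencies; mean and SEM across trials at every sample.
#'
#' @inheritParams band_power
#' @return data.frame: band, time, mean, sem
#' @export
band_power_trace <- function(ts, bands = default_bands(), class = NULL,
                             hemisphere = "pooled", baseline = c(-1, 0),
                             freqs_per_band = 6, n_cycles = 6) {
  idx <- class_idx(ts, class)
  m <- hemi_mat2(ts, hemisphere, idx)
  t <- time_axis(ts)
  base_idx <- which(t >= baseline[1] & t < baseline[2])
  freqs <- unlist(lapply(seq_len(nrow(bands)), function(b)
    band_freqs(bands$f_lo[b], bands$f_hi[b], freqs_per_band)))
  band_of <- rep(bands$band, each = freqs_per_band)
  acc <- array(0, dim = c(nrow(bands), length(t), 2))  # sum, sumsq
  for (i in seq_len(nrow(m))) {
    pow <- Mod(morlet_cwt(m[i, ], ts$fs, freqs, n_cycles))^2
    bm <- rowMeans(pow[, base_idx, drop = FALSE])
    bs <- apply(pow[, base_idx, drop = FALSE], 1, stats::sd)
    pow <- (pow - bm) / bs
    for (b in seq_len(nrow(bands))) {
      v <- colMeans(pow[band_of == bands$band[b], , drop = FALSE])
      acc[b, , 1] <- acc[b, , 1] + v
      acc[b, , 2] <- acc[b, , 2] + v^2
    }
  }
  nt <- nrow(m)
  rows <- lapply(seq_len(nrow(bands)), function(b) {
    mu <- acc[b, , 1] / nt
    va <- pmax(acc[b, , 2] / nt - mu^2, 0) * nt / max(nt - 1, 1)
    data.frame(band = bands$band[b], time = t, mean = mu,
               sem = sqrt(va / nt))
  })
  do.call(rbind, rows)
}

#' Compare band power between two groups of trials
#'
#' Wilcoxon rank-sum test per band x interval with direction and the
#' standard star-level encoding (0.05 / 0.01 / 0.001 / 0.0001).
#'
#' @param values_a,values_b long data.frames from [band_power()]
#' @param level significance level
#' @return data.frame: band, interval, group medians, direction, p, stars
#' @export
compare_band_power <- function(values_a, values_b, level = 0.05) {
  keys <- unique(values_a[, c("band", "interval")])
  rows <- lapply(seq_len(nrow(keys)), function(r) {
    sel <- function(v) v$value[v$band == keys$band[r] & v$interval == keys$interval[r]]
    a <- sel(values_a); b <- sel(values_b)
    if (length(a) < 2L || length(b) < 2L) stop_invalid("need >= 2 values per group")
    p <- rank_test_p(a, b)
    data.frame(band = keys$band[r], interval = keys$interval[r],
               median_a = stats::median(a, na.rm = TRUE),
               median_b = stats::median(b, na.rm = TRUE),
               direction = sign(stats::median(a, na.rm = TRUE) -
                                  stats::median(b, na.rm = TRUE)),
               p = p, significant = p < level,
               stars = as.character(p_stars(p)))
  })
  do.call(rbind, rows)
}

#' Bilateral band-power comparison
#'
#' Per band and interval, a paired Wilcoxon signed-rank test between the
#' ipsilateral and contralateral band power of the same trials.
#'
#' @inheritParams band_power
#' @param level significance level
#' @return data.frame: band, interval, hemisphere means, p, stars
#' @export
bilateral_band_power_comparison <- function(ts, bands = default_bands(),
                                            intervals = list(early = c(0, 0.5),
                                                             late = c(0.5, 5)),
                                            class = NULL, level = 0.05, ...) {
  va <- band_power(ts, bands, intervals, class, hemisphere = "ipsi", ...)
  vb <- band_power(ts, bands, intervals, class, hemisphere = "contra", ...)
  if (nrow(va) != nrow(vb)) stop_invalid("unpaired hemisphere inputs")
  keys <- unique(va[, c("band", "interval")])
  rows <- lapply(seq_len(nrow(keys)), function(r) {
    sel <- function(v) v$value[v$band == keys$band[r] & v$interval == keys$interval[r]]
    a <- sel(va); b <- sel(vb)
    ok <- is.finite(a) & is.finite(b)
    p <- rank_test_p(a[ok], b[ok], paired = TRUE)
    data.frame(band = keys$band[r], interval = keys$interval[r],
               mean_ipsi = mean(a[ok]), mean_contra = mean(b[ok]),
               p = p, significant = p < level,
               stars = as.character(p_stars(p)))
  })
  do.call(rbind, rows)
}
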