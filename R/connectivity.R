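# Interhemispheric connectivity: time-frequency phase-locking value,
# sliding-window Pearson correlation and cross-correlation lag estimation.

# mean resultant length of the phase-difference distribution; the PLV core
# (exposed for direct small-sample calibration against the Rayleigh-walk
# law E|PLV| ~ sqrt(pi/(4N)) for independent phases)
plv_resultant <- function(phi_x, phi_y) {
  Mod(mean(exp(1i * (phi_x - phi_y))))
}

# centred running mean of a (complex or numeric) vector over `win` samples;
# returns NA where the window does not fit
running_mean <- function(z, win) {
  n <- length(z)
  h <- win %/% 2L
  cs <- cumsum(z)
  out <- rep(NA_complex_, n)
  i <- (h + 1L):(n - (win - h - 1L))
  lo <- i - h
  hi <- i + (win - h - 1L)
  out[i] <- (cs[hi] - c(if (lo[1] == 1L) 0 else cs[lo[1] - 1L],
                        cs[lo[-1] - 1L])) / win
  out
}

#' Time-frequency phase-locking value between hemispheres
#'
#' Per trial, Morlet phases of both hemispheres are extracted and the PLV
#' `|mean over the window samples of exp(i(phi_x - phi_y))|` is computed in
#' a centred sliding window at every time point, then averaged across
#' trials. Raw PLV lies in [0, 1]; the normalized variant subtracts (or
#' z-scores, `normalize = "z"`) the per-frequency baseline mean.
#'
#' @param ts an `lfp_trial_set`
#' @param class trial class (NULL = all trials)
#' @param freqs frequency grid (Hz)
#' @param window_ms sliding-window length (ms)
#' @param n_cycles Morlet cycles
#' @param normalize "none", "subtract" or "z"
#' @param baseline baseline interval (s) for normalization
#' @return `lfp_plv_map`: list with `time`, `freq`, `plv` (raw), `plv_norm`
#'   (NULL when `normalize = "none"`), `window_ms`, `n_trials`
#' @export
plv_timefreq <- function(ts, class = NULL, freqs = default_freqs(30),
                         window_ms = 500, n_cycles = 6,
                         normalize = c("subtract", "z", "none"),
                         baseline = c(-1, 0)) {
  stopifnot(inherits(ts, "lfp_trial_set"))
  normalize <- match.arg(normalize)
  win <- round(window_ms / 1000 * ts$fs)
  if (win > n_samples(ts)) stop_invalid("window longer than epoch")
  idx <- class_idx(ts, class)
  t <- time_axis(ts)
  acc <- matrix(0, length(freqs), n_samples(ts))
  for (i in idx) {
    wx <- morlet_cwt(ts$signals[i, 1L, ], ts$fs, freqs, n_cycles)
    wy <- morlet_cwt(ts$signals[i, 2L, ], ts$fs, freqs, n_cycles)
    z <- exp(1i * (Arg(wx) - Arg(wy)))
    for (f in seq_len(length(freqs)))
      acc[f, ] <- acc[f, ] + Mod(running_mean(z[f, ], win))
  }
  plv <- acc / length(idx)
  keep <- which(!is.na(plv[1, ]))
  plv <- plv[, keep, drop = FALSE]
  tt <- t[keep]
  stopifnot(all(plv >= 0 & plv <= 1 + 1e-9))
  plv_norm <- NULL
  if (normalize != "none") {
    bidx <- which(tt >= baseline[1] & tt < baseline[2])
    if (length(bidx) < 2L) stop_invalid("baseline interval outside map")
    bm <- rowMeans(plv[, bidx, drop = FALSE])
    if (normalize == "subtract") plv_norm <- plv - bm
    else {
      bs <- apply(plv[, bidx, drop = FALSE], 1, stats::sd)
      bs[bs == 0] <- NA_real_
      plv_norm <- (plv - bm) / bs
    }
  }
  structure(list(time = tt, freq = freqs, plv = plv, plv_norm = plv_norm,
                 window_ms = window_ms, n_trials = length(idx)),
            class = "lfp_plv_map")
}

# windowed Pearson correlation of two equal-length vectors at every centre
# where the window fits (cumulative-sum implementation)
windowed_pearson <- function(x, y, win) {
  mx <- Re(running_mean(x, win)); my <- Re(running_mean(y, win))
  mxy <- Re(running_mean(x * y, win))
  mxx <- Re(running_mean(x * x, win))
  myy <- Re(running_mean(y * y, win))
  cov <- mxy - mx * my
  vx <- pmax(mxx - mx^2, 0); vy <- pmax(myy - my^2, 0)
  r <- cov / sqrt(vx * vy)
  r[vx == 0 | vy == 0] <- NA_real_    # zero-variance window: undefined
  pmin(pmax(r, -1), 1)
}

#' Sliding-window interhemispheric correlation
#'
#' Pearson correlation between the two hemispheres of each trial in a
#' sliding window (default 500 ms, 1-ms step), averaged across trials with
#' SEM. Optionally, each evaluated point on a decimated grid is tested
#' against the per-trial baseline mean by Wilcoxon signed-rank.
#'
#' @param ts an `lfp_trial_set`
#' @param class trial class (NULL = all)
#' @param window_ms window length (ms)
#' @param step_ms evaluation step (ms)
#' @param baseline baseline interval (s)
#' @param sig_step_ms step of the significance grid; NULL disables testing
#' @param level significance level
#' @return `lfp_corr_trace`: data.frame-backed list with `time`, `mean`,
#'   `sem`, optional `sig` data.frame, plus window metadata
#' @export
sliding_correlation <- function(ts, class = NULL, window_ms = 500, step_ms = 1,
                                baseline = c(-1, 0), sig_step_ms = 25,
                                level = 0.05) {
  stopifnot(inherits(ts, "lfp_trial_set"))
  win <- round(window_ms / 1000 * ts$fs)
  if (win > n_samples(ts)) stop_invalid("window longer than epoch")
  step <- max(1L, round(step_ms / 1000 * ts$fs))
  idx <- class_idx(ts, class)
  t <- time_axis(ts)
  rmat <- NULL
  for (ii in seq_along(idx)) {
    i <- idx[ii]
    r <- windowed_pearson(ts$signals[i, 1L, ], ts$signals[i, 2L, ], win)
    if (is.null(rmat)) {
      keep <- which(!is.na(windowed_pearson(seq_len(n_samples(ts)) * 1.0,
                                            seq_len(n_samples(ts)) * 1.0, win)))
      keep <- keep[seq(1L, length(keep), by = step)]
      rmat <- matrix(NA_real_, length(idx), length(keep))
    }
    rmat[ii, ] <- r[keep]
  }
  tt <- t[keep]
  n_undef <- sum(is.na(rmat))
  mu <- colMeans(rmat, na.rm = TRUE)
  sem <- apply(rmat, 2, function(v) stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
  sig <- NULL
  if (!is.null(sig_step_ms)) {
    bcols <- which(tt >= baseline[1] & tt < baseline[2])
    if (length(bcols) >= 2L) {
      base_mean <- rowMeans(rmat[, bcols, drop = FALSE], na.rm = TRUE)
      gcols <- seq(1L, length(tt), by = max(1L, round(sig_step_ms / 1000 * ts$fs / step)))
      p <- vapply(gcols, function(j) rank_test_p(rmat[, j], base_mean, paired = TRUE),
                  numeric(1))
      sig <- data.frame(time = tt[gcols], p = p, significant = p < level)
    }
  }
  structure(list(time = tt, mean = mu, sem = sem, sig = sig,
                 window_ms = window_ms, step_ms = step_ms,
                 n_trials = length(idx), n_undefined = n_undef),
            class = "lfp_corr_trace")
}

#' Biased-estimator cross-correlation
#'
#' `r_xy(k) = C_xy(k) / (S_x S_y)` with the biased covariance estimator
#' (normalization by the full length T at every lag) and population
#' standard deviations `S = sqrt(C(0))`, over a symmetric lag range.
#' `r_xx(0) = 1` exactly.
#'
#' @param x,y equal-length numeric signals
#' @param max_lag maximum lag in samples (< length)
#' @param fs optional sampling rate to report lags in ms
#' @return `lfp_crosscorr`: list with `lag` (samples), `lag_ms`, `r`,
#'   `lag_at_max` (samples), `multimodal` flag
#' @export
cross_correlation <- function(x, y, max_lag, fs = NULL) {
  T_ <- length(x)
  if (length(y) != T_) stop_invalid("signals must have equal length")
  if (max_lag >= T_) stop_invalid("max_lag must be below the signal length")
  xm <- x - mean(x); ym <- y - mean(y)
  sx <- sqrt(mean(xm^2)); sy <- sqrt(mean(ym^2))
  if (sx == 0 || sy == 0) stop_invalid("degenerate input: constant signal")
  lags <- (-max_lag):max_lag
  r <- vapply(lags, function(k) {
    if (k >= 0) sum(xm[seq_len(T_ - k)] * ym[seq_len(T_ - k) + k]) / T_
    else sum(ym[seq_len(T_ + k)] * xm[seq_len(T_ + k) - k]) / T_
  }, numeric(1)) / (sx * sy)
  stopifnot(all(abs(r) <= 1 + 1e-9))
  peak <- which(r >= max(r) - 1e-6)
  structure(list(lag = lags, lag_ms = if (is.null(fs)) NULL else lags / fs * 1000,
                 r = r, lag_at_max = lags[peak[1]],
                 multimodal = length(peak) > 1L),
            class = "lfp_crosscorr")
}

#' Interhemispheric lag from trial-averaged cross-correlation
#'
#' Cross-correlation between the two hemispheres is computed per trial,
#' averaged across trials, and the lag is the argmax of the average (ties
#' broken toward the earliest lag, flagged). A trial-pairing permutation
#' test (hemisphere signals re-paired across trials) provides a null band
#' for the peak; when the observed peak does not exceed the 95th percentile
#' of the permuted peaks, the lag is flagged unreliable.
#'
#' @param ts an `lfp_trial_set`
#' @param class trial class
#' @param max_lag_ms maximum lag (ms)
#' @param interval epoch interval used (s); default full epoch
#' @param n_perm permutations (0 disables the reliability check)
#' @return list: `lag_ms`, `lag_samples`, `r` (averaged), `lags`, `peak`,
#'   `reliable`, `perm_q95`, `multimodal`
#' @export
estimate_interhemispheric_lag <- function(ts, class = NULL, max_lag_ms = 100,
                                          interval = NULL, n_perm = 0,
                                          seed = 1) {
  stopifnot(inherits(ts, "lfp_trial_set"))
  idx <- class_idx(ts, class)
  t <- time_axis(ts)
  seg <- if (is.null(interval)) seq_along(t) else which(t >= interval[1] & t < interval[2])
  max_lag <- round(max_lag_ms / 1000 * ts$fs)
  avg <- NULL
  for (i in idx) {
    cc <- cross_correlation(ts$signals[i, 1L, seg], ts$signals[i, 2L, seg], max_lag)
    avg <- if (is.null(avg)) cc$r else avg + cc$r
  }
  avg <- avg / length(idx)
  lags <- (-max_lag):max_lag
  peak_set <- which(avg >= max(avg) - 1e-6)
  lag_samples <- lags[peak_set[1]]
  reliable <- NA
  q95 <- NA_real_
  if (n_perm > 0 && length(idx) > 2L) {
    set.seed(derive_seed(seed, 31))
    perm_peaks <- vapply(seq_len(n_perm), function(p) {
      shift <- sample(seq_along(idx))
      # re-pair ipsi of trial i with contra of a different trial
      m <- 0
      for (j in seq_along(idx)) {
        jj <- shift[j]
        if (jj == j) jj <- shift[(j %% length(idx)) + 1L]
        cc <- cross_correlation(ts$signals[idx[j], 1L, seg],
                                ts$signals[idx[jj], 2L, seg], max_lag)
        m <- m + cc$r
      }
      max(m / length(idx))
    }, numeric(1))
    q95 <- stats::quantile(perm_peaks, 0.95, names = FALSE)
    reliable <- max(avg) > q95
  }
  list(lag_ms = lag_samples / ts$fs * 1000, lag_samples = lag_samples,
       r = avg, lags = lags, peak = max(avg), reliable = reliable,
       perm_q95 = q95, multimodal = length(peak_set) > 1L)
}

#' Estimate when post-stimulus coupling returns to baseline
#'
#' Reads the end of the below-baseline interval off a sliding-correlation
#' trace (or a band-averaged normalized PLV trace): the trace is lightly
#' smoothed, the dip minimum after `search_from` located, and the recovery
#' time is the first moment after the minimum where the trace rises back to
#' the baseline mean minus `margin` (default twice the mean SEM).
#'
#' @param time,value,sem trace vectors (or pass an `lfp_corr_trace` as
#'   `time`)
#' @param baseline baseline interval (s)
#' @param search_from earliest dip time considered (s)
#' @param smooth_s smoothing width (s)
#' @param margin recovery margin; default the larger of `2 * mean(sem)` and
#'   5% of the dip depth
#' @return list: `recovery_s`, `dip_time_s`, `dip_value`, `baseline_mean`
#' @export
coupling_recovery_time <- function(time, value = NULL, sem = NULL,
                                   baseline = c(-1, 0), search_from = 0.4,
                                   smooth_s = 0.1, margin = NULL) {
  if (inherits(time, "lfp_corr_trace")) {
    tr <- time; time <- tr$time; value <- tr$mean; sem <- tr$sem
  }
  dt <- mean(diff(time))
  v <- moving_average(value, round(smooth_s / dt))
  bidx <- which(time >= baseline[1] & time < baseline[2])
  mu <- mean(v[bidx])
  post <- which(time >= search_from)
  j_min <- post[which.min(v[post])]
  margin <- margin %||% max(2 * mean(sem %||% 0), 0.05 * (mu - v[j_min]))
  after <- which(time > time[j_min])
  rec <- after[which(v[after] >= mu - margin)[1]]
  list(recovery_s = if (length(rec) && !is.na(rec)) time[rec] else NA_real_,
       dip_time_s = time[j_min], dip_value = v[j_min], baseline_mean = mu)
}
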