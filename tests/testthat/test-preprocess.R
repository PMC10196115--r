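test_that("band-pass filter passes mid-band and attenuates out-of-band content", {
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)
  rms <- function(x) sqrt(mean(x^2))
  mid <- sin(2 * pi * 50 * t)
  expect_equal(rms(lfp_bandpass(mid, fs)) / rms(mid), 1, tolerance = 0.01)
  slow <- sin(2 * pi * 1 * t)
  expect_lt(rms(lfp_bandpass(slow, fs)[500:3500]) / rms(slow), 0.05)
  expect_lt(max(abs(lfp_bandpass(rep(2, 4000), fs))), 1e-6)
  expect_error(lfp_bandpass(mid, fs, lo = 3, hi = 600), "edges")
})

test_that("notch removes mains harmonics but not neighbours", {
  fs <- 1000
  t <- seq(0, 3, by = 1 / fs)
  rms <- function(x) sqrt(mean(x^2))
  m50 <- sin(2 * pi * 50 * t)
  expect_lt(rms(lfp_notch(m50, fs)) / rms(m50), 0.1)
  m150 <- sin(2 * pi * 150 * t)
  expect_lt(rms(lfp_notch(m150, fs)) / rms(m150), 0.1)
  m40 <- sin(2 * pi * 40 * t)
  expect_gt(rms(lfp_notch(m40, fs)) / rms(m40), 0.7)
  expect_identical(lfp_notch(numeric(2000), fs), numeric(2000))
})

test_that("z-score normalization satisfies its postconditions and is invertible", {
  z <- zscore_session(c(1, 2, 3))
  expect_equal(z$signal, c(-1, 0, 1))
  set.seed(1)
  x <- rnorm(500, 5, 3)
  z <- zscore_session(x)
  expect_equal(mean(z$signal), 0, tolerance = 1e-9)
  expect_equal(sd(z$signal), 1, tolerance = 1e-9)
  # affine invariance
  expect_equal(zscore_session(2.5 * x + 7)$signal, z$signal, tolerance = 1e-12)
  # inversion
  expect_equal(z$signal * z$params$sd + z$params$mean, x, tolerance = 1e-12)
  expect_error(zscore_session(rep(1, 10)), "degenerate")
  expect_error(zscore_session(1), "length")
})

test_that("Grubbs flags a planted gross outlier and nothing in tame data", {
  set.seed(2)
  x <- rnorm(30)
  x[17] <- 15
  # oracle: the Grubbs statistic of the planted point versus the critical value
  G <- max(abs(x - mean(x))) / sd(x)
  n <- 30
  tq <- qt(0.05 / (2 * n), n - 2, lower.tail = FALSE)
  crit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
  expect_gt(G, crit)
  mask <- grubbs_outlier_mask(x)
  expect_identical(which(mask), 17L)

  # near-constant data with tiny jitter: statistic below critical, empty mask
  y <- 5 + seq(-1e-3, 1e-3, length.out = 30)
  Gy <- max(abs(y - mean(y))) / sd(y)
  expect_lt(Gy, crit)
  expect_false(any(grubbs_outlier_mask(y)))

  expect_error(grubbs_outlier_mask(rnorm(5)), "insufficient")
})

test_that("Grubbs false-flag rate on Gaussian data stays alpha-controlled", {
  set.seed(3)
  fracs <- replicate(30, mean(grubbs_outlier_mask(rnorm(3000), alpha = 0.05)))
  expect_lt(mean(fracs), 0.02)
})

test_that("trial rejection recovers exactly the generator-labelled artifact trials", {
  cfg <- sim_config(n_trials = c(NS = 40), epoch_s = c(pre = 0.5, post = 1.5),
                    seed = 21)
  ts <- generate_trial_set(cfg)
  inj <- inject_artifacts(ts, rate = 0.1, magnitude = 20, seed = 4)
  rr <- reject_trials(inj$trials)
  expect_identical(which(rr$report$rejected), inj$affected)  # recall & precision 1
  expect_equal(nrow(rr$report), 40)

  # threshold 1.0: nothing can exceed a full-trial outlier fraction
  rr2 <- reject_trials(inj$trials, threshold = 1.0)
  expect_false(any(rr2$report$rejected))

  # clean data at the default configuration survives almost entirely
  rr3 <- reject_trials(ts)
  expect_gte(mean(!rr3$report$rejected), 0.98)

  # behavioural flags force rejection regardless of signal content
  rr4 <- reject_trials(ts, behavioral_flags = c(TRUE, rep(FALSE, 39)))
  expect_true(rr4$report$rejected[1])
  expect_identical(rr4$report$reason[1], "behavioral")
})

test_that("hemisphere averaging follows the 1/sqrt(n) law and flags empty hemispheres", {
  n <- 4000
  s <- sin(2 * pi * 7 * seq_len(n) / 1000)
  two <- rbind(s, s)
  map2 <- data.frame(hemisphere = c("ipsi", "contra"), noisy = FALSE)
  expect_equal(average_hemisphere_channels(two, map2)["ipsi", ], s,
               ignore_attr = TRUE)
  opp <- rbind(s, -s)
  map_opp <- data.frame(hemisphere = c("ipsi", "ipsi"), noisy = FALSE)
  expect_error(average_hemisphere_channels(opp, map_opp), "unusable")
  map_opp2 <- rbind(map_opp, data.frame(hemisphere = "contra", noisy = FALSE))
  avg <- average_hemisphere_channels(rbind(s, -s, s), map_opp2)
  expect_lt(max(abs(avg["ipsi", ])), 1e-12)

  set.seed(4)
  ch <- matrix(rep(s, each = 4), 4, n) + matrix(rnorm(4 * n), 4, n)
  ch <- rbind(ch, s)   # one contra channel
  map <- data.frame(hemisphere = c(rep("ipsi", 4), "contra"), noisy = FALSE)
  resid <- average_hemisphere_channels(ch, map)["ipsi", ] - s
  expect_equal(sqrt(mean(resid^2)), 0.5, tolerance = 0.1)  # 1/sqrt(4)

  # noisy-flagged channels are ignored
  map$noisy <- c(FALSE, FALSE, FALSE, TRUE, FALSE)
  expect_equal(dim(average_hemisphere_channels(ch, map)), c(2L, n))
})

test_that("epoching follows the half-open 0-based sample convention", {
  fs <- 1000
  n <- 20000
  sig <- rbind(seq_len(n) * 1.0, -seq_len(n) * 1.0)  # encode sample index
  rec <- list(signals = sig, fs = fs)
  ev <- data.frame(trial_id = 1, subject = 1, session = 1, label = "HN",
                   onset_s = 10.0, withdrawal_ms = 220)
  ts <- epoch_trials(rec, ev)
  expect_equal(n_trials(ts), 2L)   # one stim + one NS epoch
  stim <- ts$signals[which(ts$labels == "HN"), 1, ]
  expect_equal(stim, as.numeric(10001:13000))   # 0-based samples [10000, 13000)
  ns <- ts$signals[which(ts$labels == "NS"), 1, ]
  expect_equal(ns, as.numeric(6001:9000))       # 0-based samples [6000, 9000)

  # 5 events -> 5 stim + 5 NS trials when every window fits
  ev5 <- data.frame(trial_id = 1:5, subject = 1, session = 1, label = "NN",
                    onset_s = c(5, 8, 11, 14, 17), withdrawal_ms = NA)
  ts5 <- epoch_trials(rec, ev5)
  expect_equal(as.vector(table(ts5$labels)[c("NN", "NS")]), c(5L, 5L))

  # out-of-bounds windows are skipped with a warning and counted
  ev_bad <- data.frame(trial_id = 1, subject = 1, session = 1, label = "HN",
                       onset_s = 1.0, withdrawal_ms = NA)
  expect_warning(ts_bad <- epoch_trials(rec, ev_bad), "skipped")
  expect_equal(attr(ts_bad, "skipped"), 1L)     # NS window fell before t = 0
})

test_that("preprocessing is near-idempotent and latency-preserving", {
  cfg <- sim_config(n_trials = c(HN = 6), epoch_s = c(pre = 1, post = 1),
                    seed = 31)
  pp1 <- preprocess_trials(generate_trial_set(cfg), reject = FALSE)
  pp2 <- preprocess_trials(pp1$trials, reject = FALSE)
  # re-running the chain barely changes already-clean normalized data
  r <- cor(as.vector(pp1$trials$signals), as.vector(pp2$trials$signals))
  expect_gt(r, 0.99)
  # session z-scoring alone is exactly idempotent
  z1 <- zscore_session(as.vector(pp1$trials$signals[1, 1, ]))$signal
  z2 <- zscore_session(z1)$signal
  expect_equal(z1, z2, tolerance = 1e-12)

  # zero-phase filtering keeps a symmetric template's extremum in place
  fs <- 1000
  t <- seq(-0.5, 1, by = 1 / fs)
  tmpl <- make_ep_template(default_ep_specs()$HN, fs, t)
  filt <- lfp_bandpass(tmpl, fs)
  expect_lte(abs(which.max(filt) - which.max(tmpl)), 1)
  expect_lte(abs(which.min(filt) - which.min(tmpl)), 1)
})
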