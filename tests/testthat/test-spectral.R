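test_that("Morlet power localizes pure tones and obeys the square law", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  freqs <- default_freqs(40)
  sc <- cwt_power(sin(2 * pi * 10 * t), fs, freqs)
  mid <- sc$power[, 500:1500]
  peak_f <- sc$freq[which.max(rowMeans(mid))]
  expect_equal(peak_f, freqs[which.min(abs(freqs - 10))])

  # doubling the amplitude quadruples the power
  sc2 <- cwt_power(2 * sin(2 * pi * 10 * t), fs, freqs)
  ratio <- max(rowMeans(sc2$power[, 500:1500])) / max(rowMeans(mid))
  expect_equal(ratio, 4, tolerance = 0.02)

  # amplitude normalization: unit tone has power ~ 1 at its own frequency
  sc10 <- cwt_power(sin(2 * pi * 10 * t), fs, 10)
  expect_equal(mean(sc10$power[1, 500:1500]), 1, tolerance = 0.02)

  expect_equal(max(cwt_power(numeric(2001), fs, freqs)$power), 0)
  expect_error(cwt_power(sin(t), fs, numeric(0)), "empty")
  expect_error(cwt_power(sin(t), fs, c(10, 600)), "fs/2")
})

test_that("tone frequency recovery stays within one grid step across the range", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  freqs <- default_freqs(60)
  for (f0 in c(5, 20, 60, 110)) {
    sc <- cwt_power(sin(2 * pi * f0 * t), fs, freqs)
    i_hat <- which.max(rowMeans(sc$power[, 700:1300]))
    i_true <- which.min(abs(freqs - f0))
    expect_lte(abs(i_hat - i_true), 1)
  }
})

test_that("power scales exactly quadratically with signal amplitude", {
  ts <- white_trial_set(3, 800, onset = 401L, seed = 23)
  raw1 <- band_power(ts, intervals = list(all = c(-0.4, 0.39)),
                     normalize = "raw", baseline = c(-0.4, 0))
  ts3 <- ts; ts3$signals <- 3 * ts$signals
  raw3 <- band_power(ts3, intervals = list(all = c(-0.4, 0.39)),
                     normalize = "raw", baseline = c(-0.4, 0))
  expect_equal(raw3$value, 9 * raw1$value, tolerance = 1e-12)
})

test_that("baseline z-normalization behaves on stationary, modulated and repeated input", {
  # stationary noise: post-onset normalized power stays near zero
  ts <- white_trial_set(150, 1500, onset = 1001L, seed = 17)
  sc <- baseline_normalize(cwt_power(ts, class = "NS",
                                     freqs = default_freqs(20)),
                           baseline = c(-1, 0))
  post <- sc$power[, sc$time > 0.05 & sc$time < 0.45]
  expect_lt(abs(mean(post)), 0.1)

  # generator high-gamma early gain: positive normalized high-gamma power
  cfg <- sim_config(n_trials = c(HN = 30), epoch_s = c(pre = 1, post = 1),
                    seed = 29)
  hn <- generate_trial_set(cfg)
  schn <- baseline_normalize(cwt_power(hn, class = "HN",
                                       freqs = painlfp:::band_freqs(80, 120, 6)))
  early <- schn$power[, schn$time > 0.05 & schn$time < 0.45]
  expect_gt(mean(early), 0.5)

  # normalizing twice is the identity once the baseline is standardized
  sc2 <- baseline_normalize(sc, baseline = c(-1, 0))
  expect_equal(sc2$power, sc$power, tolerance = 1e-9)

  expect_error(baseline_normalize(sc, baseline = c(5, 6)), "baseline")
})

test_that("band power separates tones by band and vanishes on zero signals", {
  fs <- 1000
  n <- 1500
  tt <- (seq_len(n) - 1001) / fs
  arr <- array(rep(sin(2 * pi * 100 * tt), each = 2 * 2), dim = c(2, 2, n))
  ts <- trial_set(arr, c("NS", "NS"), fs, rep(1001L, 2))
  bp <- band_power(ts, intervals = list(all = c(-1, 0.49)), normalize = "raw")
  hg <- mean(bp$value[bp$band == "high_gamma"])
  th <- mean(bp$value[bp$band == "theta"])
  expect_gt(hg / th, 100)

  ts0 <- ts; ts0$signals[] <- 0
  bp0 <- band_power(ts0, intervals = list(all = c(-1, 0.49)), normalize = "raw")
  expect_equal(max(abs(bp0$value)), 0)

  expect_error(band_power(ts, intervals = list(bad = c(9, 10))), "interval")
})

test_that("raw band power over a stationary epoch matches its baseline level", {
  # long epoch with the compared intervals kept clear of the wavelet cone
  # of influence (the theta support alone spans ~1 s)
  ts <- white_trial_set(30, 6000, onset = 3001L, seed = 37)
  bp <- band_power(ts, intervals = list(whole = c(-1.5, 1.5)),
                   normalize = "raw", baseline = c(-1, 0))
  bp_base <- band_power(ts, intervals = list(base = c(-1, 0)),
                        normalize = "raw", baseline = c(-1, 0))
  for (b in unique(bp$band)) {
    r <- mean(bp$value[bp$band == b]) / mean(bp_base$value[bp_base$band == b])
    expect_equal(r, 1, tolerance = 0.1)
  }
})

test_that("band-power comparison flags generator effects and respects symmetry", {
  cfg <- sim_config(n_trials = c(HN = 40, NS = 40), epoch_s = c(pre = 1, post = 5),
                    seed = 41)
  ts <- preprocess_trials(generate_trial_set(cfg), reject = FALSE)$trials
  vh <- band_power(ts, class = "HN")
  vn <- band_power(ts, class = "NS")
  cmp <- compare_band_power(vh, vn)
  th_late <- cmp[cmp$band == "theta" & cmp$interval == "late", ]
  expect_true(th_late$significant && th_late$direction < 0)   # theta power drops
  hg_early <- cmp[cmp$band == "high_gamma" & cmp$interval == "early", ]
  expect_true(hg_early$significant && hg_early$direction > 0) # gamma power rises

  swapped <- compare_band_power(vn, vh)
  expect_equal(swapped$p, cmp$p, tolerance = 1e-12)
  expect_equal(swapped$direction, -cmp$direction)

  # identical groups: mostly non-significant across random splits
  nonsig <- 0L; total <- 0L
  for (s in 1:3) {
    set.seed(s)
    ns_idx <- which(ts$labels == "NS")
    half <- sample(ns_idx, 20)
    ca <- band_power(subset_trials(ts, half))
    cb <- band_power(subset_trials(ts, setdiff(ns_idx, half)))
    cc <- compare_band_power(ca, cb)
    nonsig <- nonsig + sum(!cc$significant); total <- total + nrow(cc)
  }
  expect_gte(nonsig / total, 0.85)
})

test_that("bilateral band power reflects the ipsilateral evoked advantage", {
  cfg <- sim_config(n_trials = c(HN = 120), epoch_s = c(pre = 1, post = 1),
                    seed = 43)
  ts <- generate_trial_set(cfg, ep = default_ep_specs(hn_ipsi_gain = 1.5))
  bil <- bilateral_band_power_comparison(ts, class = "HN",
                                         intervals = list(early = c(0, 0.5)))
  th <- bil[bil$band == "theta", ]
  expect_true(th$significant && th$mean_ipsi > th$mean_contra)

  # identical hemispheres: p = 1 by convention
  ts_id <- ts; ts_id$signals[, 2, ] <- ts_id$signals[, 1, ]
  bil_id <- bilateral_band_power_comparison(ts_id, class = "HN",
                                            intervals = list(early = c(0, 0.5)))
  expect_true(all(bil_id$p == 1))
})
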