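test_that("trial averaging is exact, linear and follows the averaging law", {
  fs <- 1000
  tmpl <- make_ep_template(default_ep_specs(hn_ipsi_gain = 1)$HN, fs,
                           seq(-0.2, 0.8, by = 1 / fs))
  n <- length(tmpl)
  # noiseless identical trials: mean is the template, SEM is zero
  arr <- array(rep(tmpl, each = 3 * 2), dim = c(3, 2, n))
  ts0 <- trial_set(arr, rep("HN", 3), fs, rep(201L, 3))
  ep <- compute_ep(ts0, "HN")
  expect_equal(ep$mean, tmpl, tolerance = 1e-12)
  expect_equal(max(ep$sem), 0)

  # two opposite trials cancel
  arr2 <- array(0, dim = c(2, 2, n))
  arr2[1, , ] <- rep(tmpl, each = 2); arr2[2, , ] <- rep(-tmpl, each = 2)
  ts2 <- trial_set(arr2, rep("NN", 2), fs, rep(201L, 2))
  expect_lt(max(abs(compute_ep(ts2, "NN")$mean)), 1e-12)

  # template + iid noise: RMS error of the mean ~ sigma / sqrt(N)
  set.seed(5)
  N <- 100; sigma <- 1
  arr3 <- array(rep(tmpl, each = N * 2) + rnorm(N * 2 * n, 0, sigma),
                dim = c(N, 2, n))
  ts3 <- trial_set(arr3, rep("HN", N), fs, rep(201L, N))
  ep3 <- compute_ep(ts3, "HN", "ipsi")
  rmse <- sqrt(mean((ep3$mean - tmpl)^2))
  expect_equal(rmse, sigma / sqrt(N), tolerance = 0.2)

  # linearity of the averaging operator
  epa <- compute_ep(ts0, "HN")$mean
  tsb <- ts0; tsb$signals <- 2 * ts0$signals + 1
  expect_equal(compute_ep(tsb, "HN")$mean, 2 * epa + 1, tolerance = 1e-12)

  expect_error(compute_ep(ts0, "NS"), "insufficient")
})

test_that("P1/N1/P2 parametrization recovers the noiseless template parameters", {
  fs <- 1000
  t <- seq(-0.5, 1, by = 1 / fs)
  specs <- default_ep_specs()
  hn <- list(time = t, mean = make_ep_template(specs$HN, fs, t), sem = numeric(length(t)),
             fs = fs)
  p <- extract_ep_params(hn)
  expect_equal(p$p1_latency_ms, 92)
  expect_equal(p$n1_latency_ms, 157)
  expect_equal(p$p1_amp, 1.15, tolerance = 1e-3)
  expect_equal(p$n1_amp, -1.17, tolerance = 1e-3)
  expect_true(p$p2_present)

  nn <- list(time = t, mean = make_ep_template(specs$NN, fs, t), sem = numeric(length(t)),
             fs = fs)
  pn <- extract_ep_params(nn)
  expect_equal(pn$p1_latency_ms, 61)
  expect_equal(pn$p1_amp, 0.21, tolerance = 1e-3)
  expect_false(pn$p2_present)

  flat <- list(time = t, mean = numeric(length(t)), sem = numeric(length(t)), fs = fs)
  pf <- extract_ep_params(flat)
  expect_true(is.na(pf$p1_latency_ms) && is.na(pf$n1_amp) && !pf$p2_present)
})

test_that("samplewise baseline test is calibrated on null data and powered on EPs", {
  # type-I calibration: pure white noise, flag rate ~ alpha
  ts <- white_trial_set(200, 1500, onset = 1001L, seed = 11)
  res <- samplewise_vs_baseline(ts, "NS", baseline = c(-1, 0))
  expect_equal(mean(res$significant), 0.05, tolerance = 0.4)  # 0.05 +/- 0.02
  expect_lt(abs(mean(res$significant) - 0.05), 0.02)

  # identical baseline and test values: zero-variance convention, no flags
  ts_const <- ts
  ts_const$signals[] <- rep(1:200, times = 2 * 1500)
  res0 <- samplewise_vs_baseline(ts_const, "NS", baseline = c(-1, 0))
  expect_true(all(res0$p == 1))
  expect_false(any(res0$significant))

  # strong EP: every sample inside the lobes flagged
  fs <- 1000
  tmpl <- make_ep_template(default_ep_specs(hn_ipsi_gain = 1)$HN, fs,
                           (seq_len(1500) - 1001) / fs)
  ts_ep <- ts
  ts_ep$signals <- ts$signals * 0.2 +
    array(rep(tmpl, each = 200 * 2), dim = c(200, 2, 1500))
  ts_ep$labels <- factor(rep("HN", 200), levels = c("HN", "NN", "NS"))
  res_ep <- samplewise_vs_baseline(ts_ep, "HN", baseline = c(-1, 0))
  # lobe samples = where the template is substantially nonzero (the zero
  # crossing between P1 and N1 carries no effect and is rightly unflagged)
  tmpl_at <- tmpl[match(round(res_ep$time * fs), seq_len(1500) - 1001)]
  lobe <- abs(tmpl_at) > 0.4
  expect_true(all(res_ep$significant[lobe]))
})

test_that("class comparison is symmetric, calibrated, and flags separated classes", {
  ts <- white_trial_set(120, 700, onset = 501L, seed = 13,
                        labels = rep(c("HN", "NN"), each = 60))
  res <- compare_classes_samplewise(ts, "HN", "NN", interval = c(0, 0.19))
  expect_lt(abs(mean(res$significant) - 0.05), 0.03)
  swapped <- compare_classes_samplewise(ts, "NN", "HN", interval = c(0, 0.19))
  expect_equal(res$p, swapped$p, tolerance = 1e-12)

  sep <- ts
  sep$signals[sep$labels == "HN", , ] <- sep$signals[sep$labels == "HN", , ] + 10
  res_sep <- compare_classes_samplewise(sep, "HN", "NN", interval = c(0, 0.19))
  expect_true(all(res_sep$significant))
})

test_that("per-trial parameter comparison reproduces the class amplitude ratios", {
  ts <- small_hn_nn()
  ph <- ep_params_trials(ts, "HN")
  pn <- ep_params_trials(ts, "NN")
  cmp <- compare_ep_params(ph, pn)
  expect_identical(nrow(cmp), 4L)
  r_p1 <- cmp$mean_a[cmp$parameter == "p1_amp"] / cmp$mean_b[cmp$parameter == "p1_amp"]
  expect_equal(r_p1, 5.47, tolerance = 0.2)
  # amplitudes differ sharply between intensities; N1 latency does not
  expect_lt(cmp$p[cmp$parameter == "p1_amp"], 1e-4)
  expect_gt(cmp$p[cmp$parameter == "n1_latency_ms"], 0.001)
})

test_that("identical classes yield non-significant parameter differences", {
  ts <- small_hn_nn()
  hn_idx <- which(ts$labels == "HN")
  nonsig <- 0L
  for (s in 1:5) {
    set.seed(s)
    half <- sample(hn_idx, length(hn_idx) / 2)
    a <- ep_params_trials(subset_trials(ts, half), "HN")
    b <- ep_params_trials(subset_trials(ts, setdiff(hn_idx, half)), "HN")
    cmp <- compare_ep_params(a, b)
    nonsig <- nonsig + sum(cmp$p > 0.05, na.rm = TRUE)
  }
  expect_gte(nonsig / (5 * 4), 0.9)
})

test_that("bilateral comparison detects the ipsilateral amplitude advantage", {
  cfg <- sim_config(n_trials = c(HN = 200), epoch_s = c(pre = 1, post = 1),
                    seed = 19)
  ts <- preprocess_trials(generate_trial_set(
    cfg, ep = default_ep_specs(hn_ipsi_gain = 1.3)))$trials
  bil <- bilateral_ep_comparison(ts, "HN")
  expect_lt(bil$p[bil$parameter == "p1_amp"], 0.05)
  expect_lt(bil$p[bil$parameter == "n1_amp"], 0.05)
  expect_gt(bil$mean_ipsi[bil$parameter == "p1_amp"],
            bil$mean_contra[bil$parameter == "p1_amp"])
  expect_lt(bil$mean_ipsi[bil$parameter == "n1_amp"],
            bil$mean_contra[bil$parameter == "n1_amp"])

  # identical hemisphere signals: p = 1 by convention
  ts_id <- ts
  ts_id$signals[, 2, ] <- ts_id$signals[, 1, ]
  bil_id <- bilateral_ep_comparison(ts_id, "HN")
  expect_true(all(bil_id$p == 1))
})

test_that("unit ipsi gain leaves bilateral latencies non-significant in most runs", {
  nonsig <- 0L
  for (s in 1:4) {
    cfg <- sim_config(n_trials = c(HN = 60), epoch_s = c(pre = 0.5, post = 0.6),
                      seed = 400 + s)
    ts <- generate_trial_set(cfg, ep = default_ep_specs(hn_ipsi_gain = 1))
    bil <- bilateral_ep_comparison(ts, "HN")
    nonsig <- nonsig + (bil$p[bil$parameter == "p1_latency_ms"] > 0.05)
  }
  expect_gte(nonsig, 3L)
})
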