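test_that("feature extraction yields the exact bilateral band-window layout", {
  cfg <- sim_config(n_trials = c(HN = 2, NS = 2), epoch_s = c(pre = 1, post = 3),
                    seed = 1)
  ts <- generate_trial_set(cfg)
  fm <- extract_mav_features(ts)
  expect_identical(ncol(fm$x), 1000L)   # 2 hemispheres x 5 bands x 100 windows
  expect_identical(max(fm$provenance$window), 100L)
  expect_identical(nrow(unique(fm$provenance[, c("hemisphere", "band")])), 10L)
  expect_false(anyNA(fm$x))
  # provenance start times tile [0, 3) s in 30-ms steps
  w1 <- fm$provenance[fm$provenance$hemisphere == "ipsi" &
                        fm$provenance$band == "theta", ]
  expect_equal(w1$start_ms, seq(0, 2970, by = 30))
})

test_that("MAV obeys closed forms for constant and sinusoidal signals", {
  fs <- 1000
  n <- 1200
  arr <- array(0.7, dim = c(1, 2, n))
  ts_c <- trial_set(arr, "NS", fs, 301L)
  fm_c <- extract_mav_features(ts_c, window_ms = 30, interval = c(0, 0.9),
                               bandpass = FALSE)
  expect_equal(as.vector(fm_c$x), rep(0.7, 60), tolerance = 1e-12)

  # one full sinusoid period per 30-ms window (33.33 Hz): MAV = 2A / pi
  tt <- (seq_len(n) - 301) / fs
  arr_s <- array(rep(3 * sin(2 * pi * tt / 0.03), each = 2), dim = c(1, 2, n))
  ts_s <- trial_set(arr_s, "NS", fs, 301L)
  fm_s <- extract_mav_features(ts_s, window_ms = 30, interval = c(0, 0.9),
                               bandpass = FALSE)
  expect_equal(as.vector(fm_s$x), rep(2 * 3 / pi, 60), tolerance = 0.01)

  # trailing partial window is dropped with a warning
  expect_warning(fm_p <- extract_mav_features(ts_c, window_ms = 30,
                                              interval = c(0, 0.895),
                                              bandpass = FALSE),
                 "partial")
  expect_identical(max(fm_p$provenance$window), 29L)
})

test_that("feature normalization z-scores columns and drops constants", {
  x <- cbind(c(1, 2, 3), c(5, 5, 5), c(0, 10, 20))
  expect_warning(z <- normalize_features(x), "constant")
  expect_identical(ncol(z), 2L)
  expect_equal(z[, 1], c(-1, 0, 1))
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_equal(apply(z, 2, sd), c(1, 1))
})

test_that("mRMR ranks by relevance first and penalizes redundant twins", {
  set.seed(31)
  n <- 400
  y <- rep(c(0, 1), each = n / 2)
  x1 <- y + rnorm(n, 0, 0.1)        # strongly informative
  x2 <- x1 + rnorm(n, 0, 0.01)      # near-duplicate of x1
  x3 <- y + rnorm(n, 0, 0.8)        # weaker but independent information
  x4 <- rnorm(n); x5 <- rnorm(n)
  X <- cbind(x1, x2, x3, x4, x5)
  rk <- mrmr_select(X, y, k = 3)
  expect_identical(rk$feature[1], 1L)          # max relevance first

  # oracle for the second pick: direct plug-in MI on the same discretization
  mi_oracle <- function(a, b, bins = 8) {
    da <- as.integer(ceiling(rank(a, ties.method = "first") * bins / length(a)))
    db <- if (length(unique(b)) <= bins) as.integer(factor(b))
          else as.integer(ceiling(rank(b, ties.method = "first") * bins / length(b)))
    tab <- table(da, db) / length(a)
    pa <- rowSums(tab); pb <- colSums(tab)
    sum(tab[tab > 0] * log(tab[tab > 0] / outer(pa, pb)[tab > 0]))
  }
  obj2 <- vapply(2:5, function(j)
    mi_oracle(X[, j], y) - mi_oracle(X[, j], X[, 1]), numeric(1))
  expect_identical(rk$feature[2], (2:5)[which.max(obj2)])
  expect_identical(rk$feature[2], 3L)          # twin deferred behind x3

  # shuffled labels: top relevance falls inside the permutation null
  set.seed(32)
  y_sh <- sample(y)
  rk_sh <- mrmr_select(X, y_sh, k = 1)
  null_rel <- replicate(99, max(vapply(1:5, function(j)
    mi_oracle(X[, j], sample(y)), numeric(1))))
  expect_lt(rk_sh$relevance[1], quantile(null_rel, 0.95) * 1.5)

  expect_error(mrmr_select(X, y, k = 0), "positive")
  expect_error(mrmr_select(X, rep(1, n), k = 2), "classes")
})

test_that("Cohen's kappa matches hand-computed values", {
  expect_equal(cohens_kappa(matrix(c(50, 0, 0, 50), 2)), 1)
  expect_equal(cohens_kappa(matrix(c(25, 25, 25, 25), 2)), 0)
  # p_o = 0.7, p_e = 0.5 -> kappa = 0.4
  expect_equal(cohens_kappa(matrix(c(40, 20, 10, 30), 2)), 0.4)
  # degenerate chance agreement
  expect_equal(cohens_kappa(matrix(c(10, 0, 0, 0), 2)), 0)
})

test_that("the validated SVM separates separable classes and stays at chance under shuffling", {
  set.seed(51)
  n <- 200; p <- 30
  y <- rep(c("HN", "NS"), each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  X[y == "HN", 1:3] <- X[y == "HN", 1:3] + 6   # d-prime ~ 6 on three features
  fm <- make_feature_set(X, y, subject = rep(1:4, length.out = n))

  res <- train_eval_svm(fm, c("HN", "NS"), k_grid = c(5, 10), folds = 5)
  expect_gte(res$accuracy, 95)
  expect_gte(res$kappa, 0.9)
  expect_gte(res$auc, 0.99)
  expect_equal(sum(res$confusion), n)

  # no-leakage guard: shuffling labels must give chance-band accuracy even
  # though feature selection sees highly structured columns
  set.seed(52)
  fm_sh <- fm; fm_sh$labels <- factor(sample(as.character(fm$labels)))
  res_sh <- train_eval_svm(fm_sh, c("HN", "NS"), k_grid = c(5, 10), folds = 5)
  band <- 100 * 1.96 * sqrt(0.25 / n)
  expect_lt(abs(res_sh$accuracy - 50), band + 5)

  # leave-one-subject-out: per-subject rows, near-perfect on separable data
  res_loso <- train_eval_svm(fm, c("HN", "NS"), scheme = "loso", k_grid = 5)
  expect_identical(nrow(res_loso$per_subject), 4L)
  expect_gte(mean(res_loso$per_subject$accuracy), 95)
})

test_that("feature maps aggregate selections by band and window", {
  prov <- data.frame(hemisphere = rep(c("ipsi", "contra"), each = 6),
                     band = rep(rep(c("theta", "beta"), each = 3), 2),
                     window = rep(1:3, 4),
                     start_ms = rep(c(0, 30, 60), 4))
  # all selected features from one band: a single nonzero row
  m <- feature_selection_map(data.frame(feature = c(1L, 2L, 8L)), prov)
  expect_equal(sum(m["theta", ]), 3)
  expect_equal(sum(m["beta", ]), 0)
  # hemispheres accumulate into the same cell
  m2 <- feature_selection_map(c(1L, 7L), prov)
  expect_equal(m2["theta", "w1"], 2)
  # empty ranking: all-zero map
  m0 <- feature_selection_map(integer(0), prov)
  expect_true(all(m0 == 0))
})
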