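# Shared fixtures, built lazily and cached across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# preprocessed HN/NN set used by several EP tests; NN needs enough trials
# for a stable average-EP anchor (its P1 is only 0.21 z-units)
small_hn_nn <- function() fixture("small_hn_nn", {
  cfg <- sim_config(n_trials = c(HN = 150, NN = 300),
                    epoch_s = c(pre = 1, post = 1), seed = 42)
  preprocess_trials(generate_trial_set(cfg))$trials
})

# white-noise bilateral trial set built directly (no generator structure)
white_trial_set <- function(n_trials, n_samples, fs = 1000, onset = 1L,
                            labels = "NS", seed = 1, shared = FALSE) {
  set.seed(seed)
  arr <- array(stats::rnorm(n_trials * 2 * n_samples),
               dim = c(n_trials, 2, n_samples))
  if (shared) arr[, 2, ] <- arr[, 1, ]
  trial_set(arr, rep_len(labels, n_trials), fs, rep(onset, n_trials))
}

# hand-built feature container for decoding tests
make_feature_set <- function(x, labels, subject = NULL) {
  structure(list(x = x,
                 provenance = data.frame(hemisphere = "ipsi", band = "broadband",
                                         window = seq_len(ncol(x)),
                                         start_ms = seq_len(ncol(x))),
                 labels = factor(labels),
                 subject = subject %||% rep(1L, nrow(x))),
            class = "lfp_features")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
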