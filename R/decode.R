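# Intensity decoding: band-limited MAV features in 30-ms windows, mRMR
# feature ranking by mutual information, Gaussian-kernel SVM with k-fold and
# leave-one-subject-out validation.

#' Extract mean-absolute-value (MAV) features
#'
#' Per hemisphere and frequency band (zero-phase 4th-order Butterworth
#' band-pass), the mean absolute value of the signal in non-overlapping
#' windows of `window_ms` across the post-onset interval. With the default
#' five bands, two hemispheres, a 3-s interval and 30-ms windows this gives
#' 2 x 5 x 100 = 1,000 features per trial. A trailing partial window is
#' dropped with a warning.
#'
#' @param ts an `lfp_trial_set`
#' @param bands data.frame of bands ([default_bands()])
#' @param window_ms window length (ms)
#' @param interval feature interval in seconds relative to onset
#' @param order Butterworth order
#' @param bandpass set FALSE to skip filtering (single broadband "band");
#'   used for calibration checks
#' @return `lfp_features`: list with `x` (trials x features), `provenance`
#'   (hemisphere, band, window, start_ms per column), `labels`, `subject`
#' @export
extract_mav_features <- function(ts, bands = default_bands(), window_ms = 30,
                                 interval = c(0, 3), order = 4,
                                 bandpass = TRUE) {
  stopifnot(inherits(ts, "lfp_trial_set"))
  t <- time_axis(ts)
  seg <- which(t >= interval[1] & t < interval[2])
  len <- length(seg)
  wlen <- round(window_ms / 1000 * ts$fs)
  n_win <- len %/% wlen
  if (n_win * wlen != len)
    warning("epoch interval not divisible by window; trailing partial window dropped")
  if (n_win < 1L) stop_invalid("interval shorter than one window")
  if (!bandpass) bands <- data.frame(band = "broadband", f_lo = NA, f_hi = NA)
  hemis <- c("ipsi", "contra")
  nt <- n_trials(ts)
  nf <- length(hemis) * nrow(bands) * n_win
  x <- matrix(0, nt, nf)
  prov <- data.frame(hemisphere = character(nf), band = character(nf),
                     window = integer(nf), start_ms = numeric(nf))
  win_grp <- rep(seq_len(n_win), each = wlen)
  col <- 0L
  for (h in seq_along(hemis)) {
    m <- hemi_mat2(ts, hemis[h])
    for (b in seq_len(nrow(bands))) {
      cols <- col + seq_len(n_win)
      prov$hemisphere[cols] <- hemis[h]
      prov$band[cols] <- bands$band[b]
      prov$window[cols] <- seq_len(n_win)
      prov$start_ms[cols] <- (interval[1] + (seq_len(n_win) - 1) * wlen / ts$fs) * 1000
      for (i in seq_len(nt)) {
        xi <- if (bandpass)
          lfp_bandpass(m[i, ], ts$fs, bands$f_lo[b], bands$f_hi[b], order)
        else m[i, ]
        x[i, cols] <- tapply(abs(xi[seg[seq_len(n_win * wlen)]]), win_grp, mean)
      }
      col <- col + n_win
    }
  }
  structure(list(x = x, provenance = prov, labels = ts$labels,
                 subject = ts$subject),
            class = "lfp_features")
}

#' Z-score feature columns
#'
#' Each column is normalized to mean 0 and sample SD 1; constant columns are
#' dropped with a warning.
#'
#' @param fm an `lfp_features` object (or plain matrix)
#' @return same type, normalized
#' @export
normalize_features <- function(fm) {
  x <- if (inherits(fm, "lfp_features")) fm$x else fm
  if (nrow(x) < 2L) stop_invalid("need >= 2 rows")
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  const <- sdv == 0 | !is.finite(sdv)
  if (any(const)) {
    warning(sprintf("%d constant feature column(s) dropped", sum(const)))
    x <- x[, !const, drop = FALSE]
    mu <- mu[!const]; sdv <- sdv[!const]
  }
  x <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  if (inherits(fm, "lfp_features")) {
    fm$x <- x
    fm$provenance <- fm$provenance[!const, , drop = FALSE]
    fm
  } else x
}

# equal-frequency discretization into n_bins levels (deterministic)
discretize_ef <- function(x, n_bins = 8L) {
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * n_bins / length(x)))
}

# plug-in mutual information (nats) between two integer-coded vectors
mi_disc <- function(a, ka, b, kb) {
  n <- length(a)
  joint <- tabulate((a - 1L) * kb + b, ka * kb) / n
  pa <- tabulate(a, ka) / n
  pb <- tabulate(b, kb) / n
  nz <- joint > 0
  # joint index is (a-1)*kb + b, i.e. a-major; matching marginal product:
  pp <- rep(pa, each = kb) * rep.int(pb, ka)
  sum(joint[nz] * log(joint[nz] / pp[nz]))
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy mRMR: the first feature maximizes the mutual information with the
#' label; each subsequent pick maximizes
#' `I(x_j; y) - (1/|S|) * sum_{i in S} I(x_j; x_i)`.
#' Mutual information is the plug-in estimate on equal-frequency
#' discretized features (`n_bins` levels). Deterministic given the matrix.
#'
#' @param x feature matrix (trials x features) or `lfp_features`
#' @param y labels (factor); taken from `x` when it is an `lfp_features`
#' @param k number of features to rank
#' @param n_bins discretization levels
#' @return data.frame ranking: `feature` (column index), `score` (objective
#'   at selection), `relevance`, `redundancy` (mean MI with earlier picks)
#' @export
mrmr_select <- function(x, y = NULL, k, n_bins = 8L) {
  if (inherits(x, "lfp_features")) { y <- y %||% x$labels; x <- x$x }
  if (is.null(y)) stop_invalid("labels required")
  if (k <= 0) stop_invalid("k must be positive")
  k <- min(k, ncol(x))
  y <- as.integer(factor(y))
  if (length(unique(y)) < 2L) stop_invalid("need >= 2 classes")
  ky <- max(y)
  nb <- as.integer(n_bins)
  xd <- apply(x, 2, discretize_ef, n_bins = nb)
  p <- ncol(x)
  relevance <- vapply(seq_len(p), function(j) mi_disc(xd[, j], nb, y, ky),
                      numeric(1))
  selected <- integer(0)
  redsum <- numeric(p)
  score_out <- red_out <- numeric(k)
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(p), selected)
    score <- relevance[cand] -
      if (length(selected)) redsum[cand] / length(selected) else 0
    pick <- cand[which.max(score)]
    selected <- c(selected, pick)
    score_out[step] <- max(score)
    red_out[step] <- if (length(selected) > 1L)
      redsum[pick] / (length(selected) - 1L) else 0
    if (step < k) {
      rest <- setdiff(seq_len(p), selected)
      redsum[rest] <- redsum[rest] +
        vapply(rest, function(j) mi_disc(xd[, j], nb, xd[, pick], nb), numeric(1))
    }
  }
  data.frame(feature = selected, score = score_out,
             relevance = relevance[selected], redundancy = red_out)
}

#' Cohen's kappa from a confusion matrix
#'
#' `(p_o - p_e) / (1 - p_e)` with marginal-product chance agreement;
#' defined as 0 when `p_e = 1`.
#' @param confusion square count matrix (true x predicted)
#' @export
cohens_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  n <- sum(confusion)
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (abs(1 - pe) < 1e-12) return(0)
  (po - pe) / (1 - pe)
}

# metrics for one set of pooled predictions
pooled_metrics <- function(truth, pred, scores, positive) {
  lv <- levels(truth)
  cm <- table(factor(truth, lv), factor(pred, lv))
  auc <- tryCatch(
    as.numeric(pROC::auc(pROC::roc(response = truth == positive,
                                   predictor = scores, quiet = TRUE,
                                   direction = "<"))),
    error = function(e) NA_real_)
  list(accuracy = 100 * mean(pred == truth),
       kappa = cohens_kappa(cm), auc = auc, confusion = cm)
}

#' Train and evaluate the Gaussian-kernel SVM intensity classifier
#'
#' Full validated decoding: inside every fold, feature normalization and
#' mRMR ranking are fitted on the training trials only (no leakage), an RBF
#' SVM is trained on the top `k` features for every candidate `k` in
#' `k_grid`, and predictions are pooled across folds. The selected-feature
#' count is the `k` with the best pooled accuracy. Schemes: stratified
#' `kfold` (default 10-fold) or `loso` (leave-one-subject-out, subjects in
#' sorted id order, per-subject rows plus mean +/- sd).
#'
#' @param fm `lfp_features` (will be subset to the two classes in `pair`)
#' @param pair character(2): the classes to discriminate; the first is the
#'   positive class for AUC
#' @param scheme "kfold" or "loso"
#' @param k_grid candidate selected-feature counts
#' @param folds number of folds (kfold scheme)
#' @param cost SVM cost parameter; give several values via `cost_grid` to
#'   select by inner 3-fold accuracy
#' @param cost_grid optional cost candidates for inner grid search
#' @param gamma RBF width; default `1/n_features` (e1071 default)
#' @param class_weights use inverse-frequency class weights
#' @param n_bins mRMR discretization levels
#' @param seed fold-assignment seed
#' @return `lfp_decoding`: list with `scheme`, `best_k`, `accuracy` (%),
#'   `kappa`, `auc`, `confusion`, `per_k`, `per_subject` (loso),
#'   `skipped_folds`
#' @export
train_eval_svm <- function(fm, pair, scheme = c("kfold", "loso"),
                           k_grid = c(25, 50, 100), folds = 10,
                           cost = 1, cost_grid = NULL, gamma = NULL,
                           class_weights = TRUE, n_bins = 8L, seed = 1) {
  stopifnot(inherits(fm, "lfp_features"))
  scheme <- match.arg(scheme)
  keep <- fm$labels %in% pair
  x <- fm$x[keep, , drop = FALSE]
  y <- droplevels(factor(fm$labels[keep], levels = pair))
  subj <- fm$subject[keep]
  n <- nrow(x)
  if (scheme == "loso" && length(unique(subj)) < 2L)
    stop_invalid("leave-one-subject-out needs >= 2 subjects")

  if (scheme == "kfold") {
    set.seed(derive_seed(seed, 13))
    fold_id <- integer(n)
    for (lv in levels(y)) {
      ii <- which(y == lv)
      fold_id[ii] <- sample(rep_len(seq_len(folds), length(ii)))
    }
    fold_levels <- seq_len(folds)
  } else {
    fold_levels <- sort(unique(subj))
    fold_id <- match(subj, fold_levels)
    fold_levels <- seq_along(fold_levels)
  }

  kmax <- min(max(k_grid), ncol(x))
  k_grid <- unique(pmin(k_grid, ncol(x)))
  pred <- matrix(NA_character_, n, length(k_grid))
  scores <- matrix(NA_real_, n, length(k_grid))
  sel_counts <- matrix(0L, nrow = length(k_grid), ncol = ncol(x))
  skipped <- integer(0)

  fit_predict <- function(xtr, ytr, xte, k_use, cost_use) {
    w <- if (class_weights) {
      tb <- table(ytr); stats::setNames(as.numeric(sum(tb) / (2 * tb)), names(tb))
    } else NULL
    mod <- e1071::svm(xtr[, k_use, drop = FALSE], ytr, kernel = "radial",
                      cost = cost_use, gamma = gamma %||% (1 / length(k_use)),
                      class.weights = w, probability = FALSE, scale = FALSE)
    pr <- stats::predict(mod, xte[, k_use, drop = FALSE], decision.values = TRUE)
    dv <- as.numeric(attr(pr, "decision.values"))
    # orient decision values so larger = more likely the positive (first) class
    dvn <- colnames(attr(pr, "decision.values"))[1]
    if (!startsWith(dvn, pair[1])) dv <- -dv
    list(pred = as.character(pr), score = dv)
  }

  for (f in fold_levels) {
    te <- which(fold_id == f); tr <- which(fold_id != f)
    if (length(unique(y[tr])) < 2L || length(te) == 0L) {
      skipped <- c(skipped, f); next
    }
    mu <- colMeans(x[tr, , drop = FALSE])
    sdv <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    usable <- which(sdv > 0)
    xtr <- sweep(sweep(x[tr, usable, drop = FALSE], 2, mu[usable]), 2, sdv[usable], "/")
    xte <- sweep(sweep(x[te, usable, drop = FALSE], 2, mu[usable]), 2, sdv[usable], "/")
    rank <- mrmr_select(xtr, y[tr], k = min(kmax, length(usable)), n_bins = n_bins)

    cost_use <- cost
    if (!is.null(cost_grid) && length(cost_grid) > 1L) {
      k_in <- min(k_grid[length(k_grid)], nrow(rank))
      inner_acc <- vapply(cost_grid, function(cc) {
        set.seed(derive_seed(seed, 97 + f))
        inner_fold <- sample(rep_len(1:3, length(tr)))
        mean(vapply(1:3, function(g) {
          it <- inner_fold != g
          if (length(unique(y[tr][it])) < 2L) return(NA_real_)
          r <- fit_predict(xtr[it, , drop = FALSE], y[tr][it],
                           xtr[!it, , drop = FALSE], rank$feature[seq_len(k_in)], cc)
          mean(r$pred == as.character(y[tr][!it]))
        }, numeric(1)), na.rm = TRUE)
      }, numeric(1))
      cost_use <- cost_grid[which.max(inner_acc)]
    }

    for (ki in seq_along(k_grid)) {
      k_use <- rank$feature[seq_len(min(k_grid[ki], nrow(rank)))]
      r <- fit_predict(xtr, y[tr], xte, k_use, cost_use)
      pred[te, ki] <- r$pred
      scores[te, ki] <- r$score
      sel_counts[ki, usable[k_use]] <- sel_counts[ki, usable[k_use]] + 1L
    }
  }

  eval_idx <- which(!is.na(pred[, 1]))
  per_k <- data.frame(k = k_grid, accuracy = vapply(seq_along(k_grid), function(ki)
    100 * mean(pred[eval_idx, ki] == as.character(y[eval_idx])), numeric(1)))
  best <- which.max(per_k$accuracy)
  met <- pooled_metrics(y[eval_idx], pred[eval_idx, best], scores[eval_idx, best],
                        positive = pair[1])

  per_subject <- NULL
  if (scheme == "loso") {
    per_subject <- do.call(rbind, lapply(sort(unique(subj)), function(s) {
      ii <- intersect(which(subj == s), eval_idx)
      if (!length(ii)) return(NULL)
      cm <- table(factor(y[ii], levels(y)),
                  factor(pred[ii, best], levels(y)))
      data.frame(subject = s, n = length(ii),
                 accuracy = 100 * mean(pred[ii, best] == as.character(y[ii])),
                 kappa = cohens_kappa(cm))
    }))
  }

  structure(list(scheme = scheme, pair = pair, best_k = k_grid[best],
                 accuracy = met$accuracy, kappa = met$kappa, auc = met$auc,
                 confusion = met$confusion, per_k = per_k,
                 per_subject = per_subject,
                 selection_counts = sel_counts[best, ],
                 n_evaluated = length(eval_idx), skipped_folds = skipped),
            class = "lfp_decoding")
}

#' @export
print.lfp_decoding <- function(x, ...) {
  cat(sprintf("<lfp_decoding> %s vs %s (%s): accuracy %.1f%%, kappa %.2f, AUC %.2f (k = %d)\n",
              x$pair[1], x$pair[2], x$scheme, x$accuracy, x$kappa, x$auc, x$best_k))
  if (!is.null(x$per_subject)) {
    print(x$per_subject, row.names = FALSE)
    cat(sprintf("mean %.2f +/- %.2f %%, kappa %.2f +/- %.2f\n",
                mean(x$per_subject$accuracy), stats::sd(x$per_subject$accuracy),
                mean(x$per_subject$kappa), stats::sd(x$per_subject$kappa)))
  }
  invisible(x)
}

#' Map selected features over time windows and frequency bands
#'
#' Counts how often each (band x time-window) cell was selected — the
#' feature-distribution map showing where in time and frequency the
#' discriminative information lives. Hemispheres are summed.
#'
#' @param ranking data.frame from [mrmr_select()], or a vector of feature
#'   column indices, or the `selection_counts` of an `lfp_decoding`
#' @param provenance provenance data.frame of the feature matrix
#' @return matrix bands x windows of selection counts
#' @export
feature_selection_map <- function(ranking, provenance) {
  counts <- if (is.data.frame(ranking)) {
    v <- numeric(nrow(provenance)); v[ranking$feature] <- 1; v
  } else if (length(ranking) == nrow(provenance) && !is.integer(ranking)) {
    as.numeric(ranking)
  } else {
    v <- numeric(nrow(provenance)); v[as.integer(ranking)] <- 1; v
  }
  bands <- unique(provenance$band)
  wins <- sort(unique(provenance$window))
  out <- matrix(0, length(bands), length(wins),
                dimnames = list(bands, paste0("w", wins)))
  for (i in which(counts > 0))
    out[provenance$band[i], paste0("w", provenance$window[i])] <-
      out[provenance$band[i], paste0("w", provenance$window[i])] + counts[i]
  out
}
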