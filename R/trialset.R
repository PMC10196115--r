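#' Epoched bilateral LFP trial set
#'
#' The container passed between every stage of the pipeline: an array of
#' epoched, onset-aligned bilateral LFP trials with class labels and
#' behavioural/recording metadata. Hemisphere 1 is ipsilateral (same side as
#' the stimulated left hind paw, i.e. the left hemisphere) and hemisphere 2
#' contralateral.
#'
#' @param signals numeric array, trials x 2 (hemispheres) x samples.
#' @param labels character or factor of trial classes, subset of HN/NN/NS
#'   (high-intensity noxious, non-noxious, no stimulation).
#' @param fs sampling rate in Hz.
#' @param onset 1-based sample index of stimulus onset (time 0), one per trial.
#' @param withdrawal_ms paw-withdrawal latency in ms (NA where not applicable).
#' @param session,subject session and subject identifiers, one per trial.
#' @param truth optional list of generator ground truth (templates, coupling
#'   trace, artifact ids) used as recovery oracles.
#' @return an object of class `lfp_trial_set`.
#' @export
trial_set <- function(signals, labels, fs, onset,
                      withdrawal_ms = NULL, session = NULL, subject = NULL,
                      truth = NULL) {
  if (length(dim(signals)) != 3L || dim(signals)[2] != 2L)
    stop_invalid("`signals` must be a trials x 2 x samples array")
  n <- dim(signals)[1]
  if (!all(is.finite(signals))) stop_invalid("all samples must be finite")
  labels <- as.character(labels)
  if (length(labels) != n) stop_invalid("one label per trial required")
  if (!all(labels %in% c("HN", "NN", "NS")))
    stop_invalid("labels must be within {HN, NN, NS}")
  assert_scalar_num(fs, "fs", lo = 1e-9)
  onset <- rep_len(as.integer(onset), n)
  if (any(onset < 1L) || any(onset > dim(signals)[3]))
    stop_invalid("every onset index must lie inside the sample range")
  dimnames(signals) <- list(NULL, c("ipsi", "contra"), NULL)
  structure(list(
    signals = signals,
    labels = factor(labels, levels = c("HN", "NN", "NS")),
    fs = fs,
    onset = onset,
    withdrawal_ms = rep_len(if (is.null(withdrawal_ms)) NA_real_ else withdrawal_ms, n),
    session = rep_len(if (is.null(session)) 1L else session, n),
    subject = rep_len(if (is.null(subject)) 1L else subject, n),
    truth = truth,
    schema_version = "1.0"
  ), class = "lfp_trial_set")
}

#' @export
print.lfp_trial_set <- function(x, ...) {
  d <- dim(x$signals)
  cat(sprintf("<lfp_trial_set> %d trials x 2 hemispheres x %d samples @ %g Hz\n",
              d[1], d[3], x$fs))
  print(table(x$labels))
  tm <- time_axis(x)
  cat(sprintf("epoch window: [%.3f, %.3f] s; %d session(s), %d subject(s)\n",
              tm[1], tm[length(tm)], length(unique(x$session)),
              length(unique(x$subject))))
  invisible(x)
}

#' Time axis of a trial set, in seconds relative to stimulus onset
#' @param ts an `lfp_trial_set`
#' @export
time_axis <- function(ts) {
  (seq_len(dim(ts$signals)[3]) - ts$onset[1]) / ts$fs
}

n_trials <- function(ts) dim(ts$signals)[1]
n_samples <- function(ts) dim(ts$signals)[3]

# row indices for a class (or all trials when class is NULL)
class_idx <- function(ts, class = NULL) {
  if (is.null(class)) seq_len(n_trials(ts)) else which(ts$labels %in% class)
}

# trials x samples matrix for one hemisphere ("ipsi"/"contra") or the
# hemisphere-averaged "pooled" signal
hemi_matrix <- function(ts, hemisphere = "pooled", idx = NULL) {
  idx <- idx %||% seq_len(n_trials(ts))
  hemisphere <- match.arg(hemisphere, c("pooled", "ipsi", "contra"))
  if (hemisphere == "pooled")
    (ts$signals[idx, 1L, , drop = FALSE] + ts$signals[idx, 2L, , drop = FALSE]) / 2
  else
    ts$signals[idx, hemisphere, , drop = FALSE]
}

# same, returned as a plain matrix
hemi_mat2 <- function(ts, hemisphere = "pooled", idx = NULL) {
  m <- hemi_matrix(ts, hemisphere, idx)
  dim(m) <- c(dim(m)[1], dim(m)[3])
  m
}

#' Subset a trial set by trial index
#' @param ts an `lfp_trial_set`
#' @param idx integer or logical trial index
#' @export
subset_trials <- function(ts, idx) {
  trial_set(ts$signals[idx, , , drop = FALSE], as.character(ts$labels[idx]),
            ts$fs, ts$onset[idx], ts$withdrawal_ms[idx],
            ts$session[idx], ts$subject[idx], truth = ts$truth)
}

#' Write / read the package trial container
#'
#' The on-disk trial container is a single RDS file holding the full
#' `lfp_trial_set` (signals, labels, onsets, metadata, schema version), the
#' package's equivalent of an epoched-trial archive. The events table travels
#' separately as CSV (see [write_events_csv()]).
#'
#' @param ts an `lfp_trial_set`
#' @param path file path (conventionally `.rds`)
#' @export
write_trial_set <- function(ts, path) {
  stopifnot(inherits(ts, "lfp_trial_set"))
  saveRDS(ts, path)
  invisible(path)
}

#' @rdname write_trial_set
#' @export
read_trial_set <- function(path) {
  ts <- readRDS(path)
  diag <- validate_trial_set(ts)
  if (!diag$ok) stop_invalid("malformed trial container: %s", diag$errors[1])
  ts
}

#' Events table writer/reader (CSV)
#'
#' Columns: trial_id, subject, session, label, onset_s, withdrawal_ms.
#' @param ts an `lfp_trial_set`
#' @param path CSV path
#' @export
write_events_csv <- function(ts, path) {
  ev <- data.frame(
    trial_id = seq_len(n_trials(ts)),
    subject = ts$subject,
    session = ts$session,
    label = as.character(ts$labels),
    onset_s = (ts$onset - 1) / ts$fs,
    withdrawal_ms = ts$withdrawal_ms
  )
  utils::write.csv(ev, path, row.names = FALSE)
  invisible(ev)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "subject", "session", "label", "onset_s")
  miss <- setdiff(need, names(ev))
  if (length(miss)) stop_invalid("events CSV missing column(s): %s",
                                 paste(miss, collapse = ", "))
  ev
}

#' Validate a trial container
#'
#' Schema-level diagnostics: array shape, hemisphere completeness, label set,
#' onset bounds, finiteness, sampling rate. Returns a diagnostics list rather
#' than erroring so callers can report the first violation.
#' @param ts object to check
#' @return list with `ok`, `errors`, `counts`, `fs`, `schema_version`
#' @export
validate_trial_set <- function(ts) {
  errors <- character()
  if (!is.list(ts) || is.null(ts$signals)) {
    return(list(ok = FALSE, errors = "not a trial container (no signals)",
                counts = NULL, fs = NULL, schema_version = NULL))
  }
  d <- dim(ts$signals)
  if (length(d) != 3L) errors <- c(errors, "signals must have 3 dimensions")
  else if (d[2] != 2L) errors <- c(errors, "exactly two hemisphere channels required")
  if (!all(is.finite(ts$signals))) errors <- c(errors, "non-finite samples present")
  if (!all(as.character(ts$labels) %in% c("HN", "NN", "NS")))
    errors <- c(errors, "label outside {HN, NN, NS}")
  if (is.null(ts$fs) || !is.numeric(ts$fs) || ts$fs <= 0)
    errors <- c(errors, "invalid sampling rate")
  if (length(d) == 3L && (any(ts$onset < 1L) || any(ts$onset > d[3])))
    errors <- c(errors, "onset index outside sample range")
  list(ok = length(errors) == 0L, errors = errors,
       counts = table(as.character(ts$labels)), fs = ts$fs,
       schema_version = ts$schema_version %||% "unknown")
}
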