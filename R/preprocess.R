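#' Construct a raw continuous recording
#'
#' Container for an unsegmented multichannel recording: a channels x time
#' amplitude matrix (microvolts), channel labels per the 10/20 system, the
#' sampling rate, and an event table of stimulus-timeline markers.
#'
#' @param samples Numeric channels x time matrix (microvolts).
#' @param channel_names Unique channel labels, one per row of `samples`.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param events Tibble with columns `onset` (0-based sample index, strictly
#'   increasing), `class` (label or NA) and `kind` (one of `idle`, `cue`,
#'   `stimulus`, `rest`). May be empty.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(samples, channel_names, sample_rate,
                          events = tibble(onset = integer(), class = character(),
                                          kind = character())) {
  samples <- as.matrix(samples)
  if (nrow(samples) != length(channel_names)) {
    abort("need one channel name per row of `samples`")
  }
  if (anyDuplicated(channel_names)) abort("channel names must be unique")
  if (sample_rate <= 0) abort("sample_rate must be positive")
  events <- as_tibble(events)
  if (nrow(events) > 1 && any(diff(events$onset) <= 0)) {
    abort("event onsets must be strictly increasing")
  }
  rownames(samples) <- channel_names
  structure(list(samples = samples, channel_names = channel_names,
                 sample_rate = sample_rate, events = events),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$samples), ncol(x$samples), x$sample_rate, nrow(x$events)))
  invisible(x)
}

# 4th-order Butterworth band-pass applied forward-backward (zero-phase)
bandpass_matrix <- function(m, low, high, sample_rate, order = 4) {
  nyq <- sample_rate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    abort(sprintf("band [%g, %g] Hz must satisfy 0 < low < high < Nyquist (%g)",
                  low, high, nyq))
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  t(apply(m, 1, function(ch) signal::filtfilt(bf, ch)))
}

#' Band-pass filter a recording or trial set
#'
#' Applies the 4-45 Hz front end (4th-order Butterworth, run forward and
#' backward so the net filter has zero phase and stimulus-locked latencies are
#' preserved). The band covers the theta (4-7 Hz), alpha (8-15 Hz) and beta
#' (16-31 Hz) rhythms while excluding slow ocular drift and 50 Hz line noise.
#'
#' @param x A [raw_recording()] or [trial_set()].
#' @param low,high Band edges in Hz; `0 < low < high < sample_rate/2`.
#' @param order Butterworth section order (default 4).
#' @return Object of the same type with every channel filtered.
#' @export
eeg_bandpass <- function(x, low = 4, high = 45, order = 4) {
  UseMethod("eeg_bandpass")
}

#' @export
eeg_bandpass.raw_recording <- function(x, low = 4, high = 45, order = 4) {
  x$samples <- bandpass_matrix(x$samples, low, high, x$sample_rate, order)
  rownames(x$samples) <- x$channel_names
  x
}

#' @export
eeg_bandpass.trial_set <- function(x, low = 4, high = 45, order = 4) {
  sr <- ts_sample_rate(x)
  out <- x
  out$data <- lapply(x$data, bandpass_matrix, low, high, sr, order)
  restore_ts(out, x)
}

#' Select and reorder channels
#'
#' Subsets a recording to a montage, reordering rows to the montage order.
#' The default montage is the eight language-area electrodes.
#'
#' @param recording A [raw_recording()].
#' @param montage Character vector of channel labels to keep, in order.
#' @return A [raw_recording()] with `length(montage)` channels.
#' @export
select_channels <- function(recording, montage = default_montage()) {
  missing <- setdiff(montage, recording$channel_names)
  if (length(missing) > 0) {
    abort(sprintf("channel(s) absent from recording: %s",
                  paste(missing, collapse = ", ")))
  }
  recording$samples <- recording$samples[montage, , drop = FALSE]
  recording$channel_names <- montage
  recording
}

#' Cut labelled task-window epochs from a continuous recording
#'
#' Extracts one epoch per `stimulus` event, spanning the half-open window
#' `[onset, onset + task_s * sample_rate)` (onset-aligned, 0-based sample
#' indices). Stimulus windows running past the end of the recording are
#' dropped with a warning.
#'
#' @param recording A [raw_recording()] whose events include `stimulus` rows
#'   with class labels.
#' @param design An [experiment_design()] supplying the task window length.
#' @param baseline Subtract the per-channel epoch mean (default TRUE).
#' @return A [trial_set()] with one row per retained stimulus event.
#' @export
epoch_trials <- function(recording, design, baseline = TRUE) {
  stim <- recording$events[recording$events$kind == "stimulus", ]
  if (nrow(stim) == 0) abort("recording has no stimulus events")
  n <- as.integer(round(design$task_s * recording$sample_rate))
  total <- ncol(recording$samples)
  keep <- stim$onset + n <= total
  if (any(!keep)) {
    warn(sprintf("dropping %d stimulus event(s) extending past recording end",
                 sum(!keep)))
  }
  stim <- stim[keep, ]
  labels <- class_label_set(design$n_classes)
  data <- lapply(stim$onset, function(on) {
    ep <- recording$samples[, (on + 1):(on + n), drop = FALSE]
    if (baseline) ep <- ep - rowMeans(ep)
    ep
  })
  meta <- tibble(subject = 1L, block = NA_integer_,
                 class = factor(stim$class, levels = labels))
  trial_set(meta, data, recording$channel_names, recording$sample_rate)
}

#' Reject trials with out-of-range amplitudes
#'
#' Minimal artifact-rejection rule: a trial is rejected when any sample
#' exceeds `threshold_uv` in absolute value (default 100 microvolts), the
#' conventional screen for residual ocular or movement artifacts after
#' band-pass filtering.
#'
#' @param ts A [trial_set()].
#' @param threshold_uv Rejection threshold in microvolts.
#' @return The trial set with offending rows removed; the number rejected is
#'   reported via a message attribute `n_rejected`.
#' @export
reject_artifacts <- function(ts, threshold_uv = 100) {
  bad <- vapply(ts$data, function(m) max(abs(m)) > threshold_uv, logical(1))
  out <- restore_ts(ts[!bad, ], ts)
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Z-score each trial's channels
#'
#' Standardizes every channel of every trial to zero mean and unit variance
#' over the task window. This conditions both the CSP covariance estimates
#' and the recurrent network's optimization; CSP log-variance features are in
#' any case invariant to per-trial scaling because of the trace normalization.
#'
#' @param ts A [trial_set()].
#' @return The standardized trial set.
#' @export
zscore_trials <- function(ts) {
  out <- ts
  out$data <- lapply(ts$data, function(m) {
    mu <- rowMeans(m)
    s <- apply(m, 1, sd)
    s[s == 0] <- 1
    (m - mu) / s
  })
  restore_ts(out, ts)
}

#' Stratified train/test split of a trial set
#'
#' Splits trials into disjoint train and test sets, stratified jointly by
#' subject and class. Within each subject the per-class training counts are
#' allocated by largest remainder so that each subject contributes as close
#' to `train_proportion` of its trials as integer counts allow (each class
#' count differs from `proportion * count` by less than 1).
#'
#' @param ts A [trial_set()].
#' @param train_proportion Fraction in (0, 1) of trials to train on.
#' @param seed Integer seed controlling which trials fill each stratum.
#' @return Named list with `train` and `test` trial sets; their union is the
#'   input and their intersection is empty.
#' @export
split_trials <- function(ts, train_proportion, seed = 1L) {
  if (!(train_proportion > 0 && train_proportion < 1)) {
    abort("train_proportion must be in (0, 1)")
  }
  idx <- withr::with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(ts)), ts$subject), function(rows) {
      cls <- as.character(ts$class[rows])
      counts <- table(cls)
      exact <- setNames(train_proportion * as.numeric(counts), names(counts))
      base <- floor(exact)
      rem <- exact - base
      extra <- round(sum(exact)) - sum(base)
      # largest-remainder: classes with biggest fractional part get one more
      order_rem <- order(rem, runif(length(rem)), decreasing = TRUE)
      take <- base
      if (extra > 0) take[order_rem[seq_len(extra)]] <- take[order_rem[seq_len(extra)]] + 1
      if (any(take == 0) || any(take == counts)) {
        abort("train_proportion leaves an empty class in train or test for a subject")
      }
      unlist(lapply(names(counts), function(k) {
        rows_k <- rows[cls == k]
        sample(rows_k, take[[k]])
      }))
    }), use.names = FALSE)
  })
  list(train = restore_ts(ts[sort(idx), ], ts),
       test = restore_ts(ts[-sort(idx), ], ts))
}
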