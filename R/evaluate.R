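#' Confusion matrix of a six-class decoding run
#'
#' Counts `C_ij` of trials with true class i predicted as class j. Accuracy
#' is `sum_i C_ii / sum_ij C_ij`; per-class precision, recall and F1 follow
#' the one-versus-rest definitions from the same counts.
#'
#' @param truth True labels (factor or character).
#' @param estimate Predicted labels, same length.
#' @param levels Class levels; default the union of both label sets (or the
#'   factor levels of `truth`).
#' @return An object of class `confusion_eeg` wrapping the counts matrix.
#' @export
confusion_matrix <- function(truth, estimate, levels = NULL) {
  if (length(truth) != length(estimate)) {
    abort("truth and estimate must have equal length")
  }
  if (is.null(levels)) {
    levels <- if (is.factor(truth)) base::levels(truth) else
      sort(unique(c(as.character(truth), as.character(estimate))))
  }
  truth <- factor(as.character(truth), levels = levels)
  estimate <- factor(as.character(estimate), levels = levels)
  if (anyNA(truth) || anyNA(estimate)) {
    abort("labels outside the declared class levels")
  }
  counts <- table(truth = truth, estimate = estimate)
  structure(list(counts = unclass(counts), levels = levels),
            class = "confusion_eeg")
}

#' @export
print.confusion_eeg <- function(x, ...) {
  cat(sprintf("<confusion_eeg> %d classes, %d trials, accuracy %.4f\n",
              length(x$levels), sum(x$counts), accuracy(x)))
  print(x$counts)
  invisible(x)
}

#' Accuracy and word error rate of a confusion matrix
#'
#' `accuracy()` is the trial-level fraction correct; `wer()` is the word
#' error rate of this isolated-word task, defined as `1 - accuracy` (not an
#' edit-distance rate).
#'
#' @param x A [confusion_matrix()].
#' @return Scalar in [0, 1].
#' @export
accuracy <- function(x) {
  stopifnot(inherits(x, "confusion_eeg"))
  sum(diag(x$counts)) / sum(x$counts)
}

#' @rdname accuracy
#' @export
wer <- function(x) 1 - accuracy(x)

#' Per-class metrics of a confusion matrix
#'
#' @param x A [confusion_matrix()].
#' @param ... Unused.
#' @return `tidy()`: tibble with one row per class — `class`, `n` (true
#'   count), `precision`, `recall`, `f1`. Classes with no true and no
#'   predicted trials get `NA` (undefined, 0/0) and are excluded from the
#'   macro averages in `glance()`. `glance()`: one-row tibble with
#'   `accuracy`, `wer`, macro-averaged metrics and `n_trials`.
#' @export
tidy.confusion_eeg <- function(x, ...) {
  cm <- x$counts
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  tibble(class = x$levels, n = as.integer(rowSums(cm)),
         precision = as.numeric(precision), recall = as.numeric(recall),
         f1 = as.numeric(f1))
}

#' @rdname tidy.confusion_eeg
#' @export
glance.confusion_eeg <- function(x, ...) {
  per <- tidy(x)
  tibble(accuracy = accuracy(x), wer = wer(x),
         macro_precision = mean(per$precision, na.rm = TRUE),
         macro_recall = mean(per$recall, na.rm = TRUE),
         macro_f1 = mean(per$f1, na.rm = TRUE),
         n_trials = sum(x$counts))
}

#' Across-subject summary of per-subject accuracies
#'
#' The study's headline numbers are reported as mean +/- dispersion across
#' subjects; the dispersion here is the sample standard deviation (switchable
#' to the standard error).
#'
#' @param accuracies Numeric vector of per-subject accuracies, or a tibble
#'   with an `accuracy` column.
#' @param dispersion `"sd"` (default) or `"sem"`.
#' @return One-row tibble with `mean_accuracy`, `dispersion`, `n_subjects`.
#'   With a single subject the dispersion is `NA`.
#' @export
subject_summary <- function(accuracies, dispersion = c("sd", "sem")) {
  dispersion <- match.arg(dispersion)
  if (is.data.frame(accuracies)) accuracies <- accuracies$accuracy
  n <- length(accuracies)
  disp <- if (n < 2) NA_real_ else {
    s <- sd(accuracies)
    if (dispersion == "sem") s / sqrt(n) else s
  }
  tibble(mean_accuracy = mean(accuracies), dispersion = disp, n_subjects = n)
}

#' Decoder factories for the evaluation protocols
#'
#' A decoder factory packages a fit function so the evaluation protocols can
#' train and score either model family interchangeably. `decoder_csp_svm()`
#' wraps [fit_csp_svm()]; `decoder_dual_lstm()` wraps [fit_dual_lstm()].
#' All constructor arguments are forwarded.
#'
#' @param ... Arguments forwarded to the underlying fit function.
#' @return An object of class `eeg_decoder` with elements `label` and
#'   `fit(train)`; the fitted model is scored with [predict()].
#' @export
decoder_csp_svm <- function(...) {
  args <- list(...)
  structure(list(label = "csp_svm",
                 fit = function(train) do.call(fit_csp_svm, c(list(train), args))),
            class = "eeg_decoder")
}

#' @rdname decoder_csp_svm
#' @export
decoder_dual_lstm <- function(...) {
  args <- list(...)
  structure(list(label = "dual_lstm",
                 fit = function(train) do.call(fit_dual_lstm, c(list(train), args))),
            class = "eeg_decoder")
}

# fit on train, return accuracy on test
decoder_accuracy <- function(decoder, train, test) {
  model <- decoder$fit(train)
  pred <- predict(model, test)
  cm <- confusion_matrix(test$class, pred$.pred_class)
  accuracy(cm)
}

# subject-specific protocol: per-subject split, fit and score
subject_wise_accuracy <- function(ts, decoder, train_proportion, seed) {
  subjects <- sort(unique(ts$subject))
  purrr::map_dfr(subjects, function(s) {
    ts_s <- restore_ts(ts[ts$subject == s, ], ts)
    sp <- split_trials(ts_s, train_proportion, seed = seed + s)
    tibble(subject = s,
           accuracy = decoder_accuracy(decoder, sp$train, sp$test),
           n_train = nrow(sp$train), n_test = nrow(sp$test))
  })
}

#' Compare decoders under the subject-specific protocol
#'
#' Trains and tests every decoder within each subject's own trials (no
#' cross-subject pooling) at a fixed training proportion, and reports the
#' per-subject accuracies plus the across-subject mean +/- sd per method.
#'
#' @param ts A [trial_set()].
#' @param decoders Named list of [decoder_csp_svm()] / [decoder_dual_lstm()]
#'   factories.
#' @param train_proportion Training fraction per subject (default 0.38, the
#'   study's data-efficiency operating point).
#' @param seed Integer seed.
#' @return Tibble with one row per (method, subject) and columns `method`,
#'   `subject`, `accuracy`, `n_train`, `n_test`; the across-subject summary
#'   is in `attr(, "summary")`.
#' @export
compare_decoders <- function(ts, decoders, train_proportion = 0.38,
                             seed = 1L) {
  res <- purrr::imap(decoders, function(dec, name) {
    subject_wise_accuracy(ts, dec, train_proportion, seed) |>
      mutate(method = name, .before = 1)
  }) |> dplyr::bind_rows()
  summ <- res |> group_by(.data$method) |>
    summarise(mean_accuracy = mean(.data$accuracy),
              sd_accuracy = if (dplyr::n() > 1) sd(.data$accuracy) else NA_real_,
              n_subjects = dplyr::n(), .groups = "drop")
  attr(res, "summary") <- summ
  res
}

#' Accuracy versus number of training repetitions
#'
#' For each grid value `r`, trains on the chronologically first `r`
#' repetitions of each verb within each subject (mirroring an incrementally
#' collected calibration set) and tests on that subject's remaining trials.
#'
#' @param ts A [trial_set()] with `block` and `presentation` columns.
#' @param decoder An [decoder_csp_svm()] / [decoder_dual_lstm()] factory.
#' @param reps Integer grid of repetitions per class; values leaving no test
#'   trials are skipped with a warning.
#' @param seed Integer seed (forwarded to stochastic decoders).
#' @return Tibble (class `decode_curve`) with columns `reps`,
#'   `mean_accuracy`, `sd_accuracy`, `n_subjects`; the Spearman rank
#'   correlation between `reps` and `mean_accuracy` is in
#'   `attr(, "spearman")`.
#' @export
repetitions_curve <- function(ts, decoder, reps = c(2, 5, 10, 15), seed = 1L) {
  per_class <- min(table(ts$subject, ts$class))
  usable <- reps[reps >= 1 & reps < per_class]
  if (length(usable) < length(reps)) {
    warn(sprintf("skipping repetition counts outside [1, %d)", per_class))
  }
  ord <- order(ts$subject, ts$block, ts$presentation)
  ts_ord <- restore_ts(ts[ord, ], ts)
  rows <- purrr::map_dfr(usable, function(r) {
    accs <- purrr::map_dbl(sort(unique(ts_ord$subject)), function(s) {
      ts_s <- restore_ts(ts_ord[ts_ord$subject == s, ], ts_ord)
      take <- unlist(lapply(split(seq_len(nrow(ts_s)), ts_s$class),
                            function(ix) head(ix, r)))
      train <- restore_ts(ts_s[sort(take), ], ts_s)
      test <- restore_ts(ts_s[-sort(take), ], ts_s)
      decoder_accuracy(decoder, train, test)
    })
    tibble(reps = r, mean_accuracy = mean(accs),
           sd_accuracy = if (length(accs) > 1) sd(accs) else NA_real_,
           n_subjects = length(accs))
  })
  rho <- if (nrow(rows) > 1) {
    stats::cor(rows$reps, rows$mean_accuracy, method = "spearman")
  } else NA_real_
  structure(rows, spearman = rho, kind = "repetitions",
            class = c("decode_curve", class(rows)))
}

#' Accuracy versus training-data proportion
#'
#' Sweeps the stratified training fraction via [split_trials()] under the
#' subject-specific protocol, recording mean accuracy and wall-clock training
#' time (informational only) per grid point.
#'
#' @param ts A [trial_set()].
#' @param decoder A decoder factory.
#' @param proportions Numeric grid in (0, 1).
#' @param seed Integer seed.
#' @return Tibble (class `decode_curve`) with `proportion`, `mean_accuracy`,
#'   `sd_accuracy`, `n_subjects`, `n_train`, `elapsed_s`.
#' @export
proportion_curve <- function(ts, decoder, proportions = c(0.2, 0.38, 0.6),
                             seed = 1L) {
  rows <- purrr::map_dfr(proportions, function(p) {
    t0 <- proc.time()[["elapsed"]]
    accs <- subject_wise_accuracy(ts, decoder, p, seed)
    tibble(proportion = p, mean_accuracy = mean(accs$accuracy),
           sd_accuracy = if (nrow(accs) > 1) sd(accs$accuracy) else NA_real_,
           n_subjects = nrow(accs), n_train = sum(accs$n_train),
           elapsed_s = proc.time()[["elapsed"]] - t0)
  })
  structure(rows, kind = "proportion", class = c("decode_curve", class(rows)))
}

#' Word error rate versus learning rate
#'
#' Trains one dual-LSTM per learning rate under identical data, seed and
#' configuration and reports the word error rate (`1 - accuracy`). Gradient
#' clipping is disabled by default (pass `clip_norm` to restore it) so the
#' sweep reflects the raw dynamics of each rate; a diverged run (non-finite
#' loss) is recorded as WER 1 with `diverged = TRUE` rather than failing
#' the sweep.
#'
#' @param ts A [trial_set()].
#' @param learning_rates Positive learning-rate grid.
#' @param train_proportion Training fraction per subject.
#' @param seed Integer seed.
#' @param ... Further arguments to [fit_dual_lstm()] (e.g. `epochs`).
#' @return Tibble (class `decode_curve`) with `learning_rate`, `wer`,
#'   `mean_accuracy`, `diverged`.
#' @export
lr_curve <- function(ts, learning_rates = c(0.0005, 0.005, 0.05),
                     train_proportion = 0.5, seed = 1L, ...) {
  if (any(learning_rates <= 0)) abort("learning rates must be positive")
  extra <- list(...)
  # the sweep studies raw gradient-descent dynamics: the clip that guards
  # routine training would mask the instability being measured, so it is off
  # unless explicitly requested
  if (!"clip_norm" %in% names(extra)) extra$clip_norm <- Inf
  rows <- purrr::map_dfr(learning_rates, function(lr) {
    dec <- do.call(decoder_dual_lstm,
                   c(list(learning_rate = lr, seed = seed), extra))
    res <- tryCatch({
      accs <- subject_wise_accuracy(ts, dec, train_proportion, seed)
      tibble(learning_rate = lr, wer = 1 - mean(accs$accuracy),
             mean_accuracy = mean(accs$accuracy), diverged = FALSE)
    }, eegverbs_divergence = function(e) {
      tibble(learning_rate = lr, wer = 1, mean_accuracy = 0, diverged = TRUE)
    })
    res
  })
  structure(rows, kind = "learning_rate",
            class = c("decode_curve", class(rows)))
}
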