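#' The six Mandarin action verbs used as class labels
#'
#' Pinyin labels for the six high-frequency action verbs: Chi (eat), He
#' (drink), Chuan (wear), Na (take), Kan (look), Dai (put on).
#'
#' @return Character vector of length 6.
#' @export
verb_labels <- function() {
  c("Chi", "He", "Chuan", "Na", "Kan", "Dai")
}

#' Canonical eight-channel language-area montage
#'
#' The eight 10/20-system electrodes over Broca's area (F5, FT7, FC5, FC3)
#' and Wernicke's area (TP7, CP5, CP3, P5), in canonical order.
#'
#' @return Character vector of length 8.
#' @export
default_montage <- function() {
  c("F5", "FT7", "FC5", "FC3", "TP7", "CP5", "CP3", "P5")
}

#' Describe the experimental design
#'
#' Encodes the block-structured within-subject design of the verb-reading
#' study: each subject sees each of the `n_classes` verbs `reps_per_block`
#' times per block, in randomized order, over `blocks` blocks, giving
#' `trials_per_class` trials per verb per subject. Each trial is an
#' idle / cue / task / rest sequence; only the task window is decoded.
#'
#' @param n_subjects Number of participants (default 30).
#' @param n_classes Number of verb classes (default 6).
#' @param trials_per_class Trials per class per subject (default 75).
#' @param blocks Experimental blocks per subject (default 5).
#' @param reps_per_block Presentations of each verb per block (default 15).
#' @param n_channels EEG channels recorded (default 8).
#' @param sample_rate Sampling rate in Hz (default 250).
#' @param idle_s,cue_s,task_s,rest_s Durations in seconds of the idle screen,
#'   preparation cue, task (reading-aloud) window and rest screen
#'   (defaults 2, 1, 4, 2).
#'
#' @return An object of class `experiment_design` (a named list).
#' @examples
#' design <- experiment_design()
#' design$n_subjects * design$n_classes * design$trials_per_class # 13500
#' @export
experiment_design <- function(n_subjects = 30, n_classes = 6,
                              trials_per_class = 75, blocks = 5,
                              reps_per_block = 15, n_channels = 8,
                              sample_rate = 250,
                              idle_s = 2, cue_s = 1, task_s = 4, rest_s = 2) {
  counts <- c(n_subjects = n_subjects, n_classes = n_classes,
              trials_per_class = trials_per_class, blocks = blocks,
              reps_per_block = reps_per_block, n_channels = n_channels)
  if (any(counts < 1) || any(counts != round(counts))) {
    abort("all design counts must be integers >= 1")
  }
  if (blocks * reps_per_block != trials_per_class) {
    abort(sprintf(
      "blocks (%d) x reps_per_block (%d) must equal trials_per_class (%d)",
      blocks, reps_per_block, trials_per_class))
  }
  if (sample_rate <= 0) abort("sample_rate must be positive")
  n_task <- task_s * sample_rate
  if (abs(n_task - round(n_task)) > 1e-9) {
    abort("task_s x sample_rate must be an integer number of samples")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_classes = as.integer(n_classes),
    trials_per_class = as.integer(trials_per_class),
    blocks = as.integer(blocks), reps_per_block = as.integer(reps_per_block),
    n_channels = as.integer(n_channels), sample_rate = sample_rate,
    idle_s = idle_s, cue_s = cue_s, task_s = task_s, rest_s = rest_s
  ), class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "<experiment_design> %d subjects x %d classes x %d trials (%d blocks x %d reps)\n",
    x$n_subjects, x$n_classes, x$trials_per_class, x$blocks, x$reps_per_block))
  cat(sprintf("  %d channels @ %g Hz; idle/cue/task/rest = %g/%g/%g/%g s\n",
              x$n_channels, x$sample_rate, x$idle_s, x$cue_s, x$task_s, x$rest_s))
  invisible(x)
}

#' Number of task-window samples per channel
#' @param design An [experiment_design()].
#' @return Integer sample count (1000 at the defaults: 4 s x 250 Hz).
#' @export
task_samples <- function(design) {
  as.integer(round(design$task_s * design$sample_rate))
}

#' Expand a design into its randomized trial table
#'
#' Produces one row per trial with subject, block, within-block presentation
#' index and class label. Class order is shuffled independently within each
#' block (each verb appearing exactly `reps_per_block` times per block),
#' mirroring the randomized presentation schedule of the study.
#'
#' @param design An [experiment_design()].
#' @param seed Integer seed; the table is a pure function of (design, seed).
#' @return A tibble with columns `subject`, `block`, `presentation`, `class`
#'   (factor with verb labels when `n_classes == 6`) and `trial_id`.
#' @examples
#' nrow(design_trials(experiment_design(), seed = 1)) # 13500
#' @export
design_trials <- function(design, seed = 1L) {
  stopifnot(inherits(design, "experiment_design"))
  labels <- class_label_set(design$n_classes)
  tab <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(design$n_subjects), function(s) {
      purrr::map_dfr(seq_len(design$blocks), function(b) {
        cls <- sample(rep(seq_len(design$n_classes), design$reps_per_block))
        tibble(subject = s, block = b,
               presentation = seq_along(cls), class_idx = cls)
      })
    })
  })
  tab$class <- factor(labels[tab$class_idx], levels = labels)
  tab$trial_id <- seq_len(nrow(tab))
  tab[, c("trial_id", "subject", "block", "presentation", "class")]
}

class_label_set <- function(n_classes) {
  if (n_classes == 6L) verb_labels() else paste0("class", seq_len(n_classes))
}
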