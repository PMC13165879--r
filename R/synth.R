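#' Class signature for the synthetic generator
#'
#' A class signature couples a forward-model scalp topography (a unit vector
#' over channels) with a nonnegative temporal amplitude envelope over the task
#' window and a signal-to-background ratio in dB. The generated class signal
#' for one trial is the outer product
#' `spatial_pattern %o% (temporal_envelope * carrier)`, with a band-limited
#' (8-30 Hz) unit-variance noise carrier, scaled so the total signal power is
#' `10^(snr_db/10)` times the total background power.
#'
#' @param spatial_pattern Numeric vector over channels; normalized to unit
#'   Euclidean norm.
#' @param temporal_envelope Nonnegative numeric vector, one value per task
#'   sample.
#' @param snr_db Signal-to-background power ratio in decibels; `-Inf` means
#'   no class signal.
#' @return An object of class `class_signature`.
#' @export
class_signature <- function(spatial_pattern, temporal_envelope, snr_db = 0) {
  nrm <- sqrt(sum(spatial_pattern^2))
  if (nrm == 0) abort("spatial_pattern must be non-zero")
  if (any(temporal_envelope < 0)) abort("temporal_envelope must be nonnegative")
  structure(list(spatial_pattern = spatial_pattern / nrm,
                 temporal_envelope = temporal_envelope,
                 snr_db = snr_db),
            class = "class_signature")
}

#' Background and artifact noise model
#'
#' Describes the non-neural content of the synthetic recordings: a `1/f^a`
#' background spectrum, power-line interference, frontal-weighted
#' low-frequency (< 4 Hz) ocular transients, and high-frequency (> 30 Hz)
#' myogenic bursts. The ocular and myogenic generators emulate the artifact
#' classes targeted for removal by the preprocessing front end.
#'
#' @param one_over_f_exponent Spectral slope `a` of the background (>= 0;
#'   default 1, the classic pink-noise slope of resting EEG).
#' @param line_freq Power-line frequency in Hz, 50 or 60.
#' @param line_amp_uv Peak amplitude of the line component in microvolts.
#' @param eog_rate Ocular transients per minute.
#' @param eog_amp_uv Typical peak amplitude of an ocular transient (microvolts).
#' @param emg_band Frequency interval (Hz) of the myogenic bursts.
#' @param emg_rate Myogenic bursts per minute per channel.
#' @param emg_amp_uv Root-mean-square amplitude of a myogenic burst.
#' @param background_sd_uv Per-channel standard deviation of the background
#'   (microvolts).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(one_over_f_exponent = 1, line_freq = 50,
                        line_amp_uv = 1, eog_rate = 4, eog_amp_uv = 60,
                        emg_band = c(30, 100), emg_rate = 2, emg_amp_uv = 8,
                        background_sd_uv = 10) {
  if (one_over_f_exponent < 0) abort("one_over_f_exponent must be >= 0")
  if (!line_freq %in% c(50, 60)) abort("line_freq must be 50 or 60 Hz")
  structure(list(one_over_f_exponent = one_over_f_exponent,
                 line_freq = line_freq, line_amp_uv = line_amp_uv,
                 eog_rate = eog_rate, eog_amp_uv = eog_amp_uv,
                 emg_band = emg_band, emg_rate = emg_rate,
                 emg_amp_uv = emg_amp_uv,
                 background_sd_uv = background_sd_uv),
            class = "noise_model")
}

#' Coloured 1/f^a background noise
#'
#' Unit-variance noise with power spectral density proportional to
#' `f^-exponent`, generated by spectral shaping of white Gaussian noise.
#'
#' @param n Number of samples.
#' @param exponent Spectral slope (0 gives white noise).
#' @return Numeric vector of length `n` with (sample) standard deviation 1.
#' @export
one_over_f_noise <- function(n, exponent = 1) {
  if (n < 2) return(rnorm(n))
  x <- rnorm(n)
  if (exponent == 0) return((x - mean(x)) / sd(x))
  X <- fft(x)
  # rfft-style frequency index; DC removed, amplitude ~ f^(-a/2)
  k <- c(1, seq_len(n - 1))
  k <- pmin(k, n - (k - 1) + 1)  # mirrored index for negative frequencies
  k[1] <- Inf
  X <- X * k^(-exponent / 2)
  y <- Re(fft(X, inverse = TRUE)) / n
  (y - mean(y)) / sd(y)
}

# unit-variance band-limited Gaussian noise via FFT masking
band_noise <- function(n, low, high, sample_rate) {
  x <- rnorm(n)
  X <- fft(x)
  f <- seq(0, sample_rate, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, sample_rate - f)  # two-sided frequency axis
  X[f < low | f > high] <- 0
  y <- Re(fft(X, inverse = TRUE)) / n
  s <- sd(y)
  if (s == 0) y else (y - mean(y)) / s
}

# one trial's worth of background + artifacts (channels x n, microvolts)
synth_background <- function(n_channels, n, sample_rate, noise) {
  bg <- t(vapply(seq_len(n_channels),
                 function(i) one_over_f_noise(n, noise$one_over_f_exponent),
                 numeric(n))) * noise$background_sd_uv
  tt <- seq_len(n) / sample_rate
  # power-line interference, common phase across the montage
  phase <- runif(1, 0, 2 * pi)
  line <- noise$line_amp_uv * sin(2 * pi * noise$line_freq * tt + phase)
  bg <- bg + matrix(line, n_channels, n, byrow = TRUE)
  dur_min <- n / sample_rate / 60
  # ocular transients: slow half-sine pulses, strongest frontally
  frontal <- exp(-0.6 * (seq_len(n_channels) - 1))
  n_eog <- stats::rpois(1, noise$eog_rate * dur_min)
  for (k in seq_len(n_eog)) {
    width <- round(runif(1, 0.3, 0.8) * sample_rate)  # < 4 Hz content
    onset <- sample.int(max(1, n - width), 1)
    pulse <- noise$eog_amp_uv * runif(1, 0.6, 1.2) * sin(pi * seq_len(width) / width)
    idx <- onset:(onset + width - 1)
    bg[, idx] <- bg[, idx] + outer(frontal, pulse)
  }
  # myogenic bursts: short high-frequency packets on single channels
  n_emg <- stats::rpois(1, noise$emg_rate * n_channels * dur_min)
  for (k in seq_len(n_emg)) {
    width <- round(runif(1, 0.1, 0.3) * sample_rate)
    if (width >= n) next
    ch <- sample.int(n_channels, 1)
    onset <- sample.int(n - width, 1)
    burst <- band_noise(width, noise$emg_band[1],
                        min(noise$emg_band[2], sample_rate / 2 * 0.99),
                        sample_rate) * noise$emg_amp_uv
    burst <- burst * sin(pi * seq_len(width) / width)  # taper
    bg[ch, onset:(onset + width - 1)] <- bg[ch, onset:(onset + width - 1)] + burst
  }
  bg
}

# class signal for one trial, scaled to the signature's snr against bg
synth_class_signal <- function(sig, n, sample_rate, bg) {
  if (!is.finite(sig$snr_db)) return(matrix(0, length(sig$spatial_pattern), n))
  carrier <- band_noise(n, 8, 30, sample_rate)  # alpha/beta band carrier
  src <- sig$temporal_envelope * carrier
  p_src <- sum(src^2)
  if (p_src == 0) return(matrix(0, length(sig$spatial_pattern), n))
  amp <- sqrt(10^(sig$snr_db / 10) * sum(bg^2) / p_src)
  outer(sig$spatial_pattern, amp * src)
}

#' Simulate a synthetic EEG trial set
#'
#' Generates the full study design — `n_subjects` x `n_classes` x
#' `trials_per_class` labelled task-window epochs — under the signal model
#' `trial = background(1/f) + artifacts + snr-scaled spatial_pattern %o%
#' (envelope * band-limited carrier)`. Class order is randomized within each
#' block. The output is a pure function of `(design, signatures, noise, seed)`.
#'
#' @param design An [experiment_design()].
#' @param signatures List of one [class_signature()] per class.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @return A [trial_set()] with `design$n_subjects * design$n_classes *
#'   design$trials_per_class` rows.
#' @examples
#' d <- experiment_design(n_subjects = 1, trials_per_class = 3,
#'                        blocks = 1, reps_per_block = 3)
#' sig <- spatial_signatures(d, separation = 2, snr_db = 0, seed = 1)
#' ts <- simulate_trials(d, sig, seed = 1)
#' nrow(ts) # 18
#' @export
simulate_trials <- function(design, signatures, noise = noise_model(),
                            seed = 1L) {
  stopifnot(inherits(design, "experiment_design"))
  if (length(signatures) != design$n_classes) {
    abort(sprintf("need %d signatures, got %d",
                  design$n_classes, length(signatures)))
  }
  n <- task_samples(design)
  for (sig in signatures) {
    if (length(sig$spatial_pattern) != design$n_channels) {
      abort("signature spatial_pattern length must equal design$n_channels")
    }
    if (length(sig$temporal_envelope) != n) {
      abort("signature temporal_envelope length must equal task_s * sample_rate")
    }
  }
  meta <- design_trials(design, seed = seed)
  montage <- if (design$n_channels == 8) default_montage() else
    paste0("ch", seq_len(design$n_channels))
  data <- withr::with_seed(seed + 1L, {
    lapply(seq_len(nrow(meta)), function(i) {
      cls <- as.integer(meta$class[i])
      bg <- synth_background(design$n_channels, n, design$sample_rate, noise)
      bg + synth_class_signal(signatures[[cls]], n, design$sample_rate, bg)
    })
  })
  trial_set(meta, data, montage, design$sample_rate)
}

#' Signature scenarios: spatial, temporal, and mixed class structure
#'
#' Three canonical generator scenarios used to probe the two decoder families:
#'
#' * `spatial_signatures()` gives every class the same flat envelope but a
#'   distinct scalp topography. Pairwise angles between topographies grow with
#'   `separation` (all classes identical at 0, near-orthogonal for large
#'   values), so spatial-covariance decoders (CSP) can separate the classes.
#' * `temporal_signatures()` gives every class the same topography and the
#'   same expected channel covariance, but a class-unique ordering of the same
#'   amplitude segments in time (class 2's envelope is class 1's reversed).
#'   Only decoders sensitive to temporal ordering can separate the classes.
#' * `mixed_signatures()` combines both: distinct topographies and distinct
#'   segment orderings.
#'
#' @param design An [experiment_design()].
#' @param separation Nonnegative spatial separation; the topographies are
#'   `normalize((1-t) u0 + t v_k)` with `t = 1 - exp(-separation)` and
#'   `v_k` mutually orthonormal directions orthogonal to the shared `u0`.
#' @param snr_db Per-class signal-to-background ratio in dB.
#' @param seed Integer seed.
#' @param n_segments Number of equal-length envelope segments whose ordering
#'   carries the class identity (temporal/mixed scenarios; default 5, i.e.
#'   800 ms segments of a 4 s window).
#' @return List of `design$n_classes` [class_signature()] objects.
#' @export
spatial_signatures <- function(design, separation = 2, snr_db = 0, seed = 1L) {
  n <- task_samples(design)
  pats <- scenario_patterns(design$n_classes, design$n_channels,
                            separation, seed)
  lapply(seq_len(design$n_classes), function(k) {
    class_signature(pats[, k], rep(1, n), snr_db)
  })
}

#' @rdname spatial_signatures
#' @export
temporal_signatures <- function(design, snr_db = 0, seed = 1L,
                                n_segments = 5) {
  n <- task_samples(design)
  u0 <- scenario_patterns(design$n_classes, design$n_channels, 0, seed)[, 1]
  envs <- scenario_envelopes(design$n_classes, n, n_segments, seed)
  lapply(seq_len(design$n_classes), function(k) {
    class_signature(u0, envs[[k]], snr_db)
  })
}

#' @rdname spatial_signatures
#' @export
mixed_signatures <- function(design, separation = 2, snr_db = 0, seed = 1L,
                             n_segments = 5) {
  n <- task_samples(design)
  pats <- scenario_patterns(design$n_classes, design$n_channels,
                            separation, seed)
  envs <- scenario_envelopes(design$n_classes, n, n_segments, seed)
  lapply(seq_len(design$n_classes), function(k) {
    class_signature(pats[, k], envs[[k]], snr_db)
  })
}

# channels x classes matrix of unit topographies with controlled separation
scenario_patterns <- function(n_classes, n_channels, separation, seed) {
  if (n_classes + 1 > n_channels) {
    abort("scenario needs n_channels >= n_classes + 1 for orthogonal directions")
  }
  Q <- withr::with_seed(seed, {
    qr.Q(qr(matrix(rnorm(n_channels * (n_classes + 1)),
                   n_channels, n_classes + 1)))
  })
  u0 <- Q[, 1]
  t <- 1 - exp(-separation)
  vapply(seq_len(n_classes), function(k) {
    v <- (1 - t) * u0 + t * Q[, k + 1]
    v / sqrt(sum(v^2))
  }, numeric(n_channels))
}

# class-unique permutations of a shared amplitude-segment multiset;
# class 2 is the exact time-reversal of class 1
scenario_envelopes <- function(n_classes, n, n_segments, seed) {
  amps <- seq(0.25, 1.75, length.out = n_segments)
  perms <- withr::with_seed(seed, {
    p <- list(sample(n_segments))
    p[[2]] <- rev(p[[1]])
    while (length(p) < n_classes) {
      cand <- sample(n_segments)
      if (!any(vapply(p, identical, logical(1), cand))) p <- c(p, list(cand))
    }
    p
  })
  seg_len <- n / n_segments
  if (abs(seg_len - round(seg_len)) > 1e-9) {
    abort("task window length must be divisible by n_segments")
  }
  lapply(seq_len(n_classes), function(k) {
    rep(amps[perms[[k]]], each = round(seg_len))
  })
}

#' Simulate a continuous raw recording for one subject
#'
#' Renders the full idle / cue / task / rest sequence of every trial into one
#' continuous multichannel recording with an event table, for exercising the
#' epoching front end. Class signal is present only during task windows.
#'
#' @inheritParams simulate_trials
#' @param subject Subject index used for the block randomization.
#' @return A [raw_recording()] with events of kind `idle`, `cue`, `stimulus`
#'   and `rest` (one of each per trial).
#' @export
simulate_recording <- function(design, signatures, noise = noise_model(),
                               seed = 1L, subject = 1L) {
  stopifnot(inherits(design, "experiment_design"))
  sr <- design$sample_rate
  n_task <- task_samples(design)
  seg <- function(s) as.integer(round(s * sr))
  trial_len <- seg(design$idle_s) + seg(design$cue_s) + n_task + seg(design$rest_s)
  meta <- design_trials(design, seed = seed)
  meta <- meta[meta$subject == subject, ]
  n_trials <- nrow(meta)
  total <- trial_len * n_trials
  montage <- if (design$n_channels == 8) default_montage() else
    paste0("ch", seq_len(design$n_channels))
  samples <- matrix(0, design$n_channels, total)
  events <- vector("list", n_trials)
  withr::with_seed(seed + 1000L + subject, {
    for (i in seq_len(n_trials)) {
      off <- (i - 1) * trial_len
      bg <- synth_background(design$n_channels, trial_len, sr, noise)
      task_start <- off + seg(design$idle_s) + seg(design$cue_s)
      task_idx <- (seg(design$idle_s) + seg(design$cue_s) + 1):
        (seg(design$idle_s) + seg(design$cue_s) + n_task)
      cls <- as.integer(meta$class[i])
      bg[, task_idx] <- bg[, task_idx] +
        synth_class_signal(signatures[[cls]], n_task, sr, bg[, task_idx])
      samples[, (off + 1):(off + trial_len)] <- bg
      events[[i]] <- tibble(
        onset = off + c(0, seg(design$idle_s),
                        seg(design$idle_s) + seg(design$cue_s),
                        seg(design$idle_s) + seg(design$cue_s) + n_task),
        class = as.character(meta$class[i]),
        kind = c("idle", "cue", "stimulus", "rest"))
    }
  })
  raw_recording(samples, montage, sr, dplyr::bind_rows(events))
}
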