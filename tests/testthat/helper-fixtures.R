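# small designs and datasets shared across test files

tiny_design <- function(n_subjects = 1, trials_per_class = 6, blocks = 2,
                        reps_per_block = 3, ...) {
  experiment_design(n_subjects = n_subjects,
                    trials_per_class = trials_per_class,
                    blocks = blocks, reps_per_block = reps_per_block, ...)
}

# small spatial-scenario dataset: strong topographic class structure
tiny_spatial_ts <- function(n_subjects = 1, trials_per_class = 12,
                            snr_db = 0, seed = 11) {
  d <- tiny_design(n_subjects, trials_per_class, blocks = 2,
                   reps_per_block = trials_per_class / 2)
  sig <- spatial_signatures(d, separation = 4, snr_db = snr_db, seed = seed)
  eeg_bandpass(simulate_trials(d, sig, seed = seed + 1))
}

# small temporal-scenario dataset: identical covariance, ordered envelopes
tiny_temporal_ts <- function(n_subjects = 1, trials_per_class = 12,
                             snr_db = 0, seed = 21) {
  d <- tiny_design(n_subjects, trials_per_class, blocks = 2,
                   reps_per_block = trials_per_class / 2)
  sig <- temporal_signatures(d, snr_db = snr_db, seed = seed)
  eeg_bandpass(simulate_trials(d, sig, seed = seed + 1))
}

# random trial set with no class structure at all
noise_ts <- function(n_trials = 12, n_channels = 8, n_samples = 200,
                     n_classes = 2, seed = 5) {
  withr::with_seed(seed, {
    labels <- factor(rep(paste0("class", seq_len(n_classes)),
                         length.out = n_trials))
    data <- lapply(seq_len(n_trials), function(i) {
      matrix(rnorm(n_channels * n_samples), n_channels, n_samples)
    })
    trial_set(tibble::tibble(subject = 1L, class = labels), data,
              paste0("ch", seq_len(n_channels)), 250)
  })
}

expect_identical_trials <- function(a, b) {
  expect_identical(a$class, b$class)
  expect_identical(a$data, b$data)
}
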