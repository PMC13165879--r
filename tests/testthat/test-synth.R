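test_that("simulated datasets conserve the design trial counts", {
  d <- tiny_design(n_subjects = 2)
  sig <- spatial_signatures(d, separation = 1, snr_db = 0, seed = 1)
  ts <- simulate_trials(d, sig, seed = 4)
  expect_equal(nrow(ts), 2 * 6 * 6)
  expect_true(all(table(ts$subject) == 36))
  expect_true(all(table(ts$class) == 12))
  expect_equal(dim(ts$data[[1]]), c(8, 1000))
  expect_equal(ts_montage(ts), default_montage())
})

test_that("generation is a pure function of the seed", {
  d <- tiny_design()
  sig <- spatial_signatures(d, separation = 1, snr_db = 0, seed = 1)
  a <- simulate_trials(d, sig, seed = 42)
  b <- simulate_trials(d, sig, seed = 42)
  expect_identical_trials(a, b)
  c <- simulate_trials(d, sig, seed = 43)
  expect_false(identical(a$data[[1]], c$data[[1]]))
})

test_that("signature/design dimension mismatches are rejected", {
  d <- tiny_design()
  sig <- spatial_signatures(d, seed = 1)
  expect_error(simulate_trials(d, sig[1:3], seed = 1), "signatures")
  bad <- sig
  bad[[1]] <- class_signature(rep(1, 5), rep(1, 1000), 0)
  expect_error(simulate_trials(d, bad, seed = 1), "n_channels")
  bad2 <- sig
  bad2[[2]] <- class_signature(rep(1, 8), rep(1, 999), 0)
  expect_error(simulate_trials(d, bad2, seed = 1), "envelope")
})

test_that("snr of -Inf leaves class-conditional means indistinguishable", {
  d <- tiny_design(trials_per_class = 10, blocks = 2, reps_per_block = 5)
  sig <- lapply(spatial_signatures(d, separation = 4, seed = 1),
                function(s) class_signature(s$spatial_pattern,
                                            s$temporal_envelope, -Inf))
  ts <- simulate_trials(d, sig, seed = 6)
  expect_gt(perm_test_class_means(ts, n_perm = 300), 0.01)
})

test_that("1/f background has a decreasing smoothed periodogram", {
  x <- withr::with_seed(3, one_over_f_noise(4096, exponent = 1.5))
  sp <- spec.pgram(stats::ts(x, frequency = 250), spans = 31, plot = FALSE,
                   taper = 0)
  bins <- split(sp$spec, cut(seq_along(sp$spec), 8))
  med <- vapply(bins, stats::median, numeric(1))
  expect_true(all(diff(med) < 0))
  # white case is flat by comparison
  w <- withr::with_seed(3, one_over_f_noise(4096, exponent = 0))
  spw <- spec.pgram(stats::ts(w, frequency = 250), spans = 31, plot = FALSE,
                    taper = 0)
  expect_lt(max(spw$spec) / min(spw$spec), 10)
})

test_that("spatial scenario separation controls pairwise pattern angles", {
  d <- tiny_design()
  # separation 0: all six patterns identical
  s0 <- spatial_signatures(d, separation = 0, seed = 2)
  pats0 <- vapply(s0, function(s) s$spatial_pattern, numeric(8))
  expect_true(all(abs(pats0 - pats0[, 1]) < 1e-12))
  # large separation: near-orthogonal (off-diagonal Gram < 0.3)
  s5 <- spatial_signatures(d, separation = 5, seed = 2)
  pats5 <- vapply(s5, function(s) s$spatial_pattern, numeric(8))
  gram <- crossprod(pats5)
  expect_lt(max(abs(gram[upper.tri(gram)])), 0.3)
  # all unit norm
  expect_equal(colSums(pats5^2), rep(1, 6), tolerance = 1e-12)
  # mean pairwise angle grows monotonically with separation
  angles <- vapply(c(0.25, 0.5, 1, 2, 4), function(sep) {
    p <- vapply(spatial_signatures(d, separation = sep, seed = 2),
                function(s) s$spatial_pattern, numeric(8))
    g <- crossprod(p)
    mean(acos(pmin(1, abs(g[upper.tri(g)]))))
  }, numeric(1))
  expect_true(all(diff(angles) > 0))
})

test_that("temporal scenario has matched covariance but ordered envelopes", {
  d <- tiny_design()
  sig <- temporal_signatures(d, snr_db = 0, seed = 3)
  pats <- vapply(sig, function(s) s$spatial_pattern, numeric(8))
  expect_true(all(abs(pats - pats[, 1]) < 1e-12))
  envs <- vapply(sig, function(s) s$temporal_envelope, numeric(1000))
  # same amplitude multiset, class-unique orderings
  for (k in 2:6) {
    expect_equal(sort(envs[, k]), sort(envs[, 1]))
    expect_false(identical(envs[, k], envs[, 1]))
  }
  # class 2 is the exact time reversal of class 1
  expect_equal(envs[, 2], rev(envs[, 1]))
  # expected class covariances agree: envelope power is permutation-invariant
  expect_equal(sum(envs[, 1]^2), sum(envs[, 3]^2), tolerance = 1e-12)
  # empirically: per-class mean trial covariances are close in Frobenius norm
  ts <- simulate_trials(tiny_design(trials_per_class = 12,
                                    blocks = 2, reps_per_block = 6),
                        temporal_signatures(tiny_design(), snr_db = 0,
                                            seed = 3),
                        seed = 8)
  covs <- lapply(split(ts$data, ts$class), function(dl) {
    Reduce(`+`, lapply(dl, function(m) tcrossprod(m) / sum(diag(tcrossprod(m))))) /
      length(dl)
  })
  dists <- vapply(covs[-1], function(cc) norm(cc - covs[[1]], "F"), numeric(1))
  base <- norm(covs[[1]], "F")
  expect_lt(max(dists) / base, 0.25)
})

test_that("full-window recordings epoch back to the task design", {
  d <- tiny_design()
  sig <- spatial_signatures(d, separation = 2, snr_db = 0, seed = 1)
  rec <- simulate_recording(d, sig, seed = 5, subject = 1)
  expect_s3_class(rec, "raw_recording")
  expect_equal(nrow(rec$events), 4 * 36)  # idle/cue/stimulus/rest per trial
  ts <- epoch_trials(rec, d)
  expect_equal(nrow(ts), 36)
  expect_equal(ncol(ts$data[[1]]), 1000)
  expect_true(all(table(ts$class) == 6))
})

test_that("decoding accuracy rises monotonically with spatial separation", {
  d <- experiment_design(n_subjects = 1, trials_per_class = 12, blocks = 2,
                         reps_per_block = 6)
  seps <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  accs <- vapply(seps, function(sep) {
    sig <- spatial_signatures(d, separation = sep, snr_db = -12, seed = 42)
    ts <- eeg_bandpass(simulate_trials(d, sig, seed = 43))
    sp <- split_trials(ts, 0.5, seed = 44)
    mean(predict(fit_csp_svm(sp$train, m = 2),
                 sp$test)$.pred_class == sp$test$class)
  }, numeric(1))
  expect_gt(suppressWarnings(
    stats::cor(seq_along(seps), accs, method = "spearman")), 0)
  expect_gt(accs[5], accs[1])
})
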