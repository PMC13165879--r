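test_that("normalized covariance matches direct matrix arithmetic", {
  # single channel: trace normalization forces [[1]]
  expect_equal(trial_covariance(matrix(1:10, 1)), matrix(1, 1, 1))
  # orthogonal rows with equal power: diag(0.5, 0.5)
  tt <- seq_len(512)
  d2 <- rbind(sin(2 * pi * tt / 16), cos(2 * pi * tt / 16))
  expect_equal(trial_covariance(d2), diag(2) * 0.5, tolerance = 1e-8)
  # random 8 x 1000 trial against the brute-force formula
  withr::with_seed(10, d <- matrix(rnorm(8000), 8))
  cc <- d %*% t(d) / sum(diag(d %*% t(d)))
  expect_equal(trial_covariance(d), cc, tolerance = 1e-12)
  expect_equal(sum(diag(trial_covariance(d))), 1, tolerance = 1e-12)
  expect_error(trial_covariance(matrix(0, 3, 100)), "degenerate")
})

# trial set with a prescribed per-class spatial covariance (via matrix sqrt)
covset <- function(ca, cb, n_trials = 20, n_samples = 500, seed = 1) {
  msqrt <- function(m) {
    e <- eigen(m, symmetric = TRUE)
    e$vectors %*% diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors)
  }
  withr::with_seed(seed, {
    mk <- function(cc) lapply(seq_len(n_trials), function(i) {
      msqrt(cc) %*% matrix(rnorm(nrow(cc) * n_samples), nrow(cc))
    })
    labels <- factor(rep(c("A", "B"), each = n_trials), levels = c("A", "B"))
    trial_set(tibble::tibble(subject = 1L, class = labels),
              c(mk(ca), mk(cb)), paste0("ch", seq_len(nrow(ca))), 250)
  })
}

test_that("CSP filters match the brute-force generalized eigensolve", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      ca <- random_spd(5); ca <- ca / sum(diag(ca))
      cb <- random_spd(5); cb <- cb / sum(diag(cb))
      ts <- covset(ca, cb, n_trials = 10, n_samples = 300, seed = rep)
      bank <- csp_pair(ts[ts$class == "A", ], ts[ts$class == "B", ], m = 2)
      # recompute the class means exactly as the fit sees them (shrinkage off
      # is approximated by the tiny default; compare against the same inputs)
      cam <- Reduce(`+`, lapply(ts$data[ts$class == "A"], trial_covariance)) / 10
      cbm <- Reduce(`+`, lapply(ts$data[ts$class == "B"], trial_covariance)) / 10
      eps <- 1e-6
      cam <- (1 - eps) * cam + eps * diag(5) / 5
      cbm <- (1 - eps) * cbm + eps * diag(5) / 5
      orc <- oracle_csp(cam, cbm)
      comp <- cam + cbm
      sel <- c(1, 2, 4, 5)
      for (j in seq_along(sel)) {
        w_pkg <- oracle_normalize(bank$filters[j, ], comp)
        w_orc <- oracle_normalize(orc$vectors[, sel[j]], comp)
        expect_equal(w_pkg, w_orc, tolerance = 1e-8)
        expect_equal(bank$eigenvalues[j], orc$values[sel[j]], tolerance = 1e-8)
      }
    }
  })
})

test_that("CSP recovers a planted single-channel variance contrast", {
  ca <- diag(c(1, 0.001, 0.001)); ca <- ca / sum(diag(ca))
  cb <- diag(c(0.001, 1, 0.001)); cb <- cb / sum(diag(cb))
  ts <- covset(ca, cb, n_trials = 40, n_samples = 2000, seed = 3)
  bank <- csp_pair(ts[ts$class == "A", ], ts[ts$class == "B", ], m = 1)
  top <- bank$filters[1, ] / sqrt(sum(bank$filters[1, ]^2))
  expect_gt(abs(top[1]), 0.99)  # aligned with the class-A axis
  expect_gt(bank$eigenvalues[1], 0.95)
  expect_lt(bank$eigenvalues[2], 0.05)
})

test_that("identical class covariances give eigenvalues of one half", {
  ca <- random_spd(4); ca <- ca / sum(diag(ca))
  ts <- covset(ca, ca, n_trials = 2, n_samples = 4000, seed = 5)
  # force exactly equal class means by reusing the same trials
  ts$data[ts$class == "B"] <- ts$data[ts$class == "A"]
  bank <- csp_pair(ts[ts$class == "A", ], ts[ts$class == "B", ], m = 2)
  expect_equal(bank$eigenvalues, rep(0.5, 4), tolerance = 1e-10)
})

test_that("swapping the class pair reflects eigenvalues and keeps the subspace", {
  ts <- covset(random_spd(6) / 6, random_spd(6) / 6, n_trials = 15,
               n_samples = 400, seed = 8)
  ab <- csp_pair(ts[ts$class == "A", ], ts[ts$class == "B", ], m = 3)
  ba <- csp_pair(ts[ts$class == "B", ], ts[ts$class == "A", ], m = 3)
  expect_equal(sort(ab$eigenvalues), sort(1 - ba$eigenvalues),
               tolerance = 1e-8)
  # same retained subspace: every ab filter lies in the span of ba filters
  qba <- qr(t(ba$filters))
  resid <- t(ab$filters) - qr.fitted(qba, t(ab$filters))
  expect_lt(max(abs(resid)), 1e-6)
})

test_that("filters jointly diagonalize both class means", {
  ts <- covset(random_spd(5) / 5, random_spd(5) / 5, n_trials = 12,
               n_samples = 300, seed = 13)
  ia <- which(ts$class == "A"); ib <- which(ts$class == "B")
  bank <- csp_pair(ts[ia, ], ts[ib, ], m = 2)
  eps <- 1e-6
  cam <- Reduce(`+`, lapply(ts$data[ia], trial_covariance)) / length(ia)
  cbm <- Reduce(`+`, lapply(ts$data[ib], trial_covariance)) / length(ib)
  cam <- (1 - eps) * cam + eps * diag(5) / 5
  cbm <- (1 - eps) * cbm + eps * diag(5) / 5
  da <- bank$filters %*% cam %*% t(bank$filters)
  db <- bank$filters %*% cbm %*% t(bank$filters)
  expect_lt(max(abs(da - diag(diag(da)))), 1e-8)
  expect_lt(max(abs(db - diag(diag(db)))), 1e-8)
  # diagonals sum to 1 per retained component (whitening constraint)
  expect_equal(diag(da) + diag(db), rep(1, 4), tolerance = 1e-8)
  expect_equal(diag(da), bank$eigenvalues, tolerance = 1e-8)
})

test_that("log-variance features are normalized and scale invariant", {
  ts <- tiny_spatial_ts(trials_per_class = 4)
  bank <- csp_pair(ts[ts$class == "Chi", ], ts[ts$class == "He", ], m = 3)
  withr::with_seed(31, trial <- matrix(rnorm(8 * 1000), 8))
  f <- csp_features(trial, bank)
  expect_length(f, 6)
  expect_equal(sum(exp(f)), 1, tolerance = 1e-9)
  expect_equal(csp_features(10 * trial, bank), f, tolerance = 1e-12)
  # equal filtered variances give all features log(1/2m)
  fid <- bank
  fid$filters <- diag(8)[1:6, ]
  iso <- withr::with_seed(32, {
    q <- qr.Q(qr(matrix(rnorm(64), 8)))  # rotation: unit variance all around
    q %*% matrix(rnorm(8 * 200000), 8)
  })
  expect_equal(csp_features(iso, fid), rep(log(1 / 6), 6), tolerance = 0.05)
})

test_that("one-vs-one training builds all class pairs", {
  ts6 <- tiny_spatial_ts(trials_per_class = 4)
  m6 <- fit_csp_svm(ts6, m = 2)
  expect_length(m6$fits, 15)
  pairs <- t(vapply(m6$fits, function(f) sort(f$pair), character(2)))
  expect_equal(nrow(unique(pairs)), 15)  # every unordered pair exactly once
  # 2 and 4 classes
  ts2 <- ts6[ts6$class %in% c("Chi", "He"), ]
  ts2$class <- droplevels(ts2$class)
  expect_length(fit_csp_svm(ts2, m = 2)$fits, 1)
  ts4 <- ts6[ts6$class %in% c("Chi", "He", "Chuan", "Na"), ]
  ts4$class <- droplevels(ts4$class)
  expect_length(fit_csp_svm(ts4, m = 2)$fits, 6)
  expect_error(fit_csp_svm(ts6[ts6$class != "Chi", ]), ">= 2")
})

test_that("votes sum to the pair count and amplitude scaling never flips them", {
  ts <- tiny_spatial_ts(trials_per_class = 6)
  sp <- split_trials(ts, 0.5, seed = 2)
  model <- fit_csp_svm(sp$train, m = 3)
  pred <- predict(model, sp$test)
  votes <- as.matrix(pred[, paste0("votes_", model$levels)])
  expect_true(all(rowSums(votes) == 15))
  scaled <- sp$test
  scaled$data <- lapply(scaled$data, function(m) m * 7)
  pred2 <- predict(model, scaled)
  expect_identical(pred$.pred_class, pred2$.pred_class)
})

test_that("the decoder separates a strong spatial scenario", {
  ts <- tiny_spatial_ts(n_subjects = 1, trials_per_class = 12, snr_db = 0,
                        seed = 41)
  sp <- split_trials(ts, 0.5, seed = 3)
  model <- fit_csp_svm(sp$train)
  pred <- predict(model, sp$test)
  acc <- mean(pred$.pred_class == sp$test$class)
  expect_gt(acc, 0.8)
})

test_that("the decoder stays at chance when class covariances match", {
  ts <- tiny_temporal_ts(n_subjects = 2, trials_per_class = 12, snr_db = 0,
                         seed = 51)
  sp <- split_trials(ts, 0.5, seed = 4)
  model <- fit_csp_svm(sp$train)
  pred <- predict(model, sp$test)
  acc <- mean(pred$.pred_class == sp$test$class)
  n <- nrow(sp$test)
  ci <- 1 / 6 + c(-1, 1) * stats::qnorm(0.995) * sqrt(1 / 6 * 5 / 6 / n)
  expect_gt(acc, ci[1])
  expect_lt(acc, ci[2])
})
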