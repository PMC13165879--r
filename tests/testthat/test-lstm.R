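test_that("fully connected layers compute the documented affine map", {
  # identity weights, zero bias, linear: output == input
  x <- matrix(rnorm(12), 3, 4)
  lay <- list(W = diag(4), b = rep(0, 4))
  expect_equal(fc_forward(x, lay, "linear"), x)
  # zero weights: output == activation(bias) regardless of input
  lay0 <- list(W = matrix(0, 4, 2), b = c(0.3, -0.7))
  out <- fc_forward(x, lay0, "tanh")
  expect_equal(out, matrix(tanh(c(0.3, -0.7)), 3, 2, byrow = TRUE))
  # random case against direct arithmetic
  withr::with_seed(1, {
    W <- matrix(rnorm(20), 4, 5); b <- rnorm(5)
  })
  expect_equal(fc_forward(x, list(W = W, b = b), "linear"),
               x %*% W + matrix(b, 3, 5, byrow = TRUE), tolerance = 1e-12)
})

test_that("the LSTM step has its zero-parameter closed form", {
  H <- 3
  p0 <- list(Wx = matrix(0, 2, 4 * H), Wh = matrix(0, H, 4 * H),
             b = rep(0, 4 * H))
  cp <- c(0.4, -0.2, 1.0)
  st <- lstm_step(c(1, -1), rep(0, H), cp, p0)
  # all gates sigmoid(0) = 0.5, modulation tanh(0) = 0
  expect_equal(as.numeric(st$i), rep(0.5, H))
  expect_equal(as.numeric(st$f), rep(0.5, H))
  expect_equal(as.numeric(st$c), 0.5 * cp)
  expect_equal(as.numeric(st$h), 0.5 * tanh(0.5 * cp))
  # zero state, zero input, zero params: everything stays zero
  st0 <- lstm_step(c(0, 0), rep(0, H), rep(0, H), p0)
  expect_equal(as.numeric(st0$h), rep(0, H))
  expect_equal(as.numeric(st0$c), rep(0, H))
  expect_error(lstm_step(c(NaN, 0), rep(0, H), rep(0, H), p0), "non-finite")
})

test_that("analytic gradients match central differences on a miniature net", {
  net <- lstm_network(4, fc_sizes = c(3, 3, 3), lstm_sizes = c(3, 3),
                      n_classes = 3, seed = 7)
  withr::with_seed(8, X <- array(rnorm(2 * 5 * 4), c(2, 5, 4)))
  y <- c(2L, 3L)
  for (ro in c("last", "mean")) {
    lg <- eegverbs:::net_loss_grad(net$params, X, y, "tanh", ro)
    gvec <- eegverbs:::params_flatten(lg$grads)
    v0 <- eegverbs:::params_flatten(net$params)
    f <- function(v) {
      p <- eegverbs:::params_unflatten(v, net$params)
      cross_entropy(eegverbs:::net_forward(p, X, "tanh", ro)$probs, y)
    }
    num <- numeric_gradient(f, v0)
    expect_lt(sqrt(sum((gvec - num)^2)) / sqrt(sum(num^2)), 1e-5)
  }
})

test_that("single-cell gradients match central differences", {
  # scalar loss through one LSTM step of a 3-unit cell
  net <- lstm_network(2, fc_sizes = c(2), lstm_sizes = c(3), n_classes = 2,
                      seed = 9)
  withr::with_seed(10, X <- array(rnorm(1 * 1 * 2), c(1, 1, 2)))
  lg <- eegverbs:::net_loss_grad(net$params, X, 1L, "tanh")
  v0 <- eegverbs:::params_flatten(net$params)
  f <- function(v) {
    p <- eegverbs:::params_unflatten(v, net$params)
    cross_entropy(eegverbs:::net_forward(p, X, "tanh")$probs, 1L)
  }
  num <- numeric_gradient(f, v0)
  gvec <- eegverbs:::params_flatten(lg$grads)
  expect_lt(sqrt(sum((gvec - num)^2)) / sqrt(sum(num^2)), 1e-5)
})

test_that("compiled core agrees with the plain-R reference implementation", {
  net <- lstm_network(6, fc_sizes = c(5, 4, 3), lstm_sizes = c(4, 4),
                      n_classes = 6, seed = 11)
  withr::with_seed(12, X <- array(rnorm(3 * 7 * 6), c(3, 7, 6)))
  y <- c(1L, 4L, 6L)
  a <- eegverbs:::net_loss_grad(net$params, X, y, "tanh")
  b <- eegverbs:::net_loss_grad_r(net$params, X, y, "tanh")
  expect_equal(a$loss, b$loss, tolerance = 1e-12)
  expect_equal(a$probs, b$probs, tolerance = 1e-12)
  expect_equal(eegverbs:::params_flatten(a$grads),
               eegverbs:::params_flatten(b$grads), tolerance = 1e-12)
})

test_that("forward pass obeys the softmax and symmetry contracts", {
  net <- lstm_network(8, fc_sizes = c(6, 5, 4), lstm_sizes = c(5, 5),
                      n_classes = 6, seed = 13)
  withr::with_seed(14, x <- matrix(rnorm(10 * 8), 10, 8))
  out <- lstm_forward(net, x)
  expect_equal(sum(out$probs), 1, tolerance = 1e-9)
  expect_true(all(out$probs >= 0))
  expect_equal(out$label, which.max(out$probs))
  expect_error(lstm_forward(net, x[0, , drop = FALSE]), "length 0")
  # zero output weights: exactly uniform probabilities
  net0 <- net
  net0$params$out$W[] <- 0; net0$params$out$b[] <- 0
  expect_equal(lstm_forward(net0, x)$probs, rep(1 / 6, 6), tolerance = 1e-12)
  # permuting the output projection permutes the probabilities identically
  perm <- c(3, 1, 6, 2, 5, 4)
  netp <- net
  netp$params$out$W <- net$params$out$W[, perm]
  netp$params$out$b <- net$params$out$b[perm]
  expect_equal(lstm_forward(netp, x)$probs, out$probs[perm],
               tolerance = 1e-12)
})

test_that("cross-entropy implements the per-unit binary form", {
  # exact one-hot prediction: zero loss
  y <- matrix(c(1, 0, 0, 0, 0, 0), 1)
  expect_equal(cross_entropy(y, y), 0, tolerance = 1e-9)
  # true unit at 0.5, others uniform at 1/6: true-unit term is ln 2
  a <- matrix(c(0.5, rep(1 / 6, 5)), 1)
  got <- cross_entropy(a, y)
  want <- -log(0.5) + sum(-log(1 - rep(1 / 6, 5)))
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(-log(0.5), 0.693, tolerance = 1e-3)
  # random batch against direct summation
  withr::with_seed(15, {
    p <- matrix(runif(24), 4); p <- p / rowSums(p)
    yi <- sample(1:6, 4, replace = TRUE)
  })
  yh <- matrix(0, 4, 6); yh[cbind(1:4, yi)] <- 1
  direct <- mean(vapply(1:4, function(i) {
    sum(-(yh[i, ] * log(p[i, ]) + (1 - yh[i, ]) * log(1 - p[i, ])))
  }, numeric(1)))
  expect_equal(cross_entropy(p, yi), direct, tolerance = 1e-12)
})

test_that("line search solves quadratics exactly and orthogonalizes gradients", {
  # f(x) = x^2 from x = 1: alpha* = 0.5 lands on the minimum
  phi1 <- function(a) (1 - a * 2)^2
  a1 <- line_search_alpha(phi1)
  expect_equal(a1, 0.5, tolerance = 1e-4)
  expect_equal(1 - a1 * 2, 0, tolerance = 1e-4)
  # f(x) = x' A x / 2 with SPD A: alpha* = g'g / g'Ag, new gradient orthogonal
  withr::with_seed(16, {
    for (i in 1:5) {
      A <- random_spd(4)
      x0 <- rnorm(4)
      g <- A %*% x0
      phi <- function(a) {
        xx <- x0 - a * g
        0.5 * as.numeric(t(xx) %*% A %*% xx)
      }
      a_star <- line_search_alpha(phi, alpha_max = 4)
      closed <- as.numeric(crossprod(g) / (t(g) %*% A %*% g))
      expect_equal(a_star, closed, tolerance = 1e-3)
      g_new <- A %*% (x0 - a_star * g)
      cosang <- abs(sum(g_new * g)) / sqrt(sum(g_new^2) * sum(g^2))
      expect_lt(cosang, 0.05)
    }
  })
  # unbracketable decreasing objective falls back with a warning
  expect_warning(fb <- line_search_alpha(function(a) -a, fallback = 0.1,
                                         max_expand = 3), "fallback")
  expect_equal(fb, 0.1)
})

test_that("training separates linearly separable toy sequences", {
  # two classes of 2-channel, 40-sample trials: energy arrives early vs late
  withr::with_seed(17, {
    mk <- function(cls) {
      env <- if (cls == 1) rep(c(2, 0.1), each = 20) else rep(c(0.1, 2), each = 20)
      rbind(env * rnorm(40), env * rnorm(40))
    }
    labels <- factor(rep(c("a", "b"), each = 10))
    ts <- trial_set(tibble::tibble(subject = 1L, class = labels),
                    lapply(rep(1:2, each = 10), mk), c("c1", "c2"), 250)
  })
  fit <- fit_dual_lstm(ts, frame_size = 4, fc_sizes = c(8, 8, 8),
                       lstm_sizes = c(8, 8), learning_rate = 0.05,
                       batch_size = 4, epochs = 200, seed = 18)
  expect_equal(tail(fit$trace$train_acc, 1), 1.0)
  expect_lt(tail(fit$trace$loss, 1), 0.2)
})

test_that("training is a pure function of data, config and seed", {
  ts <- tiny_temporal_ts(n_subjects = 1, trials_per_class = 4, seed = 19)
  f1 <- fit_dual_lstm(ts, epochs = 3, seed = 20)
  f2 <- fit_dual_lstm(ts, epochs = 3, seed = 20)
  expect_identical(f1$trace, f2$trace)
  expect_identical(eegverbs:::params_flatten(f1$net$params),
                   eegverbs:::params_flatten(f2$net$params))
  f3 <- fit_dual_lstm(ts, epochs = 3, seed = 21)
  expect_false(identical(eegverbs:::params_flatten(f1$net$params),
                         eegverbs:::params_flatten(f3$net$params)))
  # prediction interface
  p <- predict(f1, ts)
  probs <- as.matrix(p[, paste0(".prob_", f1$levels)])
  expect_equal(rowSums(probs), rep(1, nrow(ts)), tolerance = 1e-9)
})

test_that("line-search training decreases full-batch loss on a toy problem", {
  withr::with_seed(22, {
    mk <- function(cls) {
      env <- if (cls == 1) rep(c(2, 0.1), each = 20) else rep(c(0.1, 2), each = 20)
      rbind(env * rnorm(40), env * rnorm(40))
    }
    labels <- factor(rep(c("a", "b"), each = 6))
    ts <- trial_set(tibble::tibble(subject = 1L, class = labels),
                    lapply(rep(1:2, each = 6), mk), c("c1", "c2"), 250)
  })
  fit <- fit_dual_lstm(ts, frame_size = 4, fc_sizes = c(6, 6, 6),
                       lstm_sizes = c(6, 6), epochs = 15, seed = 23,
                       lr_mode = "line_search")
  expect_true(all(diff(fit$trace$loss) <= 1e-8))
})
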