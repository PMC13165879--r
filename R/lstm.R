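#' Construct the dual-LSTM network parameter container
#'
#' The seven-layer recurrent decoder: input layer, three fully connected
#' layers, two stacked LSTM layers, and a 6-way output projection. Each LSTM
#' cell carries input (i), forget (f), output (o) and input-modulation (m)
#' gate transforms `T(x, h) = x W_h1 + h W_h2 + b` with distinct parameters
#' per gate; sigmoid on i/f/o and tanh on m; state update
#' `c_t = f (*) c_{t-1} + i (*) m`, output `h_t = o (*) tanh(c_t)`.
#'
#' Weights are initialized uniform(-r, r) with `r = 1/sqrt(fan_in)`, and the
#' forget-gate bias at +1 (standard stabilization). Initialization is a pure
#' function of `seed`.
#'
#' @param input_size Per-step input dimension (frame samples x channels).
#' @param fc_sizes Widths of the three fully connected layers
#'   (default 128, 64, 32).
#' @param lstm_sizes Hidden sizes of the two LSTM layers (default 64, 64).
#' @param n_classes Output classes (default 6).
#' @param activation Fully connected nonlinearity, `"tanh"` or `"linear"`.
#' @param seed Integer seed for the initialization.
#' @return An object of class `lstm_network`.
#' @export
lstm_network <- function(input_size, fc_sizes = c(128, 64, 32),
                         lstm_sizes = c(64, 64), n_classes = 6,
                         activation = c("tanh", "linear"), seed = 1L) {
  activation <- match.arg(activation)
  params <- withr::with_seed(seed, {
    uin <- function(nr, nc, fan) matrix(runif(nr * nc, -1, 1) / sqrt(fan), nr, nc)
    sizes <- c(input_size, fc_sizes)
    fc <- lapply(seq_along(fc_sizes), function(l) {
      # biases off zero: an odd nonlinearity with zero bias is blind to the
      # band-power (second-order) structure of zero-mean EEG at init
      list(W = uin(sizes[l], sizes[l + 1], sizes[l]),
           b = runif(sizes[l + 1], 0.25, 0.75))
    })
    ins <- c(fc_sizes[length(fc_sizes)], lstm_sizes)
    lstm <- lapply(seq_along(lstm_sizes), function(l) {
      h <- lstm_sizes[l]
      b <- rep(0, 4 * h)
      b[(h + 1):(2 * h)] <- 1  # forget gate bias
      list(Wx = uin(ins[l], 4 * h, ins[l]),
           Wh = uin(h, 4 * h, h),
           b = b)
    })
    out <- list(W = uin(lstm_sizes[length(lstm_sizes)], n_classes,
                        lstm_sizes[length(lstm_sizes)]),
                b = rep(0, n_classes))
    list(fc = fc, lstm = lstm, out = out)
  })
  structure(list(params = params, input_size = input_size,
                 fc_sizes = fc_sizes, lstm_sizes = lstm_sizes,
                 n_classes = n_classes, activation = activation, seed = seed),
            class = "lstm_network")
}

#' @export
print.lstm_network <- function(x, ...) {
  cat(sprintf(
    "<lstm_network> %d -> fc(%s) -> lstm(%s) -> %d classes [%s], %d parameters\n",
    x$input_size, paste(x$fc_sizes, collapse = "-"),
    paste(x$lstm_sizes, collapse = "-"), x$n_classes, x$activation,
    length(params_flatten(x$params))))
  invisible(x)
}

#' One fully connected layer forward pass
#'
#' Computes `activation(x %*% W + b)`: the affine data flow between adjacent
#' layers, with the configured nonlinearity.
#'
#' @param x Input row vector or batch matrix (rows = samples).
#' @param layer List with weight matrix `W` and bias vector `b`.
#' @param activation `"tanh"` or `"linear"`.
#' @return Matrix of activations with `ncol(W)` columns.
#' @export
fc_forward <- function(x, layer, activation = c("tanh", "linear")) {
  activation <- match.arg(activation)
  x <- rbind(x)
  a <- sweep(x %*% layer$W, 2, layer$b, `+`)
  if (activation == "tanh") tanh(a) else a
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One LSTM cell step
#'
#' Applies the four gate transforms to the current input and previous hidden
#' state and performs the state update. `params` holds `Wx` (input-to-gates),
#' `Wh` (hidden-to-gates) and `b`, each spanning the four gate blocks in the
#' order i, f, o, m.
#'
#' @param x_t Input row vector / batch matrix at this step.
#' @param h_prev,c_prev Previous hidden state and cell state (same shape).
#' @param params List with `Wx` (in x 4H), `Wh` (H x 4H), `b` (4H).
#' @return List with `h` and `c`, plus the gate activations (`i`, `f`, `o`,
#'   `m`, `tanh_c`) used by backpropagation.
#' @export
lstm_step <- function(x_t, h_prev, c_prev, params) {
  x_t <- rbind(x_t); h_prev <- rbind(h_prev); c_prev <- rbind(c_prev)
  if (any(!is.finite(x_t))) abort("non-finite input to LSTM step")
  h <- ncol(params$Wh)/4
  g <- sweep(x_t %*% params$Wx + h_prev %*% params$Wh, 2, params$b, `+`)
  gi <- sigmoid(g[, 1:h, drop = FALSE])
  gf <- sigmoid(g[, (h + 1):(2 * h), drop = FALSE])
  go <- sigmoid(g[, (2 * h + 1):(3 * h), drop = FALSE])
  gm <- tanh(g[, (3 * h + 1):(4 * h), drop = FALSE])
  c_t <- gf * c_prev + gi * gm
  tc <- tanh(c_t)
  list(h = go * tc, c = c_t, i = gi, f = gf, o = go, m = gm, tanh_c = tc)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Cross-entropy loss over the six output units
#'
#' The training loss: the per-unit binary cross-entropy
#' `-(y ln a + (1 - y) ln(1 - a))` summed across the output units against the
#' one-hot target and averaged over samples. Probabilities are clipped to
#' `[eps, 1 - eps]` before the logs.
#'
#' @param probs Samples x classes matrix of predicted probabilities.
#' @param targets One-hot samples x classes matrix, or a factor/integer
#'   vector of class indices.
#' @param eps Clipping constant (default 1e-12).
#' @return Scalar loss.
#' @export
cross_entropy <- function(probs, targets, eps = 1e-12) {
  probs <- rbind(probs)
  y <- as_one_hot(targets, ncol(probs))
  a <- pmin(pmax(probs, eps), 1 - eps)
  sum(-(y * log(a) + (1 - y) * log(1 - a))) / nrow(probs)
}

as_one_hot <- function(targets, k) {
  if (is.matrix(targets)) return(targets)
  idx <- if (is.factor(targets)) as.integer(targets) else as.integer(targets)
  y <- matrix(0, length(idx), k)
  y[cbind(seq_along(idx), idx)] <- 1
  y
}

# ---- flat parameter vector helpers (gradient checks, clipping, line search)

params_flatten <- function(p) {
  unlist(p, use.names = FALSE)
}

params_unflatten <- function(vec, template) {
  rel <- utils::relist(vec, template)
  # relist returns lists of numerics; restore matrix dims from the template
  restore <- function(r, t) {
    if (is.list(t)) Map(restore, r, t)
    else if (is.matrix(t)) matrix(r, nrow(t), ncol(t))
    else as.numeric(r)
  }
  restore(rel, template)
}

params_axpy <- function(p, g, a) {
  # p + a * g, elementwise over the nested structure
  if (is.list(p)) Map(params_axpy, p, g, MoreArgs = list(a = a))
  else p + a * g
}

params_zero <- function(p) {
  if (is.list(p)) lapply(p, params_zero) else p * 0
}

# ---- batched forward/backward over a trials x steps x features array

# convert the nested parameter list to the flat layout of the C++ core
params_to_cpp <- function(params) {
  list(fc_W = lapply(params$fc, `[[`, "W"),
       fc_b = lapply(params$fc, `[[`, "b"),
       lstm_Wx = lapply(params$lstm, `[[`, "Wx"),
       lstm_Wh = lapply(params$lstm, `[[`, "Wh"),
       lstm_b = lapply(params$lstm, `[[`, "b"),
       out_W = params$out$W, out_b = params$out$b)
}

cpp_to_grads <- function(g) {
  list(fc = Map(function(W, b) list(W = W, b = as.numeric(b)),
                g$fc_W, g$fc_b),
       lstm = Map(function(Wx, Wh, b) list(Wx = Wx, Wh = Wh,
                                           b = as.numeric(b)),
                  g$lstm_Wx, g$lstm_Wh, g$lstm_b),
       out = list(W = g$out_W, b = as.numeric(g$out_b)))
}

# fold (trial, step) into rows: row index (t - 1) * B + b
stack_steps <- function(X) {
  matrix(X, dim(X)[1] * dim(X)[2], dim(X)[3])
}

net_forward <- function(params, X, activation, readout = "last") {
  p <- params_to_cpp(params)
  res <- cpp_loss_grad(p$fc_W, p$fc_b, p$lstm_Wx, p$lstm_Wh, p$lstm_b,
                       p$out_W, p$out_b, stack_steps(X), dim(X)[1], dim(X)[2],
                       rep(1L, dim(X)[1]),
                       if (activation == "tanh") 0L else 1L,
                       if (readout == "last") 0L else 1L, FALSE)
  list(probs = res$probs)
}

net_loss_grad <- function(params, X, y_idx, activation, readout = "last") {
  p <- params_to_cpp(params)
  res <- cpp_loss_grad(p$fc_W, p$fc_b, p$lstm_Wx, p$lstm_Wh, p$lstm_b,
                       p$out_W, p$out_b, stack_steps(X), dim(X)[1], dim(X)[2],
                       as.integer(y_idx),
                       if (activation == "tanh") 0L else 1L,
                       if (readout == "last") 0L else 1L, TRUE)
  list(loss = res$loss, grads = cpp_to_grads(res$grads), probs = res$probs)
}

# reference implementation in plain R (used to cross-check the compiled core)
net_forward_r <- function(params, X, activation, readout = "last",
                          keep_cache = FALSE) {
  B <- dim(X)[1]; T_steps <- dim(X)[2]
  n_fc <- length(params$fc); n_lstm <- length(params$lstm)
  # time-distributed FC stack: fold (trial, step) into rows for one matmul
  a <- matrix(aperm(X, c(1, 2, 3)), B * T_steps, dim(X)[3])
  fc_acts <- vector("list", n_fc + 1)
  fc_acts[[1]] <- a
  for (l in seq_len(n_fc)) {
    a <- fc_forward(a, params$fc[[l]], activation)
    fc_acts[[l + 1]] <- a
  }
  lstm_cache <- if (keep_cache) {
    lapply(seq_len(n_lstm), function(l) vector("list", T_steps))
  }
  hs <- lapply(params$lstm, function(l) matrix(0, B, ncol(l$Wh) / 4))
  cs <- hs
  h_sum <- NULL
  for (t in seq_len(T_steps)) {
    x_t <- fc_acts[[n_fc + 1]][((t - 1) * B + 1):(t * B), , drop = FALSE]
    for (l in seq_len(n_lstm)) {
      st <- lstm_step(x_t, hs[[l]], cs[[l]], params$lstm[[l]])
      st$x_in <- x_t; st$h_prev <- hs[[l]]; st$c_prev <- cs[[l]]
      hs[[l]] <- st$h; cs[[l]] <- st$c
      x_t <- st$h
      if (keep_cache) lstm_cache[[l]][[t]] <- st
    }
    h_sum <- if (is.null(h_sum)) x_t else h_sum + x_t
  }
  h_read <- if (readout == "last") hs[[n_lstm]] else h_sum / T_steps
  logits <- sweep(h_read %*% params$out$W, 2, params$out$b, `+`)
  probs <- softmax_rows(logits)
  list(probs = probs, h_read = h_read,
       fc_acts = if (keep_cache) fc_acts, lstm_cache = lstm_cache)
}

net_loss_grad_r <- function(params, X, y_idx, activation, readout = "last",
                            eps = 1e-12) {
  B <- dim(X)[1]; T_steps <- dim(X)[2]
  fwd <- net_forward_r(params, X, activation, readout, keep_cache = TRUE)
  k <- ncol(fwd$probs)
  y <- as_one_hot(y_idx, k)
  a <- pmin(pmax(fwd$probs, eps), 1 - eps)
  loss <- sum(-(y * log(a) + (1 - y) * log(1 - a))) / B
  # d loss / d probs, then through the softmax jacobian
  u <- (-(y / a) + (1 - y) / (1 - a)) / B
  dz <- fwd$probs * (u - rowSums(u * fwd$probs))
  g <- params_zero(params)
  g$out$W <- t(fwd$h_read) %*% dz
  g$out$b <- colSums(dz)
  dh_read <- dz %*% t(params$out$W)
  n_lstm <- length(params$lstm); n_fc <- length(params$fc)
  # external gradient arriving at the top LSTM's output per step
  dh_top <- vector("list", T_steps)
  for (t in seq_len(T_steps)) {
    dh_top[[t]] <- if (readout == "last") {
      if (t == T_steps) dh_read else matrix(0, B, ncol(dh_read))
    } else dh_read / T_steps
  }
  dh_ext <- dh_top
  for (l in rev(seq_len(n_lstm))) {
    p <- params$lstm[[l]]
    H <- ncol(p$Wh) / 4
    dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
    dx_l <- vector("list", T_steps)
    for (t in rev(seq_len(T_steps))) {
      st <- fwd$lstm_cache[[l]][[t]]
      dh <- dh_ext[[t]] + dh_next
      do_ <- dh * st$tanh_c
      dc <- dh * st$o * (1 - st$tanh_c^2) + dc_next
      di <- dc * st$m
      df <- dc * st$c_prev
      dm <- dc * st$i
      dc_next <- dc * st$f
      dg <- cbind(di * st$i * (1 - st$i),
                  df * st$f * (1 - st$f),
                  do_ * st$o * (1 - st$o),
                  dm * (1 - st$m^2))
      g$lstm[[l]]$Wx <- g$lstm[[l]]$Wx + t(st$x_in) %*% dg
      g$lstm[[l]]$Wh <- g$lstm[[l]]$Wh + t(st$h_prev) %*% dg
      g$lstm[[l]]$b <- g$lstm[[l]]$b + colSums(dg)
      dx_l[[t]] <- dg %*% t(p$Wx)
      dh_next <- dg %*% t(p$Wh)
    }
    dh_ext <- dx_l  # becomes the external gradient for the layer below
  }
  # stack per-step gradients back into (trial, step) rows for the FC stack
  da <- do.call(rbind, dh_ext)
  for (l in rev(seq_len(n_fc))) {
    acts_in <- fwd$fc_acts[[l]]
    acts_out <- fwd$fc_acts[[l + 1]]
    dpre <- if (activation == "tanh") da * (1 - acts_out^2) else da
    g$fc[[l]]$W <- t(acts_in) %*% dpre
    g$fc[[l]]$b <- colSums(dpre)
    da <- dpre %*% t(params$fc[[l]]$W)
  }
  list(loss = loss, grads = g, probs = fwd$probs)
}

#' Forward pass: classify one trial sequence
#'
#' Runs a steps x features input sequence through the fully connected stack
#' (applied at every step), the two LSTM layers scanned over time, and the
#' final-step output projection with softmax.
#'
#' @param net An [lstm_network()].
#' @param x Steps x features numeric matrix (one trial's frame sequence).
#' @param readout `"last"` (final-step hidden state, the default) or
#'   `"mean"` (time-averaged hidden state).
#' @return List with `probs` (class probabilities summing to 1) and `label`
#'   (argmax index).
#' @export
lstm_forward <- function(net, x, readout = c("last", "mean")) {
  readout <- match.arg(readout)
  if (nrow(x) == 0) abort("input sequence has length 0")
  X <- array(0, c(1, nrow(x), ncol(x)))
  X[1, , ] <- x
  fwd <- net_forward(net$params, X, net$activation, readout)
  probs <- as.numeric(fwd$probs)
  list(probs = probs, label = which.max(probs))
}

#' Exact line search for the steepest-descent learning rate
#'
#' Finds the step size minimizing `phi(alpha) = f(x - alpha g)` along the
#' negative gradient by golden-section/parabolic search, expanding the upper
#' bound until a minimum is bracketed. At the optimum the new gradient is
#' orthogonal to the search direction.
#'
#' @param phi Function of one nonnegative scalar: the objective along the ray.
#' @param alpha_max Initial upper bound of the search interval.
#' @param fallback Step returned (with a warning) if no interior minimum is
#'   bracketed within `max_expand` doublings.
#' @param tol Search tolerance.
#' @param max_expand Maximum number of interval doublings.
#' @return The selected step size alpha.
#' @export
line_search_alpha <- function(phi, alpha_max = 1, fallback = 0.005,
                              tol = 1e-8, max_expand = 12) {
  hi <- alpha_max
  for (k in seq_len(max_expand)) {
    opt <- optimize(phi, c(0, hi), tol = tol)
    if (opt$minimum < hi * (1 - 1e-3)) return(opt$minimum)
    if (!is.finite(phi(hi * 2))) break
    hi <- hi * 2
  }
  warn("line search failed to bracket a minimum; using fallback step")
  fallback
}

# frames a trial set into a trials x steps x (frame_size * channels) array
ts_frames <- function(ts, frame_size = 20) {
  n <- ncol(ts$data[[1]])
  nch <- nrow(ts$data[[1]])
  if (n %% frame_size != 0) {
    abort("trial length must be divisible by frame_size")
  }
  T_steps <- n / frame_size
  X <- array(0, c(nrow(ts), T_steps, frame_size * nch))
  for (i in seq_len(nrow(ts))) {
    d <- ts$data[[i]]
    for (t in seq_len(T_steps)) {
      X[i, t, ] <- as.numeric(d[, ((t - 1) * frame_size + 1):(t * frame_size)])
    }
  }
  X
}

#' Train the dual-LSTM decoder on a trial set
#'
#' Seeded mini-batch gradient descent on the cross-entropy loss. Each
#' 1000-sample trial is consumed as 50 steps of 20-sample frames (all 8
#' channels flattened per frame); trials are z-scored per channel first.
#' Gradients are clipped at a global norm of 5. With
#' `lr_mode = "line_search"` the step size of every full-batch update is
#' chosen by [line_search_alpha()] instead of the fixed rate.
#'
#' @param train A [trial_set()] with at least one trial per class.
#' @param frame_size Samples per sequence step (default 20).
#' @param fc_sizes,lstm_sizes,activation Network shape, see [lstm_network()].
#' @param learning_rate Fixed step size (default 0.005, the study's rate).
#' @param batch_size Mini-batch size (default 1; plain gradient descent at
#'   the study's rate needs many small steps, and single-trial batches supply
#'   them while their gradient noise acts as a regularizer).
#' @param epochs Training epochs (default 150).
#' @param seed Seed for initialization and batch shuffling.
#' @param lr_mode `"fixed"` or `"line_search"`.
#' @param validation Optional held-out [trial_set()] scored every epoch.
#' @param clip_norm Global gradient-norm clip (default 5).
#' @param readout `"last"` or `"mean"` hidden-state readout.
#' @return An object of class `dual_lstm`: the trained network, the class
#'   levels, and a per-epoch `trace` tibble (epoch, loss, train_acc,
#'   val_acc).
#' @export
fit_dual_lstm <- function(train, frame_size = 20, fc_sizes = c(128, 64, 32),
                          lstm_sizes = c(64, 64), activation = "tanh",
                          learning_rate = 0.005, batch_size = 1, epochs = 150,
                          seed = 1L, lr_mode = c("fixed", "line_search"),
                          validation = NULL, clip_norm = 5,
                          readout = c("last", "mean")) {
  lr_mode <- match.arg(lr_mode)
  readout <- match.arg(readout)
  cls <- ts_class_factor(train)
  levs <- levels(cls)
  if (any(table(cls) < 1)) abort("every class needs at least one trial")
  train_z <- zscore_trials(train)
  X <- ts_frames(train_z, frame_size)
  y <- as.integer(cls)
  net <- lstm_network(dim(X)[3], fc_sizes, lstm_sizes, length(levs),
                      activation, seed = seed)
  params <- net$params
  n <- dim(X)[1]
  trace <- vector("list", epochs)
  withr::with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      if (lr_mode == "line_search") ord <- seq_len(n)  # full batch
      batches <- if (lr_mode == "line_search") list(ord) else
        split(ord, ceiling(seq_along(ord) / batch_size))
      ep_loss <- 0; ep_correct <- 0
      for (bi in batches) {
        Xb <- X[bi, , , drop = FALSE]
        lg <- net_loss_grad(params, Xb, y[bi], activation, readout)
        if (!is.finite(lg$loss)) {
          abort(sprintf("training diverged at epoch %d (non-finite loss)", ep),
                class = "eegverbs_divergence")
        }
        gvec <- params_flatten(lg$grads)
        gn <- sqrt(sum(gvec^2))
        grads <- lg$grads
        if (is.finite(clip_norm) && gn > clip_norm) {
          grads <- params_axpy(params_zero(grads), grads, clip_norm / gn)
        }
        alpha <- if (lr_mode == "fixed") learning_rate else {
          phi <- function(a) {
            p2 <- params_axpy(params, grads, -a)
            fw <- net_forward(p2, Xb, activation, readout)
            cross_entropy(fw$probs, y[bi])
          }
          line_search_alpha(phi, alpha_max = 1, fallback = learning_rate)
        }
        params <- params_axpy(params, grads, -alpha)
        ep_loss <- ep_loss + lg$loss * length(bi)
        ep_correct <- ep_correct + sum(max.col(lg$probs) == y[bi])
      }
      val_acc <- NA_real_
      if (!is.null(validation)) {
        net$params <- params
        pv <- predict_lstm_idx(net, validation, frame_size, readout)
        val_acc <- mean(pv == as.integer(factor(validation$class,
                                                levels = levs)))
      }
      trace[[ep]] <- tibble(epoch = ep, loss = ep_loss / n,
                            train_acc = ep_correct / n, val_acc = val_acc)
    }
  })
  net$params <- params
  structure(list(net = net, levels = levs, frame_size = frame_size,
                 readout = readout, trace = dplyr::bind_rows(trace),
                 config = list(learning_rate = learning_rate,
                               batch_size = batch_size, epochs = epochs,
                               seed = seed, lr_mode = lr_mode,
                               clip_norm = clip_norm)),
            class = "dual_lstm")
}

predict_lstm_idx <- function(net, ts, frame_size, readout) {
  X <- ts_frames(zscore_trials(ts), frame_size)
  fwd <- net_forward(net$params, X, net$activation, readout)
  max.col(fwd$probs)
}

#' @export
print.dual_lstm <- function(x, ...) {
  last <- tail(x$trace, 1)
  cat(sprintf(
    "<dual_lstm> %s; %d epochs (lr %g, %s), final loss %.4f, train acc %.3f\n",
    paste(x$levels, collapse = "/"), nrow(x$trace),
    x$config$learning_rate, x$config$lr_mode, last$loss, last$train_acc))
  invisible(x)
}

#' Predict verb labels with a trained dual-LSTM
#'
#' @param object A fitted [fit_dual_lstm()] model.
#' @param newdata A [trial_set()].
#' @param ... Unused.
#' @return Tibble with `trial_id`, `.pred_class` and one `.prob_<label>`
#'   column per class (rows sum to 1).
#' @export
predict.dual_lstm <- function(object, newdata, ...) {
  X <- ts_frames(zscore_trials(newdata), object$frame_size)
  fwd <- net_forward(object$net$params, X, object$net$activation,
                     object$readout)
  probs <- fwd$probs
  colnames(probs) <- paste0(".prob_", object$levels)
  tibble(trial_id = newdata$trial_id,
         .pred_class = factor(object$levels[max.col(probs)],
                              levels = object$levels)) |>
    dplyr::bind_cols(as_tibble(as.data.frame(probs)))
}
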