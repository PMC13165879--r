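# independent oracles used to cross-check package implementations

# brute-force generalized eigensolve of Ca w = lambda (Ca + Cb) w via the
# plain (non-symmetric) eigendecomposition of solve(Ca + Cb) %*% Ca
oracle_csp <- function(ca, cb) {
  ev <- eigen(solve(ca + cb) %*% ca)
  ord <- order(Re(ev$values), decreasing = TRUE)
  list(values = Re(ev$values)[ord],
       vectors = Re(ev$vectors)[, ord, drop = FALSE])
}

# normalize a generalized eigenvector w to w' (Ca+Cb) w' == 1 with the
# largest-magnitude coefficient positive, for comparison across solvers
oracle_normalize <- function(w, comp) {
  w <- w / sqrt(as.numeric(t(w) %*% comp %*% w))
  if (w[which.max(abs(w))] < 0) -w else w
}

# random symmetric positive definite matrix
random_spd <- function(n) {
  a <- matrix(rnorm(n * n), n)
  crossprod(a) + diag(n) * 0.1
}

# naive direct-summation MFCC oracle: explicit DFT sums and per-element
# triangle/DCT arithmetic, mirroring the declared conventions step by step
oracle_mfcc <- function(samples, sample_rate, frame_length_s = 0.025,
                        frame_step_s = 0.010, n_mfcc = 13, n_filters = 26,
                        pre_emphasis = 0.97, log_floor = 1e-10) {
  frame_len <- round(frame_length_s * sample_rate)
  step <- round(frame_step_s * sample_rate)
  n_fft <- 2^ceiling(log2(frame_len))
  x <- samples
  if (pre_emphasis > 0) {
    out <- numeric(length(x)); out[1] <- x[1]
    for (i in 2:length(x)) out[i] <- x[i] - pre_emphasis * x[i - 1]
    x <- out
  }
  n_frames <- floor((length(x) - frame_len) / step) + 1
  win <- vapply(seq_len(frame_len) - 1,
                function(k) 0.54 - 0.46 * cos(2 * pi * k / (frame_len - 1)),
                numeric(1))
  # triangular filters from first principles
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  pts <- floor((n_fft + 1) *
                 imel(seq(mel(0), mel(sample_rate / 2),
                          length.out = n_filters + 2)) / sample_rate)
  n_bins <- n_fft %/% 2 + 1
  fb <- matrix(0, n_filters, n_bins)
  for (j in seq_len(n_filters)) {
    for (k in seq.int(pts[j], pts[j + 1])) {
      if (pts[j + 1] > pts[j]) fb[j, k + 1] <- (k - pts[j]) / (pts[j + 1] - pts[j])
    }
    for (k in seq.int(pts[j + 1], pts[j + 2])) {
      if (pts[j + 2] > pts[j + 1]) fb[j, k + 1] <- (pts[j + 2] - k) / (pts[j + 2] - pts[j + 1])
    }
  }
  out <- matrix(0, n_frames, n_mfcc)
  for (fr in seq_len(n_frames)) {
    seg <- x[((fr - 1) * step + 1):((fr - 1) * step + frame_len)] * win
    seg <- c(seg, rep(0, n_fft - frame_len))
    power <- numeric(n_bins)
    for (k in seq_len(n_bins) - 1) {  # explicit DFT sum per bin
      n_idx <- seq_len(n_fft) - 1
      re <- sum(seg * cos(2 * pi * k * n_idx / n_fft))
      im <- -sum(seg * sin(2 * pi * k * n_idx / n_fft))
      power[k + 1] <- (re^2 + im^2) / n_fft
    }
    loge <- log(pmax(as.numeric(fb %*% power), log_floor))
    for (k in seq_len(n_mfcc) - 1) {  # explicit orthonormal DCT-II sum
      s <- sum(loge * cos(pi * k * (2 * seq_len(n_filters) - 1) /
                            (2 * n_filters)))
      s <- s * sqrt(2 / n_filters)
      if (k == 0) s <- s / sqrt(2)
      out[fr, k + 1] <- s
    }
  }
  out
}

# central-difference gradient of a scalar function of a flat parameter vector
numeric_gradient <- function(f, v, h = 1e-5) {
  vapply(seq_along(v), function(i) {
    up <- v; up[i] <- up[i] + h
    dn <- v; dn[i] <- dn[i] - h
    (f(up) - f(dn)) / (2 * h)
  }, numeric(1))
}

# two-sample permutation test on the difference of mean channel means
perm_test_class_means <- function(ts, n_perm = 200, seed = 9) {
  cls <- levels(factor(ts$class))[1:2]
  vals <- vapply(ts$data, mean, numeric(1))
  grp <- as.character(ts$class) == cls[1]
  obs <- abs(mean(vals[grp]) - mean(vals[!grp]))
  perms <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      g <- sample(grp)
      abs(mean(vals[g]) - mean(vals[!g]))
    }, numeric(1))
  })
  mean(c(perms, obs) >= obs)  # p-value
}
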