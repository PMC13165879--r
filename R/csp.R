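#' Trace-normalized trial covariance
#'
#' For a channels x time trial matrix `D`, computes
#' `C = D %*% t(D) / trace(D %*% t(D))`, the trace-normalized spatial
#' covariance on which CSP operates. The normalization makes the estimate
#' invariant to overall trial amplitude.
#'
#' @param x Numeric channels x time matrix with at least 2 time points.
#' @return Symmetric positive semidefinite matrix with unit trace.
#' @export
trial_covariance <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) abort("trial needs at least 2 time points")
  cc <- tcrossprod(x)
  tr <- sum(diag(cc))
  if (tr <= 0) abort("degenerate trial: zero total power")
  cc / tr
}

# mean normalized covariance over a trial set, with shrinkage toward
# (trace/N) * I for numerical conditioning of the eigensolve
class_mean_cov <- function(ts, shrinkage = 1e-6) {
  covs <- lapply(ts$data, trial_covariance)
  cbar <- Reduce(`+`, covs) / length(covs)
  n <- nrow(cbar)
  (1 - shrinkage) * cbar + shrinkage * (sum(diag(cbar)) / n) * diag(n)
}

#' Fit a CSP spatial filter bank for one class pair
#'
#' Solves the generalized eigenproblem `Cbar_a w = lambda (Cbar_a + Cbar_b) w`
#' for the class-mean normalized covariances, via whitening of the composite
#' covariance. Filters with the largest eigenvalues maximize class-a variance
#' relative to total; smallest maximize class-b variance. The `m` filters from
#' each extreme are retained (2m filters total).
#'
#' @param ts_a,ts_b [trial_set()]s holding the two classes' trials.
#' @param m Filters kept per extreme; `2m <= n_channels` (default 3).
#' @param shrinkage Shrinkage weight toward the scaled identity applied to
#'   each class-mean covariance (default 1e-6).
#' @return An object of class `csp_bank`: list with `filters` (2m x channels,
#'   rows are spatial filters w), `eigenvalues` (descending, in [0, 1]),
#'   `pair` (the two class labels), `m`, `montage`.
#' @export
csp_pair <- function(ts_a, ts_b, m = 3, shrinkage = 1e-6) {
  if (nrow(ts_a) == 0 || nrow(ts_b) == 0) abort("both classes need trials")
  ca <- class_mean_cov(ts_a, shrinkage)
  cb <- class_mean_cov(ts_b, shrinkage)
  n <- nrow(ca)
  if (2 * m > n) abort("2m must not exceed the channel count")
  comp <- ca + cb
  ec <- eigen(comp, symmetric = TRUE)
  tol <- n * .Machine$double.eps * max(ec$values)
  if (min(ec$values) < tol) {
    warn("rank-deficient composite covariance; applying extra shrinkage")
    comp <- 0.99 * comp + 0.01 * (sum(diag(comp)) / n) * diag(n)
    ec <- eigen(comp, symmetric = TRUE)
    if (min(ec$values) < tol) abort("composite covariance is singular")
  }
  whitener <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)
  s <- whitener %*% ca %*% t(whitener)
  es <- eigen((s + t(s)) / 2, symmetric = TRUE)  # eigenvalues descending
  w_full <- t(es$vectors) %*% whitener
  keep <- c(seq_len(m), (n - m + 1):n)
  filters <- w_full[keep, , drop = FALSE]
  # reproducible sign: largest-magnitude coefficient positive
  for (i in seq_len(nrow(filters))) {
    j <- which.max(abs(filters[i, ]))
    if (filters[i, j] < 0) filters[i, ] <- -filters[i, ]
  }
  lambda <- pmin(pmax(es$values[keep], 0), 1)
  labels <- c(as.character(unique(ts_a$class))[1],
              as.character(unique(ts_b$class))[1])
  structure(list(filters = filters, eigenvalues = lambda, pair = labels,
                 m = m, montage = ts_montage(ts_a)),
            class = "csp_bank")
}

#' @export
print.csp_bank <- function(x, ...) {
  cat(sprintf("<csp_bank> pair %s vs %s, %d filters; eigenvalues %s\n",
              x$pair[1], x$pair[2], nrow(x$filters),
              paste(sprintf("%.3f", x$eigenvalues), collapse = " ")))
  invisible(x)
}

#' Normalized log-variance CSP features
#'
#' Projects a trial through a filter bank (`Z = W D`) and returns
#' `f_j = log(var(Z_j) / sum_i var(Z_i))`, the variance of each filtered
#' component normalized over the 2m retained components. `sum(exp(f)) == 1`
#' by construction, and the features are invariant to trial amplitude.
#'
#' @param trial Channels x time matrix.
#' @param bank A [csp_pair()] filter bank.
#' @return Numeric feature vector of length `2m`.
#' @export
csp_features <- function(trial, bank) {
  if (ncol(bank$filters) != nrow(trial)) {
    abort("trial channel count does not match the filter bank")
  }
  z <- bank$filters %*% trial
  v <- apply(z, 1, var)
  if (any(v <= 0)) {
    warn("zero-variance filtered component; flooring at machine epsilon")
    v <- pmax(v, .Machine$double.eps)
  }
  log(v / sum(v))
}

#' Fit the one-vs-one CSP + RBF-SVM decoder
#'
#' The baseline decoder: for each of the `K(K-1)/2` unordered class pairs
#' (15 pairs for six verbs), fits a CSP filter bank on that pair's trials and
#' a radial-basis-function support vector machine on the resulting 2m
#' log-variance features. Prediction is by majority vote over the pairwise
#' classifiers.
#'
#' @param train A [trial_set()] with at least 2 trials of every class.
#' @param m CSP filters per extreme (default 3, i.e. 6 features per pair).
#' @param cost Soft-margin penalty `c` of the SVM (default 1).
#' @param gamma RBF kernel width `g` in `exp(-g ||x - x'||^2)`; default
#'   `1 / (2m)`, the reciprocal feature dimension.
#' @param shrinkage Covariance shrinkage passed to [csp_pair()].
#' @return An object of class `csp_svm` with one `csp_bank` and one fitted
#'   SVM per pair.
#' @export
fit_csp_svm <- function(train, m = 3, cost = 1, gamma = NULL,
                        shrinkage = 1e-6) {
  cls <- ts_class_factor(train)
  levs <- levels(cls)
  counts <- table(cls)
  if (any(counts < 2)) {
    abort(sprintf("every class needs >= 2 training trials (worst: %s)",
                  names(counts)[which.min(counts)]))
  }
  if (is.null(gamma)) gamma <- 1 / (2 * m)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  fits <- lapply(pairs, function(pr) {
    ia <- which(cls == pr[1]); ib <- which(cls == pr[2])
    bank <- csp_pair(restore_ts(train[ia, ], train),
                     restore_ts(train[ib, ], train),
                     m = m, shrinkage = shrinkage)
    feats <- rbind(
      t(vapply(train$data[ia], csp_features, numeric(2 * m), bank = bank)),
      t(vapply(train$data[ib], csp_features, numeric(2 * m), bank = bank)))
    y <- factor(rep(pr, c(length(ia), length(ib))), levels = pr)
    svm_fit <- e1071::svm(feats, y, kernel = "radial", gamma = gamma,
                          cost = cost, scale = FALSE)
    list(pair = pr, bank = bank, svm = svm_fit)
  })
  structure(list(fits = fits, levels = levs, m = m, cost = cost,
                 gamma = gamma, montage = ts_montage(train)),
            class = "csp_svm")
}

#' @export
print.csp_svm <- function(x, ...) {
  cat(sprintf(
    "<csp_svm> %d classes, %d pairwise banks/classifiers (m = %d, c = %g, g = %g)\n",
    length(x$levels), length(x$fits), x$m, x$cost, x$gamma))
  invisible(x)
}

#' Predict verb labels by pairwise majority vote
#'
#' Each pairwise classifier extracts its own bank's features from the trial
#' and votes for one of its two classes; the predicted label is the class
#' with the most votes. Ties are broken by the summed absolute SVM decision
#' margins of the tied classes' votes.
#'
#' @param object A fitted [fit_csp_svm()] model.
#' @param newdata A [trial_set()] of trials to classify.
#' @param ... Unused.
#' @return Tibble with `trial_id`, `.pred_class`, and one `votes_<label>`
#'   column per class (vote counts sum to the number of pairs).
#' @export
predict.csp_svm <- function(object, newdata, ...) {
  n <- nrow(newdata)
  levs <- object$levels
  votes <- matrix(0L, n, length(levs), dimnames = list(NULL, levs))
  margins <- matrix(0, n, length(levs), dimnames = list(NULL, levs))
  for (fit in object$fits) {
    feats <- t(vapply(newdata$data, csp_features,
                      numeric(2 * object$m), bank = fit$bank))
    pred <- predict(fit$svm, feats, decision.values = TRUE)
    dv <- abs(as.numeric(attr(pred, "decision.values")))
    pred <- as.character(pred)
    for (i in seq_len(n)) {
      votes[i, pred[i]] <- votes[i, pred[i]] + 1L
      margins[i, pred[i]] <- margins[i, pred[i]] + dv[i]
    }
  }
  winner <- vapply(seq_len(n), function(i) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1) top <- top[which.max(margins[i, top])]
    levs[top]
  }, character(1))
  out <- tibble(trial_id = newdata$trial_id,
                .pred_class = factor(winner, levels = levs))
  votes_tbl <- as_tibble(as.data.frame(votes))
  names(votes_tbl) <- paste0("votes_", levs)
  dplyr::bind_cols(out, votes_tbl)
}
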