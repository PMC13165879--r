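#' Tidy and glance at a fitted one-vs-one CSP model
#'
#' @param x A [fit_csp_svm()] object.
#' @param ... Unused.
#' @return `tidy()`: one row per (pair, filter) with the CSP eigenvalue and
#'   the number of support vectors of the pair's classifier. `glance()`: a
#'   one-row summary (class count, pair count, hyperparameters).
#' @export
tidy.csp_svm <- function(x, ...) {
  purrr::map_dfr(x$fits, function(f) {
    tibble(class_a = f$pair[1], class_b = f$pair[2],
           filter = seq_along(f$bank$eigenvalues),
           eigenvalue = f$bank$eigenvalues,
           n_support = f$svm$tot.nSV)
  })
}

#' @rdname tidy.csp_svm
#' @export
glance.csp_svm <- function(x, ...) {
  tibble(n_classes = length(x$levels), n_pairs = length(x$fits),
         m = x$m, cost = x$cost, gamma = x$gamma,
         n_features = 2 * x$m)
}

#' Tidy and glance at a fitted dual-LSTM model
#'
#' @param x A [fit_dual_lstm()] object.
#' @param ... Unused.
#' @return `tidy()`: the per-epoch training trace (epoch, loss, train_acc,
#'   val_acc). `glance()`: one-row summary with the final loss/accuracy,
#'   parameter count and configuration.
#' @export
tidy.dual_lstm <- function(x, ...) {
  x$trace
}

#' @rdname tidy.dual_lstm
#' @export
glance.dual_lstm <- function(x, ...) {
  last <- tail(x$trace, 1)
  tibble(epochs = nrow(x$trace), final_loss = last$loss,
         final_train_acc = last$train_acc, final_val_acc = last$val_acc,
         n_parameters = length(params_flatten(x$net$params)),
         learning_rate = x$config$learning_rate,
         lr_mode = x$config$lr_mode, seed = x$config$seed)
}
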