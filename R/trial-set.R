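#' Construct a trial set
#'
#' A trial set is a tibble with one row per epoched trial and a `data`
#' list-column of channels x time matrices (rows named by the montage), plus
#' `subject`, `block`, `class` and `trial_id` metadata columns. All tidyverse
#' verbs apply; the montage and sampling rate ride along as attributes and are
#' recovered from the matrices themselves if a verb drops them.
#'
#' @param meta Tibble of per-trial metadata (must contain `subject` and
#'   `class`; `trial_id` is added if absent).
#' @param data List of channels x time numeric matrices, one per row of `meta`.
#' @param montage Character vector of channel names (matrix row order).
#' @param sample_rate Sampling rate in Hz.
#' @return A `trial_set` tibble.
#' @export
trial_set <- function(meta, data, montage, sample_rate) {
  stopifnot(nrow(meta) == length(data))
  if (!all(c("subject", "class") %in% names(meta))) {
    abort("trial metadata needs `subject` and `class` columns")
  }
  dims <- vapply(data, dim, integer(2))
  if (length(data) > 0 && (any(dims[1, ] != length(montage)) ||
                           any(dims[2, ] != dims[2, 1]))) {
    abort("all trial matrices must be n_channels x n_samples with a shared shape")
  }
  data <- lapply(data, function(m) { rownames(m) <- montage; m })
  out <- meta
  if (!"trial_id" %in% names(out)) out$trial_id <- seq_len(nrow(out))
  out$data <- data
  new_trial_set(as_tibble(out), montage, sample_rate)
}

new_trial_set <- function(tbl, montage, sample_rate) {
  structure(tbl,
            class = c("trial_set", class(as_tibble(tbl))),
            montage = montage, sample_rate = sample_rate)
}

#' Montage and sampling rate of a trial set
#'
#' @param ts A `trial_set` (or any tibble with a `data` list-column of
#'   matrices whose rownames are channel labels).
#' @return `ts_montage()`: character vector of channel names;
#'   `ts_sample_rate()`: sampling rate in Hz.
#' @export
ts_montage <- function(ts) {
  m <- attr(ts, "montage")
  if (!is.null(m)) return(m)
  if (nrow(ts) > 0) return(rownames(ts$data[[1]]))
  abort("cannot determine montage of an empty trial set")
}

#' @rdname ts_montage
#' @export
ts_sample_rate <- function(ts) {
  sr <- attr(ts, "sample_rate")
  if (is.null(sr)) 250 else sr
}

#' @export
print.trial_set <- function(x, ...) {
  nch <- if (nrow(x) > 0) nrow(x$data[[1]]) else length(attr(x, "montage"))
  nt <- if (nrow(x) > 0) ncol(x$data[[1]]) else NA_integer_
  cat(sprintf("<trial_set> %d trials, %d channels x %s samples @ %g Hz\n",
              nrow(x), nch, nt, ts_sample_rate(x)))
  NextMethod()
}

# rebuild trial_set attributes after dplyr manipulation
restore_ts <- function(tbl, template) {
  new_trial_set(as_tibble(tbl), ts_montage(template), ts_sample_rate(template))
}

# stack the data column into trials x channels x time array
ts_array <- function(ts) {
  n <- nrow(ts)
  d <- dim(ts$data[[1]])
  arr <- array(0, c(n, d[1], d[2]))
  for (i in seq_len(n)) arr[i, , ] <- ts$data[[i]]
  arr
}

# class column as a factor, preserving pre-set levels
ts_class_factor <- function(ts) {
  cl <- ts$class
  if (is.factor(cl)) cl else factor(cl)
}
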