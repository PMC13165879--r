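#' Write and read a trial-set container
#'
#' Self-describing on-disk layout for simulated or preprocessed datasets:
#' per subject, a JSON sidecar (array dimensions, channel names, sampling
#' rate, labels, blocks) plus a float64 little-endian payload holding the
#' trials x channels x time array in trial-major order, and a plain-text
#' `manifest.tsv` with one row per trial (subject, block, class, file,
#' offset).
#'
#' @param ts A [trial_set()].
#' @param dir Output directory (created if needed).
#' @param path Directory written by `write_trial_set()`.
#' @return `write_trial_set()`: `dir`, invisibly. `read_trial_set()`: the
#'   reconstructed [trial_set()].
#' @export
write_trial_set <- function(ts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  montage <- ts_montage(ts)
  sr <- ts_sample_rate(ts)
  manifest <- vector("list", 0)
  for (s in sort(unique(ts$subject))) {
    rows <- which(ts$subject == s)
    sub <- ts[rows, ]
    d <- dim(sub$data[[1]])
    bin <- sprintf("subject%03d.bin", s)
    meta <- list(subject = s, n_trials = length(rows),
                 n_channels = d[1], n_samples = d[2],
                 channels = montage, sample_rate = sr,
                 labels = as.character(sub$class),
                 blocks = if ("block" %in% names(sub)) sub$block else
                   rep(NA_integer_, length(rows)),
                 payload = bin, dtype = "float64-le")
    if ("mfcc" %in% names(sub)) {
      meta$mfcc_payload <- sprintf("subject%03d_mfcc.bin", s)
      meta$mfcc_frames <- vapply(sub$mfcc, nrow, integer(1))
      meta$mfcc_coeffs <- if (nrow(sub$mfcc[[1]]) > 0) ncol(sub$mfcc[[1]]) else 13L
      conm <- file(file.path(dir, meta$mfcc_payload), "wb")
      for (m in sub$mfcc) writeBin(as.numeric(m), conm, size = 8,
                                   endian = "little")
      close(conm)
    }
    jsonlite::write_json(meta, file.path(dir, sprintf("subject%03d.json", s)),
                         auto_unbox = TRUE, digits = NA)
    con <- file(file.path(dir, bin), "wb")
    for (m in sub$data) writeBin(as.numeric(m), con, size = 8,
                                 endian = "little")
    close(con)
    manifest[[length(manifest) + 1]] <- tibble(
      trial_id = sub$trial_id, subject = s, block = meta$blocks,
      class = as.character(sub$class), file = bin,
      offset = (seq_along(rows) - 1) * d[1] * d[2] * 8)
  }
  man <- dplyr::bind_rows(manifest)
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_trial_set
#' @export
read_trial_set <- function(path) {
  man <- utils::read.delim(file.path(path, "manifest.tsv"))
  jsons <- sort(list.files(path, pattern = "^subject[0-9]+\\.json$",
                           full.names = TRUE))
  if (length(jsons) == 0) abort("no subject sidecar files found")
  parts <- lapply(jsons, function(j) {
    meta <- jsonlite::read_json(j, simplifyVector = TRUE)
    con <- file(file.path(path, meta$payload), "rb")
    on.exit(close(con))
    per <- meta$n_channels * meta$n_samples
    data <- lapply(seq_len(meta$n_trials), function(i) {
      matrix(readBin(con, "numeric", per, size = 8, endian = "little"),
             meta$n_channels, meta$n_samples)
    })
    labels <- factor(meta$labels, levels = unique(man$class))
    mfccs <- NULL
    if (!is.null(meta$mfcc_payload)) {
      conm <- file(file.path(path, meta$mfcc_payload), "rb")
      mfccs <- lapply(meta$mfcc_frames, function(fr) {
        matrix(readBin(conm, "numeric", fr * meta$mfcc_coeffs, size = 8,
                       endian = "little"), fr, meta$mfcc_coeffs)
      })
      close(conm)
    }
    list(meta = tibble(subject = meta$subject, block = meta$blocks,
                       class = labels),
         data = data, mfcc = mfccs, channels = meta$channels,
         sample_rate = meta$sample_rate)
  })
  meta <- dplyr::bind_rows(lapply(parts, `[[`, "meta"))
  labels <- sort(unique(as.character(meta$class)))
  lev <- if (setequal(labels, verb_labels())) verb_labels() else labels
  meta$class <- factor(as.character(meta$class), levels = lev)
  meta$trial_id <- man$trial_id
  out <- trial_set(meta, unlist(lapply(parts, `[[`, "data"), recursive = FALSE),
                   parts[[1]]$channels, parts[[1]]$sample_rate)
  if (!is.null(parts[[1]]$mfcc)) {
    out$mfcc <- unlist(lapply(parts, `[[`, "mfcc"), recursive = FALSE)
  }
  out
}

pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write and read European Data Format (EDF) recordings
#'
#' Minimal EDF support for interoperability: continuous 16-bit recordings,
#' one data record per second, per-channel physical scaling from the data
#' range. Events are not stored (plain EDF has no annotation channel).
#'
#' @param recording A [raw_recording()]; samples not filling a whole final
#'   data record are zero-padded.
#' @param path File path.
#' @return `write_edf()`: the path, invisibly. `read_edf()`: a
#'   [raw_recording()] with an empty event table.
#' @export
write_edf <- function(recording, path) {
  m <- recording$samples
  ns <- nrow(m)
  sr <- as.integer(round(recording$sample_rate))
  n_rec <- ceiling(ncol(m) / sr)
  if (ncol(m) < n_rec * sr) {
    m <- cbind(m, matrix(0, ns, n_rec * sr - ncol(m)))
  }
  pmin_ <- apply(m, 1, min); pmax_ <- apply(m, 1, max)
  pmax_ <- ifelse(pmax_ > pmin_, pmax_, pmin_ + 1)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeChar(pad_ascii(x, w), con, eos = NULL)
  wr("0", 8); wr("synthetic subject", 80); wr("eegverbs recording", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 + ns * 256, 8); wr("", 44); wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  for (f in list(list(recording$channel_names, 16),
                 list(rep("synthetic EEG", ns), 80),
                 list(rep("uV", ns), 8),
                 list(sprintf("%.6g", pmin_), 8),
                 list(sprintf("%.6g", pmax_), 8),
                 list(rep("-32768", ns), 8),
                 list(rep("32767", ns), 8),
                 list(rep("", ns), 80),
                 list(rep(sr, ns), 8),
                 list(rep("", ns), 32))) {
    for (v in f[[1]]) wr(v, f[[2]])
  }
  scale <- (pmax_ - pmin_) / (32767 - (-32768))
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * sr + 1):(r * sr)
    for (ch in seq_len(ns)) {
      dig <- round((m[ch, idx] - pmin_[ch]) / scale[ch] + (-32768))
      writeBin(as.integer(pmin(32767, pmax(-32768, dig))), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_edf
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8)); dur <- as.numeric(rd(8)); ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)  # transducer
  for (i in seq_len(ns)) rd(8)   # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)  # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  out <- lapply(seq_len(ns), function(i) numeric(0))
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      phys <- pmin_[ch] + (dig - dmin[ch]) *
        (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch])
      out[[ch]] <- c(out[[ch]], phys)
    }
  }
  raw_recording(do.call(rbind, out), labels, spr[1] / dur)
}
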