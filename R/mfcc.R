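#' Mel frequency scale
#'
#' The standard mel map `mel(f) = 2595 log10(1 + f/700)` and its inverse.
#'
#' @param f Frequency in Hz.
#' @param m Frequency in mel.
#' @return `hz_to_mel()`: mel value; `mel_to_hz()`: Hz value.
#' @export
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)

#' @rdname hz_to_mel
#' @export
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank
#'
#' Builds `n_filters` triangular filters with peaks equally spaced on the mel
#' scale between `f_low` and `f_high`, evaluated on the positive-frequency
#' bins of an `n_fft`-point FFT. Adjacent filters overlap so every interior
#' bin in the band receives nonzero weight.
#'
#' @param n_filters Number of filters (default 26).
#' @param n_fft FFT length.
#' @param sample_rate Sampling rate in Hz.
#' @param f_low,f_high Band edges in Hz (`f_high <= sample_rate/2`).
#' @return `n_filters` x `(n_fft/2 + 1)` matrix of nonnegative weights.
#' @export
mel_filterbank <- function(n_filters = 26, n_fft = 1024, sample_rate = 24000,
                           f_low = 0, f_high = sample_rate / 2) {
  if (f_high > sample_rate / 2) abort("f_high must not exceed Nyquist")
  n_bins <- n_fft %/% 2 + 1
  mel_pts <- seq(hz_to_mel(f_low), hz_to_mel(f_high), length.out = n_filters + 2)
  hz_pts <- mel_to_hz(mel_pts)
  bin_pts <- floor((n_fft + 1) * hz_pts / sample_rate)
  if (any(diff(bin_pts) < 1)) {
    abort("n_filters too large for this n_fft / band: filters collapse onto one bin")
  }
  fb <- matrix(0, n_filters, n_bins)
  for (j in seq_len(n_filters)) {
    l <- bin_pts[j]; c <- bin_pts[j + 1]; r <- bin_pts[j + 2]
    for (k in seq.int(l, c)) if (c > l) fb[j, k + 1] <- (k - l) / (c - l)
    for (k in seq.int(c, r)) if (r > c) fb[j, k + 1] <- (r - k) / (r - c)
  }
  fb
}

# orthonormal DCT-II basis, rows = cepstral index 0..(n_out-1)
dct_basis <- function(n_out, n_in) {
  b <- matrix(0, n_out, n_in)
  for (k in seq_len(n_out) - 1) {
    b[k + 1, ] <- cos(pi * k * (2 * seq_len(n_in) - 1) / (2 * n_in))
  }
  b <- b * sqrt(2 / n_in)
  b[1, ] <- b[1, ] / sqrt(2)
  b
}

#' Extract Mel-Frequency Cepstral Coefficients
#'
#' The standard six-stage MFCC pipeline used as the reference acoustic
#' representation of the spoken verbs: pre-emphasis, framing, windowing
#' (Hamming), FFT power spectrum, mel filterbank log-energies, and an
#' orthonormal DCT-II keeping the first `n_mfcc` coefficients.
#'
#' @param samples Mono audio amplitude vector.
#' @param sample_rate Sampling rate in Hz (24000 for the study's microphone
#'   channel).
#' @param frame_length_s,frame_step_s Frame length and hop in seconds
#'   (defaults 25 ms / 10 ms).
#' @param n_mfcc Cepstral coefficients kept per frame (default 13).
#' @param n_filters Mel filters (default 26).
#' @param n_fft FFT length; default the next power of two >= frame length.
#' @param pre_emphasis First-difference pre-emphasis coefficient
#'   (default 0.97; 0 disables).
#' @param f_low,f_high Filterbank band edges in Hz.
#' @param log_floor Floor applied inside the log of the filterbank energies
#'   (default 1e-10).
#' @return An object of class `mfcc_matrix`: a frames x `n_mfcc` matrix with
#'   attributes `sample_rate`, `frame_length_s`, `frame_step_s`. Audio
#'   shorter than one frame yields a 0-row matrix with a warning.
#' @export
mfcc <- function(samples, sample_rate = 24000, frame_length_s = 0.025,
                 frame_step_s = 0.010, n_mfcc = 13, n_filters = 26,
                 n_fft = NULL, pre_emphasis = 0.97, f_low = 0,
                 f_high = sample_rate / 2, log_floor = 1e-10) {
  if (length(samples) == 0) abort("audio is empty")
  frame_len <- round(frame_length_s * sample_rate)
  step <- round(frame_step_s * sample_rate)
  if (is.null(n_fft)) n_fft <- 2^ceiling(log2(frame_len))
  if (length(samples) < frame_len) {
    warn("audio shorter than one frame; returning an empty MFCC matrix")
    out <- matrix(numeric(0), 0, n_mfcc)
    return(structure(out, class = c("mfcc_matrix", class(out)),
                     sample_rate = sample_rate,
                     frame_length_s = frame_length_s,
                     frame_step_s = frame_step_s))
  }
  x <- samples
  if (pre_emphasis > 0) x <- c(x[1], x[-1] - pre_emphasis * x[-length(x)])
  n_frames <- floor((length(x) - frame_len) / step) + 1
  win <- 0.54 - 0.46 * cos(2 * pi * (seq_len(frame_len) - 1) / (frame_len - 1))
  fb <- mel_filterbank(n_filters, n_fft, sample_rate, f_low, f_high)
  dct <- dct_basis(n_mfcc, n_filters)
  coeffs <- matrix(0, n_frames, n_mfcc)
  for (i in seq_len(n_frames)) {
    fr <- x[((i - 1) * step + 1):((i - 1) * step + frame_len)] * win
    spec <- fft(c(fr, rep(0, n_fft - frame_len)))
    power <- Mod(spec[seq_len(n_fft %/% 2 + 1)])^2 / n_fft
    loge <- log(pmax(fb %*% power, log_floor))
    coeffs[i, ] <- as.numeric(dct %*% loge)
  }
  structure(coeffs, class = c("mfcc_matrix", class(coeffs)),
            sample_rate = sample_rate, frame_length_s = frame_length_s,
            frame_step_s = frame_step_s)
}

#' @export
print.mfcc_matrix <- function(x, ...) {
  cat(sprintf("<mfcc_matrix> %d frames x %d coefficients (%g ms / %g ms)\n",
              nrow(x), ncol(x), attr(x, "frame_length_s") * 1000,
              attr(x, "frame_step_s") * 1000))
  invisible(x)
}

#' Read and write mono PCM WAV files
#'
#' Minimal RIFF/WAVE support for the study's 24 kHz mono microphone channel:
#' 16-bit integer PCM, single channel. Samples are scaled to [-1, 1] on read.
#'
#' @param path File path.
#' @param samples Numeric vector in [-1, 1].
#' @param sample_rate Sampling rate in Hz.
#' @return `read_wav()`: list with `samples` and `sample_rate`;
#'   `write_wav()`: the path, invisibly.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (hdr != "RIFF") abort("not a RIFF/WAVE file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (readChar(con, 4, useBytes = TRUE) != "WAVE") abort("not a WAVE file")
  sample_rate <- NULL; bits <- NULL; n_chan <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, 2, endian = "little")
      n_chan <- fmt[2]
      sample_rate <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little"))
      invisible(readBin(con, "integer", 1, 2, endian = "little"))
      bits <- readBin(con, "integer", 1, 2, endian = "little")
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (id == "data") {
      if (bits != 16 || n_chan != 1) abort("only 16-bit mono PCM supported")
      samples <- readBin(con, "integer", size / 2, 2,
                         signed = TRUE, endian = "little") / 32768
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(samples)) abort("no data chunk found")
  list(samples = samples, sample_rate = sample_rate)
}

#' @rdname read_wav
#' @export
write_wav <- function(samples, sample_rate, path) {
  pcm <- as.integer(pmax(-32768, pmin(32767, round(samples * 32767))))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")       # PCM, mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate) * 2L, con, size = 4, endian = "little")
  writeBin(c(2L, 16L), con, size = 2, endian = "little")      # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Attach per-trial MFCC reference features to a trial set
#'
#' Computes the MFCC matrix of each trial's time-aligned spoken-verb audio
#' and stores it in an `mfcc` list-column keyed by the trial rows, so the
#' reference acoustic representation travels with the EEG epochs (and through
#' [write_trial_set()] / [read_trial_set()]). The features do not enter the
#' decoders' training loss.
#'
#' @param ts A [trial_set()].
#' @param audio List of mono amplitude vectors, one per trial row.
#' @param sample_rate Audio sampling rate in Hz (default 24000).
#' @param ... Further arguments to [mfcc()].
#' @return The trial set with an added `mfcc` list-column.
#' @export
attach_mfcc <- function(ts, audio, sample_rate = 24000, ...) {
  if (length(audio) != nrow(ts)) {
    abort("need one audio segment per trial")
  }
  out <- ts
  out$mfcc <- lapply(audio, mfcc, sample_rate = sample_rate, ...)
  restore_ts(out, ts)
}
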