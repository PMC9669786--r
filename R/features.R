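# Amplitude normalization, framing and MFCC feature extraction.

#' Normalize 16-bit samples to [-1, 1]
#'
#' Divides by 2^15 so that every quantization code maps inside the unit
#' interval, with -1 attained only at full negative scale (-32768).  The
#' map is linear and bijective on the integer grid.
#'
#' @param samples integer (or bs_recording) 16-bit samples.
#' @return numeric vector in \[-1, 1\].
#' @export
normalize_amplitude <- function(samples) {
  if (inherits(samples, "bs_recording")) samples <- samples$samples
  assert_that(is.numeric(samples) && !anyNA(samples),
              "samples must be numeric without NAs")
  assert_that(all(samples >= -32768) && all(samples <= 32767) &&
                all(samples == trunc(samples)),
              "samples must be integers in [-32768, 32767]")
  samples / 32768
}

#' Slice a signal into fixed-length frames
#'
#' Frames of `frame_length_s` seconds advancing by `hop_s`; the trailing
#' partial frame is dropped.  A signal shorter than one frame yields zero
#' frames.
#'
#' @param signal numeric vector.
#' @param frame_length_s frame length in seconds (>= hop_s).
#' @param hop_s hop in seconds (> 0).
#' @param sample_rate_hz sampling rate.
#' @return matrix with one row per frame (`frame_length` columns).
#' @export
frame_signal <- function(signal, frame_length_s = 0.025, hop_s = 0.010,
                         sample_rate_hz = 4000) {
  assert_that(hop_s > 0 && frame_length_s >= hop_s,
              "need frame_length_s >= hop_s > 0")
  L <- round(frame_length_s * sample_rate_hz)
  H <- round(hop_s * sample_rate_hz)
  n <- length(signal)
  if (n < L) return(matrix(numeric(0), nrow = 0, ncol = L))
  n_frames <- (n - L) %/% H + 1L
  idx <- outer(seq_len(L), (seq_len(n_frames) - 1L) * H, `+`)
  t(matrix(signal[idx], nrow = L))
}

# HTK mel scale
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Mel filterbank matrix
#'
#' Triangular filters equally spaced on the HTK mel scale between `fmin`
#' and `fmax`, evaluated on the positive-frequency FFT bins.
#'
#' @param n_mels number of filters.
#' @param n_fft FFT size.
#' @param sample_rate_hz sampling rate.
#' @param fmin,fmax filterbank edge frequencies in Hz.
#' @return `n_mels` x `(n_fft/2 + 1)` matrix of filter weights.
#' @export
mel_filterbank <- function(n_mels = 26, n_fft = 128, sample_rate_hz = 4000,
                           fmin = 50, fmax = 2000) {
  assert_that(fmax <= sample_rate_hz / 2 + 1e-9,
              "fmax must not exceed the Nyquist frequency")
  n_bins <- n_fft %/% 2 + 1L
  bin_hz <- (seq_len(n_bins) - 1) * sample_rate_hz / n_fft
  edges <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2))
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; ctr <- edges[m + 1]; hi <- edges[m + 2]
    up <- (bin_hz - lo) / (ctr - lo)
    down <- (hi - bin_hz) / (hi - ctr)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# orthonormal type-II DCT matrix (n_coeffs x n_mels)
dct_matrix <- function(n_coeffs, n_mels) {
  k <- seq_len(n_coeffs) - 1
  m <- seq_len(n_mels) - 1
  D <- sqrt(2 / n_mels) * cos(outer(k, m + 0.5) * pi / n_mels)
  D[1, ] <- D[1, ] / sqrt(2)
  D
}

#' MFCC features
#'
#' Per frame: Hann window, zero-padded power spectrum, mel filterbank
#' (HTK scale), floored log, orthonormal type-II DCT, keeping the first
#' `n_coeffs` coefficients.  Input may be a normalized signal vector, a
#' frame matrix from [frame_signal()], or a `bs_recording` (normalized
#' internally).
#'
#' @param x signal vector, frame matrix or `bs_recording`.
#' @param sample_rate_hz sampling rate.
#' @param frame_length_s,hop_s frame geometry (used when `x` is a signal).
#' @param n_mels number of mel filters.
#' @param n_coeffs number of cepstral coefficients kept (<= n_mels).
#' @param fmin,fmax filterbank edges in Hz.
#' @param log_floor floor applied inside the log.
#' @return a `bs_features` matrix, frames x coefficients, with the frame
#'   geometry stored as attributes.
#' @export
mfcc <- function(x, sample_rate_hz = 4000, frame_length_s = 0.025,
                 hop_s = 0.010, n_mels = 26, n_coeffs = 13,
                 fmin = 50, fmax = 2000, log_floor = 1e-10) {
  assert_that(n_coeffs <= n_mels, "n_coeffs must not exceed n_mels")
  if (inherits(x, "bs_recording")) {
    sample_rate_hz <- x$sample_rate_hz
    x <- normalize_amplitude(x$samples)
  }
  frames <- if (is.matrix(x)) x else
    frame_signal(x, frame_length_s, hop_s, sample_rate_hz)
  L <- ncol(frames)
  n_fft <- 2^ceiling(log2(max(L, 2)))
  win <- hann_window(L)
  n_frames <- nrow(frames)
  n_bins <- n_fft %/% 2 + 1L
  if (n_frames == 0L) {
    out <- matrix(numeric(0), 0, n_coeffs)
  } else {
    padded <- matrix(0, n_fft, n_frames)
    padded[seq_len(L), ] <- t(frames) * win
    spec <- stats::mvfft(padded)[seq_len(n_bins), , drop = FALSE]
    power <- Re(spec)^2 + Im(spec)^2
    fb <- mel_filterbank(n_mels, n_fft, sample_rate_hz, fmin, fmax)
    logmel <- log(pmax(fb %*% power, log_floor))
    out <- t(dct_matrix(n_coeffs, n_mels) %*% logmel)
  }
  structure(out, class = c("bs_features", "matrix", "array"),
            frame_length_s = frame_length_s, hop_s = hop_s,
            sample_rate_hz = sample_rate_hz, n_mels = n_mels,
            n_coeffs = n_coeffs, n_fft = n_fft)
}

#' @export
print.bs_features <- function(x, ...) {
  cat(sprintf("<bs_features> %d frames x %d coefficients (frame %.0f ms, hop %.0f ms)\n",
              nrow(x), ncol(x), attr(x, "frame_length_s") * 1e3,
              attr(x, "hop_s") * 1e3))
  invisible(x)
}
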