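# Minimal PCM 16-bit mono RIFF/WAVE reader and writer (readBin/writeBin).

#' Read a PCM WAV file
#'
#' Supports uncompressed PCM, mono, 16-bit files only; anything else
#' (stereo, float, 8-bit, compressed) raises an unsupported-format error.
#' A data chunk shorter than its declared length raises a truncation error.
#' Sample rates other than 4000 Hz are accepted with a warning.
#'
#' @param path file path.
#' @param site,infant_id metadata attached to the returned recording.
#' @return a `bs_recording`.
#' @export
read_wav <- function(path, site = "abdomen_rlq", infant_id = NA_character_) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  assert_that(identical(riff, "RIFF"), "not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  assert_that(identical(wave, "WAVE"), "not a WAVE file")
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (!nzchar(id) || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", size)
      to_u16 <- function(off) as.integer(raw_fmt[off + 1]) +
        256L * as.integer(raw_fmt[off + 2])
      to_u32 <- function(off) sum(as.integer(raw_fmt[off + 1:4]) *
                                    c(1, 256, 65536, 16777216))
      fmt <- list(audio_format = to_u16(0), n_channels = to_u16(2),
                  sample_rate = to_u32(4), bits = to_u16(14))
    } else if (identical(id, "data")) {
      assert_that(!is.null(fmt), "data chunk before fmt chunk")
      assert_that(fmt$audio_format == 1L,
                  "unsupported format: only uncompressed PCM WAV is supported")
      assert_that(fmt$n_channels == 1L,
                  "unsupported format: only mono WAV is supported")
      assert_that(fmt$bits == 16L,
                  "unsupported format: only 16-bit WAV is supported")
      n_samp <- size %/% 2L
      samples <- readBin(con, "integer", n_samp, 2, signed = TRUE,
                         endian = "little")
      assert_that(length(samples) == n_samp,
                  "truncated WAV: data chunk shorter than declared")
      break
    } else {
      invisible(readBin(con, "raw", size + (size %% 2L)))
    }
  }
  assert_that(!is.null(samples), "no data chunk found")
  if (fmt$sample_rate != 4000L)
    warning(sprintf("sample rate %d Hz differs from the canonical 4000 Hz",
                    fmt$sample_rate), call. = FALSE)
  audio_recording(samples, fmt$sample_rate, site, infant_id)
}

#' Write a recording as PCM 16-bit mono WAV
#'
#' @param recording a `bs_recording` (or integer sample vector).
#' @param path output path.
#' @param sample_rate_hz sampling rate (taken from the recording if given).
#' @export
write_wav <- function(recording, path, sample_rate_hz = 4000) {
  if (inherits(recording, "bs_recording")) {
    samples <- recording$samples
    sample_rate_hz <- recording$sample_rate_hz
  } else {
    samples <- as.integer(recording)
  }
  assert_that(all(samples >= -32768L) && all(samples <= 32767L),
              "samples must fit 16-bit signed range")
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(samples)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")                  # PCM
  writeBin(1L, con, 2, endian = "little")                  # mono
  writeBin(as.integer(sample_rate_hz), con, 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * 2L), con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little")                  # block align
  writeBin(16L, con, 2, endian = "little")                 # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4, endian = "little")
  writeBin(samples, con, 2, endian = "little")
  invisible(path)
}
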