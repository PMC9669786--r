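# Waveform synthesis and recording rendering.

#' Audio recording container
#'
#' Holds one mono PCM recording: 16-bit integer samples, sample rate, the
#' recording site and an optional infant identifier.
#'
#' @param samples integer vector of 16-bit signed samples.
#' @param sample_rate_hz sampling rate in Hz (canonical 4000).
#' @param site one of `"abdomen_rlq"`, `"chest_left"`, `"blank"`.
#' @param infant_id optional identifier.
#' @return object of class `bs_recording` with derived `duration_s`.
#' @export
audio_recording <- function(samples, sample_rate_hz = 4000,
                            site = "abdomen_rlq", infant_id = NA_character_) {
  assert_that(site %in% SITES,
              sprintf("site must be one of: %s", paste(SITES, collapse = ", ")))
  assert_number(sample_rate_hz, "sample_rate_hz", lower = 1)
  samples <- as.integer(samples)
  assert_that(!anyNA(samples) && all(samples >= -32768L) && all(samples <= 32767L),
              "samples must be 16-bit signed integers in [-32768, 32767]")
  structure(list(samples = samples,
                 sample_rate_hz = as.integer(sample_rate_hz),
                 site = site,
                 infant_id = infant_id,
                 duration_s = length(samples) / sample_rate_hz),
            class = "bs_recording")
}

#' @export
print.bs_recording <- function(x, ...) {
  cat(sprintf("<bs_recording> %s | %.1f s @ %d Hz | site %s\n",
              if (is.na(x$infant_id)) "(no id)" else x$infant_id,
              x$duration_s, x$sample_rate_hz, x$site))
  invisible(x)
}

# Hann window (periodic endpoints handled by symmetric form; events are
# tapered to zero at both ends)
hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

# core synthesis using the current RNG stream
synth_event_core <- function(event, sample_rate_hz, noise_mix = 0.3) {
  f <- event$dom_freq_hz
  amp <- event$peak_amp_norm
  nyq <- sample_rate_hz / 2
  assert_that(is.finite(f) && f > 0 && f < nyq,
              "event dominant frequency must lie below the Nyquist frequency")
  assert_that(is.finite(amp) && amp > 0 && amp <= 1,
              "event peak amplitude must lie in (0, 1]")
  n <- round((event$offset_s - event$onset_s) * sample_rate_hz)
  if (n < 1L) return(numeric(0))
  env <- hann_window(n)
  t_idx <- (seq_len(n) - 1) / sample_rate_hz
  carrier <- sin(2 * pi * f * t_idx + stats::runif(1, 0, 2 * pi))
  x <- carrier
  # third-octave band noise centred on the dominant frequency
  if (n >= 16L && noise_mix > 0) {
    lo <- f / 2^(1 / 6)
    hi <- min(f * 2^(1 / 6), 0.98 * nyq)
    bf <- signal::butter(2, c(lo, hi) / nyq, type = "pass")
    bn <- signal::filtfilt(bf, stats::rnorm(n))
    peak <- max(abs(bn))
    if (peak > 0) x <- x + noise_mix * bn / peak
  }
  x <- env * x
  peak <- max(abs(x))
  if (peak > 0) x <- x * (amp / peak)
  x
}

#' Synthesize the waveform of one annotated event
#'
#' Renders a Hann-windowed narrow-band burst: an amplitude-modulated tone at
#' the event's dominant frequency mixed with third-octave band-limited
#' noise, scaled so the peak |sample| equals `peak_amp_norm` (within one
#' least-significant bit after 16-bit quantization).
#'
#' @param event a single-row event with `peak_amp_norm` and `dom_freq_hz` set.
#' @param sample_rate_hz sampling rate in Hz.
#' @param seed integer seed (tone phase and band noise).
#' @param noise_mix relative level of the band noise component.
#' @return numeric vector of normalized samples in \[-1, 1\], length
#'   `round((offset_s - onset_s) * sample_rate_hz)`.
#' @export
synthesize_event_waveform <- function(event, sample_rate_hz, seed,
                                      noise_mix = 0.3) {
  withr::with_seed(as.integer(seed),
                   synth_event_core(event, sample_rate_hz, noise_mix))
}

# heartbeat: periodic damped low-frequency thumps (< 200 Hz); breath:
# slow amplitude-modulated mid-band noise.  Both at modest level so leaked
# transients, not cardiac sounds, dominate chest-site detections.
heartbeat_breath <- function(n, sample_rate_hz, bpm,
                             beat_amp = 0.12, breath_rms = 0.008) {
  out <- numeric(n)
  period <- 60 / bpm
  beat_len <- round(0.09 * sample_rate_hz)
  t_beat <- (seq_len(beat_len) - 1) / sample_rate_hz
  thump <- exp(-t_beat / 0.025) * sin(2 * pi * 80 * t_beat)
  thump <- beat_amp * thump / max(abs(thump))
  starts <- seq(0.05, n / sample_rate_hz, by = period)
  starts <- starts + stats::rnorm(length(starts), 0, 0.01)
  for (s in starts) {
    i0 <- round(s * sample_rate_hz) + 1L
    i1 <- min(i0 + beat_len - 1L, n)
    if (i0 >= 1L && i0 <= n)
      out[i0:i1] <- out[i0:i1] + thump[seq_len(i1 - i0 + 1L)]
  }
  nyq <- sample_rate_hz / 2
  bf <- signal::butter(2, c(300, 600) / nyq, type = "pass")
  br <- signal::filtfilt(bf, stats::rnorm(n))
  br <- br / stats::sd(br) * breath_rms
  mod <- 0.5 + 0.5 * sin(2 * pi * 0.4 * (seq_len(n) - 1) / sample_rate_hz)
  out + br * mod
}

#' Render a full recording from an event schedule
#'
#' Sums ambient incubator noise, every event waveform and (for the chest
#' control) heartbeat plus breath noise, then quantizes to 16-bit with
#' saturating clipping.  For the blank control the schedule must contain no
#' bowel-sound events; for the chest control bowel-sound events are
#' attenuated to zero (they are absent from the rendered audio and from the
#' returned ground truth).
#'
#' @param schedule `bs_events` ground-truth schedule (see
#'   [sample_event_schedule()]).
#' @param profile the generating [acoustic_profile()].
#' @param site recording site.
#' @param duration_s recording length in seconds.
#' @param sample_rate_hz sampling rate (canonical 4000).
#' @param seed integer seed.
#' @param infant_id optional identifier stored on the recording.
#' @return list with `recording` (a `bs_recording`) and `truth` (the
#'   ground-truth `bs_events` table of audible events).
#' @export
render_recording <- function(schedule, profile, site, duration_s,
                             sample_rate_hz = 4000, seed = 1L,
                             infant_id = NA_character_) {
  assert_that(site %in% SITES,
              sprintf("site must be one of: %s", paste(SITES, collapse = ", ")))
  assert_number(duration_s, "duration_s", lower = 1e-9)
  validate_events(schedule, duration_s)
  if (site == "blank")
    assert_that(!any(schedule$label == "bowel_sound"),
                "a blank-site schedule must contain no bowel_sound events")
  truth <- schedule
  if (site == "chest_left")
    truth <- truth[truth$label != "bowel_sound", , drop = FALSE]
  n <- round(duration_s * sample_rate_hz)
  withr::with_seed(as.integer(seed), {
    x <- stats::rnorm(n) * profile$ambient_noise_rms
    if (site == "chest_left" && isTRUE(profile$heartbeat$enabled))
      x <- x + heartbeat_breath(n, sample_rate_hz, profile$heartbeat$bpm)
    if (nrow(truth)) {
      for (i in seq_len(nrow(truth))) {
        w <- synth_event_core(truth[i, ], sample_rate_hz)
        if (!length(w)) next
        i0 <- round(truth$onset_s[i] * sample_rate_hz) + 1L
        i1 <- min(i0 + length(w) - 1L, n)
        if (i0 > n) next
        x[i0:i1] <- x[i0:i1] + w[seq_len(i1 - i0 + 1L)]
      }
    }
    n_clip <- sum(abs(x) > 1)
    if (n_clip > 0)
      warning(sprintf("render_recording: %d samples exceeded full scale and were clipped",
                      n_clip), call. = FALSE)
    q <- pmin(pmax(round(x * 32768), -32768), 32767)
    rec <- audio_recording(q, sample_rate_hz, site, infant_id)
    list(recording = rec, truth = events_table(truth$onset_s, truth$offset_s,
                                               truth$label, truth$peak_amp_norm,
                                               truth$dom_freq_hz))
  })
}

#' One-call synthetic recording
#'
#' Convenience wrapper: sample a schedule for `site`'s default (or a given)
#' profile and render it.
#'
#' @inheritParams render_recording
#' @param profile optional profile; defaults to [site_profile()] for `site`.
#' @return as [render_recording()].
#' @export
simulate_recording <- function(site = "abdomen_rlq", duration_s = 600,
                               sample_rate_hz = 4000, seed = 1L,
                               profile = NULL, infant_id = NA_character_) {
  if (is.null(profile)) profile <- site_profile(site)
  schedule <- sample_event_schedule(profile, duration_s, seed)
  render_recording(schedule, profile, site, duration_s, sample_rate_hz,
                   seed = seed + 1L, infant_id = infant_id)
}
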