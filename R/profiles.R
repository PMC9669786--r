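#' Acoustic generation profile
#'
#' Describes the statistical conditions of one monitored site: the rate of
#' bowel-sound bursts, the per-event duration / peak-amplitude /
#' dominant-frequency distributions, the rates of confounder sounds (speech
#' and friction), heartbeat and breath noise (chest control), and the
#' ambient incubator noise floor.
#'
#' Default parameter values are set to the acoustic characteristics observed
#' in term neonates: a median of about 25.8 bowel sounds per minute, a median
#' event duration near 0.37 s, peak normalized amplitudes with median 0.46,
#' and dominant frequencies centred near 944 Hz.
#'
#' @param event_rate expected bowel sounds per minute (>= 0).
#' @param duration_dist list with `median_s` (log-normal median, seconds) and
#'   `sdlog` (log standard deviation).
#' @param amplitude_dist list with Beta shape parameters `shape1`, `shape2`;
#'   support is (0, 1\].
#' @param dominant_freq_dist list with `mean_hz`, `sd_hz`, `min_hz`, `max_hz`
#'   (truncated normal); must stay below the Nyquist frequency.
#' @param confounder_rates named numeric vector, expected per-minute counts
#'   for `speech` and `friction_other` events.
#' @param heartbeat list with `enabled` flag and `bpm` (beats per minute).
#' @param ambient_noise_rms normalized RMS of the background noise floor.
#' @param min_gap_s refractory gap enforced between same-label events so the
#'   labelled event count equals the nominal Poisson count (see vignette).
#' @return an object of class `bs_profile`.
#' @export
acoustic_profile <- function(event_rate = 25.8,
                             duration_dist = list(median_s = 0.3668, sdlog = 0.4),
                             amplitude_dist = list(shape1 = 2, shape2 = 2.3),
                             dominant_freq_dist = list(mean_hz = 944, sd_hz = 138,
                                                       min_hz = 400, max_hz = 1800),
                             confounder_rates = c(speech = 0.5,
                                                  friction_other = 0.5),
                             heartbeat = list(enabled = FALSE, bpm = 130),
                             ambient_noise_rms = 0.01,
                             min_gap_s = 0.08) {
  assert_number(event_rate, "event_rate", lower = 0)
  assert_number(duration_dist$median_s, "duration_dist$median_s", lower = 1e-3)
  assert_number(duration_dist$sdlog, "duration_dist$sdlog", lower = 0)
  assert_number(amplitude_dist$shape1, "amplitude_dist$shape1", lower = 1e-6)
  assert_number(amplitude_dist$shape2, "amplitude_dist$shape2", lower = 1e-6)
  assert_number(dominant_freq_dist$mean_hz, "dominant_freq_dist$mean_hz",
                lower = 50, upper = 2000)
  assert_number(dominant_freq_dist$sd_hz, "dominant_freq_dist$sd_hz", lower = 0)
  assert_that(dominant_freq_dist$min_hz > 50 - 1e-9 &&
                dominant_freq_dist$max_hz < 2000 + 1e-9 &&
                dominant_freq_dist$min_hz < dominant_freq_dist$max_hz,
              "dominant frequency support must lie within (50, 2000) Hz")
  assert_that(all(confounder_rates >= 0) &&
                all(c("speech", "friction_other") %in% names(confounder_rates)),
              "confounder_rates must be non-negative and name speech and friction_other")
  assert_number(ambient_noise_rms, "ambient_noise_rms", lower = 0, upper = 0.5)
  assert_number(min_gap_s, "min_gap_s", lower = 0)
  structure(list(event_rate = event_rate,
                 duration_dist = duration_dist,
                 amplitude_dist = amplitude_dist,
                 dominant_freq_dist = dominant_freq_dist,
                 confounder_rates = confounder_rates,
                 heartbeat = heartbeat,
                 ambient_noise_rms = ambient_noise_rms,
                 min_gap_s = min_gap_s),
            class = "bs_profile")
}

#' Default per-site generation profiles
#'
#' * `abdomen_rlq` — the normal auscultation site: bowel-sound bursts at the
#'   default rate plus occasional speech and friction confounders.
#' * `chest_left` — the specificity control on the chest: heartbeat and
#'   breath noise present, bowel sounds attenuated to zero at render time,
#'   rare leaked friction transients.
#' * `blank` — sensor in the incubator space: ambient noise only.
#'
#' @param site one of `"abdomen_rlq"`, `"chest_left"`, `"blank"`.
#' @param ... overrides forwarded to [acoustic_profile()].
#' @return a `bs_profile`.
#' @export
site_profile <- function(site = c("abdomen_rlq", "chest_left", "blank"), ...) {
  site <- match.arg(site)
  switch(site,
         abdomen_rlq = acoustic_profile(...),
         chest_left = acoustic_profile(
           confounder_rates = c(speech = 0.5, friction_other = 1.0),
           heartbeat = list(enabled = TRUE, bpm = 130), ...),
         blank = acoustic_profile(
           event_rate = 0,
           confounder_rates = c(speech = 0, friction_other = 0), ...))
}

#' @export
print.bs_profile <- function(x, ...) {
  cat("Acoustic generation profile\n")
  cat(sprintf("  bowel-sound rate: %.2f /min, duration median %.3f s (sdlog %.2f)\n",
              x$event_rate, x$duration_dist$median_s, x$duration_dist$sdlog))
  cat(sprintf("  amplitude ~ Beta(%.2f, %.2f); dominant freq ~ N(%.0f, %.0f) on (%.0f, %.0f) Hz\n",
              x$amplitude_dist$shape1, x$amplitude_dist$shape2,
              x$dominant_freq_dist$mean_hz, x$dominant_freq_dist$sd_hz,
              x$dominant_freq_dist$min_hz, x$dominant_freq_dist$max_hz))
  cat(sprintf("  confounders: speech %.2f /min, friction %.2f /min; heartbeat %s (%g bpm)\n",
              x$confounder_rates[["speech"]],
              x$confounder_rates[["friction_other"]],
              if (isTRUE(x$heartbeat$enabled)) "on" else "off", x$heartbeat$bpm))
  cat(sprintf("  ambient noise RMS %.3f\n", x$ambient_noise_rms))
  invisible(x)
}

# fixed per-class distributions for the confounder sounds; bowel-sound
# events use the profile's own distributions
confounder_dists <- function(label) {
  switch(label,
         speech = list(dur = list(median_s = 0.9, sdlog = 0.5),
                       amp = list(shape1 = 2, shape2 = 4),
                       freq = list(min_hz = 150, max_hz = 400)),
         friction_other = list(dur = list(median_s = 0.30, sdlog = 0.5),
                               amp = list(shape1 = 2, shape2 = 3),
                               freq = list(min_hz = 300, max_hz = 1500)))
}
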