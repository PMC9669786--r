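# Event schedule sampling: Poisson counts per class with a refractory gap.

# truncated-normal draw via inverse CDF; vectorized
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(min(max(mean, lo), hi), n))
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# Resolve overlapping onsets by pushing later events forward so that
# consecutive same-label events are separated by >= gap.  Uses the
# max-plus recurrence a_i = max(o_i, a_{i-1} + d_{i-1} + gap), vectorized
# through cumulative sums.  Preserves the event count except at the
# recording boundary.
resolve_overlaps <- function(onset, dur, gap, duration_s) {
  n <- length(onset)
  if (n == 0L) return(list(onset = onset, offset = onset))
  o <- sort(onset)
  c_step <- dur + gap
  clag <- c(0, cumsum(c_step))[seq_len(n)]
  a <- clag + cummax(o - clag)
  off <- a + dur
  keep <- a < duration_s - 0.01
  a <- a[keep]
  off <- pmin(off[keep], duration_s)
  list(onset = a, offset = off)
}

sample_class_events <- function(label, rate_per_min, duration_s, profile) {
  n <- stats::rpois(1L, rate_per_min / 60 * duration_s)
  if (n == 0L) return(NULL)
  onset <- sort(stats::runif(n, 0, duration_s))
  if (label == "bowel_sound") {
    dd <- profile$duration_dist
    ad <- profile$amplitude_dist
    fd <- profile$dominant_freq_dist
    dur <- stats::rlnorm(n, log(dd$median_s), dd$sdlog)
    amp <- stats::rbeta(n, ad$shape1, ad$shape2)
    freq <- rtruncnorm(n, fd$mean_hz, fd$sd_hz, fd$min_hz, fd$max_hz)
  } else {
    cd <- confounder_dists(label)
    dur <- stats::rlnorm(n, log(cd$dur$median_s), cd$dur$sdlog)
    amp <- stats::rbeta(n, cd$amp$shape1, cd$amp$shape2)
    freq <- stats::runif(n, cd$freq$min_hz, cd$freq$max_hz)
  }
  amp <- pmin(pmax(amp, 1e-4), 1)
  dur <- pmin(pmax(dur, 0.02), duration_s)
  res <- resolve_overlaps(onset, dur, profile$min_gap_s, duration_s)
  m <- length(res$onset)
  if (m == 0L) return(NULL)
  data.frame(onset_s = res$onset, offset_s = res$offset,
             label = label, peak_amp_norm = amp[seq_len(m)],
             dom_freq_hz = freq[seq_len(m)])
}

#' Sample a ground-truth event schedule
#'
#' Draws sound events for one recording from an acoustic profile: per class
#' a Poisson number of events at the profile's per-minute rate, onsets
#' uniform over the recording, per-event duration / peak amplitude /
#' dominant frequency from the profile's distributions.  Same-label events
#' are kept non-overlapping by pushing later onsets forward with a small
#' refractory gap (`profile$min_gap_s`), which preserves the nominal event
#' count (see the methods vignette for the rationale).
#'
#' @param profile a [acoustic_profile()] object.
#' @param duration_s recording length in seconds (> 0).
#' @param seed integer seed; the schedule is a pure function of
#'   (profile, duration_s, seed).
#' @return a `bs_events` table with ground-truth annotations.
#' @export
sample_event_schedule <- function(profile, duration_s, seed) {
  assert_that(inherits(profile, "bs_profile"), "profile must be a bs_profile")
  assert_number(duration_s, "duration_s", lower = 1e-9)
  assert_that(!missing(seed) && is.numeric(seed), "a numeric seed is required")
  withr::with_seed(as.integer(seed), {
    parts <- list(
      sample_class_events("bowel_sound", profile$event_rate, duration_s, profile),
      sample_class_events("speech", profile$confounder_rates[["speech"]],
                          duration_s, profile),
      sample_class_events("friction_other",
                          profile$confounder_rates[["friction_other"]],
                          duration_s, profile))
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (!length(parts)) return(events_table())
    ev <- do.call(rbind, parts)
    events_table(ev$onset_s, ev$offset_s, ev$label,
                 ev$peak_amp_norm, ev$dom_freq_hz)
  })
}
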