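# The five per-minute acoustic parameters, recording aggregation and loess.

#' Dominant frequency of an event segment
#'
#' Welch power spectral density (Hann-windowed segments of up to 128
#' samples, 50% overlap, averaged periodograms); returns the frequency of
#' the maximum over \[50 Hz, Nyquist), ties broken toward the lower
#' frequency.  Segments shorter than 8 samples return 0 with a warning.
#'
#' @param samples numeric vector (normalized or raw samples of one event).
#' @param sample_rate_hz sampling rate.
#' @return dominant frequency in Hz.
#' @export
event_dominant_frequency <- function(samples, sample_rate_hz = 4000) {
  n <- length(samples)
  if (n < 8L) {
    warning("event shorter than 8 samples; dominant frequency set to 0",
            call. = FALSE)
    return(0)
  }
  seg_len <- min(128L, 2^floor(log2(n)))
  hop <- max(1L, seg_len %/% 2L)
  starts <- seq(1L, n - seg_len + 1L, by = hop)
  win <- hann_window(seg_len)
  n_bins <- seg_len %/% 2 + 1L
  psd <- numeric(n_bins)
  for (s in starts) {
    seg <- samples[s:(s + seg_len - 1L)] * win
    sp <- stats::fft(seg)[seq_len(n_bins)]
    psd <- psd + Re(sp)^2 + Im(sp)^2
  }
  freqs <- (seq_len(n_bins) - 1) * sample_rate_hz / seg_len
  sel <- freqs >= 50 & freqs < sample_rate_hz / 2
  if (!any(sel)) return(0)
  fsel <- freqs[sel]
  fsel[which.max(psd[sel])]   # which.max takes the first (lowest) on ties
}

#' Per-minute summary of the five bowel-sound parameters
#'
#' For minute `m` (the half-open window \[60 m, 60 (m+1)) seconds):
#' * `rate` — number of bowel-sound events with onset in the window;
#' * `duration_s_per_min` — summed overlap of bowel-sound event spans with
#'   the window, clipped to \[0, 60\];
#' * `amplitude` — mean per-event peak normalized amplitude over events with
#'   onset in the window (0 if none);
#' * `dominant_freq_hz` — median per-event dominant frequency (0 if none);
#' * `mean_interval_s` — mean silence gap (offset to next onset, or onset to
#'   onset with `interval_mode = "onset"`) between consecutive bowel-sound
#'   events whose onsets lie in the window (0 with fewer than 2 events);
#' * `display_class` — class with the greatest total labelled time in the
#'   window (`background` if none), the colour key of the rate timeline.
#'
#' @param events sorted `bs_events` for the recording.
#' @param minute_index 0-based minute index.
#' @param duration_s recording length in seconds.
#' @param interval_mode `"gap"` (default) or `"onset"`.
#' @return one-row `data.frame`.
#' @export
minute_summary <- function(events, minute_index, duration_s,
                           interval_mode = c("gap", "onset")) {
  interval_mode <- match.arg(interval_mode)
  validate_events(events)
  assert_that(minute_index >= 0 && 60 * minute_index < duration_s,
              "minute_index must lie within the recording")
  out <- minute_summaries(events, duration_s, interval_mode)
  out[out$minute_index == minute_index, , drop = FALSE]
}

#' All per-minute summaries of a recording
#'
#' Vectorized form of [minute_summary()] covering every (possibly partial
#' trailing) minute of the recording.
#'
#' @inheritParams minute_summary
#' @param duration_s recording length in seconds.
#' @return `data.frame` with one row per minute, class `bs_minutes`.
#' @export
minute_summaries <- function(events, duration_s,
                             interval_mode = c("gap", "onset")) {
  interval_mode <- match.arg(interval_mode)
  validate_events(events)
  n_min <- ceiling(duration_s / 60 - 1e-9)
  mins <- seq_len(n_min) - 1L
  out <- data.frame(minute_index = mins, rate = 0L,
                    duration_s_per_min = 0, amplitude = 0,
                    dominant_freq_hz = 0, mean_interval_s = 0,
                    display_class = "background",
                    stringsAsFactors = FALSE)
  if (nrow(events)) {
    bs <- events[events$label == "bowel_sound", , drop = FALSE]
    if (nrow(bs)) {
      m_on <- floor(bs$onset_s / 60)
      out$rate <- as.integer(tabulate(m_on + 1L, nbins = n_min))
      amp_sum <- rowsum_safe(bs$peak_amp_norm, m_on, n_min)
      out$amplitude <- ifelse(out$rate > 0, amp_sum / out$rate, 0)
      for (m in unique(m_on)) {
        sel <- m_on == m
        out$dominant_freq_hz[m + 1L] <-
          stats::median(bs$dom_freq_hz[sel], na.rm = TRUE)
        if (sum(sel) >= 2L) {
          on_m <- bs$onset_s[sel]; off_m <- bs$offset_s[sel]
          gaps <- if (interval_mode == "gap")
            on_m[-1] - off_m[-sum(sel)] else diff(on_m)
          out$mean_interval_s[m + 1L] <- mean(pmax(gaps, 0))
        }
      }
      # duration: overlap of each event span with each minute window
      first_m <- floor(bs$onset_s / 60)
      last_m <- pmin(floor((bs$offset_s - 1e-12) / 60), n_min - 1L)
      for (i in seq_len(nrow(bs))) {
        for (m in first_m[i]:last_m[i]) {
          ov <- min(bs$offset_s[i], 60 * (m + 1)) - max(bs$onset_s[i], 60 * m)
          out$duration_s_per_min[m + 1L] <- out$duration_s_per_min[m + 1L] + ov
        }
      }
      out$duration_s_per_min <- pmin(out$duration_s_per_min, 60)
    }
    # display class: label with most labelled time per minute
    cls_time <- matrix(0, n_min, length(EVENT_LABELS),
                       dimnames = list(NULL, EVENT_LABELS))
    fm <- floor(events$onset_s / 60)
    lm <- pmin(floor((events$offset_s - 1e-12) / 60), n_min - 1L)
    for (i in seq_len(nrow(events))) {
      for (m in fm[i]:lm[i]) {
        ov <- min(events$offset_s[i], 60 * (m + 1)) -
          max(events$onset_s[i], 60 * m)
        cls_time[m + 1L, events$label[i]] <- cls_time[m + 1L, events$label[i]] + ov
      }
    }
    any_lab <- rowSums(cls_time) > 0
    out$display_class[any_lab] <-
      EVENT_LABELS[apply(cls_time[any_lab, , drop = FALSE], 1, which.max)]
  }
  class(out) <- c("bs_minutes", "data.frame")
  out
}

rowsum_safe <- function(x, group0, nbins) {
  out <- numeric(nbins)
  s <- rowsum(x, group0)
  out[as.integer(rownames(s)) + 1L] <- s[, 1]
  out
}

PARAM_NAMES <- c("rate", "duration_s_per_min", "amplitude",
                 "dominant_freq_hz", "mean_interval_s")

#' Recording-level summary (median and IQR per parameter)
#'
#' Aggregates the per-minute summaries to a median and interquartile range
#' per parameter (type-7 linear-interpolation quantiles).  The interval
#' parameter aggregates only minutes containing at least two bowel-sound
#' events (0 if no such minute), so an interval is always the average of
#' real between-sound gaps.
#'
#' @param minutes `bs_minutes` table from [minute_summaries()].
#' @return `data.frame` with one row per parameter: `median`, `q1`, `q3`,
#'   plus the number of minutes used; class `bs_recording_summary`.
#' @export
recording_summary <- function(minutes) {
  assert_that(is.data.frame(minutes) && nrow(minutes) >= 1L,
              "need at least one minute summary")
  out <- do.call(rbind, lapply(PARAM_NAMES, function(p) {
    v <- minutes[[p]]
    n_used <- length(v)
    if (p == "mean_interval_s") {
      v <- v[minutes$rate >= 2L]
      n_used <- length(v)
      if (!n_used) v <- 0
    }
    data.frame(parameter = p,
               median = quantile7(v, 0.5),
               q1 = quantile7(v, 0.25),
               q3 = quantile7(v, 0.75),
               n_minutes = n_used)
  }))
  class(out) <- c("bs_recording_summary", "data.frame")
  out
}

#' @export
print.bs_recording_summary <- function(x, ...) {
  cat("Recording summary (median [Q1, Q3] over minutes)\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-20s %8.2f [%6.2f, %6.2f]  (n=%d)\n", x$parameter[i],
                x$median[i], x$q1[i], x$q3[i], x$n_minutes[i]))
  invisible(x)
}

#' Display timeline of minutes
#'
#' One record per minute with the dominant display class (the colour key:
#' bowel sounds red, speech green, friction/other yellow) and the rate,
#' suitable for plotting the coloured rate bar and the per-minute
#' point-curve.
#'
#' @param minutes `bs_minutes` table.
#' @return `data.frame` with `minute_index`, `display_class`, `color`,
#'   `rate`.
#' @export
minute_timeline <- function(minutes) {
  assert_that(is.data.frame(minutes) &&
                all(c("minute_index", "display_class", "rate") %in% names(minutes)),
              "minutes must come from minute_summaries()")
  assert_that(!is.unsorted(minutes$minute_index) &&
                all(diff(minutes$minute_index) == 1L),
              "minutes must be contiguous")
  key <- c(bowel_sound = "red", speech = "green",
           friction_other = "yellow", background = "grey")
  data.frame(minute_index = minutes$minute_index,
             display_class = minutes$display_class,
             color = unname(key[minutes$display_class]),
             rate = minutes$rate)
}

#' @export
plot.bs_minutes <- function(x, ...) {
  tl <- minute_timeline(x)
  graphics::plot(tl$minute_index, tl$rate, type = "n",
                 xlab = "minute", ylab = "rate (events/min)", ...)
  graphics::points(tl$minute_index, tl$rate, col = tl$color, pch = 16)
  graphics::lines(tl$minute_index, tl$rate, col = "grey60")
  invisible(x)
}

#' Loess smoothing of a parameter time course
#'
#' Local polynomial regression with tricube weights and no robustness
#' iterations: at each point the `floor(span * n)` nearest neighbours (at
#' least `degree + 1`) are fitted by weighted least squares and the local
#' polynomial is evaluated there.  A degenerate neighbourhood (all `x`
#' identical) falls back to the weighted mean.
#'
#' @param x predictor (e.g. time-point index, 1 unit = 30 min).
#' @param y response.
#' @param span neighbourhood fraction in (0, 1\].
#' @param degree local polynomial degree, 1 or 2.
#' @return object of class `bs_loess` with fields `x`, `y`, `y_fitted`,
#'   `span`, `degree`.
#' @export
loess_fit <- function(x, y, span = 0.3, degree = 1) {
  assert_that(degree %in% c(1, 2), "degree must be 1 or 2")
  assert_that(span > 0 && span <= 1, "span must be in (0, 1]")
  n <- length(x)
  assert_that(length(y) == n, "x and y lengths differ")
  assert_that(n >= degree + 2, "too few points for the requested degree")
  q <- max(degree + 1, floor(span * n))
  assert_that(q >= degree + 1, "span * n must be at least degree + 1")
  q <- min(q, n)
  fitted <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(x - x[i])
    idx <- order(d)[seq_len(q)]
    h <- max(d[idx])
    w <- if (h > 0) (1 - pmin(d[idx] / h, 1)^3)^3 else rep(1, q)
    xs <- x[idx]; ys <- y[idx]
    if (max(xs) - min(xs) < 1e-12 || sum(w > 0) <= degree) {
      fitted[i] <- if (sum(w) > 0) sum(w * ys) / sum(w) else mean(ys)
      next
    }
    X <- stats::poly(xs - x[i], degree = degree, raw = TRUE)
    X <- cbind(1, X)
    fit <- stats::lm.wfit(X, ys, w)
    fitted[i] <- fit$coefficients[1]
  }
  structure(list(x = x, y = y, y_fitted = fitted, span = span,
                 degree = degree), class = "bs_loess")
}

#' @export
print.bs_loess <- function(x, ...) {
  cat(sprintf("<bs_loess> %d points, span %.2f, degree %d\n",
              length(x$x), x$span, x$degree))
  invisible(x)
}

#' @export
plot.bs_loess <- function(x, ...) {
  graphics::plot(x$x, x$y, pch = 16, col = "grey60",
                 xlab = "time point (30-min units)", ylab = "value", ...)
  ord <- order(x$x)
  graphics::lines(x$x[ord], x$y_fitted[ord], col = "red", lwd = 2)
  invisible(x)
}
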