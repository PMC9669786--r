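# Event detection: deterministic band-energy baseline and frame->event decoding.

#' Detector configuration
#'
#' Settings shared by both detector backends: the analysis band and
#' hysteresis thresholds of the energy baseline (as multiples of the median
#' frame-energy noise floor), the minimum kept event length and the maximum
#' silence gap merged into one event, and the frame geometry.
#'
#' @param backend `"energy_baseline"` or `"crnn"`.
#' @param band_low_hz,band_high_hz analysis band of the baseline (Hz).
#' @param on_threshold,off_threshold hysteresis thresholds, multiples of the
#'   median frame energy (`on >= off`).
#' @param refine_threshold low threshold (multiple of the noise floor,
#'   `<= off_threshold`) to which span boundaries are extended over
#'   contiguous frames, correcting the onset latency of ramped bursts.
#' @param min_event_s minimum kept event length (s).
#' @param merge_gap_s maximum gap merged into one event (s).
#' @param attack_correction onset latency compensation as a fraction of the
#'   detected span (threshold crossings lag the true onset of a tapered
#'   burst by a time roughly proportional to its rise time); capped by
#'   `attack_correction_max_s`.
#' @param attack_correction_max_s cap on the onset correction (s).
#' @param frame_length_s,hop_s frame geometry (must match the feature path).
#' @return object of class `bs_detector_config`.
#' @export
detector_config <- function(backend = c("energy_baseline", "crnn"),
                            band_low_hz = 100, band_high_hz = 1500,
                            on_threshold = 6, off_threshold = 3,
                            refine_threshold = 1.3,
                            min_event_s = 0.02, merge_gap_s = 0.05,
                            attack_correction = 0.02,
                            attack_correction_max_s = 0.06,
                            frame_length_s = 0.025, hop_s = 0.010) {
  backend <- match.arg(backend)
  assert_that(band_low_hz > 0 && band_low_hz < band_high_hz,
              "need 0 < band_low_hz < band_high_hz")
  assert_that(on_threshold >= off_threshold && off_threshold > 0,
              "need on_threshold >= off_threshold > 0")
  assert_that(refine_threshold <= off_threshold && refine_threshold > 0,
              "need 0 < refine_threshold <= off_threshold")
  assert_that(min_event_s >= 0 && merge_gap_s >= 0,
              "min_event_s and merge_gap_s must be non-negative")
  assert_that(attack_correction >= 0 && attack_correction_max_s >= 0,
              "attack correction settings must be non-negative")
  structure(list(backend = backend, band_low_hz = band_low_hz,
                 band_high_hz = band_high_hz, on_threshold = on_threshold,
                 off_threshold = off_threshold,
                 refine_threshold = refine_threshold,
                 min_event_s = min_event_s,
                 attack_correction = attack_correction,
                 attack_correction_max_s = attack_correction_max_s,
                 merge_gap_s = merge_gap_s, frame_length_s = frame_length_s,
                 hop_s = hop_s),
            class = "bs_detector_config")
}

# merge events of the same class whose gap is below merge_gap_s, then drop
# events shorter than min_event_s
merge_and_prune <- function(onset, offset, min_event_s, merge_gap_s) {
  n <- length(onset)
  if (n == 0L) return(list(onset = onset, offset = offset))
  ord <- order(onset)
  onset <- onset[ord]; offset <- offset[ord]
  mo <- onset[1]; mf <- offset[1]
  out_on <- numeric(0); out_off <- numeric(0)
  for (i in seq_len(n)[-1]) {
    if (onset[i] - mf < merge_gap_s) {
      mf <- max(mf, offset[i])
    } else {
      out_on <- c(out_on, mo); out_off <- c(out_off, mf)
      mo <- onset[i]; mf <- offset[i]
    }
  }
  out_on <- c(out_on, mo); out_off <- c(out_off, mf)
  keep <- (out_off - out_on) >= min_event_s
  list(onset = out_on[keep], offset = out_off[keep])
}

#' Deterministic band-energy baseline detector
#'
#' Band-passes the normalized signal, computes per-frame energy, estimates
#' the noise floor as the median frame energy, and applies hysteresis
#' thresholding: a candidate span opens where energy exceeds
#' `on_threshold` x floor and extends over all contiguous frames above
#' `off_threshold` x floor.  Spans closer than `merge_gap_s` are merged and
#' spans shorter than `min_event_s` dropped.  All kept spans are labelled
#' `bowel_sound` (the baseline is single-class); each event also carries its
#' measured peak normalized amplitude and dominant frequency.
#'
#' @param recording a `bs_recording`.
#' @param config a [detector_config()].
#' @return a `bs_events` table (possibly empty).
#' @export
detect_events_baseline <- function(recording, config = detector_config()) {
  assert_that(inherits(recording, "bs_recording"),
              "recording must be a bs_recording")
  assert_that(inherits(config, "bs_detector_config"),
              "config must be a bs_detector_config")
  sr <- recording$sample_rate_hz
  nyq <- sr / 2
  assert_that(config$band_high_hz < nyq,
              "band_high_hz must lie below the Nyquist frequency")
  x <- normalize_amplitude(recording$samples)
  L <- round(config$frame_length_s * sr)
  H <- round(config$hop_s * sr)
  if (length(x) < L) return(events_table())
  bf <- signal::butter(4, c(config$band_low_hz, config$band_high_hz) / nyq,
                       type = "pass")
  xb <- signal::filtfilt(bf, x)
  # per-frame band energy via cumulative sums (frames as in frame_signal)
  cs <- c(0, cumsum(xb^2))
  n_frames <- (length(x) - L) %/% H + 1L
  starts <- (seq_len(n_frames) - 1L) * H
  energy <- cs[starts + L + 1L] - cs[starts + 1L]
  floor_e <- stats::median(energy)
  above_off <- energy > config$off_threshold * floor_e
  above_on <- energy > config$on_threshold * floor_e
  r <- rle(above_off)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  keep <- r$values & vapply(seq_along(r$values), function(i)
    r$values[i] && any(above_on[begins[i]:ends[i]]), logical(1))
  if (!any(keep)) return(events_table())
  b_keep <- begins[keep]; e_keep <- ends[keep]
  # merge spans whose raw (off-threshold) gap is below merge_gap_s; the
  # merge decision is taken before boundary refinement so that refinement
  # cannot bridge distinct events
  gap_frames <- max(0L, ceiling((config$merge_gap_s + config$frame_length_s -
                                   config$hop_s) / config$hop_s))
  mb <- b_keep[1]; me <- e_keep[1]
  out_b <- integer(0); out_e <- integer(0)
  for (i in seq_along(b_keep)[-1]) {
    if (b_keep[i] - me <= gap_frames) {
      me <- max(me, e_keep[i])
    } else {
      out_b <- c(out_b, mb); out_e <- c(out_e, me)
      mb <- b_keep[i]; me <- e_keep[i]
    }
  }
  out_b <- c(out_b, mb); out_e <- c(out_e, me)
  # boundary refinement: extend each span over frames above the low refine
  # threshold (tolerating single-frame dips), clamped at neighbour spans so
  # the tapered onset/offset of a burst is recovered without bridging
  above_ref <- energy > config$refine_threshold * floor_e
  n_span <- length(out_b)
  for (i in seq_len(n_span)) {
    lo <- if (i == 1L) 1L else out_e[i - 1L] + 1L
    while (out_b[i] > lo &&
           (above_ref[out_b[i] - 1L] ||
            (out_b[i] > lo + 1L && above_ref[out_b[i] - 2L])))
      out_b[i] <- out_b[i] - 1L
  }
  for (i in seq_len(n_span)) {
    hi <- if (i == n_span) n_frames else out_b[i + 1L] - 1L
    while (out_e[i] < hi &&
           (above_ref[out_e[i] + 1L] ||
            (out_e[i] < hi - 1L && above_ref[out_e[i] + 2L])))
      out_e[i] <- out_e[i] + 1L
  }
  on_s <- (out_b - 1L) * config$hop_s
  off_s <- (out_e - 1L) * config$hop_s + config$frame_length_s
  keep_len <- (off_s - on_s) >= config$min_event_s
  on_s <- on_s[keep_len]; off_s <- off_s[keep_len]
  if (!length(on_s)) return(events_table())
  # attack compensation: move onsets earlier by a span-proportional amount,
  # clamped so events stay ordered and non-overlapping
  corr <- pmin(config$attack_correction * (off_s - on_s),
               config$attack_correction_max_s)
  on_s <- pmax(on_s - corr, 0)
  if (length(on_s) > 1L)
    for (i in 2:length(on_s)) on_s[i] <- max(on_s[i], off_s[i - 1L])
  mp <- list(onset = on_s, offset = off_s)
  # per-event measured amplitude / dominant frequency from the raw signal
  peak <- numeric(length(mp$onset))
  domf <- numeric(length(mp$onset))
  for (i in seq_along(mp$onset)) {
    i0 <- max(1L, round(mp$onset[i] * sr) + 1L)
    i1 <- min(length(x), round(mp$offset[i] * sr))
    seg <- x[i0:i1]
    peak[i] <- max(abs(seg))
    domf[i] <- event_dominant_frequency(seg, sr)
  }
  events_table(mp$onset, pmin(mp$offset, recording$duration_s),
               rep("bowel_sound", length(mp$onset)), peak, domf)
}

#' Decode frame labels into events
#'
#' Maximal runs of a non-background class become events spanning from the
#' run's first frame start to its last frame start plus one frame length.
#' Same-class events separated by less than `merge_gap_s` are merged; events
#' shorter than `min_event_s` are dropped.
#'
#' @param frame_labels character vector of per-frame labels (`"background"`
#'   or an event class), or a `bs_frame_labels` object from
#'   [predict.bs_crnn()].
#' @param hop_s,frame_length_s frame geometry (taken from the object when
#'   `frame_labels` is classed).
#' @param min_event_s,merge_gap_s decoding thresholds.
#' @return a `bs_events` table.
#' @export
frames_to_events <- function(frame_labels, hop_s = 0.010,
                             frame_length_s = 0.025,
                             min_event_s = 0.02, merge_gap_s = 0.05) {
  if (inherits(frame_labels, "bs_frame_labels")) {
    hop_s <- frame_labels$hop_s
    frame_length_s <- frame_labels$frame_length_s
    frame_labels <- frame_labels$labels
  }
  assert_that(is.character(frame_labels), "frame_labels must be character")
  if (!length(frame_labels)) return(events_table())
  r <- rle(frame_labels)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  out <- list()
  for (cls in setdiff(unique(r$values), "background")) {
    sel <- r$values == cls
    on_s <- (begins[sel] - 1L) * hop_s
    off_s <- (ends[sel] - 1L) * hop_s + frame_length_s
    mp <- merge_and_prune(on_s, off_s, min_event_s, merge_gap_s)
    if (length(mp$onset))
      out[[cls]] <- data.frame(onset_s = mp$onset, offset_s = mp$offset,
                               label = cls)
  }
  if (!length(out)) return(events_table())
  ev <- do.call(rbind, out)
  events_table(ev$onset_s, ev$offset_s, ev$label)
}

#' Evaluate a detector against ground truth
#'
#' Greedy one-to-one matching of predicted to truth events by onset
#' proximity: candidate pairs with |onset difference| <= `tolerance_s` are
#' accepted in order of increasing onset distance, each event matched at
#' most once.  Sensitivity and precision count matched pairs whose labels
#' agree; the confusion table crosses truth labels against predicted labels
#' for matched pairs, with `missed` / `spurious` margins for unmatched
#' events.
#'
#' @param predicted,truth `bs_events` tables for the same recording.
#' @param tolerance_s onset matching tolerance in seconds (>= 0).
#' @return list with `sensitivity`, `precision`, `f1`, `n_truth`, `n_pred`,
#'   `confusion` (a table).
#' @export
evaluate_detector <- function(predicted, truth, tolerance_s = 0.025) {
  assert_that(tolerance_s >= 0, "tolerance_s must be non-negative")
  validate_events(predicted); validate_events(truth)
  np <- nrow(predicted); nt <- nrow(truth)
  match_p <- integer(0); match_t <- integer(0)
  if (np > 0 && nt > 0) {
    d <- abs(outer(predicted$onset_s, truth$onset_s, `-`))
    cand <- which(d <= tolerance_s, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      used_p <- logical(np); used_t <- logical(nt)
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_p[i] && !used_t[j]) {
          used_p[i] <- TRUE; used_t[j] <- TRUE
          match_p <- c(match_p, i); match_t <- c(match_t, j)
        }
      }
    }
  }
  tp <- sum(predicted$label[match_p] == truth$label[match_t])
  sens <- if (nt > 0) tp / nt else NA_real_
  prec <- if (np > 0) tp / np else NA_real_
  f1 <- if (!is.na(sens) && !is.na(prec) && (sens + prec) > 0)
    2 * sens * prec / (sens + prec) else 0
  lvl_t <- c(EVENT_LABELS, "spurious")
  lvl_p <- c(EVENT_LABELS, "missed")
  conf <- table(factor(character(), lvl_t), factor(character(), lvl_p),
                dnn = c("truth", "predicted"))
  if (length(match_p))
    conf <- conf + table(factor(truth$label[match_t], lvl_t),
                         factor(predicted$label[match_p], lvl_p))
  un_t <- setdiff(seq_len(nt), match_t)
  if (length(un_t))
    conf <- conf + table(factor(truth$label[un_t], lvl_t),
                         factor(rep("missed", length(un_t)), lvl_p))
  un_p <- setdiff(seq_len(np), match_p)
  if (length(un_p))
    conf <- conf + table(factor(rep("spurious", length(un_p)), lvl_t),
                         factor(predicted$label[un_p], lvl_p))
  list(sensitivity = sens, precision = prec, f1 = f1,
       n_truth = nt, n_pred = np, n_matched_correct = tp,
       confusion = conf)
}

#' Run the configured detector backend
#'
#' Dispatches to the deterministic energy baseline or, when
#' `config$backend == "crnn"` and a trained model is supplied, to the CRNN
#' frame classifier followed by [frames_to_events()].
#'
#' @param recording a `bs_recording`.
#' @param config a [detector_config()].
#' @param model a trained `bs_crnn` (required for the crnn backend).
#' @return a `bs_events` table.
#' @export
detect_events <- function(recording, config = detector_config(), model = NULL) {
  if (config$backend == "energy_baseline")
    return(detect_events_baseline(recording, config))
  assert_that(inherits(model, "bs_crnn"),
              "the crnn backend needs a trained bs_crnn model")
  feats <- mfcc(recording, frame_length_s = config$frame_length_s,
                hop_s = config$hop_s)
  fl <- stats::predict(model, feats)
  frames_to_events(fl, min_event_s = config$min_event_s,
                   merge_gap_s = config$merge_gap_s)
}
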