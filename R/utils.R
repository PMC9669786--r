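#' @keywords internal
"_PACKAGE"

# -- internal validation helpers ------------------------------------------

stop_bs <- function(...) stop(..., call. = FALSE)

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop_bs(msg)
  invisible(TRUE)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          allow_zero = TRUE) {
  assert_that(is.numeric(x) && length(x) == 1L && is.finite(x),
              sprintf("`%s` must be a single finite number", name))
  assert_that(x >= lower && x <= upper,
              sprintf("`%s` must be in [%s, %s]", name, lower, upper))
  if (!allow_zero) assert_that(x != 0, sprintf("`%s` must be nonzero", name))
  invisible(TRUE)
}

EVENT_LABELS <- c("bowel_sound", "speech", "friction_other")
SITES <- c("abdomen_rlq", "chest_left", "blank")
USABILITY <- c("usable", "sensor_fell_off", "battery_ran_out", "removed_early")

#' Construct an event annotation table
#'
#' Events are the package's exchange currency between the generator, the
#' detectors and the parameter extractor: one row per sound event with its
#' onset/offset in seconds from recording start, a class label
#' (`bowel_sound`, `speech` or `friction_other`), and optionally the peak
#' normalized amplitude and dominant frequency of the event.
#'
#' @param onset_s,offset_s numeric vectors, seconds from recording start.
#' @param label character vector of class labels.
#' @param peak_amp_norm optional peak |normalized amplitude| in \[0, 1\].
#' @param dom_freq_hz optional dominant frequency in Hz.
#' @return a `data.frame` with class `bs_events`, sorted by onset.
#' @export
events_table <- function(onset_s = numeric(), offset_s = numeric(),
                         label = character(), peak_amp_norm = NA_real_,
                         dom_freq_hz = NA_real_) {
  n <- length(onset_s)
  assert_that(length(offset_s) == n && length(label) == n,
              "onset_s, offset_s and label must have equal length")
  assert_that(all(label %in% EVENT_LABELS),
              sprintf("event labels must be one of: %s",
                      paste(EVENT_LABELS, collapse = ", ")))
  assert_that(all(onset_s < offset_s), "every onset must precede its offset")
  assert_that(all(onset_s >= 0), "onsets must be non-negative")
  ev <- data.frame(onset_s = as.numeric(onset_s),
                   offset_s = as.numeric(offset_s),
                   label = as.character(label),
                   peak_amp_norm = rep_len(as.numeric(peak_amp_norm), n),
                   dom_freq_hz = rep_len(as.numeric(dom_freq_hz), n))
  ev <- ev[order(ev$onset_s, ev$offset_s), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("bs_events", "data.frame")
  ev
}

validate_events <- function(events, duration_s = NULL) {
  assert_that(is.data.frame(events) &&
                all(c("onset_s", "offset_s", "label") %in% names(events)),
              "events must be a data.frame with onset_s, offset_s, label")
  if (nrow(events)) {
    assert_that(all(events$onset_s < events$offset_s),
                "every onset must precede its offset")
    assert_that(!is.unsorted(events$onset_s),
                "events must be sorted by onset")
    if (!is.null(duration_s))
      assert_that(all(events$offset_s <= duration_s + 1e-9),
                  "events extend past the end of the recording")
  }
  invisible(events)
}

#' Read or write an event table as CSV
#'
#' The on-disk schema is `onset_s,offset_s,label,peak_amp_norm,dom_freq_hz`,
#' shared between ground-truth annotations and detector output.
#'
#' @param events a `bs_events` table (for writing).
#' @param path file path.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events)[, c("onset_s", "offset_s", "label",
                                             "peak_amp_norm", "dom_freq_hz")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  events_table(df$onset_s, df$offset_s, df$label,
               df$peak_amp_norm, df$dom_freq_hz)
}

# FNV-1a over a serialized object; used only for logging config identity.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# quantiles pinned to type 7 (linear interpolation) package-wide
quantile7 <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))
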