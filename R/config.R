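# Pipeline configuration: one nested key-value structure drives all stages.

#' Default pipeline configuration
#'
#' Every constant of the pipeline in one nested list: sampling format,
#' feature extraction geometry, detector thresholds, parameter-extraction
#' switches, statistics settings and desk-scale simulation sizes.  Unknown
#' keys in a user configuration are rejected.
#'
#' @return nested list of class `bs_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    sampling = list(rate_hz = 4000L, bit_depth = 16L),
    features = list(frame_length_s = 0.025, hop_s = 0.010, n_mels = 26L,
                    n_coeffs = 13L, fmin_hz = 50, fmax_hz = 2000,
                    log_floor = 1e-10),
    detector = list(backend = "energy_baseline", band_low_hz = 100,
                    band_high_hz = 1500, on_threshold = 6, off_threshold = 3,
                    min_event_s = 0.02, merge_gap_s = 0.05),
    parameters = list(interval_mode = "gap", amplitude_pooling = "mean_peak",
                      loess_span = 0.3, loess_degree = 1L),
    statistics = list(alpha = 0.05, adjust = "bonferroni"),
    simulate = list(duration_s = 120, group_sizes = c(lt50 = 2, `50to75` = 2,
                                                      gt75 = 2),
                    exclusions = c(sensor_fell_off = 1, battery_ran_out = 0,
                                   removed_early = 0),
                    control_n = 2, n_control_sites = 2,
                    ambient_noise_rms = 0.01)
  ), class = "bs_config")
}

merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    key <- if (nzchar(path)) paste(path, nm, sep = ".") else nm
    if (!nm %in% names(base))
      stop_bs(sprintf("unknown configuration key: %s", key))
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      assert_that(is.list(user[[nm]]),
                  sprintf("configuration key %s must be a section", key))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], key)
    } else if (!is.null(names(base[[nm]])) && is.numeric(base[[nm]])) {
      v <- unlist(user[[nm]])
      bad <- setdiff(names(v), names(base[[nm]]))
      if (length(bad))
        stop_bs(sprintf("unknown configuration key: %s.%s", key, bad[1]))
      base[[nm]][names(v)] <- v
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration file
#'
#' YAML key-value file with nested sections; values override the defaults
#' of [default_config()], unknown keys are rejected.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return a `bs_config`.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    assert_that(file.exists(path), sprintf("config file not found: %s", path))
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- structure(merge_config(unclass(cfg), user),
                                         class = "bs_config")
  }
  cfg
}

cfg_detector <- function(cfg) {
  d <- cfg$detector
  detector_config(backend = d$backend, band_low_hz = d$band_low_hz,
                  band_high_hz = d$band_high_hz,
                  on_threshold = d$on_threshold,
                  off_threshold = d$off_threshold,
                  min_event_s = d$min_event_s, merge_gap_s = d$merge_gap_s,
                  frame_length_s = cfg$features$frame_length_s,
                  hop_s = cfg$features$hop_s)
}
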