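# Synthetic audio and cohort generation.

test_that("zero-rate profiles yield empty schedules", {
  prof <- acoustic_profile(event_rate = 0,
                           confounder_rates = c(speech = 0,
                                                friction_other = 0))
  sched <- sample_event_schedule(prof, 600, seed = 1)
  expect_s3_class(sched, "bs_events")
  expect_equal(nrow(sched), 0L)
})

test_that("schedules are deterministic in the seed and vary across seeds", {
  prof <- site_profile("abdomen_rlq")
  s1 <- sample_event_schedule(prof, 300, seed = 42)
  s2 <- sample_event_schedule(prof, 300, seed = 42)
  s3 <- sample_event_schedule(prof, 300, seed = 43)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
})

test_that("schedule sampling rejects invalid inputs", {
  prof <- site_profile("abdomen_rlq")
  expect_error(sample_event_schedule(prof, -10, seed = 1), "duration_s")
  expect_error(acoustic_profile(event_rate = -1), "event_rate")
  expect_error(acoustic_profile(ambient_noise_rms = -0.1), "ambient")
})

test_that("bowel-sound counts are Poisson-calibrated at the profile rate", {
  # closed-form expectation: rate * minutes; mean count over independent
  # seeds must fall within 3 standard errors of the Poisson mean
  prof <- site_profile("abdomen_rlq")   # 25.8 / min
  n_rep <- 200
  minutes <- 60
  counts <- vapply(seq_len(n_rep), function(s) {
    sched <- sample_event_schedule(prof, minutes * 60, seed = 1000 + s)
    sum(sched$label == "bowel_sound")
  }, numeric(1))
  lambda <- 25.8 * minutes
  se <- sqrt(lambda / n_rep)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("schedules keep same-label events separated and within bounds", {
  prof <- site_profile("abdomen_rlq")
  for (s in 1:5) {
    sched <- sample_event_schedule(prof, 120, seed = s)
    expect_true(all(sched$onset_s < sched$offset_s))
    expect_true(all(sched$offset_s <= 120 + 1e-9))
    for (cls in unique(sched$label)) {
      ev <- sched[sched$label == cls, ]
      if (nrow(ev) > 1)
        expect_true(all(ev$onset_s[-1] >= ev$offset_s[-nrow(ev)] - 1e-9))
    }
  }
})

test_that("event waveforms hit the requested peak, length and frequency", {
  ev <- data.frame(onset_s = 0, offset_s = 0.3, label = "bowel_sound",
                   peak_amp_norm = 0.5, dom_freq_hz = 944)
  w <- synthesize_event_waveform(ev, 4000, seed = 1)
  expect_length(w, 1200L)
  q <- pmin(pmax(round(w * 32768), -32768), 32767)
  expect_lte(abs(max(abs(q)) - 16384), 1)       # 0.5 * 2^15
  # FFT oracle: spectral argmax at the dominant frequency within resolution
  spec <- Mod(fft(w))[1:600]
  f_hat <- (which.max(spec[-1])) * 4000 / length(w)
  expect_lt(abs(f_hat - 944), 4000 / length(w) + 1e-9)
})

test_that("full-scale events never overflow 16-bit range", {
  ev <- data.frame(onset_s = 0, offset_s = 0.2, label = "bowel_sound",
                   peak_amp_norm = 1.0, dom_freq_hz = 800)
  w <- synthesize_event_waveform(ev, 4000, seed = 3)
  q <- pmin(pmax(round(w * 32768), -32768), 32767)
  expect_true(all(q <= 32767 & q >= -32768))
  expect_equal(max(abs(w)), 1.0)
})

test_that("events at or above Nyquist are rejected", {
  ev <- data.frame(onset_s = 0, offset_s = 0.2, label = "bowel_sound",
                   peak_amp_norm = 0.5, dom_freq_hz = 2000)
  expect_error(synthesize_event_waveform(ev, 4000, seed = 1), "Nyquist")
})

test_that("blank-site rendering has no bowel sounds and rejects them", {
  prof <- site_profile("blank")
  sched <- sample_event_schedule(prof, 600, seed = 2)
  rr <- render_recording(sched, prof, "blank", 600, seed = 3)
  expect_equal(sum(rr$truth$label == "bowel_sound"), 0L)
  bad <- events_table(1, 1.2, "bowel_sound", 0.5, 900)
  expect_error(render_recording(bad, prof, "blank", 10, seed = 1),
               "blank-site")
})

test_that("chest-site rendering attenuates bowel sounds to zero", {
  prof <- site_profile("chest_left")
  sched <- events_table(c(1, 3), c(1.3, 3.5),
                        c("bowel_sound", "friction_other"), c(0.5, 0.3),
                        c(900, 700))
  rr <- render_recording(sched, prof, "chest_left", 10, seed = 5)
  expect_equal(sum(rr$truth$label == "bowel_sound"), 0L)
  expect_equal(sum(rr$truth$label == "friction_other"), 1L)
})

test_that("an event adds energy over its span relative to silence", {
  prof <- site_profile("abdomen_rlq")
  ev <- events_table(2, 2.5, "bowel_sound", 0.5, 944)
  rr <- render_recording(ev, prof, "abdomen_rlq", 10, seed = 6)
  x <- normalize_amplitude(rr$recording$samples)
  rms <- function(v) sqrt(mean(v^2))
  ev_span <- x[(2 * 4000):(2.5 * 4000)]
  silent <- x[(6 * 4000):(6.5 * 4000)]
  expect_gt(rms(ev_span), rms(silent))
})

test_that("rendering is bit-reproducible for identical arguments and seed", {
  prof <- site_profile("abdomen_rlq")
  sched <- sample_event_schedule(prof, 30, seed = 8)
  r1 <- render_recording(sched, prof, "abdomen_rlq", 30, seed = 9)
  r2 <- render_recording(sched, prof, "abdomen_rlq", 30, seed = 9)
  expect_identical(r1$recording$samples, r2$recording$samples)
})

test_that("ground-truth bowel events sit above the ambient energy floor", {
  # annotation fidelity: band-passed energy over each event span exceeds
  # the ambient floor, so detection is well-posed
  rr <- quick_recording(duration_s = 60, seed = 21)
  x <- normalize_amplitude(rr$recording$samples)
  bf <- signal::butter(4, c(100, 1500) / 2000, type = "pass")
  xb <- signal::filtfilt(bf, x)
  floor_e <- median(xb^2)
  tr <- rr$truth[rr$truth$label == "bowel_sound", ]
  for (i in seq_len(nrow(tr))) {
    seg <- xb[round(tr$onset_s[i] * 4000 + 1):round(tr$offset_s[i] * 4000)]
    expect_gt(max(seg^2), floor_e)
  }
})

test_that("cohort manifests honor enrollment and exclusion arithmetic", {
  spec <- cohort_spec()   # 68 usable study + 14 exclusions + 10 controls
  cohort <- generate_cohort(spec, seed = 1)
  man <- cohort$manifest
  study <- man[man$hyperbilirubinemia, ]
  expect_equal(nrow(study), 82L)
  expect_equal(sum(study$usability == "sensor_fell_off"), 6L)
  expect_equal(sum(study$usability == "battery_ran_out"), 4L)
  expect_equal(sum(study$usability == "removed_early"), 4L)
  expect_equal(sum(study$usability == "usable"), 68L)
  grp <- table(study$breastmilk_group[study$usability == "usable"])
  expect_equal(unname(grp[c("lt50", "50to75", "gt75")]),
               c(40L, 12L, 16L), ignore_attr = TRUE)
})

test_that("cohorts with no exclusions are fully usable", {
  spec <- cohort_spec(group_sizes = c(lt50 = 3, `50to75` = 3, gt75 = 3),
                      exclusions = c(sensor_fell_off = 0, battery_ran_out = 0,
                                     removed_early = 0), control_n = 2)
  cohort <- generate_cohort(spec, seed = 2)
  expect_true(all(cohort$manifest$usability == "usable"))
})

test_that("different seeds change demographics but not the structure", {
  spec <- cohort_spec(group_sizes = c(lt50 = 4, `50to75` = 3, gt75 = 3),
                      control_n = 2)
  c1 <- generate_cohort(spec, seed = 1)
  c2 <- generate_cohort(spec, seed = 2)
  expect_false(identical(c1$manifest$birth_weight_g,
                         c2$manifest$birth_weight_g))
  expect_equal(table(c1$manifest$usability), table(c2$manifest$usability))
  expect_equal(nrow(c1$manifest), nrow(c2$manifest))
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohort_spec(group_sizes = c(lt50 = 0, `50to75` = 2, gt75 = 2)),
               "positive")
})
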