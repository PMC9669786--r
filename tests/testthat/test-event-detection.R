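# Baseline detector, frame decoding and detector evaluation.

test_that("a single burst in low noise is found with tight boundaries", {
  prof <- site_profile("abdomen_rlq")
  ev <- events_table(5.0, 5.3, "bowel_sound", 0.5, 944)
  rr <- render_recording(ev, prof, "abdomen_rlq", 10, seed = 4)
  det <- detect_events_baseline(rr$recording)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$onset_s - 5.0), 0.025)
  expect_lt(abs(det$offset_s - 5.3), 0.025)
  expect_equal(det$label, "bowel_sound")
})

test_that("pure ambient noise produces zero events", {
  rb <- quick_recording(duration_s = 300, seed = 5, site = "blank")
  expect_equal(nrow(detect_events_baseline(rb$recording)), 0L)
})

test_that("the merge rule joins only bursts closer than merge_gap_s", {
  prof <- site_profile("abdomen_rlq")
  far <- events_table(c(3, 3.5), c(3.3, 3.8), rep("bowel_sound", 2),
                      c(0.5, 0.5), c(944, 800))
  near <- events_table(c(3, 3.32), c(3.3, 3.62), rep("bowel_sound", 2),
                       c(0.5, 0.5), c(944, 800))
  d_far <- detect_events_baseline(
    render_recording(far, prof, "abdomen_rlq", 10, seed = 4)$recording)
  d_near <- detect_events_baseline(
    render_recording(near, prof, "abdomen_rlq", 10, seed = 4)$recording)
  expect_equal(nrow(d_far), 2L)
  expect_equal(nrow(d_near), 1L)
})

test_that("the baseline detector is deterministic", {
  rr <- quick_recording(duration_s = 60, seed = 12)
  d1 <- detect_events_baseline(rr$recording)
  d2 <- detect_events_baseline(rr$recording)
  expect_identical(d1, d2)
})

test_that("sub-frame recordings return an empty event list", {
  rec <- audio_recording(integer(50), 4000, "abdomen_rlq")
  expect_equal(nrow(detect_events_baseline(rec)), 0L)
})

test_that("frame decoding follows the run-length rule", {
  labs <- c("background", "background", "bowel_sound", "bowel_sound",
            "bowel_sound", "background")
  ev <- frames_to_events(labs, hop_s = 0.010, frame_length_s = 0.025,
                         min_event_s = 0.02, merge_gap_s = 0)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$onset_s, 0.020)
  expect_equal(ev$offset_s, 0.065)
  expect_equal(nrow(frames_to_events(rep("background", 50))), 0L)
})

test_that("frame decoding matches a brute-force oracle on random inputs", {
  set.seed(10)
  classes <- c("background", "bowel_sound", "speech")
  for (rep in 1:25) {
    labs <- sample(classes, 40, replace = TRUE, prob = c(0.6, 0.25, 0.15))
    got <- frames_to_events(labs, min_event_s = 0.02, merge_gap_s = 0.05)
    want <- oracle_frames_to_events(labs, 0.010, 0.025, 0.02, 0.05)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$onset_s, want$onset_s, tolerance = 1e-12)
      expect_equal(got$offset_s, want$offset_s, tolerance = 1e-12)
      expect_equal(got$label, want$label)
    }
  }
})

test_that("decoded events of one class never overlap", {
  set.seed(11)
  for (rep in 1:10) {
    labs <- sample(c("background", "bowel_sound"), 100, replace = TRUE)
    ev <- frames_to_events(labs, min_event_s = 0, merge_gap_s = 0.03)
    ev <- ev[ev$label == "bowel_sound", ]
    if (nrow(ev) > 1)
      expect_true(all(ev$onset_s[-1] >= ev$offset_s[-nrow(ev)]))
  }
})

test_that("detector evaluation handles the identity and empty cases", {
  tr <- events_table(c(1, 5, 9), c(1.4, 5.2, 9.3), rep("bowel_sound", 3))
  self <- evaluate_detector(tr, tr, 0.025)
  expect_equal(self$sensitivity, 1.0)
  expect_equal(self$precision, 1.0)
  expect_equal(self$f1, 1.0)
  none <- evaluate_detector(events_table(), tr, 0.025)
  expect_equal(none$sensitivity, 0.0)
  expect_error(evaluate_detector(tr, tr, -1), "non-negative")
})

test_that("partial detection gives the expected sensitivity and precision", {
  tr <- events_table(c(1, 5, 9), c(1.4, 5.2, 9.3), rep("bowel_sound", 3))
  pr <- events_table(c(1.01, 9.01), c(1.4, 9.3), rep("bowel_sound", 2))
  res <- evaluate_detector(pr, tr, 0.025)
  expect_equal(res$sensitivity, 2 / 3)
  expect_equal(res$precision, 1.0)
})

test_that("greedy matching never exceeds, and on separated events attains, the exhaustive maximum", {
  set.seed(12)
  tol <- 0.05
  for (rep in 1:20) {
    # truth events separated by more than 2 * tolerance, predictions are a
    # jittered subset plus spurious detections
    n_t <- sample(1:5, 1)
    on_t <- cumsum(runif(n_t, 0.2, 1))
    keep <- runif(n_t) < 0.7
    on_p <- sort(c(on_t[keep] + runif(sum(keep), -tol, tol),
                   max(on_t) + 1 + runif(sample(0:2, 1))))
    tr <- events_table(on_t, on_t + 0.05, rep("bowel_sound", n_t))
    pr <- if (length(on_p)) events_table(on_p, on_p + 0.05,
                                         rep("bowel_sound", length(on_p)))
    else events_table()
    res <- evaluate_detector(pr, tr, tol)
    want <- oracle_max_matching(pr$onset_s, tr$onset_s, tol)
    expect_equal(res$n_matched_correct, want)
  }
  # the bound holds even on adversarial overlapping configurations
  for (rep in 1:10) {
    on_t <- sort(runif(4, 0, 0.5))
    on_p <- sort(runif(4, 0, 0.5))
    tr <- events_table(on_t, on_t + 0.05, rep("bowel_sound", 4))
    pr <- events_table(on_p, on_p + 0.05, rep("bowel_sound", 4))
    res <- evaluate_detector(pr, tr, 0.1)
    expect_lte(res$n_matched_correct,
               oracle_max_matching(on_p, on_t, 0.1))
  }
})
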