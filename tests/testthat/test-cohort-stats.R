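# Usability filtering, descriptive routing and the statistical layer.

test_that("the usability filter reproduces the enrollment arithmetic", {
  man <- data.frame(
    infant_id = sprintf("i%02d", 1:82),
    usability = c(rep("usable", 68), rep("sensor_fell_off", 6),
                  rep("battery_ran_out", 4), rep("removed_early", 4)))
  uf <- usability_filter(man)
  expect_equal(nrow(uf$usable), 68L)
  expect_equal(unname(uf$tally),
               c(6L, 4L, 4L))
  all_ok <- data.frame(infant_id = "a", usability = "usable")
  expect_identical(usability_filter(all_ok)$usable, all_ok)
  empty <- man[0, ]
  uf0 <- usability_filter(empty)
  expect_equal(nrow(uf0$usable), 0L)
  expect_true(all(uf0$tally == 0L))
  bad <- data.frame(usability = "lost_in_mail")
  expect_error(usability_filter(bad), "unknown usability")
})

test_that("description routes by Shapiro-Wilk and matches direct formulas", {
  set.seed(20)
  v <- rnorm(20)
  d <- describe(v)
  expect_equal(d$mean, sum(v) / 20, tolerance = 1e-9)
  expect_equal(d$sd, sqrt(sum((v - mean(v))^2) / 19), tolerance = 1e-9)
  expect_equal(d$route, "normal")
  skewed <- exp(rnorm(50, 0, 1.5))
  expect_equal(describe(skewed)$route, "non_normal")
  expect_equal(describe(c(1, 2, 3))$median, 2)
  expect_message(dc <- describe(rep(5, 10)), "constant")
  expect_equal(dc$route, "non_normal")
  expect_equal(dc$q3 - dc$q1, 0)
})

test_that("identical groups give a null Kruskal-Wallis result", {
  g <- rep(c("a", "b", "c"), each = 4)
  v <- rep(c(1, 2, 3, 4), times = 3)
  res <- compare_groups_ranksum(v, g, pairwise = FALSE)
  expect_equal(res$omnibus$statistic, 0, tolerance = 1e-12)
  expect_equal(res$omnibus$p, 1, tolerance = 1e-12)
})

test_that("the Kruskal-Wallis statistic matches the rank-formula oracle", {
  groups <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  v <- unlist(groups)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- compare_groups_ranksum(v, g, pairwise = FALSE)
  expect_equal(res$omnibus$statistic, oracle_kruskal_h(groups),
               tolerance = 1e-12)
})

test_that("site comparison separates abdomen from blank profiles", {
  set.seed(21)
  rates_abd <- vapply(1:10, function(s) {
    sched <- sample_event_schedule(site_profile("abdomen_rlq"), 600,
                                   seed = 500 + s)
    rs <- recording_summary(minute_summaries(sched, 600))
    rs$median[rs$parameter == "rate"]
  }, numeric(1))
  df <- data.frame(site = rep(c("abdomen_rlq", "blank"), each = 10),
                   rate = c(rates_abd, rep(0, 10)),
                   duration_s_per_min = c(rates_abd * 0.3, rep(0, 10)),
                   amplitude = 0.4, dominant_freq_hz = 900,
                   mean_interval_s = 2)
  res <- suppressWarnings(compare_sites(df, parameters = "rate"))
  expect_lt(res$rate$omnibus$p, 0.001)
})

test_that("a missing site triggers a warning but still compares", {
  df <- data.frame(site = rep(c("abdomen_rlq", "blank"), each = 5),
                   rate = c(rnorm(5, 25), rep(0, 5)))
  expect_warning(res <- compare_sites(df, parameters = "rate"),
                 "missing")
})

test_that("pairwise rank-sum tests apply the Bonferroni definition", {
  set.seed(22)
  v <- c(rnorm(6), rnorm(6, 3), rnorm(6, 6))
  g <- rep(c("a", "b", "c"), each = 6)
  res <- compare_groups_ranksum(v, g, adjust = "bonferroni")
  expect_equal(res$pairwise$p_adj, pmin(1, res$pairwise$p_raw * 3))
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p_raw))
  # identical groups: adjusted pairwise p collapses to 1
  same <- compare_groups_ranksum(rep(c(1, 2, 3, 4), 2),
                                 rep(c("x", "y"), each = 4))
  expect_equal(same$pairwise$p_adj, 1)
})

test_that("small-sample rank-sum p equals the exact enumeration oracle", {
  a <- c(1, 2, 3, 4); b <- c(10, 11, 12, 13)
  res <- compare_groups_ranksum(c(a, b), rep(c("a", "b"), each = 4))
  expect_equal(res$pairwise$p_raw, oracle_ranksum_exact_p(a, b),
               tolerance = 1e-12)
})

test_that("groups below the minimum size are excluded with a warning", {
  v <- c(1, 2, 3, 4, 5, 6, 99)
  g <- c(rep("a", 3), rep("b", 3), "tiny")
  expect_warning(res <- compare_groups_ranksum(v, g), "n < 2")
  expect_equal(nrow(res$summaries), 2L)
})

test_that("two-cohort contrasts route by normality and handle identity", {
  set.seed(23)
  study <- data.frame(rate = rnorm(10, 25, 3))
  ctrl <- data.frame(rate = rnorm(10, 25, 3))
  res <- compare_two_cohorts(study, study, parameters = "rate")
  expect_gt(res$p, 0.99)
  shifted <- data.frame(rate = ctrl$rate + 15)   # 5 SD apart
  res2 <- compare_two_cohorts(shifted, ctrl, parameters = "rate")
  expect_lt(res2$p, 0.05)
  skew <- data.frame(rate = exp(rnorm(30, 0, 1.5)))
  res3 <- compare_two_cohorts(skew, skew, parameters = "rate")
  expect_equal(res3$test, "mann_whitney")
  expect_error(compare_two_cohorts(study[1:2, , drop = FALSE], ctrl),
               "at least 3")
})

test_that("Welch t on identical toy vectors is zero", {
  tt <- stats::t.test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(tt$statistic), 0)
})

test_that("chi-square matches the direct Pearson formula", {
  res0 <- chi_square_counts(matrix(c(10, 10, 10, 10), 2))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)
  tab <- matrix(c(20, 10, 10, 20), 2, byrow = TRUE)
  res <- chi_square_counts(tab)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - e)^2 / e), tolerance = 1e-12)
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(res$df, 1)
  tab3 <- matrix(c(5, 6, 7, 8, 9, 10), 2, 3)
  expect_equal(chi_square_counts(tab3)$df, (2 - 1) * (3 - 1))
  expect_error(chi_square_counts(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

fake_minutes <- function(rate_vec) {
  n <- length(rate_vec)
  data.frame(minute_index = 0:(n - 1), rate = rate_vec,
             duration_s_per_min = rate_vec * 0.3, amplitude = 0.4,
             dominant_freq_hz = 900, mean_interval_s = 2,
             display_class = "bowel_sound")
}

test_that("paired phototherapy contrast matches the closed-form t", {
  # ten infants, first 5 of 10 minutes under phototherapy; rate differences
  # across infants are exactly {1,2,3,4,5} repeated
  diffs <- rep(c(1, 2, 3, 4, 5), 2)
  mins <- list(); ivs <- list()
  for (i in seq_along(diffs)) {
    id <- sprintf("i%02d", i)
    mins[[id]] <- fake_minutes(c(rep(20 + diffs[i], 5), rep(20, 5)))
    ivs[[id]] <- data.frame(start_s = 0, end_s = 300)
  }
  res <- phototherapy_paired(mins, ivs, duration_s = 600,
                             parameters = "rate")
  d <- diffs
  expect_equal(res$mean_diff, mean(d), tolerance = 1e-12)
  expect_equal(res$sd_diff, sd(d), tolerance = 1e-12)
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(length(d))), tolerance = 1e-12)
  tc <- qt(0.975, length(d) - 1)
  expect_equal(res$ci95_low, mean(d) - tc * sd(d) / sqrt(length(d)),
               tolerance = 1e-12)
  expect_equal(res$n_pairs, 10L)
})

test_that("zero differences give a null paired result centred at zero", {
  mins <- list(); ivs <- list()
  for (i in 1:5) {
    id <- sprintf("i%02d", i)
    mins[[id]] <- fake_minutes(rep(20, 10))
    ivs[[id]] <- data.frame(start_s = 0, end_s = 300)
  }
  res <- phototherapy_paired(mins, ivs, 600, parameters = "rate")
  expect_equal(res$mean_diff, 0)
  expect_equal(res$t, 0)
  expect_equal(res$ci95_low, 0)
  expect_equal(res$ci95_high, 0)
})

test_that("infants without both statuses are excluded before testing", {
  mins <- list(); ivs <- list()
  for (i in 1:4) {
    id <- sprintf("i%02d", i)
    mins[[id]] <- fake_minutes(rep(20, 10))
    ivs[[id]] <- data.frame(start_s = 0, end_s = 300)
  }
  ivs$i03 <- data.frame(start_s = numeric(0), end_s = numeric(0))  # none
  ivs$i04 <- data.frame(start_s = 0, end_s = 600)                  # throughout
  res <- phototherapy_paired(mins, ivs, 600, parameters = "rate")
  expect_equal(res$n_pairs, 2L)
})
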