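# Cohort-level statistics: usability filtering, normality-routed
# description, site and feeding-group comparisons, two-cohort contrast,
# chi-square counts and the paired phototherapy self-comparison.
#
# The statistical machinery (Shapiro-Wilk, Kruskal-Wallis, rank-sum, Welch
# t, chi-square, paired t) is base R; this layer pins the routing rules,
# adjustment and reporting shapes.

#' Filter a manifest to usable infants
#'
#' Splits the manifest into usable records and an exclusion tally per
#' reason (sensor fell off, battery ran out, removed early).
#'
#' @param manifest `data.frame` with a `usability` column.
#' @return list with `usable` (data.frame) and `tally` (named integer).
#' @export
usability_filter <- function(manifest) {
  assert_that(is.data.frame(manifest) && "usability" %in% names(manifest),
              "manifest must have a usability column")
  bad <- setdiff(unique(manifest$usability), USABILITY)
  assert_that(length(bad) == 0,
              sprintf("unknown usability code(s): %s", paste(bad, collapse = ", ")))
  tally <- vapply(USABILITY[-1], function(r) sum(manifest$usability == r),
                  integer(1))
  list(usable = manifest[manifest$usability == "usable", , drop = FALSE],
       tally = tally)
}

#' Normality-routed description of a sample
#'
#' Shapiro-Wilk at alpha = 0.05 routes between mean +/- SD (normal) and
#' median \[Q1, Q3\] (non-normal); both summaries are always reported along
#' with the route taken.  Constant input cannot be tested and takes the
#' non-normal route with a zero-width IQR.
#'
#' @param values numeric vector (n >= 3).
#' @param alpha routing significance level.
#' @return list of class `bs_describe`: `route`, `shapiro_p`, `mean`, `sd`,
#'   `median`, `q1`, `q3`, `n`.
#' @export
describe <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  assert_that(length(values) >= 3, "need at least 3 finite values")
  sw_p <- tryCatch(stats::shapiro.test(values)$p.value,
                   error = function(e) {
                     message("describe(): constant input, non-normal route")
                     0
                   })
  structure(list(route = if (sw_p >= alpha) "normal" else "non_normal",
                 shapiro_p = sw_p,
                 mean = mean(values), sd = stats::sd(values),
                 median = quantile7(values, 0.5),
                 q1 = quantile7(values, 0.25), q3 = quantile7(values, 0.75),
                 n = length(values)),
            class = "bs_describe")
}

#' @export
print.bs_describe <- function(x, ...) {
  cat(sprintf("n=%d, route=%s (Shapiro-Wilk p=%.3g)\n", x$n, x$route,
              x$shapiro_p))
  cat(sprintf("  mean +/- SD: %.3f +/- %.3f | median [IQR]: %.3f [%.3f, %.3f]\n",
              x$mean, x$sd, x$median, x$q1, x$q3))
  invisible(x)
}

group_summary_df <- function(values, group) {
  do.call(rbind, lapply(levels(group), function(g) {
    v <- values[group == g]
    data.frame(group = g, n = length(v),
               median = quantile7(v, 0.5), q1 = quantile7(v, 0.25),
               q3 = quantile7(v, 0.75))
  }))
}

#' Kruskal-Wallis comparison with optional pairwise rank-sum tests
#'
#' The non-parametric group comparison used for both the site-specificity
#' contrast and the feeding-group tables: a Kruskal-Wallis omnibus test
#' plus, when requested, pairwise two-sided Wilcoxon rank-sum tests with
#' multiplicity adjustment (Bonferroni by default: raw p times the number
#' of pairs, capped at 1).  Groups with fewer than 2 observations are
#' excluded with a warning.
#'
#' @param values numeric vector.
#' @param group grouping factor (or coercible).
#' @param pairwise compute pairwise rank-sum tests?
#' @param adjust p-adjustment method for the pairwise tests
#'   (see [stats::p.adjust()]).
#' @param parameter optional label carried in the result.
#' @return object of class `bs_group_comparison`.
#' @export
compare_groups_ranksum <- function(values, group, pairwise = TRUE,
                                   adjust = "bonferroni",
                                   parameter = NA_character_) {
  group <- factor(group)
  keep_g <- names(which(table(group) >= 2))
  if (length(keep_g) < nlevels(group))
    warning("excluding group(s) with n < 2: ",
            paste(setdiff(levels(group), keep_g), collapse = ", "),
            call. = FALSE)
  sel <- group %in% keep_g
  values <- values[sel]; group <- droplevels(group[sel])
  assert_that(nlevels(group) >= 2, "need at least 2 groups with n >= 2")
  kw <- stats::kruskal.test(values, group)
  pw <- NULL
  if (pairwise && nlevels(group) >= 2) {
    pairs <- utils::combn(levels(group), 2)
    p_raw <- apply(pairs, 2, function(pr)
      suppressWarnings(stats::wilcox.test(values[group == pr[1]],
                                          values[group == pr[2]],
                                          exact = NULL)$p.value))
    p_adj <- stats::p.adjust(p_raw, method = adjust)
    pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                     p_raw = p_raw, p_adj = p_adj)
  }
  structure(list(parameter = parameter,
                 summaries = group_summary_df(values, group),
                 omnibus = list(test = "Kruskal-Wallis",
                                statistic = unname(kw$statistic),
                                df = unname(kw$parameter),
                                p = kw$p.value),
                 pairwise = pw, adjust = adjust),
            class = "bs_group_comparison")
}

#' @export
print.bs_group_comparison <- function(x, ...) {
  if (!is.na(x$parameter)) cat(sprintf("Parameter: %s\n", x$parameter))
  for (i in seq_len(nrow(x$summaries)))
    cat(sprintf("  %-10s n=%3d  %.2f [%.2f, %.2f]\n", x$summaries$group[i],
                x$summaries$n[i], x$summaries$median[i], x$summaries$q1[i],
                x$summaries$q3[i]))
  cat(sprintf("  %s: H = %.3f, df = %d, p = %.4g\n", x$omnibus$test,
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p))
  if (!is.null(x$pairwise))
    for (i in seq_len(nrow(x$pairwise)))
      cat(sprintf("  %s vs %s: raw p = %.4g, adj p (%s) = %.4g\n",
                  x$pairwise$group1[i], x$pairwise$group2[i],
                  x$pairwise$p_raw[i], x$adjust, x$pairwise$p_adj[i]))
  invisible(x)
}

#' Site-specificity comparison
#'
#' Kruskal-Wallis omnibus per acoustic parameter across the recording sites
#' (normal abdominal site, chest control, blank control), with per-site
#' median \[IQR\] summaries.  A site absent from the data is dropped with a
#' warning and the remaining sites compared.
#'
#' @param summaries `data.frame` of per-recording parameter medians with a
#'   `site` column (see [cohort_recording_summaries()]).
#' @param parameters parameter columns to compare.
#' @param site_col name of the site column.
#' @return named list of `bs_group_comparison`, one per parameter.
#' @export
compare_sites <- function(summaries, parameters = PARAM_NAMES,
                          site_col = "site") {
  assert_that(site_col %in% names(summaries),
              sprintf("summaries must have a `%s` column", site_col))
  present <- intersect(SITES, unique(summaries[[site_col]]))
  if (length(present) < 3)
    warning("site(s) missing: ", paste(setdiff(SITES, present), collapse = ", "),
            "; comparing the remaining sites", call. = FALSE)
  assert_that(length(present) >= 2, "need at least two sites")
  out <- lapply(parameters, function(p)
    compare_groups_ranksum(summaries[[p]],
                           factor(summaries[[site_col]], levels = present),
                           pairwise = FALSE, parameter = p))
  stats::setNames(out, parameters)
}

#' Two-cohort comparison with normality routing
#'
#' For each parameter, both cohorts are tested with Shapiro-Wilk; when both
#' pass (p >= alpha) a Welch two-sample t-test is used and the summaries are
#' mean +/- SD, otherwise a two-sided Mann-Whitney rank-sum test with
#' median \[IQR\] summaries.
#'
#' @param study,control `data.frame`s of per-infant parameter values.
#' @param parameters columns to compare.
#' @param alpha Shapiro-Wilk routing level.
#' @return `data.frame`, one row per parameter, class `bs_cohort_contrast`.
#' @export
compare_two_cohorts <- function(study, control, parameters = PARAM_NAMES,
                                alpha = 0.05) {
  assert_that(nrow(study) >= 3 && nrow(control) >= 3,
              "both cohorts need at least 3 infants")
  rows <- lapply(parameters, function(p) {
    a <- study[[p]]; b <- control[[p]]
    sw_a <- tryCatch(stats::shapiro.test(a)$p.value, error = function(e) 0)
    sw_b <- tryCatch(stats::shapiro.test(b)$p.value, error = function(e) 0)
    normal <- sw_a >= alpha && sw_b >= alpha
    if (normal) {
      tt <- stats::t.test(a, b)
      data.frame(parameter = p, test = "welch_t",
                 statistic = unname(tt$statistic), p = tt$p.value,
                 study_summary = sprintf("%.2f (%.2f)", mean(a), stats::sd(a)),
                 control_summary = sprintf("%.2f (%.2f)", mean(b), stats::sd(b)))
    } else {
      wt <- suppressWarnings(stats::wilcox.test(a, b))
      data.frame(parameter = p, test = "mann_whitney",
                 statistic = unname(wt$statistic), p = wt$p.value,
                 study_summary = sprintf("%.2f [%.2f, %.2f]",
                                         quantile7(a, .5), quantile7(a, .25),
                                         quantile7(a, .75)),
                 control_summary = sprintf("%.2f [%.2f, %.2f]",
                                           quantile7(b, .5), quantile7(b, .25),
                                           quantile7(b, .75)))
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bs_cohort_contrast", "data.frame")
  out
}

#' Pearson chi-square test on a contingency table
#'
#' Without continuity correction, as used for count data expressed by
#' frequency and percentage.
#'
#' @param tab matrix (or table) of non-negative counts.
#' @return list with `statistic`, `df`, `p`, `expected`.
#' @export
chi_square_counts <- function(tab) {
  tab <- as.matrix(tab)
  assert_that(all(tab >= 0) && all(is.finite(tab)),
              "counts must be non-negative and finite")
  assert_that(all(rowSums(tab) > 0) && all(colSums(tab) > 0),
              "contingency table has a zero marginal")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}

interval_overlap <- function(lo, hi, intervals) {
  if (!nrow(intervals)) return(0)
  sum(pmax(0, pmin(hi, intervals$end_s) - pmax(lo, intervals$start_s)))
}

#' Paired phototherapy self-comparison
#'
#' Implements the within-infant phototherapy contrast: infants with no
#' phototherapy or with phototherapy throughout the monitoring window are
#' excluded first; every minute is assigned phototherapy / non-phototherapy
#' status by majority temporal overlap with the infant's interval log;
#' infants with fewer than `min_minutes` minutes in either status are
#' excluded with a warning.  Per infant and status the parameter means are
#' taken, and a paired t-test is run on the per-infant (phototherapy minus
#' non-phototherapy) differences, with a 95% t-distribution confidence
#' interval on n-1 degrees of freedom.
#'
#' @param minutes_list named list of `bs_minutes` tables keyed by infant id.
#' @param intervals_list named list of interval `data.frame`s
#'   (`start_s`, `end_s`) keyed by infant id.
#' @param duration_s monitoring duration per infant (s).
#' @param parameters parameter columns to compare.
#' @param min_minutes minimum minutes required in each status.
#' @return `data.frame` of class `bs_paired_comparison`: one row per
#'   parameter with `mean_diff`, `sd_diff`, `ci95_low`, `ci95_high`, `t`,
#'   `p`, `n_pairs`.
#' @export
phototherapy_paired <- function(minutes_list, intervals_list, duration_s,
                                parameters = PARAM_NAMES, min_minutes = 5) {
  ids <- names(minutes_list)
  assert_that(all(ids %in% names(intervals_list)),
              "every infant needs a phototherapy interval log")
  diffs <- list()
  dropped <- character(0)
  for (id in ids) {
    iv <- intervals_list[[id]]
    cover <- interval_overlap(0, duration_s, iv)
    if (cover <= 0 || cover >= duration_s - 1e-6) next  # none or throughout
    mins <- minutes_list[[id]]
    ov <- vapply(mins$minute_index, function(m) {
      w_lo <- 60 * m; w_hi <- min(60 * (m + 1), duration_s)
      interval_overlap(w_lo, w_hi, iv) / (w_hi - w_lo)
    }, numeric(1))
    photo <- ov > 0.5
    if (sum(photo) < min_minutes || sum(!photo) < min_minutes) {
      dropped <- c(dropped, id)
      next
    }
    d <- vapply(parameters, function(p)
      mean(mins[[p]][photo]) - mean(mins[[p]][!photo]), numeric(1))
    diffs[[id]] <- d
  }
  if (length(dropped))
    warning(sprintf("excluded %d infant(s) with < %d minutes in a status",
                    length(dropped), min_minutes), call. = FALSE)
  assert_that(length(diffs) >= 2,
              "fewer than 2 infants with both statuses present")
  D <- do.call(rbind, diffs)
  n <- nrow(D)
  rows <- lapply(parameters, function(p) {
    d <- D[, p]
    m <- mean(d); s <- stats::sd(d)
    se <- s / sqrt(n)
    tstat <- if (se > 0) m / se else 0
    tc <- stats::qt(0.975, n - 1)
    data.frame(parameter = p, mean_diff = m, sd_diff = s,
               ci95_low = m - tc * se, ci95_high = m + tc * se,
               t = tstat,
               p = if (se > 0) 2 * stats::pt(-abs(tstat), n - 1) else 1,
               n_pairs = n)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bs_paired_comparison", "data.frame")
  out
}
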