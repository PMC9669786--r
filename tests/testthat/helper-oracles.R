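# Independent oracle implementations used to cross-check the package.
# Everything here is written directly from textbook definitions and kept
# free of the package's own code paths.

# --- MFCC reference chain: explicit per-frame filterbank multiplication and
#     DCT summation -----------------------------------------------------------
oracle_mfcc_frame <- function(frame, sample_rate_hz, n_mels, n_coeffs,
                              fmin, fmax, log_floor = 1e-10) {
  L <- length(frame)
  n_fft <- 2^ceiling(log2(L))
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / (L - 1))
  padded <- c(frame * win, rep(0, n_fft - L))
  spec <- fft(padded)[1:(n_fft / 2 + 1)]
  power <- Mod(spec)^2
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  edges <- imel(seq(mel(fmin), mel(fmax), length.out = n_mels + 2))
  bin_hz <- (0:(n_fft / 2)) * sample_rate_hz / n_fft
  energies <- numeric(n_mels)
  for (m in 1:n_mels) {
    w <- pmax(0, pmin((bin_hz - edges[m]) / (edges[m + 1] - edges[m]),
                      (edges[m + 2] - bin_hz) / (edges[m + 2] - edges[m + 1])))
    energies[m] <- sum(w * power)
  }
  loge <- log(pmax(energies, log_floor))
  out <- numeric(n_coeffs)
  for (k in 0:(n_coeffs - 1)) {
    s <- 0
    for (m in 0:(n_mels - 1))
      s <- s + loge[m + 1] * cos(pi * k * (m + 0.5) / n_mels)
    scale <- if (k == 0) sqrt(1 / n_mels) else sqrt(2 / n_mels)
    out[k + 1] <- scale * s
  }
  out
}

# --- loess: direct per-point tricube weighted least squares -----------------
oracle_loess_point <- function(x, y, x0, span, degree) {
  n <- length(x)
  q <- min(n, max(degree + 1, floor(span * n)))
  d <- abs(x - x0)
  idx <- order(d)[1:q]
  h <- max(d[idx])
  w <- if (h > 0) (1 - pmin(d[idx] / h, 1)^3)^3 else rep(1, q)
  X <- outer(x[idx] - x0, 0:degree, `^`)
  WX <- X * w
  beta <- solve(t(WX) %*% X, t(WX) %*% y[idx])
  beta[1]
}

# --- Kruskal-Wallis statistic from the rank formula -------------------------
oracle_kruskal_h <- function(groups) {
  all_v <- unlist(groups)
  N <- length(all_v)
  rk <- rank(all_v)
  idx <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  h <- 12 / (N * (N + 1)) *
    sum(vapply(seq_along(groups), function(i) {
      ri <- rk[idx == i]
      length(ri) * (mean(ri) - (N + 1) / 2)^2
    }, numeric(1)))
  ties <- table(all_v)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# --- exact two-sided rank-sum p by full enumeration (no ties) ---------------
oracle_ranksum_exact_p <- function(a, b) {
  n <- length(a); m <- length(b)
  all_v <- c(a, b)
  rk <- rank(all_v)
  w_obs <- sum(rk[1:n]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  ws <- apply(combs, 2, function(ix) sum(rank(all_v)[ix]) - n * (n + 1) / 2)
  mu <- n * m / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# --- exhaustive one-to-one onset matching: maximum number of matches --------
oracle_max_matching <- function(on_pred, on_truth, tol) {
  np <- length(on_pred); nt <- length(on_truth)
  if (np == 0 || nt == 0) return(0L)
  best <- 0L
  # recursion over truth indices
  rec <- function(ti, used_pred) {
    if (ti > nt) return(0L)
    res <- rec(ti + 1, used_pred)          # leave truth ti unmatched
    for (pi in seq_len(np)) {
      if (!used_pred[pi] && abs(on_pred[pi] - on_truth[ti]) <= tol) {
        u <- used_pred; u[pi] <- TRUE
        res <- max(res, 1L + rec(ti + 1, u))
      }
    }
    res
  }
  rec(1L, logical(np))
}

# --- brute-force run-length decoding of frame labels ------------------------
oracle_frames_to_events <- function(labels, hop, flen, min_event, merge_gap) {
  out <- list()
  for (cls in setdiff(unique(labels), "background")) {
    is_c <- labels == cls
    spans <- list()
    i <- 1
    while (i <= length(labels)) {
      if (is_c[i]) {
        j <- i
        while (j < length(labels) && is_c[j + 1]) j <- j + 1
        spans[[length(spans) + 1]] <- c((i - 1) * hop, (j - 1) * hop + flen)
        i <- j + 1
      } else i <- i + 1
    }
    if (!length(spans)) next
    merged <- list(spans[[1]])
    for (s in spans[-1]) {
      last <- merged[[length(merged)]]
      if (s[1] - last[2] < merge_gap)
        merged[[length(merged)]] <- c(last[1], max(last[2], s[2]))
      else merged[[length(merged) + 1]] <- s
    }
    for (s in merged)
      if (s[2] - s[1] >= min_event)
        out[[length(out) + 1]] <- data.frame(onset_s = s[1], offset_s = s[2],
                                             label = cls)
  }
  if (!length(out)) return(data.frame(onset_s = numeric(0),
                                      offset_s = numeric(0),
                                      label = character(0)))
  df <- do.call(rbind, out)
  df[order(df$onset_s), , drop = FALSE]
}

EVENT_LABELS_TEST <- c("bowel_sound", "speech", "friction_other")

# small convenience: a quick abdomen rendering reused across tests
quick_recording <- function(duration_s = 60, seed = 11, site = "abdomen_rlq",
                            profile = NULL) {
  simulate_recording(site, duration_s = duration_s, seed = seed,
                     profile = profile)
}
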