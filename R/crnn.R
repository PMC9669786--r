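# Convolutional-recurrent frame classifier: five 1-D convolution layers over
# time, a bi-directional GRU, and a fully connected softmax output, with
# hand-written backpropagation and Adam.  Implemented in base R matrix ops.
#
# Batch layout: a batch of B sequences of T frames is a (T*B) x C matrix in
# time-major order, row (t-1)*B + b holding frame t of sequence b.  This
# makes both the convolution (row-block shifts) and the GRU (one B x C slice
# per timestep) single matrix products.

CRNN_CLASSES <- c("background", "bowel_sound", "speech", "friction_other")

#' CRNN configuration
#'
#' Architecture and training settings for the frame classifier: five
#' 1-D convolutional layers (kernel width 3 over time) with the given
#' channel counts, a bi-directional gated recurrent unit layer, and one
#' fully connected output layer over the four classes (background,
#' bowel sound, speech, friction/other).
#'
#' @param conv_channels integer vector of length 5, output channels per
#'   convolutional layer.
#' @param hidden GRU hidden size per direction.
#' @param epochs,batch_size,learning_rate Adam training settings.
#' @param chunk_len training sequence length in frames.
#' @param class_weights `"equal"` (default), `"balanced"` (inverse class
#'   frequency, the standard remedy when background frames dominate), or a
#'   named numeric vector of per-class loss weights.
#' @param seed integer seed controlling initialization and batch order.
#' @return object of class `bs_crnn_config`.
#' @export
crnn_config <- function(conv_channels = c(8, 16, 16, 32, 32), hidden = 64,
                        epochs = 12, batch_size = 32, learning_rate = 3e-3,
                        chunk_len = 50, class_weights = "equal",
                        seed = 42L) {
  assert_that(length(conv_channels) == 5L && all(conv_channels >= 1),
              "the CNN stack has exactly five layers")
  assert_that(hidden >= 1 && epochs >= 1 && batch_size >= 1 && chunk_len >= 2,
              "invalid training settings")
  structure(list(conv_channels = as.integer(conv_channels),
                 hidden = as.integer(hidden), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 chunk_len = as.integer(chunk_len),
                 class_weights = class_weights, seed = as.integer(seed),
                 classes = CRNN_CLASSES),
            class = "bs_crnn_config")
}

glorot <- function(nin, nout) {
  matrix(stats::runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)), nin, nout)
}

crnn_init_params <- function(n_in, cfg) {
  p <- list()
  cin <- n_in
  for (l in 1:5) {
    cout <- cfg$conv_channels[l]
    for (k in 1:3) p[[sprintf("conv%d_W%d", l, k)]] <- glorot(cin, cout) / sqrt(3)
    p[[sprintf("conv%d_b", l)]] <- numeric(cout)
    cin <- cout
  }
  H <- cfg$hidden
  for (d in c("f", "b")) {
    p[[paste0("gru_Wx_", d)]] <- glorot(cin, 3 * H)
    p[[paste0("gru_Wh_", d)]] <- glorot(H, 3 * H)
    p[[paste0("gru_b_", d)]] <- numeric(3 * H)
  }
  p$out_W <- glorot(2 * H, length(cfg$classes))
  p$out_b <- numeric(length(cfg$classes))
  p
}

# row-block shifts in time-major layout
shift_prev <- function(M, T_len, B) {   # block t <- block t-1, zeros at t=1
  if (T_len == 1L) return(matrix(0, B, ncol(M)))
  rbind(matrix(0, B, ncol(M)), M[seq_len((T_len - 1) * B), , drop = FALSE])
}
shift_next <- function(M, T_len, B) {   # block t <- block t+1, zeros at t=T
  if (T_len == 1L) return(matrix(0, B, ncol(M)))
  rbind(M[(B + 1):(T_len * B), , drop = FALSE], matrix(0, B, ncol(M)))
}
rev_time_perm <- function(T_len, B)
  unlist(lapply(rev(seq_len(T_len)), function(t) ((t - 1) * B + 1):(t * B)))

sigm <- function(x) 1 / (1 + exp(-x))

gru_forward <- function(M, T_len, B, Wx, Wh, b) {
  H <- nrow(Wh)
  Gx <- M %*% Wx
  Gx <- sweep(Gx, 2, b, `+`)
  h <- matrix(0, B, H)
  Hs <- matrix(0, T_len * B, H)
  cache <- vector("list", T_len)
  iz <- seq_len(H); ir <- H + iz; inn <- 2 * H + iz
  for (t in seq_len(T_len)) {
    rows <- ((t - 1) * B + 1):(t * B)
    gh <- h %*% Wh
    z <- sigm(Gx[rows, iz, drop = FALSE] + gh[, iz, drop = FALSE])
    r <- sigm(Gx[rows, ir, drop = FALSE] + gh[, ir, drop = FALSE])
    hn_h <- gh[, inn, drop = FALSE]
    nn <- tanh(Gx[rows, inn, drop = FALSE] + r * hn_h)
    h_new <- (1 - z) * nn + z * h
    cache[[t]] <- list(h_prev = h, z = z, r = r, n = nn, hn_h = hn_h)
    h <- h_new
    Hs[rows, ] <- h
  }
  list(Hs = Hs, cache = cache)
}

gru_backward <- function(dHs, M, T_len, B, Wx, Wh, fwd) {
  H <- nrow(Wh)
  iz <- seq_len(H); ir <- H + iz; inn <- 2 * H + iz
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, H, 3 * H)
  db <- numeric(3 * H)
  dM <- matrix(0, nrow(M), ncol(M))
  dh <- matrix(0, B, H)
  for (t in rev(seq_len(T_len))) {
    rows <- ((t - 1) * B + 1):(t * B)
    dh_t <- dHs[rows, , drop = FALSE] + dh
    cc <- fwd$cache[[t]]
    dn <- dh_t * (1 - cc$z)
    dz <- dh_t * (cc$h_prev - cc$n)
    dh_prev <- dh_t * cc$z
    da_n <- dn * (1 - cc$n^2)
    dr <- da_n * cc$hn_h
    dhn_h <- da_n * cc$r
    da_z <- dz * cc$z * (1 - cc$z)
    da_r <- dr * cc$r * (1 - cc$r)
    dG <- cbind(da_z, da_r, da_n)          # grads of x-side pre-activations
    dGh <- cbind(da_z, da_r, dhn_h)        # grads of h-side pre-activations
    x <- M[rows, , drop = FALSE]
    dWx <- dWx + crossprod(x, dG)
    dWh <- dWh + crossprod(cc$h_prev, dGh)
    db <- db + colSums(dG)
    dM[rows, ] <- dG %*% t(Wx)
    dh <- dh_prev + dGh %*% t(Wh)
  }
  list(dWx = dWx, dWh = dWh, db = db, dM = dM)
}

crnn_forward <- function(p, M, T_len, B, n_classes, want_cache = TRUE) {
  acts <- list(M)
  A <- M
  for (l in 1:5) {
    W1 <- p[[sprintf("conv%d_W1", l)]]
    W2 <- p[[sprintf("conv%d_W2", l)]]
    W3 <- p[[sprintf("conv%d_W3", l)]]
    Y <- shift_prev(A, T_len, B) %*% W1 + A %*% W2 +
      shift_next(A, T_len, B) %*% W3
    Y <- sweep(Y, 2, p[[sprintf("conv%d_b", l)]], `+`)
    A <- pmax(Y, 0)
    acts[[l + 1]] <- A
  }
  fwd_f <- gru_forward(A, T_len, B, p$gru_Wx_f, p$gru_Wh_f, p$gru_b_f)
  perm <- rev_time_perm(T_len, B)
  fwd_b <- gru_forward(A[perm, , drop = FALSE], T_len, B,
                       p$gru_Wx_b, p$gru_Wh_b, p$gru_b_b)
  Hcat <- cbind(fwd_f$Hs, fwd_b$Hs[perm, , drop = FALSE])
  logits <- sweep(Hcat %*% p$out_W, 2, p$out_b, `+`)
  out <- list(logits = logits)
  if (want_cache)
    out <- c(out, list(acts = acts, fwd_f = fwd_f, fwd_b = fwd_b,
                       Hcat = Hcat, perm = perm))
  out
}

softmax_rows <- function(logits) {
  z <- exp(logits - apply(logits, 1, max))
  z / rowSums(z)
}

crnn_backward <- function(p, fw, y_int, T_len, B, w_class = NULL) {
  N <- length(y_int)
  probs <- softmax_rows(fw$logits)
  w <- if (is.null(w_class)) rep(1, N) else w_class[y_int]
  wsum <- sum(w)
  loss <- -sum(w * log(pmax(probs[cbind(seq_len(N), y_int)], 1e-12))) / wsum
  dlogits <- probs
  dlogits[cbind(seq_len(N), y_int)] <- dlogits[cbind(seq_len(N), y_int)] - 1
  dlogits <- dlogits * (w / wsum)
  g <- list()
  g$out_W <- crossprod(fw$Hcat, dlogits)
  g$out_b <- colSums(dlogits)
  dHcat <- dlogits %*% t(p$out_W)
  H <- ncol(fw$fwd_f$Hs)
  A <- fw$acts[[6]]
  gf <- gru_backward(dHcat[, seq_len(H), drop = FALSE], A, T_len, B,
                     p$gru_Wx_f, p$gru_Wh_f, fw$fwd_f)
  perm <- fw$perm
  gb <- gru_backward(dHcat[perm, H + seq_len(H), drop = FALSE],
                     A[perm, , drop = FALSE], T_len, B,
                     p$gru_Wx_b, p$gru_Wh_b, fw$fwd_b)
  g$gru_Wx_f <- gf$dWx; g$gru_Wh_f <- gf$dWh; g$gru_b_f <- gf$db
  g$gru_Wx_b <- gb$dWx; g$gru_Wh_b <- gb$dWh; g$gru_b_b <- gb$db
  dA <- gf$dM + gb$dM[perm, , drop = FALSE]
  for (l in 5:1) {
    A_in <- fw$acts[[l]]
    A_out <- fw$acts[[l + 1]]
    dY <- dA * (A_out > 0)
    g[[sprintf("conv%d_W1", l)]] <- crossprod(shift_prev(A_in, T_len, B), dY)
    g[[sprintf("conv%d_W2", l)]] <- crossprod(A_in, dY)
    g[[sprintf("conv%d_W3", l)]] <- crossprod(shift_next(A_in, T_len, B), dY)
    g[[sprintf("conv%d_b", l)]] <- colSums(dY)
    dA <- shift_next(dY, T_len, B) %*% t(p[[sprintf("conv%d_W1", l)]]) +
      dY %*% t(p[[sprintf("conv%d_W2", l)]]) +
      shift_prev(dY, T_len, B) %*% t(p[[sprintf("conv%d_W3", l)]])
  }
  list(loss = loss, grads = g)
}

adam_step <- function(p, g, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(g)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mh <- state$m[[nm]] / (1 - beta1^t)
    vh <- state$v[[nm]] / (1 - beta2^t)
    p[[nm]] <- p[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(p = p, state = state)
}

#' Frame labels from a ground-truth event table
#'
#' Labels each analysis frame by the event class covering the frame centre
#' (`background` when no event does).  Used to build training targets for
#' the CRNN from generator annotations.
#'
#' @param events `bs_events` ground truth.
#' @param n_frames number of frames.
#' @param hop_s,frame_length_s frame geometry.
#' @return character vector of length `n_frames`.
#' @export
frame_labels_from_events <- function(events, n_frames, hop_s = 0.010,
                                     frame_length_s = 0.025) {
  validate_events(events)
  centers <- (seq_len(n_frames) - 1) * hop_s + frame_length_s / 2
  labels <- rep("background", n_frames)
  if (nrow(events)) {
    for (cls in rev(EVENT_LABELS)) {   # bowel_sound applied last: wins overlaps
      ev <- events[events$label == cls, , drop = FALSE]
      for (i in seq_len(nrow(ev))) {
        sel <- centers >= ev$onset_s[i] & centers < ev$offset_s[i]
        labels[sel] <- cls
      }
    }
  }
  labels
}

# chunk a list of (features, labels) pairs into fixed-length sequences
crnn_make_chunks <- function(features_list, labels_list, chunk_len, classes) {
  xs <- list(); ys <- list()
  for (i in seq_along(features_list)) {
    f <- unclass(features_list[[i]])
    y <- match(labels_list[[i]], classes)
    assert_that(!anyNA(y), "unknown frame label")
    assert_that(nrow(f) == length(y),
                "features and frame labels must have equal length")
    n_chunks <- nrow(f) %/% chunk_len
    for (k in seq_len(n_chunks)) {
      rows <- ((k - 1) * chunk_len + 1):(k * chunk_len)
      xs[[length(xs) + 1]] <- f[rows, , drop = FALSE]
      ys[[length(ys) + 1]] <- y[rows]
    }
  }
  list(x = xs, y = ys)
}

# assemble chunks idx into the time-major batch matrix
crnn_batch <- function(chunks, idx, T_len) {
  B <- length(idx)
  C <- ncol(chunks$x[[1]])
  M <- matrix(0, T_len * B, C)
  y <- integer(T_len * B)
  for (b in seq_along(idx)) {
    rows <- seq(b, T_len * B, by = B)
    M[rows, ] <- chunks$x[[idx[b]]]
    y[rows] <- chunks$y[[idx[b]]]
  }
  list(M = M, y = y, B = B)
}

#' Train the CRNN frame classifier
#'
#' Trains the five-layer CNN + bi-GRU + fully-connected network on MFCC
#' feature matrices with aligned per-frame labels, using minibatch Adam on
#' fixed-length sequence chunks.  Features are standardized per coefficient
#' (the scaler is stored in the model and reapplied at prediction).
#' Training is a pure function of (data, config): the same corpus and seed
#' give bit-identical final parameters and loss.
#'
#' @param features_list list of `bs_features` matrices (one per recording).
#' @param labels_list list of character frame-label vectors aligned to
#'   `features_list`.
#' @param config a [crnn_config()].
#' @return object of class `bs_crnn` with the trained parameters, the
#'   feature scaler, and `loss_history` (mean training loss per epoch).
#' @export
train_crnn <- function(features_list, labels_list, config = crnn_config()) {
  assert_that(inherits(config, "bs_crnn_config"), "config must be a crnn_config")
  assert_that(length(features_list) == length(labels_list) &&
                length(features_list) >= 1,
              "features_list and labels_list must be non-empty and aligned")
  for (i in seq_along(features_list))
    assert_that(nrow(features_list[[i]]) == length(labels_list[[i]]),
                "features and frame labels must have equal length")
  all_lab <- unlist(labels_list)
  assert_that(length(unique(all_lab)) >= 2,
              "training data must contain at least two classes")
  X_all <- do.call(rbind, lapply(features_list, unclass))
  mu <- colMeans(X_all)
  sd_ <- pmax(apply(X_all, 2, stats::sd), 1e-8)
  feats_std <- lapply(features_list, function(f)
    sweep(sweep(unclass(f), 2, mu), 2, sd_, `/`))
  chunks <- crnn_make_chunks(feats_std, labels_list, config$chunk_len,
                             config$classes)
  w_class <- NULL
  cw <- config$class_weights
  if (is.character(cw) && identical(cw, "balanced")) {
    cnt <- table(factor(all_lab, levels = config$classes))
    cnt[cnt == 0] <- NA
    w_class <- as.numeric(length(all_lab) / (length(config$classes) * cnt))
    w_class[is.na(w_class)] <- 0
  } else if (is.numeric(cw)) {
    assert_that(all(config$classes %in% names(cw)),
                "class_weights must name every class")
    w_class <- as.numeric(cw[config$classes])
  }
  n_chunks <- length(chunks$x)
  assert_that(n_chunks >= 1, "corpus shorter than one training chunk")
  T_len <- config$chunk_len
  withr::with_seed(config$seed, {
    p <- crnn_init_params(ncol(chunks$x[[1]]), config)
    state <- list(m = lapply(p, function(w) w * 0),
                  v = lapply(p, function(w) w * 0))
    loss_history <- numeric(config$epochs)
    step <- 0L
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n_chunks)
      losses <- numeric(0)
      for (start in seq(1, n_chunks, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n_chunks)]
        bt <- crnn_batch(chunks, idx, T_len)
        fw <- crnn_forward(p, bt$M, T_len, bt$B, length(config$classes))
        bw <- crnn_backward(p, fw, bt$y, T_len, bt$B, w_class)
        step <- step + 1L
        upd <- adam_step(p, bw$grads, state, config$learning_rate, step)
        p <- upd$p; state <- upd$state
        losses <- c(losses, bw$loss)
      }
      loss_history[epoch] <- mean(losses)
    }
    structure(list(params = p, config = config, mu = mu, sd = sd_,
                   classes = config$classes, loss_history = loss_history,
                   n_features = ncol(chunks$x[[1]])),
              class = "bs_crnn")
  })
}

#' @export
print.bs_crnn <- function(x, ...) {
  cat(sprintf("<bs_crnn> 5 conv layers (%s) + bi-GRU(%d) + FC(%d classes)\n",
              paste(x$config$conv_channels, collapse = ","),
              x$config$hidden, length(x$classes)))
  cat(sprintf("  trained %d epochs; loss %.4f -> %.4f\n",
              length(x$loss_history), x$loss_history[1],
              x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' Predict per-frame class probabilities
#'
#' Applies the trained CRNN to a feature matrix.  Long recordings are
#' processed in batched sequence chunks; per-frame class probabilities sum
#' to one and the label is the argmax class.
#'
#' @param object a trained `bs_crnn`.
#' @param features a `bs_features` matrix (same geometry as training).
#' @param chunk_len sequence length used at inference.
#' @param ... unused.
#' @return object of class `bs_frame_labels`: list with `labels`, `probs`,
#'   `hop_s`, `frame_length_s`.
#' @export
predict.bs_crnn <- function(object, features, chunk_len = 400L, ...) {
  assert_that(ncol(features) == object$n_features,
              "feature geometry differs from the training geometry")
  n <- nrow(features)
  X <- sweep(sweep(unclass(features), 2, object$mu), 2, object$sd, `/`)
  if (n == 0L) {
    probs <- matrix(numeric(0), 0, length(object$classes),
                    dimnames = list(NULL, object$classes))
    labels <- character(0)
  } else {
    T_len <- min(chunk_len, n)
    n_chunks <- ceiling(n / T_len)
    pad <- n_chunks * T_len - n
    if (pad > 0) X <- rbind(X, matrix(0, pad, ncol(X)))
    B <- n_chunks
    M <- matrix(0, T_len * B, ncol(X))
    for (b in seq_len(B)) {
      rows_src <- ((b - 1) * T_len + 1):(b * T_len)
      M[seq(b, T_len * B, by = B), ] <- X[rows_src, , drop = FALSE]
    }
    fw <- crnn_forward(object$params, M, T_len, B, length(object$classes),
                       want_cache = FALSE)
    pr <- softmax_rows(fw$logits)
    probs <- matrix(0, T_len * B, length(object$classes))
    for (b in seq_len(B))
      probs[((b - 1) * T_len + 1):(b * T_len), ] <-
      pr[seq(b, T_len * B, by = B), , drop = FALSE]
    probs <- probs[seq_len(n), , drop = FALSE]
    colnames(probs) <- object$classes
    labels <- object$classes[max.col(probs, ties.method = "first")]
  }
  structure(list(labels = labels, probs = probs,
                 hop_s = attr(features, "hop_s") %||% 0.010,
                 frame_length_s = attr(features, "frame_length_s") %||% 0.025),
            class = "bs_frame_labels")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bs_frame_labels <- function(x, ...) {
  cat(sprintf("<bs_frame_labels> %d frames; class counts: %s\n",
              length(x$labels),
              paste(names(table(x$labels)), table(x$labels),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Save / load a trained CRNN as plain text
#'
#' Serializes the model (parameters, scaler, config) to a single
#' JSON-free plain-text file using \code{dput} formatting.
#'
#' @param model a `bs_crnn`.
#' @param path file path.
#' @export
save_crnn <- function(model, path) {
  obj <- unclass(model)
  obj$config <- unclass(obj$config)
  dput(obj, file = path,
       control = c("keepNA", "keepInteger", "niceNames", "showAttributes",
                   "hexNumeric"))
  invisible(path)
}

#' @rdname save_crnn
#' @export
load_crnn <- function(path) {
  obj <- dget(path)
  obj$config <- structure(obj$config, class = "bs_crnn_config")
  structure(obj, class = "bs_crnn")
}
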