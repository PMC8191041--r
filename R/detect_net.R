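#' BrdU detection network
#'
#' A small residual 1-D convolutional network mapping each thymidine's
#' signal-alignment tensor (window of k-mer feature rows) to a two-way
#' softmax over thymidine vs BrdU. Each residual block applies a depthwise
#' convolution along the window, a pointwise (1x1) convolution across
#' channels, batch normalisation and ReLU, with an identity shortcut; the
#' window axis is then flattened into a position-aware two-unit softmax
#' head, so the rows covering the centre thymidine can be weighted
#' differently from context rows.
#'
#' @param blocks Number of residual blocks.
#' @param channels Channel width of the trunk.
#' @param kernel Depthwise kernel width (odd).
#' @param window_W Tensor window width in k-mers.
#' @param features Features per k-mer row.
#' @param seed Seed for weight initialisation (two builds with the same seed
#'   are identical).
#' @return A `detect_model`.
#' @export
build_detect_model <- function(blocks = 6L, channels = 16L, kernel = 5L,
                               window_W = 15L, features = N_TENSOR_FEATURES,
                               seed = 42L) {
  if (kernel %% 2L != 1L) stopf("kernel must be odd")
  if (blocks < 1L || channels < 1L) stopf("invalid architecture shape")
  if (window_W < kernel) stopf("window_W must be at least the kernel width")
  par <- with_seed(seed, {
    p <- list(
      stem_W = matrix(rnorm(features * channels, 0, sqrt(2 / features)), features, channels),
      stem_b = numeric(channels),
      head_W = matrix(rnorm(window_W * channels * 2, 0, sqrt(2 / (window_W * channels))),
                      window_W * channels, 2),
      head_b = numeric(2)
    )
    for (b in seq_len(blocks)) {
      p[[paste0("blk", b, "_dw")]] <- matrix(rnorm(kernel * channels, 0, sqrt(2 / kernel)), kernel, channels)
      p[[paste0("blk", b, "_pw")]] <- matrix(rnorm(channels * channels, 0, sqrt(2 / channels)), channels, channels)
      p[[paste0("blk", b, "_pb")]] <- numeric(channels)
      p[[paste0("blk", b, "_gamma")]] <- rep(1, channels)
      p[[paste0("blk", b, "_beta")]] <- numeric(channels)
    }
    p
  })
  bn <- lapply(seq_len(blocks), function(b) list(mean = numeric(channels),
                                                 var = rep(1, channels)))
  structure(list(par = par, bn = bn,
                 config = list(blocks = blocks, channels = channels,
                               kernel = kernel, window_W = window_W,
                               features = features, seed = seed),
                 trained = FALSE, history = NULL),
            class = "detect_model")
}

#' Number of trainable parameters of a model
#' @param model A `detect_model` or `forksense_model`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$par, length, integer(1)))
}

#' @export
print.detect_model <- function(x, ...) {
  cat(sprintf("<detect_model> %d blocks x %d channels (kernel %d), %d parameters, %s\n",
              x$config$blocks, x$config$channels, x$config$kernel,
              count_parameters(x), if (x$trained) "trained" else "untrained"))
  invisible(x)
}

.BN_EPS <- 1e-5

# Rows of the flattened (sample, window) matrix are ordered sample-fastest;
# shifting the window coordinate by s moves a row by s*N. im2col gathers the
# k shifted copies side by side (zero beyond the window edge), so the
# depthwise convolution followed by the pointwise convolution collapses into
# one matrix product with the composite weight matrix
#   Wcomb[(o,c), c2] = dw[o, c] * pw[c, c2]
# (no nonlinearity sits between the two convolutions).
im2col_w <- function(Hm, N, W, k) {
  C <- ncol(Hm)
  pad <- (k - 1L) %/% 2L
  Xc <- matrix(0, N * W, k * C)
  for (o in seq_len(k)) {
    s <- o - pad - 1L
    wsrc <- (1L + max(0L, s)):(W + min(0L, s))
    rsrc <- as.vector(outer(seq_len(N), (wsrc - 1L) * N, "+"))
    rdst <- rsrc - s * N
    Xc[rdst, ((o - 1L) * C + 1L):(o * C)] <- Hm[rsrc, , drop = FALSE]
  }
  Xc
}

col2im_w <- function(dXc, N, W, k, C) {
  pad <- (k - 1L) %/% 2L
  dH <- matrix(0, N * W, C)
  for (o in seq_len(k)) {
    s <- o - pad - 1L
    wsrc <- (1L + max(0L, s)):(W + min(0L, s))
    rsrc <- as.vector(outer(seq_len(N), (wsrc - 1L) * N, "+"))
    rdst <- rsrc - s * N
    dH[rsrc, ] <- dH[rsrc, ] + dXc[rdst, ((o - 1L) * C + 1L):(o * C), drop = FALSE]
  }
  dH
}

composite_conv_weights <- function(dw, pw) {
  k <- nrow(dw)
  do.call(rbind, lapply(seq_len(k), function(o) pw * dw[o, ]))
}

detect_forward <- function(model, X, train = FALSE) {
  cfg <- model$config
  par <- model$par
  N <- dim(X)[1]; W <- dim(X)[2]
  if (W != cfg$window_W || dim(X)[3] != cfg$features) {
    stopf("tensor shape (%d x %d) does not match model (%d x %d)",
          W, dim(X)[3], cfg$window_W, cfg$features)
  }
  C <- cfg$channels; k <- cfg$kernel
  cache <- list(X = X)
  Hm <- matrix(X, N * W, cfg$features) %*% par$stem_W
  Hm <- sweep(Hm, 2, par$stem_b, "+")
  bn_batch <- vector("list", cfg$blocks)
  for (b in seq_len(cfg$blocks)) {
    dw <- par[[paste0("blk", b, "_dw")]]
    pw <- par[[paste0("blk", b, "_pw")]]
    pb <- par[[paste0("blk", b, "_pb")]]
    gamma <- par[[paste0("blk", b, "_gamma")]]
    beta <- par[[paste0("blk", b, "_beta")]]
    Xc <- im2col_w(Hm, N, W, k)
    Zm <- sweep(Xc %*% composite_conv_weights(dw, pw), 2, pb, "+")
    if (train) {
      mu <- colMeans(Zm)
      v <- colMeans(Zm^2) - mu^2
      bn_batch[[b]] <- list(mean = mu, var = v)
    } else {
      mu <- model$bn[[b]]$mean
      v <- model$bn[[b]]$var
    }
    istd <- 1 / sqrt(v + .BN_EPS)
    Zhat <- sweep(sweep(Zm, 2, mu, "-"), 2, istd, "*")
    Ym <- sweep(sweep(Zhat, 2, gamma, "*"), 2, beta, "+")
    mask <- Ym > 0
    if (train) {
      cache[[paste0("blk", b)]] <- list(Xc = Xc, Zhat = Zhat, istd = istd,
                                        mask = mask)
    }
    Hm <- Hm + Ym * mask
  }
  # position-aware readout: the window axis is flattened, not pooled, so the
  # head can weight the rows covering the centre thymidine differently
  P <- flatten_window(Hm, N, W, C)
  logits <- sweep(P %*% par$head_W, 2, par$head_b, "+")
  m <- pmax(logits[, 1], logits[, 2])
  ez <- exp(logits - m)
  prob <- ez / rowSums(ez)
  cache$P <- P; cache$prob <- prob
  cache$bn_batch <- bn_batch
  list(prob = prob, cache = cache)
}

flatten_window <- function(Hm, N, W, C) {
  P <- matrix(0, N, W * C)
  for (w in seq_len(W)) {
    P[, ((w - 1L) * C + 1L):(w * C)] <- Hm[((w - 1L) * N + 1L):(w * N), , drop = FALSE]
  }
  P
}

unflatten_window <- function(dP, N, W, C) {
  dHm <- matrix(0, N * W, C)
  for (w in seq_len(W)) {
    dHm[((w - 1L) * N + 1L):(w * N), ] <- dP[, ((w - 1L) * C + 1L):(w * C), drop = FALSE]
  }
  dHm
}

detect_backward <- function(model, cache, y) {
  cfg <- model$config
  par <- model$par
  N <- dim(cache$X)[1]; W <- cfg$window_W; C <- cfg$channels; k <- cfg$kernel
  onehot <- cbind(1 - y, y)
  dlogits <- (cache$prob - onehot) / N
  g <- list(head_W = t(cache$P) %*% dlogits,
            head_b = colSums(dlogits))
  dP <- dlogits %*% t(par$head_W)
  dHm <- unflatten_window(dP, N, W, C)
  for (b in rev(seq_len(cfg$blocks))) {
    cb <- cache[[paste0("blk", b)]]
    dw <- par[[paste0("blk", b, "_dw")]]
    pw <- par[[paste0("blk", b, "_pw")]]
    gamma <- par[[paste0("blk", b, "_gamma")]]
    dYm <- dHm * cb$mask
    g[[paste0("blk", b, "_gamma")]] <- colSums(dYm * cb$Zhat)
    g[[paste0("blk", b, "_beta")]] <- colSums(dYm)
    dZhat <- sweep(dYm, 2, gamma, "*")
    m1 <- colMeans(dZhat)
    m2 <- colMeans(dZhat * cb$Zhat)
    dZm <- sweep(sweep(dZhat, 2, m1, "-") -
                   sweep(cb$Zhat, 2, m2, "*"), 2, cb$istd, "*")
    g[[paste0("blk", b, "_pb")]] <- colSums(dZm)
    dWcomb <- t(cb$Xc) %*% dZm
    gdw <- matrix(0, k, C); gpw <- matrix(0, C, C)
    for (o in seq_len(k)) {
      rows <- ((o - 1L) * C + 1L):(o * C)
      gdw[o, ] <- rowSums(dWcomb[rows, , drop = FALSE] * pw)
      gpw <- gpw + dWcomb[rows, , drop = FALSE] * dw[o, ]
    }
    g[[paste0("blk", b, "_dw")]] <- gdw
    g[[paste0("blk", b, "_pw")]] <- gpw
    dXc <- dZm %*% t(composite_conv_weights(dw, pw))
    dHm <- dHm + col2im_w(dXc, N, W, k, C)
  }
  g$stem_W <- t(matrix(cache$X, N * W, cfg$features)) %*% dHm
  g$stem_b <- colSums(dHm)
  g
}

adam_state <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0),
       t = 0L)
}

adam_step <- function(par, grads, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    gmat <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * gmat
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * gmat^2
    par[[nm]] <- par[[nm]] - lr * (st$m[[nm]] / bc1) /
      (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(par = par, state = st)
}

ce_loss <- function(prob, y) {
  p <- pmin(pmax(prob[cbind(seq_along(y), y + 1L)], 1e-12), 1)
  -mean(log(p))
}

#' Train the BrdU detection network
#'
#' Cross-entropy training with a held-out validation split, Adam updates and
#' early stopping on the validation loss. The training set must contain both
#' per-thymidine classes (thymidine and BrdU); labels come from simulator
#' truth, so unsubstituted thymidines inside BrdU-rich reads are genuine
#' negatives.
#'
#' @param model An untrained (or partially trained) `detect_model`.
#' @param x Tensor array `n` x window x features (see
#'   [build_input_tensors()]).
#' @param y Integer/logical labels, 1 = BrdU.
#' @param epochs Maximum epochs.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param val_frac Fraction held out for validation.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param seed Seed controlling the data order and split.
#' @param verbose Print per-epoch losses.
#' @return The trained `detect_model` with a `history` data frame attached.
#' @export
train_detect <- function(model, x, y, epochs = 30L, lr = 3e-3,
                         batch_size = 256L, val_frac = 0.15, patience = 4L,
                         seed = 1234L, verbose = FALSE) {
  y <- as.integer(y)
  n <- length(y)
  if (dim(x)[1] != n) stopf("x and y disagree on the number of tensors")
  if (length(unique(y)) < 2L) {
    stopf("training set contains a single class; need both thymidine and BrdU labels")
  }
  idx <- with_seed(seed, sample.int(n))
  n_val <- max(1L, floor(n * val_frac))
  val_idx <- idx[seq_len(n_val)]
  tr_idx <- idx[-seq_len(n_val)]
  xv <- x[val_idx, , , drop = FALSE]; yv <- y[val_idx]
  st <- adam_state(model$par)
  best <- list(loss = Inf, par = model$par, bn = model$bn, epoch = 0L)
  hist <- NULL
  bad <- 0L
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, ep), sample(tr_idx))
    nb <- ceiling(length(ord) / batch_size)
    tr_loss <- 0
    for (bi in seq_len(nb)) {
      take <- ord[((bi - 1L) * batch_size + 1L):min(bi * batch_size, length(ord))]
      xb <- x[take, , , drop = FALSE]; yb <- y[take]
      fw <- detect_forward(model, xb, train = TRUE)
      # running BN statistics (momentum 0.1)
      for (b in seq_along(model$bn)) {
        bb <- fw$cache$bn_batch[[b]]
        model$bn[[b]]$mean <- 0.9 * model$bn[[b]]$mean + 0.1 * bb$mean
        model$bn[[b]]$var <- 0.9 * model$bn[[b]]$var + 0.1 * bb$var
      }
      tr_loss <- tr_loss + ce_loss(fw$prob, yb) * length(take)
      grads <- detect_backward(model, fw$cache, yb)
      upd <- adam_step(model$par, grads, st, lr)
      model$par <- upd$par; st <- upd$state
    }
    tr_loss <- tr_loss / length(ord)
    pv <- detect_forward(model, xv, train = FALSE)$prob
    val_loss <- ce_loss(pv, yv)
    val_acc <- mean((pv[, 2] > 0.5) == (yv == 1L))
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tr_loss,
                                   val_loss = val_loss, val_acc = val_acc))
    if (verbose) message(sprintf("epoch %d: train %.4f val %.4f acc %.4f",
                                 ep, tr_loss, val_loss, val_acc))
    if (val_loss < best$loss - 1e-5) {
      best <- list(loss = val_loss, par = model$par, bn = model$bn, epoch = ep)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) break
    }
  }
  model$par <- best$par
  model$bn <- best$bn
  model$trained <- TRUE
  model$history <- hist
  model
}

#' Per-tensor BrdU probabilities
#'
#' Inference folds each block's batch normalisation into the composite
#' convolution weights (one matrix product per block), which is exactly
#' equivalent to the training-time forward pass under the running BN
#' statistics.
#'
#' @param model A trained `detect_model`.
#' @param x Tensor array (n x window x features).
#' @param chunk Tensors per compiled-kernel call (bounds working memory).
#' @return Numeric vector of BrdU probabilities, one per tensor; the implied
#'   softmax pair is `(1 - p, p)`.
#' @export
predict_detect <- function(model, x, chunk = 4096L) {
  N <- dim(x)[1]
  if (N == 0L) return(numeric(0))
  cfg <- model$config
  par <- model$par
  fold <- folded_weights(model)
  run <- function(xs) {
    as.numeric(.detect_infer_cpp(xs, par$stem_W, par$stem_b, fold$W, fold$b,
                                 par$head_W, par$head_b, cfg$kernel))
  }
  if (N <= chunk) return(run(x))
  out <- numeric(N)
  at <- 1L
  while (at <= N) {
    hi <- min(at + chunk - 1L, N)
    out[at:hi] <- run(x[at:hi, , , drop = FALSE])
    at <- hi + 1L
  }
  out
}

folded_weights <- function(model) {
  par <- model$par
  Ws <- vector("list", model$config$blocks)
  bs <- vector("list", model$config$blocks)
  for (b in seq_len(model$config$blocks)) {
    istd <- 1 / sqrt(model$bn[[b]]$var + .BN_EPS)
    a <- par[[paste0("blk", b, "_gamma")]] * istd
    Wfold <- composite_conv_weights(par[[paste0("blk", b, "_dw")]],
                                    par[[paste0("blk", b, "_pw")]])
    Ws[[b]] <- Wfold * rep(a, each = nrow(Wfold))
    bs[[b]] <- par[[paste0("blk", b, "_beta")]] +
      a * (par[[paste0("blk", b, "_pb")]] - model$bn[[b]]$mean)
  }
  list(W = Ws, b = bs)
}

# Pure-R reference inference path (BN folded into the composite conv),
# retained as an independent check of the compiled kernel.
predict_detect_reference <- function(model, x) {
  N <- dim(x)[1]
  if (N == 0L) return(numeric(0))
  cfg <- model$config
  par <- model$par
  W <- cfg$window_W; k <- cfg$kernel
  fold <- folded_weights(model)
  Hm <- sweep(matrix(x, N * W, cfg$features) %*% par$stem_W, 2, par$stem_b, "+")
  for (b in seq_len(cfg$blocks)) {
    Ym <- sweep(im2col_w(Hm, N, W, k) %*% fold$W[[b]], 2, fold$b[[b]], "+")
    Hm <- Hm + Ym * (Ym > 0)
  }
  P <- flatten_window(Hm, N, W, cfg$channels)
  logits <- sweep(P %*% par$head_W, 2, par$head_b, "+")
  1 / (1 + exp(logits[, 1] - logits[, 2]))
}
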