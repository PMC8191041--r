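#' Fork-sense network
#'
#' A fully convolutional 1-D encoder-decoder that reads a per-thymidine BrdU
#' probability track (plus a spacing channel encoding the gap between
#' successive thymidines) and emits, per position, two sigmoid probabilities:
#' that a leftward-moving and that a rightward-moving replication fork passed
#' through the position during the analogue pulse. Three 4x average-pooling
#' stages give the bottleneck a receptive field of several kilobases, enough
#' to see the plateau-plus-gradient shape of a fork footprint, and skip
#' connections restore per-position resolution on the way back up.
#'
#' @name forksense_model
NULL

conv1d_fwd <- function(X, Wt, b, k) {
  L <- nrow(X); Cin <- ncol(X)
  pad <- (k - 1L) %/% 2L
  Xc <- matrix(0, L, k * Cin)
  for (o in seq_len(k)) {
    s <- o - pad - 1L
    src <- (1L + max(0L, s)):(L + min(0L, s))
    if (src[1] > src[length(src)]) next
    dst <- src - s
    Xc[dst, ((o - 1L) * Cin + 1L):(o * Cin)] <- X[src, , drop = FALSE]
  }
  Y <- sweep(Xc %*% Wt, 2, b, "+")
  list(Y = Y, Xc = Xc)
}

conv1d_bwd <- function(Xc, Wt, dY, k, Cin) {
  L <- nrow(dY)
  pad <- (k - 1L) %/% 2L
  dW <- t(Xc) %*% dY
  db <- colSums(dY)
  dXc <- dY %*% t(Wt)
  dX <- matrix(0, L, Cin)
  for (o in seq_len(k)) {
    s <- o - pad - 1L
    src <- (1L + max(0L, s)):(L + min(0L, s))
    if (src[1] > src[length(src)]) next
    dst <- src - s
    dX[src, ] <- dX[src, ] + dXc[dst, ((o - 1L) * Cin + 1L):(o * Cin), drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

pool4_fwd <- function(X) {
  L <- nrow(X); C <- ncol(X)
  Lp <- ceiling(L / 4)
  Xp <- rbind(X, matrix(0, Lp * 4L - L, C))
  Y <- colSums(array(Xp, c(4L, Lp, C))) / 4
  if (C == 1L) Y <- matrix(Y, ncol = 1L)
  Y
}

pool4_bwd <- function(dY, L) {
  dX <- dY[rep(seq_len(nrow(dY)), each = 4L), , drop = FALSE] / 4
  dX[seq_len(L), , drop = FALSE]
}

up4_fwd <- function(X, L_target) {
  X[rep(seq_len(nrow(X)), each = 4L)[seq_len(L_target)], , drop = FALSE]
}

up4_bwd <- function(dY, L_src) {
  grp <- (seq_len(nrow(dY)) - 1L) %/% 4L + 1L
  out <- rowsum(dY, grp)
  if (nrow(out) < L_src) {
    out <- rbind(out, matrix(0, L_src - nrow(out), ncol(dY)))
  }
  out
}

.FS_LAYERS <- function(channels) {
  c0 <- channels[1]; c1 <- channels[2]
  list(enc1 = c(2L, c0), enc2 = c(c0, c1), enc3 = c(c1, c1), enc4 = c(c1, c1),
       enc5 = c(c1, c1),
       dec4 = c(2L * c1, c1), dec3 = c(2L * c1, c1), dec2 = c(2L * c1, c1),
       dec1 = c(c1 + c0, c0), out = c(c0, 2L))
}

#' Build the fork-sense encoder-decoder
#'
#' @param channels Two channel widths `c(outer, inner)` for the full-
#'   resolution and pooled stages.
#' @param kernel Convolution kernel width (odd); the output head is 1x1.
#' @param seed Seed for weight initialisation.
#' @return A `forksense_model`.
#' @export
build_forksense_model <- function(channels = c(8L, 16L), kernel = 9L,
                                  seed = 7L) {
  if (kernel %% 2L != 1L) stopf("kernel must be odd")
  if (length(channels) != 2L || any(channels < 1L)) stopf("channels must be two positive widths")
  layers <- .FS_LAYERS(as.integer(channels))
  par <- with_seed(seed, {
    p <- list()
    for (nm in names(layers)) {
      k <- if (nm == "out") 1L else kernel
      cin <- layers[[nm]][1]; cout <- layers[[nm]][2]
      p[[paste0(nm, "_W")]] <- matrix(rnorm(k * cin * cout, 0, sqrt(2 / (k * cin))),
                                      k * cin, cout)
      p[[paste0(nm, "_b")]] <- numeric(cout)
    }
    p
  })
  structure(list(par = par,
                 config = list(channels = as.integer(channels),
                               kernel = as.integer(kernel), seed = seed),
                 trained = FALSE, history = NULL),
            class = "forksense_model")
}

#' @export
print.forksense_model <- function(x, ...) {
  cat(sprintf("<forksense_model> channels %s, kernel %d, %d parameters, %s\n",
              paste(x$config$channels, collapse = "/"), x$config$kernel,
              count_parameters(x), if (x$trained) "trained" else "untrained"))
  invisible(x)
}

forksense_forward <- function(model, X) {
  par <- model$par
  k <- model$config$kernel
  relu_conv <- function(X, nm, kk = k) {
    f <- conv1d_fwd(X, par[[paste0(nm, "_W")]], par[[paste0(nm, "_b")]], kk)
    mask <- f$Y > 0
    list(A = f$Y * mask, Xc = f$Xc, mask = mask)
  }
  L <- nrow(X)
  e1 <- relu_conv(X, "enc1")
  p1 <- pool4_fwd(e1$A)
  e2 <- relu_conv(p1, "enc2")
  p2 <- pool4_fwd(e2$A)
  e3 <- relu_conv(p2, "enc3")
  p3 <- pool4_fwd(e3$A)
  e4 <- relu_conv(p3, "enc4")
  p4 <- pool4_fwd(e4$A)
  e5 <- relu_conv(p4, "enc5")
  u4 <- up4_fwd(e5$A, nrow(e4$A))
  d4 <- relu_conv(cbind(u4, e4$A), "dec4")
  u3 <- up4_fwd(d4$A, nrow(e3$A))
  d3 <- relu_conv(cbind(u3, e3$A), "dec3")
  u2 <- up4_fwd(d3$A, nrow(e2$A))
  d2 <- relu_conv(cbind(u2, e2$A), "dec2")
  u1 <- up4_fwd(d2$A, L)
  d1 <- relu_conv(cbind(u1, e1$A), "dec1")
  o <- conv1d_fwd(d1$A, par$out_W, par$out_b, 1L)
  P <- 1 / (1 + exp(-o$Y))
  list(P = P,
       cache = list(X = X, e1 = e1, e2 = e2, e3 = e3, e4 = e4, e5 = e5,
                    d4 = d4, d3 = d3, d2 = d2, d1 = d1, o = o,
                    L = L, L1 = nrow(e2$A), L2 = nrow(e3$A), L3 = nrow(e4$A),
                    L4 = nrow(e5$A)))
}

forksense_backward <- function(model, cache, dP_logit) {
  par <- model$par
  k <- model$config$kernel
  layers <- .FS_LAYERS(model$config$channels)
  g <- list()
  bwd <- function(layer, nm, dA, kk = k) {
    dY <- dA * layer$mask
    cin <- layers[[nm]][1]
    r <- conv1d_bwd(layer$Xc, par[[paste0(nm, "_W")]], dY, kk, cin)
    g[[paste0(nm, "_W")]] <<- r$dW
    g[[paste0(nm, "_b")]] <<- r$db
    r$dX
  }
  ro <- conv1d_bwd(cache$o$Xc, par$out_W, dP_logit, 1L, ncol(cache$d1$A))
  g$out_W <- ro$dW; g$out_b <- ro$db
  dd1 <- bwd(cache$d1, "dec1", ro$dX)
  c0 <- model$config$channels[1]
  c1 <- model$config$channels[2]
  du1 <- dd1[, seq_len(ncol(dd1) - c0), drop = FALSE]
  de1_skip <- dd1[, (ncol(dd1) - c0 + 1L):ncol(dd1), drop = FALSE]
  dd2 <- bwd(cache$d2, "dec2", up4_bwd(du1, nrow(cache$d2$A)))
  du2 <- dd2[, seq_len(c1), drop = FALSE]
  de2_skip <- dd2[, (c1 + 1L):(2L * c1), drop = FALSE]
  dd3 <- bwd(cache$d3, "dec3", up4_bwd(du2, nrow(cache$d3$A)))
  du3 <- dd3[, seq_len(c1), drop = FALSE]
  de3_skip <- dd3[, (c1 + 1L):(2L * c1), drop = FALSE]
  dd4 <- bwd(cache$d4, "dec4", up4_bwd(du3, nrow(cache$d4$A)))
  du4 <- dd4[, seq_len(c1), drop = FALSE]
  de4_skip <- dd4[, (c1 + 1L):(2L * c1), drop = FALSE]
  de5 <- bwd(cache$e5, "enc5", up4_bwd(du4, cache$L4))
  de4 <- bwd(cache$e4, "enc4", pool4_bwd(de5, nrow(cache$e4$A)) + de4_skip)
  de3 <- bwd(cache$e3, "enc3", pool4_bwd(de4, nrow(cache$e3$A)) + de3_skip)
  de2 <- bwd(cache$e2, "enc2", pool4_bwd(de3, nrow(cache$e2$A)) + de2_skip)
  de1 <- bwd(cache$e1, "enc1", pool4_bwd(de2, cache$L) + de1_skip)
  g
}

# Two-channel network input from a detect record: the BrdU probability and a
# bounded spacing feature for the irregular thymidine grid. Fork footprints
# live on the kilobase scale, so the track is viewed at a thymidine stride
# (default every 4th), which widens the receptive field in bp and keeps
# training cheap; per-position output is restored by piecewise-constant
# upsampling.
.FS_STRIDE <- 4L

forksense_input <- function(record, stride = .FS_STRIDE) {
  keep <- seq(1L, nrow(record$rows), by = stride)
  p <- record$rows$probability[keep]
  pos <- record$rows$position[keep]
  gaps <- diff(pos)
  gap_feat <- c(0, pmin(gaps, 50L * stride) / (50 * stride))
  list(x = cbind(p, gap_feat, deparse.level = 0), keep = keep)
}

fork_label_matrix <- function(labels) {
  cbind(as.numeric(labels == "left"), as.numeric(labels == "right"))
}

#' Train the fork-sense network
#'
#' Per-position binary cross-entropy on both direction channels against
#' simulator truth labels, one read per gradient step (Adam), with a held-out
#' validation split of reads and early stopping.
#'
#' @param model A `forksense_model`.
#' @param records List of `detect_record` from simulated fork cohorts.
#' @param labels List of character label vectors (`"left"`, `"right"`,
#'   `"none"`), aligned with each record's rows (see
#'   [truth_fork_labels()]).
#' @param epochs,lr,val_frac,patience,seed Training controls as in
#'   [train_detect()].
#' @param verbose Print per-epoch losses.
#' @return The trained `forksense_model`.
#' @export
train_forksense <- function(model, records, labels, epochs = 20L, lr = 2e-3,
                            val_frac = 0.15, patience = 3L, seed = 5678L,
                            verbose = FALSE) {
  if (length(records) != length(labels)) stopf("records and labels differ in length")
  keep <- vapply(records, function(r) nrow(r$rows) >= 8L, logical(1))
  records <- records[keep]; labels <- labels[keep]
  n <- length(records)
  if (n < 2L) stopf("need at least two usable training tracks")
  ins <- lapply(records, forksense_input)
  xs <- lapply(ins, `[[`, "x")
  ys <- lapply(seq_along(labels), function(i) {
    fork_label_matrix(labels[[i]][ins[[i]]$keep])
  })
  if (sum(vapply(ys, sum, numeric(1))) == 0) {
    stopf("training data contains no positive fork labels")
  }
  idx <- with_seed(seed, sample.int(n))
  n_val <- max(1L, floor(n * val_frac))
  val_idx <- idx[seq_len(n_val)]
  tr_idx <- idx[-seq_len(n_val)]
  st <- adam_state(model$par)
  best <- list(loss = Inf, par = model$par)
  hist <- NULL; bad <- 0L
  bce <- function(P, Y) {
    P <- pmin(pmax(P, 1e-9), 1 - 1e-9)
    -mean(Y * log(P) + (1 - Y) * log(1 - P))
  }
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, ep), sample(tr_idx))
    tr_loss <- 0
    for (i in ord) {
      fw <- forksense_forward(model, xs[[i]])
      Y <- ys[[i]]
      tr_loss <- tr_loss + bce(fw$P, Y)
      dlogit <- (fw$P - Y) / length(Y)
      grads <- forksense_backward(model, fw$cache, dlogit)
      upd <- adam_step(model$par, grads, st, lr)
      model$par <- upd$par; st <- upd$state
    }
    tr_loss <- tr_loss / length(ord)
    val_loss <- mean(vapply(val_idx, function(i) {
      bce(forksense_forward(model, xs[[i]])$P, ys[[i]])
    }, numeric(1)))
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tr_loss,
                                   val_loss = val_loss))
    if (verbose) message(sprintf("epoch %d: train %.4f val %.4f", ep, tr_loss, val_loss))
    if (val_loss < best$loss - 1e-5) {
      best <- list(loss = val_loss, par = model$par); bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) break
    }
  }
  model$par <- best$par
  model$trained <- TRUE
  model$history <- hist
  model
}

#' Fork-direction probabilities along one read
#'
#' @param model A trained `forksense_model`.
#' @param record A `detect_record`.
#' @return A `fork_track`: read metadata plus `positions`, `p_left`,
#'   `p_right`.
#' @export
predict_forksense <- function(model, record) {
  L <- nrow(record$rows)
  if (L == 0L) {
    P <- matrix(numeric(0), 0, 2)
  } else {
    inp <- forksense_input(record)
    Ps <- forksense_forward(model, inp$x)$P
    # piecewise-constant upsampling back to every thymidine position
    f <- findInterval(seq_len(L), inp$keep)
    P <- Ps[pmax(f, 1L), , drop = FALSE]
  }
  structure(list(read_id = record$read_id, contig = record$contig,
                 strand = record$strand, ref_start = record$ref_start,
                 ref_end = record$ref_end, mapq = record$mapq,
                 positions = record$rows$position,
                 p_left = as.numeric(P[, 1]), p_right = as.numeric(P[, 2])),
            class = "fork_track")
}

#' @export
print.fork_track <- function(x, ...) {
  cat(sprintf("<fork_track> %s %s:%d-%d, %d positions\n", x$read_id, x$contig,
              x$ref_start, x$ref_end, length(x$positions)))
  invisible(x)
}
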