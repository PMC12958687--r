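# Minimal convolutional encoder-decoder engine used by the sinogram
# denoiser: 3x3 convolutions via im2col with clamp-to-edge padding
# (a constant field maps to a constant field), 2x2 max pooling, nearest
# upsampling, channel concatenation, residual output head, manual
# backpropagation and Adam updates. Feature maps are stored as
# (H*W) x channels matrices.

# cache of im2col / pooling index maps keyed by geometry
.net_cache <- new.env(parent = emptyenv())

im2col_idx <- function(H, W) {
  key <- paste0("i", H, "x", W)
  if (!is.null(.net_cache[[key]])) return(.net_cache[[key]])
  r <- rep(seq_len(H), times = W)
  c <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, 9L)
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1L
    rr <- pmin(pmax(r + dr, 1L), H)
    cc <- pmin(pmax(c + dc, 1L), W)
    idx[, k] <- rr + (cc - 1L) * H
  }
  .net_cache[[key]] <- idx
  idx
}

pool_idx <- function(H, W) {
  key <- paste0("p", H, "x", W)
  if (!is.null(.net_cache[[key]])) return(.net_cache[[key]])
  Ho <- H %/% 2L; Wo <- W %/% 2L
  r <- rep(seq_len(Ho), times = Wo)
  c <- rep(seq_len(Wo), each = Ho)
  base <- function(dr, dc) (2L * r - 1L + dr) + (2L * c - 2L + dc) * H
  m <- cbind(base(0L, 0L), base(1L, 0L), base(0L, 1L), base(1L, 1L))
  # upsample map: fine pixel -> coarse cell
  rf <- rep(seq_len(H), times = W)
  cf <- rep(seq_len(W), each = H)
  upmap <- ((rf + 1L) %/% 2L) + (((cf + 1L) %/% 2L) - 1L) * Ho
  out <- list(pool = m, up = upmap, Ho = Ho, Wo = Wo)
  .net_cache[[key]] <- out
  out
}

conv_fwd <- function(X, idx, Wm, b) {
  Cin <- ncol(X)
  HW <- nrow(X)
  Xc <- matrix(0, HW, 9L * Cin)
  for (k in 1:9) Xc[, ((k - 1L) * Cin + 1L):(k * Cin)] <- X[idx[, k], , drop = FALSE]
  Y <- Xc %*% Wm
  Y <- sweep(Y, 2, b, "+")
  list(Y = Y, Xc = Xc)
}

conv_bwd <- function(dY, Xc, idx, Wm, HW, Cin) {
  dW <- crossprod(Xc, dY)
  db <- colSums(dY)
  dXc <- dY %*% t(Wm)
  dX <- matrix(0, HW, Cin)
  for (k in 1:9) {
    blk <- dXc[, ((k - 1L) * Cin + 1L):(k * Cin), drop = FALSE]
    g <- rowsum(blk, group = idx[, k])
    rows <- as.integer(rownames(g))
    dX[rows, ] <- dX[rows, , drop = FALSE] + g
  }
  list(dW = dW, db = db, dX = dX)
}

pool_fwd <- function(X, pi) {
  m <- pi$pool
  n <- nrow(m); C <- ncol(X)
  Y <- X[m[, 1], , drop = FALSE]
  choice <- matrix(m[, 1], n, C)
  for (k in 2:4) {
    cand <- X[m[, k], , drop = FALSE]
    sel <- cand > Y
    Y[sel] <- cand[sel]
    choice[sel] <- matrix(m[, k], n, C)[sel]
  }
  list(Y = Y, choice = choice)
}

pool_bwd <- function(dY, choice, HW) {
  C <- ncol(dY)
  dX <- matrix(0, HW, C)
  for (ch in seq_len(C)) dX[choice[, ch], ch] <- dY[, ch]
  dX
}

up_fwd <- function(X, pi) X[pi$up, , drop = FALSE]

up_bwd <- function(dY, pi, HWc) {
  g <- rowsum(dY, group = pi$up)
  out <- matrix(0, HWc, ncol(dY))
  out[as.integer(rownames(g)), ] <- g
  out
}

# He-initialized parameter set; the output head starts at zero so the
# network is the identity (pure residual) before training.
net_init <- function(base_channels = 8L, seed = 1L) {
  cs <- base_channels * c(1L, 2L, 4L, 4L)
  dims <- list(
    c(1L, cs[1]),               # enc1
    c(cs[1], cs[2]),            # enc2
    c(cs[2], cs[3]),            # enc3
    c(cs[3], cs[4]),            # bottom
    c(cs[4] + cs[3], cs[3]),    # dec3
    c(cs[3] + cs[2], cs[2]),    # dec2
    c(cs[2] + cs[1], cs[1]),    # dec1
    c(cs[1], 1L)                # head
  )
  with_seed(seed, {
    layers <- lapply(seq_along(dims), function(i) {
      cin <- dims[[i]][1]; cout <- dims[[i]][2]
      sdv <- sqrt(2 / (9 * cin))
      Wm <- matrix(stats::rnorm(9 * cin * cout, sd = sdv), 9 * cin, cout)
      if (i == length(dims)) Wm[] <- 0
      list(W = Wm, b = numeric(cout))
    })
    list(layers = layers, channels = cs)
  })
}

relu <- function(x) { x[x < 0] <- 0; x }

# forward pass; keep = TRUE retains intermediates for backprop
net_forward <- function(net, x, H, W, keep = FALSE) {
  i1 <- im2col_idx(H, W); p1 <- pool_idx(H, W)
  H2 <- p1$Ho; W2 <- p1$Wo
  i2 <- im2col_idx(H2, W2); p2 <- pool_idx(H2, W2)
  H3 <- p2$Ho; W3 <- p2$Wo
  i3 <- im2col_idx(H3, W3); p3 <- pool_idx(H3, W3)
  H4 <- p3$Ho; W4 <- p3$Wo
  i4 <- im2col_idx(H4, W4)
  L <- net$layers
  cv <- function(X, idx, l) conv_fwd(X, idx, L[[l]]$W, L[[l]]$b)
  f1 <- cv(x, i1, 1);  e1 <- relu(f1$Y)
  q1 <- pool_fwd(e1, p1)
  f2 <- cv(q1$Y, i2, 2); e2 <- relu(f2$Y)
  q2 <- pool_fwd(e2, p2)
  f3 <- cv(q2$Y, i3, 3); e3 <- relu(f3$Y)
  q3 <- pool_fwd(e3, p3)
  f4 <- cv(q3$Y, i4, 4); e4 <- relu(f4$Y)
  u3 <- up_fwd(e4, p3); c3 <- cbind(u3, e3)
  f5 <- cv(c3, i3, 5); d3 <- relu(f5$Y)
  u2 <- up_fwd(d3, p2); c2 <- cbind(u2, e2)
  f6 <- cv(c2, i2, 6); d2 <- relu(f6$Y)
  u1 <- up_fwd(d2, p1); c1 <- cbind(u1, e1)
  f7 <- cv(c1, i1, 7); d1 <- relu(f7$Y)
  f8 <- cv(d1, i1, 8)
  y <- x + f8$Y
  if (!keep) return(y)
  list(y = y,
       ctx = list(x = x, f = list(f1, f2, f3, f4, f5, f6, f7, f8),
                  act = list(e1 = e1, e2 = e2, e3 = e3, e4 = e4,
                             d3 = d3, d2 = d2, d1 = d1),
                  q = list(q1, q2, q3),
                  idx = list(i1 = i1, i2 = i2, i3 = i3, i4 = i4),
                  pools = list(p1, p2, p3),
                  geo = c(H, W, H2, W2, H3, W3, H4, W4)))
}

# backward pass from dL/dy; returns per-layer gradients
net_backward <- function(net, fwd, dY) {
  ctx <- fwd$ctx
  L <- net$layers
  g <- ctx$geo
  HW1 <- g[1] * g[2]; HW2 <- g[3] * g[4]; HW3 <- g[5] * g[6]; HW4 <- g[7] * g[8]
  i <- ctx$idx; p <- ctx$pools; f <- ctx$f; a <- ctx$act
  grads <- vector("list", 8)
  bw <- function(dOut, l, Xc, idx, HW, Cin) conv_bwd(dOut, Xc, idx, L[[l]]$W, HW, Cin)
  cs <- net$channels
  # head (no relu)
  g8 <- bw(dY, 8, f[[8]]$Xc, i$i1, HW1, cs[1]); grads[[8]] <- g8
  dd1 <- g8$dX * (a$d1 > 0)
  g7 <- bw(dd1, 7, f[[7]]$Xc, i$i1, HW1, cs[2] + cs[1]); grads[[7]] <- g7
  du1 <- g7$dX[, seq_len(cs[2]), drop = FALSE]
  de1_skip <- g7$dX[, cs[2] + seq_len(cs[1]), drop = FALSE]
  dd2 <- up_bwd(du1, p[[1]], HW2) * (a$d2 > 0)
  g6 <- bw(dd2, 6, f[[6]]$Xc, i$i2, HW2, cs[3] + cs[2]); grads[[6]] <- g6
  du2 <- g6$dX[, seq_len(cs[3]), drop = FALSE]
  de2_skip <- g6$dX[, cs[3] + seq_len(cs[2]), drop = FALSE]
  dd3 <- up_bwd(du2, p[[2]], HW3) * (a$d3 > 0)
  g5 <- bw(dd3, 5, f[[5]]$Xc, i$i3, HW3, cs[4] + cs[3]); grads[[5]] <- g5
  du3 <- g5$dX[, seq_len(cs[4]), drop = FALSE]
  de3_skip <- g5$dX[, cs[4] + seq_len(cs[3]), drop = FALSE]
  de4 <- up_bwd(du3, p[[3]], HW4) * (a$e4 > 0)
  g4 <- bw(de4, 4, f[[4]]$Xc, i$i4, HW4, cs[3]); grads[[4]] <- g4
  de3 <- (pool_bwd(g4$dX, ctx$q[[3]]$choice, HW3) + de3_skip) * (a$e3 > 0)
  g3 <- bw(de3, 3, f[[3]]$Xc, i$i3, HW3, cs[2]); grads[[3]] <- g3
  de2 <- (pool_bwd(g3$dX, ctx$q[[2]]$choice, HW2) + de2_skip) * (a$e2 > 0)
  g2 <- bw(de2, 2, f[[2]]$Xc, i$i2, HW2, cs[1]); grads[[2]] <- g2
  de1 <- (pool_bwd(g2$dX, ctx$q[[1]]$choice, HW1) + de1_skip) * (a$e1 > 0)
  g1 <- bw(de1, 1, f[[1]]$Xc, i$i1, HW1, 1L); grads[[1]] <- g1
  grads
}

adam_init <- function(net) {
  lapply(net$layers, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                      mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(net, state, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (l in seq_along(net$layers)) {
    s <- state[[l]]; g <- grads[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    mhW <- s$mW / (1 - beta1^t); vhW <- s$vW / (1 - beta2^t)
    mhb <- s$mb / (1 - beta1^t); vhb <- s$vb / (1 - beta2^t)
    net$layers[[l]]$W <- net$layers[[l]]$W - lr * mhW / (sqrt(vhW) + eps)
    net$layers[[l]]$b <- net$layers[[l]]$b - lr * mhb / (sqrt(vhb) + eps)
    state[[l]] <- s
  }
  list(net = net, state = state)
}
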