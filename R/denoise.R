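# Self-supervised sinogram denoising: even/odd projection pairing and a
# small 4-level encoder-decoder trained with an MSE loss in the
# Noise2Noise fashion (each half-sinogram predicts the other).

#' Build even/odd training pairs from sinograms
#'
#' Splits every sinogram into its even- and odd-indexed projection lines
#' (parity of the 0-based line index); the two halves interleave exactly
#' back to the parent. Whole sinograms are partitioned into train and
#' test sets (default 80/20), deterministically per seed.
#'
#' @param sinos list of [sinogram()] objects or plain matrices.
#' @param seed integer seed for the split.
#' @param split train fraction of whole sinograms.
#' @return object of class `training_pair_set`: `pairs` (each with `even`,
#'   `odd`, `defect_cols`), `train_idx`, `test_idx`, `seed`.
#' @export
make_pairs <- function(sinos, seed = 1, split = 0.8) {
  if (!is.list(sinos) || inherits(sinos, "sinogram")) sinos <- list(sinos)
  pairs <- lapply(sinos, function(s) {
    v <- if (inherits(s, "sinogram")) s$values else as.matrix(s)
    dc <- if (inherits(s, "sinogram")) s$defect_cols else rep(FALSE, ncol(v))
    n <- nrow(v)
    if (n %% 2 != 0) {
      warning("odd projection count; dropping the last line")
      v <- v[-n, , drop = FALSE]
      n <- n - 1
    }
    even <- v[seq(1, n, by = 2), , drop = FALSE]   # 0-based even lines
    odd <- v[seq(2, n, by = 2), , drop = FALSE]
    list(even = even, odd = odd, defect_cols = dc)
  })
  m <- length(pairs)
  n_train <- max(1L, min(m - 1L, round(split * m)))
  if (m == 1) n_train <- 1L
  idx <- with_seed(seed, sample.int(m))
  structure(list(pairs = pairs,
                 train_idx = sort(idx[seq_len(n_train)]),
                 test_idx = sort(idx[-seq_len(n_train)]),
                 seed = seed),
            class = "training_pair_set")
}

#' Interleave an even/odd half-sinogram pair back to the original
#'
#' @param even,odd matrices of alternating projection lines.
#' @return the reassembled sinogram matrix.
#' @export
interleave_pair <- function(even, odd) {
  stopifnot(nrow(even) == nrow(odd), ncol(even) == ncol(odd))
  out <- matrix(0, 2 * nrow(even), ncol(even))
  out[seq(1, nrow(out), by = 2), ] <- even
  out[seq(2, nrow(out), by = 2), ] <- odd
  out
}

#' Denoiser training specification
#'
#' A fixed 4-level encoder-decoder (3x3 convolutions, 2x2 max pooling,
#' nearest upsampling, skip concatenations, residual output head) trained
#' with a mean-square-error loss on random patches.
#'
#' @param base_channels channels of the first level (doubling below).
#' @param patch_px square training patch side; must be divisible by 8.
#' @param batch_size patches per optimization step.
#' @param max_epochs epoch cap.
#' @param steps_per_epoch optimization steps per epoch.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param lr Adam learning rate.
#' @param seed seed for initialization, cropping and shuffling.
#' @return object of class `denoiser_spec` (`levels` fixed at 4,
#'   `loss` fixed at `"mse"`).
#' @export
denoiser_spec <- function(base_channels = 8, patch_px = 64, batch_size = 4,
                          max_epochs = 30, steps_per_epoch = 25,
                          patience = 3, lr = 2e-3, seed = 1) {
  if (patch_px %% 8 != 0) stop("patch_px must be divisible by 8")
  structure(list(levels = 4L, loss = "mse", base_channels = base_channels,
                 patch_px = patch_px, batch_size = batch_size,
                 max_epochs = max_epochs, steps_per_epoch = steps_per_epoch,
                 patience = patience, lr = lr, seed = seed),
            class = "denoiser_spec")
}

# sample a random patch pair (input, target, mask) from a pair entry
sample_patch <- function(pair, patch) {
  H <- nrow(pair$even); W <- ncol(pair$even)
  ph <- min(patch, 8 * (H %/% 8)); pw <- min(patch, 8 * (W %/% 8))
  if (ph < 8 || pw < 8) stop("sinogram halves too small for training patches")
  r0 <- sample.int(H - ph + 1L, 1L)
  c0 <- sample.int(W - pw + 1L, 1L)
  rows <- r0:(r0 + ph - 1L); cols <- c0:(c0 + pw - 1L)
  if (stats::runif(1) < 0.5) {
    a <- pair$even[rows, cols]; b <- pair$odd[rows, cols]
  } else {
    a <- pair$odd[rows, cols]; b <- pair$even[rows, cols]
  }
  live <- !pair$defect_cols[cols]
  mask <- matrix(rep(live, each = ph), ph, pw)
  list(x = a, t = b, mask = mask, H = ph, W = pw)
}

#' Train the self-supervised sinogram denoiser
#'
#' Minimizes the mean square error of predicting one half-sinogram from
#' the other (both directions, random patches) with Adam. Validation MSE
#' is tracked on the held-out sinograms; training stops at `max_epochs`
#' or once validation fails to improve for `patience` epochs. Defective
#' detector columns are excluded from the loss. Training diverging to
#' more than 10x the initial validation loss aborts with a diagnostic.
#'
#' @param pairset a [make_pairs()] result with at least one training pair
#'   (two or more sinograms recommended so a validation pair exists).
#' @param spec a [denoiser_spec()].
#' @return object of class `sino_denoiser`: network weights, input
#'   normalization, the training log (`data.frame` epoch/train/val loss),
#'   `epochs_run`, `stopped_early`.
#' @export
train_denoiser <- function(pairset, spec = denoiser_spec()) {
  stopifnot(inherits(pairset, "training_pair_set"),
            inherits(spec, "denoiser_spec"))
  train_pairs <- pairset$pairs[pairset$train_idx]
  val_pairs <- pairset$pairs[pairset$test_idx]
  if (length(val_pairs) == 0) val_pairs <- train_pairs
  if (length(train_pairs) < 1) stop("at least one training pair required")
  all_tr <- unlist(lapply(train_pairs, function(p) c(p$even, p$odd)))
  mu <- mean(all_tr); sdv <- stats::sd(all_tr)
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  norm <- list(mu = mu, sd = sdv)
  net <- net_init(spec$base_channels, seed = spec$seed)
  state <- adam_init(net)
  val_loss <- function(nt) {
    tot <- 0; cnt <- 0
    for (p in val_pairs) {
      cp <- with_seed(spec$seed + 9999, sample_patch(p, spec$patch_px))
      x <- (cp$x - mu) / sdv; tgt <- (cp$t - mu) / sdv
      y <- net_forward(nt, matrix(x, ncol = 1), cp$H, cp$W)
      m <- as.vector(cp$mask)
      tot <- tot + sum(((y - as.vector(tgt))[m])^2)
      cnt <- cnt + sum(m)
    }
    tot / cnt
  }
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric())
  v0 <- val_loss(net)
  best <- v0; best_net <- net; bad <- 0L; t <- 0L
  stopped_early <- FALSE
  epochs_run <- 0L
  with_seed(spec$seed + 1, {
    for (ep in seq_len(spec$max_epochs)) {
      tr_acc <- 0
      for (st in seq_len(spec$steps_per_epoch)) {
        t <- t + 1L
        gsum <- NULL
        lsum <- 0
        for (bi in seq_len(spec$batch_size)) {
          p <- train_pairs[[sample.int(length(train_pairs), 1L)]]
          cp <- sample_patch(p, spec$patch_px)
          x <- matrix((cp$x - mu) / sdv, ncol = 1)
          tgt <- as.vector((cp$t - mu) / sdv)
          fw <- net_forward(net, x, cp$H, cp$W, keep = TRUE)
          resid <- as.vector(fw$y) - tgt
          m <- as.vector(cp$mask)
          resid[!m] <- 0
          nlive <- sum(m)
          lsum <- lsum + sum(resid^2) / nlive
          dY <- matrix(2 * resid / nlive, ncol = 1)
          g <- net_backward(net, fw, dY)
          if (is.null(gsum)) gsum <- g else {
            for (l in seq_along(g)) {
              gsum[[l]]$dW <- gsum[[l]]$dW + g[[l]]$dW
              gsum[[l]]$db <- gsum[[l]]$db + g[[l]]$db
            }
          }
        }
        for (l in seq_along(gsum)) {
          gsum[[l]]$dW <- gsum[[l]]$dW / spec$batch_size
          gsum[[l]]$db <- gsum[[l]]$db / spec$batch_size
        }
        upd <- adam_step(net, state, gsum, spec$lr, t)
        net <- upd$net; state <- upd$state
        tr_acc <- tr_acc + lsum / spec$batch_size
      }
      vl <- val_loss(net)
      log <- rbind(log, data.frame(epoch = ep,
                                   train_loss = tr_acc / spec$steps_per_epoch,
                                   val_loss = vl))
      epochs_run <- ep
      if (vl > 10 * max(v0, 1e-12)) {
        stop(sprintf(
          "training diverged: validation loss %.3g exceeds 10x initial %.3g at epoch %d",
          vl, v0, ep))
      }
      if (vl < best * (1 - 1e-4)) {
        best <- vl; best_net <- net; bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= spec$patience) { stopped_early <- TRUE; break }
      }
    }
  })
  structure(list(net = best_net, norm = norm, spec = spec, log = log,
                 epochs_run = epochs_run, stopped_early = stopped_early,
                 best_val_loss = best, initial_val_loss = v0),
            class = "sino_denoiser")
}

#' @export
print.sino_denoiser <- function(x, ...) {
  cat(sprintf(
    "<sino_denoiser> 4-level encoder-decoder, %d base channels; %d epochs%s, best val MSE %.4g\n",
    x$spec$base_channels, x$epochs_run,
    if (x$stopped_early) " (early-stopped)" else "", x$best_val_loss))
  invisible(x)
}

#' Apply a trained denoiser to a sinogram
#'
#' Tiled inference with overlap averaging (cosine-feathered tiles); the
#' output has the same shape, is clamped at zero, and carries the
#' `denoised` provenance flag. Deterministic.
#'
#' @param sino a [sinogram()] or plain matrix.
#' @param model a [train_denoiser()] result.
#' @param tile_px tile side used at inference (divisible by 8).
#' @param overlap_px overlap between neighboring tiles.
#' @return denoised sinogram (same class as the input).
#' @export
denoise <- function(sino, model, tile_px = 64, overlap_px = 16) {
  stopifnot(inherits(model, "sino_denoiser"))
  is_sino <- inherits(sino, "sinogram")
  V <- if (is_sino) sino$values else as.matrix(sino)
  H <- nrow(V); W <- ncol(V)
  out <- denoise_matrix(V, model, tile_px, overlap_px)
  out <- pmax(out, 0)
  if (is_sino) {
    sino$values <- out
    sino$flags$denoised <- TRUE
    sino
  } else out
}

denoise_matrix <- function(V, model, tile_px, overlap_px) {
  mu <- model$norm$mu; sdv <- model$norm$sd
  H <- nrow(V); W <- ncol(V)
  Hp <- max(8 * ceiling(H / 8), min(tile_px, 8 * ceiling(H / 8)))
  Wp <- max(8 * ceiling(W / 8), min(tile_px, 8 * ceiling(W / 8)))
  pad <- pad_edge(V, Hp, Wp)
  X <- (pad$x - mu) / sdv
  th <- min(tile_px, Hp); tw <- min(tile_px, Wp)
  stride_h <- max(th - overlap_px, 1)
  stride_w <- max(tw - overlap_px, 1)
  starts <- function(total, tl, stp) {
    if (total <= tl) return(1L)
    s <- seq(1L, total - tl, by = stp)
    unique(c(s, total - tl + 1L))
  }
  hs <- starts(Hp, th, stride_h)
  ws <- starts(Wp, tw, stride_w)
  acc <- matrix(0, Hp, Wp); wsum <- matrix(0, Hp, Wp)
  wt <- outer(tile_window(th), tile_window(tw))
  for (r0 in hs) for (c0 in ws) {
    rows <- r0:(r0 + th - 1L); cols <- c0:(c0 + tw - 1L)
    y <- net_forward(model$net, matrix(X[rows, cols], ncol = 1), th, tw)
    acc[rows, cols] <- acc[rows, cols] + matrix(y, th, tw) * wt
    wsum[rows, cols] <- wsum[rows, cols] + wt
  }
  Y <- acc / wsum
  (Y * sdv + mu)[pad$rows, pad$cols, drop = FALSE]
}

tile_window <- function(n) {
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 0.5) / n)
  w + 1e-3
}
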