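# Detector-domain corrections and sinogram assembly.

#' Sinogram container
#'
#' Angle-by-detector-column view of one detector row of a projection
#' stack, flat-normalized. Angles are stored explicitly (degrees,
#' counter-clockwise); provenance flags record inpainting, denoising and
#' extended-FOV conversion.
#'
#' @param values matrix (n_angles x n_cols), flat-normalized intensity.
#' @param angles_deg angle per row, strictly increasing.
#' @param axis_offset_px lateral rotation-axis offset (px).
#' @param pixel_um effective pixel size (um).
#' @param defect_cols logical vector flagging defective detector columns.
#' @param flags named list of provenance flags.
#' @param dose optional dose bookkeeping carried through subsampling.
#' @return object of class `sinogram`.
#' @export
sinogram <- function(values, angles_deg, axis_offset_px = 0, pixel_um = NA,
                     defect_cols = NULL, flags = list(), dose = NULL) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(angles_deg))
  if (any(diff(angles_deg) <= 0)) stop("angles must be strictly increasing")
  if (is.null(defect_cols)) defect_cols <- rep(FALSE, ncol(values))
  fl <- list(inpainted = FALSE, denoised = FALSE, extended = FALSE)
  fl[names(flags)] <- flags
  structure(list(values = values, angles_deg = angles_deg,
                 axis_offset_px = axis_offset_px, pixel_um = pixel_um,
                 defect_cols = defect_cols, flags = fl, dose = dose),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d angles (%.4g..%.4g deg) x %d columns, offset %g px\n",
              nrow(x$values), min(x$angles_deg), max(x$angles_deg),
              ncol(x$values), x$axis_offset_px))
  on <- names(Filter(isTRUE, x$flags))
  if (length(on)) cat("  flags:", paste(on, collapse = ", "), "\n")
  invisible(x)
}

#' Flat-field correction of a projection stack
#'
#' Divides every projection by the mean flat frame (dark-subtracted when
#' dark frames are present). Pixels whose flat is zero or flagged defective
#' are added to the defect mask and not divided, so the output is finite
#' everywhere.
#'
#' @param stack a `projection_stack` from [simulate_scan()] or
#'   [read_projection_stack()].
#' @return the stack with `intensities` and `flats` normalized
#'   (`normalized = TRUE`) and an updated defect mask.
#' @export
flat_field_correct <- function(stack) {
  stopifnot(inherits(stack, "projection_stack"))
  if (isTRUE(stack$normalized)) return(stack)
  nf <- dim(stack$flats)[1]
  if (nf < 1) stop("at least one flat frame is required")
  mean_flat <- apply(stack$flats, c(2, 3), mean)
  if (!is.null(stack$darks)) {
    mean_dark <- apply(stack$darks, c(2, 3), mean)
    mean_flat <- mean_flat - mean_dark
  } else mean_dark <- 0
  if (all(mean_flat <= 0)) stop("fatal input error: flat field is all zero")
  bad <- mean_flat <= 0
  mask <- stack$defect_mask | bad
  cls <- stack$defect_class
  cls[bad & cls == 0L] <- 1L
  safe_flat <- ifelse(bad, 1, mean_flat)
  n_proj <- dim(stack$intensities)[1]
  for (i in seq_len(n_proj)) {
    fr <- (stack$intensities[i, , ] - mean_dark) / safe_flat
    fr[bad] <- 0
    stack$intensities[i, , ] <- pmax(fr, 0)
  }
  stack$defect_mask <- mask
  stack$defect_class <- cls
  stack$normalized <- TRUE
  stack
}

#' Extract the sinogram of one detector row
#'
#' @param stack a flat-normalized `projection_stack`.
#' @param row detector row index.
#' @return a [sinogram()].
#' @export
sinogram_from_stack <- function(stack, row = 1) {
  stopifnot(inherits(stack, "projection_stack"))
  if (!isTRUE(stack$normalized)) stack <- flat_field_correct(stack)
  vals <- stack$intensities[, row, , drop = TRUE]
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = dim(stack$intensities)[1])
  sinogram(vals, stack$angles_deg, stack$axis_offset_px, stack$pixel_um,
           defect_cols = stack$defect_mask[row, ])
}

#' Inpaint detector defects by diffusion
#'
#' Replaces defect pixels with the harmonic (Laplace) interpolant of their
#' live neighbors, computed by Jacobi iteration to a fixed tolerance; live
#' pixels are bit-unchanged and the fill is deterministic, hence idempotent
#' on a fixed mask. Contiguous fully-masked column bands wider than
#' `max_gap` trigger a warning and a row-wise linear interpolation
#' fallback before diffusion.
#'
#' @param image numeric matrix.
#' @param defect_mask logical matrix, `TRUE` at pixels to fill.
#' @param max_gap widest fully-masked column band (px) the diffusion fill
#'   will handle without the linear fallback.
#' @param tol convergence tolerance relative to the live-pixel range.
#' @param max_iter iteration cap.
#' @return the inpainted matrix.
#' @export
inpaint_defects <- function(image, defect_mask, max_gap = 8,
                            tol = 1e-9, max_iter = 5000) {
  stopifnot(all(dim(image) == dim(defect_mask)))
  if (!any(defect_mask)) return(image)
  if (all(defect_mask)) stop("defect mask covers the entire image")
  n <- nrow(image); m <- ncol(image)
  x <- image
  mask <- defect_mask
  # wide fully-masked column bands: linear interpolation fallback
  full_cols <- which(colSums(mask) == n)
  if (length(full_cols) > 0) {
    r <- rle(diff(c(-1, full_cols)) == 1)
    runs <- split(full_cols, cumsum(c(TRUE, diff(full_cols) != 1)))
    for (run in runs) {
      if (length(run) > max_gap) {
        warning(sprintf("masked column band of width %d exceeds max_gap = %d; using linear interpolation",
                        length(run), max_gap))
        lo <- min(run) - 1; hi <- max(run) + 1
        if (lo < 1 || hi > m) {
          edge <- if (lo < 1) hi else lo
          x[, run] <- x[, edge]
        } else {
          w <- (run - lo) / (hi - lo)
          x[, run] <- outer(x[, lo], 1 - w) + outer(x[, hi], w)
        }
        mask[, run] <- FALSE
      }
    }
  }
  if (any(mask)) {
    live_rng <- diff(range(image[!defect_mask]))
    thresh <- if (live_rng > 0) tol * live_rng else tol
    x[mask] <- mean(image[!defect_mask])
    idx <- which(mask)
    ri <- seq_len(n); ci <- seq_len(m)
    for (it in seq_len(max_iter)) {
      nb <- (x[pmax(ri - 1, 1), , drop = FALSE] +
             x[pmin(ri + 1, n), , drop = FALSE] +
             x[, pmax(ci - 1, 1), drop = FALSE] +
             x[, pmin(ci + 1, m), drop = FALSE]) / 4
      delta <- max(abs(nb[idx] - x[idx]))
      x[idx] <- nb[idx]
      if (delta < thresh) break
    }
  }
  x
}

#' Inpaint a sinogram's defective columns
#'
#' Convenience wrapper applying [inpaint_defects()] to the defect columns
#' of a sinogram and setting the provenance flag.
#'
#' @param sino a [sinogram()].
#' @param ... passed to [inpaint_defects()].
#' @return the inpainted sinogram.
#' @export
inpaint_sinogram <- function(sino, ...) {
  stopifnot(inherits(sino, "sinogram"))
  if (!any(sino$defect_cols)) return(sino)
  mask <- matrix(rep(sino$defect_cols, each = nrow(sino$values)),
                 nrow(sino$values), ncol(sino$values))
  sino$values <- inpaint_defects(sino$values, mask, ...)
  sino$flags$inpainted <- TRUE
  sino
}

#' Estimate the rotation-axis offset of a 360-degree sinogram
#'
#' Cross-correlates each projection with the mirrored conjugate projection
#' half a turn away; the correlation peak sits at twice the axis offset.
#' The integer peak is refined by a parabolic fit and estimates are
#' averaged over a sample of angle pairs.
#'
#' @param sino a 360-degree [sinogram()].
#' @param n_pairs number of angle pairs to sample.
#' @return numeric offset in pixels, with attributes `confidence` (mean
#'   peak correlation) and `low_confidence` (TRUE when below 0.5).
#' @export
estimate_axis_offset <- function(sino, n_pairs = 16) {
  stopifnot(inherits(sino, "sinogram"))
  n <- nrow(sino$values)
  if (n %% 2 != 0) stop("360-degree sinogram with an even projection count required")
  half <- n / 2
  W <- ncol(sino$values)
  pick <- unique(round(seq(1, half, length.out = min(n_pairs, half))))
  lags <- -(W - 2):(W - 2)
  ests <- conf <- numeric(0)
  for (i in pick) {
    a <- sino$values[i, ]
    b <- rev(sino$values[i + half, ])
    cc <- vapply(lags, function(L) {
      ia <- max(1, 1 + L):min(W, W + L)
      ib <- ia - L
      if (length(ia) < 8) return(-Inf)
      sa <- a[ia]; sb <- b[ib]
      if (stats::sd(sa) == 0 || stats::sd(sb) == 0) return(-Inf)
      stats::cor(sa, sb)
    }, numeric(1))
    j <- which.max(cc)
    peak <- lags[j]
    if (j > 1 && j < length(lags) && is.finite(cc[j - 1]) && is.finite(cc[j + 1])) {
      denom <- cc[j - 1] - 2 * cc[j] + cc[j + 1]
      if (denom < 0) peak <- peak + 0.5 * (cc[j - 1] - cc[j + 1]) / denom
    }
    ests <- c(ests, -peak / 2)
    conf <- c(conf, max(cc[is.finite(cc)]))
  }
  est <- stats::median(ests)
  # reliable estimates require both strong peaks and agreement across the
  # sampled angle pairs
  low <- mean(conf) < 0.5 || stats::IQR(ests) > 2
  structure(est, confidence = mean(conf), low_confidence = low)
}

#' Convert an off-center 360-degree sinogram to an extended 180-degree one
#'
#' Each projection at angle theta + 180 is mirrored about the rotation
#' axis and fused with the projection at theta on their overlap using a
#' cosine-feathered blend, yielding a 180-degree sinogram of roughly twice
#' the lateral width with the rotation axis at its center column.
#'
#' @param sino a 360-degree [sinogram()] with known or estimable axis
#'   offset.
#' @param axis_offset_px override for the stored offset; `NULL` uses the
#'   sinogram metadata, falling back to [estimate_axis_offset()].
#' @param blend_px width of the cosine feather across the overlap (px).
#' @param check verify that the two halves agree on the overlap: their
#'   angle-averaged lateral profiles must not differ by more than noise
#'   allows (chi-square-like score, with the noise level estimated from
#'   angle-to-angle differences).
#' @param max_mismatch largest accepted mismatch score (1 = consistent
#'   within noise) when `check = TRUE`.
#' @return an extended 180-degree [sinogram()] (axis offset 0).
#' @export
extend_offcenter <- function(sino, axis_offset_px = NULL, blend_px = 20,
                             check = TRUE, max_mismatch = 25) {
  stopifnot(inherits(sino, "sinogram"))
  n <- nrow(sino$values)
  rng <- max(sino$angles_deg) - min(sino$angles_deg)
  if (rng < 270) stop("a 360-degree sinogram is required")
  if (n %% 2 != 0) stop("even projection count required")
  o <- axis_offset_px
  if (is.null(o)) {
    o <- sino$axis_offset_px
    if (is.null(o) || is.na(o)) o <- as.numeric(estimate_axis_offset(sino))
  }
  half <- n / 2
  vals360 <- sino$values
  W <- ncol(vals360)
  flip <- o < 0
  if (flip) { vals360 <- vals360[, W:1, drop = FALSE]; o <- -o }
  # snap to the native sample grid: when 2*o is integral, the mirrored
  # conjugate samples land exactly on the direct half's grid and no
  # interpolation is needed (the generic case is interpolated onto that
  # grid).
  t2 <- round(2 * o)
  m <- (W + 1) / 2
  h1 <- vals360[1:half, , drop = FALSE]
  h2 <- vals360[(half + 1):n, , drop = FALSE]
  h2r <- h2[, W:1, drop = FALSE]
  W_out <- W + t2
  # output column k holds lateral position s = k - m - o (axis at the
  # center column); direct half covers k = t2+1 .. W+t2, the mirrored
  # conjugate covers k = 1 .. W
  direct <- matrix(0, half, W_out)
  conj <- matrix(0, half, W_out)
  if (abs(2 * o - t2) < 1e-6) {
    direct[, t2 + seq_len(W)] <- h1
    conj[, seq_len(W)] <- h2r
  } else {
    jd <- (seq_len(W_out)) - t2 + (2 * o - t2)   # fractional source columns
    gather <- function(M, jpos) {
      out <- matrix(0, half, length(jpos))
      j0 <- floor(jpos); fr <- jpos - j0
      ok <- j0 >= 1 & j0 <= W - 1
      out[, ok] <- M[, j0[ok], drop = FALSE] * rep(1 - fr[ok], each = half) +
        M[, j0[ok] + 1, drop = FALSE] * rep(fr[ok], each = half)
      out
    }
    direct <- gather(h1, (seq_len(W_out)) - 2 * o)
    conj <- gather(h2r, seq_len(W_out) + (t2 - 2 * o))
    conj[, seq_len(min(W, W_out))] <- h2r[, seq_len(min(W, W_out))]
  }
  s_k <- seq_len(W_out) - m - o
  cov_d <- seq_len(W_out) > t2
  cov_c <- seq_len(W_out) <= W
  both <- cov_d & cov_c
  if (check && sum(both) >= 4) {
    # angle-averaged lateral profiles of the two halves must agree within
    # noise; the per-column noise level is estimated from angle-to-angle
    # first differences (structure varies slowly with angle)
    D <- direct[, both, drop = FALSE]
    C <- conj[, both, drop = FALSE]
    d1 <- colMeans(D); c1 <- colMeans(C)
    v <- (mean(diff_var(D)) + mean(diff_var(C))) / 2
    msd <- mean((d1 - c1)^2)
    denom <- 2 * v / half + (1e-6 * mean(abs(d1)))^2
    score <- msd / denom
    if (!is.finite(score) || score > max_mismatch) {
      stop(sprintf(
        "estimation error: overlap mismatch score %.1f exceeds %.1f; axis offset %.2f px is likely inconsistent",
        score, max_mismatch, o))
    }
  }
  b <- min(blend_px, max(sum(both) - 2, 1))
  w1 <- ifelse(s_k > b / 2, 1,
               ifelse(s_k < -b / 2, 0,
                      0.5 * (1 - cos(pi * (s_k + b / 2) / b))))
  w1[!cov_c] <- 1
  w1[!cov_d] <- 0
  vals <- direct * rep(w1, each = half) + conj * rep(1 - w1, each = half)
  if (flip) vals <- vals[, W_out:1, drop = FALSE]
  sinogram(vals, sino$angles_deg[1:half], axis_offset_px = 0,
           pixel_um = sino$pixel_um,
           flags = utils::modifyList(sino$flags, list(extended = TRUE)),
           dose = sino$dose)
}

# per-column noise variance estimate from first differences along angles
diff_var <- function(M) {
  d <- diff(M)
  colSums(d^2) / (2 * nrow(d))
}

#' Retain a regular subset of projections
#'
#' Keeps every k-th projection with the stated parity (indexed from 0) and
#' rescales any dose metadata linearly, mirroring a scan acquired at the
#' reduced projection count.
#'
#' @param sino a [sinogram()].
#' @param fraction fraction of projections retained; `fraction * n_proj`
#'   must be integral.
#' @param phase `"even"` or `"odd"` parity of retained 0-based indices.
#' @return the subsampled sinogram.
#' @export
subsample_projections <- function(sino, fraction = 0.5,
                                  phase = c("even", "odd")) {
  stopifnot(inherits(sino, "sinogram"))
  phase <- match.arg(phase)
  n <- nrow(sino$values)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (abs(n * fraction - round(n * fraction)) > 1e-9) {
    stop("parameter error: fraction * n_proj must be integral")
  }
  if (fraction == 1) return(sino)
  k <- round(1 / fraction)
  if (abs(k - 1 / fraction) > 1e-9) {
    stop("parameter error: 1/fraction must be an integer step")
  }
  start <- if (phase == "even") 1L else 2L
  idx <- seq(start, n, by = k)
  out <- sino
  out$values <- sino$values[idx, , drop = FALSE]
  out$angles_deg <- sino$angles_deg[idx]
  if (!is.null(sino$dose)) {
    out$dose$entrance_mGy <- sino$dose$entrance_mGy * fraction
    out$dose$tissue_mGy <- sino$dose$tissue_mGy * fraction
    out$dose$projection_fraction <- sino$dose$projection_fraction * fraction
  }
  out
}
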