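# Quantitative image-quality suite: CNR, edge-profile FWHM, radial power
# spectra, edge enhancement, edge-blur measurement and MSCT-resolution
# simulation.

#' Contrast-to-noise ratio between two regions
#'
#' `CNR = |S1 - S2| / sqrt(0.5 * (sd1^2 + sd2^2))` over two disjoint
#' homogeneous regions of one image. If both region standard deviations
#' are zero the value is 0 for equal means and `Inf` (flagged) otherwise.
#'
#' @param image numeric matrix.
#' @param region1,region2 logical masks (same shape as `image`) or index
#'   vectors; each region must hold at least 25 pixels and the regions
#'   must be disjoint.
#' @return CNR value with attribute `regions` (per-region mean and sd).
#' @examples
#' img <- matrix(rnorm(64 * 64, 10), 64)
#' img[, 33:64] <- img[, 33:64] - 4
#' m1 <- m2 <- matrix(FALSE, 64, 64)
#' m1[20:40, 5:25] <- TRUE; m2[20:40, 40:60] <- TRUE
#' cnr(img, m1, m2)
#' @export
cnr <- function(image, region1, region2) {
  idx1 <- if (is.logical(region1)) which(region1) else as.integer(region1)
  idx2 <- if (is.logical(region2)) which(region2) else as.integer(region2)
  if (length(idx1) < 25 || length(idx2) < 25) {
    stop("each region must contain at least 25 pixels")
  }
  if (length(intersect(idx1, idx2)) > 0) stop("regions must be disjoint")
  s1 <- mean(image[idx1]); s2 <- mean(image[idx2])
  v1 <- stats::sd(image[idx1])^2; v2 <- stats::sd(image[idx2])^2
  denom <- sqrt(0.5 * (v1 + v2))
  val <- if (denom == 0) {
    if (s1 == s2) 0 else Inf
  } else abs(s1 - s2) / denom
  structure(val,
            regions = data.frame(region = 1:2, mean = c(s1, s2),
                                 sd = sqrt(c(v1, v2))),
            degenerate = denom == 0)
}

#' CNR over a batch of region pairs
#'
#' Replicates the triplicate measurement protocol: one CNR value per
#' region pair on the same image.
#'
#' @param image numeric matrix.
#' @param pairs list of `list(region1, region2)` mask pairs.
#' @return numeric vector of CNR values.
#' @export
cnr_batch <- function(image, pairs) {
  vapply(pairs, function(p) as.numeric(cnr(image, p[[1]], p[[2]])),
         numeric(1))
}

#' Edge sharpness from a profile: FWHM of the normalized derivative
#'
#' Approximates the absolute first derivative of a 1-D intensity profile
#' by the difference coefficient, min-max normalizes it to \[0, 1\], and
#' measures the full width at half maximum between the two half-maximum
#' crossings found by linear interpolation around the (leftmost) peak.
#'
#' The 1-px difference coefficient convolves the underlying line-spread
#' function with a unit box, inflating the width; with
#' `correct_sampling = TRUE` (default) the reported FWHM removes that
#' 1/12 px^2 variance contribution in quadrature, so a Gaussian edge of
#' scale sigma reports `2*sqrt(2*log(2))*sigma` to subpixel accuracy.
#' A single-sample derivative spike reports the conventional floor of
#' 1 px.
#'
#' @param profile numeric vector crossing one dominant edge.
#' @param pixel_um pixel size for the micron-valued FWHM.
#' @param correct_sampling remove the finite-difference box contribution.
#' @return object of class `edge_profile`: `fwhm_px`, `fwhm_um`,
#'   `derivative` (normalized), `peak_index`, `multiple_peaks` flag.
#' @export
edge_fwhm <- function(profile, pixel_um = 1, correct_sampling = TRUE) {
  if (length(profile) < 3) stop("profile too short")
  d <- abs(diff(profile))
  if (max(d) == 0) stop("no-edge error: profile is constant")
  if (diff(range(d)) == 0) stop("no-edge error: derivative has no peak")
  dn <- (d - min(d)) / (max(d) - min(d))
  peaks <- which(dn == 1)
  multiple <- length(peaks) > 1
  pk <- peaks[1]
  spike <- !multiple &&
    (pk == 1 || dn[pk - 1] < 0.3) && (pk == length(dn) || dn[pk + 1] < 0.3)
  raw <- if (spike) 1 else fwhm_of_samples(dn, pk)
  fw <- raw
  if (correct_sampling) {
    box <- (2 * sqrt(2 * log(2)))^2 / 12   # FWHM^2 contribution of a unit box
    fw <- sqrt(max(raw^2 - box, 0))
  }
  fw <- max(fw, 1)
  structure(list(fwhm_px = fw, fwhm_um = fw * pixel_um,
                 derivative = dn, peak_index = pk,
                 multiple_peaks = multiple, raw_fwhm_px = max(raw, 1)),
            class = "edge_profile")
}

#' Measure the blur of a straight high-contrast edge in an image
#'
#' Extracts many 1-D profiles perpendicular to a near-vertical or
#' near-horizontal edge, aligns them at subpixel precision on the edge
#' position (centroid of the absolute derivative), averages the aligned
#' profiles, and reports both the derivative FWHM and the 10-90%
#' transition width of the averaged edge.
#'
#' @param image numeric matrix containing one dominant straight edge.
#' @param axis `"horizontal"` for profiles along rows (a near-vertical
#'   edge), `"vertical"` for profiles along columns.
#' @param pixel_um pixel size (um).
#' @param n_profiles number of profiles to average (>= 20 when available).
#' @return list: `fwhm_px`, `fwhm_um`, `width_10_90_px`, `width_10_90_um`,
#'   `edge_profile` (the averaged profile).
#' @export
measure_edge_blur <- function(image, axis = c("horizontal", "vertical"),
                              pixel_um = 1, n_profiles = 40) {
  axis <- match.arg(axis)
  M <- if (axis == "horizontal") image else t(image)
  n <- nrow(M); m <- ncol(M)
  rows <- unique(round(seq(1, n, length.out = min(n, n_profiles))))
  # the edge is straight: locate it on the row-averaged profile first,
  # estimate per-row subpixel positions inside a narrow window around that
  # global position, then regularize them with a line fit across rows so
  # single-profile noise cannot scatter the alignment
  gd <- abs(diff(colMeans(M)))
  if (max(gd) == 0) stop("no edge found in the image")
  gpk <- which.max(stats::filter(gd, rep(1 / 3, 3), sides = 2, circular = TRUE))
  pos <- vapply(rows, function(r) {
    d <- abs(diff(M[r, ]))
    win <- max(1, gpk - 8):min(length(d), gpk + 8)
    if (max(d[win]) == 0) return(NA_real_)
    pk <- win[which.max(d[win])]
    cw <- max(1, pk - 4):min(length(d), pk + 4)
    w <- d[cw]^2
    sum((cw + 0.5) * w) / sum(w)
  }, numeric(1))
  if (sum(is.finite(pos)) >= 5) {
    fit <- stats::lm(pos ~ rows, subset = is.finite(pos))
    res <- pos - stats::predict(fit, data.frame(rows = rows))
    good <- is.finite(res) & abs(res - stats::median(res, na.rm = TRUE)) < 2.5
    if (sum(good) >= 5) {
      fit <- stats::lm(pos ~ rows, subset = good)
      pos <- as.vector(stats::predict(fit, data.frame(rows = rows)))
    }
  }
  ok <- is.finite(pos)
  rows <- rows[ok]; pos <- pos[ok]
  if (length(rows) < 3) stop("no usable edge profiles found")
  # integer-shift alignment at native pitch; the residual subpixel jitter
  # (uniform within +-0.5 px) is removed in quadrature below together with
  # the difference-coefficient box
  ref <- round(stats::median(pos))
  shifts <- round(pos - ref)
  # widest window such that at least 3 aligned profiles fit the matrix
  halfw <- min(64, floor(min(ref - 1, m - ref - 1)))
  repeat {
    keep <- ref + shifts - halfw >= 1 & ref + shifts + halfw <= m
    if (sum(keep) >= min(3, length(rows)) || halfw <= 3) break
    halfw <- halfw - 1
  }
  if (halfw < 3 || sum(keep) < 3) stop("edge too close to the image border")
  xs <- -halfw:halfw
  rows <- rows[keep]; shifts <- shifts[keep]
  acc <- matrix(NA_real_, length(rows), length(xs))
  for (i in seq_along(rows)) {
    acc[i, ] <- M[rows[i], ref + shifts[i] + xs]
  }
  prof <- colMeans(acc)
  ef <- edge_fwhm(prof, pixel_um = pixel_um, correct_sampling = FALSE)
  box <- (2 * sqrt(2 * log(2)))^2 / 12
  fwhm_px <- max(sqrt(max(ef$raw_fwhm_px^2 - 2 * box, 0)), 1)
  # 10-90% transition width on the averaged (monotonized) edge
  lo <- stats::median(utils::head(prof, 4)); hi <- stats::median(utils::tail(prof, 4))
  a <- min(lo, hi); b <- max(lo, hi)
  t10 <- a + 0.1 * (b - a); t90 <- a + 0.9 * (b - a)
  pr <- if (lo > hi) rev(prof) else prof
  x10 <- crossing_position(pr, t10); x90 <- crossing_position(pr, t90)
  w1090 <- abs(x90 - x10)
  list(fwhm_px = fwhm_px, fwhm_um = fwhm_px * pixel_um,
       width_10_90_px = w1090, width_10_90_um = w1090 * pixel_um,
       edge_profile = prof, n_profiles = length(rows))
}

# Full width at half maximum of a sampled peak, in sample units.
# The samples are oversampled 8x by band-limited (FFT) interpolation after
# removing the linear ramp between the endpoints, then the half-maximum
# crossings nearest the peak are located by linear interpolation on the
# fine grid. Falls back to direct linear interpolation for very short
# inputs.
fwhm_of_samples <- function(d, pk = which.max(d), oversample = 8L) {
  n <- length(d)
  if (n >= 8) {
    ramp <- d[1] + (d[n] - d[1]) * (seq_len(n) - 1) / (n - 1)
    r <- d - ramp
    Df <- stats::fft(r)
    m <- n * oversample
    half_n <- floor(n / 2)
    Dp <- complex(real = numeric(m), imaginary = numeric(m))
    Dp[1:(half_n + 1)] <- Df[1:(half_n + 1)]
    if (half_n > 1) Dp[(m - half_n + 2):m] <- Df[(n - half_n + 2):n]
    fine <- Re(stats::fft(Dp, inverse = TRUE)) / n
    xf <- 1 + (seq_len(m) - 1) / oversample
    fine <- fine + d[1] + (d[n] - d[1]) * (xf - 1) / (n - 1)
    pkf <- which.max(fine)
    hl <- 0.5 * fine[pkf]
    li <- pkf
    while (li > 1 && fine[li - 1] >= hl) li <- li - 1
    xl <- if (li == 1) xf[1] else {
      xf[li - 1] + (hl - fine[li - 1]) / (fine[li] - fine[li - 1]) / oversample
    }
    ri <- pkf
    while (ri < m && fine[ri + 1] >= hl) ri <- ri + 1
    xr <- if (ri == m) xf[m] else {
      xf[ri] + (fine[ri] - hl) / (fine[ri] - fine[ri + 1]) / oversample
    }
    return(xr - xl)
  }
  hl <- 0.5 * max(d)
  left <- pk
  while (left > 1 && d[left - 1] >= hl) left <- left - 1
  xl <- if (left == 1 && d[1] >= hl) 1 else {
    left - 1 + (hl - d[left - 1]) / (d[left] - d[left - 1])
  }
  right <- pk
  while (right < n && d[right + 1] >= hl) right <- right + 1
  xr <- if (right == n && d[n] >= hl) n else {
    right + (d[right] - hl) / (d[right] - d[right + 1])
  }
  xr - xl
}

# first upward crossing of level `lev` in profile y (index units)
crossing_position <- function(y, lev) {
  above <- which(y >= lev)
  if (length(above) == 0 || above[1] == 1) return(above[1] %||% NA_real_)
  i <- above[1]
  (i - 1) + (lev - y[i - 1]) / (y[i] - y[i - 1])
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Phase-contrast edge enhancement above baseline
#'
#' Percentage by which the brightest fringe peak exceeds the baseline,
#' with the baseline taken as the median of the flanking windows of the
#' profile: `(peak - baseline) / baseline * 100`.
#'
#' @param profile 1-D intensity profile across a fringe.
#' @param flank_frac fraction of the profile length used as flanking
#'   baseline windows on each side.
#' @return percentage above baseline (0, flagged, if no peak exceeds
#'   baseline + 3 flanking noise SDs).
#' @export
edge_enhancement <- function(profile, flank_frac = 0.2) {
  n <- length(profile)
  k <- max(3, round(flank_frac * n))
  flank <- c(profile[1:k], profile[(n - k + 1):n])
  baseline <- stats::median(flank)
  sigma <- stats::sd(flank)
  peak <- max(profile)
  if (peak <= baseline + 3 * sigma) {
    return(structure(0, no_peak = TRUE))
  }
  structure((peak - baseline) / baseline * 100, no_peak = FALSE)
}

#' Radially averaged power spectrum
#'
#' 2-D power spectrum of a square region with the zero-frequency power
#' set to zero, radially binned in cycles/mm (so differently sampled
#' images share a frequency axis) and normalized to total power 1.
#'
#' @param region square numeric matrix (side >= 64 px).
#' @param pixel_um pixel size (um).
#' @param n_bins number of radial bins; defaults to half the side length.
#' @return object of class `radial_spectrum`: `freq_cyc_mm` (bin centers),
#'   `power` (sums to 1), `region_mm2`, `degenerate` flag.
#' @export
radial_power_spectrum <- function(region, pixel_um, n_bins = NULL) {
  n <- nrow(region)
  if (ncol(region) != n) stop("region must be square")
  if (n < 64) stop("region side must be >= 64 px")
  px_mm <- pixel_um / 1000
  P <- Mod(fft2(region))^2
  P[1, 1] <- 0
  f <- fft_freqs(n) / px_mm          # cycles per mm
  fr <- sqrt(outer(f^2, rep(1, n)) + outer(rep(1, n), f^2))
  if (is.null(n_bins)) n_bins <- floor(n / 2)
  bin_width <- 1 / (n * px_mm)
  bins <- pmin(pmax(ceiling(fr / bin_width), 1), n_bins)
  total <- sum(P)
  if (total == 0) {
    return(structure(list(freq_cyc_mm = (seq_len(n_bins) - 0.5) * bin_width,
                          power = rep(0, n_bins),
                          region_mm2 = (n * px_mm)^2, degenerate = TRUE),
                     class = "radial_spectrum"))
  }
  pw <- as.vector(rowsum(as.vector(P), as.vector(bins)))
  power <- numeric(n_bins)
  power[sort(unique(as.vector(bins)))] <- pw
  power <- power / total
  structure(list(freq_cyc_mm = (seq_len(n_bins) - 0.5) * bin_width,
                 power = power, region_mm2 = (n * px_mm)^2,
                 degenerate = FALSE),
            class = "radial_spectrum")
}

#' Fraction of spectral power above a frequency cutoff
#'
#' @param spec a [radial_power_spectrum()] result.
#' @param cutoff_frac cutoff as a fraction of the maximum binned frequency.
#' @return scalar in \[0, 1\].
#' @export
high_frequency_fraction <- function(spec, cutoff_frac = 0.5) {
  stopifnot(inherits(spec, "radial_spectrum"))
  sum(spec$power[spec$freq_cyc_mm > cutoff_frac * max(spec$freq_cyc_mm)])
}

#' Simulate multislice-CT resolution by downsampling
#'
#' Degrades a reconstructed volume to clinical MSCT sampling by exact
#' area-weighted (boxcar) averaging to the target in-plane pixel spacing
#' and slice thickness; the box average is itself the anti-alias filter.
#' Both factors may be non-integer.
#'
#' @param volume a [recon_volume()] (or matrix / 3-D array with
#'   `pixel_um` given).
#' @param target_pixel_mm target in-plane spacing (default 0.76 mm).
#' @param target_slice_mm target slice thickness (default 0.625 mm).
#' @param pixel_um,slice_um source spacings when `volume` is a bare array.
#' @return a [recon_volume()] at the degraded sampling.
#' @export
simulate_msct_resolution <- function(volume, target_pixel_mm = 0.76,
                                     target_slice_mm = 0.625,
                                     pixel_um = NULL, slice_um = NULL) {
  if (!inherits(volume, "recon_volume")) {
    stopifnot(!is.null(pixel_um))
    volume <- recon_volume(volume, pixel_um, slice_um %||% pixel_um)
  }
  f_xy <- target_pixel_mm * 1000 / volume$pixel_um
  f_z <- target_slice_mm * 1000 / volume$slice_um
  if (f_xy < 1 || f_z < 1) {
    stop("parameter error: target sampling must be coarser than the source")
  }
  v <- volume$values
  d <- dim(v)
  if (f_xy > 1) {
    nx <- floor(d[1] / f_xy); ny <- floor(d[2] / f_xy)
    out <- array(0, c(nx, ny, d[3]))
    for (z in seq_len(d[3])) {
      tmp <- box_resample_cols(v[, , z], f_xy)              # rows
      out[, , z] <- t(box_resample_cols(t(tmp), f_xy))      # cols
    }
    v <- out; d <- dim(v)
  }
  if (f_z > 1 && d[3] > 1) {
    nz <- floor(d[3] / f_z)
    if (nz < 1) stop("volume too thin for the target slice thickness")
    flat <- matrix(aperm(v, c(3, 1, 2)), nrow = d[3])
    res <- box_resample_cols(flat, f_z)
    v <- aperm(array(res, c(nz, d[1], d[2])), c(2, 3, 1))
  }
  recon_volume(v, target_pixel_mm * 1000,
               if (dim(volume$values)[3] > 1) target_slice_mm * 1000
               else volume$slice_um)
}

#' Structural similarity index between two images
#'
#' Mean local SSIM with a Gaussian weighting window (standard constants
#' K1 = 0.01, K2 = 0.03; dynamic range from the reference image).
#'
#' @param x,y numeric matrices of identical shape.
#' @param sigma Gaussian window scale (px).
#' @return mean SSIM in \[-1, 1\].
#' @export
ssim <- function(x, y, sigma = 1.5) {
  stopifnot(all(dim(x) == dim(y)))
  L <- diff(range(x))
  if (L == 0) L <- 1
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  blur <- function(z) gaussian_blur_fft(z, sigma, sigma)
  mx <- blur(x); my <- blur(y)
  sxx <- blur(x * x) - mx^2
  syy <- blur(y * y) - my^2
  sxy <- blur(x * y) - mx * my
  s <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
    ((mx^2 + my^2 + C1) * (sxx + syy + C2))
  mean(s)
}
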