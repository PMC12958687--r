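# Single-distance TIE-Hom phase retrieval, filtered back projection, and
# vertical stitching.

#' Phase-retrieval specification
#'
#' Parameters of single-distance homogeneous-object (TIE-Hom) retrieval:
#' the delta/beta ratio, wavelength, effective propagation distance and
#' effective pixel size. The frequency-domain filter is
#' `1 / (1 + pi * lambda * z_eff * (delta/beta) * |f|^2)` applied to the
#' flat-normalized intensity, followed by `-log`.
#'
#' @param delta_beta delta-to-beta ratio (default 2000).
#' @param wavelength_m wavelength (m).
#' @param z_eff_m effective propagation distance (m).
#' @param pixel_um effective pixel size (um).
#' @return object of class `retrieval_spec`.
#' @export
retrieval_spec <- function(delta_beta = 2000, wavelength_m, z_eff_m,
                           pixel_um) {
  if (delta_beta <= 0) stop("delta_beta must be > 0")
  if (z_eff_m < 0) stop("z_eff must be >= 0")
  structure(list(delta_beta = delta_beta, wavelength_m = wavelength_m,
                 z_eff_m = z_eff_m, pixel_um = pixel_um),
            class = "retrieval_spec")
}

#' Retrieval specification implied by an imaging geometry
#'
#' Derives wavelength from the photon energy, the effective propagation
#' distance `z_sd * z_ss / (z_ss + z_sd)` and the effective pixel size from
#' a [geometry_spec()].
#'
#' @param g a [geometry_spec()].
#' @param delta_beta delta-to-beta ratio.
#' @return a [retrieval_spec()].
#' @export
retrieval_spec_from_geometry <- function(g, delta_beta = 2000) {
  stopifnot(inherits(g, "geometry_spec"))
  retrieval_spec(delta_beta, keV_to_wavelength(g$energy_keV),
                 effective_distance(g), effective_pixel_size(g))
}

# TIE-Hom low-pass on a matrix of flat-normalized intensity; dims_1d = TRUE
# filters along columns only (each row an independent 1-D projection).
tie_hom_filter <- function(I, spec, dims_1d = FALSE, eps = 1e-8) {
  coef <- pi * spec$wavelength_m * spec$z_eff_m * spec$delta_beta
  px_m <- spec$pixel_um * 1e-6
  if (coef == 0) return(pmax(I, eps))
  if (dims_1d) {
    nc <- next_pow2(2 * ncol(I))
    pad <- pad_edge(I, nrow(I), nc)
    f <- fft_freqs(nc) / px_m
    H <- 1 / (1 + coef * f^2)
    Xf <- t(stats::mvfft(t(pad$x)))
    filt <- Re(t(stats::mvfft(t(Xf * rep(H, each = nrow(I))), inverse = TRUE))) / nc
    out <- filt[, pad$cols, drop = FALSE]
  } else {
    nr <- next_pow2(2 * nrow(I)); nc <- next_pow2(2 * ncol(I))
    pad <- pad_edge(I, nr, nc)
    fr <- fft_freqs(nr) / px_m
    fc <- fft_freqs(nc) / px_m
    H <- 1 / (1 + coef * outer(fr^2, rep(1, nc)) + coef * outer(rep(1, nr), fc^2))
    filt <- Re(fft2(fft2(pad$x) * H, inverse = TRUE)) / (nr * nc)
    out <- filt[pad$rows, pad$cols, drop = FALSE]
  }
  pmax(out, eps)
}

#' Single-distance TIE-Hom phase retrieval
#'
#' Applies the homogeneous-object low-pass filter to flat-normalized
#' intensity and takes `-log`, yielding an image proportional to projected
#' thickness times the attenuation coefficient. Inputs are padded
#' symmetrically to the next power of two before the transform; any
#' non-positive filtered intensities are clamped at a small epsilon and
#' counted.
#'
#' For a 2-D projection the filter is two-dimensional; for a [sinogram()]
#' each row (one projection's trace) is filtered along the detector axis.
#' With `z_eff = 0` (or a vanishing delta/beta) the filter is the identity
#' and the result is the pure absorption signal `-log(I/I0)`.
#'
#' @param x a matrix / vector of flat-normalized intensity, or a
#'   [sinogram()].
#' @param spec a [retrieval_spec()].
#' @return retrieved projection of the same shape (a sinogram stays a
#'   sinogram, flagged `retrieved`), with attribute `n_clamped`.
#' @export
phase_retrieve <- function(x, spec) {
  stopifnot(inherits(spec, "retrieval_spec"))
  if (inherits(x, "sinogram")) {
    filt <- tie_hom_filter(x$values, spec, dims_1d = TRUE)
    n_clamped <- sum(filt <= 1e-8)
    x$values <- -log(filt)
    x$flags$retrieved <- TRUE
    attr(x, "n_clamped") <- n_clamped
    return(x)
  }
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  filt <- tie_hom_filter(x, spec, dims_1d = nrow(x) == 1)
  out <- -log(filt)
  if (vec) out <- drop(out)
  attr(out, "n_clamped") <- sum(filt <= 1e-8)
  out
}

# Discrete ramp (Ram-Lak) convolver response of length N (unit spacing),
# optionally Shepp-Logan apodized.
ramp_response <- function(N, filter = c("ramp", "shepp-logan")) {
  filter <- match.arg(filter)
  n <- c(0:(N / 2 - 1), -(N / 2):-1)
  h <- numeric(N)
  h[n == 0] <- 1 / 4
  odd <- n %% 2 != 0
  h[odd] <- -1 / (pi * n[odd])^2
  H <- Re(stats::fft(h))
  if (filter == "shepp-logan") {
    f <- fft_freqs(N)
    sc <- ifelse(f == 0, 1, sin(pi * f) / (pi * f))
    H <- H * sc
  }
  H
}

#' Filtered back projection of a 180-degree parallel sinogram
#'
#' Classical FBP: each projection is ramp-filtered (discrete Ram-Lak
#' convolver, optional Shepp-Logan apodization) and back-projected with
#' linear interpolation onto a square grid whose side equals the sinogram
#' width. Output values are scaled by the pixel size to per-length
#' attenuation units (1/m).
#'
#' @param sino a [sinogram()] spanning 180 degrees with uniform angles
#'   (axis at the center column), or a plain matrix (angles assumed
#'   uniform over \[0, 180)).
#' @param pixel_um pixel size (um); taken from the sinogram when present.
#' @param filter `"ramp"` or `"shepp-logan"`.
#' @param circle_mask set pixels outside the inscribed circle to 0.
#' @return object of class `recon_slice` with `values` (1/m) and
#'   `pixel_um`.
#' @export
fbp_reconstruct <- function(sino, pixel_um = NULL,
                            filter = c("ramp", "shepp-logan"),
                            circle_mask = FALSE) {
  filter <- match.arg(filter)
  if (inherits(sino, "sinogram")) {
    P <- sino$values
    angles <- sino$angles_deg
    if (is.null(pixel_um)) pixel_um <- sino$pixel_um
    prov <- sino$flags
  } else {
    P <- as.matrix(sino)
    angles <- (seq_len(nrow(P)) - 1) * 180 / nrow(P)
    prov <- list()
  }
  if (is.null(pixel_um) || is.na(pixel_um)) pixel_um <- 1
  n_ang <- nrow(P); W <- ncol(P)
  if (n_ang < 16) warning("fewer than 16 angles: severe angular undersampling")
  N <- next_pow2(2 * W)
  H <- ramp_response(N, filter)
  Ppad <- matrix(0, n_ang, N)
  Ppad[, 1:W] <- P
  Fp <- stats::mvfft(t(Ppad)) * H        # N x n_ang; H recycles per column
  Q <- Re(t(stats::mvfft(Fp, inverse = TRUE))) / N
  Q <- Q[, 1:W, drop = FALSE]
  c0 <- (W + 1) / 2
  u <- rep(seq_len(W) - c0, times = W)
  v <- rep(seq_len(W) - c0, each = W)
  rec <- numeric(W * W)
  th <- angles * pi / 180
  for (a in seq_len(n_ang)) {
    t_px <- -u * sin(th[a]) + v * cos(th[a]) + c0
    i0 <- floor(t_px)
    fr <- t_px - i0
    ok <- i0 >= 1 & i0 <= W - 1
    q <- Q[a, ]
    add <- numeric(W * W)
    add[ok] <- q[i0[ok]] * (1 - fr[ok]) + q[i0[ok] + 1] * fr[ok]
    rec <- rec + add
  }
  rec <- rec * pi / n_ang / (pixel_um * 1e-6)
  img <- matrix(rec, W, W)
  if (circle_mask) {
    rr <- sqrt(u^2 + v^2)
    img[matrix(rr > (W - 1) / 2, W, W)] <- 0
  }
  structure(list(values = img, pixel_um = pixel_um,
                 provenance = list(filter = filter, flags = prov)),
            class = "recon_slice")
}

#' Reconstructed volume container
#'
#' @param values 3-D array (x, y, z).
#' @param pixel_um in-plane voxel size (um).
#' @param slice_um axial slice spacing (um).
#' @return object of class `recon_volume`.
#' @export
recon_volume <- function(values, pixel_um, slice_um = pixel_um) {
  if (length(dim(values)) == 2) values <- array(values, c(dim(values), 1))
  stopifnot(length(dim(values)) == 3, pixel_um > 0, slice_um > 0)
  structure(list(values = values, pixel_um = pixel_um, slice_um = slice_um),
            class = "recon_volume")
}

#' Stitch reconstructed slabs vertically
#'
#' Concatenates slabs along the axial direction. The slice overlap between
#' consecutive slabs is either declared or estimated by cross-correlating
#' their axial mean-intensity profiles; overlapping slices are fused with
#' a linear feather.
#'
#' @param slabs list of [recon_volume()] objects with congruent lateral
#'   grids.
#' @param overlaps integer vector of declared overlaps (slices) between
#'   consecutive slabs, or `NULL` to estimate each.
#' @param min_correlation required profile correlation for an estimated
#'   overlap.
#' @return a single stitched [recon_volume()], with attribute `overlaps`.
#' @export
stitch_vertical <- function(slabs, overlaps = NULL, min_correlation = 0.5) {
  stopifnot(length(slabs) >= 1)
  for (s in slabs) stopifnot(inherits(s, "recon_volume"))
  if (length(slabs) == 1) return(slabs[[1]])
  dims <- vapply(slabs, function(s) dim(s$values)[1:2], numeric(2))
  if (any(dims != dims[, 1])) stop("slabs must share the lateral grid")
  used <- integer(0)
  out <- slabs[[1]]
  for (k in 2:length(slabs)) {
    a <- out$values; b <- slabs[[k]]$values
    na <- dim(a)[3]; nb <- dim(b)[3]
    v <- if (!is.null(overlaps)) overlaps[k - 1] else {
      est_overlap(a, b, min_correlation)
    }
    v <- max(0, min(v, min(na, nb)))
    if (v == 0) {
      vals <- array(c(a, b), c(dim(a)[1:2], na + nb))
    } else {
      w <- seq(0, 1, length.out = v + 2)[2:(v + 1)]
      fused <- a[, , na - v + seq_len(v), drop = FALSE]
      for (i in seq_len(v)) {
        fused[, , i] <- (1 - w[i]) * a[, , na - v + i] + w[i] * b[, , i]
      }
      vals <- array(c(a[, , seq_len(na - v)], fused,
                      b[, , v + seq_len(nb - v)]),
                    c(dim(a)[1:2], na + nb - v))
    }
    out <- recon_volume(vals, out$pixel_um, out$slice_um)
    used <- c(used, v)
  }
  attr(out, "overlaps") <- used
  out
}

# estimate slice overlap by correlating axial mean profiles
est_overlap <- function(a, b, min_correlation) {
  pa <- apply(a, 3, mean); pb <- apply(b, 3, mean)
  na <- length(pa); nb <- length(pb)
  vmax <- min(na, nb)
  best_v <- 0; best_c <- -Inf
  if (vmax < 4) stop("stitching error: slabs too thin for blind overlap estimation")
  for (v in 4:vmax) {
    ca <- pa[na - v + seq_len(v)]; cb <- pb[seq_len(v)]
    if (stats::sd(ca) == 0 || stats::sd(cb) == 0) next
    cc <- stats::cor(ca, cb)
    if (!is.finite(cc) || cc < min_correlation) next
    # demand statistical significance, not just a high short-run correlation
    tstat <- if (cc >= 1) Inf else cc * sqrt((v - 2) / (1 - cc^2))
    if (tstat < 4) next
    score <- cc + 0.02 * v / vmax
    if (score > best_c) { best_c <- score; best_v <- v }
  }
  if (best_v == 0) {
    stop("stitching error: no overlap with profile correlation >= ",
         min_correlation, "; declare the overlap explicitly")
  }
  best_v
}
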