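# Coherent-imaging forward model: parallel-beam path integrals on the
# effective-pixel grid, single-FFT Fresnel propagation over the effective
# distance, projected source-spot blur, and a photon-counting detector
# stage with Poisson statistics and panel defects.

#' Beam model
#'
#' Monochromatic beam description: wavelength derived from the photon
#' energy of the geometry, anisotropic source-spot FWHM, and the mean flat
#' counts delivered per pixel per projection.
#'
#' @param geometry a [geometry_spec()].
#' @param source_spot_fwhm_um length-2 vector, horizontal and vertical
#'   source-spot FWHM (um).
#' @param mean_flat_counts mean photon counts per pixel in a flat frame.
#' @return object of class `beam_model`.
#' @export
beam_model <- function(geometry, source_spot_fwhm_um = c(515, 172),
                       mean_flat_counts = 230) {
  stopifnot(inherits(geometry, "geometry_spec"))
  if (any(source_spot_fwhm_um < 0)) stop("spot FWHM must be >= 0")
  if (mean_flat_counts <= 0) stop("mean_flat_counts must be > 0")
  structure(list(wavelength_m = keV_to_wavelength(geometry$energy_keV),
                 source_spot_fwhm_um = source_spot_fwhm_um,
                 mean_flat_counts = mean_flat_counts,
                 geometry = geometry),
            class = "beam_model")
}

# Effective (parallel-beam equivalent) propagation distance for the
# cone-like geometry, by the Fresnel scaling theorem.
effective_distance <- function(geometry) {
  geometry$z_sd * geometry$z_ss / (geometry$z_ss + geometry$z_sd)
}

#' Photon-counting detector model
#'
#' The fine-pixel ("lambda"-like) preset carries a two-panel layout with a
#' central gap, single rows/columns of enlarged pixels at module contact
#' zones, and sparse random dead pixels; the coarse-pixel ("hydra"-like)
#' preset has a 100% filling rate and an empty defect mask. Defect classes:
#' 0 live, 1 dead, 2 panel gap, 3 enlarged module-boundary pixel.
#'
#' @param shape `c(rows, cols)` of the detector.
#' @param pixel_um nominal pixel size (um).
#' @param preset `"lambda"`, `"hydra"` or `"none"`.
#' @param gap_px width of the inter-panel gap in pixels (lambda preset).
#' @param dead_rate fraction of randomly dead pixels (lambda preset).
#' @param seed seed for the dead-pixel draw.
#' @return object of class `detector_model` with `defect_class` (integer
#'   matrix) and `defect_mask` (logical matrix).
#' @export
detector_model <- function(shape, pixel_um = 55,
                           preset = c("lambda", "hydra", "none"),
                           gap_px = 3, dead_rate = 5e-4, seed = 1) {
  preset <- match.arg(preset)
  nr <- shape[1]; nc <- shape[2]
  cls <- matrix(0L, nr, nc)
  if (preset == "lambda") {
    mid <- floor(nc / 2)
    gap_cols <- mid + seq_len(gap_px) - ceiling(gap_px / 2)
    gap_cols <- gap_cols[gap_cols >= 1 & gap_cols <= nc]
    cls[, gap_cols] <- 2L
    # enlarged pixels where detector modules meet (quarter positions)
    bc <- unique(pmax(1, pmin(nc, round(c(0.25, 0.75) * nc))))
    cls[, bc] <- pmax(cls[, bc], 3L)
    if (nr >= 8) {
      br <- unique(pmax(1, pmin(nr, round(0.5 * nr))))
      cls[br, ] <- pmax(cls[br, ], 3L)
    }
    cls <- with_seed(seed, {
      dead <- which(stats::runif(nr * nc) < dead_rate & cls == 0L)
      cls[dead] <- 1L
      cls
    })
  }
  structure(list(shape = c(nr, nc), pixel_um = pixel_um, preset = preset,
                 defect_class = cls, defect_mask = cls > 0L),
            class = "detector_model")
}

#' Parallel-beam path integrals of a phantom
#'
#' Line integrals of the delta and beta maps along rays at the given
#' rotation angle, sampled on the effective-pixel detector grid. The beam
#' divergence (3 mrad at ~23 m) is treated as negligible over the thin
#' vertical field of view, so rays are parallel within each slice.
#'
#' @param phantom a [phantom_volume()].
#' @param angle_deg rotation angle in degrees (counter-clockwise).
#' @param detector_cols number of detector columns (defaults to the
#'   phantom's in-plane width).
#' @param axis_offset_px lateral offset of the projected rotation axis from
#'   the detector center, in pixels; positive values shift the axis so the
#'   detector covers the positive lateral side (off-center scanning).
#' @return list with matrices `delta_path` and `beta_path`
#'   (`nz` rows x `detector_cols` columns), path integrals in meters.
#' @export
project_thickness <- function(phantom, angle_deg, detector_cols = NULL,
                              axis_offset_px = 0) {
  stopifnot(inherits(phantom, "phantom_volume"))
  d <- dim(phantom$delta)
  n <- d[1]; nz <- d[3]
  if (is.null(detector_cols)) detector_cols <- d[2]
  vox_m <- phantom$voxel_size_um * 1e-6
  dp <- matrix(0, nz, detector_cols)
  bp <- matrix(0, nz, detector_cols)
  native_centered <- detector_cols == d[2] && axis_offset_px == 0
  s_det <- (seq_len(detector_cols) - (detector_cols + 1) / 2 + axis_offset_px)
  for (z in seq_len(nz)) {
    rd <- rotate_image(phantom$delta[, , z], -angle_deg)
    rb <- rotate_image(phantom$beta[, , z], -angle_deg)
    pd <- colSums(rd) * vox_m
    pb <- colSums(rb) * vox_m
    if (native_centered) {
      dp[z, ] <- pd
      bp[z, ] <- pb
    } else {
      s0 <- 1 - (d[2] + 1) / 2
      dp[z, ] <- interp_uniform(pd, s0, 1, s_det)
      bp[z, ] <- interp_uniform(pb, s0, 1, s_det)
    }
  }
  list(delta_path = dp, beta_path = bp)
}

#' Fresnel propagation of the exit wave to the detector plane
#'
#' Forms the monochromatic exit wave
#' `exp(-(2*pi/lambda) * beta_path) * exp(-1i * (2*pi/lambda) * delta_path)`
#' and propagates it by a single-FFT Fresnel transfer function
#' `exp(-1i * pi * lambda * z_eff * f^2)` over the effective distance
#' `z_eff = z_sd * z_ss / (z_ss + z_sd)`, on the effective-pixel grid.
#' Fields are edge-padded to powers of two before the transform; the
#' unit-modulus kernel conserves energy over the padded field exactly.
#'
#' @param delta_path,beta_path matrices of path integrals (m), rows are
#'   detector rows; vectors are treated as a single row.
#' @param beam a [beam_model()].
#' @param z_eff_m effective propagation distance (m); defaults to the value
#'   implied by the beam geometry. Zero returns the unpropagated intensity.
#' @return intensity matrix at the detector plane, normalized to unit flat.
#' @export
fresnel_propagate <- function(delta_path, beta_path, beam, z_eff_m = NULL) {
  stopifnot(inherits(beam, "beam_model"))
  if (is.null(dim(delta_path))) delta_path <- matrix(delta_path, nrow = 1)
  if (is.null(dim(beta_path))) beta_path <- matrix(beta_path, nrow = 1)
  stopifnot(identical(dim(delta_path), dim(beta_path)))
  lambda <- beam$wavelength_m
  if (is.null(z_eff_m)) z_eff_m <- effective_distance(beam$geometry)
  k <- 2 * pi / lambda
  amp <- exp(-k * beta_path)
  if (z_eff_m <= 0) return(amp^2)
  px_m <- effective_pixel_size(beam$geometry) * 1e-6
  nr0 <- nrow(delta_path); nc0 <- ncol(delta_path)
  nr <- next_pow2(nr0 + 32); nc <- next_pow2(nc0 + 32)
  # anti-alias bound of the quadratic kernel: z <= N * px^2 / lambda
  z_max <- min(nr, nc) * px_m^2 / lambda
  while (z_eff_m > z_max) {
    warning("Fresnel kernel undersampled; enlarging padded field")
    nr <- nr * 2; nc <- nc * 2
    z_max <- min(nr, nc) * px_m^2 / lambda
  }
  padA <- pad_edge(delta_path, nr, nc)
  padB <- pad_edge(beta_path, nr, nc)
  u <- exp(-k * padB$x) * exp(-1i * k * padA$x)
  fr <- fft_freqs(nr) / px_m
  fc <- fft_freqs(nc) / px_m
  H <- exp(-1i * pi * lambda * z_eff_m * outer(fr^2, rep(1, nc))) *
    exp(-1i * pi * lambda * z_eff_m * outer(rep(1, nr), fc^2))
  U <- fft2(fft2(u) * H, inverse = TRUE) / (nr * nc)
  I <- Mod(U)^2
  I[padA$rows, padA$cols, drop = FALSE]
}

#' Apply projected source-spot blur
#'
#' Convolves the detector-plane intensity with an anisotropic Gaussian
#' whose FWHM per axis equals the source-spot FWHM scaled by
#' `z_sd / z_ss` (the penumbra of an extended incoherent source), the
#' standard partially-coherent approximation applied after propagation.
#' The convolution is flux preserving.
#'
#' @param intensity matrix, rows = vertical axis, columns = horizontal.
#' @param beam a [beam_model()].
#' @return blurred intensity matrix.
#' @export
apply_source_blur <- function(intensity, beam) {
  stopifnot(inherits(beam, "beam_model"))
  g <- beam$geometry
  fwhm_det_um <- beam$source_spot_fwhm_um * g$z_sd / g$z_ss
  px_um <- effective_pixel_size(g)
  sig <- fwhm_to_sigma(fwhm_det_um) / px_um   # c(horizontal, vertical) in px
  if (all(sig <= 0)) return(intensity)
  gaussian_blur_fft(intensity, sigma_r = sig[2], sigma_c = sig[1])
}

#' Photon-counting detector stage
#'
#' Draws Poisson counts with per-pixel mean `intensity * mean_flat_counts`
#' for live pixels, then overwrites defect pixels by class: dead pixels
#' read 0; panel-gap pixels read 0; enlarged module-boundary pixels pool
#' their 3x3 neighborhood (double effective area). Output is integer and
#' deterministic per seed.
#'
#' @param intensity matrix normalized to unit flat.
#' @param detector a [detector_model()] with shape matching `intensity`.
#' @param mean_flat_counts mean counts per pixel at unit intensity (> 0).
#' @param seed integer seed.
#' @return integer matrix of counts.
#' @export
apply_detector <- function(intensity, detector, mean_flat_counts, seed = 1) {
  stopifnot(inherits(detector, "detector_model"))
  if (mean_flat_counts <= 0) {
    stop("configuration error: mean_flat_counts must be > 0")
  }
  if (!identical(dim(intensity), as.integer(detector$shape)) &&
      !identical(dim(intensity), detector$shape)) {
    if (!all(dim(intensity) == detector$shape)) {
      stop("intensity shape does not match detector shape")
    }
  }
  with_seed(seed, {
    mu <- pmax(intensity, 0) * mean_flat_counts
    counts <- matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
    cls <- detector$defect_class
    if (any(cls == 3L)) {
      # pooled neighborhood: enlarged pixels integrate ~2x the area
      pooled <- local_mean3(mu)
      idx <- which(cls == 3L)
      counts[idx] <- stats::rpois(length(idx), 2 * pooled[idx])
    }
    counts[cls == 1L | cls == 2L] <- 0L
    storage.mode(counts) <- "integer"
    counts
  })
}

# 3x3 neighborhood mean with edge replication (degenerates gracefully for
# single-row/column inputs)
local_mean3 <- function(x) {
  n <- nrow(x); m <- ncol(x)
  ri <- seq_len(n); ci <- seq_len(m)
  v <- x[pmax(ri - 1, 1), , drop = FALSE] + x +
    x[pmin(ri + 1, n), , drop = FALSE]
  (v[, pmax(ci - 1, 1), drop = FALSE] + v +
     v[, pmin(ci + 1, m), drop = FALSE]) / 9
}

#' Simulate a tomographic scan
#'
#' Runs the full forward chain (path integrals, Fresnel propagation,
#' source blur, photon-counting detection) for every projection angle and
#' simulates a set of flat frames with matching statistics. Angles are
#' uniform over the protocol's angular range, starting at 0.
#'
#' @param phantom a [phantom_volume()].
#' @param beam a [beam_model()].
#' @param detector a [detector_model()]; rows must equal the phantom's
#'   axial slice count.
#' @param protocol a [scan_protocol()].
#' @param axis_offset_px lateral rotation-axis offset in pixels (off-center
#'   scanning); the phantom must fit the doubled lateral field of view.
#' @param seed integer seed driving all randomness of the stack.
#' @param n_flats number of flat frames.
#' @param propagate,blur,noise logical switches for the Fresnel, source-blur
#'   and Poisson stages (noiseless mode returns expected counts).
#' @return object of class `projection_stack`: `intensities` (n_proj x
#'   rows x cols), `flats`, `angles_deg`, `defect_class`, `axis_offset_px`,
#'   `pixel_um`, plus the input models and seed.
#' @export
simulate_scan <- function(phantom, beam, detector, protocol,
                          axis_offset_px = 0, seed = 1, n_flats = 20,
                          propagate = TRUE, blur = TRUE, noise = TRUE) {
  stopifnot(inherits(phantom, "phantom_volume"),
            inherits(beam, "beam_model"),
            inherits(detector, "detector_model"),
            inherits(protocol, "scan_protocol"))
  d <- dim(phantom$delta)
  nz <- d[3]
  if (detector$shape[1] != nz) {
    stop("detector row count must equal the phantom slice count")
  }
  W <- detector$shape[2]
  # field-of-view check: object radius vs detector coverage about the axis
  occ <- which(phantom$label[, , 1] != 0, arr.ind = TRUE)
  if (nrow(occ) > 0) {
    cx <- (d[1] + 1) / 2
    r_obj <- max(sqrt((occ[, 1] - cx)^2 + (occ[, 2] - cx)^2))
    reach <- (W - 1) / 2 + abs(axis_offset_px)
    if (r_obj > reach + 0.5) {
      stop(sprintf(
        "truncation error: object radius %.1f px exceeds detector reach %.1f px%s",
        r_obj, reach,
        if (axis_offset_px == 0) " (consider off-center scanning)" else ""))
    }
  }
  n_proj <- protocol$n_proj
  angles <- (seq_len(n_proj) - 1) * protocol$angular_range_deg / n_proj
  mfc <- protocol$mean_flat_counts
  proj <- array(0, c(n_proj, nz, W))
  for (i in seq_len(n_proj)) {
    paths <- project_thickness(phantom, angles[i], detector_cols = W,
                               axis_offset_px = axis_offset_px)
    I <- if (propagate) {
      fresnel_propagate(paths$delta_path, paths$beta_path, beam)
    } else {
      exp(-4 * pi / beam$wavelength_m * paths$beta_path)
    }
    if (blur) I <- apply_source_blur(I, beam)
    frame <- if (noise) {
      apply_detector(I, detector, mfc, seed = seed + i)
    } else {
      I * mfc
    }
    proj[i, , ] <- frame
  }
  flats <- array(0, c(n_flats, nz, W))
  ones <- matrix(1, nz, W)
  for (i in seq_len(n_flats)) {
    flats[i, , ] <- if (noise) {
      apply_detector(ones, detector, mfc, seed = seed + n_proj + i)
    } else {
      ones * mfc
    }
  }
  structure(list(intensities = proj, flats = flats, angles_deg = angles,
                 defect_class = detector$defect_class,
                 defect_mask = detector$defect_mask,
                 axis_offset_px = axis_offset_px,
                 pixel_um = effective_pixel_size(beam$geometry),
                 protocol = protocol, beam = beam, detector = detector,
                 seed = seed, normalized = FALSE),
            class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<projection_stack> %d projections of %d x %d px (%.2f um), %s, offset %g px\n",
    d[1], d[2], d[3], x$pixel_um,
    if (x$normalized) "flat-normalized" else "raw counts", x$axis_offset_px))
  invisible(x)
}
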