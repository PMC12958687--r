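#' Imaging geometry specification
#'
#' Describes the synchrotron imaging geometry: a quasi-parallel beam from a
#' distant bending-magnet source, the specimen on a rotation stage, and a
#' photon-counting detector downstream. Distances are in meters, the nominal
#' detector pixel in micrometers; the cone-like divergence demagnifies the
#' detector pixel to an effective pixel at the sample plane.
#'
#' @param z_ss source-to-sample distance (m).
#' @param z_sd sample-to-detector distance (m).
#' @param p_nom nominal detector pixel size (um).
#' @param energy_keV photon energy (keV).
#' @param bandwidth_keV spectral width of the monochromatized beam (keV).
#' @param divergence_mrad beam divergence (mrad).
#' @return object of class `geometry_spec`.
#' @examples
#' g <- geometry_spec(z_ss = 23, z_sd = 10.25, p_nom = 55)
#' effective_pixel_size(g)
#' @export
geometry_spec <- function(z_ss = 23, z_sd = 10.25, p_nom = 55,
                          energy_keV = 40, bandwidth_keV = 0.04,
                          divergence_mrad = 3) {
  if (!is.numeric(z_ss) || z_ss <= 0) stop("invalid geometry: z_ss must be > 0")
  if (!is.numeric(z_sd) || z_sd < 0) stop("invalid geometry: z_sd must be >= 0")
  if (!is.numeric(p_nom) || p_nom <= 0) stop("invalid geometry: p_nom must be > 0")
  if (energy_keV <= 0) stop("invalid geometry: energy_keV must be > 0")
  structure(list(z_ss = z_ss, z_sd = z_sd, p_nom = p_nom,
                 energy_keV = energy_keV, bandwidth_keV = bandwidth_keV,
                 divergence_mrad = divergence_mrad),
            class = "geometry_spec")
}

#' @export
print.geometry_spec <- function(x, ...) {
  cat(sprintf(
    "<geometry_spec> z_ss = %g m, z_sd = %g m, p_nom = %g um, E = %g keV\n",
    x$z_ss, x$z_sd, x$p_nom, x$energy_keV))
  cat(sprintf("  effective pixel: %.2f um, distance ratio z_ss/z_sd: %.4f\n",
              effective_pixel_size(x),
              if (x$z_sd > 0) distance_ratio(x) else NA_real_))
  invisible(x)
}

#' Scan protocol
#'
#' Acquisition parameters of a step-and-shoot tomographic scan.
#'
#' @param n_proj number of projections.
#' @param exposure_ms exposure time per projection (ms).
#' @param angular_range_deg total rotation, 180 or 360 degrees.
#' @param off_center logical; rotation axis laterally offset to double the
#'   lateral field of view (requires 360-degree range).
#' @param vertical_fov_mm vertical beam footprint (mm).
#' @param mean_flat_counts mean photon counts per pixel in a flat field.
#' @param energy_threshold_keV detector counting threshold (keV).
#' @return object of class `scan_protocol`.
#' @export
scan_protocol <- function(n_proj = 3600, exposure_ms = 10,
                          angular_range_deg = 360, off_center = TRUE,
                          vertical_fov_mm = 2.5, mean_flat_counts = 400,
                          energy_threshold_keV = 20) {
  if (n_proj < 1) stop("invalid protocol: n_proj must be >= 1")
  if (exposure_ms <= 0) stop("invalid protocol: exposure_ms must be > 0")
  if (!angular_range_deg %in% c(180, 360)) {
    stop("invalid protocol: angular_range_deg must be 180 or 360")
  }
  if (off_center && angular_range_deg != 360) {
    stop("invalid protocol: off-center scanning requires a 360-degree range")
  }
  structure(list(n_proj = as.integer(n_proj), exposure_ms = exposure_ms,
                 angular_range_deg = angular_range_deg,
                 off_center = isTRUE(off_center),
                 vertical_fov_mm = vertical_fov_mm,
                 mean_flat_counts = mean_flat_counts,
                 energy_threshold_keV = energy_threshold_keV),
            class = "scan_protocol")
}

#' Effective pixel size at the sample plane
#'
#' The detector pixel demagnified to the sample plane by the
#' source-sample-detector geometry: `p_nom * z_ss / (z_ss + z_sd)`.
#' Full precision is returned; round only for display.
#'
#' @param g a [geometry_spec()].
#' @return effective pixel size in micrometers.
#' @export
effective_pixel_size <- function(g) {
  stopifnot(inherits(g, "geometry_spec"))
  g$p_nom * g$z_ss / (g$z_ss + g$z_sd)
}

#' Source-to-sample over sample-to-detector distance ratio
#'
#' Used to project a blur measured at the detector plane back to the source
#' spot: a source extent `s` blurs the detector image by `s * z_sd / z_ss`,
#' so the spot is recovered as blur times this ratio.
#'
#' @param g a [geometry_spec()].
#' @return dimensionless ratio `z_ss / z_sd`.
#' @export
distance_ratio <- function(g) {
  stopifnot(inherits(g, "geometry_spec"))
  if (g$z_sd <= 0) stop("invalid geometry: z_sd must be > 0 for a distance ratio")
  g$z_ss / g$z_sd
}

#' Estimate the source spot from measured edge blur
#'
#' Geometric-optics inversion: an incoherent source of lateral extent `s`
#' projects a penumbra of width `s * z_sd / z_ss` onto the detector, so the
#' spot per axis is the measured blur multiplied by the source-to-sample /
#' sample-to-detector distance ratio. The projected spot at the sample plane
#' is the spot demagnified by `z_sd / (z_ss + z_sd)` (roughly half of the
#' spot for these distances).
#'
#' @param blur_um numeric vector of blur widths at the detector plane (um),
#'   typically `c(horizontal, vertical)`.
#' @param g a [geometry_spec()].
#' @return object of class `source_spot_estimate` with fields
#'   `blur_detector_um`, `ratio_ss_sd`, `spot_um`,
#'   `projected_spot_sample_um`.
#' @examples
#' g <- geometry_spec(z_ss = 23, z_sd = 10.25)
#' source_spot_from_blur(c(230, 77), g)$spot_um
#' @export
source_spot_from_blur <- function(blur_um, g) {
  stopifnot(inherits(g, "geometry_spec"))
  if (any(blur_um < 0)) stop("blur must be >= 0")
  r <- distance_ratio(g)
  spot <- blur_um * r
  structure(list(blur_detector_um = blur_um,
                 ratio_ss_sd = r,
                 spot_um = spot,
                 projected_spot_sample_um = spot * g$z_sd / (g$z_ss + g$z_sd)),
            class = "source_spot_estimate")
}

#' Exposed-tissue dose bookkeeping
#'
#' Pure dose accounting for step-and-shoot scans. In an off-center
#' 360-degree scan most tissue sits inside the beam for only half of the
#' rotation, so the exposed-tissue dose is half the entrance dose; dropping
#' projections scales the dose linearly.
#'
#' @param entrance_mGy entrance dose for the full protocol (mGy).
#' @param protocol a [scan_protocol()].
#' @param projection_fraction fraction of projections retained, in (0, 1].
#' @return object of class `dose_model` with `entrance_mGy`, `tissue_mGy`
#'   and `projection_fraction`.
#' @examples
#' p <- scan_protocol(n_proj = 3600, off_center = TRUE)
#' tissue_dose(23, p)$tissue_mGy          # 11.5
#' tissue_dose(23, p, 0.5)$tissue_mGy     # 5.75
#' @export
tissue_dose <- function(entrance_mGy, protocol, projection_fraction = 1) {
  stopifnot(inherits(protocol, "scan_protocol"))
  if (entrance_mGy < 0) stop("entrance dose must be >= 0")
  if (projection_fraction <= 0 || projection_fraction > 1) {
    stop("projection_fraction must be in (0, 1]")
  }
  geom_factor <- if (protocol$off_center && protocol$angular_range_deg == 360) 0.5 else 1
  tissue <- entrance_mGy * geom_factor * projection_fraction
  structure(list(entrance_mGy = entrance_mGy * projection_fraction,
                 tissue_mGy = tissue,
                 projection_fraction = projection_fraction),
            class = "dose_model")
}

#' Scan time per rotation
#'
#' Step-and-shoot total exposure time: `n_proj * exposure_ms / 1000`.
#' Stage dead time is not modeled.
#'
#' @param protocol a [scan_protocol()].
#' @return scan time in seconds.
#' @export
scan_time <- function(protocol) {
  stopifnot(inherits(protocol, "scan_protocol"))
  protocol$n_proj * protocol$exposure_ms / 1000
}
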