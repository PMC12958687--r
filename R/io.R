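# On-disk formats: multi-frame 32-bit float TIFF stacks with a JSON
# metadata sidecar for projection data and reconstructions; YAML configs.

#' Write a projection stack to disk
#'
#' Projections and flats are stored as multi-frame 32-bit float TIFF
#' files; angles, defect classes, axis offset, protocol and seed go into
#' a JSON sidecar next to them.
#'
#' @param stack a `projection_stack`.
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_projection_stack <- function(stack, path) {
  stopifnot(inherits(stack, "projection_stack"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  # TIFF values live in [0, 1]; counts are stored divided by a recorded
  # scale and restored on read
  scale <- max(stack$intensities, stack$flats, 1)
  n <- dim(stack$intensities)[1]
  frames <- lapply(seq_len(n), function(i) {
    stack$intensities[i, , , drop = FALSE][1, , , drop = TRUE] / scale
  })
  frames <- lapply(frames, function(f) matrix(f, dim(stack$intensities)[2]))
  tiff::writeTIFF(frames, file.path(path, "projections.tif"),
                  bits.per.sample = 32, reduce = FALSE)
  nf <- dim(stack$flats)[1]
  flats <- lapply(seq_len(nf), function(i) {
    matrix(stack$flats[i, , , drop = FALSE][1, , , drop = TRUE] / scale,
           dim(stack$flats)[2])
  })
  tiff::writeTIFF(flats, file.path(path, "flats.tif"),
                  bits.per.sample = 32, reduce = FALSE)
  meta <- list(scale = scale,
               angles_deg = stack$angles_deg,
               defect_class = as.vector(stack$defect_class),
               defect_dim = dim(stack$defect_class),
               axis_offset_px = stack$axis_offset_px,
               pixel_um = stack$pixel_um,
               normalized = isTRUE(stack$normalized),
               seed = stack$seed,
               protocol = unclass(stack$protocol))
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a projection stack written by [write_projection_stack()]
#'
#' @param path directory containing `projections.tif`, `flats.tif` and
#'   `metadata.json`.
#' @return a `projection_stack`.
#' @export
read_projection_stack <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "metadata.json"),
                              simplifyVector = TRUE)
  pr <- tiff::readTIFF(file.path(path, "projections.tif"), all = TRUE)
  fl <- tiff::readTIFF(file.path(path, "flats.tif"), all = TRUE)
  to_arr <- function(lst) {
    d <- dim(lst[[1]])
    out <- array(0, c(length(lst), d))
    for (i in seq_along(lst)) out[i, , ] <- lst[[i]]
    out
  }
  cls <- matrix(as.integer(meta$defect_class), meta$defect_dim[1],
                meta$defect_dim[2])
  prot <- do.call(scan_protocol, meta$protocol[
    intersect(names(meta$protocol), names(formals(scan_protocol)))])
  sc <- meta$scale %||% 1
  structure(list(intensities = to_arr(pr) * sc, flats = to_arr(fl) * sc,
                 angles_deg = meta$angles_deg,
                 defect_class = cls, defect_mask = cls > 0L,
                 axis_offset_px = meta$axis_offset_px,
                 pixel_um = meta$pixel_um, protocol = prot,
                 seed = meta$seed, normalized = isTRUE(meta$normalized)),
            class = "projection_stack")
}

#' Write a reconstructed slice as float TIFF + JSON sidecar
#'
#' @param slice a `recon_slice`.
#' @param file output TIFF path (sidecar gets a `.json` suffix).
#' @return `file`, invisibly.
#' @export
write_recon_slice <- function(slice, file) {
  stopifnot(inherits(slice, "recon_slice"))
  dir.create(dirname(file), recursive = TRUE, showWarnings = FALSE)
  lo <- min(slice$values); hi <- max(slice$values)
  rng <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((slice$values - lo) / rng, file, bits.per.sample = 32,
                  reduce = FALSE)
  jsonlite::write_json(list(pixel_um = slice$pixel_um,
                            window = c(lo, hi),
                            provenance = slice$provenance),
                       paste0(file, ".json"), auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(file)
}

#' Load a detector/acquisition configuration
#'
#' Reads a YAML configuration (see the `lambda.yaml` and `hydra.yaml`
#' presets shipped under `extdata`) and materializes the geometry, scan
#' protocol and beam model.
#'
#' @param preset `"lambda"`, `"hydra"`, or a path to a YAML file.
#' @param alt_setting for the lambda preset: use the second acquisition
#'   setting (3600 projections at doubled exposure).
#' @return list with `name`, `geometry`, `protocol`, `beam`,
#'   `entrance_mGy`, `delta_beta`, `detector_preset` and the raw config.
#' @export
load_config <- function(preset = "lambda", alt_setting = FALSE) {
  file <- if (file.exists(preset)) preset else {
    system.file("extdata", paste0(preset, ".yaml"), package = "pbict",
                mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(file)
  g <- do.call(geometry_spec, cfg$geometry)
  p <- cfg$protocol
  alt <- p$alt_setting
  p$alt_setting <- NULL
  if (alt_setting && !is.null(alt)) p[names(alt)] <- alt
  prot <- do.call(scan_protocol, p)
  beam <- beam_model(g, source_spot_fwhm_um = unlist(cfg$source_spot_fwhm_um),
                     mean_flat_counts = prot$mean_flat_counts)
  list(name = cfg$detector, geometry = g, protocol = prot, beam = beam,
       entrance_mGy = cfg$dose$entrance_mGy,
       delta_beta = cfg$retrieval$delta_beta,
       detector_preset = cfg$detector, raw = cfg)
}
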