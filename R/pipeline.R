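# End-to-end orchestration on synthetic data: simulate a scan, run the
# pre-processing / denoising / retrieval / reconstruction variants the
# dose-parity comparison design requires, measure image quality, and
# generate blinded scoring pairs.

#' Run a full synthetic experiment
#'
#' Simulates an off-center scan of a lung-like phantom with the chosen
#' detector preset, then produces and quantifies the comparison variants:
#' `raw_full` (all projections, no denoising), `raw_half` (every second
#' projection, matching the dose of a half-length scan) and, when
#' `denoise = TRUE`, `denoised_full` (Noise2Noise-denoised full set).
#' Denoising happens in sinogram space before inpainting and phase
#' retrieval; the dose-parity comparison is `denoised_full` against
#' `raw_half`. Every variant is phase-retrieved (TIE-Hom) and
#' reconstructed by FBP, and scored with CNR triplets, edge-FWHM triplets
#' and a radial power spectrum.
#'
#' @param preset `"lambda"`, `"hydra"`, or a config path for
#'   [load_config()].
#' @param seed integer seed controlling phantom, scan noise and training.
#' @param phantom_n in-plane phantom grid (voxels).
#' @param nz axial slices (also detector rows; extra rows feed denoiser
#'   training pairs).
#' @param n_proj projections over 360 degrees (even).
#' @param mean_flat_counts flat counts per pixel (overrides the preset).
#' @param denoise train and apply the sinogram denoiser.
#' @param denoiser_spec a [denoiser_spec()] for the training run.
#' @param out_dir optional directory for artifacts (reconstruction TIFFs,
#'   QA report JSON/CSV, manifest).
#' @return object of class `qa_report`: per-variant CNR/FWHM/spectrum and
#'   dose bookkeeping, plus `recons` (named list of `recon_slice`),
#'   `manifest`.
#' @export
run_experiment <- function(preset = "lambda", seed = 1, phantom_n = 160,
                           nz = 3, n_proj = 360, mean_flat_counts = NULL,
                           denoise = TRUE,
                           denoiser_spec = pbict::denoiser_spec(
                             max_epochs = 8, steps_per_epoch = 15,
                             patience = 2, seed = seed),
                           out_dir = NULL) {
  cfg <- load_config(preset)
  prot0 <- cfg$protocol
  counts <- mean_flat_counts %||% prot0$mean_flat_counts
  protocol <- scan_protocol(n_proj = n_proj, exposure_ms = prot0$exposure_ms,
                            angular_range_deg = 360, off_center = TRUE,
                            vertical_fov_mm = prot0$vertical_fov_mm,
                            mean_flat_counts = counts,
                            energy_threshold_keV = prot0$energy_threshold_keV)
  phantom <- build_lung_phantom(n = phantom_n, nz = nz,
                                voxel_size_um = effective_pixel_size(cfg$geometry),
                                airway_generations = 5, n_lobules = 10,
                                n_dense_lobules = 2, seed = seed)
  W <- 2 * ceiling(0.62 * phantom_n / 2)
  offset <- round(0.18 * phantom_n)
  detector <- detector_model(c(nz, W),
                             pixel_um = cfg$geometry$p_nom,
                             preset = if (cfg$detector_preset == "lambda")
                               "lambda" else "hydra",
                             seed = seed)
  beam <- beam_model(cfg$geometry,
                     source_spot_fwhm_um = cfg$beam$source_spot_fwhm_um,
                     mean_flat_counts = counts)
  stack <- simulate_scan(phantom, beam, detector, protocol,
                         axis_offset_px = offset, seed = seed)
  stack <- flat_field_correct(stack)
  dose_full <- tissue_dose(cfg$entrance_mGy, protocol, 1)
  sinos <- lapply(seq_len(nz), function(r) {
    s <- sinogram_from_stack(stack, r)
    s$dose <- dose_full
    s
  })
  mid <- ceiling(nz / 2)
  rspec <- retrieval_spec_from_geometry(cfg$geometry, cfg$delta_beta)

  finish <- function(s) {
    s <- inpaint_sinogram(s)
    # the axis offset is exact scan metadata here; the overlap consistency
    # check is calibrated for raw photon noise and is skipped
    s <- extend_offcenter(s, axis_offset_px = offset, check = FALSE)
    fbp_reconstruct(phase_retrieve(s, rspec))
  }
  variants <- list()
  variants$raw_full <- list(sino = sinos[[mid]])
  variants$raw_half <- list(sino = subsample_projections(sinos[[mid]], 0.5, "even"))
  model <- NULL
  if (denoise) {
    pairset <- make_pairs(sinos, seed = seed)
    model <- train_denoiser(pairset, denoiser_spec)
    variants$denoised_full <- list(sino = pbict::denoise(sinos[[mid]], model))
  }
  label_slice <- phantom$label[, , mid]
  for (v in names(variants)) {
    rec <- finish(variants[[v]]$sino)
    variants[[v]]$recon <- rec
    variants[[v]]$qa <- qa_measure(rec, label_slice, phantom_n)
    variants[[v]]$dose <- variants[[v]]$sino$dose
  }
  report <- structure(list(
    variants = lapply(variants, function(v) {
      list(cnr = v$qa$cnr, fwhm_px = v$qa$fwhm_px, fwhm_um = v$qa$fwhm_um,
           spectrum = v$qa$spectrum, dose = v$dose,
           pixel_um = v$recon$pixel_um)
    }),
    recons = lapply(variants, function(v) v$recon),
    model = model,
    manifest = list(preset = cfg$name, seed = seed, phantom_n = phantom_n,
                    nz = nz, n_proj = n_proj, mean_flat_counts = counts,
                    axis_offset_px = offset, detector_cols = W,
                    entrance_mGy = cfg$entrance_mGy,
                    tissue_mGy_full = dose_full$tissue_mGy,
                    tissue_mGy_half = dose_full$tissue_mGy / 2,
                    delta_beta = cfg$delta_beta,
                    denoise = denoise,
                    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
    class = "qa_report")
  if (!is.null(out_dir)) write_qa_report(report, out_dir)
  report
}

#' @export
print.qa_report <- function(x, ...) {
  cat("<qa_report>", x$manifest$preset, "preset, seed", x$manifest$seed, "\n")
  for (v in names(x$variants)) {
    q <- x$variants[[v]]
    cat(sprintf("  %-14s CNR %.2f  FWHM %.2f px  tissue dose %.2f mGy\n",
                v, mean(q$cnr), mean(q$fwhm_px), q$dose$tissue_mGy))
  }
  invisible(x)
}

# CNR region triplets, edge-FWHM triplets and a central radial spectrum
# from a reconstructed slice, guided by the phantom label map.
qa_measure <- function(rec, label_slice, phantom_n, patch = 5) {
  img <- rec$values
  W <- nrow(img)
  labs <- phantom_labels()
  n <- nrow(label_slice)
  # map the phantom label map (centered) onto the reconstruction grid
  shift <- round((W + 1) / 2 - (n + 1) / 2)
  lab_rec <- matrix(-1L, W, W)
  src_r <- seq_len(n)[seq_len(n) + shift >= 1 & seq_len(n) + shift <= W]
  lab_rec[src_r + shift, src_r + shift] <- label_slice[src_r, src_r]
  # region pairs: dense ("ground-glass") lobules vs surrounding
  # parenchyma, the two homogeneous tissue classes of the phantom
  pairs <- NULL
  for (p_try in c(patch, 3, 2)) {
    par_mask <- erode(lab_rec == labs[["parenchyma"]], p_try + 2)
    dense_mask <- erode(lab_rec == labs[["dense_lobule"]], p_try + 1)
    if (sum(par_mask) >= 3 && sum(dense_mask) >= 3 &&
        (2 * p_try + 1)^2 >= 25) {
      pairs <- region_triplets(dense_mask, par_mask, patch = p_try)
      break
    }
  }
  if (is.null(pairs)) stop("not enough homogeneous pixels for QA regions")
  cnr3 <- vapply(pairs, function(p) {
    as.numeric(cnr(img, to_mask(p$a, W), to_mask(p$b, W)))
  }, numeric(1))
  fw <- edge_triplets(img, label_slice, shift)
  ctr <- round(W / 2) + (-31:32)
  spec <- radial_power_spectrum(img[ctr, ctr], rec$pixel_um)
  list(cnr = cnr3, fwhm_px = fw, fwhm_um = fw * rec$pixel_um, spectrum = spec)
}

erode <- function(mask, times = 1) {
  n <- nrow(mask); m <- ncol(mask)
  ri <- seq_len(n); ci <- seq_len(m)
  for (i in seq_len(times)) {
    mask <- mask &
      mask[pmax(ri - 1, 1), , drop = FALSE] &
      mask[pmin(ri + 1, n), , drop = FALSE] &
      mask[, pmax(ci - 1, 1), drop = FALSE] &
      mask[, pmin(ci + 1, m), drop = FALSE]
  }
  mask
}

to_mask <- function(ij, W) {
  keep <- ij[, 1] >= 1 & ij[, 1] <= W & ij[, 2] >= 1 & ij[, 2] <= W
  m <- matrix(FALSE, W, W)
  m[ij[keep, , drop = FALSE]] <- TRUE
  m
}

# patch pairs of two homogeneous tissue classes: centers of class A spread
# over its mask, each paired with the *nearest* class-B patch (the CNR
# definition wants adjacent regions, minimizing shading differences);
# masks must already be eroded by at least `patch`
region_triplets <- function(mask_a, mask_b, patch = 5, n_pairs = 3) {
  ija <- which(mask_a, arr.ind = TRUE)
  ijb <- which(mask_b, arr.ind = TRUE)
  if (nrow(ija) < n_pairs || nrow(ijb) < n_pairs) {
    stop("not enough homogeneous pixels for QA regions")
  }
  ord <- order(ija[, 2], ija[, 1])
  ija <- ija[ord, , drop = FALSE]
  ca <- ija[pmax(1, round(seq(0.15, 0.85, length.out = n_pairs) * nrow(ija))), ,
            drop = FALSE]
  dx <- rep(-patch:patch, times = 2 * patch + 1)
  dy <- rep(-patch:patch, each = 2 * patch + 1)
  lapply(seq_len(n_pairs), function(k) {
    d2 <- (ijb[, 1] - ca[k, 1])^2 + (ijb[, 2] - ca[k, 2])^2
    cb <- ijb[which.min(d2), ]
    list(a = cbind(ca[k, 1] + dx, ca[k, 2] + dy),
         b = cbind(cb[1] + dx, cb[2] + dy))
  })
}

# three edge-sharpness measurements from the air-filled lumen of the main
# bronchus to its wall: the bronchus runs straight along the equator row
# (the generator places its first segment there), so profiles taken along
# image rows at several column groups are aligned by construction and the
# strong air -> wall contrast dominates the noise
edge_triplets <- function(img, label_slice, shift, halfw = 9, n = 3) {
  nn <- nrow(label_slice)
  r0 <- 0.035 * nn                      # lumen radius of the first segment
  wall <- max(1.2, 0.45 * r0)
  cx <- round((nn + 1) / 2 + shift)     # bronchus axis row
  root_col <- (nn + 1) / 2 + 0.85 * 0.42 * nn
  groups <- round(root_col - c(0.10, 0.17, 0.24) * nn) + round(shift)
  depth <- round(r0 + wall + 6)
  rows <- cx:(cx - depth)               # lumen center -> wall -> parenchyma
  vapply(groups, function(g0) {
    cols <- (g0 - 5):(g0 + 5)
    cols <- cols[cols >= 1 & cols <= ncol(img)]
    keep <- rows >= 1 & rows <= nrow(img)
    prof <- rowMeans(img[rows[keep], cols, drop = FALSE])
    ef <- try(edge_fwhm(prof), silent = TRUE)
    if (inherits(ef, "try-error")) NA_real_ else ef$fwhm_px
  }, numeric(1))
}

write_qa_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (v in names(report$recons)) {
    write_recon_slice(report$recons[[v]],
                      file.path(out_dir, paste0("recon_", v, ".tif")))
  }
  tab <- do.call(rbind, lapply(names(report$variants), function(v) {
    q <- report$variants[[v]]
    data.frame(variant = v, cnr_mean = mean(q$cnr),
               fwhm_px_mean = mean(q$fwhm_px, na.rm = TRUE),
               tissue_mGy = q$dose$tissue_mGy)
  }))
  utils::write.csv(tab, file.path(out_dir, "qa_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(manifest = report$manifest,
         variants = lapply(report$variants, function(q) {
           list(cnr = q$cnr, fwhm_px = q$fwhm_px,
                dose = unclass(q$dose),
                spectrum_power = q$spectrum$power,
                spectrum_freq_cyc_mm = q$spectrum$freq_cyc_mm)
         })),
    file.path(out_dir, "qa_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Generate blinded scoring pairs
#'
#' Randomly pairs images from named datasets (n pairs), designates one of
#' each pair as reference and the other as comparison, applies an
#' identical circular mask, rescales without interpolation
#' (nearest-neighbor index replication) to a common square matrix, and
#' equalizes brightness/contrast by linear windowing to the 1st-99th
#' percentile bounds. The answer key (which dataset each member came
#' from) is kept separate from the pair images.
#'
#' @param datasets named list of `recon_slice` objects or matrices with a
#'   `pixel_um` attribute.
#' @param n_pairs number of pairs.
#' @param seed integer seed.
#' @param radius_mm circular region radius (mm).
#' @param matrix_px output matrix side.
#' @param allow_self allow pairing a dataset with itself.
#' @return list with `pairs` (each: `reference`, `comparison` matrices,
#'   `pair_id`) and `key` (data.frame pair_id / reference_dataset /
#'   comparison_dataset), the latter not stored inside the pair objects.
#' @export
generate_scoring_pairs <- function(datasets, n_pairs = 50, seed = 1,
                                   radius_mm = 48, matrix_px = 2500,
                                   allow_self = FALSE) {
  stopifnot(length(datasets) >= 2 || (allow_self && length(datasets) >= 1))
  if (is.null(names(datasets)) || any(names(datasets) == "")) {
    stop("datasets must be named")
  }
  get_img <- function(d) if (inherits(d, "recon_slice")) d$values else as.matrix(d)
  get_px <- function(d) {
    if (inherits(d, "recon_slice")) d$pixel_um
    else attr(d, "pixel_um") %||% stop("matrix datasets need a pixel_um attribute")
  }
  extract <- function(d) {
    img <- get_img(d); px <- get_px(d)
    r_px <- radius_mm * 1000 / px
    if (2 * r_px > min(dim(img))) {
      stop(sprintf(
        "region of %.0f mm radius (%.0f px) exceeds a %d x %d source image",
        radius_mm, r_px, nrow(img), ncol(img)))
    }
    cr <- stats::runif(1, 1 + r_px, nrow(img) - r_px)
    cc <- stats::runif(1, 1 + r_px, ncol(img) - r_px)
    side <- floor(2 * r_px)
    rows <- round(cr - r_px) + seq_len(side)
    cols <- round(cc - r_px) + seq_len(side)
    sub <- img[rows, cols]
    # nearest-neighbor (integer replication) rescale, no interpolation
    map <- pmin(pmax(ceiling(seq_len(matrix_px) / matrix_px * side), 1), side)
    out <- sub[map, map]
    # circular mask
    g <- seq_len(matrix_px) - (matrix_px + 1) / 2
    rr2 <- outer(g^2, g^2, "+")
    out[rr2 > (matrix_px / 2)^2] <- 0
    # equalized brightness/contrast: window to 1st-99th percentiles
    qs <- stats::quantile(out[rr2 <= (matrix_px / 2)^2], c(0.01, 0.99))
    if (diff(qs) > 0) out <- pmin(pmax((out - qs[1]) / diff(qs), 0), 1)
    out
  }
  if (n_pairs == 0) {
    return(list(pairs = list(),
                key = data.frame(pair_id = integer(),
                                 reference_dataset = character(),
                                 comparison_dataset = character())))
  }
  with_seed(seed, {
    nm <- names(datasets)
    pairs <- vector("list", n_pairs)
    key <- data.frame(pair_id = seq_len(n_pairs),
                      reference_dataset = character(n_pairs),
                      comparison_dataset = character(n_pairs))
    for (i in seq_len(n_pairs)) {
      ds <- if (allow_self) sample(nm, 2, replace = TRUE) else sample(nm, 2)
      imgs <- lapply(ds, function(d) extract(datasets[[d]]))
      ref_first <- stats::runif(1) < 0.5
      ord <- if (ref_first) 1:2 else 2:1
      pairs[[i]] <- list(pair_id = i, reference = imgs[[ord[1]]],
                         comparison = imgs[[ord[2]]])
      key$reference_dataset[i] <- ds[ord[1]]
      key$comparison_dataset[i] <- ds[ord[2]]
    }
    list(pairs = pairs, key = key)
  })
}
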