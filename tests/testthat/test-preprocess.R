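test_that("flat-field correction normalizes and flags dead flat pixels", {
  ph <- disk_phantom(n = 64, r = 20)
  st <- noiseless_scan(ph, n_proj = 4)
  # projection equal to the flat -> unit image
  st$intensities[1, , ] <- st$flats[1, , ]
  stc <- flat_field_correct(st)
  expect_equal(as.vector(stc$intensities[1, , ]), rep(1, 64), tolerance = 1e-12)
  expect_true(all(is.finite(stc$intensities)))
  # idempotent on normalized data
  expect_identical(flat_field_correct(stc), stc)

  # flat with one zero pixel: added to the defect mask, output finite
  st2 <- noiseless_scan(ph, n_proj = 4)
  st2$flats[, 1, 10] <- 0
  st2c <- flat_field_correct(st2)
  expect_true(st2c$defect_mask[1, 10])
  expect_true(all(is.finite(st2c$intensities)))
  # all-zero flat is fatal
  st3 <- noiseless_scan(ph, n_proj = 4)
  st3$flats[] <- 0
  expect_error(flat_field_correct(st3), "fatal input error")
})

test_that("flat-field correction removes a known vignette", {
  # transparent object so any residual column structure is vignette, not
  # object shadow
  ph <- disk_phantom(n = 96, r = 20, delta = 0)
  g <- lambda_geometry(); beam <- beam_model(g, mean_flat_counts = 400)
  det <- detector_model(c(1, 96), preset = "none")
  prot <- scan_protocol(64, 10, 360, FALSE, mean_flat_counts = 400)
  st <- simulate_scan(ph, beam, det, prot, seed = 2, n_flats = 100)
  vign <- 0.7 + 0.3 * cos(seq(-pi / 3, pi / 3, length.out = 96))
  for (i in 1:64) st$intensities[i, 1, ] <- with_seed(100 + i,
    stats::rpois(96, 400 * vign))
  for (i in 1:100) st$flats[i, 1, ] <- with_seed(300 + i,
    stats::rpois(96, 400 * vign))
  for (i in 1:20) st$flats[i, 1, ] <- with_seed(200 + i,
    stats::rpois(96, 400 * vign))
  stc <- flat_field_correct(st)
  cm <- colMeans(stc$intensities[, 1, ])
  expect_lt(stats::sd(cm) / mean(cm), 0.01)
})

test_that("diffusion inpainting restores smooth structure under the mask", {
  img <- outer(seq_len(40), seq_len(60), function(i, j) 2 + 0.05 * j + 0.01 * i)
  # empty mask: identity
  expect_identical(inpaint_defects(img, matrix(FALSE, 40, 60)), img)
  # 3-px gap across a linear ramp restored within 1%
  mask <- matrix(FALSE, 40, 60); mask[, 30:32] <- TRUE
  filled <- inpaint_defects(img, mask)
  expect_lt(max(abs(filled[, 30:32] - img[, 30:32]) / img[, 30:32]), 0.01)
  # live pixels bit-unchanged
  expect_identical(filled[!mask], img[!mask])
  # idempotent on a fixed mask
  again <- inpaint_defects(filled, mask)
  expect_equal(again, filled, tolerance = 1e-8)
  # wide gap: warning + linear fallback still within 1% on a ramp
  mask2 <- matrix(FALSE, 40, 60); mask2[, 25:40] <- TRUE
  expect_warning(f2 <- inpaint_defects(img, mask2, max_gap = 8), "max_gap")
  expect_lt(max(abs(f2[, 25:40] - img[, 25:40]) / img[, 25:40]), 0.01)
})

test_that("inpainting round-trips simulated detector gaps within the noise", {
  ph <- disk_phantom(n = 96, r = 30)
  g <- lambda_geometry(); beam <- beam_model(g, mean_flat_counts = 400)
  detL <- detector_model(c(1, 96), preset = "lambda", seed = 1)
  det0 <- detector_model(c(1, 96), preset = "none")
  prot <- scan_protocol(32, 10, 360, FALSE, mean_flat_counts = 400)
  stL <- flat_field_correct(simulate_scan(ph, beam, detL, prot, seed = 3))
  st0 <- flat_field_correct(simulate_scan(ph, beam, det0, prot, seed = 3))
  sL <- inpaint_sinogram(sinogram_from_stack(stL, 1))
  s0 <- sinogram_from_stack(st0, 1)
  gap <- sL$defect_cols
  noise_sd <- 1 / sqrt(400)
  med_err <- stats::median(abs(sL$values[, gap] - s0$values[, gap]))
  expect_lt(med_err, 2 * noise_sd)
  expect_true(sL$flags$inpainted)
  # coarse-pixel configuration: nothing to inpaint, data untouched
  sH <- sinogram_from_stack(st0, 1)
  expect_identical(inpaint_sinogram(sH), sH)
})

test_that("rotation-axis offset is estimated to subpixel accuracy", {
  ph <- disk_phantom(n = 160, r = 55, feature = TRUE)
  st <- flat_field_correct(noiseless_scan(ph, n_proj = 180, W = 120, offset = 40))
  est <- estimate_axis_offset(sinogram_from_stack(st, 1))
  expect_equal(as.numeric(est), 40, tolerance = 0.5)
  expect_false(attr(est, "low_confidence"))
  st0 <- flat_field_correct(noiseless_scan(ph, n_proj = 180, W = 160, offset = 0))
  expect_lt(abs(as.numeric(estimate_axis_offset(sinogram_from_stack(st0, 1)))), 0.5)
  # featureless pure-noise sinogram: low-confidence flag
  noise <- with_seed(3, matrix(stats::rpois(120 * 96, 200) / 200, 120, 96))
  sn <- sinogram(noise, (0:119) * 3, pixel_um = 38)
  expect_true(attr(estimate_axis_offset(sn), "low_confidence"))
})

test_that("off-center extension reproduces a directly simulated wide-detector sinogram", {
  ph <- disk_phantom(n = 256, r = 100, feature = TRUE)
  st <- flat_field_correct(noiseless_scan(ph, n_proj = 240, W = 160, offset = 40))
  ext <- extend_offcenter(sinogram_from_stack(st, 1), axis_offset_px = 40)
  expect_true(ext$flags$extended)
  expect_equal(nrow(ext$values), 120)
  # oracle: centered scan with a wide detector over 180 degrees
  sto <- flat_field_correct(noiseless_scan(ph, n_proj = 120, range_deg = 180,
                                           W = ncol(ext$values)))
  oracle <- sinogram_from_stack(sto, 1)
  rms <- sqrt(mean((ext$values - oracle$values)^2)) /
    sqrt(mean(oracle$values^2))
  expect_lt(rms, 0.005)
  # sinogram mass conserved
  expect_equal(sum(ext$values), sum(oracle$values), tolerance = 0.005 * sum(oracle$values))

  # symmetric case: output equals either half up to the blend
  st0 <- flat_field_correct(noiseless_scan(ph, n_proj = 240, W = 220, offset = 0))
  s0 <- sinogram_from_stack(st0, 1)
  e0 <- extend_offcenter(s0, axis_offset_px = 0)
  h1 <- s0$values[1:120, ]
  expect_lt(max(abs(e0$values - h1)) / max(h1), 1e-3)

  # an inconsistent axis offset is rejected
  expect_error(extend_offcenter(sinogram_from_stack(st, 1), axis_offset_px = 25),
               "estimation error")
})

test_that("extended reconstruction recovers features outside the native half-FOV", {
  ph <- disk_phantom(n = 256, r = 100, feature = TRUE)  # hole at (+40, -30)
  st <- flat_field_correct(noiseless_scan(ph, n_proj = 240, W = 160, offset = 40))
  ext <- extend_offcenter(sinogram_from_stack(st, 1), axis_offset_px = 40)
  rec <- fbp_reconstruct(phase_retrieve(ext,
    retrieval_spec(2000, beam_model(lambda_geometry())$wavelength_m, 0, 38)))
  W <- nrow(rec$values)
  c0 <- (W + 1) / 2
  hole <- rec$values[c0 + 40 + (-10:10), c0 - 30 + (-10:10)]
  disk <- rec$values[c0 + (-10:10), c0 + 60 + (-10:10)]
  # the air-filled hole reads far below the surrounding disk material
  expect_lt(mean(hole), 0.3 * mean(disk))
})

test_that("projection subsampling preserves parity structure and rescales dose", {
  vals <- matrix(as.numeric(seq_len(1800 * 8)), 1800, 8)
  sn <- sinogram(vals, (0:1799) * 0.2, pixel_um = 38,
                 dose = tissue_dose(23, scan_protocol(1800, 10, off_center = TRUE)))
  expect_equal(sn$dose$tissue_mGy, 11.5)
  ev <- subsample_projections(sn, 0.5, "even")
  od <- subsample_projections(sn, 0.5, "odd")
  expect_equal(nrow(ev$values), 900)
  expect_equal(ev$angles_deg[1:3], c(0, 0.4, 0.8))
  expect_equal(od$angles_deg[1], 0.2)
  expect_equal(ev$dose$tissue_mGy, 5.75)
  # identity at fraction 1
  expect_identical(subsample_projections(sn, 1), sn)
  # union of the two phases reorders to the original exactly
  merged <- matrix(0, 1800, 8)
  merged[seq(1, 1800, 2), ] <- ev$values
  merged[seq(2, 1800, 2), ] <- od$values
  expect_identical(merged, vals)
  expect_error(subsample_projections(sn, 1 / 7), "parameter error")
})
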