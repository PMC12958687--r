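test_that("path integrals match analytic oracles", {
  # uniform square: shadow equals side length x delta
  n <- 64
  lab <- matrix(0L, n, n); lab[20:43, 20:43] <- 1L
  d <- matrix(0, n, n); d[lab == 1L] <- 1e-7
  ph <- phantom_volume(d, d / 2000, lab, 38)
  p <- project_thickness(ph, 0)$delta_path[1, ]
  expect_equal(p[25:40], rep(24 * 1e-7 * 38e-6, 16), tolerance = 1e-10)

  # empty phantom projects to zero at any angle
  ph0 <- phantom_volume(matrix(0, 48, 48), matrix(0, 48, 48),
                        matrix(0L, 48, 48), 38)
  expect_equal(max(abs(project_thickness(ph0, 37)$delta_path)), 0)

  # disk: chord-length profile 2*sqrt(r^2 - s^2) within 2% in the interior
  ph <- disk_phantom(n = 256, r = 60)
  pt <- project_thickness(ph, 0)$delta_path[1, ]
  s <- seq_len(256) - 128.5
  chord <- ifelse(abs(s) < 60, 2 * sqrt(pmax(60^2 - s^2, 0)), 0) * 1.4e-7 * 38e-6
  interior <- abs(s) < 0.9 * 60
  expect_lt(max(abs(pt[interior] - chord[interior]) / chord[interior]), 0.02)
})

test_that("conjugate projections at theta and theta+180 are mirror images", {
  ph <- disk_phantom(n = 128, r = 40, feature = TRUE)
  for (th in c(0, 37, 121.5)) {
    p0 <- project_thickness(ph, th)$delta_path[1, ]
    p180 <- project_thickness(ph, th + 180)$delta_path[1, ]
    expect_lt(max(abs(rev(p180) - p0)) / max(p0), 1e-6)
  }
})

test_that("Fresnel propagation conserves energy and produces edge fringes", {
  g <- lambda_geometry()
  beam <- beam_model(g)
  # zero-thickness object: flat unit intensity
  I <- fresnel_propagate(rep(0, 200), rep(0, 200), beam)
  expect_equal(as.vector(I), rep(1, 200), tolerance = 1e-9)

  # pure-phase straight edge: overshoot on one side, undershoot on the other
  dp <- c(rep(0, 128), rep(5e-9, 128))
  I <- as.vector(fresnel_propagate(dp, dp * 0, beam))
  expect_gt(max(I), 1.01)
  expect_lt(min(I), 0.99)
  # flux is conserved over the field
  expect_equal(mean(I), 1, tolerance = 1e-6)

  # propagation converges to the unpropagated intensity as z -> 0
  dp2 <- 5e-9 * (1 + sin(seq(0, 6 * pi, length.out = 256))) / 2
  bp2 <- dp2 / 2000
  I0 <- fresnel_propagate(dp2, bp2, beam, z_eff_m = 0)
  sup <- vapply(c(1, 0.1, 0.01), function(z) {
    max(abs(fresnel_propagate(dp2, bp2, beam, z_eff_m = z) - I0))
  }, numeric(1))
  expect_true(all(diff(sup) < 0))
  expect_lt(sup[3], 1e-3)
})

test_that("absorption-only simulation inverts to the attenuation line integrals", {
  ph <- disk_phantom(n = 128, r = 40)
  st <- noiseless_scan(ph, n_proj = 4)
  st <- flat_field_correct(st)
  mu_t_sim <- -log(pmax(st$intensities[1, 1, ], 1e-12))
  paths <- project_thickness(ph, 0)
  lam <- beam_model(lambda_geometry())$wavelength_m
  mu_t_true <- 4 * pi / lam * paths$beta_path[1, ]
  expect_lt(max(abs(mu_t_sim - mu_t_true)) / max(mu_t_true), 1e-6)
})

test_that("source blur has the projected-spot width and is recovered by edge analysis", {
  g <- lambda_geometry()
  beam <- beam_model(g, source_spot_fwhm_um = c(515, 172))
  px <- effective_pixel_size(g)
  # detector-plane FWHM = spot * z_sd / z_ss ~ (230, 77) um ~ (6, 2) px
  fwhm_det <- c(515, 172) * 10.25 / 23
  expect_equal(round(fwhm_det), c(230, 77), tolerance = 0.01)
  expect_equal(round(fwhm_det / px), c(6, 2))

  imgH <- matrix(0, 48, 256); imgH[, 129:256] <- 1
  ebH <- measure_edge_blur(apply_source_blur(imgH, beam), "horizontal", px)
  expect_equal(ebH$fwhm_px, fwhm_det[1] / px, tolerance = 0.10)
  imgV <- matrix(0, 256, 48); imgV[129:256, ] <- 1
  ebV <- measure_edge_blur(apply_source_blur(imgV, beam), "vertical", px)
  expect_equal(ebV$fwhm_px, fwhm_det[2] / px, tolerance = 0.25)
  # zero spot: identity
  beam0 <- beam_model(g, source_spot_fwhm_um = c(0, 0))
  expect_identical(apply_source_blur(imgH, beam0), imgH)
  # flux preserved
  expect_equal(sum(apply_source_blur(imgH, beam)), sum(imgH), tolerance = 1e-9)
})

test_that("photon-counting stage has Poisson statistics and honors defects", {
  det <- detector_model(c(100, 100), preset = "none")
  flat <- matrix(1, 100, 100)
  counts <- apply_detector(flat, det, 400, seed = 4)
  expect_true(is.integer(counts))
  expect_equal(mean(counts), 400, tolerance = 3 * sqrt(400 / 1e4) / 400 * 3)
  # variance ~ mean (relative error < 5% at 1e4 samples)
  expect_equal(stats::var(as.vector(counts)) / mean(counts), 1, tolerance = 0.05)
  # determinism
  expect_identical(counts, apply_detector(flat, det, 400, seed = 4))
  expect_false(identical(counts, apply_detector(flat, det, 400, seed = 5)))
  expect_error(apply_detector(flat, det, 0, seed = 1), "configuration error")

  detL <- detector_model(c(20, 100), preset = "lambda", seed = 2)
  cl <- apply_detector(matrix(1, 20, 100), detL, 400, seed = 1)
  expect_true(all(cl[detL$defect_class %in% c(1L, 2L)] == 0))
  # coarse-pixel preset has a 100% filling rate
  expect_false(any(detector_model(c(20, 100), preset = "hydra")$defect_mask))
})

test_that("simulate_scan produces a complete, deterministic stack and guards the FOV", {
  ph <- disk_phantom(n = 96, r = 30, nz = 2)
  st <- noiseless_scan(ph, n_proj = 8)
  expect_s3_class(st, "projection_stack")
  expect_equal(dim(st$intensities), c(8, 2, 96))
  expect_equal(st$angles_deg, seq(0, 360 - 45, by = 45))
  expect_equal(dim(st$flats)[1], 20)
  # determinism of the noisy path
  g <- lambda_geometry(); beam <- beam_model(g, mean_flat_counts = 300)
  det <- detector_model(c(2, 96), preset = "none")
  prot <- scan_protocol(6, 10, 360, FALSE, mean_flat_counts = 300)
  s1 <- simulate_scan(ph, beam, det, prot, seed = 9)
  s2 <- simulate_scan(ph, beam, det, prot, seed = 9)
  expect_identical(s1$intensities, s2$intensities)
  # object exceeding the FOV triggers a truncation error
  det_small <- detector_model(c(2, 40), preset = "none")
  expect_error(simulate_scan(ph, beam, det_small, prot, seed = 1),
               "truncation error")
})
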