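test_that("TIE-Hom retrieval reduces to pure absorption at zero distance", {
  lam <- 1.23984193e-9 / 40
  mu_t <- 0.3 * (1 + sin(seq(0, 4 * pi, length.out = 200)))
  I <- exp(-mu_t)
  r0 <- phase_retrieve(I, retrieval_spec(2000, lam, 0, 38))
  expect_equal(as.vector(r0), mu_t, tolerance = 1e-12)
  # flat field retrieves to zero
  rs <- retrieval_spec(2000, lam, 7.09, 38)
  expect_equal(max(abs(phase_retrieve(rep(1, 128), rs))), 0, tolerance = 1e-9)
})

test_that("retrieval is linear in the small-contrast signal", {
  g <- lambda_geometry()
  rs <- retrieval_spec_from_geometry(g, 2000)
  base <- 1 + 0.01 * sin(seq(0, 8 * pi, length.out = 256))
  r1 <- phase_retrieve(base, rs)
  r2 <- phase_retrieve(1 + 2 * (base - 1), rs)
  expect_equal(as.vector(r2), as.vector(2 * r1), tolerance = 0.01)
})

test_that("Fresnel-simulated homogeneous cylinder retrieves to its chord profile", {
  g <- lambda_geometry()
  beam <- beam_model(g)
  px_um <- effective_pixel_size(g)
  lam <- beam$wavelength_m
  delta <- 1.4e-7; beta <- delta / 2000
  mu <- 4 * pi * beta / lam
  W <- 512
  s <- (seq_len(W) - (W + 1) / 2) * px_um * 1e-6
  r_m <- 2.5e-3
  chord <- ifelse(abs(s) < r_m, 2 * sqrt(pmax(r_m^2 - s^2, 0)), 0)
  I <- fresnel_propagate(chord * delta, chord * beta, beam)
  ret <- as.vector(phase_retrieve(I, retrieval_spec_from_geometry(g, 2000)))
  truth <- mu * chord
  interior <- abs(s) < 0.8 * r_m
  rms <- sqrt(mean((ret[interior] - truth[interior])^2)) / mean(truth[interior])
  expect_lt(rms, 0.03)
})

test_that("FBP reconstructs an analytic disk to its attenuation value", {
  W <- 256; n_ang <- 360; r <- 60
  s <- seq_len(W) - (W + 1) / 2
  chord <- ifelse(abs(s) < r, 2 * sqrt(pmax(r^2 - s^2, 0)), 0)
  sino <- sinogram(matrix(rep(chord, each = n_ang), n_ang, W),
                   (0:(n_ang - 1)) * 180 / n_ang, pixel_um = 1)
  rec <- fbp_reconstruct(sino)
  expect_s3_class(rec, "recon_slice")
  gg <- seq_len(W) - (W + 1) / 2
  rr <- sqrt(outer(gg^2, gg^2, "+"))
  # pixel_um = 1 -> attenuation 1 per pixel = 1e6 per meter
  expect_equal(mean(rec$values[rr < 0.85 * r]) / 1e6, 1, tolerance = 0.02)
  expect_lt(abs(mean(rec$values[rr > 1.3 * r])) / 1e6, 0.02)
  # zero sinogram reconstructs to zero
  z <- fbp_reconstruct(sinogram(matrix(0, 90, 64), (0:89) * 2, pixel_um = 1))
  expect_equal(max(abs(z$values)), 0)
  # shepp-logan apodization also reconstructs the disk (slightly smoother)
  rec_sl <- fbp_reconstruct(sino, filter = "shepp-logan")
  expect_equal(mean(rec_sl$values[rr < 0.85 * r]) / 1e6, 1, tolerance = 0.02)
  expect_warning(fbp_reconstruct(sinogram(matrix(1, 8, 32), (0:7) * 22.5,
                                          pixel_um = 1)),
                 "undersampling")
})

test_that("FBP error decreases monotonically with the number of angles", {
  W <- 256; r <- 60
  s <- seq_len(W) - (W + 1) / 2
  chord <- ifelse(abs(s) < r, 2 * sqrt(pmax(r^2 - s^2, 0)), 0)
  gg <- seq_len(W) - (W + 1) / 2
  rr <- sqrt(outer(gg^2, gg^2, "+"))
  truth <- 1e6 * (rr < r)
  errs <- vapply(c(45, 90, 180, 360, 720), function(na) {
    sn <- sinogram(matrix(rep(chord, each = na), na, W),
                   (0:(na - 1)) * 180 / na, pixel_um = 1)
    mean(abs(fbp_reconstruct(sn)$values[rr < 1.2 * r] - truth[rr < 1.2 * r]))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("forward-project / reconstruct loop preserves structure", {
  ph <- disk_phantom(n = 160, r = 55, feature = TRUE)
  st <- flat_field_correct(noiseless_scan(ph, n_proj = 360, range_deg = 180))
  sino <- sinogram_from_stack(st, 1)
  rs <- retrieval_spec(2000, beam_model(lambda_geometry())$wavelength_m, 0, 38)
  rec <- fbp_reconstruct(phase_retrieve(sino, rs))
  lam <- beam_model(lambda_geometry())$wavelength_m
  mu <- 4 * pi * (1.4e-7 / 2000) / lam
  # FBP recovers band-limited content: compare against a lightly smoothed
  # ground-truth map, both anchored on a unit background (SSIM's luminance
  # term is unstable around exactly-zero means)
  # 0.6 px Gaussian approximates the interpolating backprojection's PSF
  truth <- pbict:::gaussian_blur_fft((ph$label[, , 1] == 1L) * 1, 0.6, 0.6)
  expect_gt(ssim(rec$values / mu + 1, truth + 1), 0.95)
  # interior material value within 5%
  inside <- ph$label[, , 1] == 1L
  core <- pbict:::erode(inside, 6)
  expect_equal(mean(rec$values[core]) / mu, 1, tolerance = 0.05)
})

test_that("full noiseless chain recovers relative material contrast within 5%", {
  # two-material phantom: parenchyma disk with a dense inclusion
  n <- 160
  gg <- seq_len(n) - (n + 1) / 2
  lab <- matrix(0L, n, n)
  lab[outer(gg^2, gg^2, "+") <= 55^2] <- 1L
  lab[outer((gg + 20)^2, gg^2, "+") <= 15^2] <- 5L
  mats <- phantom_materials()
  d <- matrix(mats$delta[match(lab, mats$label)], n, n)
  b <- matrix(mats$beta[match(lab, mats$label)], n, n)
  ph <- phantom_volume(d, b, lab, 38)
  st <- flat_field_correct(noiseless_scan(ph, n_proj = 360, range_deg = 180))
  rs <- retrieval_spec(2000, beam_model(lambda_geometry())$wavelength_m, 0, 38)
  rec <- fbp_reconstruct(phase_retrieve(sinogram_from_stack(st, 1), rs))
  m_par <- mean(rec$values[pbict:::erode(lab == 1L, 6)])
  m_dense <- mean(rec$values[pbict:::erode(lab == 5L, 4)])
  ratio_true <- mats$beta[mats$name == "dense_lobule"] /
    mats$beta[mats$name == "parenchyma"]
  expect_equal(m_dense / m_par, ratio_true, tolerance = 0.05 * ratio_true)
})

test_that("vertical stitching recovers declared and estimated overlaps", {
  with_seed(8, {
    base <- array(stats::runif(40 * 40 * 30), c(40, 40, 30))
  })
  a <- recon_volume(base[, , 1:20], 38)
  b <- recon_volume(base[, , 11:30], 38)
  # estimated overlap of 10 slices (+- 1)
  out <- stitch_vertical(list(a, b))
  expect_equal(attr(out, "overlaps"), 10, tolerance = 1)
  expect_equal(dim(out$values)[3], 30, tolerance = 1)
  # declared overlap reproduces the original exactly
  out2 <- stitch_vertical(list(a, b), overlaps = 10)
  expect_equal(out2$values, base, tolerance = 1e-12)
  # identical slabs with declared full overlap collapse to one slab
  out3 <- stitch_vertical(list(a, a), overlaps = 20)
  expect_equal(out3$values, a$values, tolerance = 1e-12)
  # zero declared overlap concatenates
  out4 <- stitch_vertical(list(a, b), overlaps = 0)
  expect_equal(dim(out4$values)[3], 40)
  # uncorrelated slabs cannot be stitched blind
  with_seed(9, {
    c2 <- recon_volume(array(stats::runif(40 * 40 * 12), c(40, 40, 12)), 38)
  })
  expect_error(stitch_vertical(list(a, c2)), "stitching error")
})
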