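test_that("CNR matches the closed formula and a brute-force oracle", {
  # closed example: S1=10, S2=6, sd1=sd2=2 -> CNR = 2
  img <- matrix(0, 20, 20)
  r1 <- matrix(FALSE, 20, 20); r1[1:10, 1:10] <- TRUE
  r2 <- matrix(FALSE, 20, 20); r2[11:20, 11:20] <- TRUE
  v <- rep(c(-2, 2), 50)
  img[r1] <- 10 + v
  img[r2] <- 6 + v
  sdv <- stats::sd(10 + v)
  expect_equal(as.numeric(cnr(img, r1, r2)), 4 / sdv, tolerance = 1e-12)

  # identical regions -> 0
  img2 <- matrix(stats::rnorm(400), 20, 20)
  img2[r2] <- img2[r1]
  expect_equal(as.numeric(cnr(img2, r1, r2)), 0, tolerance = 1e-12)

  # brute-force two-pass oracle on random regions to 1e-12
  with_seed(21, {
    for (k in 1:5) {
      im <- matrix(stats::rnorm(900, 5, 2), 30, 30)
      i1 <- sample(900, 60); i2 <- sample(setdiff(1:900, i1), 60)
      m1 <- mean(im[i1]); m2 <- mean(im[i2])
      v1 <- sum((im[i1] - m1)^2) / (length(i1) - 1)
      v2 <- sum((im[i2] - m2)^2) / (length(i2) - 1)
      oracle <- abs(m1 - m2) / sqrt(0.5 * (v1 + v2))
      expect_equal(as.numeric(cnr(im, i1, i2)), oracle, tolerance = 1e-12)
    }
  })

  # doubling both SDs at fixed means halves the CNR
  imgA <- matrix(0, 20, 20); imgA[r1] <- 10 + v; imgA[r2] <- 6 + v
  imgB <- matrix(0, 20, 20); imgB[r1] <- 10 + 2 * v; imgB[r2] <- 6 + 2 * v
  expect_equal(as.numeric(cnr(imgA, r1, r2)),
               2 * as.numeric(cnr(imgB, r1, r2)), tolerance = 1e-12)

  # degenerate cases
  flat <- matrix(5, 20, 20)
  expect_equal(as.numeric(cnr(flat, r1, r2)), 0)
  flat2 <- flat; flat2[r2] <- 7
  expect_true(is.infinite(cnr(flat2, r1, r2)))
  expect_error(cnr(img, r1[1:20, 1:2], r2), "25")
  expect_error(cnr(img, r1, r1), "disjoint")
})

test_that("Gaussian-edge FWHM follows 2*sqrt(2*log(2))*sigma and is translation invariant", {
  tr <- 2 * sqrt(2 * log(2))
  for (s in c(1, 1.5, 2, 3, 4.5, 6)) {
    for (phase in c(0, 0.3)) {
      p <- stats::pnorm((seq(-45, 45) + phase) / s)
      expect_equal(edge_fwhm(p)$fwhm_px, tr * s, tolerance = 0.02)
    }
  }
  # slope of FWHM vs sigma = 2.355 within 2%
  sig <- seq(1, 6, by = 0.5)
  fw <- vapply(sig, function(s) edge_fwhm(stats::pnorm(seq(-45, 45) / s))$fwhm_px,
               numeric(1))
  slope <- stats::coef(stats::lm(fw ~ sig))[2]
  expect_equal(as.numeric(slope), tr, tolerance = 0.02)
  # translation invariance
  p1 <- stats::pnorm((seq(-40, 40) + 0.3) / 2)
  p2 <- stats::pnorm((seq(-40, 40) - 12 + 0.3) / 2)
  expect_equal(edge_fwhm(p1)$fwhm_px, edge_fwhm(p2)$fwhm_px, tolerance = 1e-9)
  # unit conversion at the fine-pixel scale
  e <- edge_fwhm(stats::pnorm(seq(-40, 40) / 2), pixel_um = 38)
  expect_equal(e$fwhm_um, e$fwhm_px * 38)
  expect_equal(e$fwhm_um, tr * 2 * 38, tolerance = 0.02 * tr * 2 * 38)
  # ideal step: degenerate spike convention
  expect_equal(edge_fwhm(c(rep(0, 10), rep(1, 10)))$fwhm_px, 1)
  # failure modes
  expect_error(edge_fwhm(rep(1, 20)), "no-edge")
  expect_error(edge_fwhm(c(1, 2)), "short")
})

test_that("edge blur measurement resolves the anisotropic source blur", {
  g <- lambda_geometry()
  beam <- beam_model(g, source_spot_fwhm_um = c(515, 172))
  px <- effective_pixel_size(g)
  mk_edge <- function(nr, nc, horizontal) {
    if (horizontal) {
      img <- matrix(0, nr, nc); img[, (nc / 2 + 1):nc] <- 1
    } else {
      img <- matrix(0, nc, nr); img[(nc / 2 + 1):nc, ] <- 1
    }
    img
  }
  bH <- measure_edge_blur(apply_source_blur(mk_edge(48, 256, TRUE), beam),
                          "horizontal", px)
  bV <- measure_edge_blur(apply_source_blur(mk_edge(48, 256, FALSE), beam),
                          "vertical", px)
  expect_equal(bH$fwhm_px, 6, tolerance = 0.5 / 6)
  expect_equal(bV$fwhm_px, 2, tolerance = 0.5 / 2)
  # unblurred edge stays at or below one pixel
  b0 <- measure_edge_blur(mk_edge(48, 256, TRUE), "horizontal", px)
  expect_lte(b0$fwhm_px, 1)
  # 10-90% width is also reported
  expect_gt(bH$width_10_90_px, 0)
})

test_that("edge enhancement is measured relative to the flanking baseline", {
  expect_equal(as.numeric(edge_enhancement(rep(1, 50))), 0)
  prof <- c(rep(1, 20), 1.02, 1.05, 1.08, 1.05, 1.02, rep(1, 20))
  expect_equal(as.numeric(edge_enhancement(prof)), 8, tolerance = 1e-9)
  # scale invariance of the percentage
  prof2 <- c(rep(2, 20), 2.02, 2.04, 2.06, 2.04, 2.02, rep(2, 20))
  expect_equal(as.numeric(edge_enhancement(prof2)), 3, tolerance = 1e-9)
  # a peak buried in noise is flagged as absent
  with_seed(4, {
    noisy <- 1 + stats::rnorm(60, 0, 0.05)
  })
  e <- edge_enhancement(noisy)
  expect_true(attr(e, "no_peak") || as.numeric(e) < 20)
})

test_that("simulated fringes show the anisotropic edge-enhancement direction", {
  # phase edge of a polyethylene-like slab: the weaker vertical source
  # blur preserves more of the propagation fringe than the horizontal one
  os <- 8; W <- 256
  gf <- geometry_spec(23, 10.25, 55 / os)   # resolve the sub-pixel fringe
  beam_f <- beam_model(gf, source_spot_fwhm_um = c(515, 172))
  delta_pe <- 1.05e-7
  thick <- c(rep(0, W * os / 2), rep(0.5e-3, W * os / 2))
  I <- fresnel_propagate(thick * delta_pe, thick * 0, beam_f)  # pure phase
  Ih <- as.vector(apply_source_blur(matrix(I, 1, W * os), beam_f))
  Iv <- as.vector(apply_source_blur(matrix(I, W * os, 1), beam_f))
  bin8 <- function(x) colMeans(matrix(x, os, W))
  eh <- as.numeric(edge_enhancement(bin8(Ih)))
  ev <- as.numeric(edge_enhancement(bin8(Iv)))
  expect_gt(ev, eh)  # weaker vertical blur preserves more enhancement
  expect_gt(ev, 0)
})

test_that("radial power spectrum is normalized, localized and invariant", {
  with_seed(5, {
    img <- matrix(stats::rnorm(256^2), 256, 256)
  })
  sp <- radial_power_spectrum(img, pixel_um = 38)
  expect_equal(sum(sp$power), 1, tolerance = 1e-9)
  expect_false(sp$degenerate)

  # invariance to gain and offset (DC removal)
  sp2 <- radial_power_spectrum(3.7 * img + 42, pixel_um = 38)
  expect_equal(sp$power, sp2$power, tolerance = 1e-9)

  # pure sinusoid concentrates its power in one bin
  n <- 128
  f0 <- 10  # cycles over the region
  sine <- matrix(sin(2 * pi * f0 * (seq_len(n) - 1) / n), n, n)
  sps <- radial_power_spectrum(sine, pixel_um = 100)
  peak_bin <- which.max(sps$power)
  expect_gt(sps$power[peak_bin], 0.99)
  f0_mm <- f0 / (n * 0.1)  # cycles per mm at 100 um pixels
  expect_equal(sps$freq_cyc_mm[peak_bin], f0_mm, tolerance = 1 / (n * 0.1))

  # white noise: bin power proportional to the annulus pixel count within
  # 10% (flat-spectrum oracle averaged over seeds)
  pw <- rowMeans(vapply(1:16, function(k) {
    with_seed(100 + k, radial_power_spectrum(
      matrix(stats::rnorm(128^2), 128, 128), pixel_um = 38)$power)
  }, numeric(64)))
  nn <- 128; px_mm <- 38 / 1000
  f <- pbict:::fft_freqs(nn) / px_mm
  fr <- sqrt(outer(f^2, rep(1, nn)) + outer(rep(1, nn), f^2))
  b <- pmin(pmax(ceiling(fr / (1 / (nn * px_mm))), 1), 64)
  cnt <- tabulate(as.vector(b), 64)
  cnt[1] <- cnt[1] - 1                 # DC pixel carries no power
  oracle <- cnt / (nn^2 - 1)
  bins <- 8:45   # bins populated enough for the 10% band at 16 seeds
  expect_lt(max(abs(pw[bins] - oracle[bins]) / oracle[bins]), 0.1)

  # constant region: degenerate flag and zero spectrum
  spc <- radial_power_spectrum(matrix(1, 64, 64), pixel_um = 38)
  expect_true(spc$degenerate)
  expect_equal(sum(spc$power), 0)
  expect_error(radial_power_spectrum(matrix(1, 64, 32), 38), "square")
  expect_error(radial_power_spectrum(matrix(1, 32, 32), 38), "64")
})

test_that("MSCT-resolution simulation degrades sampling with exact box averaging", {
  with_seed(7, {
    vol <- recon_volume(array(stats::runif(100 * 100 * 40), c(100, 100, 40)),
                        pixel_um = 38, slice_um = 38)
  })
  out <- simulate_msct_resolution(vol)
  expect_equal(out$pixel_um, 760)
  expect_equal(out$slice_um, 625)
  expect_equal(dim(out$values)[1:2], c(5, 5))
  expect_equal(dim(out$values)[3], floor(40 / (625 / 38)))
  # volume mean preserved over the covered region
  f <- 760 / 38
  nz <- floor(40 / (625 / 38))
  covered <- vol$values[1:floor(5 * f), 1:floor(5 * f),
                        1:floor(nz * 625 / 38)]
  expect_equal(mean(out$values), mean(covered), tolerance = 0.01)
  # identity when target equals source
  same <- simulate_msct_resolution(vol, target_pixel_mm = 38 / 1000,
                                   target_slice_mm = 38 / 1000)
  expect_equal(same$values, vol$values, tolerance = 1e-12)
  expect_error(simulate_msct_resolution(vol, target_pixel_mm = 0.01),
               "parameter error")
})

test_that("SSIM behaves as a similarity index", {
  with_seed(9, {
    a <- matrix(stats::rnorm(64^2), 64, 64)
  })
  expect_equal(ssim(a, a), 1, tolerance = 1e-9)
  expect_lt(ssim(a, matrix(stats::rnorm(64^2), 64, 64)), 0.2)
})
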