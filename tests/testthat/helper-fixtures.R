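# Programmatic fixtures shared across the test files.

# disk phantom: parenchyma-like material, optional off-center hole feature
disk_phantom <- function(n = 256, r = 100, feature = FALSE, nz = 1,
                         delta = 1.4e-7, voxel_um = 38) {
  g <- seq_len(n) - (n + 1) / 2
  lab <- matrix(0L, n, n)
  lab[outer(g^2, g^2, "+") <= r^2] <- 1L
  if (feature) lab[outer((g - 40)^2, (g + 30)^2, "+") <= 25^2] <- 0L
  d <- matrix(0, n, n); d[lab == 1L] <- delta
  phantom_volume(array(d, c(n, n, nz)), array(d / 2000, c(n, n, nz)),
                 array(lab, c(n, n, nz)), voxel_um)
}

lambda_geometry <- function() geometry_spec(z_ss = 23, z_sd = 10.25, p_nom = 55)

# noiseless absorption-only scan of a phantom
noiseless_scan <- function(phantom, n_proj, range_deg = 360, W = NULL,
                           offset = 0, counts = 400) {
  g <- lambda_geometry()
  beam <- beam_model(g, mean_flat_counts = counts)
  if (is.null(W)) W <- dim(phantom$delta)[2]
  det <- detector_model(c(dim(phantom$delta)[3], W), preset = "none")
  prot <- scan_protocol(n_proj, 10, range_deg, off_center = range_deg == 360 && offset != 0,
                        mean_flat_counts = counts)
  simulate_scan(phantom, beam, det, prot, axis_offset_px = offset, seed = 1,
                propagate = FALSE, blur = FALSE, noise = FALSE)
}

# synthetic smooth "clean" sinograms plus Poisson-noisy realizations
make_sino_set <- function(n_sino = 3, n_ang = 384, W = 176, counts = 200,
                          seed = 5) {
  with_seed(seed, {
    cleans <- lapply(seq_len(n_sino), function(i) {
      a <- matrix(0, n_ang, W)
      th <- (seq_len(n_ang) - 1) * pi / n_ang
      for (k in 1:6) {
        r0 <- stats::runif(1, -W / 4, W / 4)
        phs <- stats::runif(1, 0, pi)
        amp <- stats::runif(1, 0.1, 0.4)
        wd <- stats::runif(1, 8, 30)
        ctr <- r0 * cos(th - phs) + (W + 1) / 2
        a <- a + amp * exp(-outer(ctr, seq_len(W),
                                  function(c, j) (j - c)^2) / (2 * wd^2))
      }
      exp(-a)
    })
    noisy <- lapply(cleans, function(cl) {
      matrix(stats::rpois(length(cl), cl * counts) / counts, n_ang, W)
    })
    list(clean = cleans, noisy = noisy)
  })
}

with_seed <- pbict:::with_seed

fast_denoiser_spec <- function(seed = 1, epochs = 6) {
  denoiser_spec(base_channels = 4, patch_px = 48, batch_size = 2,
                max_epochs = epochs, steps_per_epoch = 10, patience = 2,
                seed = seed)
}
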