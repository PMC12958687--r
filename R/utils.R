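# Internal numerical helpers shared across modules.

# hc / keV -> wavelength in meters
keV_to_wavelength <- function(energy_keV) {
  stopifnot(energy_keV > 0)
  1.23984193e-9 / energy_keV
}

next_pow2 <- function(n) 2^ceiling(log2(max(n, 1)))

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so deterministic generators do not disturb the global stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# FFT frequency axis (cycles per sample), matching fft() ordering.
fft_freqs <- function(n) {
  k <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2):1))
  k / n
}

# 2-D FFT of a matrix (stats::fft handles arrays natively).
fft2 <- function(x, inverse = FALSE) stats::fft(x, inverse = inverse)

# Pad a matrix to (nr, nc) by edge replication, centered; returns padded
# matrix plus the row/col ranges of the original region.
pad_edge <- function(x, nr, nc) {
  r0 <- nrow(x); c0 <- ncol(x)
  stopifnot(nr >= r0, nc >= c0)
  top <- floor((nr - r0) / 2)
  left <- floor((nc - c0) / 2)
  ri <- pmin(pmax(seq_len(nr) - top, 1L), r0)
  ci <- pmin(pmax(seq_len(nc) - left, 1L), c0)
  list(x = x[ri, ci, drop = FALSE],
       rows = top + seq_len(r0), cols = left + seq_len(c0))
}

# Rotate a matrix by `theta_deg` (counter-clockwise) about its center with
# bilinear interpolation; values outside the source are 0.
rotate_image <- function(img, theta_deg) {
  n <- nrow(img); m <- ncol(img)
  th <- theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  cx <- (n + 1) / 2; cy <- (m + 1) / 2
  gx <- rep(seq_len(n) - cx, times = m)
  gy <- rep(seq_len(m) - cy, each = n)
  # inverse map: sample source at R(-theta) * target
  sx <- ct * gx + st * gy + cx
  sy <- -st * gx + ct * gy + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  out <- numeric(n * m)
  ok <- x0 >= 1 & x0 <= n - 1 & y0 >= 1 & y0 <= m - 1
  # include one-sided border cells where the fractional part is exactly 0
  okx1 <- x0 == n & fx == 0; oky1 <- y0 == m & fy == 0
  ok <- ok | (okx1 & y0 >= 1 & y0 <= m - 1) | (oky1 & x0 >= 1 & x0 <= n - 1) |
    (okx1 & oky1)
  x0k <- pmin(x0[ok], n - 1L); y0k <- pmin(y0[ok], m - 1L)
  fxk <- sx[ok] - x0k; fyk <- sy[ok] - y0k
  i00 <- x0k + (y0k - 1) * n
  v <- (1 - fxk) * (1 - fyk) * img[i00] +
    fxk * (1 - fyk) * img[i00 + 1] +
    (1 - fxk) * fyk * img[i00 + n] +
    fxk * fyk * img[i00 + n + 1]
  out[ok] <- v
  matrix(out, n, m)
}

# Linear interpolation of y (sampled at uniform x0 + (0:(n-1))*dx) at xout,
# zero outside the support. Vectorized, no sorting requirements.
interp_uniform <- function(y, x0, dx, xout) {
  n <- length(y)
  idx <- (xout - x0) / dx + 1
  i0 <- floor(idx)
  fr <- idx - i0
  out <- numeric(length(xout))
  ok <- i0 >= 1 & i0 <= n - 1
  out[ok] <- y[i0[ok]] * (1 - fr[ok]) + y[i0[ok] + 1] * fr[ok]
  edge <- i0 == n & fr == 0
  out[edge] <- y[n]
  out
}

# Exact area-weighted (boxcar) 1-D downsample of each column of `x` by a
# possibly non-integer factor f >= 1: output cell k averages input interval
# [(k-1)*f, k*f). Implemented via cumulative sums; used as the anti-alias
# filter for resolution degradation.
box_resample_cols <- function(x, f) {
  stopifnot(f >= 1)
  n <- nrow(x)
  n_out <- floor(n / f)
  stopifnot(n_out >= 1)
  cs <- rbind(0, apply(x, 2, cumsum))
  # fractional cumulative sum at positions p in [0, n]
  frac_cs <- function(p) {
    i0 <- floor(p)
    fr <- p - i0
    base <- cs[i0 + 1, , drop = FALSE]
    nxt <- cs[pmin(i0 + 2, n + 1), , drop = FALSE]
    add <- (nxt - base) * ifelse(i0 >= n, 0, fr)
    base + add
  }
  lo <- (seq_len(n_out) - 1) * f
  hi <- seq_len(n_out) * f
  (frac_cs(hi) - frac_cs(lo)) / f
}

# Gaussian low-pass via FFT, flux preserving; sigma in pixels per axis.
# Edge-replicated padding avoids wrap-around of the circular convolution.
gaussian_blur_fft <- function(img, sigma_r, sigma_c) {
  if (sigma_r <= 0 && sigma_c <= 0) return(img)
  pr <- ceiling(4 * sigma_r); pc <- ceiling(4 * sigma_c)
  padded <- pad_edge(img, nrow(img) + 2 * pr, ncol(img) + 2 * pc)
  out <- gaussian_blur_fft_raw(padded$x, sigma_r, sigma_c)
  out[padded$rows, padded$cols, drop = FALSE]
}

gaussian_blur_fft_raw <- function(img, sigma_r, sigma_c) {
  nr <- nrow(img); nc <- ncol(img)
  fr <- fft_freqs(nr); fc <- fft_freqs(nc)
  # OTF of a Gaussian PSF with sd sigma: exp(-2 pi^2 sigma^2 f^2)
  hr <- exp(-2 * pi^2 * sigma_r^2 * fr^2)
  hc <- exp(-2 * pi^2 * sigma_c^2 * fc^2)
  H <- outer(hr, hc)
  Re(fft2(fft2(img) * H, inverse = TRUE)) / (nr * nc)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
sigma_to_fwhm <- function(sigma) sigma * 2 * sqrt(2 * log(2))
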