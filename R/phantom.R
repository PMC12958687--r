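# Digital lung-like phantom: refractive-index decrement (delta) and
# absorption index (beta) maps plus an integer tissue label map, built from
# geometric primitives (branching airway tree, vessel tree, lobular septa,
# optional dense "ground-glass" lobules with retained air-filled airways).

#' Tissue labels used by the phantom generator
#'
#' @return named integer vector mapping tissue names to label codes.
#' @export
phantom_labels <- function() {
  c(air = 0L, parenchyma = 1L, airway_wall = 2L, vessel = 3L,
    septum = 4L, dense_lobule = 5L)
}

#' Optical constants of the phantom materials at 40 keV
#'
#' Per-material refractive-index decrement `delta` and absorption index
#' `beta`. Values follow soft tissue (approximately water-equivalent,
#' density 1.0) at 40 keV, scaled by representative densities: inflated
#' parenchyma ~0.25 g/cm3, partially collapsed ("ground-glass") lobules
#' ~0.6 g/cm3. A single delta/beta ratio of 2000 is used for every
#' material, consistent with the homogeneous-object assumption of
#' single-distance phase retrieval.
#'
#' @return data.frame with columns `label`, `name`, `delta`, `beta`.
#' @export
phantom_materials <- function() {
  tissue_delta <- 1.4e-7    # water-like soft tissue at 40 keV
  db <- 2000                # single-material delta/beta ratio
  dens <- c(air = 0, parenchyma = 0.25, airway_wall = 1.0, vessel = 1.05,
            septum = 1.0, dense_lobule = 0.6)
  lab <- phantom_labels()
  data.frame(label = unname(lab[names(dens)]), name = names(dens),
             delta = unname(tissue_delta * dens),
             beta = unname(tissue_delta * dens / db))
}

#' Assemble a phantom volume from explicit maps
#'
#' @param delta,beta,label congruent 2-D matrices or 3-D arrays; `delta`
#'   and `beta` must be non-negative and zero wherever `label` is air.
#' @param voxel_size_um isotropic voxel size (um).
#' @param seed optional seed recorded in metadata.
#' @return object of class `phantom_volume`.
#' @export
phantom_volume <- function(delta, beta, label, voxel_size_um, seed = NULL) {
  to3d <- function(x) if (length(dim(x)) == 2) array(x, c(dim(x), 1L)) else x
  delta <- to3d(delta); beta <- to3d(beta); label <- to3d(label)
  if (!identical(dim(delta), dim(beta)) || !identical(dim(delta), dim(label))) {
    stop("delta, beta and label maps must be congruent")
  }
  if (any(delta < 0) || any(beta < 0)) stop("delta and beta must be >= 0")
  air <- label == phantom_labels()[["air"]]
  if (any(delta[air] != 0) || any(beta[air] != 0)) {
    stop("air voxels must have delta = beta = 0")
  }
  structure(list(delta = delta, beta = beta, label = label,
                 voxel_size_um = voxel_size_um, seed = seed),
            class = "phantom_volume")
}

#' @export
print.phantom_volume <- function(x, ...) {
  d <- dim(x$label)
  tab <- table(factor(x$label, levels = phantom_labels(),
                      labels = names(phantom_labels())))
  cat(sprintf("<phantom_volume> %d x %d x %d voxels @ %g um\n",
              d[1], d[2], d[3], x$voxel_size_um))
  print(round(tab / length(x$label), 3))
  invisible(x)
}

# draw a thick segment ("capsule") of radius r onto label matrix L
draw_capsule <- function(L, p0, p1, r, value) {
  n <- nrow(L); m <- ncol(L)
  lo <- pmax(floor(pmin(p0, p1) - r - 1), 1)
  hi <- pmin(ceiling(pmax(p0, p1) + r + 1), c(n, m))
  if (any(lo > hi)) return(L)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]
  gx <- rep(xs, times = length(ys)); gy <- rep(ys, each = length(xs))
  d <- p1 - p0
  len2 <- sum(d^2)
  if (len2 == 0) {
    dist2 <- (gx - p0[1])^2 + (gy - p0[2])^2
  } else {
    t <- pmin(pmax(((gx - p0[1]) * d[1] + (gy - p0[2]) * d[2]) / len2, 0), 1)
    dist2 <- (gx - (p0[1] + t * d[1]))^2 + (gy - (p0[2] + t * d[2]))^2
  }
  sel <- dist2 <= r^2
  L[cbind(gx[sel], gy[sel])] <- value
  L
}

# recursive binary tree of segments; returns list of (p0, p1, r, generation)
grow_tree <- function(root, direction, length0, radius0, generations,
                      length_decay = 0.72, radius_decay = 0.7,
                      branch_angle_deg = 32, jitter_deg = 8) {
  segs <- list()
  recurse <- function(p0, dir_deg, len, r, gen) {
    if (gen > generations) return(invisible(NULL))
    th <- dir_deg * pi / 180
    p1 <- p0 + len * c(cos(th), sin(th))
    segs[[length(segs) + 1L]] <<- list(p0 = p0, p1 = p1, r = r, gen = gen)
    if (gen < generations) {
      for (sgn in c(-1, 1)) {
        ang <- dir_deg + sgn * (branch_angle_deg + stats::runif(1, -jitter_deg, jitter_deg))
        recurse(p1, ang, len * length_decay, r * radius_decay, gen + 1L)
      }
    }
  }
  recurse(root, direction, length0, radius0, 1L)
  segs
}

#' Build a lung-like digital phantom
#'
#' Generates a deterministic (per seed) voxelized phantom emulating an
#' inflated lung slab: low-density parenchyma bounded by an elliptical
#' pleural outline, polygonal secondary lobules separated by thin
#' (1-2 voxel) septa, a branching air-filled airway tree with soft-tissue
#' walls, a vessel tree, and optionally dense "ground-glass" lobules in
#' which parenchyma density is raised while air-filled airway branches are
#' retained. The in-plane structure is extruded along the axial (z)
#' direction, matching the thin vertical field of view of the scans it
#' feeds.
#'
#' @param n in-plane grid side (voxels).
#' @param nz number of axial slices.
#' @param voxel_size_um isotropic voxel size (um); defaults to the 38 um
#'   effective pixel of the fine-pixel detector geometry.
#' @param airway_generations number of airway branching generations
#'   (0 for a uniform parenchyma slab).
#' @param n_lobules number of secondary lobules (0 disables septa).
#' @param n_dense_lobules number of lobules rendered at raised density.
#' @param vessels logical; add a vessel tree.
#' @param seed integer seed; the same seed yields a bit-identical volume.
#' @return a [phantom_volume()].
#' @examples
#' ph <- build_lung_phantom(n = 96, airway_generations = 3, seed = 1)
#' table(ph$label)
#' @export
build_lung_phantom <- function(n = 192, nz = 1, voxel_size_um = 38,
                               airway_generations = 5, n_lobules = 12,
                               n_dense_lobules = 0, vessels = TRUE,
                               seed = 1) {
  if (n < 32) stop("configuration error: grid side must be >= 32 voxels")
  labs <- phantom_labels()
  r_trachea <- n * 0.035
  if (airway_generations > 0 &&
      r_trachea * 0.7^(airway_generations - 1) < 0.6) {
    stop("configuration error: grid too small to host ",
         airway_generations, " airway generations")
  }
  with_seed(seed, {
    cx <- (n + 1) / 2; cy <- (n + 1) / 2
    a <- 0.46 * n; b <- 0.42 * n
    gx <- rep(seq_len(n), times = n); gy <- rep(seq_len(n), each = n)
    inside <- ((gx - cx) / a)^2 + ((gy - cy) / b)^2 <= 1
    L <- matrix(labs[["air"]], n, n)
    L[inside] <- labs[["parenchyma"]]

    lobule_id <- NULL
    if (n_lobules > 0) {
      sx <- stats::runif(n_lobules, cx - 0.9 * a, cx + 0.9 * a)
      sy <- stats::runif(n_lobules, cy - 0.9 * b, cy + 0.9 * b)
      d2 <- matrix(0, n * n, n_lobules)
      for (k in seq_len(n_lobules)) d2[, k] <- (gx - sx[k])^2 + (gy - sy[k])^2
      ord1 <- max.col(-d2)
      d1 <- d2[cbind(seq_len(n * n), ord1)]
      d2k <- d2; d2k[cbind(seq_len(n * n), ord1)] <- Inf
      dsec <- d2k[cbind(seq_len(n * n), max.col(-d2k))]
      septum <- inside & (sqrt(dsec) - sqrt(d1)) < 1.2
      L[septum] <- labs[["septum"]]
      lobule_id <- ord1
      if (n_dense_lobules > 0) {
        dense_cells <- sample.int(n_lobules, min(n_dense_lobules, n_lobules))
        dense <- inside & (lobule_id %in% dense_cells) & !septum
        L[dense] <- labs[["dense_lobule"]]
      }
    }

    if (vessels) {
      vsegs <- grow_tree(root = c(cx, cy - 0.85 * b), direction = 90,
                         length0 = 0.30 * n, radius0 = r_trachea * 0.55,
                         generations = max(airway_generations, 3),
                         branch_angle_deg = 38)
      for (s in vsegs) L <- draw_capsule(L, s$p0, s$p1, s$r, labs[["vessel"]])
    }

    if (airway_generations > 0) {
      asegs <- grow_tree(root = c(cx, cy + 0.85 * b), direction = -90,
                         length0 = 0.32 * n, radius0 = r_trachea,
                         generations = airway_generations)
      for (s in asegs) {
        wall <- max(1.2, 0.45 * s$r)
        L <- draw_capsule(L, s$p0, s$p1, s$r + wall, labs[["airway_wall"]])
      }
      for (s in asegs) L <- draw_capsule(L, s$p0, s$p1, s$r, labs[["air"]])
    }

    # clip vascular / airway trees to the pleural outline
    L[!inside] <- labs[["air"]]

    mat <- phantom_materials()
    delta_lut <- beta_lut <- numeric(max(mat$label) + 1)
    delta_lut[mat$label + 1] <- mat$delta
    beta_lut[mat$label + 1] <- mat$beta
    D <- matrix(delta_lut[L + 1], n, n)
    B <- matrix(beta_lut[L + 1], n, n)
    phantom_volume(array(D, c(n, n, nz)), array(B, c(n, n, nz)),
                   array(L, c(n, n, nz)), voxel_size_um, seed = seed)
  })
}
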