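# Class colors used by the renderer. Each sits unambiguously inside exactly
# one classification rule: droplets are white space (all channels >= 235 and
# >= 190), nuclei purple (R,G <= 150, B <= 200), collagen inside the
# trichrome ranges, background tissue outside all three.
RENDER_COLORS <- list(
  droplet = c(245, 245, 245),
  nucleus = c(110, 90, 160),
  collagen = c(200, 210, 230),
  background = c(180, 140, 130)
)

disk_pixels <- function(cx, cy, r, h, w) {
  rows <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
  grid <- expand.grid(row = rows, col = cols)
  d2 <- (grid$row - cy)^2 + (grid$col - cx)^2
  sel <- grid[d2 <= r^2, ]
  (sel$col - 1L) * h + sel$row     # linear indices, column-major
}

#' Render a synthetic H&E-like adipose section with known truth
#'
#' Lipid droplets are near-white disks, nuclei small purple disks, collagen
#' a set fraction of the remaining tissue pixels, background a neutral
#' tissue tone; every class satisfies exactly its defining color rule and
#' nothing else, so classification ground truth is exact. Droplets are
#' placed by rejection sampling without overlap (hard cap of 10,000
#' attempts; a shortfall is an error reporting the achieved count, never a
#' silent reduction).
#'
#' @param n_droplets Number of lipid droplets.
#' @param radius_meanlog,radius_sdlog Log-normal droplet radius parameters
#'   (pixels; defaults give radii around 65 px, i.e. areas > 10,000 px^2).
#' @param n_nuclei Number of nuclei (radius 8-14 px).
#' @param collagen_fraction_target Target collagen fraction of tissue area.
#' @param width,height Image size in pixels.
#' @param margin Minimum distance of droplet rims from the border (default
#'   25 px, clear of the 20 px exclusion band).
#' @param seed Integer seed.
#' @return A list: `image` (h x w x 3, 0-255), `droplet_labels` and
#'   `nucleus_labels` (label matrices), `truth` (data.frame type, id, cx,
#'   cy, radius in 1-based pixel coordinates), `collagen_pixels` (count),
#'   `seed`.
#' @export
render_adipose_image <- function(n_droplets = 4, radius_meanlog = log(65),
                                 radius_sdlog = 0.08, n_nuclei = 8,
                                 collagen_fraction_target = 0.1,
                                 width = 512, height = 512, margin = 25,
                                 seed = 1L) {
  local_rng(seed)
  h <- as.integer(height); w <- as.integer(width)
  if (collagen_fraction_target < 0 || collagen_fraction_target > 0.9) {
    stop("collagen_fraction_target must be in [0, 0.9]")
  }
  droplet_labels <- matrix(0L, h, w)
  nucleus_labels <- matrix(0L, h, w)
  truth <- list()

  placed <- data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0))
  attempts <- 0L
  i <- 0L
  while (i < n_droplets) {
    if (attempts >= 10000L) {
      stop(sprintf(paste0("could not place %d non-overlapping droplets ",
                          "after 10000 attempts (placed %d); enlarge the ",
                          "image or reduce n_droplets"), n_droplets, i))
    }
    attempts <- attempts + 1L
    r <- stats::rlnorm(1, radius_meanlog, radius_sdlog)
    if (2 * r + 2 * margin >= min(h, w)) next
    cx <- stats::runif(1, r + margin, w - r - margin)
    cy <- stats::runif(1, r + margin, h - r - margin)
    if (nrow(placed) > 0 &&
        any(sqrt((placed$cx - cx)^2 + (placed$cy - cy)^2) < placed$r + r + 2)) {
      next
    }
    i <- i + 1L
    placed <- rbind(placed, data.frame(cx = cx, cy = cy, r = r))
    droplet_labels[disk_pixels(cx, cy, r, h, w)] <- i
    truth[[length(truth) + 1L]] <- data.frame(
      type = "droplet", id = i, cx = cx, cy = cy, radius = r)
  }

  j <- 0L
  attempts <- 0L
  while (j < n_nuclei) {
    if (attempts >= 10000L) {
      stop(sprintf("could not place %d nuclei after 10000 attempts (placed %d)",
                   n_nuclei, j))
    }
    attempts <- attempts + 1L
    r <- stats::runif(1, 8, 14)
    cx <- stats::runif(1, r + 1, w - r - 1)
    cy <- stats::runif(1, r + 1, h - r - 1)
    p <- disk_pixels(cx, cy, r, h, w)
    if (any(droplet_labels[p] != 0) || any(nucleus_labels[p] != 0)) next
    j <- j + 1L
    nucleus_labels[p] <- j
    truth[[length(truth) + 1L]] <- data.frame(
      type = "nucleus", id = j, cx = cx, cy = cy, radius = r)
  }

  free <- which(droplet_labels == 0L & nucleus_labels == 0L)
  n_white <- sum(droplet_labels != 0L)
  tissue <- h * w - n_white
  k <- round(collagen_fraction_target * tissue)
  if (k > length(free)) stop("not enough tissue pixels for the collagen target")
  collagen_idx <- sample(free, k)

  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    plane <- matrix(RENDER_COLORS$background[ch], h, w)
    plane[droplet_labels != 0L] <- RENDER_COLORS$droplet[ch]
    plane[nucleus_labels != 0L] <- RENDER_COLORS$nucleus[ch]
    plane[collagen_idx] <- RENDER_COLORS$collagen[ch]
    img[, , ch] <- plane
  }
  list(image = img, droplet_labels = droplet_labels,
       nucleus_labels = nucleus_labels,
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(type = character(0), id = integer(0), cx = numeric(0),
                    cy = numeric(0), radius = numeric(0)),
       collagen_pixels = k, seed = as.integer(seed))
}

ball_mask <- function(dim3, center, r, axis_scale = c(1, 1, 1)) {
  ix <- seq_len(dim3[1]); iy <- seq_len(dim3[2]); iz <- seq_len(dim3[3])
  dx2 <- ((ix - center[1]) / axis_scale[1])^2
  dy2 <- ((iy - center[2]) / axis_scale[2])^2
  dz2 <- ((iz - center[3]) / axis_scale[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
}

#' Render a labeled 3D volume of mitochondria-like objects
#'
#' Places non-touching balls and rods (prolate ellipsoids elongated 4x along
#' a random axis) in an integer label volume by rejection sampling. Truth
#' records each object's class, center, radius and analytic volume in voxel
#' units.
#'
#' @param n_objects Number of objects.
#' @param shape_mix Named fractions for classes `ball` and `rod`
#'   (default 50/50).
#' @param radius_range Ball radius range in voxels (default 3-6; rods use
#'   the same equatorial radius with a 4x polar axis).
#' @param dim3 Volume dimensions in voxels (x, y, z).
#' @param voxel_dim Voxel size in micrometers (length 3), recorded for
#'   downstream morphometry.
#' @param seed Integer seed.
#' @return A list: `labels` (3D integer array), `voxel_dim`, `truth`
#'   (data.frame label, class, cx, cy, cz, radius, analytic_volume_vox).
#' @export
render_mito_volume <- function(n_objects = 6,
                               shape_mix = c(ball = 0.5, rod = 0.5),
                               radius_range = c(3, 6),
                               dim3 = c(96, 96, 64),
                               voxel_dim = c(0.2, 0.2, 0.3),
                               seed = 1L) {
  local_rng(seed)
  labels <- array(0L, dim = dim3)
  truth <- list()
  if (n_objects > 65535L) stop("label overflow: more than 65535 objects")
  classes <- if (n_objects > 0) {
    sample(names(shape_mix), n_objects, replace = TRUE, prob = shape_mix)
  } else character(0)
  attempts <- 0L
  i <- 0L
  while (i < n_objects) {
    if (attempts >= 10000L) {
      stop(sprintf("could not place %d non-touching objects (placed %d)",
                   n_objects, i))
    }
    attempts <- attempts + 1L
    cls <- classes[i + 1L]
    r <- stats::runif(1, radius_range[1], radius_range[2])
    ax <- if (cls == "rod") sample(3, 1) else 0L
    scale <- c(1, 1, 1)
    if (cls == "rod") scale[ax] <- 4
    half <- r * scale + 2     # 2-voxel clearance enforces non-touching
    if (any(2 * half + 2 >= dim3)) next  # object cannot fit; resample
    center <- vapply(1:3, function(d) {
      stats::runif(1, half[d] + 1, dim3[d] - half[d])
    }, numeric(1))
    m <- ball_mask(dim3, center, r, scale)
    grown <- ball_mask(dim3, center, r + 2, scale)
    if (any(labels[grown] != 0L)) next
    i <- i + 1L
    labels[m] <- i
    truth[[i]] <- data.frame(
      label = i, class = cls, cx = center[1], cy = center[2], cz = center[3],
      radius = r,
      analytic_volume_vox = 4 / 3 * pi * r^3 * prod(scale))
  }
  list(labels = labels, voxel_dim = voxel_dim,
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(label = integer(0), class = character(0), cx = numeric(0),
                    cy = numeric(0), cz = numeric(0), radius = numeric(0),
                    analytic_volume_vox = numeric(0)),
       seed = as.integer(seed))
}
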