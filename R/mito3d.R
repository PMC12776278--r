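# --- isosurface surface area ------------------------------------------------
# Surface area of {field >= 0.5} via marching tetrahedra on the Kuhn
# 6-tetrahedra cube decomposition. The binary object indicator is first
# smoothed with a separable Gaussian so the 0.5 level set tracks the true
# boundary instead of the voxel staircase; vertex coordinates are scaled by
# the voxel dimensions, so anisotropic voxels are handled exactly.

gauss_smooth_3d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  rad <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-rad:rad, sd = sigma)
  k <- k / sum(k)
  conv_axis <- function(a, axis) {
    d <- dim(a)
    out <- array(0, d)
    for (off in -rad:rad) {
      w <- k[off + rad + 1L]
      idx_src <- pmin(pmax(seq_len(d[axis]) + off, 1L), d[axis])  # replicate edges
      out <- out + w * switch(axis,
                              a[idx_src, , , drop = FALSE],
                              a[, idx_src, , drop = FALSE],
                              a[, , idx_src, drop = FALSE])
    }
    out
  }
  conv_axis(conv_axis(conv_axis(x, 1L), 2L), 3L)
}

# Kuhn decomposition: each tet is (corner 0, corner a, corner a|b, corner 7)
# with corners bit-coded (x = 1, y = 2, z = 4).
KUHN_TETS <- rbind(
  c(0L, 1L, 3L, 7L), c(0L, 1L, 5L, 7L), c(0L, 2L, 3L, 7L),
  c(0L, 2L, 6L, 7L), c(0L, 4L, 5L, 7L), c(0L, 4L, 6L, 7L))

CORNER_OFFSET <- t(vapply(0:7, function(b) {
  c(bitwAnd(b, 1L), bitwAnd(b, 2L) %/% 2L, bitwAnd(b, 4L) %/% 4L)
}, numeric(3)))

tri_area <- function(p1, p2, p3) {
  u <- p2 - p1; v <- p3 - p1
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Isosurface area of a 3D binary mask
#'
#' Estimates the boundary surface area of a voxelized object by extracting
#' the 0.5-level isosurface of its Gaussian-smoothed indicator field with
#' marching tetrahedra and summing triangle areas. Voxel dimensions scale
#' the mesh, so anisotropic stacks are measured in physical units.
#'
#' @param mask Logical/0-1 3D array (the object).
#' @param voxel_dim Voxel size in micrometers (length 3).
#' @param sigma Gaussian smoothing sd in voxels (default 1; 0 = none, which
#'   overestimates area through voxel staircasing).
#' @return Surface area in square micrometers.
#' @export
isosurface_area <- function(mask, voxel_dim = c(1, 1, 1), sigma = 1) {
  stopifnot(length(dim(mask)) == 3L)
  pad <- max(2L, ceiling(3 * sigma) + 1L)
  d <- dim(mask) + 2L * pad
  f <- array(0, d)
  f[pad + seq_len(dim(mask)[1]), pad + seq_len(dim(mask)[2]),
    pad + seq_len(dim(mask)[3])] <- as.numeric(mask != 0)
  f <- gauss_smooth_3d(f, sigma)
  iso <- 0.5

  nx <- d[1] - 1L; ny <- d[2] - 1L; nz <- d[3] - 1L
  # field values at the 8 corners of every cube, cubes in linear order
  corner_vals <- matrix(0, nx * ny * nz, 8L)
  base_x <- rep(seq_len(nx), times = ny * nz)
  base_y <- rep(rep(seq_len(ny), each = nx), times = nz)
  base_z <- rep(seq_len(nz), each = nx * ny)
  for (cidx in 1:8) {
    off <- CORNER_OFFSET[cidx, ]
    corner_vals[, cidx] <- f[cbind(base_x + off[1], base_y + off[2],
                                   base_z + off[3])]
  }
  # drop cubes entirely inside or outside
  active <- rowSums(corner_vals >= iso) %in% 1:7
  if (!any(active)) return(0)
  corner_vals <- corner_vals[active, , drop = FALSE]
  cube_origin <- cbind(base_x, base_y, base_z)[active, , drop = FALSE]

  vd <- voxel_dim
  edge_point <- function(vals, orig, c_a, c_b) {
    fa <- vals[, c_a + 1L]; fb <- vals[, c_b + 1L]
    t <- (iso - fa) / (fb - fa)
    pa <- sweep(orig, 2, -CORNER_OFFSET[c_a + 1L, ])  # orig + offset
    pb <- sweep(orig, 2, -CORNER_OFFSET[c_b + 1L, ])
    p <- pa + t * (pb - pa)
    sweep(p, 2, vd, "*")
  }

  total <- 0
  for (ti in seq_len(nrow(KUHN_TETS))) {
    tet <- KUHN_TETS[ti, ]
    tv <- corner_vals[, tet + 1L, drop = FALSE]
    inside <- tv >= iso
    k <- rowSums(inside)
    sel1 <- which(k == 1L | k == 3L)
    if (length(sel1) > 0) {
      # lone vertex (inside if k==1, outside if k==3); triangle on its edges
      lone <- ifelse(k[sel1] == 1L,
                     max.col(inside[sel1, , drop = FALSE], "first"),
                     max.col(!inside[sel1, , drop = FALSE], "first"))
      vals <- corner_vals[sel1, , drop = FALSE]
      orig <- cube_origin[sel1, , drop = FALSE]
      for (lv in 1:4) {
        rows <- lone == lv
        if (!any(rows)) next
        others <- setdiff(1:4, lv)
        p1 <- edge_point(vals[rows, , drop = FALSE], orig[rows, , drop = FALSE],
                         tet[lv], tet[others[1]])
        p2 <- edge_point(vals[rows, , drop = FALSE], orig[rows, , drop = FALSE],
                         tet[lv], tet[others[2]])
        p3 <- edge_point(vals[rows, , drop = FALSE], orig[rows, , drop = FALSE],
                         tet[lv], tet[others[3]])
        total <- total + sum(tri_area(p1, p2, p3))
      }
    }
    sel2 <- which(k == 2L)
    if (length(sel2) > 0) {
      ins <- inside[sel2, , drop = FALSE]
      # 2-in/2-out: quad over the four crossing edges, split in two triangles
      pattern <- ins %*% c(1L, 2L, 4L, 8L)
      for (pat in unique(pattern)) {
        rows <- which(pattern == pat)
        in_v <- which(bitwAnd(pat, c(1L, 2L, 4L, 8L)) > 0)
        out_v <- setdiff(1:4, in_v)
        vals <- corner_vals[sel2[rows], , drop = FALSE]
        orig <- cube_origin[sel2[rows], , drop = FALSE]
        q1 <- edge_point(vals, orig, tet[in_v[1]], tet[out_v[1]])
        q2 <- edge_point(vals, orig, tet[in_v[1]], tet[out_v[2]])
        q3 <- edge_point(vals, orig, tet[in_v[2]], tet[out_v[2]])
        q4 <- edge_point(vals, orig, tet[in_v[2]], tet[out_v[1]])
        total <- total + sum(tri_area(q1, q2, q3)) + sum(tri_area(q1, q3, q4))
      }
    }
  }
  total
}

#' 3D mitochondrial morphometry
#'
#' Per labeled object: volume `V` (voxel count x voxel volume), surface
#' area `A` ([isosurface_area()] on the object's padded bounding box) and
#' sphericity `psi = pi^(1/3) (6 V)^(2/3) / A`, clamped to at most
#' `psi_max` to absorb discretization overshoot. Mitochondrial density is
#' the object count divided by the cytoplasmic volume: the volume of
#' `cytoplasm_mask` when supplied (e.g. cell interior minus perinuclear
#' regions), otherwise the full stack volume.
#'
#' @param labels Integer 3D label array (0 = background).
#' @param voxel_dim Voxel size in micrometers (length 3, positive).
#' @param cytoplasm_mask Optional logical array delimiting the cytoplasmic
#'   compartment used for the density denominator.
#' @param sigma Smoothing for the surface estimate (voxels, default 1).
#' @param psi_max Sphericity clamp (default 1.05).
#' @return A list: `objects` (data.frame label, voxels, volume_um3,
#'   surface_um2, sphericity), `density_per_um3`, `cytoplasm_volume_um3`.
#' @export
mito_morphology <- function(labels, voxel_dim, cytoplasm_mask = NULL,
                            sigma = 1, psi_max = 1.05) {
  stopifnot(length(dim(labels)) == 3L)
  if (length(voxel_dim) != 3L || any(voxel_dim <= 0)) {
    stop("voxel_dim must be three positive micrometers")
  }
  voxvol <- prod(voxel_dim)
  ids <- sort(setdiff(unique(as.vector(labels)), 0))
  rows <- lapply(ids, function(id) {
    m <- labels == id
    idx <- which(m, arr.ind = TRUE)
    lo <- pmax(apply(idx, 2, min) - 1L, 1L)
    hi <- pmin(apply(idx, 2, max) + 1L, dim(labels))
    sub <- m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    v <- nrow(idx) * voxvol
    a <- isosurface_area(sub, voxel_dim, sigma = sigma)
    psi <- min(pi^(1 / 3) * (6 * v)^(2 / 3) / a, psi_max)
    data.frame(label = id, voxels = nrow(idx), volume_um3 = v,
               surface_um2 = a, sphericity = psi)
  })
  objects <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), voxels = integer(0),
               volume_um3 = numeric(0), surface_um2 = numeric(0),
               sphericity = numeric(0))
  cyto <- if (is.null(cytoplasm_mask)) {
    prod(dim(labels)) * voxvol
  } else {
    sum(cytoplasm_mask != 0) * voxvol
  }
  if (cyto <= 0) stop("cytoplasmic volume is zero")
  list(objects = objects, density_per_um3 = nrow(objects) / cyto,
       cytoplasm_volume_um3 = cyto)
}
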