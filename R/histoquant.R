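#' Build an object table from a label matrix
#'
#' Converts a segmentation label matrix (0 = background) plus the RGB image
#' into per-object measurements: area (pixel count), mean RGB, bounding box
#' and border flag. Pixel coordinates are 0-based row/column indices; an
#' object touches the border iff any of its pixels has row or column index
#' < `border_px` or >= dimension - `border_px`.
#'
#' @param labels Integer matrix of object labels (0 = background).
#' @param image `h x w x 3` array of 8-bit RGB values (0-255).
#' @param border_px Border exclusion band width in pixels (default 20).
#' @return A list: `table` (data.frame id, area, mean_r, mean_g, mean_b,
#'   border, bbox columns) and `pixels` (list of linear pixel indices per
#'   object, aligned with `table` rows).
#' @export
objects_from_labels <- function(labels, image, border_px = 20) {
  check_rgb_image(image)
  if (!all(dim(labels) == dim(image)[1:2])) {
    stop("label matrix and image dimensions differ")
  }
  h <- nrow(labels); w <- ncol(labels)
  ids <- sort(setdiff(unique(as.vector(labels)), 0))
  pix <- split(which(labels != 0), labels[labels != 0])
  pix <- pix[as.character(ids)]
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  tab <- do.call(rbind, lapply(seq_along(ids), function(i) {
    p <- pix[[i]]
    rows <- ((p - 1) %% h)       # 0-based
    cols <- ((p - 1) %/% h)
    data.frame(id = ids[i], area = length(p),
               mean_r = mean(r[p]), mean_g = mean(g[p]), mean_b = mean(b[p]),
               border = any(rows < border_px | rows >= h - border_px |
                              cols < border_px | cols >= w - border_px),
               row_min = min(rows), row_max = max(rows),
               col_min = min(cols), col_max = max(cols))
  }))
  if (is.null(tab)) {
    tab <- data.frame(id = integer(0), area = integer(0), mean_r = numeric(0),
                      mean_g = numeric(0), mean_b = numeric(0),
                      border = logical(0), row_min = integer(0),
                      row_max = integer(0), col_min = integer(0),
                      col_max = integer(0))
  }
  rownames(tab) <- NULL
  list(table = tab, pixels = unname(pix), dim = c(h, w))
}

#' Classify lipid droplets among segmented objects
#'
#' Keeps objects whose mean RGB is at least `rgb_min` on all three channels,
#' whose area strictly exceeds `min_area` pixels, and which do not touch the
#' image border within `border_px` pixels. Among surviving objects whose
#' pixel sets overlap, only the largest is retained (processed in descending
#' area with the object ID as deterministic tie-break).
#'
#' @param objects Result of [objects_from_labels()] (or the same structure
#'   built from external masks, e.g. [read_masks_json()]).
#' @param rgb_min Per-channel mean-RGB threshold (default 190).
#' @param min_area Area threshold in pixels, strict (default 10000).
#' @param border_px Border band width (default 20; the border flag in
#'   `objects` must have been computed with the same band).
#' @return The droplet subset of the object table (same columns).
#' @export
classify_droplets <- function(objects, rgb_min = 190, min_area = 10000,
                              border_px = 20) {
  tab <- objects$table
  keep <- tab$mean_r >= rgb_min & tab$mean_g >= rgb_min &
    tab$mean_b >= rgb_min & tab$area > min_area & !tab$border
  tab <- tab[keep, , drop = FALSE]
  pix <- objects$pixels[keep]
  if (nrow(tab) == 0L) return(tab)
  ord <- order(-tab$area, tab$id)
  claimed <- integer(0)
  retain <- logical(nrow(tab))
  for (i in ord) {
    if (!any(pix[[i]] %in% claimed)) {
      retain[i] <- TRUE
      claimed <- c(claimed, pix[[i]])
    }
  }
  out <- tab[retain, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify cell nuclei among segmented objects
#'
#' Keeps objects with the characteristic purple stain (mean R <= `max_r`,
#' G <= `max_g`, B <= `max_b`) and area strictly below `max_area` pixels.
#'
#' @param objects Result of [objects_from_labels()].
#' @param max_r,max_g,max_b Per-channel mean-RGB ceilings (150, 150, 200).
#' @param max_area Area ceiling in pixels, strict (default 5000).
#' @return The nucleus subset of the object table.
#' @export
classify_nuclei <- function(objects, max_r = 150, max_g = 150, max_b = 200,
                            max_area = 5000) {
  tab <- objects$table
  keep <- tab$mean_r <= max_r & tab$mean_g <= max_g & tab$mean_b <= max_b &
    tab$area < max_area
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Log-scale droplet size summary
#'
#' Natural-log droplet areas summarized as mean and standard deviation (the
#' population heterogeneity score) with their standard errors
#' (`sem = sd/sqrt(n)` for the mean; `sqrt(sd^2 / (2(n-1)))` for the sd).
#' When more than `subsample_max` droplets are supplied, a seeded random
#' subsample of that size is taken first, mirroring per-sample sampling of
#' 50-200 adipocytes.
#'
#' @param areas Droplet areas in pixels (> 0).
#' @param subsample_max Maximum droplets used (default 200).
#' @param seed Seed for the subsample (default 1).
#' @return data.frame with n, mean_log, sd_log, sem_mean, sem_sd.
#' @export
droplet_summary <- function(areas, subsample_max = 200, seed = 1L) {
  if (any(areas <= 0)) stop("droplet areas must be positive")
  if (length(areas) > subsample_max) {
    local_rng(seed)
    areas <- sample(areas, subsample_max)
  }
  n <- length(areas)
  if (n < 2L) stop("need at least 2 droplets for a size summary")
  la <- log(areas)
  s <- stats::sd(la)
  data.frame(n = n, mean_log = mean(la), sd_log = s,
             sem_mean = s / sqrt(n), sem_sd = sqrt(s^2 / (2 * (n - 1))))
}

#' Collagen-positive fraction of tissue area
#'
#' Pixels are collagen-positive iff R in \[170,220\], G in \[190,240\] and
#' B in \[210,255\] (inclusive); white space (adipocyte lipid droplets) is
#' excluded from the tissue area as pixels with all channels >=
#' `white_threshold`. The fraction is collagen / (total - white).
#'
#' @param image `h x w x 3` 8-bit RGB array.
#' @param r_range,g_range,b_range Inclusive channel ranges for collagen.
#' @param white_threshold Min-channel threshold defining white space
#'   (default 235).
#' @return Collagen fraction in \[0, 1\].
#' @export
collagen_fraction <- function(image, r_range = c(170, 220),
                              g_range = c(190, 240), b_range = c(210, 255),
                              white_threshold = 235) {
  check_rgb_image(image)
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  collagen <- r >= r_range[1] & r <= r_range[2] &
    g >= g_range[1] & g <= g_range[2] &
    b >= b_range[1] & b <= b_range[2]
  white <- r >= white_threshold & g >= white_threshold & b >= white_threshold
  tissue <- length(r) - sum(white)
  if (tissue == 0L) stop("zero tissue area: the whole image is white space")
  sum(collagen & !white) / tissue
}

#' Classical droplet segmentation backend
#'
#' Reference segmentation for rendered or well-contrasted sections:
#' brightness threshold (all channels >= `rgb_min`), hole filling,
#' watershed splitting on the distance transform, connected labeling.
#' Emits the same object structure as [objects_from_labels()], ready for
#' [classify_droplets()]. External segmentation masks (e.g. from a neural
#' segmenter) can be supplied instead via label TIFFs or run-length JSON.
#'
#' @param image `h x w x 3` 8-bit RGB array.
#' @param rgb_min Brightness threshold (default 190).
#' @param watershed_tolerance Minimum depth between distance-transform
#'   maxima for a split (default 2 px).
#' @param border_px Border band for the object border flag (default 20).
#' @return As [objects_from_labels()].
#' @export
segment_droplets_classical <- function(image, rgb_min = 190,
                                       watershed_tolerance = 2,
                                       border_px = 20) {
  check_rgb_image(image)
  bright <- image[, , 1] >= rgb_min & image[, , 2] >= rgb_min &
    image[, , 3] >= rgb_min
  if (!any(bright)) {
    return(objects_from_labels(matrix(0L, nrow(bright), ncol(bright)),
                               image, border_px))
  }
  mask <- EBImage::fillHull(matrix(as.numeric(bright), nrow(bright)))
  dm <- EBImage::distmap(mask)
  labels <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  objects_from_labels(matrix(as.integer(labels), nrow(bright)), image,
                      border_px)
}

#' Total imaged depth of a confocal stack
#'
#' `depth = n_slices * step`.
#'
#' @param n_slices Number of optical slices (>= 1).
#' @param step Z-step size in micrometers (> 0).
#' @return Depth in micrometers.
#' @export
stack_depth <- function(n_slices, step) {
  if (n_slices < 1) stop("need at least one slice")
  if (step <= 0) stop("step size must be positive")
  n_slices * step
}

check_rgb_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("image must be an h x w x 3 array")
  }
  if (max(image) <= 1 && min(image) >= 0 && !all(image %in% c(0, 1))) {
    stop("image appears to be on a [0,1] scale; rescale to 8-bit 0-255 first")
  }
  if (any(image < 0 | image > 255)) stop("8-bit RGB values must lie in [0, 255]")
  invisible(TRUE)
}
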