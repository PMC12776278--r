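#' Read an omics matrix from TSV/CSV
#'
#' Features in column 1 (header name free), sample IDs in the header row.
#' Modality constraints are validated: `counts` must be non-negative numbers,
#' `beta` must lie in \[0,1\].
#'
#' @param path TSV (default) or CSV file.
#' @param modality `"counts"`, `"beta"` or `"numeric"` (no constraint).
#' @param sep Field separator; inferred from the extension by default.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_omics_matrix <- function(path, modality = c("counts", "beta", "numeric"),
                              sep = NULL) {
  modality <- match.arg(modality)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = NA)
  features <- as.character(tab[[1]])
  dup <- features[duplicated(features)]
  if (length(dup) > 0L) {
    stop("duplicate feature IDs: ", paste(unique(dup), collapse = ", "))
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) &
                   !is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at feature '%s', sample '%s'",
                 features[bad[1]], colnames(m)[bad[2]]))
  }
  rownames(m) <- features
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at feature '%s', sample '%s'",
                 features[bad[1]], colnames(m)[bad[2]]))
  }
  if (modality == "counts" && any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at feature '%s', sample '%s'",
                 features[bad[1]], colnames(m)[bad[2]]))
  }
  if (modality == "beta" && any(m < 0 | m > 1)) {
    bad <- which(m < 0 | m > 1, arr.ind = TRUE)[1, ]
    stop(sprintf("beta value outside [0,1] at feature '%s', sample '%s'",
                 features[bad[1]], colnames(m)[bad[2]]))
  }
  m
}

#' Write an omics matrix to TSV/CSV
#'
#' Writers emit the dialect [read_omics_matrix()] reads, so write-then-read
#' round-trips losslessly.
#'
#' @param m Numeric matrix with feature rownames and sample colnames.
#' @param path Destination (`.tsv` or `.csv`).
#' @param feature_column Header name of the feature column (default
#'   "feature").
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(m, path, feature_column = "feature") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- feature_column
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an 8-bit RGB image as PNG
#' @param image `h x w x 3` array on the 0-255 scale.
#' @param path PNG path.
#' @return `path` (write) or the image array on 0-255 (read).
#' @export
write_rgb_png <- function(image, path) {
  check_rgb_image(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname write_rgb_png
#' @export
read_rgb_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  round(img[, , 1:3, drop = FALSE] * 255)
}

#' Write / read a 16-bit label volume as multi-page TIFF
#'
#' Labels (0-65535) round-trip losslessly.
#'
#' @param labels 3D integer array (x, y, z); z becomes the page axis.
#' @param path TIFF path.
#' @return `path` (write) or the label array (read).
#' @export
write_label_volume <- function(labels, path) {
  stopifnot(length(dim(labels)) == 3L)
  if (max(labels) > 65535L || min(labels) < 0L) {
    stop("labels must fit 16-bit unsigned range")
  }
  pages <- lapply(seq_len(dim(labels)[3]), function(z) labels[, , z] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0L, c(dim(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) arr[, , z] <- as.integer(round(pages[[z]] * 65535))
  arr
}

#' Read external segmentation masks from run-length JSON
#'
#' Format: a JSON array of objects `{"id": int, "runs": [[row, col_start,
#' col_end], ...]}` with 0-based inclusive coordinates, plus top-level
#' `"height"`/`"width"`. Returns the same structure as
#' [objects_from_labels()], measured against the supplied image. Unlike a
#' label matrix, run-length masks may overlap; overlap resolution is left
#' to [classify_droplets()].
#'
#' @param path JSON file.
#' @param image `h x w x 3` RGB array the masks refer to.
#' @param border_px Border band width (default 20).
#' @return As [objects_from_labels()].
#' @export
read_masks_json <- function(path, image, border_px = 20) {
  check_rgb_image(image)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  h <- obj$height; w <- obj$width
  if (!all(dim(image)[1:2] == c(h, w))) stop("mask/image dimensions differ")
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  pix <- list(); rows_l <- list()
  for (mk in obj$masks) {
    p <- unlist(lapply(mk$runs, function(run) {
      row <- run[[1]]; c0 <- run[[2]]; c1 <- run[[3]]
      if (row < 0 || row >= h || c0 < 0 || c1 >= w || c1 < c0) {
        stop("mask ", mk$id, " references out-of-image pixels")
      }
      (c0:c1) * h + row + 1L     # 0-based rc to 1-based linear (col-major)
    }))
    rows0 <- (p - 1) %% h
    cols0 <- (p - 1) %/% h
    pix[[length(pix) + 1L]] <- as.integer(p)
    rows_l[[length(rows_l) + 1L]] <- data.frame(
      id = mk$id, area = length(p),
      mean_r = mean(r[p]), mean_g = mean(g[p]), mean_b = mean(b[p]),
      border = any(rows0 < border_px | rows0 >= h - border_px |
                     cols0 < border_px | cols0 >= w - border_px),
      row_min = min(rows0), row_max = max(rows0),
      col_min = min(cols0), col_max = max(cols0))
  }
  tab <- if (length(rows_l)) do.call(rbind, rows_l) else
    data.frame(id = integer(0), area = integer(0), mean_r = numeric(0),
               mean_g = numeric(0), mean_b = numeric(0), border = logical(0),
               row_min = integer(0), row_max = integer(0),
               col_min = integer(0), col_max = integer(0))
  list(table = tab, pixels = pix, dim = c(h, w))
}

#' Write an object/result table as TSV
#' @param tab data.frame.
#' @param path Destination.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
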