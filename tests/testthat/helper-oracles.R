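# Independent reference implementations used as oracles. These deliberately
# use naive element-wise loops and textbook formulas, never the package's
# vectorized code paths.

# BH step-up, straight from the definition
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- val
    prev <- val
  }
  adj
}

# per-object droplet/nucleus classification by explicit per-pixel loops
brute_force_object_stats <- function(pixels, image, border_px = 20) {
  h <- dim(image)[1]; w <- dim(image)[2]
  sr <- sg <- sb <- 0
  border <- FALSE
  for (p in pixels) {
    row0 <- (p - 1) %% h
    col0 <- (p - 1) %/% h
    sr <- sr + image[row0 + 1, col0 + 1, 1]
    sg <- sg + image[row0 + 1, col0 + 1, 2]
    sb <- sb + image[row0 + 1, col0 + 1, 3]
    if (row0 < border_px || row0 >= h - border_px ||
        col0 < border_px || col0 >= w - border_px) border <- TRUE
  }
  n <- length(pixels)
  list(area = n, mean_r = sr / n, mean_g = sg / n, mean_b = sb / n,
       border = border)
}

brute_force_droplet_ids <- function(objects, image, rgb_min = 190,
                                    min_area = 10000, border_px = 20) {
  kept <- list()
  for (i in seq_len(nrow(objects$table))) {
    st <- brute_force_object_stats(objects$pixels[[i]], image, border_px)
    if (st$mean_r >= rgb_min && st$mean_g >= rgb_min && st$mean_b >= rgb_min &&
        st$area > min_area && !st$border) {
      kept[[length(kept) + 1L]] <- list(id = objects$table$id[i],
                                        area = st$area,
                                        pixels = objects$pixels[[i]])
    }
  }
  if (length(kept) == 0L) return(integer(0))
  areas <- vapply(kept, `[[`, numeric(1), "area")
  ids <- vapply(kept, `[[`, numeric(1), "id")
  ord <- order(-areas, ids)
  claimed <- integer(0)
  retained <- integer(0)
  for (i in ord) {
    overlap <- FALSE
    for (p in kept[[i]]$pixels) if (p %in% claimed) { overlap <- TRUE; break }
    if (!overlap) {
      retained <- c(retained, kept[[i]]$id)
      claimed <- c(claimed, kept[[i]]$pixels)
    }
  }
  sort(retained)
}

brute_force_nucleus_ids <- function(objects, image, max_r = 150, max_g = 150,
                                    max_b = 200, max_area = 5000) {
  out <- integer(0)
  for (i in seq_len(nrow(objects$table))) {
    st <- brute_force_object_stats(objects$pixels[[i]], image)
    if (st$mean_r <= max_r && st$mean_g <= max_g && st$mean_b <= max_b &&
        st$area < max_area) out <- c(out, objects$table$id[i])
  }
  sort(out)
}

# collagen fraction by an explicit double loop over pixels
brute_force_collagen_fraction <- function(image, white_threshold = 235) {
  h <- dim(image)[1]; w <- dim(image)[2]
  n_col <- 0L; n_white <- 0L
  for (i in seq_len(h)) for (j in seq_len(w)) {
    r <- image[i, j, 1]; g <- image[i, j, 2]; b <- image[i, j, 3]
    white <- r >= white_threshold && g >= white_threshold && b >= white_threshold
    if (white) n_white <- n_white + 1L
    else if (r >= 170 && r <= 220 && g >= 190 && g <= 240 &&
             b >= 210 && b <= 255) n_col <- n_col + 1L
  }
  n_col / (h * w - n_white)
}

# least squares via the normal equations (textbook route)
normal_equations_fit <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)
}

# small standard design for statistics tests: one group, paired before/after
paired_toy_design <- function(n_donors = 4, group = "G1") {
  do.call(rbind, lapply(seq_len(n_donors), function(d) {
    donor <- sprintf("%s_d%d", group, d)
    data.frame(sample_id = paste0(donor, c("_b", "_a")),
               donor_id = donor, group = group,
               role = c("before", "after"),
               age_months = c(4, 6.5),
               batch = sprintf("b%d", (d %% 2) + 1),
               stringsAsFactors = FALSE)
  }))
}

two_group_design <- function(n_donors = 4, groups = c("G1", "G2")) {
  do.call(rbind, lapply(groups, function(g) paired_toy_design(n_donors, g)))
}

tiny_clock <- function(coefs, intercept = 0, ...) {
  clock_model(name = "toy", coefficients = coefs, intercept = intercept, ...)
}
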