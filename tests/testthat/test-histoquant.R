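# build a synthetic object table directly: a disk of given radius/color at a
# position in a blank image
place_disk <- function(image, labels, id, cx, cy, r, color) {
  h <- nrow(labels)
  rows <- pmax(1, floor(cy - r)):pmin(h, ceiling(cy + r))
  cols <- pmax(1, floor(cx - r)):pmin(ncol(labels), ceiling(cx + r))
  for (i in rows) for (j in cols) {
    if ((i - cy)^2 + (j - cx)^2 <= r^2) {
      labels[i, j] <- id
      image[i, j, ] <- color
    }
  }
  list(image = image, labels = labels)
}

blank_image <- function(h, w, color = c(120, 60, 60)) {
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- color[ch]
  img
}

test_that("droplet classification applies the color/area/border rules", {
  h <- w <- 400
  img <- blank_image(h, w)
  lab <- matrix(0L, h, w)
  # r=60 -> area ~ 11310 (> 10000, qualifies); r=55 -> area ~ 9503 (too small)
  x <- place_disk(img, lab, 1L, 100, 100, 60, c(200, 200, 200))
  x <- place_disk(x$image, x$labels, 2L, 280, 100, 55, c(200, 200, 200))
  # qualifying area but too dark
  x <- place_disk(x$image, x$labels, 3L, 100, 280, 60, c(185, 200, 200))
  # qualifying but touching the border band (center 75, r 60 -> min pixel 15)
  x <- place_disk(x$image, x$labels, 4L, 280, 75, 60, c(200, 200, 200))
  objs <- objects_from_labels(x$labels, x$image)
  kept <- classify_droplets(objs)
  expect_equal(kept$id, 1L)

  # area exactly at the threshold is rejected (strictly 'exceeding')
  o <- objs
  o$table$area[1] <- 10000
  expect_equal(nrow(classify_droplets(o)), 0L)
  o$table$area[1] <- 10001
  expect_equal(classify_droplets(o)$id, 1L)
})

test_that("overlapping droplet masks retain only the largest", {
  h <- w <- 500
  img <- blank_image(h, w)
  big <- place_disk(img, matrix(0L, h, w), 1L, 250, 250, 70, c(220, 220, 220))
  small <- place_disk(img, matrix(0L, h, w), 2L, 300, 250, 60, c(220, 220, 220))
  img2 <- pmax(big$image, small$image)
  # overlapping pixel sets built from separate label planes
  objs <- list(
    table = rbind(objects_from_labels(big$labels, img2)$table,
                  objects_from_labels(small$labels, img2)$table),
    pixels = c(objects_from_labels(big$labels, img2)$pixels,
               objects_from_labels(small$labels, img2)$pixels),
    dim = c(h, w))
  objs$table$id <- c(1L, 2L)
  kept <- classify_droplets(objs)
  expect_equal(kept$id, 1L)

  # disjoint: both kept
  small2 <- place_disk(img, matrix(0L, h, w), 2L, 120, 120, 61, c(220, 220, 220))
  img3 <- pmax(big$image, small2$image)
  objs2 <- list(
    table = rbind(objects_from_labels(big$labels, img3)$table,
                  objects_from_labels(small2$labels, img3)$table),
    pixels = c(objects_from_labels(big$labels, img3)$pixels,
               objects_from_labels(small2$labels, img3)$pixels),
    dim = c(h, w))
  objs2$table$id <- c(1L, 2L)
  expect_setequal(classify_droplets(objs2)$id, c(1L, 2L))
})

test_that("nucleus classification applies the purple-stain rules", {
  h <- w <- 200
  img <- blank_image(h, w)
  lab <- matrix(0L, h, w)
  x <- place_disk(img, lab, 1L, 50, 50, 20, c(120, 120, 180))       # nucleus
  x <- place_disk(x$image, x$labels, 2L, 120, 50, 20, c(160, 120, 180)) # R too high
  x <- place_disk(x$image, x$labels, 3L, 50, 120, 45, c(120, 120, 180)) # too big
  objs <- objects_from_labels(x$labels, x$image)
  expect_equal(classify_nuclei(objs)$id, 1L)

  o <- objs
  o$table$area[1] <- 5000   # strict <
  expect_equal(nrow(classify_nuclei(o[c("table", "pixels", "dim")])), 0L)
  o$table$area[1] <- 4999
  expect_equal(classify_nuclei(o)$id, 1L)
})

test_that("vectorized classification equals the brute-force per-pixel oracle", {
  set.seed(99)
  for (i in 1:6) {
    rend <- render_adipose_image(n_droplets = 3, n_nuclei = 4,
                                 collagen_fraction_target = runif(1, 0, 0.3),
                                 width = 420, height = 420, seed = 100 + i)
    labs <- rend$droplet_labels
    labs[rend$nucleus_labels > 0] <- rend$nucleus_labels[rend$nucleus_labels > 0] + 100L
    objs <- objects_from_labels(labs, rend$image)
    expect_identical(sort(classify_droplets(objs)$id),
                     brute_force_droplet_ids(objs, rend$image))
    expect_identical(sort(classify_nuclei(objs)$id),
                     brute_force_nucleus_ids(objs, rend$image))
    expect_equal(collagen_fraction(rend$image),
                 brute_force_collagen_fraction(rend$image), tolerance = 1e-12)
  }
})

test_that("raising the droplet area threshold never increases the kept count", {
  rend <- render_adipose_image(n_droplets = 4, radius_sdlog = 0.2,
                               width = 520, height = 520, seed = 42)
  objs <- objects_from_labels(rend$droplet_labels, rend$image)
  counts <- vapply(c(0, 5000, 10000, 12000, 15000, 1e6), function(thr) {
    nrow(classify_droplets(objs, min_area = thr))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("droplet size summaries use natural-log statistics", {
  s <- droplet_summary(c(exp(2), exp(4)))
  expect_equal(s$mean_log, 3, tolerance = 1e-12)
  expect_equal(s$sd_log, sqrt(2), tolerance = 1e-12)
  expect_equal(s$sem_mean, sqrt(2) / sqrt(2), tolerance = 1e-12)
  expect_equal(s$sem_sd, sqrt(2 / (2 * 1)), tolerance = 1e-12)

  expect_equal(droplet_summary(rep(50, 10))$sd_log, 0)
  expect_error(droplet_summary(100), "at least 2")
  expect_error(droplet_summary(c(-1, 5)), "positive")

  set.seed(1)
  areas <- runif(500, 1e4, 5e4)
  s1 <- droplet_summary(areas, seed = 9)
  s2 <- droplet_summary(areas, seed = 9)
  expect_identical(s1, s2)
  expect_equal(s1$n, 200)
})

test_that("collagen fraction applies the trichrome ranges and white exclusion", {
  img <- blank_image(50, 50, c(200, 220, 230))
  expect_equal(collagen_fraction(img), 1.0)

  img2 <- blank_image(50, 50, c(120, 60, 60))
  expect_equal(collagen_fraction(img2), 0.0)

  # known per-class pixel counts: 100 collagen, 400 white, rest background
  img3 <- blank_image(100, 100, c(120, 60, 60))
  img3[1:10, 1:10, 1] <- 200; img3[1:10, 1:10, 2] <- 210; img3[1:10, 1:10, 3] <- 230
  img3[51:70, 51:70, ] <- 250
  expect_equal(collagen_fraction(img3), 100 / (10000 - 400), tolerance = 1e-12)

  all_white <- blank_image(10, 10, c(250, 250, 250))
  expect_error(collagen_fraction(all_white), "tissue")
})

test_that("classical segmentation recovers rendered droplets", {
  rend <- render_adipose_image(n_droplets = 5, n_nuclei = 6,
                               collagen_fraction_target = 0.1,
                               width = 600, height = 600, seed = 7)
  objs <- segment_droplets_classical(rend$image)
  kept <- classify_droplets(objs)
  expect_equal(nrow(kept), 5L)
  # IoU vs truth disks
  tr <- rend$truth[rend$truth$type == "droplet", ]
  for (i in seq_len(nrow(tr))) {
    truth_pix <- which(rend$droplet_labels == tr$id[i])
    # nearest recovered object by center containment
    ious <- vapply(seq_len(nrow(kept)), function(j) {
      p <- objs$pixels[[match(kept$id[j], objs$table$id)]]
      length(intersect(p, truth_pix)) / length(union(p, truth_pix))
    }, numeric(1))
    expect_gte(max(ious), 0.9)
  }

  blank <- blank_image(200, 200)
  expect_equal(nrow(segment_droplets_classical(blank)$table), 0L)
})

test_that("watershed splits touching droplets", {
  img <- blank_image(400, 400)
  a <- place_disk(img, matrix(0L, 400, 400), 1L, 150, 200, 60, c(245, 245, 245))
  b <- place_disk(a$image, a$labels, 2L, 265, 200, 60, c(245, 245, 245))
  objs <- segment_droplets_classical(b$image)
  expect_equal(nrow(classify_droplets(objs)), 2L)
})

test_that("mitochondrial morphometry measures volume, sphericity and density", {
  # single-voxel object with anisotropic voxels
  lab <- array(0L, c(5, 5, 5)); lab[3, 3, 3] <- 1L
  m <- mito_morphology(lab, c(0.1, 0.1, 0.3))
  expect_equal(m$objects$volume_um3, 0.003, tolerance = 1e-12)

  # ball r=10: sphericity in [0.95, 1.05]
  d <- c(32, 32, 32)
  ball <- array(0L, d)
  ctr <- expand.grid(x = 1:32, y = 1:32, z = 1:32)
  ball[as.matrix(ctr[(ctr$x - 16)^2 + (ctr$y - 16)^2 + (ctr$z - 16)^2 <= 100, ])] <- 1L
  mb <- mito_morphology(ball, c(1, 1, 1))
  expect_gte(mb$objects$sphericity, 0.95)
  expect_lte(mb$objects$sphericity, 1.05)
  expect_equal(mb$objects$volume_um3, 4 / 3 * pi * 1000, tolerance = 0.05)

  # scale invariance of sphericity
  mb2 <- mito_morphology(ball, c(2, 2, 2))
  expect_equal(mb$objects$sphericity, mb2$objects$sphericity, tolerance = 0.01)

  # rods score strictly below balls of equal volume
  vol <- render_mito_volume(n_objects = 6, shape_mix = c(ball = 0.5, rod = 0.5),
                            seed = 3)
  mm <- mito_morphology(vol$labels, c(1, 1, 1))
  cls <- vol$truth$class[match(mm$objects$label, vol$truth$label)]
  expect_gt(min(mm$objects$sphericity[cls == "ball"]),
            max(mm$objects$sphericity[cls == "rod"]))

  # density denominator: full stack vs supplied cytoplasm mask
  expect_equal(mm$density_per_um3, 6 / prod(dim(vol$labels)))
  cyto <- array(TRUE, dim(vol$labels))
  cyto[1:10, , ] <- FALSE
  m2 <- mito_morphology(vol$labels, c(1, 1, 1), cytoplasm_mask = cyto)
  expect_equal(m2$density_per_um3, 6 / sum(cyto))
})

test_that("stack depth is slices times step", {
  expect_equal(stack_depth(41, 0.3), 12.3)
  expect_equal(stack_depth(1, 0.77), 0.77)
  expect_equal(stack_depth(50, 0.3), 15)
  expect_error(stack_depth(0, 0.3), "slice")
  expect_error(stack_depth(10, 0), "positive")
})
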