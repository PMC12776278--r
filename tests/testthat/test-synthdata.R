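test_that("generate_design emits the transplant record structure", {
  spec <- design_spec(donors_per_group = 1, sham_donors = 2, seed = 4)
  sheet <- generate_design(spec)
  for (g in c("YY", "YO", "OY", "OO")) {
    sub <- sheet[sheet$group == g, ]
    expect_equal(nrow(sub), 3L)
    expect_setequal(sub$role, c("before", "after", "native"))
  }
  expect_equal(sum(sheet$group == "SHAM"), 4L)  # 2 donors x 2 time points

  expect_identical(generate_design(spec), generate_design(spec))

  sheet8 <- generate_design(design_spec(donors_per_group = 8, seed = 1))
  for (g in c("YY", "YO", "OY", "OO")) {
    donors <- unique(sheet8$donor_id[sheet8$group == g])
    expect_length(donors, 8L)
    # each donor appears in exactly one group
    expect_true(all(table(sheet8$group[sheet8$donor_id %in% donors]) > 0))
    expect_equal(unique(sheet8$group[sheet8$donor_id %in% donors]), g)
  }
  expect_error(design_spec(donors_per_group = 0), "donors_per_group")
  expect_equal(design_spec()$graft_mass_fraction, 0.01)
})

test_that("generate_linear_clock honors density, scale and seed", {
  ck <- generate_linear_clock(10, density = 1, seed = 1)
  expect_equal(sum(ck$coefficients != 0), 10L)
  expect_equal(sum(generate_linear_clock(10, density = 0.3, seed = 1)$coefficients != 0), 3L)

  ck0 <- generate_linear_clock(10, coef_scale = 0, intercept = 42, seed = 1)
  expect_true(all(ck0$coefficients == 0))
  x <- matrix(rnorm(30), 10, 3, dimnames = list(ck0$features, paste0("s", 1:3)))
  expect_equal(predict_age(ck0, x)$value, rep(42, 3))

  expect_false(identical(generate_linear_clock(10, seed = 1)$coefficients,
                         generate_linear_clock(10, seed = 2)$coefficients))
  expect_identical(generate_linear_clock(10, seed = 7),
                   generate_linear_clock(10, seed = 7))
  expect_error(generate_linear_clock(10, density = 0), "density")
})

test_that("expression simulation round-trips through the clock pipeline", {
  des <- generate_design(design_spec(donors_per_group = 3, sham_donors = 4, seed = 1))
  ck <- generate_linear_clock(30, intercept = 25, seed = 2)

  # exact algebra at continuous counts
  sim <- simulate_expression(des, ck, n_genes = 200, dispersion = 0,
                             round_counts = FALSE, seed = 3)
  pp <- preprocess_for_clock(sim$counts, ck, sim$truth$reference_samples)
  pred <- predict_age(ck, pp)
  expect_equal(pred$value, sim$truth$samples$true_signal, tolerance = 1e-6)

  # integer counts keep recovery within 0.1 clock units
  sim_i <- simulate_expression(des, ck, n_genes = 200, dispersion = 0, seed = 3)
  pp_i <- preprocess_for_clock(filter_expression(sim_i$counts), ck,
                               sim_i$truth$reference_samples)
  err <- predict_age(ck, pp_i)$value - sim_i$truth$samples$true_signal
  expect_lt(max(abs(err)), 0.1)
  expect_true(all(sim_i$counts == round(sim_i$counts)))
})

test_that("planted group shifts are recovered from noiseless simulations", {
  des <- generate_design(design_spec(donors_per_group = 4, sham_donors = 4, seed = 1))
  ck <- generate_linear_clock(30, intercept = 25, seed = 2)
  sim <- simulate_expression(des, ck, n_genes = 200, dispersion = 0,
                             group_shifts = c(YY = 0, YO = 0, OY = -5, OO = 0),
                             seed = 5)
  pp <- preprocess_for_clock(filter_expression(sim$counts), ck,
                             sim$truth$reference_samples)
  pred <- predict_age(ck, pp)
  m <- merge(pred, des, by = "sample_id")
  oy <- m[m$group == "OY", ]
  dyn <- mean(oy$value[oy$role == "after"]) - mean(oy$value[oy$role == "before"])
  # Before->After = age_slope * followup + delta = 2.5 - 5
  expect_equal(dyn, -2.5, tolerance = 0.5)

  # no signal at all: predictions constant
  sim0 <- simulate_expression(des, ck, n_genes = 150, age_slope = 0,
                              group_shifts = c(YY = 0, YO = 0, OY = 0, OO = 0),
                              dispersion = 0, round_counts = FALSE, seed = 6)
  pp0 <- preprocess_for_clock(sim0$counts, ck, sim0$truth$reference_samples)
  expect_lt(diff(range(predict_age(ck, pp0)$value)), 1e-8)

  expect_error(simulate_expression(des, ck, n_genes = 10, seed = 1),
               "exceed")
  expect_identical(simulate_expression(des, ck, n_genes = 150, seed = 9)$counts,
                   simulate_expression(des, ck, n_genes = 150, seed = 9)$counts)
})

test_that("methylation simulation round-trips and exercises the filter", {
  des <- generate_design(design_spec(donors_per_group = 3, sham_donors = 4, seed = 1))
  ck <- generate_linear_clock(25, coef_scale = 2, intercept = 10,
                              feature_prefix = "cg", seed = 3)
  sim <- simulate_methylation(des, ck, noise_sd = 0, seed = 4)
  expect_true(all(sim$beta >= 0 & sim$beta <= 1))
  pred <- predict_age(ck, sim$beta)
  ok <- !sim$truth$samples$clipped
  expect_true(any(ok))
  expect_equal(pred$value[ok], sim$truth$samples$true_signal[ok],
               tolerance = 1e-9)

  # detection-p fraction 0: the filter removes nothing
  expect_equal(nrow(filter_methylation(sim$beta, sim$detection_p)),
               nrow(sim$beta))
  sim_f <- simulate_methylation(des, ck, detp_fail_fraction = 0.5, seed = 4)
  expect_lt(nrow(filter_methylation(sim_f$beta, sim_f$detection_p)),
            nrow(sim_f$beta))

  # all-0.5 beta matrix has maximal entropy
  expect_equal(unname(shannon_entropy(matrix(0.5, 10, 3))), rep(1, 3))
})

test_that("rendered adipose images agree with their truth tables", {
  rend <- render_adipose_image(n_droplets = 3, n_nuclei = 5,
                               collagen_fraction_target = 0.2,
                               width = 400, height = 400, seed = 11)
  tr <- rend$truth
  expect_equal(sum(tr$type == "droplet"), 3L)
  expect_equal(sum(tr$type == "nucleus"), 5L)
  expect_true(all(tr$radius > 0))
  expect_true(all(tr$cx > 0 & tr$cx <= 400 & tr$cy > 0 & tr$cy <= 400))

  # every truth object is recoverable from the image by its color rule
  objs <- objects_from_labels(rend$droplet_labels, rend$image)
  kept <- classify_droplets(objs)
  expect_equal(nrow(kept), 3L)
  nobj <- objects_from_labels(rend$nucleus_labels, rend$image)
  expect_equal(nrow(classify_nuclei(nobj)), 5L)

  # collagen fraction measured on the image matches the target
  expect_equal(collagen_fraction(rend$image), 0.2, tolerance = 0.02)

  # empty image
  rend0 <- render_adipose_image(n_droplets = 0, n_nuclei = 0,
                                collagen_fraction_target = 0,
                                width = 120, height = 120, seed = 1)
  o0 <- objects_from_labels(rend0$droplet_labels, rend0$image)
  expect_equal(nrow(classify_droplets(o0)), 0L)

  # droplet radius 60 -> area ~ pi*60^2 = 11310 > 10000: all kept
  r60 <- render_adipose_image(n_droplets = 5, radius_meanlog = log(60),
                              radius_sdlog = 0, width = 700, height = 700,
                              seed = 2)
  k60 <- classify_droplets(objects_from_labels(r60$droplet_labels, r60$image))
  expect_equal(nrow(k60), 5L)
  expect_equal(k60$area, rep(k60$area[1], 5), tolerance = 0.01)

  # infeasible packing errors with the achieved count
  expect_error(render_adipose_image(n_droplets = 50, width = 300, height = 300,
                                    seed = 3), "placed")
  expect_identical(render_adipose_image(seed = 8)$image,
                   render_adipose_image(seed = 8)$image)
})

test_that("rendered mitochondria volumes carry consistent truth", {
  vol <- render_mito_volume(n_objects = 4, seed = 21)
  expect_equal(length(setdiff(unique(as.vector(vol$labels)), 0)), 4L)
  for (i in seq_len(nrow(vol$truth))) {
    v_meas <- sum(vol$labels == vol$truth$label[i])
    expect_equal(v_meas, vol$truth$analytic_volume_vox[i], tolerance = 0.10)
  }
  # single ball: voxel-count volume within 5% of (4/3) pi r^3
  one <- render_mito_volume(n_objects = 1, shape_mix = c(ball = 1),
                            radius_range = c(10, 10), dim3 = c(40, 40, 40),
                            seed = 2)
  expect_equal(sum(one$labels == 1), 4 / 3 * pi * 1000, tolerance = 0.05)

  expect_equal(sum(render_mito_volume(n_objects = 0, seed = 1)$labels), 0)
  expect_false(identical(render_mito_volume(n_objects = 3, seed = 1)$labels,
                         render_mito_volume(n_objects = 3, seed = 2)$labels))
})

test_that("generators restore the caller's random state", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_linear_clock(10, seed = 5))
  expect_identical(.Random.seed, before)
  x1 <- rnorm(1)
  set.seed(123)
  invisible(runif(0))
  expect_identical(rnorm(1), x1)
})
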