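#' Run the full synthetic-to-report analysis pipeline
#'
#' Orchestrates one end-to-end analysis on simulated data with planted
#' ground truth: design generation, clock simulation, expression filtering,
#' clock preprocessing and prediction, sham-based age calibration,
#' within-group Before/After contrasts on age deviations, all-pairs
#' between-group dynamics contrasts (one BH family), clock deconvolution
#' into per-gene contributions per group, cross-group contribution
#' correlations, and (optionally) histology quantification of a rendered
#' section and volume. Results are returned and, when `output_dir` is set,
#' written as TSVs plus a JSON manifest recording stage provenance.
#'
#' @param config A [run_config()].
#' @param write_outputs Write result tables under `config$output_dir`
#'   (default TRUE when the directory is non-NULL).
#' @return A list of result tables (invisible when written to disk):
#'   `design`, `clock`, `predictions`, `calibration`, `deviations`,
#'   `within_group`, `between_group`, `contributions`, `contribution_cor`,
#'   `histology`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), write_outputs = !is.null(config$output_dir)) {
  stopifnot(inherits(config, "run_config"))
  seed <- as.integer(config$seed)
  sim <- config$simulate
  th <- config$thresholds
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  design <- stage("design", {
    generate_design(design_spec(
      donors_per_group = sim$donors_per_group, sham_donors = sim$sham_donors,
      young_age = sim$young_age, old_age = sim$old_age,
      followup_months = sim$followup_months, n_batches = sim$n_batches,
      seed = seed))
  })
  clock <- stage("clock", {
    generate_linear_clock(sim$clock_features, density = 1, coef_scale = 1,
                          intercept = 30, seed = seed + 1L)
  })
  shifts <- unlist(sim$group_shifts)
  simdata <- stage("simulate", {
    simulate_expression(design, clock, n_genes = sim$n_genes,
                        age_slope = sim$age_slope, group_shifts = shifts,
                        dispersion = sim$dispersion, seed = seed + 2L)
  })
  counts <- stage("filter", {
    filter_expression(simdata$counts, min_count = th$expr_min_count,
                      min_fraction = th$expr_min_fraction)
  })
  processed <- stage("preprocess", {
    preprocess_for_clock(counts, clock, simdata$truth$reference_samples)
  })
  predictions <- stage("predict", predict_age(clock, processed))

  sham <- design[design$role == "sham", ]
  calibration <- stage("calibrate", {
    sham_calibrate(sham$age_months,
                   predictions$value[match(sham$sample_id,
                                           predictions$sample_id)])
  })
  deviations <- stage("deviation", {
    idx <- match(design$sample_id, predictions$sample_id)
    data.frame(sample_id = design$sample_id,
               deviation = age_deviation(calibration, design$age_months,
                                         predictions$value[idx]),
               stringsAsFactors = FALSE)
  })

  dev_vec <- stats::setNames(deviations$deviation, deviations$sample_id)
  within <- stage("within_group", {
    rows <- lapply(TRANSPLANT_GROUPS, function(g) {
      sub <- design[design$group == g & design$role %in% c("before", "after"), ]
      res <- paired_contrast(dev_vec[sub$sample_id], sub, adjust = FALSE)
      res$group <- g
      res
    })
    adjust_family(do.call(rbind, rows))
  })
  between <- stage("between_group", {
    pairs <- utils::combn(TRANSPLANT_GROUPS, 2, simplify = FALSE)
    rows <- lapply(pairs, function(pr) {
      interaction_contrast(dev_vec, design, pr)
    })
    adjust_family(do.call(rbind, rows))
  })

  contributions <- stage("deconvolve", {
    out <- lapply(TRANSPLANT_GROUPS, function(g) {
      sub <- design[design$group == g & design$role %in% c("before", "after"), ]
      gc <- gene_contributions(processed, sub, clock)
      data.frame(group = g, gc$contributions,
                 total = gc$total, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  contribution_cor <- stage("contribution_cor", {
    vecs <- lapply(split(contributions, contributions$group), function(d) {
      stats::setNames(d$contribution, d$gene)
    })
    correlation_compare(vecs)
  })

  histology <- NULL
  if (isTRUE(config$analyses$histology)) {
    histology <- stage("histology", {
      rend <- render_adipose_image(seed = seed + 3L)
      objs <- objects_from_labels(rend$droplet_labels, rend$image,
                                  border_px = th$border_px)
      droplets <- classify_droplets(objs, rgb_min = th$droplet_rgb_min,
                                    min_area = th$droplet_min_area,
                                    border_px = th$border_px)
      vol <- render_mito_volume(seed = seed + 4L)
      morpho <- mito_morphology(vol$labels, vol$voxel_dim)
      list(droplets = droplets,
           droplet_summary = if (nrow(droplets) >= 2)
             droplet_summary(droplets$area, th$droplet_subsample_max,
                             seed = seed + 5L) else NULL,
           collagen_fraction = collagen_fraction(
             rend$image, white_threshold = th$white_threshold),
           mito = morpho$objects, mito_density = morpho$density_per_um3)
    })
  }

  manifest <- list(
    seed = seed,
    stages = c("design", "clock", "simulate", "filter", "preprocess",
               "predict", "calibrate", "deviation", "within_group",
               "between_group", "deconvolve", "contribution_cor",
               if (!is.null(histology)) "histology"),
    thresholds = th,
    bh_families = list(
      within_group = "role terms across the four transplant groups",
      between_group = "all 6 group-pair dynamics interactions",
      contributions = "per-group DE families (not adjusted here)"),
    n_samples = nrow(design), n_genes_filtered = nrow(counts),
    calibration = unclass(calibration))

  result <- list(design = design, clock = clock, predictions = predictions,
                 calibration = calibration, deviations = deviations,
                 within_group = within, between_group = between,
                 contributions = contributions,
                 contribution_cor = contribution_cor,
                 histology = histology, manifest = manifest)

  if (write_outputs) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(name) file.path(config$output_dir, name)
    write_sample_sheet(design, out("sample_sheet.csv"))
    write_clock(clock, out("clock.json"))
    write_result_tsv(predictions, out("predictions.tsv"))
    write_result_tsv(deviations, out("deviations.tsv"))
    write_result_tsv(within, out("within_group_contrasts.tsv"))
    write_result_tsv(between, out("between_group_contrasts.tsv"))
    write_result_tsv(contributions, out("gene_contributions.tsv"))
    if (!is.null(histology)) {
      write_result_tsv(histology$mito, out("mito_morphology.tsv"))
    }
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    return(invisible(result))
  }
  result
}
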