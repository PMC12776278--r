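#' Filter non-expressed genes from a count matrix
#'
#' Keeps genes with at least `min_count` reads in at least `min_fraction` of
#' samples (both comparisons inclusive).
#'
#' @param counts Non-negative genes x samples count matrix.
#' @param min_count Read threshold (default 10).
#' @param min_fraction Fraction-of-samples threshold (default 0.2).
#' @return The filtered count matrix (same samples).
#' @export
filter_expression <- function(counts, min_count = 10, min_fraction = 0.2) {
  check_count_matrix(counts)
  keep <- rowMeans(counts >= min_count) >= min_fraction
  counts[keep, , drop = FALSE]
}

#' Filter CpGs by detection p-value
#'
#' A CpG is removed iff the proportion of samples with detection
#' p > `p_threshold` is at least `sample_fraction`.
#'
#' @param beta CpG x samples beta-value matrix in \[0,1\].
#' @param detection_p Matrix of detection p-values, same shape as `beta`.
#' @param p_threshold Detection p-value cutoff (default 0.01).
#' @param sample_fraction Fraction of failing samples that triggers removal
#'   (default 0.25).
#' @return Filtered beta matrix.
#' @export
filter_methylation <- function(beta, detection_p, p_threshold = 0.01,
                               sample_fraction = 0.25) {
  check_beta_matrix(beta)
  if (!identical(dim(beta), dim(detection_p))) {
    stop("`beta` and `detection_p` must share dimensions")
  }
  drop_cpg <- rowMeans(detection_p > p_threshold) >= sample_fraction
  beta[!drop_cpg, , drop = FALSE]
}

#' Per-sample mean methylation
#'
#' @param beta CpG x samples beta matrix in \[0,1\].
#' @return Named numeric vector, one mean per sample.
#' @export
mean_methylation <- function(beta) {
  check_beta_matrix(beta)
  if (nrow(beta) == 0L) stop("no CpGs left to average")
  colMeans(beta)
}

#' Per-sample methylation Shannon entropy
#'
#' Mean over CpGs of the per-site binary entropy
#' \eqn{-[\beta \log_2 \beta + (1-\beta)\log_2(1-\beta)]}, with beta clamped
#' to \[eps, 1-eps\]. Values lie in \[0,1\]; 1 is reached only at beta = 0.5,
#' so rising entropy indicates loss of definitive (0/1) methylation states.
#'
#' @param beta CpG x samples beta matrix in \[0,1\].
#' @param eps Clamping constant (default 1e-6).
#' @return Named numeric vector of per-sample entropies (bits).
#' @export
shannon_entropy <- function(beta, eps = 1e-6) {
  check_beta_matrix(beta)
  if (nrow(beta) == 0L) stop("no CpGs left")
  b <- pmin(pmax(beta, eps), 1 - eps)
  h <- -(b * log2(b) + (1 - b) * log2(1 - b))
  colMeans(h)
}

#' Relative Log Expression (RLE) size factors
#'
#' Median-of-ratios scaling: reference genes are those with positive counts
#' in every sample; each sample's factor is the median over reference genes
#' of its count divided by that gene's geometric mean across samples.
#' Normalized counts are `counts / factor`.
#'
#' @param counts Non-negative genes x samples count matrix.
#' @return Named positive numeric vector of per-sample size factors.
#' @export
rle_size_factors <- function(counts) {
  check_count_matrix(counts)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    stop("no gene is positive in all samples; prefilter the matrix ",
         "(e.g. with filter_expression()) before RLE normalization")
  }
  lg <- log(counts[ref, , drop = FALSE])
  geo <- rowMeans(lg)
  apply(exp(lg - geo), 2, stats::median)
}

#' Apply RLE size factors
#' @param counts Count matrix.
#' @param factors Per-sample size factors from [rle_size_factors()].
#' @return Normalized matrix `counts / factor` (columnwise).
#' @export
rle_normalize <- function(counts, factors = rle_size_factors(counts)) {
  sweep(counts, 2, factors, "/")
}

#' Processed expression matrix with provenance
#'
#' Container returned by [preprocess_for_clock()]: features x samples reals,
#' an ordered record of the applied steps, and the reference sample set used
#' for centering.
#'
#' @param data Numeric features x samples matrix.
#' @param steps Character vector of applied step names, in order.
#' @param reference_samples Character vector of reference sample IDs.
#' @return An object of class `processed_matrix`.
#' @export
processed_matrix <- function(data, steps = character(), reference_samples = character()) {
  stopifnot(is.matrix(data), is.numeric(data))
  structure(list(data = data, steps = steps,
                 reference_samples = reference_samples),
            class = "processed_matrix")
}

#' @export
print.processed_matrix <- function(x, ...) {
  cat(sprintf("<processed_matrix> %d features x %d samples\n",
              nrow(x$data), ncol(x$data)))
  cat("  steps:", paste(x$steps, collapse = " -> "), "\n")
  invisible(x)
}

PREPROCESS_STEPS <- c("rle_normalize", "log2_plus1", "zscale_features",
                      "impute_clock_features", "center_reference_median")

#' Preprocess a count matrix for clock application
#'
#' Pipeline, in order: (1) RLE normalization; (2) log2(x + 1);
#' (3) per-feature z-scaling across samples (zero-variance features are left
#' at 0); (4) injection of clock features absent from the data as constant
#' rows at their stored imputation means; (5) centering by subtraction of the
#' per-feature median over the reference samples (by default, young donor
#' tissue before transplantation).
#'
#' @param counts Filtered genes x samples count matrix.
#' @param clock A [clock_model()] whose features must be covered (by data or
#'   imputation means).
#' @param reference_samples Character vector of sample IDs (subset of
#'   `colnames(counts)`) defining the centering reference.
#' @return A [processed_matrix()] carrying the 5-step provenance.
#' @export
preprocess_for_clock <- function(counts, clock, reference_samples) {
  check_count_matrix(counts)
  stopifnot(inherits(clock, "clock_model"))
  reference_samples <- as.character(reference_samples)
  if (length(reference_samples) == 0L ||
      !all(reference_samples %in% colnames(counts))) {
    stop("reference samples absent from the count matrix")
  }
  x <- log2(rle_normalize(counts) + 1)
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  # features constant up to floating-point jitter carry no usable variance;
  # amplifying the jitter to unit scale would inject pure rounding noise
  const <- sdv < 1e-10 * pmax(1, abs(mu))
  z <- (x - mu) / ifelse(const, 1, sdv)
  z[const, ] <- 0
  missing <- setdiff(clock$features, rownames(z))
  if (length(missing) > 0L) {
    imp <- impmean_vector(clock)[missing]
    add <- matrix(rep(imp, ncol(z)), nrow = length(missing),
                  dimnames = list(missing, colnames(z)))
    z <- rbind(z, add)
  }
  ref_med <- apply(z[, reference_samples, drop = FALSE], 1, stats::median)
  z <- z - ref_med
  processed_matrix(z, steps = PREPROCESS_STEPS,
                   reference_samples = reference_samples)
}

#' Standardize clock predictions within experimental groups
#'
#' Z-scores prediction values within each group (mean 0, sd 1 with the n-1
#' denominator), as used for module-specific clock panels.
#'
#' @param predictions data.frame from [predict_age()] (columns `sample_id`,
#'   `value`, ...).
#' @param design Sample sheet with columns `sample_id`, `group`.
#' @param constant_ok If `FALSE` (default) a zero-variance group is an error;
#'   if `TRUE` its z-scores are all 0.
#' @return `predictions` with `value` replaced by the within-group z-score.
#' @export
standardize_within_group <- function(predictions, design, constant_ok = FALSE) {
  stopifnot(all(c("sample_id", "value") %in% names(predictions)),
            all(c("sample_id", "group") %in% names(design)))
  grp <- design$group[match(predictions$sample_id, design$sample_id)]
  if (anyNA(grp)) stop("predictions contain samples absent from the design")
  out <- predictions
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2L) stop("group of size 1 cannot be standardized: ", g)
    v <- predictions$value[idx]
    s <- stats::sd(v)
    if (s == 0) {
      if (!constant_ok) stop("constant predictions in group: ", g)
      out$value[idx] <- 0
    } else {
      out$value[idx] <- (v - mean(v)) / s
    }
  }
  out
}

check_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric matrix")
  }
  if (nrow(counts) == 0L || ncol(counts) == 0L) stop("empty count matrix")
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  invisible(TRUE)
}

check_beta_matrix <- function(beta) {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    stop("beta values must form a numeric matrix")
  }
  if (ncol(beta) == 0L) stop("empty beta matrix")
  if (anyNA(beta) || any(beta < 0 | beta > 1)) {
    stop("beta values must lie in [0, 1]")
  }
  invisible(TRUE)
}
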