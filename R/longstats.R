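#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment via [stats::p.adjust()] after input validation.
#' Adjustment families are always explicit in this package: callers pass
#' exactly the p-values forming one family.
#'
#' @param p Numeric vector of p-values in \[0,1\] (NAs not allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

contrast_result <- function(term, estimate, se, p, n, model, p_adj = NA_real_) {
  data.frame(term = term, estimate = estimate, se = se, p = p, p_adj = p_adj,
             n = n, model = model, stringsAsFactors = FALSE, row.names = NULL)
}

align_values <- function(values, design) {
  if (is.null(names(values))) {
    if (length(values) != nrow(design)) {
      stop("unnamed `values` must match the design row-for-row")
    }
    return(as.numeric(values))
  }
  idx <- match(design$sample_id, names(values))
  if (anyNA(idx)) stop("values missing for samples: ",
                       paste(design$sample_id[is.na(idx)], collapse = ", "))
  as.numeric(values[idx])
}

#' Paired within-group contrast with donor covariate
#'
#' Fits `value ~ role + donor` by ordinary least squares (donor as a
#' categorical fixed effect, absorbing the within-donor pairing) and reports
#' the coefficient, standard error and t-test p-value of each non-reference
#' role. This is the within-group model used to compare tissue roles
#' (e.g. Before vs After vs Native) on clock predictions, mean methylation
#' or entropy. BH adjustment across the role terms is applied by default;
#' pass `adjust = FALSE` when the family is assembled elsewhere.
#'
#' @param values Named numeric vector (names = sample IDs) or a vector
#'   aligned with `design` rows.
#' @param design Sample sheet rows for one experimental group (columns
#'   `sample_id`, `donor_id`, `role`).
#' @param reference_role Role used as the model baseline (default "before").
#' @param adjust Apply BH across the reported role terms (default TRUE).
#' @return A `contrast_result` data.frame, one row per non-reference role.
#' @export
paired_contrast <- function(values, design, reference_role = "before",
                            adjust = TRUE) {
  v <- align_values(values, design)
  roles <- unique(design$role)
  if (length(roles) < 2L) stop("need at least two roles to contrast")
  if (!reference_role %in% roles) {
    stop("reference role absent from design: ", reference_role)
  }
  role <- stats::relevel(factor(design$role), ref = reference_role)
  donor <- factor(design$donor_id)
  fit <- stats::lm(v ~ role + donor)
  cf <- summary(fit)$coefficients
  if (anyNA(stats::coef(fit))) {
    stop("rank-deficient design: role is confounded with donor")
  }
  keep <- grep("^role", rownames(cf))
  res <- contrast_result(
    term = sub("^role", "", rownames(cf)[keep]),
    estimate = cf[keep, 1], se = cf[keep, 2], p = cf[keep, 4],
    n = length(v),
    model = "value ~ role + donor (OLS)")
  res$p_adj <- if (adjust) bh_adjust(res$p) else NA_real_
  res
}

#' Between-group dynamics (interaction) contrast
#'
#' For a pair of experimental groups, fits
#' `value ~ stage + group + stage:group` over Before/After samples and
#' extracts the interaction coefficient: the difference between the two
#' groups' Before->After dynamics.
#'
#' @param values Named numeric vector of responses.
#' @param design Sample sheet rows covering both groups (roles `before` and
#'   `after` present in each).
#' @param groups Character vector of exactly two group labels.
#' @return A single-row `contrast_result` for the interaction term (p_adj is
#'   NA: the BH family spans all group pairs and is adjusted by the caller,
#'   e.g. via [adjust_family()]).
#' @export
interaction_contrast <- function(values, design, groups) {
  if (length(groups) != 2L) stop("exactly two groups required")
  sub <- design[design$group %in% groups & design$role %in% c("before", "after"), ]
  for (g in groups) {
    have <- unique(sub$role[sub$group == g])
    if (!all(c("before", "after") %in% have)) {
      stop("group ", g, " lacks a transplantation stage")
    }
  }
  v <- align_values(values, sub)
  stage <- factor(sub$role, levels = c("before", "after"))
  grp <- factor(sub$group, levels = groups)
  fit <- stats::lm(v ~ stage * grp)
  cf <- summary(fit)$coefficients
  ix <- grep(":", rownames(cf))
  contrast_result(
    term = sprintf("dynamics[%s - %s]", groups[2], groups[1]),
    estimate = cf[ix, 1], se = cf[ix, 2], p = cf[ix, 4], n = nrow(sub),
    model = "value ~ stage * group (OLS)")
}

#' BH-adjust a family of contrast results
#'
#' @param results A `contrast_result` data.frame (rows = one family).
#' @return The same data.frame with `p_adj` filled by [bh_adjust()].
#' @export
adjust_family <- function(results) {
  results$p_adj <- bh_adjust(results$p)
  results
}

#' Measurement-error-weighted mixed-effects contrast
#'
#' Fits `value ~ stage + batch + (1 | donor)` by REML with per-observation
#' weights derived from the prediction standard deviations: observations
#' with larger clock-prediction sd carry proportionally less weight
#' (relative inverse-variance weighting; all-zero sds give unit weights, and
#' rescaling every sd by a common factor leaves the fit unchanged).
#' Satterthwaite-approximation p-values are reported for the focal stage
#' term. Designs with a single batch drop the batch term automatically.
#'
#' @param values Named numeric vector of responses (e.g. tAge deviations).
#' @param sds Per-observation prediction sds (>= 0), aligned like `values`.
#' @param design Sample sheet rows (columns `sample_id`, `donor_id`, `role`,
#'   `batch`) for one group, roles `before`/`after`.
#' @param reference_role Baseline stage (default "before").
#' @return A single-row `contrast_result` for the stage term.
#' @export
weighted_mixed_contrast <- function(values, sds, design,
                                    reference_role = "before") {
  v <- align_values(values, design)
  s <- align_values(sds, design)
  if (any(s < 0)) stop("prediction sds must be >= 0")
  if (length(unique(design$donor_id)) < 2L) stop("need at least two donors")
  msq <- mean(s^2)
  w <- if (msq == 0) rep(1, length(s)) else 1 / (s^2 + 1e-8 * msq)
  dat <- data.frame(
    v = v, w = w,
    stage = stats::relevel(factor(design$role), ref = reference_role),
    donor = factor(design$donor_id),
    batch = factor(design$batch))
  form <- if (nlevels(dat$batch) > 1L) {
    v ~ stage + batch + (1 | donor)
  } else {
    v ~ stage + (1 | donor)
  }
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(form, data = dat, weights = w, REML = TRUE))),
    error = function(e) {
      stop("mixed model failed to converge: ", conditionMessage(e))
    })
  cf <- summary(fit)$coefficients
  ix <- grep("^stage", rownames(cf))
  contrast_result(
    term = sub("^stage", "", rownames(cf)[ix]),
    estimate = cf[ix, 1], se = cf[ix, 2], p = cf[ix, 5], n = nrow(dat),
    model = "value ~ stage + batch + (1|donor), REML, 1/sd^2 weights")
}

#' Sham-based chronological-age calibration
#'
#' Ordinary least squares of predicted age on chronological age over
#' sham-operated control samples. The fitted line defines the expected
#' prediction at a given age; deviations from it isolate transplant effects
#' from normal aging. With fewer than two distinct sham ages an
#' intercept-only (mean) model is fitted and flagged.
#'
#' @param ages Chronological ages of the sham samples (months).
#' @param predictions Clock predictions for the same samples.
#' @return An object of class `sham_calibration`: `slope`, `intercept`,
#'   `n`, `residual_sd`, `intercept_only`.
#' @export
sham_calibrate <- function(ages, predictions) {
  if (length(ages) == 0L) stop("no sham samples supplied")
  if (length(ages) != length(predictions)) {
    stop("ages and predictions must be aligned")
  }
  if (length(ages) < 2L || length(unique(ages)) < 2L) {
    fitvals <- rep(mean(predictions), length(ages))
    out <- list(slope = 0, intercept = mean(predictions),
                n = length(ages),
                residual_sd = stats::sd(predictions - fitvals),
                intercept_only = TRUE)
  } else {
    fit <- stats::lm(predictions ~ ages)
    out <- list(slope = unname(stats::coef(fit)[2]),
                intercept = unname(stats::coef(fit)[1]),
                n = length(ages),
                residual_sd = stats::sd(stats::residuals(fit)),
                intercept_only = FALSE)
  }
  structure(out, class = "sham_calibration")
}

#' @export
print.sham_calibration <- function(x, ...) {
  cat(sprintf("<sham_calibration> expected = %.4g + %.4g * age (n = %d%s)\n",
              x$intercept, x$slope, x$n,
              if (x$intercept_only) ", intercept-only" else ""))
  invisible(x)
}

#' Deviation of a prediction from its age-expected value
#'
#' `deviation = prediction - (intercept + slope * age)`.
#'
#' @param calibration A [sham_calibrate()] fit.
#' @param ages Chronological ages (months).
#' @param predictions Clock predictions (same length).
#' @return Numeric vector of deviations (clock units).
#' @export
age_deviation <- function(calibration, ages, predictions) {
  stopifnot(inherits(calibration, "sham_calibration"))
  predictions - (calibration$intercept + calibration$slope * ages)
}
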