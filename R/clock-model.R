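#' Linear aging/mortality clock model
#'
#' A clock is a sparse linear predictor over named features (genes or CpGs):
#' `value = intercept + sum_i coef_i * x_i`. The target scale is either
#' chronological age (years or months, as trained) or log-hazard for
#' mortality clocks; predictions are kept on the linear-predictor scale
#' throughout. Per-feature imputation means allow clock features absent from
#' a dataset to be injected as constants on the processed scale.
#'
#' @param name Clock name (character scalar).
#' @param target Target scale, one of `"chronological_age"` or `"log_hazard"`.
#' @param coefficients Named numeric vector of coefficients (one per feature).
#' @param intercept Finite numeric scalar.
#' @param imputation_means Named numeric vector aligned with `coefficients`;
#'   defaults to zeros (sensible for centered processed profiles).
#' @param sd Non-negative scalar prediction standard deviation attached to
#'   every prediction made with this clock (0 = none supplied).
#' @return An object of class `clock_model`.
#' @export
clock_model <- function(name, target = c("chronological_age", "log_hazard"),
                        coefficients, intercept = 0,
                        imputation_means = NULL, sd = 0) {
  target <- match.arg(target)
  if (is.null(names(coefficients)) || anyNA(names(coefficients)) ||
      any(names(coefficients) == "")) {
    stop("`coefficients` must be a fully named numeric vector")
  }
  if (length(coefficients) < 1L) stop("a clock needs at least one feature")
  if (anyDuplicated(names(coefficients))) stop("duplicate clock feature IDs")
  if (!is.finite(intercept)) stop("`intercept` must be finite")
  if (is.null(imputation_means)) {
    imputation_means <- stats::setNames(numeric(length(coefficients)),
                                        names(coefficients))
  }
  if (!setequal(names(imputation_means), names(coefficients))) {
    stop("`imputation_means` must be keyed by the same features as `coefficients`")
  }
  imputation_means <- imputation_means[names(coefficients)]
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd < 0) {
    stop("`sd` must be a single non-negative number")
  }
  structure(
    list(name = as.character(name), target = target,
         features = names(coefficients),
         coefficients = as.numeric(stats::setNames(coefficients, names(coefficients))),
         intercept = as.numeric(intercept),
         imputation_means = as.numeric(imputation_means),
         sd = as.numeric(sd)),
    class = "clock_model"
  )
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model> %s (%s)\n", x$name, x$target))
  cat(sprintf("  %d features, %d nonzero coefficients, intercept %.4g, sd %.4g\n",
              length(x$features), sum(x$coefficients != 0), x$intercept, x$sd))
  invisible(x)
}

coef_vector <- function(clock) stats::setNames(clock$coefficients, clock$features)
impmean_vector <- function(clock) stats::setNames(clock$imputation_means, clock$features)

#' Read a clock definition file
#'
#' Two on-disk dialects are accepted: JSON with fields `name`, `target`,
#' `intercept`, `features`, `coefficients`, `imputation_means`, optional `sd`;
#' or a 3-column TSV (`feature`, `coefficient`, `imputation_mean`) preceded by
#' `#key: value` metadata lines for name/target/intercept/sd.
#'
#' @param path File path (`.json` or `.tsv`).
#' @return A [clock_model()].
#' @export
read_clock <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(clock_model(
      name = obj$name, target = obj$target,
      coefficients = stats::setNames(as.numeric(obj$coefficients), obj$features),
      intercept = obj$intercept,
      imputation_means = stats::setNames(as.numeric(obj$imputation_means), obj$features),
      sd = if (is.null(obj$sd)) 0 else obj$sd
    ))
  }
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)],
                           stringsAsFactors = FALSE)
  clock_model(
    name = if (is.null(meta$name)) basename(path) else meta$name,
    target = if (is.null(meta$target)) "chronological_age" else meta$target,
    coefficients = stats::setNames(tab$coefficient, tab$feature),
    intercept = if (is.null(meta$intercept)) 0 else as.numeric(meta$intercept),
    imputation_means = stats::setNames(tab$imputation_mean, tab$feature),
    sd = if (is.null(meta$sd)) 0 else as.numeric(meta$sd)
  )
}

#' Write a clock definition file
#'
#' @param clock A [clock_model()].
#' @param path Destination; extension selects the dialect (`.json` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_clock <- function(clock, path) {
  stopifnot(inherits(clock, "clock_model"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(name = clock$name, target = clock$target,
           intercept = clock$intercept, features = clock$features,
           coefficients = clock$coefficients,
           imputation_means = clock$imputation_means, sd = clock$sd),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    hdr <- c(sprintf("#name: %s", clock$name),
             sprintf("#target: %s", clock$target),
             sprintf("#intercept: %.17g", clock$intercept),
             sprintf("#sd: %.17g", clock$sd))
    tab <- data.frame(feature = clock$features,
                      coefficient = clock$coefficients,
                      imputation_mean = clock$imputation_means)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(format(tab, digits = 17, scientific = FALSE,
                              trim = TRUE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Predict ages (or log-hazards) with a linear clock
#'
#' Applies `intercept + sum(coef * x)` per sample. All clock features must be
#' present in the matrix; after [preprocess_for_clock()] this is guaranteed
#' because missing features are injected at their imputation means.
#'
#' @param clock A [clock_model()].
#' @param processed A [processed_matrix()] or a plain features x samples
#'   numeric matrix (methylation clocks are applied directly to beta values).
#' @return A data.frame with columns `sample_id`, `value`, `sd`, `clock`
#'   (one row per sample).
#' @export
predict_age <- function(clock, processed) {
  stopifnot(inherits(clock, "clock_model"))
  x <- if (inherits(processed, "processed_matrix")) processed$data else processed
  if (!is.matrix(x)) stop("`processed` must be a matrix or processed_matrix")
  missing <- setdiff(clock$features, rownames(x))
  if (length(missing) > 0L) {
    stop("clock features missing from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
  }
  vals <- drop(clock$intercept + crossprod(x[clock$features, , drop = FALSE],
                                           clock$coefficients))
  data.frame(sample_id = colnames(x), value = as.numeric(vals),
             sd = rep(clock$sd, ncol(x)), clock = clock$name,
             stringsAsFactors = FALSE, row.names = NULL)
}
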