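#' Default analysis thresholds
#'
#' Every threshold with a published value defaults to it; the table pairs
#' each default with the rule it encodes so configurations are auditable.
#'
#' @return data.frame with columns `name`, `value`, `rule`.
#' @export
default_thresholds <- function() {
  data.frame(
    name = c("expr_min_count", "expr_min_fraction",
             "meth_detection_p", "meth_fail_fraction",
             "droplet_rgb_min", "droplet_min_area", "border_px",
             "nucleus_max_r", "nucleus_max_g", "nucleus_max_b",
             "nucleus_max_area",
             "collagen_r_min", "collagen_r_max",
             "collagen_g_min", "collagen_g_max",
             "collagen_b_min", "collagen_b_max",
             "white_threshold", "droplet_subsample_max",
             "q_significance", "graft_mass_fraction",
             "stack_slices", "stack_step_um"),
    value = c(10, 0.2,
              0.01, 0.25,
              190, 10000, 20,
              150, 150, 200,
              5000,
              170, 220,
              190, 240,
              210, 255,
              235, 200,
              0.05, 0.01,
              41, 0.3),
    rule = c("gene kept iff >= 10 reads in >= 20% of samples",
             "gene kept iff >= 10 reads in >= 20% of samples",
             "CpG removed iff detection p > 0.01 in >= 25% of samples",
             "CpG removed iff detection p > 0.01 in >= 25% of samples",
             "droplet: mean RGB >= 190 on all channels",
             "droplet: area strictly > 10,000 px^2",
             "objects touching the border within 20 px are excluded",
             "nucleus: mean R <= 150", "nucleus: mean G <= 150",
             "nucleus: mean B <= 200",
             "nucleus: area strictly < 5,000 px^2",
             "collagen: R in [170, 220]", "collagen: R in [170, 220]",
             "collagen: G in [190, 240]", "collagen: G in [190, 240]",
             "collagen: B in [210, 255]", "collagen: B in [210, 255]",
             "white space: all channels >= 235 (package choice)",
             "droplet statistics subsample at most 200 cells",
             "BH-adjusted p < 0.05 declares significance",
             "graft mass = 1% of recipient body weight",
             "stacks standardized to 41 optical slices",
             "z-step 0.3 micrometers"),
    stringsAsFactors = FALSE)
}

config_defaults <- function() {
  th <- default_thresholds()
  list(
    seed = 1L,
    simulate = list(
      donors_per_group = 8L, sham_donors = 8L,
      young_age = 4, old_age = 18, followup_months = 2.5,
      n_batches = 2L, n_genes = 300L, clock_features = 40L,
      age_slope = 1, dispersion = 0.1,
      group_shifts = list(YY = 0, YO = 0, OY = 0, OO = 0)),
    thresholds = as.list(stats::setNames(th$value, th$name)),
    analyses = list(expression = TRUE, histology = TRUE),
    output_dir = "adipoclock_run"
  )
}

#' Build a validated run configuration
#'
#' Starts from package defaults (all published thresholds) and overrides
#' with the supplied values; unknown keys are errors, not silent typos.
#'
#' @param ... Named overrides, nested as in the defaults (e.g.
#'   `simulate = list(dispersion = 0)`).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  override <- list(...)
  cfg <- merge_config(config_defaults(), override, path = "config")
  structure(cfg, class = "run_config")
}

merge_config <- function(base, override, path) {
  if (length(override) == 0L) return(base)
  unknown <- setdiff(names(override), names(base))
  if (length(unknown) > 0L || is.null(names(override)) ||
      any(names(override) == "")) {
    stop("unknown configuration key(s) under ", path, ": ",
         paste(unknown, collapse = ", "))
  }
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]])) {
      merge_config(base[[k]], override[[k]], paste(path, k, sep = "$"))
    } else {
      override[[k]]
    }
  }
  base
}

#' Read / write a run configuration as YAML
#'
#' Round-trips losslessly through [run_config()] validation.
#'
#' @param config A `run_config`.
#' @param path YAML file.
#' @return `path` (write) or a validated `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}
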