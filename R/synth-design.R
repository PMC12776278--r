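#' Transplant study design specification
#'
#' The four-group design crosses donor and recipient age: young-to-young
#' (YY), young-to-old (YO), old-to-young (OY), old-to-old (OO), plus
#' sham-operated controls. Graft mass is normalized to a fixed fraction of
#' recipient body weight (default 1%).
#'
#' @param donors_per_group Donors per transplant group (>= 1).
#' @param sham_donors Sham-operated animals (half young, half old ages).
#' @param young_age,old_age Donor ages in months (young < old).
#' @param followup_months Months between the Before and After time points
#'   (default 2.5, i.e. 10 weeks).
#' @param graft_mass_fraction Graft mass as a fraction of recipient body
#'   weight (default 0.01).
#' @param n_batches Number of technical batches, assigned round-robin.
#' @param seed Integer seed.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(donors_per_group = 8, sham_donors = 8,
                        young_age = 4, old_age = 18,
                        followup_months = 2.5,
                        graft_mass_fraction = 0.01,
                        n_batches = 2, seed = 1L) {
  if (donors_per_group < 1) stop("donors_per_group must be >= 1")
  if (sham_donors < 1) stop("sham_donors must be >= 1")
  if (!(young_age < old_age)) stop("young_age must be less than old_age")
  if (followup_months <= 0) stop("followup_months must be positive")
  if (n_batches < 1) stop("n_batches must be >= 1")
  structure(list(donors_per_group = as.integer(donors_per_group),
                 sham_donors = as.integer(sham_donors),
                 young_age = young_age, old_age = old_age,
                 followup_months = followup_months,
                 graft_mass_fraction = graft_mass_fraction,
                 n_batches = as.integer(n_batches),
                 seed = as.integer(seed)),
            class = "design_spec")
}

TRANSPLANT_GROUPS <- c("YY", "YO", "OY", "OO")
ALL_GROUPS <- c(TRANSPLANT_GROUPS, "SHAM")

group_donor_age <- function(group, spec) {
  switch(group, YY = spec$young_age, YO = spec$young_age,
         OY = spec$old_age, OO = spec$old_age,
         stop("unknown group: ", group))
}

group_recipient_age <- function(group, spec) {
  switch(group, YY = spec$young_age, YO = spec$old_age,
         OY = spec$young_age, OO = spec$old_age,
         stop("unknown group: ", group))
}

#' Generate the transplant sample sheet
#'
#' For each donor in a transplant group three records are emitted: graft
#' tissue Before transplantation (donor age), the same graft After the
#' follow-up period (donor age + follow-up), and the recipient's untouched
#' Native tissue at endpoint (recipient age + follow-up). The `donor_id` of
#' all three records is the transplantation unit, enabling paired analysis.
#' Sham animals emit one record per time point (role `sham`), alternating
#' young and old starting ages so the sham set spans the age range needed
#' for calibration. Batches are assigned round-robin in emission order.
#'
#' @param spec A [design_spec()].
#' @return A data.frame sample sheet with columns `sample_id`, `donor_id`,
#'   `group`, `role`, `age_months`, `batch`.
#' @export
generate_design <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  if (spec$donors_per_group < 1) {
    stop("configuration error: zero donors in transplant groups")
  }
  rows <- list()
  for (g in TRANSPLANT_GROUPS) {
    for (d in seq_len(spec$donors_per_group)) {
      donor <- sprintf("%s_d%02d", g, d)
      d_age <- group_donor_age(g, spec)
      r_age <- group_recipient_age(g, spec)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s_%s", donor, c("before", "after", "native")),
        donor_id = donor, group = g,
        role = c("before", "after", "native"),
        age_months = c(d_age, d_age + spec$followup_months,
                       r_age + spec$followup_months),
        stringsAsFactors = FALSE)
    }
  }
  for (d in seq_len(spec$sham_donors)) {
    donor <- sprintf("SHAM_d%02d", d)
    base_age <- if (d %% 2L == 1L) spec$young_age else spec$old_age
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("%s_%s", donor, c("t0", "t1")),
      donor_id = donor, group = "SHAM", role = "sham",
      age_months = c(base_age, base_age + spec$followup_months),
      stringsAsFactors = FALSE)
  }
  sheet <- do.call(rbind, rows)
  sheet$batch <- sprintf("b%d", ((seq_len(nrow(sheet)) - 1L) %% spec$n_batches) + 1L)
  rownames(sheet) <- NULL
  sheet
}

#' Write / read a sample sheet CSV
#' @param sheet Sample sheet data.frame.
#' @param path CSV path.
#' @return `path` (write) or the sheet (read).
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "donor_id", "group", "role", "age_months", "batch")
  missing <- setdiff(need, names(sheet))
  if (length(missing) > 0L) {
    stop("sample sheet missing columns: ", paste(missing, collapse = ", "))
  }
  sheet
}
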