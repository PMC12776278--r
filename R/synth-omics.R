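#' Generate a random sparse linear clock
#'
#' Coefficients are drawn N(0, `coef_scale`^2) for exactly
#' `round(density * n_features)` randomly chosen features (the rest are 0);
#' imputation means are drawn N(0, 0.1^2), i.e. near 0 on the centered
#' processed scale.
#'
#' @param n_features Number of clock features.
#' @param density Fraction of nonzero coefficients, in (0, 1].
#' @param coef_scale Coefficient scale (>= 0; 0 gives an intercept-only clock).
#' @param intercept Clock intercept.
#' @param target `"chronological_age"` or `"log_hazard"`.
#' @param feature_prefix Prefix for generated feature IDs.
#' @param sd Prediction sd stored in the clock metadata.
#' @param seed Integer seed.
#' @return A [clock_model()].
#' @export
generate_linear_clock <- function(n_features, density = 1, coef_scale = 1,
                                  intercept = 0,
                                  target = "chronological_age",
                                  feature_prefix = "g", sd = 0, seed = 1L) {
  if (n_features < 1) stop("n_features must be >= 1")
  if (!(density > 0 && density <= 1)) stop("density must be in (0, 1]")
  if (coef_scale < 0) stop("coef_scale must be >= 0")
  local_rng(seed)
  features <- sprintf("%s%04d", feature_prefix, seq_len(n_features))
  n_nz <- max(1L, round(density * n_features))
  coefs <- stats::setNames(numeric(n_features), features)
  nz <- sample(n_features, n_nz)
  coefs[nz] <- stats::rnorm(n_nz, 0, 1) * coef_scale
  imp <- stats::setNames(stats::rnorm(n_features, 0, 0.1), features)
  clock_model(name = sprintf("synthetic_clock_s%d", seed), target = target,
              coefficients = coefs, intercept = intercept,
              imputation_means = imp, sd = sd)
}

# Seed-scoped RNG: every generator draws from its own stream and restores the
# caller's random state when the calling function exits (no global-state
# leakage between calls).
local_rng <- function(seed, envir = parent.frame()) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  withr::defer({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, envir = envir)
  set.seed(as.integer(seed))
  invisible(NULL)
}

# Orthonormal signal basis on the sample axis: returns vectors with empirical
# mean 0 and sd 1 (n-1 denominator), pairwise orthogonal, the first aligned
# with the planted signal. Z-scaling then reproduces any unit combination of
# them exactly, which is what makes the count-space inversion exact.
signal_basis <- function(signal, n_aux = 2L) {
  n <- length(signal)
  if (n < n_aux + 2L) stop("need at least ", n_aux + 2L, " samples to plant signal")
  norm1 <- function(v) v / stats::sd(v)
  proj_out <- function(v, basis) {
    v <- v - mean(v)
    for (b in basis) v <- v - sum(v * b) / sum(b * b) * b
    v
  }
  r <- norm1(signal - mean(signal))
  basis <- list(r)
  k <- 0L
  attempt <- 1L
  while (k < n_aux) {
    cand <- proj_out(sin(seq_len(n) * attempt * 0.7391 + attempt), basis)
    attempt <- attempt + 1L
    if (attempt > 50L) stop("failed to construct auxiliary directions")
    if (stats::sd(cand) < 1e-8) next
    basis[[length(basis) + 1L]] <- norm1(cand)
    k <- k + 1L
  }
  basis
}

# Per-gene mixing weights (alpha on the signal direction, beta1/beta2 on the
# auxiliary plane) such that every row is unit-variance and the
# coefficient-weighted sum of rows is exactly sd(signal) * r-tilde:
#   sum_g c_g alpha_g = sigma_t   and   sum_g c_g (beta1, beta2)_g = (0, 0).
# alpha_g = a * sign(c_g) with a = sigma_t / sum|c|; the residual unit mass
# sqrt(1 - a^2) per gene is laid out on a closed polygon (3-bin triangle
# construction) in the auxiliary plane so the contamination cancels exactly.
plant_weights <- function(coefs, sigma_t) {
  nz <- which(coefs != 0)
  m <- length(nz)
  cs <- coefs[nz]
  total <- sum(abs(cs))
  if (sigma_t > total + 1e-12) {
    stop(sprintf(paste0("clock coefficient mass (%.3g) too small for the ",
                        "requested signal spread (%.3g); increase coef_scale ",
                        "or clock density"), total, sigma_t))
  }
  if (m < 2L) {
    stop("need at least 2 nonzero clock coefficients to plant an exact signal")
  }
  alpha <- beta1 <- beta2 <- numeric(length(coefs))
  if (m == 2L) {
    # exact 2-gene solve: c1*a1 + c2*a2 = sigma_t, c1*b1 + c2*b2 = 0,
    # a_i^2 + b_i^2 = 1; parameterized by b1 with roles ordered |c1| <= |c2|
    ord <- order(abs(cs))
    c1 <- cs[ord[1]]; c2 <- cs[ord[2]]
    sol <- NULL
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
      f <- function(b) {
        s1 * c1 * sqrt(pmax(0, 1 - b^2)) +
          s2 * c2 * sqrt(pmax(0, 1 - (c1 / c2)^2 * b^2)) - sigma_t
      }
      lo <- f(0); hi <- f(1)
      if (is.finite(lo) && is.finite(hi) && lo * hi <= 0) {
        b <- stats::uniroot(f, c(0, 1), tol = 1e-14)$root
        sol <- list(a1 = s1 * sqrt(max(0, 1 - b^2)), b1 = b,
                    a2 = s2 * sqrt(max(0, 1 - (c1 / c2)^2 * b^2)),
                    b2 = -(c1 / c2) * b)
        break
      }
      if (!is.null(sol)) break
    }
    if (is.null(sol)) {
      stop("cannot plant the requested signal with only two clock ",
           "coefficients of these magnitudes")
    }
    alpha[nz[ord]] <- c(sol$a1, sol$a2)
    beta1[nz[ord]] <- c(sol$b1, sol$b2)
    return(list(alpha = alpha, beta1 = beta1, beta2 = beta2))
  }
  a <- min(sigma_t / total, 1)
  rho <- sqrt(max(0, 1 - a^2))
  alpha[nz] <- a * sign(cs)
  if (rho > 0) {
    L <- abs(cs) * rho
    if (max(L) > sum(L) - max(L) + 1e-12) {
      stop("one clock coefficient dominates all others; cannot cancel the ",
           "auxiliary contamination (add features or reduce sparsity)")
    }
    # balanced 3-bin split of the auxiliary mass; the three bin sums obey the
    # triangle inequality, so their vectors can close a triangle exactly
    bins <- rep(NA_integer_, m)
    ord <- order(L, decreasing = TRUE)
    sums <- c(0, 0, 0)
    for (i in ord) {
      b <- which.min(sums)
      bins[i] <- b
      sums[b] <- sums[b] + L[i]
    }
    s <- sums
    cosg <- (s[3]^2 - s[1]^2 - s[2]^2) / (2 * s[1] * s[2])
    cosg <- min(1, max(-1, cosg))
    ang2 <- acos(cosg)
    dirs <- rbind(c(1, 0), c(cos(ang2), sin(ang2)), c(0, 0))
    dirs[3, ] <- -(s[1] * dirs[1, ] + s[2] * dirs[2, ]) / s[3]
    # w_g = c_g * (beta1, beta2)_g has length L_g along its bin's direction
    for (i in seq_len(m)) {
      w <- L[i] * dirs[bins[i], ]
      beta1[nz[i]] <- w[1] / cs[i]
      beta2[nz[i]] <- w[2] / cs[i]
    }
  }
  list(alpha = alpha, beta1 = beta1, beta2 = beta2)
}

#' Simulate a bulk RNA-seq count matrix with planted clock signal
#'
#' Clock genes are modulated on the standardized (processed) scale so that
#' the clockcore pipeline (RLE -> log2 -> z-scale -> impute -> center to the
#' young-before median) reproduces the planted per-sample clock signal
#' exactly at zero dispersion. The planted signal is
#' `age_slope * age + delta_g` for After samples (`delta_g` from
#' `group_shifts`) and `age_slope * age` otherwise; because per-feature
#' standardization removes absolute location, the recorded truth is the
#' analytically planted prediction, whose Before/After differences equal the
#' requested shifts in absolute clock units.
#'
#' Background genes are constant across samples (so RLE size factors equal
#' the simulated library-size factors exactly); a subset can carry a planted
#' Before->After log2 fold change via `de_lfc` for differential-expression
#' tests. Counts are negative binomial with `Var = mu + dispersion * mu^2`;
#' `dispersion = 0` gives deterministic means (rounded unless
#' `round_counts = FALSE`).
#'
#' @param design Sample sheet from [generate_design()].
#' @param clock A [clock_model()] whose features are a subset of the
#'   simulated gene set.
#' @param n_genes Total genes simulated (>= number of clock features).
#' @param age_slope Clock units per month of chronological age.
#' @param group_shifts Named numeric vector of Before->After shifts delta_g
#'   (clock units) per transplant group, e.g. `c(OY = -5)`.
#' @param dispersion NB dispersion phi (>= 0).
#' @param libsize_range Relative library-size range (positive length-2).
#' @param amplitude Log2 expression amplitude of clock genes per unit of
#'   standardized signal (default 2).
#' @param de_lfc Optional named vector of planted log2 fold changes
#'   (After - Before) for background genes; names must not collide with
#'   clock features.
#' @param round_counts Round means to integers at `dispersion = 0`
#'   (default TRUE; set FALSE for exact round-trip checks).
#' @param seed Integer seed.
#' @return A list with `counts` (genes x samples integer matrix), and
#'   `truth`: `samples` (sample_id, true_signal), `group_shifts`,
#'   `gene_lfc` (planted per-gene log2 fold change), `reference_samples`
#'   (the young-before centering reference), `clock_genes`, `seed`.
#' @export
simulate_expression <- function(design, clock, n_genes = 300,
                                age_slope = 1,
                                group_shifts = c(YY = 0, YO = 0, OY = 0, OO = 0),
                                dispersion = 0.1,
                                libsize_range = c(0.7, 1.3),
                                amplitude = 2,
                                de_lfc = NULL,
                                round_counts = TRUE,
                                seed = 1L) {
  stopifnot(is.data.frame(design))
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (length(libsize_range) != 2L || any(libsize_range <= 0)) {
    stop("libsize_range must be two positive numbers")
  }
  if (length(clock$features) > n_genes) {
    stop("clock features exceed the number of simulated genes")
  }
  local_rng(seed)
  n <- nrow(design)
  shifts <- group_shifts[match(design$group, names(group_shifts))]
  shifts[is.na(shifts)] <- 0
  raw <- age_slope * design$age_months +
    ifelse(design$role == "after", shifts, 0)

  genes <- clock$features
  n_bg <- n_genes - length(genes)
  bg <- sprintf("bg%04d", seq_len(n_bg))
  if (!is.null(de_lfc)) {
    if (!all(names(de_lfc) %in% bg)) {
      stop("de_lfc genes must be background genes (bg0001 ...)")
    }
  }
  all_genes <- c(genes, bg)

  # clock genes are kept well-expressed so integer rounding of counts is a
  # negligible perturbation on the log2 scale
  base_clock <- stats::runif(length(genes), 8, 11)
  base_bg <- stats::runif(n_bg, 2, 9)
  if (!is.null(de_lfc)) {
    # genes carrying planted fold changes are kept well-expressed so the
    # pseudo-count and integer rounding do not distort the planted logFC
    base_bg[match(names(de_lfc), bg)] <- stats::runif(length(de_lfc), 6, 9)
  }
  log2mu <- matrix(rep(c(base_clock, base_bg), n), nrow = n_genes,
                   dimnames = list(all_genes, design$sample_id))

  reference <- design$sample_id[design$role == "before" &
                                  design$age_months == min(design$age_months)]
  sigma_t <- stats::sd(raw)
  truth_signal <- rep(clock$intercept, n)
  if (sigma_t > 1e-12) {
    basis <- signal_basis(raw)
    w <- plant_weights(coef_vector(clock), sigma_t)
    U <- outer(w$alpha, basis[[1]]) + outer(w$beta1, basis[[2]]) +
      outer(w$beta2, basis[[3]])
    rownames(U) <- genes
    log2mu[genes, ] <- log2mu[genes, ] + amplitude * U
    ref_idx <- match(reference, design$sample_id)
    M <- sum(clock$coefficients *
               apply(U[, ref_idx, drop = FALSE], 1, stats::median))
    truth_signal <- clock$intercept + sigma_t * basis[[1]] - M
  }
  if (!is.null(de_lfc)) {
    after <- design$role == "after"
    for (g in names(de_lfc)) {
      log2mu[g, after] <- log2mu[g, after] + de_lfc[[g]]
    }
  }

  # log2mu is the target of the pipeline's log2(normalized + 1), so mean
  # counts are factor * (2^log2mu - 1); library-size factors are normalized
  # to unit geometric mean so that RLE estimates them exactly (background
  # genes, the majority, are constant across samples)
  libsize <- stats::runif(n, libsize_range[1], libsize_range[2])
  libsize <- libsize / exp(mean(log(libsize)))
  mu <- sweep(2^log2mu - 1, 2, libsize, "*")
  if (dispersion == 0) {
    counts <- if (round_counts) round(mu) else mu
  } else {
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                     nrow = n_genes, dimnames = dimnames(mu))
  }

  gene_lfc <- stats::setNames(numeric(n_genes), all_genes)
  if (!is.null(de_lfc)) gene_lfc[names(de_lfc)] <- de_lfc
  list(counts = counts,
       truth = list(
         samples = data.frame(sample_id = design$sample_id,
                              true_signal = truth_signal,
                              stringsAsFactors = FALSE),
         group_shifts = group_shifts,
         gene_lfc = gene_lfc,
         reference_samples = reference,
         clock_genes = genes,
         seed = as.integer(seed)))
}

#' Simulate a methylation beta matrix with planted clock signal
#'
#' Beta values are planted so that direct application of the (linear)
#' methylation clock to the beta matrix returns the planted per-sample
#' signal exactly at `noise_sd = 0`, up to \[0,1\] clipping. A configurable
#' fraction of entries is given detection p-values above 0.01 to exercise
#' the detection filter.
#'
#' @param design Sample sheet from [generate_design()].
#' @param clock A [clock_model()] over CpG features.
#' @param age_slope Clock units per month.
#' @param group_shifts Named Before->After shifts per group (clock units).
#' @param noise_sd Gaussian noise sd added to beta values (>= 0).
#' @param detp_fail_fraction Fraction of entries with detection p > 0.01.
#' @param n_extra_cpgs Additional non-clock CpGs (beta ~ U(0,1) constants).
#' @param seed Integer seed.
#' @return List with `beta`, `detection_p` (same shape) and `truth`
#'   (`samples` with true_signal and a `clipped` flag, `seed`).
#' @export
simulate_methylation <- function(design, clock, age_slope = 1,
                                 group_shifts = c(YY = 0, YO = 0, OY = 0, OO = 0),
                                 noise_sd = 0, detp_fail_fraction = 0,
                                 n_extra_cpgs = 50, seed = 1L) {
  stopifnot(is.data.frame(design))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  local_rng(seed)
  n <- nrow(design)
  shifts <- group_shifts[match(design$group, names(group_shifts))]
  shifts[is.na(shifts)] <- 0
  t_s <- age_slope * design$age_months +
    ifelse(design$role == "after", shifts, 0)

  cg <- clock$features
  m_g <- stats::runif(length(cg), 0.35, 0.65)
  cvec <- clock$coefficients
  ssq <- sum(cvec^2)
  if (ssq == 0) {
    beta_clock <- matrix(rep(m_g, n), nrow = length(cg))
    truth <- rep(clock$intercept + sum(cvec * m_g), n)
  } else {
    c0 <- clock$intercept + sum(cvec * m_g)
    beta_clock <- outer(m_g, rep(1, n)) + outer(cvec / ssq, t_s - c0)
    truth <- t_s
  }
  extra <- matrix(rep(stats::runif(n_extra_cpgs, 0, 1), n), nrow = n_extra_cpgs)
  beta <- rbind(beta_clock, extra)
  rownames(beta) <- c(cg, sprintf("cgx%04d", seq_len(n_extra_cpgs)))
  colnames(beta) <- design$sample_id
  if (noise_sd > 0) beta <- beta + stats::rnorm(length(beta), 0, noise_sd)
  clipped <- beta < 0 | beta > 1
  beta <- pmin(pmax(beta, 0), 1)

  detp <- matrix(stats::runif(length(beta), 0, 0.01), nrow = nrow(beta),
                 dimnames = dimnames(beta))
  if (detp_fail_fraction > 0) {
    fail <- stats::runif(length(detp)) < detp_fail_fraction
    detp[fail] <- stats::runif(sum(fail), 0.011, 0.5)
  }
  list(beta = beta, detection_p = detp,
       truth = list(samples = data.frame(sample_id = design$sample_id,
                                         true_signal = truth,
                                         clipped = colSums(clipped[seq_along(cg), ,
                                                                   drop = FALSE]) > 0,
                                         stringsAsFactors = FALSE),
                    seed = as.integer(seed)))
}
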