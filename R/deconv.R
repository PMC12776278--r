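# Vectorized OLS over a gene x sample response matrix: fits Y_g ~ X for all
# genes at once and returns estimate/se/p for one focal column of X.
matrix_lm_term <- function(Y, X, term) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop("rank-deficient model matrix (collinear covariates)")
  coefs <- qr.coef(qr_x, t(Y))                      # p x genes
  fitted <- X %*% coefs
  res <- t(Y) - fitted
  df <- nrow(X) - ncol(X)
  if (df < 1L) stop("no residual degrees of freedom")
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  j <- match(term, colnames(X))
  if (is.na(j)) stop("term not found in model matrix: ", term)
  est <- coefs[j, ]
  se <- sqrt(sigma2 * xtx_inv[j, j])
  tstat <- ifelse(se > 0, est / se, 0)
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[se == 0 & est != 0] <- 0
  p[se == 0 & est == 0] <- 1
  list(estimate = est, se = se, p = p, df = df)
}

#' Paired differential expression on log2-CPM
#'
#' Per gene, fits `log2CPM ~ stage + donor` over the Before/After samples of
#' one experimental group and reports the stage coefficient as logFC with
#' its t-test p-value and BH-adjusted p across genes. CPM values are counts
#' per million after RLE size-factor normalization with a 0.5 pseudo-count.
#' The paired linear model targets the same scientific quantity as a
#' count-model fit (the within-donor stage effect) on the log scale.
#'
#' @param counts Filtered genes x samples count matrix (one group's
#'   Before/After samples).
#' @param design Matching sample sheet rows (columns `sample_id`,
#'   `donor_id`, `role` with values before/after).
#' @return data.frame with `gene`, `logFC`, `p`, `p_adj`, sorted as input.
#' @export
paired_de <- function(counts, design) {
  design <- design[design$role %in% c("before", "after"), ]
  counts <- counts[, design$sample_id, drop = FALSE]
  if (length(unique(design$donor_id)) < 2L) stop("need at least two donors")
  y <- log2_cpm(counts)
  stage <- factor(design$role, levels = c("before", "after"))
  donor <- factor(design$donor_id)
  X <- stats::model.matrix(~ stage + donor)
  fit <- matrix_lm_term(y, X, "stageafter")
  data.frame(gene = rownames(counts), logFC = unname(fit$estimate),
             p = unname(fit$p), p_adj = bh_adjust(unname(fit$p)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' log2 counts-per-million after RLE normalization
#' @param counts Count matrix.
#' @param pseudo Pseudo-count added before the log (default 0.5).
#' @return Matrix of log2-CPM values.
#' @export
log2_cpm <- function(counts, pseudo = 0.5) {
  norm <- rle_normalize(counts)
  log2(sweep(norm + pseudo, 2, colSums(norm) / 1e6, "/"))
}

#' Per-gene contributions to a clock's predicted age change
#'
#' Decomposes the Before->After change in clock-predicted age into additive
#' per-gene contributions: for each clock feature,
#' `contribution = coefficient * (mean processed After - mean processed
#' Before)`. By linearity of the clock the contributions sum exactly to the
#' prediction difference between the mean profiles (conservation identity).
#' Optionally, externally supplied per-gene logFC values (e.g. from
#' [paired_de()]) may replace the processed-scale mean differences; the sum
#' then no longer obeys the exact identity (documented in the output).
#'
#' @param processed A [processed_matrix()] covering all clock features.
#' @param design Sample sheet rows for one group with roles before/after.
#' @param clock A [clock_model()].
#' @param lfc Optional named per-gene log fold changes replacing the
#'   processed-scale deltas.
#' @param de Optional [paired_de()] result; its `p_adj` is joined onto the
#'   contribution table as inherited significance.
#' @return A list: `contributions` (data.frame gene, delta, coefficient,
#'   contribution, and `p_adj` if `de` given), `total` (sum of
#'   contributions), `exact` (TRUE iff the conservation identity holds by
#'   construction).
#' @export
gene_contributions <- function(processed, design, clock, lfc = NULL, de = NULL) {
  x <- if (inherits(processed, "processed_matrix")) processed$data else processed
  missing <- setdiff(clock$features, rownames(x))
  if (length(missing) > 0L) {
    stop("clock features missing from processed matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  before <- design$sample_id[design$role == "before"]
  after <- design$sample_id[design$role == "after"]
  if (length(before) == 0L || length(after) == 0L) {
    stop("need both Before and After samples")
  }
  delta <- rowMeans(x[clock$features, after, drop = FALSE]) -
    rowMeans(x[clock$features, before, drop = FALSE])
  exact <- is.null(lfc)
  if (!is.null(lfc)) {
    idx <- match(clock$features, names(lfc))
    if (anyNA(idx)) stop("lfc missing for some clock features")
    delta <- as.numeric(lfc[idx])
  }
  tab <- data.frame(gene = clock$features, delta = unname(delta),
                    coefficient = clock$coefficients,
                    contribution = clock$coefficients * unname(delta),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(de)) tab$p_adj <- de$p_adj[match(tab$gene, de$gene)]
  list(contributions = tab, total = sum(tab$contribution), exact = exact)
}

#' Signed log-p ranking metric
#'
#' `-log(p) * sgn(lfc)` with `sgn(0) = 0`; the log base defaults to natural
#' log. Zero p-values are clamped to the smallest positive double with a
#' warning.
#'
#' @param p P-values in (0, 1\].
#' @param lfc Log fold changes (same length).
#' @param base Log base (default `exp(1)`).
#' @return Numeric vector of signed scores.
#' @export
ranking_metric <- function(p, lfc, base = exp(1)) {
  if (length(p) != length(lfc)) stop("p and lfc must be aligned")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (any(p == 0, na.rm = TRUE)) {
    warning("zero p-values clamped to the smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  -log(p, base = base) * sign(lfc)
}

#' Screen genes for association with tissue-age dynamics
#'
#' Per gene, regresses expression on the donor-level tAge change
#' (`dtage`, entering the model as `dtage x 1[stage == after]`, the
#' identifiable encoding of a donor-level dynamic covariate alongside donor
#' fixed effects), with transplantation stage and donor ID as covariates.
#' Reports the dtage-term estimate, p and BH q; genes with q below
#' `q_threshold` form the significant set, ordered by q, then |estimate|,
#' then gene ID.
#'
#' @param y Genes x samples matrix of expression values (e.g. log2-CPM or
#'   clock-processed values) over Before/After samples.
#' @param dtage Named per-donor tAge differences (clock units).
#' @param design Matching sample sheet rows (`sample_id`, `donor_id`,
#'   `role`).
#' @param q_threshold Significance cutoff on adjusted p (default 0.05).
#' @return A list: `table` (gene, estimate, se, p, q), `significant`
#'   (ordered gene IDs with q < threshold).
#' @export
tage_association_screen <- function(y, dtage, design, q_threshold = 0.05) {
  design <- design[design$role %in% c("before", "after"), ]
  y <- y[, design$sample_id, drop = FALSE]
  idx <- match(design$donor_id, names(dtage))
  if (anyNA(idx)) stop("dtage missing for donors: ",
                       paste(unique(design$donor_id[is.na(idx)]), collapse = ", "))
  d <- as.numeric(dtage[idx]) * (design$role == "after")
  stage <- factor(design$role, levels = c("before", "after"))
  donor <- factor(design$donor_id)
  X <- stats::model.matrix(~ d + stage + donor)
  fit <- matrix_lm_term(y, X, "d")
  tab <- data.frame(gene = rownames(y), estimate = unname(fit$estimate),
                    se = unname(fit$se), p = unname(fit$p),
                    q = bh_adjust(unname(fit$p)),
                    stringsAsFactors = FALSE, row.names = NULL)
  sig <- tab[tab$q < q_threshold, ]
  sig <- sig[order(sig$q, -abs(sig$estimate), sig$gene), ]
  list(table = tab, significant = sig$gene)
}

#' Fisher-exact pathway over-representation
#'
#' One-sided hypergeometric test of over-representation of `hits` in each
#' pathway relative to `universe`, with BH adjustment across pathways.
#' Run separately for positively and negatively associated gene sets.
#'
#' @param hits Character vector of significant genes (subset of universe).
#' @param universe Character vector of all tested genes.
#' @param pathways Named list of character vectors (pathway members), e.g.
#'   from [read_gmt()].
#' @param q_threshold Significance cutoff on adjusted p (default 0.05).
#' @return data.frame: pathway, overlap, pathway_size, odds_ratio, p, q,
#'   significant; ordered by q then pathway name.
#' @export
fisher_enrichment <- function(hits, universe, pathways, q_threshold = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  hits <- unique(hits)
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  N <- length(universe); k <- length(hits)
  rows <- lapply(names(pathways), function(pw) {
    members <- intersect(pathways[[pw]], universe)
    m <- length(members)
    q <- length(intersect(hits, members))
    p <- if (m == 0L) 1 else stats::phyper(q - 1, m, N - m, k, lower.tail = FALSE)
    or <- (q * (N - m - k + q)) / max(1e-300, (m - q) * (k - q))
    data.frame(pathway = pw, overlap = q, pathway_size = m,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < q_threshold
  out[order(out$q, out$pathway), ]
}

#' Pairwise Pearson correlation of aligned gene vectors
#'
#' Inner-joins the named vectors on shared gene IDs, then computes the
#' pairwise Pearson correlation matrix with two-sided p-values from the t
#' transform and BH adjustment over the upper triangle.
#'
#' @param vectors Named list of named numeric vectors (e.g. per-group gene
#'   contributions).
#' @return A list: `r` (correlation matrix, unit diagonal), `p` (two-sided
#'   p-values; diagonal 0, flagged), `q` (BH over distinct pairs),
#'   `n_shared` (genes used), `self_p_flag`.
#' @export
correlation_compare <- function(vectors) {
  stopifnot(is.list(vectors), length(vectors) >= 1L)
  shared <- Reduce(intersect, lapply(vectors, names))
  if (length(shared) < 3L) stop("fewer than 3 shared genes across vectors")
  mat <- sapply(vectors, function(v) as.numeric(v[shared]))
  r <- stats::cor(mat)
  n <- length(shared)
  tstat <- r * sqrt((n - 2) / pmax(1e-300, 1 - r^2))
  p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  diag(p) <- 0
  q <- matrix(NA_real_, nrow(r), ncol(r), dimnames = dimnames(r))
  ut <- upper.tri(r)
  if (any(ut)) {
    q[ut] <- bh_adjust(p[ut])
    q[lower.tri(q)] <- t(q)[lower.tri(q)]
  }
  list(r = r, p = p, q = q, n_shared = n,
       self_p_flag = "diagonal and |r|=1 p-values reported as 0")
}

#' Read a GMT pathway file
#'
#' @param path GMT file (tab-separated: pathway, description, members...).
#' @return Named list of member-gene character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  out
}

#' Write a GMT pathway file
#' @param pathways Named list of gene vectors.
#' @param path Destination file.
#' @param descriptions Optional named descriptions (default "na").
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path, descriptions = NULL) {
  lines <- vapply(names(pathways), function(pw) {
    desc <- if (is.null(descriptions)) "na" else descriptions[[pw]]
    paste(c(pw, desc, pathways[[pw]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
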