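#' Scan configuration
#'
#' Aggregates every tuning constant of the two-stage analysis. Defaults are
#' the pipeline's standard operating point: LD expansion at r2 > 0.5,
#' +/-1 Mb stage-1 interval windows, +/-1.1 Mb stage-2 gene windows, a median
#' count filter at 14, SNP QC at call rate 0.95 / HWE 1e-5 / MAF 0.01, and
#' expression PCs kept above 1% variance explained.
#'
#' @param alpha family-wise significance level for Bonferroni control.
#' @param r2_expand LD-expansion threshold (strict).
#' @param flank_stage1 stage-1 window half-width around interval spans (bp).
#' @param flank_stage2 stage-2 window half-width around gene TSS/TES (bp).
#' @param median_min expression median-count filter.
#' @param maf_min,callrate_min,hwe_min SNP QC thresholds.
#' @param pc_var_min expression-PC variance-explained threshold.
#' @param ld_search_flank search radius for LD partners of a risk SNP (bp).
#' @param collinear_r2 r2 above which a SNP is treated as collinear with the
#'   conditioning peak.
#' @param drop_log10,r2_link minimal-region rule: SNPs within `drop_log10`
#'   of the peak -log10 p and with r2 > `r2_link` to the peak.
#' @param proximity_bp peak-to-TSS/TES proximity flag distance.
#' @return list of class `scan_config`.
#' @export
scan_config <- function(alpha = 0.05, r2_expand = 0.5, flank_stage1 = 1e6,
                        flank_stage2 = 1.1e6, median_min = 14, maf_min = 0.01,
                        callrate_min = 0.95, hwe_min = 1e-5, pc_var_min = 0.01,
                        ld_search_flank = 2e6, collinear_r2 = 0.99,
                        drop_log10 = 2, r2_link = 0.5, proximity_bp = 2e4) {
  check_fraction(alpha, "alpha", 0, 1, open_lo = TRUE, open_hi = TRUE)
  check_fraction(r2_expand, "r2_expand", 0, 1, open_lo = TRUE)
  if (flank_stage1 <= 0 || flank_stage2 <= 0)
    stopf("flanks must be positive", class = "invalid_argument")
  structure(list(alpha = alpha, r2_expand = r2_expand, flank_stage1 = flank_stage1,
                 flank_stage2 = flank_stage2, median_min = median_min,
                 maf_min = maf_min, callrate_min = callrate_min, hwe_min = hwe_min,
                 pc_var_min = pc_var_min, ld_search_flank = ld_search_flank,
                 collinear_r2 = collinear_r2, drop_log10 = drop_log10,
                 r2_link = r2_link, proximity_bp = proximity_bp),
            class = "scan_config")
}

#' Project out covariates
#'
#' Returns `M - C (C'C)^-1 C' M`: each column of `M` replaced by its
#' least-squares residual on the covariate matrix. The operation is
#' idempotent and the residuals are orthogonal to every covariate column.
#'
#' @param M numeric matrix, samples x features.
#' @param C covariate matrix including the intercept column, full column
#'   rank, rows aligned with `M`.
#' @return residual matrix of the same shape as `M`.
#' @export
residualize <- function(M, C) {
  M <- as.matrix(M); C <- as.matrix(C)
  if (nrow(M) != nrow(C)) stopf("row mismatch between M and C", class = "invalid_argument")
  qc <- qr(C)
  if (qc$rank < ncol(C)) {
    dep <- qc$pivot[-seq_len(qc$rank)]
    nm <- colnames(C)[dep] %||% as.character(dep)
    stopf("covariate matrix is rank deficient (dependent column(s): %s)",
          paste(nm, collapse = ", "), class = "collinearity_error")
  }
  qr.resid(qc, M)
}

#' Fast residual-correlation association scan
#'
#' The matrix-eQTL computation: on genotype and expression residuals (both
#' projected on the same covariates), the per-pair slope is
#' `cov(g, e) / var(g)` and the t statistic is `r * sqrt(df) / sqrt(1 - r^2)`
#' with `df = n - n_covariates - 2`, which is exactly the full-model OLS t
#' for the genotype term by the Frisch--Waugh--Lovell identity. Pairs whose
#' residual genotype has (numerically) zero variance are flagged untestable
#' and carry NA statistics.
#'
#' @param G_resid residualized dosage matrix, samples x SNPs (named columns).
#' @param E_resid residualized expression matrix, samples x genes.
#' @param n_covariates number of covariate columns projected out, excluding
#'   the intercept.
#' @param pairs optional data frame with columns `snp`, `gene` (column names
#'   of `G_resid` / `E_resid`); default all pairs.
#' @return data frame: `snp_id`, `gene_id`, `beta`, `se`, `t_stat`,
#'   `p_value`, `n_samples`, `df`, `untestable`.
#' @export
assoc_scan_fast <- function(G_resid, E_resid, n_covariates = 0L, pairs = NULL) {
  G_resid <- as.matrix(G_resid); E_resid <- as.matrix(E_resid)
  n <- nrow(G_resid)
  if (nrow(E_resid) != n) stopf("sample mismatch", class = "invalid_argument")
  df <- n - n_covariates - 2L
  if (df < 1) stopf("non-positive residual degrees of freedom", class = "invalid_argument")
  ssg <- colSums(G_resid^2); sse <- colSums(E_resid^2)
  if (is.null(pairs)) {
    pairs <- expand.grid(snp = seq_len(ncol(G_resid)), gene = seq_len(ncol(E_resid)),
                         KEEP.OUT.ATTRS = FALSE)
    cp <- crossprod(G_resid, E_resid)
    cps <- cp[cbind(pairs$snp, pairs$gene)]
    si <- pairs$snp; gi <- pairs$gene
  } else {
    si <- if (is.numeric(pairs$snp)) pairs$snp else match(pairs$snp, colnames(G_resid))
    gi <- if (is.numeric(pairs$gene)) pairs$gene else match(pairs$gene, colnames(E_resid))
    if (anyNA(si) || anyNA(gi)) stopf("pair refers to unknown column", class = "invalid_argument")
    cps <- colSums(G_resid[, si, drop = FALSE] * E_resid[, gi, drop = FALSE])
  }
  tol <- 1e-12 * n
  untestable <- ssg[si] <= tol | sse[gi] <= 0
  beta <- cps / ssg[si]
  r2 <- pmin(cps^2 / (ssg[si] * sse[gi]), 1)
  one_m <- pmax(1 - r2, 0)
  t_stat <- sign(cps) * sqrt(r2 * df) / sqrt(pmax(one_m, 1e-300))
  se <- sqrt(one_m * sse[gi] / (df * ssg[si]))
  p <- 2 * stats::pt(-abs(t_stat), df)
  p <- pmax(p, .Machine$double.xmin)
  beta[untestable] <- se[untestable] <- t_stat[untestable] <- p[untestable] <- NA_real_
  data.frame(
    snp_id = colnames(G_resid)[si] %||% as.character(si),
    gene_id = colnames(E_resid)[gi] %||% as.character(gi),
    beta = beta, se = se, t_stat = t_stat, p_value = p,
    n_samples = n, df = df, untestable = untestable,
    stringsAsFactors = FALSE
  )
}

#' Single-pair OLS oracle
#'
#' Fits the full linear model `e ~ intercept + g + C` by QR and returns the
#' genotype coefficient's slope, standard error, t and two-sided p with
#' explicit `n - k - 2` residual degrees of freedom. This is the independent
#' reference against which [assoc_scan_fast()] is verified.
#'
#' @param g dosage vector; `e` expression vector; `C` optional covariate
#'   matrix (no intercept column).
#' @param e response vector.
#' @param C optional covariate matrix.
#' @return one-row data frame with the [assoc_scan_fast()] schema.
#' @export
assoc_ols_oracle <- function(g, e, C = NULL) {
  X <- cbind(`(Intercept)` = 1, g = g)
  if (!is.null(C)) X <- cbind(X, as.matrix(C))
  n <- length(e)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stopf("singular design (collinear genotype or covariate)",
          class = "collinearity_error")
  coefs <- qr.coef(qx, e)
  res <- e - X %*% coefs
  df <- n - ncol(X)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  t <- coefs[["g"]] / se
  p <- max(2 * stats::pt(-abs(t), df), .Machine$double.xmin)
  data.frame(snp_id = "g", gene_id = "e", beta = coefs[["g"]], se = se, t_stat = t,
             p_value = p, n_samples = n, df = df, untestable = FALSE,
             stringsAsFactors = FALSE)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise level in (0, 1).
#' @param n_tests number of tests actually performed (untestable pairs
#'   excluded), >= 1.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  check_fraction(alpha, "alpha", 0, 1, open_lo = TRUE, open_hi = TRUE)
  if (!is_count(n_tests, 1L)) stopf("n_tests must be >= 1", class = "invalid_argument")
  alpha / n_tests
}

# mean-imputed numeric dosage matrix with SNP-id column names
dosage_matrix <- function(G) {
  D <- apply(G$dosage, 2L, impute_mean)
  colnames(D) <- G$snp_meta$id
  rownames(D) <- G$sample_ids
  D
}

# covariate design with intercept, from NULL / matrix / data.frame
design_with_intercept <- function(C, n) {
  if (is.null(C) || (!is.null(dim(C)) && ncol(as.matrix(C)) == 0L))
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  C <- as.matrix(C)
  cbind(`(Intercept)` = 1, C)
}

#' Stage-1 scan: LD-SNPs of each risk interval against in-window genes
#'
#' Tests every LD-SNP of every risk interval against every expressed gene
#' whose body overlaps the interval span widened by `flank_stage1`, using the
#' fast residual scan, and applies one Bonferroni threshold across all
#' testable pairs of all intervals. Genes with a significant pair are the
#' interval's target genes.
#'
#' @param G a post-QC [genotype_matrix()].
#' @param N a [normalize_counts()] result on the filtered genes.
#' @param C covariate matrix or data frame (samples x k, no intercept), or
#'   NULL.
#' @param intervals a [build_risk_intervals()] result.
#' @param cfg a [scan_config()].
#' @return list of class `eqtl_stage1`: `results` (association rows plus
#'   `interval_id`, `stage`, `significant`, `threshold_used`), `threshold`,
#'   `n_tests`, `interval_summary` (per interval: tests, significance flag,
#'   target genes).
#' @export
stage1_scan <- function(G, N, C = NULL, intervals, cfg = scan_config()) {
  D <- dosage_matrix(G)
  X <- design_with_intercept(C, nrow(D))
  k <- ncol(X) - 1L
  E <- t(N$values)
  Dr <- residualize(D, X); Er <- residualize(E, X)
  gm <- N$gene_meta
  res_list <- list()
  for (i in seq_len(nrow(intervals))) {
    snps <- intersect(intervals$ld_snp_ids[[i]], colnames(Dr))
    w <- c(max(intervals$span_start[i] - cfg$flank_stage1, 1),
           intervals$span_end[i] + cfg$flank_stage1)
    genes <- gm$id[gm$chrom == intervals$chrom[i] & gm$start <= w[2] & gm$end >= w[1]]
    if (!length(snps) || !length(genes)) {
      res_list[[i]] <- NULL
      next
    }
    r <- assoc_scan_fast(Dr[, snps, drop = FALSE], Er[, genes, drop = FALSE],
                         n_covariates = k)
    r$interval_id <- intervals$interval_id[i]
    res_list[[i]] <- r
  }
  results <- do.call(rbind, res_list)
  if (is.null(results))
    results <- data.frame(snp_id = character(), gene_id = character(), beta = numeric(),
                          se = numeric(), t_stat = numeric(), p_value = numeric(),
                          n_samples = integer(), df = integer(), untestable = logical(),
                          interval_id = character(), stringsAsFactors = FALSE)
  n_tests <- sum(!results$untestable)
  threshold <- if (n_tests > 0) bonferroni_threshold(cfg$alpha, n_tests) else NA_real_
  results$stage <- rep(1L, nrow(results))
  results$threshold_used <- rep(threshold, nrow(results))
  results$significant <- !results$untestable & !is.na(results$p_value) &
    results$p_value < threshold
  summ <- do.call(rbind, lapply(seq_len(nrow(intervals)), function(i) {
    ri <- results[results$interval_id == intervals$interval_id[i], , drop = FALSE]
    data.frame(interval_id = intervals$interval_id[i],
               n_tests = sum(!ri$untestable),
               any_significant = any(ri$significant),
               n_target_genes = length(unique(ri$gene_id[ri$significant])),
               stringsAsFactors = FALSE)
  }))
  summ$target_genes <- lapply(seq_len(nrow(intervals)), function(i) {
    ri <- results[results$interval_id == intervals$interval_id[i], , drop = FALSE]
    unique(ri$gene_id[ri$significant])
  })
  structure(list(results = results, threshold = threshold, n_tests = n_tests,
                 interval_summary = summ, n_covariates = k),
            class = "eqtl_stage1")
}

#' Stage-2 scan: all SNPs around each target gene
#'
#' For every target gene, tests each SNP whose position lies within
#' `flank_stage2` of the gene's TSS/TES span and that was not already tested
#' in stage 1 (the stage-1 LD-SNP exclusion set), against that gene only. One
#' Bonferroni threshold is applied across all stage-2 tests.
#'
#' @param G,N,C,cfg as in [stage1_scan()].
#' @param target_genes character vector of gene ids (stage-1 targets).
#' @param stage1_snp_ids SNP ids excluded because stage 1 tested them.
#' @return list of class `eqtl_stage2`: `results`, `threshold`, `n_tests`,
#'   `gene_summary`.
#' @export
stage2_scan <- function(G, N, C = NULL, target_genes, stage1_snp_ids = character(),
                        cfg = scan_config()) {
  if (!length(target_genes)) stopf("target_genes is empty", class = "invalid_argument")
  D <- dosage_matrix(G)
  X <- design_with_intercept(C, nrow(D))
  k <- ncol(X) - 1L
  E <- t(N$values)
  Dr <- residualize(D, X); Er <- residualize(E, X)
  gm <- N$gene_meta
  sm <- G$snp_meta
  res_list <- list(); zero_genes <- character()
  for (gid in target_genes) {
    g <- gm[gm$id == gid, ]
    if (!nrow(g)) stopf("unknown target gene %s", gid, class = "invalid_argument")
    w <- c(max(min(g$tss, g$tes) - cfg$flank_stage2, 1), max(g$tss, g$tes) + cfg$flank_stage2)
    snps <- sm$id[sm$chrom == g$chrom & sm$pos >= w[1] & sm$pos <= w[2]]
    snps <- setdiff(snps, stage1_snp_ids)
    if (!length(snps)) { zero_genes <- c(zero_genes, gid); next }
    r <- assoc_scan_fast(Dr[, snps, drop = FALSE], Er[, gid, drop = FALSE],
                         n_covariates = k)
    r$gene_id <- gid
    res_list[[gid]] <- r
  }
  results <- do.call(rbind, res_list)
  if (is.null(results))
    results <- data.frame(snp_id = character(), gene_id = character(), beta = numeric(),
                          se = numeric(), t_stat = numeric(), p_value = numeric(),
                          n_samples = integer(), df = integer(), untestable = logical(),
                          stringsAsFactors = FALSE)
  rownames(results) <- NULL
  n_tests <- sum(!results$untestable)
  threshold <- if (n_tests > 0) bonferroni_threshold(cfg$alpha, n_tests) else NA_real_
  results$stage <- rep(2L, nrow(results))
  results$threshold_used <- rep(threshold, nrow(results))
  results$significant <- !results$untestable & !is.na(results$p_value) &
    results$p_value < threshold
  gene_summary <- data.frame(
    gene_id = target_genes,
    n_tests = vapply(target_genes, function(g)
      sum(results$gene_id == g & !results$untestable), numeric(1)),
    n_significant = vapply(target_genes, function(g)
      sum(results$gene_id == g & results$significant), numeric(1)),
    stringsAsFactors = FALSE
  )
  structure(list(results = results, threshold = threshold, n_tests = n_tests,
                 gene_summary = gene_summary, n_covariates = k,
                 excluded_snp_ids = stage1_snp_ids, zero_test_genes = zero_genes),
            class = "eqtl_stage2")
}

#' Negative binomial GLM association for one gene
#'
#' Sensitivity model for the linear pipeline: a log-link NB GLM of the raw
#' gene counts on dosage and covariates with the normalization constants as
#' an offset. The per-gene dispersion is estimated by method of moments on
#' Pearson residuals of an initial Poisson fit and refined once after the NB
#' refit; the genotype coefficient's Wald z test is reported.
#'
#' @param counts_g non-negative integer count vector for one gene.
#' @param g dosage vector.
#' @param C optional covariate matrix (no intercept).
#' @param offsets per-sample natural-log offsets (e.g. a row of
#'   `normalize_counts()$log_offset`); default 0.
#' @param size optional fixed NB size parameter; default NULL estimates it.
#' @param max_iter IRLS iteration cap per fit.
#' @return one-row data frame: `beta`, `se`, `z`, `p_value`, `size`,
#'   `n_samples`.
#' @export
nb_glm_assoc <- function(counts_g, g, C = NULL, offsets = NULL, size = NULL,
                         max_iter = 50L) {
  if (any(counts_g < 0) || any(counts_g != floor(counts_g)))
    stopf("counts must be non-negative integers", class = "invalid_argument")
  n <- length(counts_g)
  off <- offsets %||% rep(0, n)
  if (any(!is.finite(off))) stopf("offsets must be finite", class = "invalid_argument")
  dat <- data.frame(y = counts_g, g = g)
  if (!is.null(C)) {
    C <- as.matrix(C)
    colnames(C) <- colnames(C) %||% paste0("c", seq_len(ncol(C)))
    dat <- cbind(dat, C)
  }
  form <- stats::as.formula(paste("y ~", paste(setdiff(names(dat), "y"), collapse = " + ")))
  mom_size <- function(fit) {
    mu <- stats::fitted(fit)
    p <- length(stats::coef(fit))
    a <- sum((dat$y - mu)^2 - mu) / sum(mu^2)        # moment estimate of 1/size
    if (!is.finite(a) || a <= 1e-8) 1e6 else min(1 / a, 1e6)
  }
  if (is.null(size)) {
    f0 <- stats::glm(form, data = dat, family = stats::poisson(), offset = off,
                     control = stats::glm.control(maxit = max_iter))
    size <- mom_size(f0)
    f1 <- stats::glm(form, data = dat, family = MASS::negative.binomial(theta = size),
                     offset = off, control = stats::glm.control(maxit = max_iter))
    size <- mom_size(f1)                              # one refinement
  }
  fit <- stats::glm(form, data = dat, family = MASS::negative.binomial(theta = size),
                    offset = off, control = stats::glm.control(maxit = max_iter))
  if (!fit$converged)
    stopf("NB GLM did not converge in %d iterations (deviance %.4g)",
          max_iter, fit$deviance, class = "convergence_error")
  # dispersion fixed at 1: the NB variance function already carries the
  # overdispersion, so the Wald z must not be rescaled by a Pearson estimate
  cs <- summary(fit, dispersion = 1)$coefficients
  data.frame(beta = cs["g", 1], se = cs["g", 2], z = cs["g", 3],
             p_value = max(cs["g", 4], .Machine$double.xmin),
             size = size, n_samples = n, stringsAsFactors = FALSE)
}
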