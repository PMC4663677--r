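#' Filter low-expression genes
#'
#' Removes genes whose per-gene median count across samples falls strictly
#' below `median_min`; genes with zero counts in every sample are reported
#' separately as undetectable. Gene order is preserved and the operation is
#' idempotent.
#'
#' @param E an [expression_counts()].
#' @param median_min median-count threshold (default 14; a gene whose median
#'   equals `median_min` is kept).
#' @return list with `counts` (filtered `expression_counts`) and `removed`
#'   (data frame: `id`, `median_count`, `reason` in
#'   `"undetectable"`/`"low_median"`).
#' @export
filter_genes <- function(E, median_min = 14) {
  if (median_min < 0) stopf("median_min must be >= 0", class = "invalid_argument")
  med <- apply(E$counts, 1L, stats::median)
  zero <- rowSums(E$counts) == 0
  keep <- !zero & med >= median_min
  if (!any(keep)) stopf("no gene survives expression filtering", class = "filter_empty")
  removed <- data.frame(id = E$gene_meta$id[!keep], median_count = med[!keep],
                        reason = ifelse(zero[!keep], "undetectable", "low_median"),
                        stringsAsFactors = FALSE)
  list(counts = expression_counts(E$counts[keep, , drop = FALSE],
                                  E$gene_meta[keep, , drop = FALSE]),
       removed = removed)
}

#' Normalize counts for depth, GC content and gene length
#'
#' A conditional-quantile-style transform built from smooth offsets: values
#' are `log2(count + 0.5) - log2(library_cpm_factor) - smooth(gc, log
#' length)`, where the smooth term is a per-sample fit of log2 count on GC
#' fraction, squared GC fraction and log gene length (one Huber reweighting
#' pass on top of least squares), centred to mean zero within each sample so
#' depth is carried by the library term alone. The fitted offsets are also
#' returned on the natural-log scale for reuse in the negative binomial
#' model.
#'
#' @param E an [expression_counts()] whose `gene_meta` supplies
#'   `gc_fraction` and `length_bp`.
#' @param robust apply one Huber reweighting pass (default TRUE).
#' @return object of class `normalized_expression`: list with `values`
#'   (genes x samples), `log_offset` (natural-log offsets, genes x samples),
#'   `lib_size_factor` (per sample, counts-per-million scale), `gene_meta`.
#' @export
normalize_counts <- function(E, robust = TRUE) {
  cnt <- E$counts
  lib <- colSums(cnt) / 1e6
  if (any(lib <= 0)) stopf("zero library size", class = "invalid_argument")
  y <- log2(cnt + 0.5)
  gm <- E$gene_meta
  Z <- cbind(1, gm$gc_fraction, gm$gc_fraction^2, log(gm$length_bp))
  # drop constant / collinear predictor columns
  qz <- qr(Z)
  Z <- Z[, qz$pivot[seq_len(qz$rank)], drop = FALSE]
  fit <- qr.coef(qr(Z), y)                      # one QR shared by all samples
  fitted <- Z %*% fit
  if (robust && ncol(Z) > 1L) {
    res <- y - fitted
    s <- pmax(apply(res, 2L, stats::mad), 1e-8)
    k <- 1.345
    for (j in seq_len(ncol(y))) {
      w <- pmin(1, k * s[j] / pmax(abs(res[, j]), 1e-12))
      fj <- stats::lm.wfit(Z, y[, j], w)
      fitted[, j] <- Z %*% fj$coefficients
    }
  }
  offset2 <- sweep(fitted, 2L, colMeans(fitted))   # centred per sample, log2 scale
  values <- sweep(y - offset2, 2L, log2(lib))
  if (any(!is.finite(values))) stopf("non-finite normalized value", class = "internal_error")
  log_offset <- log(2) * sweep(offset2, 2L, log2(lib), `+`)
  dimnames(values) <- dimnames(log_offset) <- dimnames(cnt)
  structure(list(values = values, log_offset = log_offset, lib_size_factor = lib,
                 gene_meta = gm),
            class = "normalized_expression")
}

#' @export
print.normalized_expression <- function(x, ...) {
  cat(sprintf("normalized_expression: %d genes x %d samples (log2 scale)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Expression principal components as covariates
#'
#' Centres each gene, decomposes the sample-space covariance and returns
#' every component whose individual variance-explained fraction strictly
#' exceeds `var_min`, ordered by decreasing eigenvalue.
#'
#' @param N a [normalize_counts()] result, or a plain genes-by-samples
#'   matrix.
#' @param var_min per-component variance-explained threshold (default 0.01).
#' @return list with `scores` (samples x n_selected), `var_explained` (all
#'   components), `cum_var_selected`, `n_selected`.
#' @export
expression_pcs <- function(N, var_min = 0.01) {
  V <- if (inherits(N, "normalized_expression")) N$values else as.matrix(N)
  if (ncol(V) < 3L) stopf("need at least 3 samples", class = "invalid_argument")
  X <- t(V - rowMeans(V))                       # samples x genes, genes centred
  sv <- svd(X, nu = min(dim(X)), nv = 0)
  if (max(sv$d) <= 1e-12) stopf("degenerate expression matrix", class = "decomposition_failure")
  ve <- sv$d^2 / sum(sv$d^2)
  sel <- which(ve > var_min)
  scores <- sv$u[, sel, drop = FALSE] %*% diag(sv$d[sel], nrow = length(sel))
  rownames(scores) <- colnames(V)
  if (length(sel)) colnames(scores) <- paste0("PC", sel)
  list(scores = scores, var_explained = ve,
       cum_var_selected = sum(ve[sel]), n_selected = length(sel))
}

#' Screen candidate covariates against global expression
#'
#' For each candidate column, regresses every gene's normalized expression on
#' the candidate and records the minimum p-value across genes; a candidate
#' whose minimum p falls below `p_min` is flagged as associated with global
#' transcript abundance (and hence worth adjusting for).
#'
#' @param N a [normalize_counts()] result or genes-by-samples matrix.
#' @param candidates data frame or matrix, samples x candidates.
#' @param p_min flagging threshold on the minimum p (default 1e-5).
#' @return data frame: `covariate`, `min_p`, `testable`, `associated`.
#' @export
screen_covariates <- function(N, candidates, p_min = 1e-5) {
  V <- if (inherits(N, "normalized_expression")) N$values else as.matrix(N)
  C <- as.matrix(candidates)
  if (nrow(C) != ncol(V))
    stopf("candidate rows must align with samples", class = "invalid_argument")
  n <- ncol(V); df <- n - 2L
  Vc <- V - rowMeans(V)
  Vs <- Vc / sqrt(pmax(rowSums(Vc^2), 1e-300))
  out <- lapply(seq_len(ncol(C)), function(j) {
    x <- C[, j]
    if (stats::sd(x) == 0)
      return(data.frame(covariate = colnames(C)[j] %||% paste0("cov", j),
                        min_p = NA_real_, testable = FALSE, associated = FALSE))
    xs <- (x - mean(x)) / sqrt(sum((x - mean(x))^2))
    r <- as.vector(Vs %*% xs)
    r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
    t <- r * sqrt(df) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(t), df)
    data.frame(covariate = colnames(C)[j] %||% paste0("cov", j),
               min_p = min(p), testable = TRUE, associated = min(p) < p_min)
  })
  do.call(rbind, out)
}
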