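#' Peak eQTL SNP of one gene
#'
#' Returns the significant SNP with the smallest p-value; ties are broken by
#' larger |t|, then by smaller genomic position, so the choice is
#' deterministic and invariant to input order.
#'
#' @param results association rows for one gene (any mix of stages) with
#'   columns `snp_id`, `p_value`, `t_stat`, `significant`.
#' @param positions named numeric vector of SNP positions (bp), covering at
#'   least the significant SNPs; may be omitted if `results` has a `snp_pos`
#'   column.
#' @return the peak SNP id (character scalar).
#' @export
find_peak <- function(results, positions = NULL) {
  sig <- results[!is.na(results$significant) & results$significant, , drop = FALSE]
  if (!nrow(sig)) stopf("no significant association to pick a peak from",
                        class = "no_peak")
  pos <- if (!is.null(positions)) unname(positions[sig$snp_id])
         else if ("snp_pos" %in% names(sig)) sig$snp_pos
         else rep(0, nrow(sig))
  ord <- order(sig$p_value, -abs(sig$t_stat), pos)
  sig$snp_id[ord[1L]]
}

#' Peak-conditioned association rescan
#'
#' Re-runs the association model for one gene with the peak SNP's dosage
#' appended to the covariate matrix, to ask whether any independent signal
#' remains. SNPs nearly collinear with the peak (r2 above the configured
#' guard) are flagged untestable instead of fitted; the peak itself is never
#' scanned.
#'
#' @param G a post-QC [genotype_matrix()].
#' @param N a [normalize_counts()] result.
#' @param C covariate matrix (samples x k, no intercept) or NULL.
#' @param gene gene id to rescan.
#' @param peak_snp the conditioning SNP id (must vary in the panel).
#' @param window_snp_ids SNP ids to scan (the peak is removed if present).
#' @param cfg a [scan_config()].
#' @param conditional_threshold significance threshold; by convention the
#'   stage-2 Bonferroni threshold is reused.
#' @return data frame with the association schema plus `r2_with_peak`,
#'   `stage = "conditional"`, `significant`, `threshold_used`.
#' @export
conditional_scan <- function(G, N, C = NULL, gene, peak_snp, window_snp_ids,
                             cfg = scan_config(), conditional_threshold) {
  pi <- match(peak_snp, G$snp_meta$id)
  if (is.na(pi)) stopf("peak SNP %s is not in the panel", peak_snp, class = "unknown_snp")
  D <- dosage_matrix(G)
  gpeak <- D[, peak_snp]
  if (stats::var(gpeak) == 0)
    stopf("peak SNP has zero dosage variance", class = "invalid_argument")
  snps <- setdiff(intersect(window_snp_ids, colnames(D)), peak_snp)
  if (!length(snps))
    return(data.frame(snp_id = character(), gene_id = character(), beta = numeric(),
                      se = numeric(), t_stat = numeric(), p_value = numeric(),
                      n_samples = integer(), df = integer(), untestable = logical(),
                      r2_with_peak = numeric(), stage = character(),
                      threshold_used = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  r2p <- vapply(snps, function(s) {
    v <- D[, s]
    if (stats::var(v) == 0) return(1)       # constant: untestable anyway
    stats::cor(gpeak, v)^2
  }, numeric(1))
  X <- cbind(design_with_intercept(C, nrow(D)), peak = gpeak)
  k <- ncol(X) - 1L
  Dr <- residualize(D[, snps, drop = FALSE], X)
  Er <- residualize(N$values[gene, , drop = FALSE] |> t(), X)
  colnames(Er) <- gene
  res <- assoc_scan_fast(Dr, Er, n_covariates = k)
  res$r2_with_peak <- unname(r2p[res$snp_id])
  collinear <- res$r2_with_peak > cfg$collinear_r2
  res$untestable <- res$untestable | collinear
  res[res$untestable, c("beta", "se", "t_stat", "p_value")] <- NA_real_
  res$stage <- "conditional"
  res$threshold_used <- conditional_threshold
  res$significant <- !res$untestable & !is.na(res$p_value) &
    res$p_value < conditional_threshold
  res
}

#' Classify a gene's regulatory-domain structure
#'
#' A gene has a single regulatory domain when no SNP stays significant after
#' conditioning on its peak, and multiple domains otherwise. When residual
#' signals exist, the record also flags whether any of them is in high LD
#' (r2 > `r2_high`) with a risk SNP of the gene's originating interval --
#' the case where the risk SNP itself tags a second, independent signal.
#'
#' @param cond a [conditional_scan()] result for the gene.
#' @param G a [genotype_matrix()] containing the SNPs involved.
#' @param risk_snp_ids risk SNP ids of the gene's originating interval.
#' @param r2_high LD threshold for the residual-risk flag (default 0.5).
#' @return one-row data frame: `residual_significant_snps`, `domain_class`
#'   (`"single"`/`"multiple"`), `residual_high_ld_with_risk`.
#' @export
classify_domains <- function(cond, G, risk_snp_ids = character(), r2_high = 0.5) {
  sig <- cond$snp_id[!is.na(cond$significant) & cond$significant]
  high <- FALSE
  if (length(sig) && length(risk_snp_ids)) {
    D <- dosage_matrix(G)
    rs <- intersect(risk_snp_ids, colnames(D))
    for (s in sig) {
      if (any(vapply(rs, function(r) {
        if (stats::var(D[, r]) == 0 || stats::var(D[, s]) == 0) return(FALSE)
        stats::cor(D[, r], D[, s])^2 > r2_high
      }, logical(1)))) { high <- TRUE; break }
    }
  }
  data.frame(residual_significant_snps = length(sig),
             domain_class = if (length(sig)) "multiple" else "single",
             residual_high_ld_with_risk = high, stringsAsFactors = FALSE)
}
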