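#' Two-stage risk-SNP-anchored cis-eQTL mapping
#'
#' Runs the whole pipeline: SNP quality control; expression filtering,
#' normalization and expression-PC covariates; LD expansion of each risk SNP
#' and merging into unique risk intervals; the stage-1 scan of interval
#' LD-SNPs against in-window genes under one Bonferroni threshold; the
#' stage-2 scan of all remaining SNPs around each stage-1 target gene; the
#' peak-conditioned rescan with domain classification; and the LD grouping
#' of each target gene by r2 between its best risk SNP and peak SNP.
#'
#' @param G a [genotype_matrix()] (raw; QC is applied here unless
#'   `qc = FALSE`).
#' @param counts an [expression_counts()].
#' @param risk_snps data frame with columns `id`, `chrom`, `pos`; ids must
#'   exist in the panel after QC.
#' @param covariates optional sample-level covariates (e.g. histology
#'   fractions), samples x q; expression PCs are appended automatically.
#' @param cfg a [scan_config()].
#' @param qc apply SNP QC (default TRUE).
#' @return object of class `eqtl_map`: list with `panel`, `qc_report`,
#'   `normalized`, `covariates` (the full design used, without intercept),
#'   `pc_var_explained`, `intervals`, `stage1`, `stage2`, `conditional`
#'   (named list per target gene), `genes` (per-target-gene record: peak,
#'   r2 to risk SNP, group, distances, minimal region, domain class),
#'   `regional` (per-gene locus tables), `cfg`.
#' @export
eqtl_map <- function(G, counts, risk_snps, covariates = NULL, cfg = scan_config(),
                     qc = TRUE) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(counts, "expression_counts"))
  qc_report <- NULL
  if (qc) {
    q <- apply_snp_qc(G, call_rate_min = cfg$callrate_min, hwe_p_min = cfg$hwe_min,
                      maf_min = cfg$maf_min)
    G <- q$panel; qc_report <- q$report
  }
  missing_rs <- setdiff(risk_snps$id, G$snp_meta$id)
  if (length(missing_rs))
    stopf("risk SNP(s) absent from the post-QC panel: %s",
          paste(missing_rs, collapse = ", "), class = "unknown_snp")

  fg <- filter_genes(counts, cfg$median_min)
  N <- normalize_counts(fg$counts)
  pcs <- expression_pcs(N, cfg$pc_var_min)
  C <- if (is.null(covariates)) pcs$scores
       else cbind(as.matrix(covariates), pcs$scores)

  ld_sets <- lapply(risk_snps$id, function(rs)
    expand_ld_set(G, rs, r2_min = cfg$r2_expand, search_flank = cfg$ld_search_flank))
  names(ld_sets) <- risk_snps$id
  intervals <- build_risk_intervals(risk_snps$id, ld_sets, G$snp_meta)

  s1 <- stage1_scan(G, N, C, intervals, cfg)
  target_genes <- unique(s1$results$gene_id[s1$results$significant])

  s2 <- NULL; cond <- list(); regional <- list()
  gene_records <- NULL
  if (length(target_genes)) {
    excl <- unique(unlist(intervals$ld_snp_ids))
    s2 <- stage2_scan(G, N, C, target_genes, stage1_snp_ids = excl, cfg = cfg)
    cond_threshold <- if (!is.na(s2$threshold)) s2$threshold else s1$threshold
    pos_lookup <- stats::setNames(G$snp_meta$pos, G$snp_meta$id)
    D <- dosage_matrix(G)

    recs <- list()
    for (gid in target_genes) {
      r1 <- s1$results[s1$results$gene_id == gid, , drop = FALSE]
      r2_ <- s2$results[s2$results$gene_id == gid, , drop = FALSE]
      comb <- rbind(r1[, names(r2_)[names(r2_) %in% names(r1)], drop = FALSE],
                    r2_[, names(r2_)[names(r2_) %in% names(r1)], drop = FALSE])
      peak <- find_peak(comb, positions = pos_lookup)
      # originating interval: the one carrying this gene's best stage-1 pair
      iv_id <- r1$interval_id[which.min(r1$p_value)]
      iv <- intervals[intervals$interval_id == iv_id, ]
      members <- iv$member_risk_snps[[1]]
      r2_to_peak <- vapply(members, function(rs) {
        if (stats::var(D[, rs]) == 0 || stats::var(D[, peak]) == 0) return(0)
        stats::cor(D[, rs], D[, peak])^2
      }, numeric(1))
      best_rs <- members[which.max(r2_to_peak)]
      r2rp <- max(r2_to_peak)
      gmeta <- N$gene_meta[N$gene_meta$id == gid, ]
      w <- c(max(min(gmeta$tss, gmeta$tes) - cfg$flank_stage2, 1),
             max(gmeta$tss, gmeta$tes) + cfg$flank_stage2)
      win_snps <- G$snp_meta$id[G$snp_meta$chrom == gmeta$chrom &
                                  G$snp_meta$pos >= w[1] & G$snp_meta$pos <= w[2]]
      cg <- conditional_scan(G, N, C, gid, peak, win_snps, cfg, cond_threshold)
      cond[[gid]] <- cg
      dom <- classify_domains(cg, G, members, r2_high = 0.5)
      mr <- estimate_minimal_region(comb, peak, G, cfg$drop_log10, cfg$r2_link)
      peak_pos <- unname(pos_lookup[peak])
      recs[[gid]] <- data.frame(
        gene_id = gid, interval_id = iv_id, best_risk_snp_id = best_rs,
        peak_snp_id = peak, peak_p = min(comb$p_value, na.rm = TRUE),
        peak_beta = comb$beta[which.min(comb$p_value)],
        r2_risk_peak = r2rp, group = classify_gene_group(min(r2rp, 1)),
        dist_risk_to_peak = abs(unname(pos_lookup[best_rs]) - peak_pos),
        peak_pos = peak_pos,
        minimal_region_start = mr[["start"]], minimal_region_end = mr[["end"]],
        residual_significant_snps = dom$residual_significant_snps,
        domain_class = dom$domain_class,
        residual_high_ld_with_risk = dom$residual_high_ld_with_risk,
        stringsAsFactors = FALSE)
      # regional table for locus plots
      rr <- comb[!comb$untestable, c("snp_id", "p_value", "stage")]
      rr$pos <- unname(pos_lookup[rr$snp_id])
      rr$r2_risk <- vapply(rr$snp_id, function(s)
        if (stats::var(D[, s]) == 0) NA_real_ else stats::cor(D[, best_rs], D[, s])^2,
        numeric(1))
      rr$r2_peak <- vapply(rr$snp_id, function(s)
        if (stats::var(D[, s]) == 0) NA_real_ else stats::cor(D[, peak], D[, s])^2,
        numeric(1))
      regional[[gid]] <- rr[order(rr$pos), ]
    }
    gene_records <- do.call(rbind, recs)
    rownames(gene_records) <- NULL
    prof <- peak_distance_profile(
      data.frame(gene_id = gene_records$gene_id,
                 peak_snp_id = gene_records$peak_snp_id,
                 peak_pos = gene_records$peak_pos, stringsAsFactors = FALSE),
      N$gene_meta, proximity_bp = cfg$proximity_bp)
    gene_records <- cbind(gene_records,
                          prof[, c("dist_tss", "dist_tes", "min_dist",
                                   "within_proximity", "norm_coord")])
  }
  structure(list(panel = G, qc_report = qc_report, normalized = N,
                 covariates = C, pc_var_explained = pcs$var_explained,
                 n_pcs = pcs$n_selected, filtered_genes = fg$removed,
                 risk_snps = risk_snps, ld_sets = ld_sets, intervals = intervals,
                 stage1 = s1, stage2 = s2, conditional = cond,
                 genes = gene_records, regional = regional, cfg = cfg),
            class = "eqtl_map")
}

#' @export
print.eqtl_map <- function(x, ...) {
  cat("Two-stage risk-SNP cis-eQTL map\n")
  cat(sprintf("  panel: %d samples x %d SNPs; %d expressed genes\n",
              nrow(x$panel$dosage), ncol(x$panel$dosage), nrow(x$normalized$values)))
  cat(sprintf("  %d risk SNP(s) -> %d risk interval(s)\n",
              nrow(x$risk_snps), nrow(x$intervals)))
  cat(sprintf("  stage 1: %d tests, threshold %.3g, %d significant interval(s)\n",
              x$stage1$n_tests, x$stage1$threshold,
              sum(x$stage1$interval_summary$any_significant)))
  if (!is.null(x$genes)) {
    cat(sprintf("  target genes: %d (groups 1/2/3: %d/%d/%d; single-domain: %d)\n",
                nrow(x$genes), sum(x$genes$group == 1), sum(x$genes$group == 2),
                sum(x$genes$group == 3), sum(x$genes$domain_class == "single")))
    if (!is.null(x$stage2))
      cat(sprintf("  stage 2: %d tests, threshold %.3g\n",
                  x$stage2$n_tests, x$stage2$threshold))
  } else cat("  no significant target gene\n")
  invisible(x)
}

#' @export
summary.eqtl_map <- function(object, ...) {
  out <- list(
    n_samples = nrow(object$panel$dosage),
    n_snps = ncol(object$panel$dosage),
    n_genes = nrow(object$normalized$values),
    n_pcs = object$n_pcs,
    n_intervals = nrow(object$intervals),
    stage1_tests = object$stage1$n_tests,
    stage1_threshold = object$stage1$threshold,
    n_significant_intervals = sum(object$stage1$interval_summary$any_significant),
    stage2_tests = if (!is.null(object$stage2)) object$stage2$n_tests else 0L,
    stage2_threshold = if (!is.null(object$stage2)) object$stage2$threshold else NA_real_,
    genes = object$genes
  )
  class(out) <- "summary.eqtl_map"
  out
}

#' @export
print.summary.eqtl_map <- function(x, ...) {
  cat(sprintf("cohort: %d samples, %d SNPs, %d genes (%d expression PCs adjusted)\n",
              x$n_samples, x$n_snps, x$n_genes, x$n_pcs))
  cat(sprintf("stage 1: %d tests at threshold %.3g; %d / %d intervals significant\n",
              x$stage1_tests, x$stage1_threshold, x$n_significant_intervals,
              x$n_intervals))
  if (!is.null(x$genes)) {
    cat(sprintf("stage 2: %d tests at threshold %.3g\n", x$stage2_tests,
                x$stage2_threshold))
    cat("target genes:\n")
    print(x$genes[, c("gene_id", "peak_snp_id", "peak_p", "r2_risk_peak", "group",
                      "domain_class", "min_dist")], row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.eqtl_map <- function(object, ...) {
  r1 <- object$stage1$results
  out <- r1[r1$significant, c("snp_id", "gene_id", "beta", "se", "p_value", "stage")]
  if (!is.null(object$stage2)) {
    r2 <- object$stage2$results
    out <- rbind(out, r2[r2$significant,
                         c("snp_id", "gene_id", "beta", "se", "p_value", "stage")])
  }
  rownames(out) <- NULL
  out
}

#' Regional association plot for one target gene
#'
#' -log10 p against SNP position, points keyed by LD with the risk SNP
#' (r2 > 0.5 filled red, 0.2--0.5 green, < 0.2 blue), the risk SNP as a
#' diamond, the Bonferroni threshold dashed, and the gene body marked along
#' the axis.
#'
#' @param x an [eqtl_map()] result with at least one target gene.
#' @param gene gene id (default: first target gene).
#' @param ... passed to [plot()].
#' @export
plot.eqtl_map <- function(x, gene = NULL, ...) {
  if (is.null(x$genes)) stopf("no target gene to plot", class = "invalid_argument")
  gene <- gene %||% x$genes$gene_id[1]
  rr <- x$regional[[gene]]
  if (is.null(rr)) stopf("unknown target gene %s", gene, class = "invalid_argument")
  rec <- x$genes[x$genes$gene_id == gene, ]
  col <- ifelse(rr$r2_risk > 0.5, "red3", ifelse(rr$r2_risk >= 0.2, "green4", "blue3"))
  lp <- -log10(rr$p_value)
  plot(rr$pos / 1e6, lp, col = col, pch = 16, cex = 0.7,
       xlab = sprintf("position on %s (Mb)", x$panel$snp_meta$chrom[1]),
       ylab = expression(-log[10](italic(p))),
       main = sprintf("%s (group %d, peak %s)", gene, rec$group, rec$peak_snp_id), ...)
  thr <- x$stage1$threshold
  graphics::abline(h = -log10(thr), lty = 2, col = "grey40")
  rs_pos <- x$risk_snps$pos[x$risk_snps$id == rec$best_risk_snp_id]
  if (length(rs_pos)) {
    graphics::abline(v = rs_pos / 1e6, lty = 3, col = "red3")
    i <- match(rec$best_risk_snp_id, rr$snp_id)
    if (!is.na(i)) graphics::points(rr$pos[i] / 1e6, lp[i], pch = 5, cex = 1.4)
  }
  gm <- x$normalized$gene_meta
  gm <- gm[gm$id == gene, ]
  graphics::segments(gm$start / 1e6, 0, gm$end / 1e6, 0, lwd = 4, col = "grey30")
  invisible(x)
}
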