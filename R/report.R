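#' LD group of a target gene
#'
#' Groups a gene by the LD between its best risk SNP and its peak eQTL SNP:
#' group 1 (high LD) when r2 > 0.5, group 2 (moderate) when r2 lies in
#' \[0.2, 0.5\], group 3 (low/no LD) when r2 < 0.2. The band edges are closed
#' into group 2 by convention.
#'
#' @param r2_risk_peak r2 between the risk SNP and the peak SNP, in \[0, 1\].
#' @return integer 1, 2 or 3.
#' @export
classify_gene_group <- function(r2_risk_peak) {
  check_fraction(r2_risk_peak, "r2_risk_peak", 0, 1)
  if (r2_risk_peak > 0.5) 1L else if (r2_risk_peak >= 0.2) 2L else 3L
}

#' Peak position relative to gene anchors
#'
#' For each peak, reports the distance to the nearest of TSS and TES, a
#' proximity flag, and a transcription-oriented normalized coordinate in
#' which the gene body spans 0 (TSS) to 100 (TES) regardless of its true
#' length, with flanks kept in bp (negative upstream of the TSS, `100 + bp`
#' downstream of the TES).
#'
#' @param peaks data frame with `gene_id`, `peak_snp_id`, `peak_pos` (bp).
#' @param genes gene annotation (`id`, `tss`, `tes`, `strand`).
#' @param proximity_bp flag distance (default 20000).
#' @return data frame: `gene_id`, `peak_snp_id`, `dist_tss`, `dist_tes`,
#'   `min_dist`, `within_proximity`, `norm_coord`.
#' @export
peak_distance_profile <- function(peaks, genes, proximity_bp = 2e4) {
  gi <- match(peaks$gene_id, genes$id)
  if (anyNA(gi)) stopf("peak refers to unknown gene", class = "invalid_argument")
  tss <- genes$tss[gi]; tes <- genes$tes[gi]
  dir <- ifelse(genes$strand[gi] == "-", -1, 1)
  pos <- peaks$peak_pos
  s <- (pos - tss) * dir                 # bp along transcription from the TSS
  L <- abs(tes - tss)
  norm <- ifelse(s < 0, s, ifelse(s <= L, 100 * s / pmax(L, 1), 100 + (s - L)))
  d_tss <- abs(pos - tss); d_tes <- abs(pos - tes)
  data.frame(gene_id = peaks$gene_id, peak_snp_id = peaks$peak_snp_id,
             dist_tss = d_tss, dist_tes = d_tes,
             min_dist = pmin(d_tss, d_tes),
             within_proximity = pmin(d_tss, d_tes) <= proximity_bp,
             norm_coord = norm, stringsAsFactors = FALSE)
}

#' Minimal candidate-regulatory region around a peak
#'
#' Algorithmic surrogate for reading a regional association plot: the
#' minimal genomic span covering every SNP that is both (a) within
#' `drop_log10` units of the peak's -log10 p and (b) in LD r2 > `r2_link`
#' with the peak. The peak itself always qualifies, so the span is never
#' empty; if nothing else qualifies the span degenerates to the peak
#' position. Widening `drop_log10` can only widen the span.
#'
#' @param results association rows for the gene (`snp_id`, `p_value`).
#' @param peak peak SNP id (must appear in `results` or the panel).
#' @param G a [genotype_matrix()] holding positions and dosages for the SNPs
#'   in `results`.
#' @param drop_log10 -log10 p tolerance below the peak (default 2).
#' @param r2_link LD link threshold to the peak (default 0.5).
#' @return numeric `c(start, end)` in bp, 1-based inclusive.
#' @export
estimate_minimal_region <- function(results, peak, G, drop_log10 = 2, r2_link = 0.5) {
  D <- dosage_matrix(G)
  sm <- G$snp_meta
  pi <- match(peak, sm$id)
  if (is.na(pi)) stopf("peak SNP %s not in panel", peak, class = "unknown_snp")
  res <- results[!is.na(results$p_value), , drop = FALSE]
  ppeak <- res$p_value[match(peak, res$snp_id)]
  if (is.na(ppeak)) stopf("peak has no association row", class = "invalid_argument")
  floor_lp <- -log10(ppeak) - drop_log10
  cand <- res$snp_id[-log10(res$p_value) >= floor_lp]
  cand <- intersect(cand, sm$id)
  gpeak <- D[, peak]
  keep <- vapply(cand, function(s) {
    if (s == peak) return(TRUE)
    v <- D[, s]
    if (stats::var(v) == 0) return(FALSE)
    stats::cor(gpeak, v)^2 > r2_link
  }, logical(1))
  pos <- sm$pos[match(c(peak, cand[keep]), sm$id)]
  c(start = min(pos), end = max(pos))
}

collapse_listcol <- function(x) vapply(x, paste, character(1), collapse = ",")

write_tsv <- function(df, path) {
  for (nm in names(df)) if (is.list(df[[nm]])) df[[nm]] <- collapse_listcol(df[[nm]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write all pipeline tables to a directory
#'
#' Emits the association tables (stages 1, 2, conditional), the risk-interval
#' BED (converted to 0-based half-open on disk), the peak/group table,
#' per-gene regional association tables for locus plotting, and a run
#' manifest carrying the seed and a hash of the configuration. Re-running on
#' identical inputs reproduces byte-identical files.
#'
#' @param tables named list; recognized elements: `stage1`, `stage2`,
#'   `conditional` (association data frames), `intervals` (a
#'   [build_risk_intervals()] result), `peaks` (peak/group table),
#'   `regional` (named list of per-gene data frames), `config` (a
#'   [scan_config()]), `seed`.
#' @param outdir output directory (created if absent).
#' @return data frame manifest (file, md5), invisibly.
#' @export
write_results <- function(tables, outdir) {
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE))
    stopf("cannot create output directory %s", outdir, class = "io_error")
  files <- character()
  assoc_schema <- data.frame(snp_id = character(), gene_id = character(),
                             beta = numeric(), se = numeric(), t_stat = numeric(),
                             p_value = numeric(), n_samples = integer(),
                             df = integer(), untestable = logical(),
                             stringsAsFactors = FALSE)
  for (nm in c("stage1", "stage2", "conditional")) {
    df <- tables[[nm]] %||% assoc_schema
    files <- c(files, write_tsv(df, file.path(outdir, paste0("associations_", nm, ".tsv"))))
  }
  iv <- tables$intervals
  if (!is.null(iv)) {
    bed <- data.frame(chrom = iv$chrom, start = iv$span_start - 1L,  # BED half-open
                      end = iv$span_end, name = iv$interval_id)
    p <- file.path(outdir, "risk_intervals.bed")
    utils::write.table(bed, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    files <- c(files, p, write_tsv(as.data.frame(iv), file.path(outdir, "risk_intervals.tsv")))
  }
  if (!is.null(tables$peaks))
    files <- c(files, write_tsv(tables$peaks, file.path(outdir, "peak_genes.tsv")))
  for (g in names(tables$regional %||% list()))
    files <- c(files, write_tsv(tables$regional[[g]],
                                file.path(outdir, sprintf("regional_%s.tsv", g))))
  cfg_txt <- paste(deparse(tables$config %||% list()), collapse = "\n")
  tf <- tempfile(); writeLines(cfg_txt, tf)
  cfg_hash <- unname(tools::md5sum(tf)); unlink(tf)
  run <- data.frame(key = c("config_hash", "seed"),
                    value = c(cfg_hash, as.character(tables$seed %||% NA)),
                    stringsAsFactors = FALSE)
  files <- c(files, write_tsv(run, file.path(outdir, "run_info.tsv")))
  manifest <- data.frame(file = basename(files), md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  invisible(manifest)
}
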