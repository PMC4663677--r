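# Plain-text readers and writers. Coordinates are 1-based inclusive in TSV,
# GFF3 and VCF; BED output is 0-based half-open, converted at this boundary.

#' Read a gene-by-sample count table
#'
#' @param path TSV with gene ids in the first column and sample ids in the
#'   header.
#' @param gene_meta gene annotation data frame (or path to a TSV with the
#'   [simulate_gene_annotation()] columns) covering every gene.
#' @return an [expression_counts()].
#' @export
read_counts_tsv <- function(path, gene_meta) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  if (is.character(gene_meta))
    gene_meta <- utils::read.table(gene_meta, header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE)
  gm <- gene_meta[match(rownames(counts), gene_meta$id), , drop = FALSE]
  if (anyNA(gm$id)) stopf("annotation missing for some genes", class = "invalid_argument")
  expression_counts(counts, gm)
}

#' Write a gene-by-sample count table
#' @param E an [expression_counts()].
#' @param path output TSV path.
#' @export
write_counts_tsv <- function(E, path) {
  df <- data.frame(gene_id = rownames(E$counts), E$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dosage matrix from TSV
#'
#' Expects columns `id`, `chrom`, `pos`, `ref`, `alt` followed by one column
#' per sample holding dosages 0/1/2 (`NA` for missing).
#' @param path input TSV path.
#' @return a [genotype_matrix()].
#' @export
read_dosage_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  meta_cols <- intersect(c("id", "chrom", "pos", "ref", "alt"), names(tab))
  dos <- t(as.matrix(tab[, setdiff(names(tab), meta_cols), drop = FALSE]))
  genotype_matrix(dos, tab[, meta_cols, drop = FALSE], rownames(dos))
}

#' Write a dosage matrix to TSV
#' @param G a [genotype_matrix()].
#' @param path output TSV path.
#' @export
write_dosage_tsv <- function(G, path) {
  df <- data.frame(G$snp_meta[, intersect(c("id", "chrom", "pos", "ref", "alt"),
                                          names(G$snp_meta))],
                   t(G$dosage), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a minimal VCF (CHROM POS ID REF ALT GT)
#'
#' Dosages are emitted as unphased GT calls counting the ALT allele
#' (0 -> 0/0, 1 -> 0/1, 2 -> 1/1, NA -> ./.).
#' @param G a [genotype_matrix()].
#' @param path output path (uncompressed `.vcf`).
#' @export
write_vcf <- function(G, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", G$sample_ids), collapse = "\t")), con)
  gt <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(G$dosage))) {
    d <- G$dosage[, j]
    calls <- ifelse(is.na(d), "./.", gt[d + 1L])
    writeLines(paste(c(G$snp_meta$chrom[j], G$snp_meta$pos[j], G$snp_meta$id[j],
                       G$snp_meta$ref[j] %||% "A", G$snp_meta$alt[j] %||% "G",
                       ".", "PASS", ".", "GT", calls), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Parses the GT field into dosages of the ALT allele (the counted allele);
#' with `orient_minor = TRUE` every SNP whose ALT frequency exceeds 0.5 is
#' flipped so dosages count the cohort minor allele.
#' @param path VCF path (requires the vcfR package).
#' @param orient_minor re-orient dosages to the cohort minor allele.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, orient_minor = FALSE) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stopf("reading VCF requires the vcfR package", class = "missing_dependency")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    out <- rep(NA_real_, length(x))
    ok <- !is.na(x) & x != "./." & x != ".|."
    out[ok] <- vapply(strsplit(gsub("\\|", "/", x[ok]), "/"),
                      function(a) sum(a == "1"), numeric(1))
    out
  }
  dos <- t(apply(gt, 1L, count_alt))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  meta <- data.frame(id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  dos <- t(dos)                     # samples x snps
  if (orient_minor) {
    f <- colMeans(dos, na.rm = TRUE) / 2
    flip <- !is.na(f) & f > 0.5
    dos[, flip] <- 2 - dos[, flip]
  }
  genotype_matrix(dos, meta, colnames(gt))
}

#' Read a risk-SNP list
#' @param path TSV with columns `id`, `chrom`, `pos`.
#' @return data frame.
#' @export
read_risk_snps_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos")
  if (!all(need %in% names(tab)))
    stopf("risk-SNP table needs columns %s", paste(need, collapse = ", "),
          class = "invalid_argument")
  tab
}

#' Write gene annotation as GFF3
#' @param genes annotation data frame ([simulate_gene_annotation()] columns).
#' @param path output path.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\triskeqtl\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gc_fraction=%.4f;length_bp=%d",
                     genes$chrom, genes$start, genes$end, genes$strand, genes$id,
                     genes$gc_fraction, genes$length_bp), con)
  invisible(path)
}

#' Write covariates TSV
#' @param covariates data frame or matrix, samples in rows.
#' @param path output path.
#' @export
write_covariates_tsv <- function(covariates, path) {
  df <- data.frame(sample_id = rownames(covariates) %||%
                     paste0("sample", seq_len(nrow(covariates))),
                   covariates, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
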