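#' Genotype panel container
#'
#' Bundles a sample-by-SNP minor-allele dosage matrix with its SNP map. Dosages
#' are counts of the minor allele in \{0, 1, 2\}; `NA` marks a missing call.
#' Positions are 1-based base pairs, the convention used by VCF.
#'
#' @param dosage numeric matrix, samples in rows, SNPs in columns; entries
#'   0, 1, 2 or `NA`.
#' @param snp_meta data frame with one row per SNP: `id`, `chrom`, `pos`
#'   (1-based), and optionally `ref`, `alt`.
#' @param sample_ids character vector of sample identifiers, one per row of
#'   `dosage`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `snp_meta`, `sample_ids`.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 1), 2, 2,
#'                             dimnames = list(NULL, c("s1", "s2"))),
#'                      data.frame(id = c("s1", "s2"), chrom = "chr1",
#'                                 pos = c(100L, 200L)),
#'                      c("A", "B"))
#' @export
genotype_matrix <- function(dosage, snp_meta, sample_ids = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(sample_ids)) sample_ids <- rownames(dosage) %||% paste0("sample", seq_len(nrow(dosage)))
  if (anyDuplicated(snp_meta$id))
    stopf("SNP ids must be unique", class = "invalid_argument")
  if (ncol(dosage) != nrow(snp_meta))
    stopf("dosage has %d columns but snp_meta %d rows", ncol(dosage), nrow(snp_meta),
          class = "invalid_argument")
  if (length(sample_ids) != nrow(dosage))
    stopf("sample_ids length does not match dosage rows", class = "invalid_argument")
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stopf("dosage entries must be 0, 1, 2 or NA", class = "invalid_argument")
  for (ch in unique(snp_meta$chrom)) {
    p <- snp_meta$pos[snp_meta$chrom == ch]
    if (is.unsorted(p)) stopf("positions must be non-decreasing within %s", ch,
                              class = "invalid_argument")
  }
  colnames(dosage) <- snp_meta$id
  rownames(dosage) <- sample_ids
  structure(list(dosage = dosage, snp_meta = as.data.frame(snp_meta),
                 sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs on %s\n",
              nrow(x$dosage), ncol(x$dosage),
              paste(unique(x$snp_meta$chrom), collapse = ", ")))
  nm <- sum(is.na(x$dosage))
  if (nm) cat(sprintf("  %d missing calls (%.2f%%)\n", nm, 100 * nm / length(x$dosage)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype panel by SNP
#'
#' @param G a [genotype_matrix()].
#' @param snp_ids character vector of SNP ids to keep (order preserved from
#'   the panel, not from `snp_ids`).
#' @return A `genotype_matrix` restricted to the requested SNPs.
#' @export
subset_snps <- function(G, snp_ids) {
  keep <- G$snp_meta$id %in% snp_ids
  genotype_matrix(G$dosage[, keep, drop = FALSE], G$snp_meta[keep, , drop = FALSE],
                  G$sample_ids)
}

#' Expression count container
#'
#' Gene-by-sample integer counts plus the gene annotation the pipeline needs:
#' coordinates (TSS/TES in genomic 1-based bp; for minus-strand genes the TSS
#' is the larger coordinate), GC fraction and gene length.
#'
#' @param counts non-negative integer matrix, genes in rows, samples in
#'   columns.
#' @param gene_meta data frame with one row per gene: `id`, `chrom`, `start`,
#'   `end`, `strand` (`"+"`/`"-"`), `tss`, `tes`, `gc_fraction`, `length_bp`.
#' @return An object of class `expression_counts`.
#' @export
expression_counts <- function(counts, gene_meta) {
  counts <- as.matrix(counts)
  if (anyDuplicated(gene_meta$id))
    stopf("gene ids must be unique", class = "invalid_argument")
  if (nrow(counts) != nrow(gene_meta))
    stopf("counts has %d rows but gene_meta %d", nrow(counts), nrow(gene_meta),
          class = "invalid_argument")
  if (any(counts < 0) || any(counts != floor(counts)))
    stopf("counts must be non-negative integers", class = "invalid_argument")
  rownames(counts) <- gene_meta$id
  structure(list(counts = counts, gene_meta = as.data.frame(gene_meta)),
            class = "expression_counts")
}

#' @export
print.expression_counts <- function(x, ...) {
  cat(sprintf("expression_counts: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.expression_counts <- function(x) dim(x$counts)
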