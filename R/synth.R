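#' Simulate an LD-structured genotype panel
#'
#' Generates minor-allele dosages by haplotype-mosaic copying from a small
#' founder panel (a Li-and-Stephens-flavoured scheme). Founder haplotypes are
#' sticky Markov chains along each LD block, so adjacent SNPs inside a block
#' are strongly correlated; at block boundaries the founder alleles are drawn
#' afresh and each sample haplotype re-picks its founder, so correlation
#' decays across blocks. Each of the `2 * n_samples` haplotypes copies one
#' founder at a time, switching founders at a small per-SNP rate, with a small
#' per-SNP mutation rate. Columns whose realized minor allele frequency falls
#' below `maf_min` are re-drawn (bounded attempts) so the returned panel needs
#' no MAF filtering.
#'
#' @param n_samples number of diploid samples (>= 4).
#' @param n_snp number of SNPs (>= 2).
#' @param block_len SNPs per LD block.
#' @param maf_min minimum sample minor allele frequency, in (0, 0.5).
#' @param seed integer seed; output is bit-identical for identical arguments.
#' @param n_founders founder haplotypes per block (default 8).
#' @param switch_rate per-SNP probability that a haplotype switches founder
#'   within a block.
#' @param mutation_rate per-SNP allele flip probability.
#' @param founder_stickiness probability that a founder keeps its allele at
#'   the next SNP of the same block; controls within-block LD strength.
#' @param chrom chromosome label.
#' @param max_attempts resampling attempts per low-MAF column before failing.
#' @return A [genotype_matrix()] with `n_samples` rows and `n_snp` columns;
#'   every column has sample MAF >= `maf_min`.
#' @export
simulate_genotypes <- function(n_samples, n_snp, block_len = 15L, maf_min = 0.05,
                               seed = 1L, n_founders = 8L, switch_rate = 0.02,
                               mutation_rate = 0.008, founder_stickiness = 0.90,
                               chrom = "chr1", max_attempts = 50L) {
  if (!is_count(n_samples, 4L) || !is_count(n_snp, 2L) || !is_count(block_len, 1L))
    stopf("n_samples >= 4, n_snp >= 2 and block_len >= 1 are required",
          class = "invalid_argument")
  check_fraction(maf_min, "maf_min", 0, 0.5, open_lo = TRUE, open_hi = TRUE)
  with_seed(seed, {
    n_hap <- 2L * n_samples
    block <- (seq_len(n_snp) - 1L) %/% block_len
    # founder alleles: sticky Markov chain within block, fresh draw across
    founders <- matrix(0L, n_founders, n_snp)
    founders[, 1L] <- stats::rbinom(n_founders, 1L, 0.5)
    for (j in seq_len(n_snp)[-1L]) {
      if (block[j] != block[j - 1L]) {
        founders[, j] <- stats::rbinom(n_founders, 1L, 0.5)
      } else {
        keep <- stats::rbinom(n_founders, 1L, founder_stickiness) == 1L
        founders[, j] <- ifelse(keep, founders[, j - 1L],
                                stats::rbinom(n_founders, 1L, 0.5))
      }
    }
    # mosaic copying paths
    path <- matrix(0L, n_hap, n_snp)
    path[, 1L] <- sample.int(n_founders, n_hap, replace = TRUE)
    for (j in seq_len(n_snp)[-1L]) {
      if (block[j] != block[j - 1L]) {
        path[, j] <- sample.int(n_founders, n_hap, replace = TRUE)
      } else {
        sw <- stats::runif(n_hap) < switch_rate
        path[, j] <- ifelse(sw, sample.int(n_founders, n_hap, replace = TRUE),
                            path[, j - 1L])
      }
    }
    hap <- matrix(0L, n_hap, n_snp)
    for (j in seq_len(n_snp)) hap[, j] <- founders[path[, j], j]
    flip <- matrix(stats::runif(n_hap * n_snp) < mutation_rate, n_hap, n_snp)
    hap <- (hap + flip) %% 2L
    dos <- hap[seq(1L, n_hap, 2L), , drop = FALSE] + hap[seq(2L, n_hap, 2L), , drop = FALSE]

    maf <- function(col) { f <- mean(col) / 2; min(f, 1 - f) }
    for (j in seq_len(n_snp)) {
      attempt <- 0L
      while (maf(dos[, j]) < maf_min) {
        attempt <- attempt + 1L
        if (attempt > max_attempts)
          stopf("could not reach maf_min at SNP index %d after %d attempts", j,
                max_attempts, class = "generation_failure")
        founders[, j] <- stats::rbinom(n_founders, 1L, stats::runif(1, 0.35, 0.5))
        col <- founders[path[, j], j]
        col <- (col + (stats::runif(n_hap) < mutation_rate)) %% 2L
        dos[, j] <- col[seq(1L, n_hap, 2L)] + col[seq(2L, n_hap, 2L)]
      }
    }
    pos <- cumsum(sample(800:1200, n_snp, replace = TRUE))
    snp_meta <- data.frame(id = sprintf("snp%05d", seq_len(n_snp)), chrom = chrom,
                           pos = as.integer(pos), ref = "A", alt = "G",
                           block = block, stringsAsFactors = FALSE)
    genotype_matrix(dos, snp_meta, sprintf("sample%04d", seq_len(n_samples)))
  })
}

#' Simulate gene annotation
#'
#' Places non-overlapping genes along one chromosome with random strand, GC
#' fraction in \[0.3, 0.7\] and a gene length drawn inside the available
#' spacing. TSS/TES follow transcription order: for a minus-strand gene the
#' TSS is the larger genomic coordinate.
#'
#' @param n_genes number of genes (>= 1).
#' @param chrom_length chromosome length in bp.
#' @param seed integer seed.
#' @param chrom chromosome label.
#' @return data frame with columns `id`, `chrom`, `start`, `end`, `strand`,
#'   `tss`, `tes`, `gc_fraction`, `length_bp` (coordinates 1-based inclusive).
#' @export
simulate_gene_annotation <- function(n_genes, chrom_length, seed = 1L, chrom = "chr1") {
  if (!is_count(n_genes, 1L)) stopf("n_genes must be >= 1", class = "invalid_argument")
  spacing <- floor(chrom_length / n_genes)
  if (spacing < 2000L)
    stopf("cannot place %d non-degenerate genes on %g bp", n_genes, chrom_length,
          class = "generation_failure")
  with_seed(seed, {
    max_len <- max(1000L, min(50000L, floor(spacing * 0.8)))
    len <- sample(seq(1000L, max_len), n_genes, replace = TRUE)
    slack <- spacing - len
    start <- (seq_len(n_genes) - 1L) * spacing + 1L +
      floor(stats::runif(n_genes) * pmax(slack - 1L, 0L))
    end <- start + len - 1L
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    data.frame(
      id = sprintf("gene%04d", seq_len(n_genes)), chrom = chrom,
      start = as.integer(start), end = as.integer(end), strand = strand,
      tss = as.integer(ifelse(strand == "+", start, end)),
      tes = as.integer(ifelse(strand == "+", end, start)),
      gc_fraction = stats::runif(n_genes, 0.3, 0.7),
      length_bp = as.integer(len), stringsAsFactors = FALSE
    )
  })
}

#' Generative settings for synthetic expression
#'
#' Collects the knobs of the negative binomial generative model used by
#' [simulate_expression()]. Defaults describe a clean, confounded bulk
#' RNA-seq cohort: lognormal library sizes, three latent sample factors with
#' per-gene loadings (the variation an analyst would absorb with expression
#' principal components), and a smooth multiplicative GC/length artifact that
#' the normalization module is expected to remove.
#'
#' @param causal data frame with columns `gene_id`, `snp_id`, `beta`; `beta`
#'   is the additive effect of one minor-allele dosage on natural-log mean
#'   expression. May have zero rows (global null).
#' @param n_latent number of latent confounder factors.
#' @param loading_sd standard deviation of per-gene factor loadings (log
#'   scale); factor scores are standard normal per sample.
#' @param baseline_log_range range of per-gene baseline natural-log means.
#' @param dispersion_range range of per-gene NB size parameters (size ->
#'   Inf is Poisson).
#' @param lib_size_sd sd of log-normal library size factors (mean 1).
#' @param gc_coef length-2 numeric `c(b1, b2)`: multiplicative GC artifact
#'   `exp(b1 * gc + b2 * gc^2)`.
#' @param length_exponent exponent of the multiplicative `(length_bp / 1e4)`
#'   artifact.
#' @return list of class `truth_config`.
#' @export
truth_config <- function(causal = NULL, n_latent = 3L, loading_sd = 0.15,
                         baseline_log_range = c(log(50), log(500)),
                         dispersion_range = c(5, 20), lib_size_sd = 0.2,
                         gc_coef = c(2, 2), length_exponent = 0.3) {
  if (is.null(causal))
    causal <- data.frame(gene_id = character(), snp_id = character(), beta = numeric())
  if (any(dispersion_range <= 0))
    stopf("dispersions must be > 0", class = "invalid_argument")
  structure(list(causal = as.data.frame(causal), n_latent = as.integer(n_latent),
                 loading_sd = loading_sd, baseline_log_range = baseline_log_range,
                 dispersion_range = dispersion_range, lib_size_sd = lib_size_sd,
                 gc_coef = gc_coef, length_exponent = length_exponent),
            class = "truth_config")
}

#' Simulate negative binomial expression with planted cis effects
#'
#' Draws gene-by-sample counts from `NB(mu, size)` with
#' `mu[g, s] = lib[s] * gc_len(g) * exp(base_g + sum(beta * dosage) +
#' sum(loading * factor))`, where `gc_len(g) = exp(b1 * gc + b2 * gc^2) *
#' (length_bp / 1e4)^c` is the planted technical artifact and the latent
#' factors are the planted biological confounders. Everything drawn is
#' recorded in the returned truth table so downstream stages can be scored
#' against ground truth.
#'
#' @param G a [genotype_matrix()].
#' @param genes gene annotation as returned by [simulate_gene_annotation()].
#' @param config a [truth_config()].
#' @param seed integer seed.
#' @return list with `counts` (an [expression_counts()]) and `truth` (class
#'   `truth_table`: per-gene parameters, the causal table, per-sample library
#'   factors, latent factor scores and loadings, the annotation, and the
#'   config).
#' @export
simulate_expression <- function(G, genes, config = truth_config(), seed = 1L) {
  stopifnot(inherits(G, "genotype_matrix"))
  causal <- config$causal
  if (nrow(causal)) {
    bad <- setdiff(causal$snp_id, G$snp_meta$id)
    if (length(bad))
      stopf("unknown causal SNP id(s): %s", paste(bad, collapse = ", "),
            class = "invalid_argument")
    bad <- setdiff(causal$gene_id, genes$id)
    if (length(bad))
      stopf("unknown causal gene id(s): %s", paste(bad, collapse = ", "),
            class = "invalid_argument")
  }
  n_s <- nrow(G$dosage); n_g <- nrow(genes)
  with_seed(seed, {
    base <- stats::runif(n_g, config$baseline_log_range[1], config$baseline_log_range[2])
    size <- stats::runif(n_g, config$dispersion_range[1], config$dispersion_range[2])
    lib <- exp(stats::rnorm(n_s, 0, config$lib_size_sd))
    lib <- lib / mean(lib)
    K <- config$n_latent
    latent <- if (K > 0) matrix(stats::rnorm(n_s * K), n_s, K) else matrix(0, n_s, 0)
    loadings <- if (K > 0) matrix(stats::rnorm(n_g * K, 0, config$loading_sd), n_g, K)
                else matrix(0, n_g, 0)
    gc_len <- exp(config$gc_coef[1] * genes$gc_fraction +
                  config$gc_coef[2] * genes$gc_fraction^2) *
      (genes$length_bp / 1e4)^config$length_exponent

    log_mu <- matrix(base, n_g, n_s) + loadings %*% t(latent)
    if (nrow(causal)) {
      gi <- match(causal$gene_id, genes$id)
      si <- match(causal$snp_id, G$snp_meta$id)
      for (k in seq_len(nrow(causal)))
        log_mu[gi[k], ] <- log_mu[gi[k], ] + causal$beta[k] * G$dosage[, si[k]]
    }
    mu <- sweep(exp(log_mu) * gc_len, 2L, lib, `*`)
    if (any(!is.finite(mu)) || any(mu < 0))
      stopf("non-finite or negative NB mean", class = "internal_error")
    counts <- matrix(stats::rnbinom(n_g * n_s, mu = mu, size = rep(size, n_s)), n_g, n_s)
    colnames(counts) <- G$sample_ids
    gm <- genes
    ec <- expression_counts(counts, gm)
    truth <- structure(list(
      genes = data.frame(gene_id = genes$id, baseline_log_mean = base,
                         dispersion = size, gc_fraction = genes$gc_fraction,
                         length_bp = genes$length_bp, stringsAsFactors = FALSE),
      causal = causal,
      samples = data.frame(sample_id = G$sample_ids, library_size_factor = lib,
                           stringsAsFactors = FALSE),
      latent = latent, loadings = loadings, annotation = genes, config = config
    ), class = "truth_table")
    list(counts = ec, truth = truth)
  })
}

#' Simulate a risk-SNP configuration with known LD to the causal SNP
#'
#' Constructs the scenarios behind the pipeline's gene grouping: a risk SNP
#' whose realized LD with a planted causal SNP falls in a designed band
#' (`group1`: r2 > 0.5, `group2`: r2 in \[0.2, 0.5\], `group3`: r2 < 0.2 but
#' inside the causal gene's cis window) or, for `null`, a SNP near a gene
#' with no planted effect. Candidates are drawn from a comfortably interior
#' sub-band when one is populated, so realized LD sits away from the band
#' edges.
#'
#' @param G a [genotype_matrix()].
#' @param truth a `truth_table` from [simulate_expression()].
#' @param scenario one of `"group1"`, `"group2"`, `"group3"`, `"null"`.
#' @param seed integer seed.
#' @param cis_flank cis window half-width around the causal gene (bp).
#' @return one-row data frame: `id`, `chrom`, `pos`, `scenario`,
#'   `causal_gene`, `causal_snp`, `realized_r2` (NA for `null`).
#' @export
simulate_risk_snps <- function(G, truth, scenario = c("group1", "group2", "group3", "null"),
                               seed = 1L, cis_flank = 1e6) {
  scenario <- match.arg(scenario)
  ann <- truth$annotation
  with_seed(seed, {
    if (scenario == "null") {
      free <- setdiff(ann$id, truth$causal$gene_id)
      if (!length(free)) stopf("no effect-free gene available", class = "generation_failure")
      gid <- sample(free, 1L)
      g <- ann[ann$id == gid, ]
      w <- c(min(g$tss, g$tes) - cis_flank, max(g$tss, g$tes) + cis_flank)
      cand <- which(G$snp_meta$chrom == g$chrom & G$snp_meta$pos >= w[1] &
                      G$snp_meta$pos <= w[2])
      if (!length(cand)) stopf("no SNP inside the null gene's cis window",
                               class = "generation_failure")
      j <- sample(cand, 1L)
      return(data.frame(id = G$snp_meta$id[j], chrom = G$snp_meta$chrom[j],
                        pos = G$snp_meta$pos[j], scenario = scenario,
                        causal_gene = gid, causal_snp = NA_character_,
                        realized_r2 = NA_real_, stringsAsFactors = FALSE))
    }
    if (!nrow(truth$causal))
      stopf("scenario %s requires at least one causal SNP", scenario,
            class = "invalid_argument")
    k <- sample.int(nrow(truth$causal), 1L)
    csnp <- truth$causal$snp_id[k]
    cgene <- truth$causal$gene_id[k]
    g <- ann[ann$id == cgene, ]
    w <- c(min(g$tss, g$tes) - cis_flank, max(g$tss, g$tes) + cis_flank)
    cand <- which(G$snp_meta$chrom == g$chrom & G$snp_meta$pos >= w[1] &
                    G$snp_meta$pos <= w[2])
    ci <- match(csnp, G$snp_meta$id)
    r2 <- vapply(cand, function(j) ld_r2(G$dosage[, ci], G$dosage[, j]), numeric(1))
    # preferred sub-bands sit away from the band edges; group3 additionally
    # keeps some residual LD with the causal SNP so a first-stage scan
    # anchored on the risk SNP retains power, as low-LD target genes must
    # still enter through stage 1
    band <- switch(scenario,
                   group1 = list(pref = c(0.65, 1.0001), full = c(0.5 + 1e-12, 1.0001)),
                   group2 = list(pref = c(0.25, 0.45), full = c(0.2, 0.5 + 1e-12)),
                   group3 = list(pref = c(0.08, 0.18), full = c(0, 0.2)))
    inb <- function(b) cand[r2 >= b[1] & r2 < b[2]]
    pick <- inb(band$pref)
    if (!length(pick)) pick <- inb(band$full)
    if (!length(pick))
      stopf("no SNP with r2 in [%g, %g) to causal SNP %s", band$full[1], band$full[2],
            csnp, class = "generation_failure")
    j <- if (length(pick) == 1L) pick else sample(pick, 1L)
    data.frame(id = G$snp_meta$id[j], chrom = G$snp_meta$chrom[j],
               pos = G$snp_meta$pos[j], scenario = scenario,
               causal_gene = cgene, causal_snp = csnp,
               realized_r2 = r2[match(j, cand)], stringsAsFactors = FALSE)
  })
}
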