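# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct factorial enumeration for HWE, lm() /
# normal equations for regression, union-find for interval merging, and
# naive all-pairs scans for LD sets and windows.

# exact HWE p by direct log-factorial enumeration of heterozygote counts
hwe_enum_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  rare <- 2 * min(nAA, naa) + nAa
  if (rare == 0) return(1)
  hs <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  lp <- vapply(hs, function(h) {
    homr <- (rare - h) / 2; homc <- n - h - homr
    lfactorial(n) - lfactorial(homr) - lfactorial(h) - lfactorial(homc) +
      h * log(2) + lfactorial(rare) + lfactorial(2 * n - rare) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(lp - max(lp)); p <- p / sum(p)
  pobs <- p[match(nAa, hs)]
  min(1, sum(p[p <= pobs * (1 + 1e-9)]))
}

# genotype-term t-test from a full lm() fit (external reference for the
# package's own OLS oracle and fast scan)
lm_oracle <- function(g, e, C = NULL) {
  dat <- data.frame(e = e, g = g)
  if (!is.null(C)) {
    C <- as.matrix(C); colnames(C) <- paste0("c", seq_len(ncol(C)))
    dat <- cbind(dat, C)
  }
  fit <- stats::lm(e ~ ., data = dat)
  cs <- summary(fit)$coefficients
  list(beta = cs["g", 1], se = cs["g", 2], t = cs["g", 3], p = cs["g", 4],
       df = fit$df.residual)
}

# union-find merge of risk-SNP LD spans (transitive closure over overlap/abut)
unionfind_intervals_oracle <- function(risk_snps, ld_sets, snp_meta) {
  span <- lapply(risk_snps, function(rs) {
    ids <- union(rs, ld_sets[[rs]])
    p <- snp_meta$pos[match(ids, snp_meta$id)]
    c(min(p), max(p))
  })
  chrom <- vapply(risk_snps, function(rs)
    snp_meta$chrom[match(rs, snp_meta$id)], character(1))
  n <- length(risk_snps)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j || chrom[i] != chrom[j]) next
    if (span[[i]][1] <= span[[j]][2] + 1 && span[[j]][1] <= span[[i]][2] + 1) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lapply(unique(roots), function(r) sort(risk_snps[roots == r]))
}

# naive all-pairs LD expansion
ld_expand_oracle <- function(G, risk_snp, r2_min, flank) {
  i <- match(risk_snp, G$snp_meta$id)
  g0 <- G$dosage[, i]
  keep <- vapply(seq_len(ncol(G$dosage)), function(j) {
    if (G$snp_meta$chrom[j] != G$snp_meta$chrom[i]) return(FALSE)
    if (abs(G$snp_meta$pos[j] - G$snp_meta$pos[i]) > flank) return(FALSE)
    if (j == i) return(TRUE)
    if (stats::var(G$dosage[, j]) == 0) return(FALSE)
    stats::cor(g0, G$dosage[, j])^2 > r2_min
  }, logical(1))
  G$snp_meta$id[keep]
}

# quick powered cohort with one causal gene; returns everything a scan needs
make_causal_cohort <- function(seed, n_samples = 400, n_snp = 200, n_genes = 800,
                               beta = 0.6, block_len = 15, causal_block = NULL,
                               n_latent = 3) {
  G <- simulate_genotypes(n_samples, n_snp, block_len = block_len,
                          maf_min = 0.1, seed = seed)
  chrom_len <- max(max(G$snp_meta$pos) + 1000, n_genes * 5000)
  ann <- simulate_gene_annotation(n_genes, chrom_len, seed = seed + 1)
  blocks <- G$snp_meta$block
  cb <- causal_block %||% blocks[ceiling(n_snp / 2)]
  ci <- which(blocks == cb)[ceiling(block_len / 2)]
  csnp <- G$snp_meta$id[ci]
  # causal gene: the one whose body lies nearest the causal SNP, so it is
  # always inside the cis windows
  gid <- ann$id[which.min(abs((ann$start + ann$end) / 2 - G$snp_meta$pos[ci]))]
  cfg <- truth_config(causal = data.frame(gene_id = gid, snp_id = csnp, beta = beta),
                      n_latent = n_latent)
  sim <- simulate_expression(G, ann, cfg, seed = seed + 2)
  list(G = G, ann = ann, counts = sim$counts, truth = sim$truth,
       causal_gene = gid, causal_snp = csnp)
}

# normalized expression + expression-PC covariates for a cohort
prep_cohort <- function(cohort, pc_var_min = 0.01) {
  fg <- filter_genes(cohort$counts, 0)
  N <- normalize_counts(fg$counts)
  pcs <- expression_pcs(N, pc_var_min)
  list(N = N, C = pcs$scores)
}
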