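#' Minor allele frequency of one SNP
#'
#' @param dosages numeric dosage vector (0/1/2, `NA` allowed); at least one
#'   non-missing entry.
#' @return `min(f, 1 - f)` with `f = sum(dosage) / (2 * n_nonmissing)`.
#' @export
snp_maf <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (!length(d)) stopf("MAF undefined for an all-missing SNP",
                        class = "undefined_statistic")
  f <- sum(d) / (2 * length(d))
  min(f, 1 - f)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test on the conditional distribution of the heterozygote
#' count given the allele counts: the p-value is the sum of probabilities of
#' all heterozygote counts whose probability does not exceed that of the
#' observed count. Probabilities are built by the stable two-directional
#' recurrence from the modal heterozygote count.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total >= 1).
#' @return exact p-value in (0, 1\].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  cnt <- c(n_AA, n_Aa, n_aa)
  if (any(cnt < 0) || any(cnt != floor(cnt)))
    stopf("genotype counts must be non-negative integers", class = "invalid_argument")
  n <- sum(cnt)
  if (n < 1) stopf("at least one genotype is required", class = "invalid_argument")
  rare <- 2 * min(n_AA, n_aa) + n_Aa
  if (rare == 0) return(1)
  # attainable heterozygote counts share the parity of the rare-allele count
  h_min <- rare %% 2
  h_max <- min(rare, 2 * n - rare)
  hs <- seq(h_min, h_max, by = 2)
  probs <- numeric(length(hs))
  # start at the modal count and recurse outward (vectorized via cumprod)
  mid <- rare * (2 * n - rare) / (2 * n)
  mid <- round(mid)
  if ((mid %% 2) != (rare %% 2)) mid <- mid + if (mid < h_max) 1 else -1
  mid <- min(max(mid, h_min), h_max)
  i_mid <- match(mid, hs)
  probs[i_mid] <- 1
  if (i_mid > 1) {
    h <- hs[seq(i_mid, 2L)]             # step h -> h - 2, walking down
    hom_r <- (rare - h) / 2; hom_c <- n - h - hom_r
    probs[seq(i_mid - 1L, 1L)] <- cumprod(h * (h - 1) / (4 * (hom_r + 1) * (hom_c + 1)))
  }
  if (i_mid < length(hs)) {
    h <- hs[seq(i_mid, length(hs) - 1L)]  # step h -> h + 2, walking up
    hom_r <- (rare - h) / 2; hom_c <- n - h - hom_r
    probs[seq(i_mid + 1L, length(hs))] <-
      cumprod(4 * hom_r * hom_c / ((h + 2) * (h + 1)))
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, hs)]
  if (is.na(p_obs)) stopf("inconsistent genotype counts", class = "invalid_argument")
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

#' Apply SNP-level quality control
#'
#' Removes SNPs in a fixed rule order -- duplicate physical position (first
#' copy kept), call rate, exact Hardy-Weinberg p, minor allele frequency --
#' and reports, per SNP, its statistics and the first rule it violated.
#' Filtering is idempotent: a panel that passes is returned unchanged.
#'
#' @param G a [genotype_matrix()].
#' @param call_rate_min minimum call rate (default 0.95; a SNP with call rate
#'   strictly below is removed).
#' @param hwe_p_min minimum exact HWE p-value (default 1e-5).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @return list with `panel` (the filtered `genotype_matrix`) and `report`
#'   (data frame: `id`, `call_rate`, `maf`, `hwe_p`, `kept`, `reason`).
#' @export
apply_snp_qc <- function(G, call_rate_min = 0.95, hwe_p_min = 1e-5, maf_min = 0.01) {
  D <- G$dosage
  n <- nrow(D)
  call_rate <- colMeans(!is.na(D))
  maf <- apply(D, 2L, function(col) if (all(is.na(col))) NA_real_ else snp_maf(col))
  hwe_p <- apply(D, 2L, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(NA_real_)
    hwe_exact_test(sum(col == 0), sum(col == 1), sum(col == 2))
  })
  reason <- rep(NA_character_, ncol(D))
  dup <- duplicated(paste(G$snp_meta$chrom, G$snp_meta$pos))
  reason[dup] <- "duplicate_position"
  todo <- is.na(reason)
  reason[todo & (is.na(call_rate) | call_rate < call_rate_min)] <- "call_rate"
  todo <- is.na(reason)
  reason[todo & (is.na(hwe_p) | hwe_p < hwe_p_min)] <- "hwe"
  todo <- is.na(reason)
  reason[todo & (is.na(maf) | maf < maf_min)] <- "maf"
  kept <- is.na(reason)
  if (!any(kept)) stopf("no SNP survives quality control", class = "qc_empty")
  report <- data.frame(id = G$snp_meta$id, call_rate = call_rate, maf = maf,
                       hwe_p = hwe_p, kept = kept, reason = reason,
                       stringsAsFactors = FALSE)
  attr(report, "thresholds") <- list(call_rate_min = call_rate_min,
                                     hwe_p_min = hwe_p_min, maf_min = maf_min)
  list(panel = genotype_matrix(D[, kept, drop = FALSE],
                               G$snp_meta[kept, , drop = FALSE], G$sample_ids),
       report = report)
}

#' Tracy-Widom TW1 cumulative distribution function
#'
#' Shifted-gamma approximation to the Tracy-Widom distribution of order 1
#' (largest-eigenvalue fluctuation law of a Gaussian orthogonal ensemble),
#' accurate to ~1e-3 over the tail used for eigenvalue screening.
#'
#' @param x quantile(s).
#' @return `P(TW1 <= x)`.
#' @export
ptw1 <- function(x) stats::pgamma(x + 9.84801, shape = 46.446, scale = 0.186054)

#' Genotype principal components with Tracy-Widom screening
#'
#' Mean-imputes missing dosages, centres each SNP at twice its allele
#' frequency and scales by `sqrt(p * (1 - p))` (the binomial standard
#' deviation), then eigen-decomposes the sample covariance of the scaled
#' matrix. Each leading eigenvalue is assigned a TW1 p-value after
#' moment-based effective-marker normalization of the remaining spectrum, the
#' standard screen for population structure.
#'
#' @param G a [genotype_matrix()] (post-QC).
#' @param n_components number of component scores to return.
#' @return list with `scores` (samples x `n_components`), `eigenvalues`
#'   (non-increasing, all `min(n - 1, m)` of them), `tw_stat`, `tw_p`
#'   (aligned with `eigenvalues`), and `n_snps_used`.
#' @export
genotype_pca_tw <- function(G, n_components = 10L) {
  D <- apply(G$dosage, 2L, impute_mean)
  n <- nrow(D)
  if (n < n_components + 2L)
    stopf("need n_samples >= n_components + 2", class = "invalid_argument")
  p_hat <- colMeans(D) / 2
  ok <- p_hat > 0 & p_hat < 1
  if (!all(ok)) {
    warning(sprintf("%d constant SNP(s) excluded from PCA scaling", sum(!ok)))
    D <- D[, ok, drop = FALSE]; p_hat <- p_hat[ok]
  }
  m <- ncol(D)
  X <- sweep(D, 2L, 2 * p_hat, `-`)
  X <- sweep(X, 2L, sqrt(p_hat * (1 - p_hat)), `/`)
  sv <- svd(X, nu = min(n, m), nv = 0)
  K <- min(n - 1L, m)
  lambda <- (sv$d^2 / m)[seq_len(K)]
  tw_stat <- tw_p <- rep(NA_real_, K)
  for (i in seq_len(K)) {
    tail_l <- lambda[i:K]; nl <- length(tail_l)
    if (nl < 2) break
    s1 <- sum(tail_l); s2 <- sum(tail_l^2)
    n_eff <- ((nl + 1) * s1^2) / ((nl - 1) * s2 - s1^2)
    if (!is.finite(n_eff) || n_eff <= 1) break
    l_std <- nl * tail_l[1] / s1
    mu <- (sqrt(n_eff - 1) + sqrt(nl))^2 / n_eff
    sig <- (sqrt(n_eff - 1) + sqrt(nl)) / n_eff *
      (1 / sqrt(n_eff - 1) + 1 / sqrt(nl))^(1 / 3)
    tw_stat[i] <- (l_std - mu) / sig
    tw_p[i] <- 1 - ptw1(tw_stat[i])
  }
  scores <- sv$u[, seq_len(min(n_components, K)), drop = FALSE] %*%
    diag(sv$d[seq_len(min(n_components, K))], nrow = min(n_components, K))
  rownames(scores) <- G$sample_ids
  colnames(scores) <- paste0("gPC", seq_len(ncol(scores)))
  list(scores = scores, eigenvalues = lambda, tw_stat = tw_stat, tw_p = tw_p,
       n_snps_used = m)
}
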