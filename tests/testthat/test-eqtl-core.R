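test_that("residualize projects onto the covariate complement", {
  set.seed(21)
  M <- matrix(rnorm(50 * 10), 50, 10)
  # intercept only: mean-centred columns
  R0 <- residualize(M, matrix(1, 50, 1))
  expect_lt(max(abs(colMeans(R0))), 1e-12)
  expect_equal(R0, sweep(M, 2, colMeans(M)), tolerance = 1e-12)
  # random covariates: match an explicit normal-equations oracle
  C <- cbind(1, matrix(rnorm(50 * 4), 50, 4))
  R1 <- residualize(M, C)
  oracle <- M - C %*% solve(t(C) %*% C, t(C) %*% M)
  expect_lt(max(abs(R1 - oracle)), 1e-10)
  expect_lt(max(abs(crossprod(C, R1))), 1e-8)       # orthogonality
  expect_lt(max(abs(residualize(R1, C) - R1)), 1e-10)  # idempotence
  expect_error(residualize(M, cbind(C, C[, 2])), class = "collinearity_error")
})

test_that("fast scan equals the full-model OLS oracle and lm()", {
  set.seed(22)
  n <- 120; n_cov <- 5
  C <- matrix(rnorm(n * n_cov), n, n_cov)
  X <- cbind(1, C)
  G <- matrix(rbinom(n * 40, 2, 0.3), n, 40,
              dimnames = list(NULL, paste0("s", 1:40)))
  E <- matrix(rnorm(n * 25), n, 25, dimnames = list(NULL, paste0("g", 1:25)))
  fast <- assoc_scan_fast(residualize(G, X), residualize(E, X), n_covariates = n_cov)
  idx <- sample(nrow(fast), 60)
  for (i in idx) {
    si <- match(fast$snp_id[i], colnames(G)); gi <- match(fast$gene_id[i], colnames(E))
    o <- assoc_ols_oracle(G[, si], E[, gi], C)
    expect_equal(fast$t_stat[i], o$t_stat, tolerance = 1e-8)
    expect_equal(fast$beta[i], o$beta, tolerance = 1e-8)
    expect_equal(fast$se[i], o$se, tolerance = 1e-8)
    expect_lt(abs(fast$p_value[i] - o$p_value) / o$p_value, 1e-6)
    lmref <- lm_oracle(G[, si], E[, gi], C)        # external anchor
    expect_equal(o$t_stat, lmref$t, tolerance = 1e-10)
    expect_equal(o$df, lmref$df)
  }
  expect_equal(unique(fast$df), n - n_cov - 2)
})

test_that("the scan handles perfect fits and untestable genotypes", {
  set.seed(23)
  g <- rbinom(60, 2, 0.4)
  X <- matrix(1, 60, 1)
  r <- assoc_scan_fast(residualize(cbind(g = g), X),
                       residualize(cbind(e = g), X), n_covariates = 0)
  expect_equal(r$beta, 1, tolerance = 1e-12)
  expect_equal(r$p_value, .Machine$double.xmin)     # underflow floor
  # zero-variance residual genotype
  r2 <- assoc_scan_fast(residualize(cbind(k = rep(2, 60)), X),
                        residualize(cbind(e = rnorm(60)), X), 0)
  expect_true(r2$untestable)
  expect_true(is.na(r2$p_value))
  # collinear covariate in the oracle
  expect_error(assoc_ols_oracle(g, rnorm(60), cbind(g)),
               class = "collinearity_error")
  # near-noiseless limit recovers the slope
  e <- 2 * g + rnorm(60, 0, 1e-8)
  expect_equal(assoc_ols_oracle(g, e)$beta, 2, tolerance = 1e-6)
})

test_that("null p-values are uniform after breaking the pairing", {
  set.seed(24)
  n <- 200
  G <- matrix(rbinom(n * 100, 2, 0.3), n, 100)
  E <- matrix(rnorm(n * 100), n, 100)
  X <- matrix(1, n, 1)
  r <- assoc_scan_fast(residualize(G, X), residualize(E, X), 0)
  expect_true(mean(r$p_value < 0.05) > 0.04 && mean(r$p_value < 0.05) < 0.06)
})

test_that("Bonferroni threshold arithmetic", {
  expect_equal(bonferroni_threshold(0.05, 10), 0.005)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_gt(bonferroni_threshold(0.05, 7), bonferroni_threshold(0.05, 8))
  expect_error(bonferroni_threshold(0.05, 0), class = "invalid_argument")
})

test_that("degenerate single-pair stage-1 scan reduces to the OLS oracle", {
  co <- make_causal_cohort(71, n_samples = 150, n_snp = 30, n_genes = 40,
                           beta = 0.8, n_latent = 0)
  pr <- prep_cohort(co)
  rs_id <- co$causal_snp
  iv <- build_risk_intervals(rs_id,
                             stats::setNames(list(rs_id), rs_id), co$G$snp_meta)
  # restrict to one SNP and one gene via a tiny window
  cfg <- scan_config(flank_stage1 = 1e9)
  s1 <- stage1_scan(co$G, pr$N, pr$C, iv, cfg)
  row <- s1$results[s1$results$snp_id == rs_id &
                      s1$results$gene_id == co$causal_gene, ]
  D <- co$G$dosage[, rs_id]
  o <- assoc_ols_oracle(D, pr$N$values[co$causal_gene, ], pr$C)
  expect_equal(row$t_stat, o$t_stat, tolerance = 1e-8)
  expect_equal(s1$threshold, 0.05 / s1$n_tests)
})

test_that("stage-1 and stage-2 pair sets are disjoint", {
  co <- make_causal_cohort(72, n_samples = 200, n_snp = 120, n_genes = 800,
                           beta = 0.8)
  pr <- prep_cohort(co)
  rs <- simulate_risk_snps(co$G, co$truth, "group1", seed = 73)
  ld <- stats::setNames(list(expand_ld_set(co$G, rs$id)), rs$id)
  iv <- build_risk_intervals(rs$id, ld, co$G$snp_meta)
  s1 <- stage1_scan(co$G, pr$N, pr$C, iv, scan_config())
  tg <- unique(s1$results$gene_id[s1$results$significant])
  expect_true(co$causal_gene %in% tg)
  excl <- unique(unlist(iv$ld_snp_ids))
  s2 <- stage2_scan(co$G, pr$N, pr$C, tg, stage1_snp_ids = excl, cfg = scan_config())
  p1 <- paste(s1$results$snp_id, s1$results$gene_id)
  p2 <- paste(s2$results$snp_id, s2$results$gene_id)
  expect_length(intersect(p1, p2), 0)
  # exclusion of every in-window SNP yields a zero-test record, not an error
  s2b <- stage2_scan(co$G, pr$N, pr$C, tg, stage1_snp_ids = co$G$snp_meta$id,
                     cfg = scan_config())
  expect_equal(s2b$n_tests, 0L)
  expect_true(all(tg %in% s2b$zero_test_genes))
})

test_that("NB GLM is calibrated under the null and concordant with OLS", {
  set.seed(26)
  n <- 150
  g <- rbinom(n, 2, 0.3)
  off <- rnorm(n, 0, 0.2)
  ps <- vapply(1:1000, function(i) {
    y <- rnbinom(n, mu = exp(log(60) + off), size = 8)
    nb_glm_assoc(y, g, offsets = off)$p_value
  }, numeric(1))
  frac <- mean(ps < 0.05)
  expect_true(frac > 0.03 && frac < 0.07)

  # concordance with the linear pipeline on planted effects
  co <- make_causal_cohort(74, n_samples = 250, n_snp = 40, n_genes = 50,
                           beta = 0.5, n_latent = 0)
  pr <- prep_cohort(co, pc_var_min = 1)              # no PCs, clean cohort
  D <- co$G$dosage
  X <- matrix(1, 250, 1)
  fast <- assoc_scan_fast(residualize(D, X), residualize(t(pr$N$values), X), 0)
  strong <- fast[!fast$untestable & fast$p_value < 1e-4, ]
  agree <- vapply(seq_len(nrow(strong)), function(i) {
    y <- co$counts$counts[strong$gene_id[i], ]
    nb <- nb_glm_assoc(y, D[, strong$snp_id[i]],
                       offsets = pr$N$log_offset[strong$gene_id[i], ])
    sign(nb$beta) == sign(strong$beta[i])
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})

test_that("NB Wald approaches the Poisson limit as dispersion vanishes", {
  set.seed(27)
  n <- 300
  g <- rbinom(n, 2, 0.4)
  y <- rpois(n, exp(log(50) + 0.3 * g))
  nb <- nb_glm_assoc(y, g, size = 1e6)
  po <- summary(stats::glm(y ~ g, family = stats::poisson()))$coefficients
  expect_lt(abs(nb$z - po["g", 3]) / abs(po["g", 3]), 0.01)
})
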