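make_counts <- function(counts, gc = NULL, len = NULL) {
  n_g <- nrow(counts)
  expression_counts(counts, data.frame(
    id = paste0("g", seq_len(n_g)), chrom = "chr1",
    start = seq_len(n_g) * 1000L, end = seq_len(n_g) * 1000L + 500L,
    strand = "+", tss = seq_len(n_g) * 1000L, tes = seq_len(n_g) * 1000L + 500L,
    gc_fraction = gc %||% rep(0.5, n_g), length_bp = len %||% rep(501L, n_g)))
}

test_that("gene filtering applies the strict median rule and keeps order", {
  cnt <- rbind(rep(0, 6), rep(5, 6), rep(13, 6), rep(14, 6), rep(100, 6))
  E <- make_counts(cnt)
  f <- filter_genes(E, 14)
  expect_identical(f$counts$gene_meta$id, c("g4", "g5"))   # median 14 kept
  expect_identical(f$removed$reason, c("undetectable", "low_median", "low_median"))
  # idempotent and order preserving
  f2 <- filter_genes(f$counts, 14)
  expect_identical(f2$counts$counts, f$counts$counts)
  expect_equal(nrow(f2$removed), 0L)
  expect_error(filter_genes(E, 1000), class = "filter_empty")
})

test_that("normalization reduces to a per-sample shift without GC/length variation", {
  set.seed(4)
  cnt <- matrix(rnbinom(200 * 10, mu = 100, size = 10), 200, 10)
  E <- make_counts(cnt)                      # constant gc and length
  N <- normalize_counts(E)
  diffs <- N$values - log2(cnt + 0.5)
  expect_lt(max(apply(diffs, 2, var)), 1e-8) # column-wise constant shift
})

test_that("normalization is invariant to library depth", {
  set.seed(5)
  n_g <- 500
  gc <- runif(n_g, 0.3, 0.7)
  len <- sample(1000:20000, n_g, replace = TRUE)
  cnt <- matrix(rnbinom(n_g * 8, mu = 300, size = 10), n_g, 8)
  E1 <- make_counts(cnt, gc, len)
  cnt2 <- cnt; cnt2[, 3] <- cnt[, 3] * 2L
  E2 <- make_counts(cnt2, gc, len)
  N1 <- normalize_counts(E1); N2 <- normalize_counts(E2)
  expect_lt(max(abs(N1$values[, 3] - N2$values[, 3])), 0.05)
  expect_lt(max(abs(N1$values[, -3] - N2$values[, -3])), 1e-8)
  expect_error(normalize_counts(make_counts(matrix(0L, 5, 4))),
               class = "invalid_argument")
})

test_that("a planted quadratic GC artifact is removed", {
  # bounds fixed from 10 seeded replicates: raw |cor| with GC > 0.3 in every
  # sample, normalized |cor| < 0.05
  for (s in 1:10) {
    G <- simulate_genotypes(60, 10, block_len = 5, seed = s)
    ann <- simulate_gene_annotation(800, 8e6, seed = s + 100)
    sim <- simulate_expression(G, ann, truth_config(n_latent = 0), seed = s + 200)
    N <- normalize_counts(sim$counts)
    gc <- ann$gc_fraction
    raw <- apply(log2(sim$counts$counts + 0.5), 2, function(y) abs(cor(y, gc)))
    post <- apply(N$values, 2, function(y) abs(cor(y, gc)))
    expect_gt(min(raw), 0.3)
    expect_lt(max(post), 0.05)
  }
})

test_that("normalization is monotone in the count within a slot", {
  set.seed(6)
  n_g <- 300
  gc <- runif(n_g, 0.3, 0.7)
  cnt <- matrix(rnbinom(n_g * 5, mu = 150, size = 8), n_g, 5)
  cnt2 <- cnt; cnt2[7, 2] <- cnt[7, 2] + 25L
  # same metadata and same fitted offsets apply; larger count in the slot
  # must give a larger normalized value when offsets are held fixed
  E <- make_counts(cnt, gc)
  N <- normalize_counts(E)
  v1 <- N$values[7, 2]
  v2 <- log2(cnt2[7, 2] + 0.5) - log2(N$lib_size_factor[2]) -
    (log2(cnt[7, 2] + 0.5) - N$values[7, 2] - log2(N$lib_size_factor[2]))
  expect_gt(v2, v1)
})

test_that("expression PCs recover planted factors", {
  set.seed(7)
  n_s <- 80; n_g <- 400
  f <- rnorm(n_s)
  load <- rnorm(n_g, 0, 1)
  V <- outer(load, f) + matrix(rnorm(n_g * n_s, 0, 0.05), n_g, n_s)
  pcs <- expression_pcs(V, 0.01)
  expect_equal(pcs$n_selected, 1L)
  expect_gt(abs(cor(pcs$scores[, 1], f)), 0.99)
  expect_equal(expression_pcs(V, 1.0)$n_selected, 0L)    # extreme threshold
  ve <- pcs$var_explained
  expect_true(all(diff(ve) <= 1e-12))
  expect_lte(sum(ve), 1 + 1e-8)
  # three strong well-separated factors
  FF <- matrix(rnorm(n_s * 3), n_s, 3)
  L <- matrix(rnorm(n_g * 3, 0, c(3, 2, 1.5)), n_g, 3, byrow = TRUE)
  V3 <- L %*% t(FF) + matrix(rnorm(n_g * n_s, 0, 0.1), n_g, n_s)
  p3 <- expression_pcs(V3, 0.01)
  expect_gte(p3$n_selected, 3L)
  cc <- cancor(p3$scores[, 1:3], FF)$cor
  expect_gt(min(cc), 0.95)
})

test_that("covariate screen flags planted confounders and stays calibrated", {
  # planted confounder: flagged in 10 of 10 seeded runs
  for (s in 1:10) {
    set.seed(s)
    n_s <- 60; n_g <- 300
    f <- rnorm(n_s)
    V <- outer(rnorm(n_g, 0, 0.6), f) + matrix(rnorm(n_g * n_s), n_g, n_s)
    sc <- screen_covariates(V, cbind(conf = f), p_min = 1e-5)
    expect_true(sc$associated)
  }
  # pure-noise candidate against 1000 genes: flag rate ~ 1%
  set.seed(77)
  flags <- vapply(1:200, function(i) {
    V <- matrix(rnorm(1000 * 40), 1000, 40)
    screen_covariates(V, cbind(x = rnorm(40)), p_min = 1e-5)$associated
  }, logical(1))
  expect_lte(mean(flags), 0.025)
  # alignment invariance under joint permutation
  set.seed(9)
  V <- matrix(rnorm(200 * 30), 200, 30); x <- rnorm(30)
  p1 <- screen_covariates(V, cbind(x = x))$min_p
  perm <- sample(30)
  p2 <- screen_covariates(V[, perm], cbind(x = x[perm]))$min_p
  expect_equal(p1, p2, tolerance = 1e-12)
  # constant candidate is non-testable
  expect_false(screen_covariates(V, cbind(k = rep(1, 30)))$testable)
})
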