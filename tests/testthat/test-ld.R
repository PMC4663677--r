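test_that("ld_r2 is symmetric, flip-invariant and bounded", {
  G <- simulate_genotypes(200, 30, block_len = 10, seed = 12)
  g1 <- G$dosage[, 5]; g2 <- G$dosage[, 6]
  expect_identical(ld_r2(g1, g1), 1)
  expect_equal(ld_r2(g1, 2 - g1), 1)
  expect_equal(ld_r2(g1, g2), ld_r2(g2, g1), tolerance = 1e-12)
  for (j in 2:30) {
    r <- ld_r2(G$dosage[, 1], G$dosage[, j])
    expect_true(r >= 0 && r <= 1)
  }
  expect_error(ld_r2(rep(1, 10), g1[1:10]), class = "undefined_ld")
})

test_that("independent SNPs have mean r2 near 1/(n-1)", {
  set.seed(13)
  n <- 1000
  A <- matrix(rbinom(n * 100, 2, 0.3), n, 100)
  B <- matrix(rbinom(n * 100, 2, 0.3), n, 100)
  # 10,000 independent pairs via the 100 x 100 cross grid
  As <- scale(A); Bs <- scale(B)
  r2 <- (crossprod(As, Bs) / (n - 1))^2
  expect_equal(mean(r2), 1 / (n - 1), tolerance = 0.2)
})

test_that("LD expansion equals the naive all-pairs scan and is strict", {
  for (s in 1:5) {
    G <- simulate_genotypes(150, 80, block_len = 8, seed = s + 20)
    rs <- G$snp_meta$id[40]
    got <- expand_ld_set(G, rs, r2_min = 0.5, search_flank = 2e6)
    expect_identical(got, ld_expand_oracle(G, rs, 0.5, 2e6))
    expect_true(rs %in% got)
  }
  # strictness at the boundary: a SNP whose r2 equals the threshold exactly
  # is excluded, and included once the threshold drops below it
  G <- simulate_genotypes(100, 10, block_len = 5, seed = 30)
  r2 <- ld_r2(G$dosage[, 3], G$dosage[, 4])
  rs <- G$snp_meta$id[3]
  expect_false(G$snp_meta$id[4] %in% expand_ld_set(G, rs, r2_min = r2))
  expect_true(G$snp_meta$id[4] %in% expand_ld_set(G, rs, r2_min = r2 - 1e-9))
  # no correlated neighbour: singleton set
  set.seed(31)
  D <- cbind(rbinom(500, 2, 0.4), rbinom(500, 2, 0.4), rbinom(500, 2, 0.4))
  Gi <- genotype_matrix(D, data.frame(id = c("a", "b", "c"), chrom = "chr1",
                                      pos = c(1, 2, 3) * 1000))
  expect_identical(expand_ld_set(Gi, "b", 0.5), "b")
  expect_error(expand_ld_set(Gi, "zz", 0.5), class = "unknown_snp")
})

test_that("risk-interval merging matches a union-find oracle", {
  # two well-separated risk SNPs stay apart; a shared LD-SNP merges them
  meta <- data.frame(id = paste0("s", 1:6), chrom = "chr1",
                     pos = c(100, 200, 300, 5e6, 5.1e6, 5.2e6))
  iv <- build_risk_intervals(c("s1", "s5"),
                             list(s1 = c("s1", "s2"), s5 = c("s5", "s6")), meta)
  expect_equal(nrow(iv), 2L)
  iv2 <- build_risk_intervals(c("s1", "s3"),
                              list(s1 = c("s1", "s2"), s3 = c("s2", "s3")), meta)
  expect_equal(nrow(iv2), 1L)
  expect_setequal(iv2$member_risk_snps[[1]], c("s1", "s3"))
  # transitive chain: A-B overlap, B-C overlap, A-C disjoint
  meta3 <- data.frame(id = paste0("s", 1:3), chrom = "chr1", pos = c(100, 500, 900))
  ch <- build_risk_intervals(paste0("s", 1:3),
                             list(s1 = c("s1", "s2"), s2 = c("s1", "s3"),
                                  s3 = c("s2", "s3")), meta3)
  expect_equal(nrow(ch), 1L)
  # 100 random fixtures against the union-find oracle
  set.seed(14)
  for (i in 1:100) {
    n_snp <- 30
    meta_r <- data.frame(id = paste0("s", 1:n_snp),
                         chrom = sample(c("chr1", "chr2"), 1),
                         pos = sort(sample(1:20000, n_snp)))
    rs <- paste0("s", sort(sample(n_snp, 5)))
    ld <- lapply(rs, function(r) {
      i <- match(r, meta_r$id)
      near_idx <- which(abs(meta_r$pos - meta_r$pos[i]) < 3000)
      unique(c(r, meta_r$id[sample(near_idx, min(length(near_idx), 3))]))
    })
    names(ld) <- rs
    got <- build_risk_intervals(rs, ld, meta_r)
    want <- unionfind_intervals_oracle(rs, ld, meta_r)
    got_sets <- lapply(got$member_risk_snps, sort)
    expect_setequal(vapply(got_sets, paste, character(1), collapse = ","),
                    vapply(want, paste, character(1), collapse = ","))
    # partition: every risk SNP in exactly one interval; LD union preserved
    expect_setequal(unlist(got$member_risk_snps), rs)
    expect_equal(anyDuplicated(unlist(got$member_risk_snps)), 0L)
    expect_setequal(unlist(got$ld_snp_ids), unique(c(rs, unlist(ld))))
  }
})

test_that("windows are correct arithmetic and match brute-force membership", {
  iv <- data.frame(interval_id = "i1", chrom = "chr1",
                   span_start = 5000000, span_end = 5010000)
  class(iv) <- c("risk_intervals", "data.frame")
  w <- make_windows(iv, "stage1", flank = 1e6)
  expect_equal(c(w$window_start, w$window_end), c(4000000, 6010000))
  expect_error(make_windows(iv, "stage1", flank = -1), class = "invalid_argument")
  # stage-2 gene windows and membership vs brute force
  set.seed(15)
  genes <- simulate_gene_annotation(20, 5e6, seed = 16)
  w2 <- make_windows(genes, "stage2", flank = 1.1e6)
  pos <- sort(sample(1:5e6, 500))
  for (k in sample(20, 5)) {
    inw <- pos >= w2$window_start[k] & pos <= w2$window_end[k]
    brute <- abs(pos - pmin(genes$tss[k], genes$tes[k])) <= 1.1e6 |
      abs(pos - pmax(genes$tss[k], genes$tes[k])) <= 1.1e6 |
      (pos >= genes$start[k] & pos <= genes$end[k])
    expect_identical(inw, brute)
  }
  # a gene strictly beyond flank + span is excluded from a stage-1 window
  far_gene_start <- 6010000 + 1
  expect_false(far_gene_start <= w$window_end)
})
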