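#' Pairwise LD as squared Pearson correlation of dosages
#'
#' Computes r2 between two dosage vectors on unphased genotypes (composite
#' LD). Missing calls are mean-imputed per SNP before correlating. The value
#' is symmetric and invariant to allele flips (`g -> 2 - g`).
#'
#' @param g1,g2 numeric dosage vectors of equal length (0/1/2, `NA` allowed).
#' @return r2 in \[0, 1\].
#' @export
ld_r2 <- function(g1, g2) {
  if (length(g1) != length(g2))
    stopf("dosage vectors must have equal length", class = "invalid_argument")
  g1 <- impute_mean(g1); g2 <- impute_mean(g2)
  v1 <- stats::var(g1); v2 <- stats::var(g2)
  if (is.na(v1) || is.na(v2) || v1 == 0 || v2 == 0)
    stopf("LD undefined for a zero-variance dosage vector", class = "undefined_ld")
  r <- stats::cor(g1, g2)
  min(r * r, 1)
}

impute_mean <- function(g) {
  if (anyNA(g)) {
    m <- mean(g, na.rm = TRUE)
    if (is.nan(m)) stopf("all-missing dosage vector", class = "undefined_statistic")
    g[is.na(g)] <- m
  }
  g
}

#' Expand one risk SNP into its LD-SNP set
#'
#' Returns the ids of all SNPs within `search_flank` bp of the risk SNP whose
#' r2 with it strictly exceeds `r2_min`, always including the risk SNP
#' itself. This is the set scanned against expression in the first-stage
#' analysis.
#'
#' @param G a [genotype_matrix()].
#' @param risk_snp SNP id present in `G`.
#' @param r2_min LD threshold, in (0, 1\]; strict inequality (`r2 = r2_min`
#'   is excluded).
#' @param search_flank search radius in bp around the risk SNP position.
#' @return character vector of SNP ids, in panel order.
#' @export
expand_ld_set <- function(G, risk_snp, r2_min = 0.5, search_flank = 2e6) {
  i <- match(risk_snp, G$snp_meta$id)
  if (is.na(i)) stopf("risk SNP %s is not in the panel", risk_snp, class = "unknown_snp")
  check_fraction(r2_min, "r2_min", 0, 1, open_lo = TRUE)
  pos <- G$snp_meta$pos[i]; ch <- G$snp_meta$chrom[i]
  cand <- which(G$snp_meta$chrom == ch & abs(G$snp_meta$pos - pos) <= search_flank)
  g0 <- impute_mean(G$dosage[, i])
  keep <- vapply(cand, function(j) {
    if (j == i) return(TRUE)
    gj <- impute_mean(G$dosage[, j])
    if (stats::var(gj) == 0) return(FALSE)
    stats::cor(g0, gj)^2 > r2_min
  }, logical(1))
  G$snp_meta$id[cand[keep]]
}

#' Merge risk SNPs into unique risk intervals
#'
#' Each risk SNP spans the positions of its LD-SNP set; risk SNPs on the same
#' chromosome whose spans overlap or abut are merged transitively into one
#' interval, so nearby tag SNPs sharing LD structure are analysed once.
#'
#' @param risk_snps character vector of risk SNP ids.
#' @param ld_sets named list (one element per risk SNP) of LD-SNP id vectors,
#'   as from [expand_ld_set()].
#' @param snp_meta data frame with `id`, `chrom`, `pos` covering every SNP
#'   referenced.
#' @return data frame of class `risk_intervals`, sorted by coordinate, with
#'   columns `interval_id`, `chrom`, `span_start`, `span_end`,
#'   `member_risk_snps` and `ld_snp_ids` (list columns).
#' @export
build_risk_intervals <- function(risk_snps, ld_sets, snp_meta) {
  if (!all(risk_snps %in% names(ld_sets)))
    stopf("every risk SNP needs an LD set", class = "invalid_argument")
  miss <- setdiff(unique(unlist(ld_sets[risk_snps])), snp_meta$id)
  if (length(miss))
    stopf("SNP(s) missing coordinates: %s", paste(miss, collapse = ", "),
          class = "invalid_argument")
  span <- lapply(risk_snps, function(rs) {
    ids <- union(rs, ld_sets[[rs]])
    m <- snp_meta[match(ids, snp_meta$id), ]
    if (length(unique(m$chrom)) != 1L)
      stopf("LD set of %s spans chromosomes", rs, class = "invalid_argument")
    list(chrom = m$chrom[1], start = min(m$pos), end = max(m$pos), ids = ids)
  })
  names(span) <- risk_snps
  # sweep per chromosome; merge when spans overlap or abut (gap <= 1 bp)
  out <- list()
  for (ch in unique(vapply(span, `[[`, character(1), "chrom"))) {
    rs <- risk_snps[vapply(span, function(s) s$chrom == ch, logical(1))]
    ord <- order(vapply(span[rs], `[[`, numeric(1), "start"))
    rs <- rs[ord]
    cur <- NULL
    for (r in rs) {
      s <- span[[r]]
      if (is.null(cur)) {
        cur <- list(chrom = ch, start = s$start, end = s$end, members = r, ids = s$ids)
      } else if (s$start <= cur$end + 1) {
        cur$end <- max(cur$end, s$end)
        cur$members <- c(cur$members, r)
        cur$ids <- union(cur$ids, s$ids)
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- list(chrom = ch, start = s$start, end = s$end, members = r, ids = s$ids)
      }
    }
    if (!is.null(cur)) out[[length(out) + 1L]] <- cur
  }
  ord <- order(vapply(out, `[[`, character(1), "chrom"),
               vapply(out, `[[`, numeric(1), "start"))
  out <- out[ord]
  res <- data.frame(
    interval_id = sprintf("interval%03d", seq_along(out)),
    chrom = vapply(out, `[[`, character(1), "chrom"),
    span_start = vapply(out, `[[`, numeric(1), "start"),
    span_end = vapply(out, `[[`, numeric(1), "end"),
    stringsAsFactors = FALSE
  )
  res$member_risk_snps <- lapply(out, `[[`, "members")
  res$ld_snp_ids <- lapply(out, `[[`, "ids")
  class(res) <- c("risk_intervals", "data.frame")
  res
}

#' Construct stage-1 or stage-2 cis windows
#'
#' Stage 1 windows flank a risk interval span; a gene belongs to the window
#' when any part of its body overlaps it. Stage 2 windows flank the gene
#' (min/max of TSS and TES); a SNP belongs when its position lies inside,
#' inclusive. Windows are clipped at 1 and, when given, the chromosome
#' length. All coordinates are 1-based inclusive.
#'
#' @param x for `mode = "stage1"` a `risk_intervals` data frame; for
#'   `mode = "stage2"` a gene annotation data frame (`id`, `chrom`, `tss`,
#'   `tes`).
#' @param mode `"stage1"` or `"stage2"`.
#' @param flank window half-width in bp (> 0).
#' @param chrom_length optional upper clip.
#' @return data frame with `id`, `chrom`, `window_start`, `window_end`.
#' @export
make_windows <- function(x, mode = c("stage1", "stage2"), flank, chrom_length = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(flank) || flank <= 0)
    stopf("flank must be positive", class = "invalid_argument")
  if (mode == "stage1") {
    ws <- x$span_start - flank; we <- x$span_end + flank
    id <- x$interval_id
  } else {
    ws <- pmin(x$tss, x$tes) - flank; we <- pmax(x$tss, x$tes) + flank
    id <- x$id
  }
  ws <- pmax(ws, 1)
  if (!is.null(chrom_length)) we <- pmin(we, chrom_length)
  data.frame(id = id, chrom = x$chrom, window_start = ws, window_end = we,
             stringsAsFactors = FALSE)
}

#' @export
print.risk_intervals <- function(x, ...) {
  cat(sprintf("risk_intervals: %d interval(s) from %d risk SNP(s), %d LD-SNPs\n",
              nrow(x), length(unique(unlist(x$member_risk_snps))),
              length(unique(unlist(x$ld_snp_ids)))))
  invisible(x)
}
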