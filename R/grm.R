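#' Genomic relationship matrix (VanRaden method 1)
#'
#' Centers dosages by twice the observed allele frequency per SNP and scales
#' by the total expected heterozygosity: `G = Z Z' / (2 * sum(p * (1 - p)))`.
#' SNPs with minor-allele frequency below `min_maf` or with zero variance are
#' excluded (count recorded in attributes).
#'
#' @param geno Integer matrix of dosages in `{0, 1, 2}`, individuals in rows
#'   (rownames are individual ids), SNPs in columns.
#' @param min_maf Minimum minor-allele frequency for a SNP to be used.
#' @return A dense symmetric matrix of class `relatedness_matrix` with
#'   attributes `kind = "genomic_G"`, `n_snps_used`, `n_snps_excluded`.
#' @export
compute_grm <- function(geno, min_maf = 0.01) {
  geno <- as.matrix(geno)
  if (nrow(geno) < 2) abort("need at least two individuals")
  check_number(min_maf, "min_maf", lower = 0, upper = 0.5)
  p <- colMeans(geno) / 2
  maf <- pmin(p, 1 - p)
  use <- maf >= min_maf & maf > 0
  if (!any(use)) abort("no SNP passes the MAF filter; cannot build a GRM")
  Z <- sweep(geno[, use, drop = FALSE], 2, 2 * p[use])
  denom <- 2 * sum(p[use] * (1 - p[use]))
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(geno), rownames(geno))
  structure(G, kind = "genomic_G",
            n_snps_used = sum(use), n_snps_excluded = sum(!use),
            class = c("relatedness_matrix", class(G)))
}

#' Greedy windowed LD pruning
#'
#' Walks left to right within each chromosome (map position order) and drops
#' a SNP whenever its squared Pearson correlation of dosages with any of the
#' most recently retained `window_snps` SNPs exceeds `r2_threshold` (the
#' earlier SNP is kept). Zero-variance SNPs carry no LD information and are
#' retained without affecting other decisions. Deterministic.
#'
#' @param geno Dosage matrix, individuals x SNPs.
#' @param map Optional tibble with per-SNP `chrom` and `pos` (one row per
#'   column of `geno`, in column order). When `NULL` all SNPs are treated as
#'   one chromosome in column order.
#' @param r2_threshold Squared-correlation threshold; default 0.7.
#' @param window_snps Number of trailing retained SNPs compared against.
#' @return Sorted integer vector of retained column indices.
#' @export
ld_prune <- function(geno, map = NULL, r2_threshold = 0.7, window_snps = 50) {
  geno <- as.matrix(geno)
  m <- ncol(geno)
  check_number(r2_threshold, "r2_threshold", lower = 0, upper = 1)
  if (r2_threshold == 0) abort("`r2_threshold` must be in (0, 1]")
  check_number(window_snps, "window_snps", lower = 2)
  if (is.null(map)) {
    map <- tibble::tibble(chrom = rep("1", m), pos = seq_len(m))
  }
  check_columns(map, c("chrom", "pos"), "map")
  if (nrow(map) != m) abort("`map` must have one row per SNP column")

  sds <- apply(geno, 2, sd)
  kept <- integer(0)
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    idx <- idx[order(map$pos[idx])]
    kept_chr <- integer(0)
    for (j in idx) {
      if (sds[j] == 0) { kept_chr <- c(kept_chr, j); next }
      cmp <- tail(kept_chr[sds[kept_chr] > 0], window_snps)
      drop <- FALSE
      if (length(cmp)) {
        r2 <- drop(cor(geno[, j], geno[, cmp, drop = FALSE]))^2
        drop <- any(r2 > r2_threshold, na.rm = TRUE)
      }
      if (!drop) kept_chr <- c(kept_chr, j)
    }
    kept <- c(kept, kept_chr)
  }
  sort(kept)
}
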