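#' Map SNPs to genes within a basepair window
#'
#' A gene is linked to a SNP when the SNP position falls in the closed
#' interval `[start - window_bp, end + window_bp]` on the same chromosome
#' (1-based, fully closed coordinates; strand-agnostic). Fails, listing the
#' offending names, when a SNP chromosome is absent from the gene table.
#'
#' @param snps Tibble with `snp_id`, `chrom`, `pos`.
#' @param genes Tibble with `gene_id`, `chrom`, `start`, `end` (optional
#'   `strand`, ignored).
#' @param window_bp Flanking window, default 100000.
#' @return A list: `genes` (deduplicated gene ids) and `hits` (per SNP-gene
#'   pair table).
#' @export
map_snps_to_genes <- function(snps, genes, window_bp = 100000) {
  check_columns(snps, c("snp_id", "chrom", "pos"), "snps")
  check_columns(genes, c("gene_id", "chrom", "start", "end"), "genes")
  check_number(window_bp, "window_bp", lower = 0)
  unmatched <- setdiff(unique(snps$chrom), unique(genes$chrom))
  if (length(unmatched)) {
    abort(sprintf("SNP chromosome(s) absent from the gene table: %s",
                  paste(unmatched, collapse = ", ")))
  }
  hits <- dplyr::inner_join(
    dplyr::select(snps, "snp_id", "chrom", "pos"),
    dplyr::select(genes, "gene_id", "chrom", "start", "end"),
    by = "chrom", relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$pos >= .data$start - window_bp,
                  .data$pos <= .data$end + window_bp)
  list(genes = unique(hits$gene_id), hits = hits)
}

#' Hypergeometric gene-set over-representation test
#'
#' One-sided upper-tail hypergeometric test per gene set: with `N` universe
#' genes, `K` of them in the set, and `n` query genes (after intersecting the
#' query with the universe) of which `k` are in the set, the p-value is
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`. P-values are
#' Bonferroni-adjusted across the sets tested; sets with `k = 0` get `p = 1`.
#'
#' @param query Character vector of query gene ids.
#' @param gene_sets Named list of character vectors (or a tibble with
#'   columns `set` and `gene_id`).
#' @param universe Character vector of all annotated genes.
#' @return A tibble of class `enrichment_result` with `set`, `k`, `n`, `K`,
#'   `N`, `gene_ratio`, `p`, `p_adjusted`.
#' @export
enrichment_test <- function(query, gene_sets, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) abort("`universe` is empty")
  if (is.data.frame(gene_sets)) {
    check_columns(gene_sets, c("set", "gene_id"), "gene_sets")
    gene_sets <- split(as.character(gene_sets$gene_id), gene_sets$set)
  }
  if (is.null(names(gene_sets))) abort("`gene_sets` must be named")
  q <- intersect(unique(as.character(query)), universe)
  n <- length(q)
  N <- length(universe)
  n_sets <- length(gene_sets)
  out <- purrr::imap_dfr(gene_sets, function(g, nm) {
    gs <- intersect(unique(as.character(g)), universe)
    K <- length(gs)
    k <- length(intersect(q, gs))
    p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(set = nm, k = k, n = n, K = K, N = N,
                   gene_ratio = sprintf("%d/%d", k, n), p = p)
  })
  out$p_adjusted <- pmin(1, out$p * n_sets)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Read gene sets from a GMT file
#'
#' Tab-separated: set name, description, then member gene ids, one set per
#' line.
#'
#' @param path Path to the `.gmt` file.
#' @return A named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3
  if (any(bad)) abort(sprintf("malformed GMT line(s): %s",
                              paste(which(bad), collapse = ", ")))
  setNames(lapply(parts, function(x) x[-(1:2)]),
           vapply(parts, `[[`, character(1), 1))
}
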