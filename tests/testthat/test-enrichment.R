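test_that("window mapping uses closed bounds and matches a brute-force scan", {
  genes <- tibble::tibble(gene_id = c("gA", "gB"), chrom = c("1", "1"),
                          start = c(5000L, 900000L), end = c(7000L, 950000L))
  inside <- tibble::tibble(snp_id = "in", chrom = "1", pos = 6000L)
  expect_identical(map_snps_to_genes(inside, genes)$genes, "gA")
  # exactly window downstream of gene end: included; one bp further: excluded
  edge <- tibble::tibble(snp_id = "e", chrom = "1", pos = 7000L + 100000L)
  expect_identical(map_snps_to_genes(edge, genes)$genes, "gA")
  out <- tibble::tibble(snp_id = "o", chrom = "1", pos = 7000L + 100001L)
  expect_identical(length(map_snps_to_genes(out, genes)$genes), 0L)

  # random annotation equals a brute-force interval scan
  set.seed(101)
  genes2 <- tibble::tibble(gene_id = paste0("g", 1:60),
                           chrom = as.character(sample(1:3, 60, TRUE)),
                           start = sample.int(5e6, 60))
  genes2$end <- genes2$start + sample.int(5e4, 60)
  snps <- tibble::tibble(snp_id = paste0("s", 1:40),
                         chrom = as.character(sample(1:3, 40, TRUE)),
                         pos = sample.int(5e6, 40))
  w <- 1e5
  got <- map_snps_to_genes(snps, genes2, window_bp = w)
  brute <- unique(unlist(lapply(seq_len(nrow(snps)), function(i) {
    sel <- genes2$chrom == snps$chrom[i] &
      snps$pos[i] >= genes2$start - w & snps$pos[i] <= genes2$end + w
    genes2$gene_id[sel]
  })))
  expect_setequal(got$genes, brute)

  expect_error(map_snps_to_genes(
    tibble::tibble(snp_id = "x", chrom = "zz", pos = 1L), genes), "zz")
})

test_that("hypergeometric p equals exhaustive enumeration on small universes", {
  # all cases with N <= 12: compare against enumeration over all draws
  set.seed(102)
  universe <- paste0("g", 1:10)
  gs <- list(s = paste0("g", 1:4))
  for (n_query in c(3, 5, 7)) {
    for (k_target in 0:min(4, n_query)) {
      # enumeration oracle: P(overlap >= k) over all C(10, n) query draws
      combs <- utils::combn(10, n_query)
      overl <- colSums(combs <= 4)
      p_enum <- mean(overl >= k_target)
      # construct a query with exactly k_target hits
      query <- c(paste0("g", seq_len(k_target)),
                 paste0("g", 4 + seq_len(n_query - k_target)))
      res <- enrichment_test(query, gs, universe)
      expect_equal(res$p, max(p_enum, if (k_target == 0) 1 else 0),
                   tolerance = 1e-12)
    }
  }
})

test_that("enrichment degenerate cases and Bonferroni behave", {
  universe <- paste0("g", 1:10)
  gs <- list(a = paste0("g", 1:4), b = paste0("g", 9:10),
             c = paste0("g", 5:6))
  # query = universe: k = K and p = 1
  res <- enrichment_test(universe, gs, universe)
  expect_identical(res$k, res$K)
  expect_true(all(res$p == 1))
  # Bonferroni multiplies by the number of sets tested, capped at 1
  res2 <- enrichment_test(paste0("g", 1:4), gs, universe)
  expect_equal(res2$p_adjusted, pmin(1, res2$p * 3))
  expect_true(all(res2$p_adjusted >= res2$p))
  # monotone in k for fixed margins
  ps <- vapply(1:4, function(k) {
    q <- c(paste0("g", seq_len(k)), paste0("g", 4 + seq_len(4 - k)))
    enrichment_test(q, gs["a"], universe)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(enrichment_test("g1", gs, character(0)), "empty")
  # gene-ratio text matches the field convention
  expect_match(res2$gene_ratio[1], "^4/4$")
})

test_that("GMT round trip parses names and members", {
  p <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg9"), p)
  gs <- read_gmt(p)
  expect_named(gs, c("setA", "setB"))
  expect_identical(gs$setA, c("g1", "g2", "g3"))
  writeLines("broken_line", p)
  expect_error(read_gmt(p), "malformed")
})
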