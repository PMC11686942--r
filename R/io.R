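# Readers and writers for the package's tabular artifacts, plus the
# end-to-end pipeline. Readers reject malformed input rather than coercing.

#' Write genotypes to VCF or CSV
#'
#' VCF output is a minimal diploid VCFv4.2 with `GT` fields consistent with
#' the dosages (dosage = count of the ALT allele); CSV output is a plain
#' individuals x SNPs table with an `id` column and SNP ids as headers.
#'
#' @param geno Dosage matrix (individuals x SNPs, rownames ids).
#' @param snp_map Tibble `snp_id`, `chrom`, `pos` (ignored for CSV).
#' @param path Output file path.
#' @param format `"vcf"` or `"csv"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, snp_map = NULL, path,
                            format = c("auto", "vcf", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "csv"
  }
  ids <- rownames(geno) %||% as.character(seq_len(nrow(geno)))
  if (format == "csv") {
    df <- tibble::as_tibble(as.data.frame(geno))
    names(df) <- colnames(geno) %||% paste0("snp", seq_len(ncol(geno)))
    readr::write_csv(dplyr::bind_cols(tibble::tibble(id = ids), df), path)
    return(invisible(path))
  }
  if (is.null(snp_map)) {
    snp_map <- tibble::tibble(
      snp_id = colnames(geno) %||% paste0("snp", seq_len(ncol(geno))),
      chrom = "1", pos = seq_len(ncol(geno)))
  }
  gt <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(ncol(geno)), function(j) {
    paste(c(snp_map$chrom[j], snp_map$pos[j], snp_map$snp_id[j], "A", "C",
            ".", "PASS", ".", "GT", gt[geno[, j] + 1L]), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=matwealth",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from VCF or CSV
#'
#' Returns dosages as ALT-allele counts together with the SNP map; the
#' REF/ALT mapping and per-SNP ALT allele frequencies are recorded in
#' attributes so minor-allele orientation can be recovered. Rejects
#' non-diploid GT fields, missing genotypes and duplicated SNP ids, naming
#' the offending record.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"vcf"` or `"csv"`.
#' @return A list with `genotypes` (integer matrix) and `snp_map`.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "csv"
  }
  if (format == "csv") {
    df <- readr::read_csv(path, show_col_types = FALSE)
    if (names(df)[1] != "id") abort("genotype CSV must start with an `id` column")
    geno <- as.matrix(df[, -1, drop = FALSE])
    if (anyNA(geno)) abort("missing genotypes are not supported")
    if (any(geno != round(geno)) || any(geno < 0 | geno > 2)) {
      abort("dosages must be integers in {0, 1, 2}")
    }
    storage.mode(geno) <- "integer"
    rownames(geno) <- as.character(df$id)
    if (anyDuplicated(colnames(geno))) abort("duplicated SNP ids")
    return(list(genotypes = geno,
                snp_map = tibble::tibble(snp_id = colnames(geno),
                                         chrom = "1",
                                         pos = seq_len(ncol(geno)))))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  if (is.null(dim(gt))) {
    gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  }
  snp_ids <- unname(fix[, "ID"])
  if (anyDuplicated(snp_ids)) {
    abort(sprintf("duplicated SNP id(s): %s",
                  paste(head(unique(snp_ids[duplicated(snp_ids)]), 5),
                        collapse = ", ")))
  }
  if (anyNA(gt)) {
    bad <- which(is.na(gt), arr.ind = TRUE)[1, ]
    abort(sprintf("missing genotype at SNP %s, sample %s",
                  snp_ids[bad[1]], colnames(gt)[bad[2]]))
  }
  diploid <- array(grepl("^[01][/|][01]$", gt), dim = dim(gt))
  if (!all(diploid)) {
    bad <- which(!diploid, arr.ind = TRUE)[1, ]
    abort(sprintf("non-diploid or non-biallelic GT '%s' at SNP %s, sample %s",
                  gt[bad[1], bad[2]], snp_ids[bad[1]], colnames(gt)[bad[2]]))
  }
  dose <- (substr(gt, 1, 1) == "1") + (substr(gt, 3, 3) == "1")
  geno <- t(dose)
  storage.mode(geno) <- "integer"
  colnames(geno) <- snp_ids
  snp_map <- tibble::tibble(snp_id = snp_ids,
                            chrom = unname(fix[, "CHROM"]),
                            pos = as.integer(fix[, "POS"]))
  structure(list(genotypes = geno, snp_map = snp_map),
            ref = unname(fix[, "REF"]), alt = unname(fix[, "ALT"]),
            alt_freq = unname(colMeans(geno) / 2))
}

#' Write a relatedness matrix as square CSV with an id header
#' @param K Relatedness matrix. @param path Output path.
#' @return `path`, invisibly.
#' @export
write_relatedness <- function(K, path) {
  ids <- rownames(K) %||% as.character(seq_len(nrow(K)))
  df <- tibble::as_tibble(as.data.frame(unclass(K)))
  names(df) <- ids
  readr::write_csv(dplyr::bind_cols(tibble::tibble(id = ids), df), path)
  invisible(path)
}

#' Read a relatedness matrix written by [write_relatedness()]
#' @param path CSV path. @param kind Kind tag to attach.
#' @return A `relatedness_matrix`.
#' @export
read_relatedness <- function(path, kind = "pedigree_A") {
  df <- readr::read_csv(path, show_col_types = FALSE)
  ids <- as.character(df$id)
  K <- as.matrix(df[, -1, drop = FALSE])
  dimnames(K) <- list(ids, ids)
  if (max(abs(K - t(K))) > 1e-8) abort("relatedness matrix is not symmetric")
  structure(K, kind = kind, class = c("relatedness_matrix", class(K)))
}

#' Run the full simulate-and-analyse pipeline
#'
#' Simulates a population, writes the standard artifacts (territory map,
#' wealth field, pedigree, breeding records, genotypes as VCF and CSV),
#' runs the switched-on analyses (genomic relationship matrix, pedigree
#' A-matrix, heritability by REML and Haseman-Elston, GWAS, repeatability,
#' dispersal and similarity models, cross-fostering contrast, spatial null
#' simulation) and writes a JSON manifest with input checksums, the seed and
#' package version. Identical config and seed reproduce identical outputs.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for the whole run.
#' @param analyses Character subset of `c("grm", "amatrix", "h2", "gwas",
#'   "repeatability", "dispersal", "similarity", "crossfoster", "nullsim")`.
#' @param max_genotyped Cap on the number of genotyped breeders entering the
#'   genomic analyses (a random subsample is taken above it).
#' @return Invisibly, a named list of result objects and file paths.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, seed = 1,
                         analyses = c("grm", "h2", "similarity"),
                         max_genotyped = 800) {
  analyses <- match.arg(analyses,
                        c("grm", "amatrix", "h2", "gwas", "repeatability",
                          "dispersal", "similarity", "crossfoster", "nullsim"),
                        several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- run_simulation(config, seed = seed)
  res <- list(sim = sim)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(df, p)
    paths[[name]] <<- p
  }
  wr(sim$map, "territories.csv")
  wr(sim$field, "wealth_field.csv")
  wr(sim_pedigree(sim), "pedigree.csv")
  wr(sim$records, "breeding_records.csv")
  if (ncol(sim$genotypes) > 0) {
    write_genotypes(sim$genotypes, sim$snp_map,
                    file.path(out_dir, "genotypes.vcf"), format = "vcf")
    write_genotypes(sim$genotypes, sim$snp_map,
                    file.path(out_dir, "genotypes.csv"), format = "csv")
    paths[["genotypes.vcf"]] <- file.path(out_dir, "genotypes.vcf")
    paths[["genotypes.csv"]] <- file.path(out_dir, "genotypes.csv")
  }

  breeders <- unique(sim$records$individual_id)
  genotyped <- intersect(breeders, as.integer(rownames(sim$genotypes)))
  if (length(genotyped) > max_genotyped) {
    genotyped <- sort(sample(genotyped, max_genotyped))
  }
  mean_wealth <- individual_mean_wealth(
    sim$records[sim$records$individual_id %in% genotyped, ])

  if (any(c("grm", "h2", "gwas") %in% analyses) && ncol(sim$genotypes) > 0) {
    G <- compute_grm(sim$genotypes[as.character(genotyped), , drop = FALSE])
    res$grm <- G
    if ("grm" %in% analyses) wr_mat <- write_relatedness(G, file.path(out_dir, "grm.csv"))
    if ("h2" %in% analyses) {
      y <- mean_wealth$wealth[match(genotyped, mean_wealth$individual_id)]
      res$h2_reml <- fit_genomic_h2(G, y)
      res$h2_he <- haseman_elston(G, y)
      wr(dplyr::bind_rows(
        dplyr::mutate(res$h2_reml$ratios, estimator = "reml"),
        tibble::tibble(component = "h2", ratio = res$h2_he$h2,
                       se = res$h2_he$se, lower = NA, upper = NA,
                       estimator = "haseman_elston")), "heritability.csv")
    }
    if ("gwas" %in% analyses) {
      recs <- sim$records[sim$records$individual_id %in% genotyped, ]
      info <- tibble::tibble(
        individual_id = sim$individuals$id, sex = sim$individuals$sex)
      res$gwas <- gwas_scan(recs,
                            sim$genotypes[as.character(genotyped), , drop = FALSE],
                            G, info = info, snp_map = sim$snp_map)
      wr(tibble::as_tibble(res$gwas), "gwas.csv")
    }
  }
  if ("amatrix" %in% analyses) {
    ped <- prune_pedigree(sim_pedigree(sim), breeders)
    res$amatrix <- compute_A_matrix(ped)
    write_relatedness(res$amatrix, file.path(out_dir, "amatrix.csv"))
  }
  if ("repeatability" %in% analyses) {
    res$repeatability <- repeatability(sim$records, n_boot = 200)
  }
  rr <- recruit_records(sim)
  res$recruits <- rr
  if ("similarity" %in% analyses && nrow(rr) >= 50) {
    res$similarity <- similarity_by_distance(rr)
  }
  if ("dispersal" %in% analyses && nrow(rr) >= 10) {
    res$dispersal <- dispersal_vs_natal_wealth(rr)
  }
  if ("crossfoster" %in% analyses) {
    cfr <- crossfoster_records(sim)
    if (nrow(cfr) >= 10) res$crossfoster <- crossfoster_analysis(cfr)
  }
  if ("nullsim" %in% analyses && nrow(rr) >= 10) {
    res$nullsim <- spatial_null_simulation(rr, sim$map, sim$field,
                                           n_sim = 500)
  }

  manifest <- list(
    package = "matwealth",
    version = as.character(utils::packageVersion("matwealth")),
    seed = seed,
    analyses = analyses,
    n_individuals = nrow(sim$individuals),
    n_records = nrow(sim$records),
    checksums = as.list(tools::md5sum(unlist(paths)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
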