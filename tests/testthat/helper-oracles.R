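# Independent oracles and small fixture builders shared across tests.

# Gene-dropping oracle for the additive relationship matrix: founders get
# unique allele labels, alleles are transmitted down the pedigree
# independently `n_drops` times, and A_ij is estimated as twice the mean
# kinship (probability a random allele from i matches a random allele from j).
gene_drop_A <- function(ped, n_drops = 1e5) {
  ped$id <- as.character(ped$id)
  ped$sire <- as.character(ped$sire)
  ped$dam <- as.character(ped$dam)
  n <- nrow(ped)
  ord <- order(is.na(ped$sire) + is.na(ped$dam), decreasing = TRUE)
  # topological order: founders first, then iterate until resolved
  done <- is.na(ped$sire) & is.na(ped$dam)
  order_idx <- which(done)
  while (length(order_idx) < n) {
    ready <- which(!done &
                     (is.na(ped$sire) | ped$sire %in% ped$id[done]) &
                     (is.na(ped$dam) | ped$dam %in% ped$id[done]))
    stopifnot(length(ready) > 0)
    order_idx <- c(order_idx, ready)
    done[ready] <- TRUE
  }
  M1 <- matrix(0L, n, n_drops)  # paternal allele label
  M2 <- matrix(0L, n, n_drops)  # maternal allele label
  lab <- 0L
  for (i in order_idx) {
    s <- match(ped$sire[i], ped$id)
    d <- match(ped$dam[i], ped$id)
    if (is.na(s)) {
      lab <- lab + 1L
      M1[i, ] <- lab
    } else {
      pickl <- runif(n_drops) < 0.5
      M1[i, ] <- ifelse(pickl, M1[s, ], M2[s, ])
    }
    if (is.na(d)) {
      lab <- lab + 1L
      M2[i, ] <- lab
    } else {
      pickl <- runif(n_drops) < 0.5
      M2[i, ] <- ifelse(pickl, M1[d, ], M2[d, ])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  SE <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- ((M1[i, ] == M1[j, ]) + (M1[i, ] == M2[j, ]) +
              (M2[i, ] == M1[j, ]) + (M2[i, ] == M2[j, ])) / 2
      A[i, j] <- A[j, i] <- mean(s)
      SE[i, j] <- SE[j, i] <- stats::sd(s) / sqrt(n_drops)
    }
  }
  attr(A, "se") <- SE
  A
}

# Random valid pedigree with n_founders founders and n_desc descendants whose
# parents are drawn from earlier individuals of the right sex.
random_pedigree <- function(n_founders = 6, n_desc = 10) {
  sex <- c(rep(c("M", "F"), length.out = n_founders),
           sample(c("M", "F"), n_desc, replace = TRUE))
  id <- paste0("i", seq_len(n_founders + n_desc))
  sire <- dam <- rep(NA_character_, n_founders + n_desc)
  for (i in (n_founders + 1):(n_founders + n_desc)) {
    males <- which(sex[seq_len(i - 1)] == "M")
    females <- which(sex[seq_len(i - 1)] == "F")
    sire[i] <- id[males[sample.int(length(males), 1)]]
    dam[i] <- id[females[sample.int(length(females), 1)]]
  }
  tibble::tibble(id = id, sire = sire, dam = dam)
}

# Genotypes dropped through a simple 3-generation pedigree; returns the
# pedigree, genotype matrix and the per-individual generation.
three_gen_genotypes <- function(n_founders = 100, n_per_gen = 100,
                                n_snps = 2000, maf_range = c(0.1, 0.5)) {
  p <- runif(n_snps, maf_range[1], maf_range[2])
  ids <- paste0("f", seq_len(n_founders))
  sex <- rep(c("M", "F"), length.out = n_founders)
  G <- matrix(rbinom(n_founders * n_snps, 2, rep(p, each = n_founders)),
              n_founders, n_snps)
  rownames(G) <- ids
  ped <- tibble::tibble(id = ids, sire = NA_character_, dam = NA_character_)
  mate_and_add <- function(ped, G, sex, gen, n_new) {
    males <- ped$id[sex == "M"]
    females <- ped$id[sex == "F"]
    new_ids <- paste0("g", gen, "_", seq_len(n_new))
    sire <- sample(males, n_new, replace = TRUE)
    dam <- sample(females, n_new, replace = TRUE)
    gd <- G[dam, , drop = FALSE]
    gs <- G[sire, , drop = FALSE]
    off <- matrix(rbinom(n_new * ncol(G), 1, as.vector(gd) / 2), n_new) +
      matrix(rbinom(n_new * ncol(G), 1, as.vector(gs) / 2), n_new)
    rownames(off) <- new_ids
    list(ped = dplyr::bind_rows(ped, tibble::tibble(id = new_ids, sire = sire,
                                                    dam = dam)),
         G = rbind(G, off),
         sex = c(sex, sample(c("M", "F"), n_new, replace = TRUE)))
  }
  st <- list(ped = ped, G = G, sex = sex)
  for (gen in 1:2) st <- mate_and_add(st$ped, st$G, st$sex, gen, n_per_gen)
  st
}

# Small, fast simulation config used by several tests; `...` overrides.
small_sim_config <- function(...) {
  defaults <- list(n_territories = 100, extent = 3000, min_spacing = 100,
                   n_patches = 2, years = 8, n_founders = 60, n_snps = 200,
                   kernel = dispersal_kernel("lognormal", 400, 400))
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Forces the dense AI route (non-identity incidence) for engine cross-checks.
reml_ai_for_test <- function(y, Z, K) {
  fit_lmm_reml(y, random = list(genetic = list(Z = Z, K = K)))
}

# Wealth simulated directly from the generating model for h2 recovery tests.
mvn_trait <- function(K, h2) {
  n <- nrow(K)
  V <- h2 * unclass(K) + diag(1 - h2, n)
  drop(crossprod(chol(V + diag(1e-8, n)), rnorm(n)))
}
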