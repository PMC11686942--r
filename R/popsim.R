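#' Genetic architecture of wealth-acquisition ability
#'
#' Describes the latent "ability" trait that can causally bias settlement
#' toward high-wealth territories. With `n_causal = 0` (the default) ability
#' plays no role and any heritability of wealth must arise from the landscape
#' and dispersal behaviour alone. With causal loci, ability is a standardised
#' additive score over `n_causal` SNPs with heritability `h2_true`, and
#' recruits choose among the `k_nearest` vacant territories around their
#' dispersal target with probability proportional to
#' `exp(settlement_weight * ability * wealth)`.
#'
#' @param n_causal Number of causal SNPs.
#' @param h2_true Heritability of the latent ability, in `[0, 1]`.
#' @param settlement_weight Strength of ability-biased settlement (0 = the
#'   nearest vacant territory is always taken).
#' @param k_nearest Number of nearest vacancies entering the choice set.
#' @return A list of class `arch_spec`.
#' @export
arch_spec <- function(n_causal = 0, h2_true = 0.3, settlement_weight = 0,
                      k_nearest = 10) {
  check_number(n_causal, "n_causal", lower = 0)
  check_number(h2_true, "h2_true", lower = 0, upper = 1)
  check_number(settlement_weight, "settlement_weight")
  check_number(k_nearest, "k_nearest", lower = 1)
  structure(list(n_causal = as.integer(n_causal), h2_true = h2_true,
                 settlement_weight = settlement_weight,
                 k_nearest = as.integer(k_nearest)),
            class = "arch_spec")
}

#' Simulation configuration
#'
#' Bundles all parameters of a multi-year simulation of a philopatric
#' nest-box population. Defaults describe the study conditions: 400
#' territories over a 5 x 5 km patchy area, a wealth field with mean 1.31 and
#' SD 0.35 with strong between-year persistence, a lognormal natal dispersal
#' kernel with mean 1272 m and SD 1382 m, one breeding pair per territory,
#' clutch size Poisson with mean 6 (weakly increasing with territory wealth,
#' which lets clutch-size-matched cross-fostering induce a positive
#' correlation between genetic and foster wealth as in the field experiment),
#' recruitment probability 0.25 and adult survival 0.5 with perfect adult
#' site fidelity (the recruitment rate balances adult mortality so the
#' population sits at carrying capacity).
#'
#' @param n_territories,extent,min_spacing,n_patches Territory layout, see
#'   [generate_territories()].
#' @param years Number of breeding seasons.
#' @param field A [field_params()] object.
#' @param kernel A [dispersal_kernel()].
#' @param n_founders Number of founders (even; placed as pairs).
#' @param n_snps,maf_range,n_chrom Founder genotype settings.
#' @param architecture An [arch_spec()].
#' @param clutch_mean Mean clutch size at mean wealth.
#' @param clutch_wealth_effect Log-linear effect of territory wealth on
#'   expected clutch size.
#' @param p_recruit Probability a nestling enters the next season's recruit
#'   pool.
#' @param p_surv Adult annual survival probability.
#' @param crossfoster_years Years in which broods are cross-fostered.
#' @param crossfoster_mode `"partial"` (2-4 nestlings exchanged) or
#'   `"complete"` (whole clutches exchanged).
#' @param crossfoster_fraction Fraction of eligible broods entering the
#'   exchange in a cross-fostering year.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_territories = 400, extent = 5000, min_spacing = 150,
                       n_patches = 4, years = 20,
                       field = field_params(),
                       kernel = dispersal_kernel(),
                       n_founders = 300, n_snps = 2000,
                       maf_range = c(0.1, 0.5), n_chrom = 10,
                       architecture = arch_spec(),
                       clutch_mean = 6, clutch_wealth_effect = 0.3,
                       p_recruit = 0.25, p_surv = 0.5,
                       crossfoster_years = integer(0),
                       crossfoster_mode = c("partial", "complete"),
                       crossfoster_fraction = 0) {
  crossfoster_mode <- match.arg(crossfoster_mode)
  check_number(years, "years", lower = 1)
  check_number(n_founders, "n_founders", lower = 4)
  if (n_founders %% 2 != 0) abort("`n_founders` must be even")
  if (n_founders / 2 > n_territories) {
    abort("`n_founders` exceeds the pair capacity of the territories (one pair per territory)")
  }
  check_number(clutch_mean, "clutch_mean", lower = 0)
  check_number(p_recruit, "p_recruit", lower = 0, upper = 1)
  check_number(p_surv, "p_surv", lower = 0, upper = 1)
  check_number(crossfoster_fraction, "crossfoster_fraction", lower = 0, upper = 1)
  if (!inherits(field, "field_params")) abort("`field` must come from field_params()")
  if (!inherits(kernel, "dispersal_kernel")) abort("`kernel` must come from dispersal_kernel()")
  if (!inherits(architecture, "arch_spec")) abort("`architecture` must come from arch_spec()")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be within (0, 0.5]")
  }
  structure(list(
    n_territories = n_territories, extent = extent, min_spacing = min_spacing,
    n_patches = n_patches, years = as.integer(years), field = field,
    kernel = kernel, n_founders = as.integer(n_founders),
    n_snps = as.integer(n_snps), maf_range = maf_range,
    n_chrom = as.integer(n_chrom), architecture = architecture,
    clutch_mean = clutch_mean, clutch_wealth_effect = clutch_wealth_effect,
    p_recruit = p_recruit, p_surv = p_surv,
    crossfoster_years = as.integer(crossfoster_years),
    crossfoster_mode = crossfoster_mode,
    crossfoster_fraction = crossfoster_fraction
  ), class = "sim_config")
}

#' Initialise founders and their genotypes
#'
#' Places `n_founders / 2` breeding pairs on distinct random territories and
#' draws founder genotypes per SNP as `Binomial(2, p)` with allele frequency
#' `p` uniform in `maf_range`.
#'
#' @inheritParams sim_config
#' @param map Territory map.
#' @param seed Optional integer seed.
#' @return A list with `individuals` (tibble), `genotypes` (dosage matrix
#'   with ids as rownames) and `snp_map` (tibble `snp_id`, `chrom`, `pos`).
#' @export
initialize_population <- function(map, n_founders = 300, n_snps = 2000,
                                  maf_range = c(0.1, 0.5), n_chrom = 10,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  check_number(n_founders, "n_founders", lower = 4)
  if (n_founders %% 2 != 0) abort("`n_founders` must be even")
  if (n_founders / 2 > nrow(map)) {
    abort("`n_founders` exceeds the pair capacity of the territories (one pair per territory)")
  }
  n_pairs <- n_founders / 2
  terrs <- sample(map$territory_id, n_pairs)
  individuals <- tibble::tibble(
    id = seq_len(n_founders),
    sex = rep(c("M", "F"), n_pairs),
    dam_id = NA_integer_, sire_id = NA_integer_,
    foster_dam_id = NA_integer_, foster_sire_id = NA_integer_,
    natal_territory_id = rep(terrs, each = 2),
    rearing_territory_id = rep(terrs, each = 2),
    birth_year = 0L, recruited = TRUE, alive = TRUE
  )
  snp_map <- make_snp_map(n_snps, n_chrom)
  if (n_snps > 0) {
    p <- runif(n_snps, maf_range[1], maf_range[2])
    geno <- matrix(rbinom(n_founders * n_snps, 2, rep(p, each = n_founders)),
                   n_founders, n_snps)
  } else {
    geno <- matrix(integer(0), n_founders, 0)
  }
  rownames(geno) <- individuals$id
  colnames(geno) <- snp_map$snp_id
  list(individuals = individuals, genotypes = geno, snp_map = snp_map)
}

make_snp_map <- function(n_snps, n_chrom) {
  if (n_snps == 0) {
    return(tibble::tibble(snp_id = character(0), chrom = character(0),
                          pos = integer(0)))
  }
  chrom <- sort(rep_len(seq_len(n_chrom), n_snps))
  pos <- unlist(lapply(split(seq_len(n_snps), chrom), function(ix) {
    sort(sample.int(5e7, length(ix)))
  }), use.names = FALSE)
  tibble::tibble(
    snp_id = sprintf("snp_%d_%d", chrom, pos),
    chrom = as.character(chrom),
    pos = as.integer(pos)
  )
}

# Independent Mendelian sampling per locus: dosage = Bern(dam/2) + Bern(sire/2).
mendelian_offspring <- function(geno, dam_rows, sire_rows) {
  m <- length(dam_rows); L <- ncol(geno)
  if (L == 0) return(matrix(integer(0), m, 0))
  dam <- geno[dam_rows, , drop = FALSE]
  sire <- geno[sire_rows, , drop = FALSE]
  matrix(rbinom(m * L, 1, as.vector(dam) / 2), m, L) +
    matrix(rbinom(m * L, 1, as.vector(sire) / 2), m, L)
}

#' Cross-foster broods of one cohort
#'
#' Pairs selected broods by closest clutch size (ties broken by smallest
#' distance between nests) and exchanges nestlings' foster assignments:
#' `complete` mode swaps whole broods, `partial` mode swaps 2-4 nestlings per
#' pair while leaving at least one genetic chick in each brood (eligible
#' broods therefore need 3+ chicks in partial mode). Genetic parentage is
#' untouched; foster parents and rearing territory are updated. With an odd
#' number of selected broods the largest is left unfostered.
#'
#' @param nestlings Tibble of one year's nestlings as produced internally by
#'   [run_simulation()] (columns `id`, `dam_id`, `sire_id`, `foster_dam_id`,
#'   `foster_sire_id`, `natal_territory_id`, `rearing_territory_id`).
#' @param map Territory map (for nest distances).
#' @param mode `"partial"` or `"complete"`.
#' @param fraction Fraction of eligible broods selected for the exchange.
#' @return The nestling tibble with updated foster fields; attribute
#'   `"pairs"` holds the paired nests, `"n_unpaired"` the leftover count.
#' @export
apply_cross_fostering <- function(nestlings, map,
                                  mode = c("partial", "complete"),
                                  fraction = 1) {
  mode <- match.arg(mode)
  check_number(fraction, "fraction", lower = 0, upper = 1)
  check_columns(nestlings, c("id", "dam_id", "sire_id", "foster_dam_id",
                             "foster_sire_id", "natal_territory_id",
                             "rearing_territory_id"), "nestlings")
  empty_out <- function(nl, n_unpaired = 0L) {
    attr(nl, "pairs") <- tibble::tibble(terr_a = integer(0), terr_b = integer(0),
                                        n_swapped = integer(0))
    attr(nl, "n_unpaired") <- n_unpaired
    nl
  }
  if (fraction == 0 || nrow(nestlings) == 0) return(empty_out(nestlings))

  broods <- dplyr::count(nestlings, .data$natal_territory_id, name = "size")
  min_size <- if (mode == "partial") 3L else 1L
  eligible <- broods[broods$size >= min_size, ]
  n_sel <- round(fraction * nrow(eligible))
  if (n_sel < 2) return(empty_out(nestlings))
  sel <- eligible[sample.int(nrow(eligible), n_sel), ]
  n_unpaired <- 0L
  if (nrow(sel) %% 2 == 1) {
    sel <- sel[-which.max(sel$size), ]
    n_unpaired <- 1L
  }

  xy <- map[match(sel$natal_territory_id, map$territory_id), c("x", "y")]
  Dn <- dist_xy(xy$x, xy$y)
  Ds <- abs(outer(sel$size, sel$size, "-"))
  diag(Ds) <- NA; diag(Dn) <- NA
  remaining <- seq_len(nrow(sel))
  pair_list <- list()
  while (length(remaining) >= 2) {
    sub_s <- Ds[remaining, remaining, drop = FALSE]
    sub_d <- Dn[remaining, remaining, drop = FALSE]
    best <- which(sub_s == min(sub_s, na.rm = TRUE), arr.ind = TRUE)
    if (nrow(best) > 1) best <- best[which.min(sub_d[best]), , drop = FALSE]
    a <- remaining[best[1, 1]]; b <- remaining[best[1, 2]]
    pair_list[[length(pair_list) + 1L]] <- c(a, b)
    remaining <- setdiff(remaining, c(a, b))
  }

  nl <- nestlings
  pairs_log <- purrr::map_dfr(pair_list, function(pr) {
    ta <- sel$natal_territory_id[pr[1]]; tb <- sel$natal_territory_id[pr[2]]
    ia <- which(nl$natal_territory_id == ta)
    ib <- which(nl$natal_territory_id == tb)
    if (mode == "partial") {
      smax <- min(4, min(length(ia), length(ib)) - 1)
      s <- if (smax <= 2) 2L else sample(2:smax, 1)
      ia <- ia[sample.int(length(ia), s)]
      ib <- ib[sample.int(length(ib), s)]
    }
    pa <- c(nl$dam_id[ia[1]], nl$sire_id[ia[1]])
    pb <- c(nl$dam_id[ib[1]], nl$sire_id[ib[1]])
    nl$foster_dam_id[ia] <<- pb[1]; nl$foster_sire_id[ia] <<- pb[2]
    nl$rearing_territory_id[ia] <<- tb
    nl$foster_dam_id[ib] <<- pa[1]; nl$foster_sire_id[ib] <<- pa[2]
    nl$rearing_territory_id[ib] <<- ta
    tibble::tibble(terr_a = ta, terr_b = tb, n_swapped = length(ia))
  })
  attr(nl, "pairs") <- pairs_log
  attr(nl, "n_unpaired") <- n_unpaired
  nl
}

#' Run a multi-year philopatric population simulation
#'
#' Simulates the landscape, founders and `years` breeding seasons. Each
#' season: surviving adults return to their previous territory; recruits draw
#' a dispersal distance from the kernel in a uniform random direction from
#' the nest they were reared in and occupy the nearest vacant territory to
#' that target point (or, under ability-biased settlement, choose among the
#' `k_nearest` vacancies, see [arch_spec()]); pairs form where a male and a
#' female share a territory (one pair per territory); pairs produce
#' Poisson-distributed clutches; nestlings enter the pedigree, recruiting the
#' following season with probability `p_recruit`, at which point their
#' genotypes are drawn by independent Mendelian sampling per locus; adults
#' survive with probability `p_surv`. Cross-fostering can be applied to
#' selected years ([apply_cross_fostering()]); fostered birds treat the
#' rearing nest as their natal reference when dispersing.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return An object of class `wealth_sim`: `map`, `field`, `individuals`
#'   (pedigree with foster fields), `genotypes` (founders and recruits),
#'   `snp_map`, `records` (one row per breeder per year with wealth, natal
#'   wealth and dispersal distance), `crossfoster_log`, `config`, `seed`.
#' @export
run_simulation <- function(config = sim_config(), seed = 1) {
  if (!inherits(config, "sim_config")) abort("`config` must come from sim_config()")
  set.seed(seed)
  cf <- config

  map <- generate_territories(cf$n_territories, cf$extent, cf$min_spacing,
                              cf$n_patches)
  field <- simulate_wealth_field(map, cf$field, years = cf$years + 1L,
                                 start_year = 0L)
  n_terr <- nrow(map)
  W <- matrix(NA_real_, n_terr, cf$years + 1L)
  W[cbind(match(field$territory_id, map$territory_id), field$year + 1L)] <- field$wealth
  xs <- map$x; ys <- map$y

  pop <- initialize_population(map, cf$n_founders, cf$n_snps, cf$maf_range,
                               cf$n_chrom)
  founders <- pop$individuals
  snp_map <- pop$snp_map
  L <- cf$n_snps

  # growable genotype store
  cap <- cf$n_founders +
    ceiling(cf$years * n_terr * cf$clutch_mean * cf$p_recruit * 0.8) + 256L
  G <- matrix(0L, cap, L)
  G[seq_len(cf$n_founders), ] <- pop$genotypes
  g_used <- cf$n_founders
  g_ids <- c(founders$id, rep(NA_integer_, cap - cf$n_founders))
  geno_add <- function(mat, ids) {
    m <- nrow(mat)
    if (g_used + m > nrow(G)) {
      G <<- rbind(G, matrix(0L, nrow(G) + m, L))
      g_ids <<- c(g_ids, rep(NA_integer_, nrow(G) - length(g_ids)))
    }
    rows <- g_used + seq_len(m)
    G[rows, ] <<- mat
    g_ids[rows] <<- ids
    g_used <<- g_used + m
    rows
  }

  # latent ability
  arch <- cf$architecture
  causal <- if (arch$n_causal > 0 && L > 0) {
    sample.int(L, min(arch$n_causal, L))
  } else integer(0)
  eff <- if (length(causal)) rnorm(length(causal)) else numeric(0)
  score_center <- 0; score_scale <- 1
  ability_of <- function(rows) {
    m <- length(rows)
    if (!length(causal)) return(rnorm(m))
    raw <- drop(G[rows, causal, drop = FALSE] %*% eff)
    std <- (raw - score_center) / score_scale
    sqrt(arch$h2_true) * std + sqrt(1 - arch$h2_true) * rnorm(m)
  }
  if (length(causal)) {
    raw0 <- drop(G[seq_len(cf$n_founders), causal, drop = FALSE] %*% eff)
    score_center <- mean(raw0)
    score_scale <- if (sd(raw0) > 0) sd(raw0) else 1
  }

  # adult registry (parallel vectors)
  ad <- list(id = founders$id, sex = founders$sex,
             terr = match(founders$natal_territory_id, map$territory_id),
             rear = match(founders$rearing_territory_id, map$territory_id),
             natal = match(founders$natal_territory_id, map$territory_id),
             birth_year = founders$birth_year,
             ability = ability_of(seq_len(cf$n_founders)),
             grow = seq_len(cf$n_founders))

  all_nestlings <- vector("list", cf$years)
  records <- vector("list", cf$years)
  cf_log <- vector("list", cf$years)
  next_id <- cf$n_founders + 1L
  nest_prev <- NULL
  extinct <- FALSE
  years_run <- 0L

  for (t in seq_len(cf$years)) {
    w_t <- W[, t + 1L]

    # 1. recruits from last year's nestlings
    cand <- NULL
    if (!is.null(nest_prev) && nrow(nest_prev) > 0) {
      rec <- rbinom(nrow(nest_prev), 1, cf$p_recruit) == 1
      all_nestlings[[t - 1L]]$recruited[rec] <- TRUE
      if (any(rec)) {
        nl <- nest_prev[rec, ]
        off_geno <- mendelian_offspring(G, nl$dam_row, nl$sire_row)
        rows <- geno_add(off_geno, nl$id)
        cand <- list(id = nl$id, sex = nl$sex,
                     rear = match(nl$rearing_territory_id, map$territory_id),
                     natal = match(nl$natal_territory_id, map$territory_id),
                     birth_year = nl$birth_year,
                     ability = ability_of(rows), grow = rows)
      }
    }

    # 2. settlement of recruits around their rearing nest
    occ_m <- logical(n_terr); occ_f <- logical(n_terr)
    occ_m[ad$terr[ad$sex == "M"]] <- TRUE
    occ_f[ad$terr[ad$sex == "F"]] <- TRUE
    if (!is.null(cand)) {
      m <- length(cand$id)
      dists <- draw_dispersal(cf$kernel, m)
      angs <- runif(m, 0, 2 * pi)
      settled <- rep(NA_integer_, m)
      # males prospect for vacant territories first; females then settle
      # where an unpaired male holds a territory
      perm <- function(v) v[sample.int(length(v))]
      ord <- c(perm(which(cand$sex == "M")), perm(which(cand$sex == "F")))
      for (i in ord) {
        free <- if (cand$sex[i] == "M") which(!occ_m) else which(occ_m & !occ_f)
        if (!length(free)) next
        tx <- xs[cand$rear[i]] + dists[i] * cos(angs[i])
        ty <- ys[cand$rear[i]] + dists[i] * sin(angs[i])
        d2 <- (xs[free] - tx)^2 + (ys[free] - ty)^2
        if (arch$settlement_weight == 0) {
          pick <- free[which.min(d2)]
        } else {
          k <- min(arch$k_nearest, length(free))
          near <- free[order(d2)[seq_len(k)]]
          lw <- arch$settlement_weight * cand$ability[i] * w_t[near]
          pick <- if (length(near) == 1) near else
            near[sample.int(k, 1, prob = exp(lw - max(lw)))]
        }
        settled[i] <- pick
        if (cand$sex[i] == "M") occ_m[pick] <- TRUE else occ_f[pick] <- TRUE
      }
      ok <- !is.na(settled)
      if (any(ok)) {
        ad <- list(id = c(ad$id, cand$id[ok]),
                   sex = c(ad$sex, cand$sex[ok]),
                   terr = c(ad$terr, settled[ok]),
                   rear = c(ad$rear, cand$rear[ok]),
                   natal = c(ad$natal, cand$natal[ok]),
                   birth_year = c(ad$birth_year, cand$birth_year[ok]),
                   ability = c(ad$ability, cand$ability[ok]),
                   grow = c(ad$grow, cand$grow[ok]))
      }
    }

    # 3. pair formation: one male + one female on the same territory
    terr_m <- ad$terr[ad$sex == "M"]; terr_f <- ad$terr[ad$sex == "F"]
    paired_terr <- intersect(terr_m, terr_f)
    midx <- which(ad$sex == "M")[match(paired_terr, terr_m)]
    fidx <- which(ad$sex == "F")[match(paired_terr, terr_f)]

    # 4. breeding records for all breeders
    breeders <- c(midx, fidx)
    if (length(breeders)) {
      bt <- ad$terr[breeders]
      ddist <- sqrt((xs[bt] - xs[ad$rear[breeders]])^2 +
                    (ys[bt] - ys[ad$rear[breeders]])^2)
      records[[t]] <- tibble::tibble(
        individual_id = ad$id[breeders],
        year = t,
        territory_id = map$territory_id[bt],
        wealth = w_t[bt],
        natal_wealth = W[cbind(ad$natal[breeders], ad$birth_year[breeders] + 1L)],
        dispersal_distance = ddist
      )
    }

    # 5. clutches
    nest_t <- NULL
    if (length(paired_terr)) {
      lam <- cf$clutch_mean *
        exp(cf$clutch_wealth_effect * (w_t[paired_terr] - cf$field$mean))
      sizes <- rpois(length(paired_terr), lam)
      total <- sum(sizes)
      if (total > 0) {
        brood <- rep(seq_along(paired_terr), sizes)
        ids <- next_id - 1L + seq_len(total)
        next_id <- next_id + total
        nest_t <- tibble::tibble(
          id = ids,
          sex = ifelse(rbinom(total, 1, 0.5) == 1, "M", "F"),
          dam_id = ad$id[fidx][brood],
          sire_id = ad$id[midx][brood],
          dam_row = ad$grow[fidx][brood],
          sire_row = ad$grow[midx][brood],
          foster_dam_id = ad$id[fidx][brood],
          foster_sire_id = ad$id[midx][brood],
          natal_territory_id = map$territory_id[paired_terr][brood],
          rearing_territory_id = map$territory_id[paired_terr][brood],
          birth_year = t,
          recruited = FALSE
        )
        # 6. cross-fostering
        if (t %in% cf$crossfoster_years && cf$crossfoster_fraction > 0) {
          nest_t <- apply_cross_fostering(nest_t, map, cf$crossfoster_mode,
                                          cf$crossfoster_fraction)
          cf_log[[t]] <- dplyr::mutate(attr(nest_t, "pairs"), year = t)
        }
      }
    }
    all_nestlings[[t]] <- nest_t

    # 7. adult survival (perfect site fidelity for survivors)
    if (length(ad$id)) {
      surv <- rbinom(length(ad$id), 1, cf$p_surv) == 1
      ad <- purrr::map(ad, ~ .x[surv])
    }
    nest_prev <- nest_t
    years_run <- t
    if (!length(ad$id) && (is.null(nest_t) || nrow(nest_t) == 0)) {
      extinct <- TRUE
      break
    }
  }

  nestlings <- dplyr::bind_rows(all_nestlings)
  individuals <- dplyr::bind_rows(
    founders,
    if (nrow(nestlings)) {
      dplyr::select(nestlings, "id", "sex", "dam_id", "sire_id",
                    "foster_dam_id", "foster_sire_id", "natal_territory_id",
                    "rearing_territory_id", "birth_year", "recruited")
    } else NULL
  )
  individuals$alive[is.na(individuals$alive)] <- FALSE
  individuals$alive[individuals$id %in% ad$id] <- TRUE
  individuals$alive[!individuals$id %in% ad$id] <- FALSE

  geno <- G[seq_len(g_used), , drop = FALSE]
  rownames(geno) <- g_ids[seq_len(g_used)]
  colnames(geno) <- snp_map$snp_id

  structure(list(
    map = map, field = field, W = W,
    individuals = individuals,
    genotypes = geno, snp_map = snp_map,
    records = dplyr::bind_rows(records),
    crossfoster_log = dplyr::bind_rows(cf_log),
    causal_snps = if (length(causal)) snp_map$snp_id[causal] else character(0),
    extinct = extinct, years_run = years_run,
    config = cf, seed = seed
  ), class = "wealth_sim")
}

#' @export
print.wealth_sim <- function(x, ...) {
  cat("Philopatric population simulation\n")
  cat("  territories:", nrow(x$map), " years run:", x$years_run,
      if (x$extinct) " (extinct)" else "", "\n")
  cat("  individuals:", nrow(x$individuals),
      " genotyped:", nrow(x$genotypes),
      " breeding records:", nrow(x$records), "\n")
  invisible(x)
}

#' Check referential and genetic integrity of a simulation
#'
#' Verifies that ids are unique, every non-founder's parents exist with
#' consistent sexes, the pedigree is acyclic, every breeding record points to
#' an existing individual and to the wealth value of its territory-year,
#' dispersal distances are nonnegative, wealth honours the field floor, and
#' no genotyped offspring carries a dosage impossible under Mendelian
#' transmission from its parents.
#'
#' @param sim A `wealth_sim` object.
#' @return `TRUE` invisibly; aborts with a message on the first violation.
#' @export
validate_simulation <- function(sim) {
  ind <- sim$individuals
  if (anyDuplicated(ind$id)) abort("duplicated individual ids")
  idset <- ind$id
  for (col in c("dam_id", "sire_id", "foster_dam_id", "foster_sire_id")) {
    bad <- !is.na(ind[[col]]) & !(ind[[col]] %in% idset)
    if (any(bad)) abort(sprintf("%s references missing individuals", col))
  }
  sex_of <- setNames(ind$sex, ind$id)
  if (any(sex_of[as.character(stats::na.omit(ind$dam_id))] != "F")) {
    abort("a dam is not female")
  }
  if (any(sex_of[as.character(stats::na.omit(ind$sire_id))] != "M")) {
    abort("a sire is not male")
  }
  pedigree_toposort(normalize_pedigree(
    tibble::tibble(id = ind$id, sire = ind$sire_id, dam = ind$dam_id)))
  rec <- sim$records
  if (nrow(rec)) {
    if (!all(rec$individual_id %in% idset)) abort("record for unknown individual")
    if (any(rec$dispersal_distance < 0)) abort("negative dispersal distance")
    if (anyDuplicated(rec[, c("individual_id", "year")])) {
      abort("more than one record per individual-year")
    }
    ti <- match(rec$territory_id, sim$map$territory_id)
    if (any(abs(sim$W[cbind(ti, rec$year + 1L)] - rec$wealth) > 1e-12)) {
      abort("record wealth does not match the wealth field")
    }
  }
  if (any(sim$field$wealth < sim$config$field$floor - 1e-12)) {
    abort("wealth below the field floor")
  }
  # Mendelian consistency for genotyped offspring with genotyped parents
  g <- sim$genotypes
  if (ncol(g) > 0 && nrow(g) > 0) {
    gid <- as.integer(rownames(g))
    off <- ind[!is.na(ind$dam_id) & ind$id %in% gid &
               ind$dam_id %in% gid & ind$sire_id %in% gid, ]
    if (nrow(off)) {
      oi <- match(off$id, gid); di <- match(off$dam_id, gid)
      si <- match(off$sire_id, gid)
      from_dam <- g[oi, , drop = FALSE] - 0  # dosage
      lo <- (g[di, , drop = FALSE] == 2) + (g[si, , drop = FALSE] == 2)
      hi <- 2 - ((g[di, , drop = FALSE] == 0) + (g[si, , drop = FALSE] == 0))
      if (any(from_dam < lo | from_dam > hi)) {
        abort("offspring dosage impossible under Mendelian transmission")
      }
    }
  }
  invisible(TRUE)
}
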