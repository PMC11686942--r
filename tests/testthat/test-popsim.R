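test_that("founder initialisation places pairs and draws binomial genotypes", {
  map <- generate_territories(30, extent = 2000, min_spacing = 50, seed = 61)
  pop <- initialize_population(map, n_founders = 20, n_snps = 400,
                               maf_range = c(0.5, 0.5), seed = 62)
  expect_equal(nrow(pop$individuals), 20)
  expect_equal(sum(pop$individuals$sex == "M"), 10)
  # pairs share a territory
  by_terr <- table(pop$individuals$natal_territory_id)
  expect_true(all(by_terr == 2))
  # maf 0.5 exactly: frequencies near 0.5 within binomial error
  freq <- colMeans(pop$genotypes) / 2
  expect_lt(abs(mean(freq) - 0.5), 3 * sqrt(0.25 / (2 * 20 * 400)))

  pop2 <- initialize_population(map, n_founders = 20, n_snps = 400,
                                maf_range = c(0.5, 0.5), seed = 62)
  expect_identical(pop, pop2)

  empty <- initialize_population(map, n_founders = 10, n_snps = 0, seed = 63)
  expect_identical(ncol(empty$genotypes), 0L)
  expect_error(initialize_population(map, n_founders = 80), "capacity")
})

test_that("simulations are deterministic, internally consistent and capacity-bounded", {
  cfg <- small_sim_config()
  sim <- run_simulation(cfg, seed = 64)
  sim2 <- run_simulation(cfg, seed = 64)
  expect_identical(sim$records, sim2$records)
  expect_identical(sim$genotypes, sim2$genotypes)
  expect_true(validate_simulation(sim))
  per_year <- table(sim$records$year)
  expect_true(all(per_year <= 2 * nrow(sim$map)))

  tiny <- run_simulation(sim_config(n_territories = 3, extent = 1000,
                                    min_spacing = 10, years = 2,
                                    n_founders = 4, n_snps = 10), seed = 65)
  expect_true(validate_simulation(tiny))
})

test_that("Mendelian transmission: dam 0 x sire 2 always gives dosage 1", {
  g <- rbind(dam = c(0L, 2L, 1L), sire = c(2L, 0L, 1L))
  off <- matwealth:::mendelian_offspring(g, rep(1, 50), rep(2, 50))
  expect_true(all(off[, 1] == 1))
  expect_true(all(off[, 2] == 1))
  expect_true(all(off[, 3] %in% 0:2))
})

test_that("no adult survives with p_surv = 0", {
  cfg <- small_sim_config(p_surv = 0)
  sim <- run_simulation(cfg, seed = 66)
  expect_lte(max(table(sim$records$individual_id)), 1)
})

test_that("perfect philopatry sends every recruit to its natal territory", {
  cfg <- small_sim_config(kernel = dispersal_kernel("fixed", 0),
                          n_territories = 120, n_founders = 40)
  sim <- run_simulation(cfg, seed = 67)
  rr <- recruit_records(sim)
  expect_gt(nrow(rr), 30)
  # a recruit takes its natal box whenever it is free; otherwise the nearest
  # vacancy, so distances stay tiny relative to the landscape
  expect_gt(mean(rr$dispersal_distance == 0), 0.1)
  expect_lt(median(rr$dispersal_distance), 400)
  short <- rr[rr$dispersal_distance == 0, ]
  expect_true(all(short$territory_id == short$rearing_territory))
})

test_that("allele-frequency drift is of the order p(1-p)/2N per generation", {
  cfg <- small_sim_config(n_snps = 400, years = 6, maf_range = c(0.5, 0.5))
  sim <- run_simulation(cfg, seed = 68)
  ind <- sim$individuals
  gids <- as.integer(rownames(sim$genotypes))
  first <- ind$id[ind$birth_year == 0]
  last_by <- max(ind$birth_year[ind$id %in% gids & ind$recruited])
  last <- ind$id[ind$birth_year == last_by & ind$id %in% gids]
  p0 <- colMeans(sim$genotypes[as.character(intersect(first, gids)), ]) / 2
  p1 <- colMeans(sim$genotypes[as.character(last), ]) / 2
  # variance of the frequency change across SNPs: roughly t * p(1-p) / 2Ne
  # with Ne below census; check the order of magnitude only (factor 5)
  drift <- var(p1 - p0)
  N <- length(unique(ind$id[ind$recruited]))  / sim$years_run
  expected <- last_by * 0.25 / (2 * N)
  expect_lt(drift, 5 * expected + 0.01)
  expect_gt(drift, expected / 25)
})

test_that("cross-fostering bookkeeping keeps genetic parentage and swaps fosters", {
  cfg <- small_sim_config(crossfoster_years = 2:5, crossfoster_fraction = 0.8,
                          crossfoster_mode = "complete")
  sim <- run_simulation(cfg, seed = 69)
  expect_true(validate_simulation(sim))
  ind <- sim$individuals
  moved <- ind[!is.na(ind$foster_dam_id) & !is.na(ind$dam_id) &
                 ind$foster_dam_id != ind$dam_id, ]
  expect_gt(nrow(moved), 20)
  # complete mode: whole broods moved together, and swaps are reciprocal
  log <- sim$crossfoster_log
  expect_gt(nrow(log), 0)
  yr <- log$year[1]
  pair1 <- log[1, ]
  a_chicks <- ind[ind$birth_year == yr &
                    ind$natal_territory_id == pair1$terr_a, ]
  expect_true(all(a_chicks$rearing_territory_id == pair1$terr_b))

  # fraction 0: nobody fostered
  cfg0 <- small_sim_config(crossfoster_years = 2:5, crossfoster_fraction = 0)
  sim0 <- run_simulation(cfg0, seed = 69)
  ind0 <- sim0$individuals
  same <- is.na(ind0$foster_dam_id) | ind0$foster_dam_id == ind0$dam_id
  expect_true(all(same))
})

test_that("partial cross-fostering leaves a genetic chick and hosts a foster chick", {
  cfg <- small_sim_config(crossfoster_years = 2:6, crossfoster_fraction = 0.9,
                          crossfoster_mode = "partial")
  sim <- run_simulation(cfg, seed = 70)
  ind <- sim$individuals
  nl <- ind[!is.na(ind$dam_id), ]
  swapped_broods <- unique(paste0(nl$natal_territory_id, "_", nl$birth_year)[
    !is.na(nl$foster_dam_id) & nl$foster_dam_id != nl$dam_id])
  expect_gt(length(swapped_broods), 5)
  for (b in utils::head(swapped_broods, 10)) {
    parts <- strsplit(b, "_")[[1]]
    brood <- nl[nl$natal_territory_id == as.integer(parts[1]) &
                  nl$birth_year == as.integer(parts[2]), ]
    stay <- sum(brood$foster_dam_id == brood$dam_id)
    expect_gte(stay, 1)                  # retains a genetic chick
    gone <- sum(brood$foster_dam_id != brood$dam_id)
    expect_true(gone >= 2 && gone <= 4)  # 2-4 exchanged
    # hosts at least one foster chick from the partner brood
    hosted <- nl[nl$rearing_territory_id == as.integer(parts[1]) &
                   nl$birth_year == as.integer(parts[2]) &
                   nl$natal_territory_id != as.integer(parts[1]), ]
    expect_gte(nrow(hosted), 1)
  }
})

test_that("parent-offspring wealth regression follows the field persistence under pure philopatry", {
  # kernel fixed 0, no causal loci: lineage wealth tracks the field's AR(1)
  pars <- field_params(year_sd = 0)
  cfg <- sim_config(n_territories = 250, extent = 6000, min_spacing = 100,
                    years = 10, n_founders = 150, n_snps = 0, field = pars,
                    kernel = dispersal_kernel("fixed", 0))
  sim <- run_simulation(cfg, seed = 71)
  rr <- recruit_records(sim)
  rr <- rr[rr$dispersal_distance == 0, ]
  expect_gt(nrow(rr), 150)
  b <- coef(lm(breeding_wealth ~ natal_wealth, data = rr))[2]
  lag <- rr$breeding_year - rr$birth_year
  expected <- mean(pars$persistence^lag) * pars$sill / (pars$sill + pars$nugget)
  expect_lt(abs(b - expected), 0.12)
})

test_that("random settlement breaks the parent-offspring wealth covariance", {
  cfg <- sim_config(n_territories = 250, extent = 6000, min_spacing = 100,
                    years = 10, n_founders = 150, n_snps = 0,
                    kernel = dispersal_kernel("fixed", 60000))
  sim <- run_simulation(cfg, seed = 72)
  rr <- recruit_records(sim)
  b <- coef(lm(breeding_wealth ~ natal_wealth, data = rr))[2]
  expect_lt(abs(b), 0.1)
})
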