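test_that("territory generation respects spacing, determinism and degenerate cases", {
  one <- generate_territories(1, extent = 1000, min_spacing = 0, seed = 1)
  expect_equal(nrow(one), 1)
  expect_true(all(is.finite(c(one$x, one$y))))

  map <- generate_territories(100, extent = 5000, min_spacing = 150, seed = 2)
  expect_equal(nrow(map), 100)
  expect_gte(min(dist(cbind(map$x, map$y))), 150)
  expect_false(anyDuplicated(map$territory_id) > 0)

  again <- generate_territories(100, extent = 5000, min_spacing = 150, seed = 2)
  expect_identical(map, again)

  # infeasible density fails informatively
  expect_error(generate_territories(200, extent = 500, min_spacing = 150,
                                    seed = 3), "infeasible")
})

test_that("patchy layouts cluster territories around patch centres", {
  map <- generate_territories(120, extent = 6000, min_spacing = 50,
                              n_patches = 3, seed = 4)
  expect_setequal(unique(map$patch_id), 1:3)
  # within-patch spread is smaller than the full extent
  spread <- tapply(map$x, map$patch_id, sd)
  expect_true(all(spread < 6000 / 2))
})

test_that("wealth field matches the study moments and honours the floor", {
  map <- generate_territories(250, extent = 6000, min_spacing = 100, seed = 5)
  f <- simulate_wealth_field(map, field_params(), years = 20, seed = 6)
  expect_equal(nrow(f), 250 * 20)
  expect_false(anyDuplicated(f[, c("territory_id", "year")]) > 0)
  expect_true(all(f$wealth >= field_params()$floor))
  expect_equal(mean(f$wealth), 1.31, tolerance = 0.05)
  expect_equal(sd(f$wealth), 0.35, tolerance = 0.25)

  again <- simulate_wealth_field(map, field_params(), years = 20, seed = 6)
  expect_identical(f, again)
})

test_that("independence and persistence limits behave", {
  map <- generate_territories(80, extent = 4000, min_spacing = 200, seed = 7)
  # range -> 0: distinct territories uncorrelated
  p0 <- field_params(range = 1e-6, year_sd = 0, persistence = 0)
  f0 <- simulate_wealth_field(map, p0, years = 40, seed = 8)
  cg <- empirical_correlogram(f0, map, breaks = c(0, 2000, 4000))
  expect_lt(max(abs(cg$correlation), na.rm = TRUE), 0.08)

  # persistence 1, no nugget/year noise: per-territory repeatability 1
  p1 <- field_params(persistence = 1, nugget = 0, year_sd = 0)
  f1 <- simulate_wealth_field(map, p1, years = 5, seed = 9)
  w <- tidyr::pivot_wider(f1, names_from = "year", values_from = "wealth")
  expect_true(all(abs(w[[2]] - w[[3]]) < 1e-12))

  # persistence 0 with dominant nugget: repeatability near 0
  p2 <- field_params(sill = 0.001, nugget = 0.12, year_sd = 0, persistence = 0)
  f2 <- simulate_wealth_field(map, p2, years = 30, seed = 10)
  recs <- tibble::tibble(individual_id = f2$territory_id, wealth = f2$wealth)
  r <- repeatability(recs, n_boot = 0)
  expect_lt(r$R, 0.1)
})

test_that("correlogram recovers the generating covariance decay", {
  map <- generate_territories(220, extent = 6000, min_spacing = 100, seed = 11)
  pars <- field_params(range = 500, year_sd = 0, persistence = 0)
  f <- simulate_wealth_field(map, pars, years = 20, seed = 12)
  breaks <- c(0, 250, 500, 1000, 2000, 3000)
  cg <- empirical_correlogram(f, map, breaks = breaks)
  theo <- function(d) pars$sill * exp(-d / pars$range) / (pars$sill + pars$nugget)
  expect_gt(cg$correlation[1], cg$correlation[5])
  # short-distance bin close to theory; long distances near zero
  expect_equal(cg$correlation[1], theo(cg$bin_mid[1]), tolerance = 0.12)
  expect_lt(abs(cg$correlation[5]), 0.1)

  # constant field: correlation undefined, reported missing
  pc <- field_params(sill = 0, nugget = 0, year_sd = 0)
  fc <- simulate_wealth_field(map, pc, years = 3, seed = 13)
  cgc <- empirical_correlogram(fc, map, breaks = c(0, 3000))
  expect_true(is.na(cgc$correlation[1]))

  # empty bin reported missing with zero pairs
  cge <- empirical_correlogram(f, map, breaks = c(0, 1, 3000))
  expect_true(is.na(cge$correlation[1]))
  expect_identical(cge$n_pairs[1], 0L)
})

test_that("field parameter validation rejects invalid values", {
  expect_error(field_params(range = 0), "range")
  expect_error(field_params(persistence = 1.5), "persistence")
  expect_error(field_params(nugget = -1), "nugget")
})
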