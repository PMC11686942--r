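test_that("animal model recovers a null and a planted heritability", {
  set.seed(81)
  st <- three_gen_genotypes(n_founders = 80, n_per_gen = 80, n_snps = 100)
  A <- compute_A_matrix(st$ped)
  n <- nrow(A)
  # pure noise: h2 estimate small and CI covers 0
  y0 <- rnorm(n)
  recs0 <- tibble::tibble(individual_id = rownames(A), wealth = y0)
  am0 <- fit_animal_model(recs0, A, include = character(0))
  expect_lt(am0$h2, 0.1)
  expect_lte(am0$ratios$lower[am0$ratios$component == "h2"], 0.02)

  # planted h2 = 0.4 via the generating covariance
  ests <- replicate(6, {
    y <- mvn_trait(A, 0.4)
    recs <- tibble::tibble(individual_id = rownames(A), wealth = y)
    fit_animal_model(recs, A, include = character(0))$h2
  })
  expect_lt(abs(mean(ests) - 0.4), 0.1)
})

test_that("animal model ratios are location-invariant and scale-equivariant", {
  set.seed(82)
  st <- three_gen_genotypes(n_founders = 50, n_per_gen = 50, n_snps = 80)
  A <- compute_A_matrix(st$ped)
  y <- mvn_trait(A, 0.5)
  ids <- rownames(A)
  recs <- tibble::tibble(individual_id = ids, wealth = y)
  base <- fit_animal_model(recs, A, include = character(0))
  shifted <- fit_animal_model(dplyr::mutate(recs, wealth = .data$wealth + 7),
                              A, include = character(0))
  scaled <- fit_animal_model(dplyr::mutate(recs, wealth = .data$wealth * 3),
                             A, include = character(0))
  expect_equal(base$h2, shifted$h2, tolerance = 1e-6)
  expect_equal(base$h2, scaled$h2, tolerance = 1e-4)
  expect_equal(scaled$vc$estimate, base$vc$estimate * 9, tolerance = 1e-3)
})

test_that("repeated-records animal model separates additive and permanent environment", {
  set.seed(83)
  st <- three_gen_genotypes(n_founders = 70, n_per_gen = 70, n_snps = 80)
  A <- compute_A_matrix(st$ped)
  n <- nrow(A)
  a <- drop(crossprod(chol(unclass(A) + diag(1e-8, n)), rnorm(n))) * sqrt(0.3)
  pe <- rnorm(n, 0, sqrt(0.3))
  recs <- tibble::tibble(
    individual_id = rep(rownames(A), each = 3),
    year = rep(1:3, n),
    wealth = rep(a + pe, each = 3) + rnorm(3 * n, 0, sqrt(0.4))
  )
  am <- fit_animal_model(recs, A, include = "pe")
  expect_lt(abs(am$h2 - 0.3), 0.15)
  expect_lt(abs(am$ratios$ratio[am$ratios$component == "pe2"] - 0.3), 0.15)
  expect_true(all(am$ratios$ratio >= 0 & am$ratios$ratio <= 1))
  expect_lte(sum(am$ratios$ratio), 1 + 1e-8)
  expect_error(fit_animal_model(
    tibble::tibble(individual_id = "ghost", wealth = 1), A), "ghost")
})

test_that("Haseman-Elston matches the planted value and REML within joint error", {
  set.seed(84)
  n <- 400
  g <- matrix(rbinom(n * 800, 2, runif(800, 0.1, 0.5)[rep(1:800, each = n)]),
              n, 800)
  rownames(g) <- 1:n
  K <- compute_grm(g)
  he <- sapply(1:8, function(i) {
    y <- mvn_trait(K, 0.4)
    c(haseman_elston(K, y)$h2, fit_genomic_h2(K, y)$h2)
  })
  expect_lt(abs(mean(he[1, ]) - 0.4), 0.1)
  expect_lt(abs(mean(he[2, ]) - 0.4), 0.1)
  expect_lt(abs(mean(he[1, ] - he[2, ])), 0.1)

  # independent phenotype: slope near zero
  y0 <- rnorm(n)
  expect_lt(abs(haseman_elston(K, y0)$h2), 0.15)

  # identity K: no off-diagonal contrast
  expect_error(haseman_elston(diag(n), rnorm(n)), "contrast")
})

test_that("repeatability handles exact repeats, noise, and the study's generating value", {
  recs1 <- tibble::tibble(individual_id = rep(1:20, each = 3),
                          wealth = rep(rnorm(20), each = 3))
  r1 <- repeatability(recs1, n_boot = 0)
  expect_gt(r1$R, 0.999)

  set.seed(85)
  recs0 <- tibble::tibble(individual_id = rep(1:50, each = 3),
                          wealth = rnorm(150))
  r0 <- repeatability(recs0, n_boot = 100, seed = 1)
  expect_lt(r0$R, 0.12)
  expect_lte(r0$ci[1], 0.03)

  # generating truth 0.74: R close and bootstrap CI covers it
  set.seed(86)
  n <- 300
  ind <- rnorm(n, 0, sqrt(0.74))
  recs <- tibble::tibble(individual_id = rep(1:n, each = 3),
                         wealth = 1.31 + rep(ind, each = 3) +
                           rnorm(3 * n, 0, sqrt(0.26)))
  r <- repeatability(recs, n_boot = 200, seed = 2)
  expect_lt(abs(r$R - 0.74), 0.06)
  expect_true(r$ci[1] <= r$R && r$R <= r$ci[2])

  expect_error(repeatability(tibble::tibble(individual_id = 1:5,
                                            wealth = rnorm(5)), n_boot = 0),
               "two or more records")
})
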