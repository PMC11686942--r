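# Observational inheritance analyses: natal-vs-breeding wealth similarity,
# dispersal, cross-fostering contrast, trait-wealth model, spatial null.

quiet_lmer <- function(formula, data, REML = TRUE) {
  ctl <- lme4::lmerControl(
    check.nobs.vs.nlev = "ignore", check.nobs.vs.rankZ = "ignore",
    check.nobs.vs.nRE = "ignore",
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4)
  )
  suppressMessages(suppressWarnings(
    lme4::lmer(formula, data = data, REML = REML, control = ctl)
  ))
}

fixef_table <- function(fit, df2) {
  cf <- summary(fit)$coefficients
  tibble::tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    se = cf[, "Std. Error"],
    statistic = cf[, "t value"],
    df = df2,
    p = 2 * pt(abs(cf[, "t value"]), df2, lower.tail = FALSE)
  )
}

#' Natal-versus-breeding wealth similarity and its decay with dispersal
#'
#' Linear mixed model of first-breeding wealth on natal wealth, dispersal
#' distance (in km internally) and their interaction, with the birth nest as
#' a random intercept. The interaction is tested two ways: a Wald F
#' (`t^2`, 1 numerator df, containment denominator df `n - rank(X)`) and a
#' 1-df likelihood-ratio test comparing maximum-likelihood refits with and
#' without the interaction. Post-hoc natal-wealth slopes are reported within
#' the short (`< cut_m`) and long (`> cut_m`) dispersal strata.
#'
#' @param recruits Tibble from [recruit_records()] (needs `breeding_wealth`,
#'   `natal_wealth`, `dispersal_distance`, `birth_nest`).
#' @param cut_m Distance cut separating the strata, default 1000 m.
#' @return An object of class `similarity_fit`.
#' @export
similarity_by_distance <- function(recruits, cut_m = 1000) {
  check_columns(recruits, c("breeding_wealth", "natal_wealth",
                            "dispersal_distance", "birth_nest"), "recruits")
  if (nrow(recruits) < 50) abort("need at least 50 recruits")
  if (any(recruits$dispersal_distance < 0)) abort("negative dispersal distance")
  dat <- data.frame(
    bw = recruits$breeding_wealth,
    nw = recruits$natal_wealth - mean(recruits$natal_wealth),
    d = recruits$dispersal_distance / 1000,
    nest = factor(recruits$birth_nest)
  )
  degenerate <- sd(dat$d) == 0
  if (degenerate) {
    fit <- lm(bw ~ nw, data = dat)
    cf <- summary(fit)$coefficients
    coefs <- tibble::tibble(term = rownames(cf), estimate = cf[, 1],
                            se = cf[, 2], statistic = cf[, 3],
                            df = fit$df.residual, p = cf[, 4])
    res <- list(coefficients = coefs, F = NA_real_, df1 = NA_integer_,
                df2 = NA_integer_, p_interaction = NA_real_,
                lrt_chisq = NA_real_, p_lrt = NA_real_,
                slopes = slope_by_stratum(recruits, cut_m),
                degenerate = TRUE, n = nrow(dat))
    return(structure(res, class = "similarity_fit"))
  }
  fit <- quiet_lmer(bw ~ nw * d + (1 | nest), dat, REML = TRUE)
  df2 <- nrow(dat) - 4L
  coefs <- fixef_table(fit, df2)
  t_int <- coefs$statistic[coefs$term == "nw:d"]
  Fstat <- t_int^2
  full_ml <- quiet_lmer(bw ~ nw * d + (1 | nest), dat, REML = FALSE)
  red_ml <- quiet_lmer(bw ~ nw + d + (1 | nest), dat, REML = FALSE)
  lrt <- max(0, 2 * (as.numeric(logLik(full_ml)) - as.numeric(logLik(red_ml))))
  structure(list(
    coefficients = coefs,
    F = unname(Fstat), df1 = 1L, df2 = df2,
    p_interaction = unname(pf(Fstat, 1, df2, lower.tail = FALSE)),
    lrt_chisq = lrt, p_lrt = pchisq(lrt, 1, lower.tail = FALSE),
    interaction = unname(coefs$estimate[coefs$term == "nw:d"]),
    slopes = slope_by_stratum(recruits, cut_m),
    degenerate = FALSE, n = nrow(dat), cut_m = cut_m
  ), class = "similarity_fit")
}

slope_by_stratum <- function(recruits, cut_m) {
  strata <- list(short = recruits$dispersal_distance < cut_m,
                 long = recruits$dispersal_distance > cut_m)
  purrr::imap_dfr(strata, function(sel, nm) {
    sub <- recruits[sel, ]
    if (nrow(sub) < 3 || sd(sub$natal_wealth) == 0) {
      return(tibble::tibble(stratum = nm, slope = NA_real_, se = NA_real_,
                            n = nrow(sub)))
    }
    cf <- summary(lm(breeding_wealth ~ natal_wealth, data = sub))$coefficients
    tibble::tibble(stratum = nm, slope = cf[2, 1], se = cf[2, 2], n = nrow(sub))
  })
}

#' Does natal wealth predict dispersal distance?
#'
#' One-predictor mixed model: dispersal distance (km) on natal wealth with a
#' birth-nest random intercept; slope with a Wald F test (containment df).
#'
#' @param recruits Tibble as in [similarity_by_distance()].
#' @return A list of class `dispersal_fit` with `slope` (km per wealth
#'   unit), `se`, `F`, `df1`, `df2`, `p`.
#' @export
dispersal_vs_natal_wealth <- function(recruits) {
  check_columns(recruits, c("natal_wealth", "dispersal_distance",
                            "birth_nest"), "recruits")
  dat <- data.frame(d = recruits$dispersal_distance / 1000,
                    nw = recruits$natal_wealth,
                    nest = factor(recruits$birth_nest))
  fit <- quiet_lmer(d ~ nw + (1 | nest), dat, REML = TRUE)
  df2 <- nrow(dat) - 2L
  coefs <- fixef_table(fit, df2)
  t_nw <- coefs$statistic[coefs$term == "nw"]
  structure(list(
    coefficients = coefs,
    slope = unname(coefs$estimate[coefs$term == "nw"]),
    se = unname(coefs$se[coefs$term == "nw"]),
    F = unname(t_nw^2), df1 = 1L, df2 = df2,
    p = unname(pf(t_nw^2, 1, df2, lower.tail = FALSE)),
    n = nrow(dat)
  ), class = "dispersal_fit")
}

#' Cross-fostering contrast: foster versus genetic parents' wealth
#'
#' Joint linear mixed model of a recruit's first-breeding wealth on the
#' wealth of its foster parents' and its genetic parents' territories, with
#' genetic and foster nests as random intercepts. Each predictor's
#' significance is a 1-df likelihood-ratio chi-squared comparing
#' maximum-likelihood refits with and without it. Also reports the
#' correlation between genetic and foster wealth (the design-induced
#' confound) and the two marginal slopes. Refuses, as inseparable, designs
#' where that correlation exceeds 0.98.
#'
#' @param recruits Tibble from [crossfoster_records()] (needs
#'   `breeding_wealth`, `genetic_wealth`, `foster_wealth`, `genetic_nest`,
#'   `foster_nest`).
#' @return An object of class `crossfoster_fit`.
#' @export
crossfoster_analysis <- function(recruits) {
  check_columns(recruits, c("breeding_wealth", "genetic_wealth",
                            "foster_wealth", "genetic_nest", "foster_nest"),
                "recruits")
  if (nrow(recruits) < 10) abort("need at least 10 cross-fostered recruits")
  if (any(!complete.cases(recruits[, c("breeding_wealth", "genetic_wealth",
                                       "foster_wealth")]))) {
    abort("every recruit needs both parental wealth values")
  }
  r_gf <- cor(recruits$genetic_wealth, recruits$foster_wealth)
  if (!is.finite(r_gf) || r_gf > 0.98) {
    abort("genetic and foster wealth are (nearly) identical; the design cannot separate the two channels")
  }
  dat <- data.frame(bw = recruits$breeding_wealth,
                    gw = recruits$genetic_wealth,
                    fw = recruits$foster_wealth,
                    gn = factor(recruits$genetic_nest),
                    fn = factor(recruits$foster_nest))
  full_reml <- quiet_lmer(bw ~ gw + fw + (1 | gn) + (1 | fn), dat, REML = TRUE)
  df2 <- nrow(dat) - 3L
  coefs <- fixef_table(full_reml, df2)
  full_ml <- quiet_lmer(bw ~ gw + fw + (1 | gn) + (1 | fn), dat, REML = FALSE)
  no_g <- quiet_lmer(bw ~ fw + (1 | gn) + (1 | fn), dat, REML = FALSE)
  no_f <- quiet_lmer(bw ~ gw + (1 | gn) + (1 | fn), dat, REML = FALSE)
  ll <- as.numeric(logLik(full_ml))
  chi_g <- max(0, 2 * (ll - as.numeric(logLik(no_g))))
  chi_f <- max(0, 2 * (ll - as.numeric(logLik(no_f))))
  marg_g <- coef(lm(bw ~ gw, dat))[2]
  marg_f <- coef(lm(bw ~ fw, dat))[2]
  structure(list(
    coefficients = coefs,
    foster = list(slope = unname(coefs$estimate[coefs$term == "fw"]),
                  se = unname(coefs$se[coefs$term == "fw"]),
                  chisq = chi_f, p = pchisq(chi_f, 1, lower.tail = FALSE)),
    genetic = list(slope = unname(coefs$estimate[coefs$term == "gw"]),
                   se = unname(coefs$se[coefs$term == "gw"]),
                   chisq = chi_g, p = pchisq(chi_g, 1, lower.tail = FALSE)),
    marginal_slopes = c(genetic = unname(marg_g), foster = unname(marg_f)),
    r_genetic_foster = r_gf,
    n = nrow(dat)
  ), class = "crossfoster_fit")
}

#' Mixed model of adult phenotypic traits on material wealth
#'
#' Regresses the wealth of the first recorded breeding territory on a set of
#' (mean-centred) phenotypic predictors with year, family and measurer as
#' random intercepts. Reports Wald t per fixed effect (containment df),
#' variance inflation factors computed from the predictor correlation matrix
#' (`VIF_j = [R^-1]_jj`), and the condition number of that correlation
#' matrix. Fails, naming the aliased predictors, on a rank-deficient design.
#'
#' @param adults Data frame with a `wealth` column, numeric predictor
#'   columns, optionally `sex`, and grouping columns `year`, `family`,
#'   `measurer`.
#' @param predictors Character vector naming the predictor columns.
#' @return An object of class `trait_wealth_fit` with `coefficients`, `vif`,
#'   `kappa`.
#' @export
trait_wealth_model <- function(adults,
                               predictors = c("forehead_patch", "wing",
                                              "tarsus", "adult_mass", "age",
                                              "laying_date", "nestling_mass")) {
  check_columns(adults, c("wealth", predictors, "year", "family", "measurer"),
                "adults")
  Xp <- as.matrix(adults[, predictors, drop = FALSE])
  Xp <- scale(Xp, center = TRUE, scale = FALSE)
  has_sex <- "sex" %in% names(adults) && length(unique(adults$sex)) > 1
  Xfull <- if (has_sex) cbind(Xp, sex = as.numeric(factor(adults$sex)) - 1) else Xp
  qrx <- qr(cbind(1, Xfull))
  if (qrx$rank < ncol(Xfull) + 1) {
    kept <- qrx$pivot[seq_len(qrx$rank)]
    aliased <- setdiff(seq_len(ncol(Xfull) + 1), kept) - 1L
    abort(sprintf("rank-deficient design; aliased predictor(s): %s",
                  paste(colnames(Xfull)[aliased], collapse = ", ")))
  }
  R <- cor(Xfull)
  vif <- diag(solve(R))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  kap <- max(ev) / min(ev)

  dat <- data.frame(wealth = adults$wealth, Xfull,
                    year = factor(adults$year),
                    family = factor(adults$family),
                    measurer = factor(adults$measurer))
  fml <- as.formula(paste("wealth ~", paste(colnames(Xfull), collapse = " + "),
                          "+ (1 | year) + (1 | family) + (1 | measurer)"))
  fit <- quiet_lmer(fml, dat, REML = TRUE)
  df2 <- nrow(dat) - (ncol(Xfull) + 1L)
  structure(list(
    coefficients = fixef_table(fit, df2),
    vif = tibble::tibble(predictor = colnames(Xfull), vif = unname(vif)),
    kappa = kap,
    n = nrow(dat)
  ), class = "trait_wealth_fit")
}

#' Spatial-autocorrelation null for natal-breeding wealth similarity
#'
#' Tests whether the observed regression of first-breeding wealth on natal
#' wealth is explained by spatial autocorrelation alone. Each replicate
#' reassigns every recruit a breeding territory drawn uniformly from the
#' territories within the distance ring `[d (1 - tau), d (1 + tau)]` around
#' its natal (rearing) nest, where `d` is its observed dispersal distance --
#' preserving each bird's dispersal distance and the landscape while
#' randomising direction -- and recomputes the natal-to-breeding wealth
#' regression slope. The ring is widened stepwise (tau doubled) until at
#' least one candidate exists; a recruit whose ring stays empty keeps its
#' observed territory and is counted.
#'
#' @param recruits Tibble from [recruit_records()] (needs
#'   `rearing_territory`, `dispersal_distance`, `natal_wealth`,
#'   `breeding_year`, `breeding_wealth`).
#' @param map Territory map of the landscape.
#' @param field Wealth field covering the recruits' breeding years.
#' @param n_sim Number of replicates, default 500.
#' @param tau Relative half-width of the distance ring, default 0.15.
#' @param seed Optional integer seed.
#' @return An object of class `spatial_null`: simulated `slopes`, the
#'   `observed_slope`, the central 95% `envelope`, `prop_ge` (share of
#'   replicates with slope >= observed) and `n_kept_observed`.
#' @export
spatial_null_simulation <- function(recruits, map, field, n_sim = 500,
                                    tau = 0.15, seed = NULL) {
  check_columns(recruits, c("rearing_territory", "dispersal_distance",
                            "natal_wealth", "breeding_year",
                            "breeding_wealth"), "recruits")
  check_number(n_sim, "n_sim", lower = 1)
  check_number(tau, "tau", lower = 0, upper = 1)
  if (!is.null(seed)) set.seed(seed)

  years <- sort(unique(field$year))
  W <- matrix(NA_real_, nrow(map), length(years),
              dimnames = list(NULL, years))
  W[cbind(match(field$territory_id, map$territory_id),
          match(field$year, years))] <- field$wealth
  D <- dist_xy(map$x, map$y)
  nr <- nrow(recruits)
  ti <- match(recruits$rearing_territory, map$territory_id)
  yi <- match(recruits$breeding_year, years)
  if (anyNA(yi)) abort("field does not cover every breeding year")

  n_kept <- 0L
  candidates <- vector("list", nr)
  for (i in seq_len(nr)) {
    d <- recruits$dispersal_distance[i]
    tt <- tau
    cand <- integer(0)
    repeat {
      lo <- d * (1 - tt); hi <- d * (1 + tt)
      cand <- which(D[ti[i], ] >= lo & D[ti[i], ] <= hi)
      if (length(cand) || tt > 4) break
      tt <- max(tt * 2, 0.05)
    }
    if (!length(cand)) {
      obs_t <- if ("territory_id" %in% names(recruits)) {
        recruits$territory_id[i]
      } else recruits$rearing_territory[i]
      cand <- match(obs_t, map$territory_id)
      n_kept <- n_kept + 1L
    }
    candidates[[i]] <- cand
  }
  nw <- recruits$natal_wealth
  nw_c <- nw - mean(nw)
  sxx <- sum(nw_c^2)
  slopes <- vapply(seq_len(n_sim), function(s) {
    pick <- vapply(candidates, function(cs)
      if (length(cs) == 1) cs else cs[sample.int(length(cs), 1)], integer(1))
    bw <- W[cbind(pick, yi)]
    sum(nw_c * (bw - mean(bw))) / sxx
  }, numeric(1))
  obs <- sum(nw_c * (recruits$breeding_wealth -
                       mean(recruits$breeding_wealth))) / sxx
  structure(list(
    slopes = slopes,
    observed_slope = obs,
    envelope = unname(quantile(slopes, c(0.025, 0.975))),
    prop_ge = mean(slopes >= obs),
    n_sim = n_sim, tau = tau, n_kept_observed = n_kept, n_recruits = nr
  ), class = "spatial_null")
}

#' @export
print.similarity_fit <- function(x, ...) {
  cat("Natal-vs-breeding wealth similarity (n =", x$n, ")\n")
  print(as.data.frame(x$coefficients), row.names = FALSE)
  if (!x$degenerate) {
    cat(sprintf("interaction: F(%d, %d) = %.3f, p = %.4g (LRT chi2 = %.3f)\n",
                x$df1, x$df2, x$F, x$p_interaction, x$lrt_chisq))
  }
  print(as.data.frame(x$slopes), row.names = FALSE)
  invisible(x)
}

#' @export
print.crossfoster_fit <- function(x, ...) {
  cat("Cross-fostering contrast (n =", x$n,
      ", r(genetic, foster) =", round(x$r_genetic_foster, 3), ")\n")
  cat(sprintf("  foster wealth:  slope = %.3f (se %.3f), chi2(1) = %.2f, p = %.4g\n",
              x$foster$slope, x$foster$se, x$foster$chisq, x$foster$p))
  cat(sprintf("  genetic wealth: slope = %.3f (se %.3f), chi2(1) = %.2f, p = %.4g\n",
              x$genetic$slope, x$genetic$se, x$genetic$chisq, x$genetic$p))
  invisible(x)
}

#' @export
print.spatial_null <- function(x, ...) {
  cat("Spatial null simulation:", x$n_sim, "replicates,",
      x$n_recruits, "recruits\n")
  cat(sprintf("  observed slope %.3f; null envelope [%.3f, %.3f]; P(slope >= obs) = %.3f\n",
              x$observed_slope, x$envelope[1], x$envelope[2], x$prop_ge))
  if (x$n_kept_observed > 0) {
    cat("  recruits keeping their observed territory:", x$n_kept_observed, "\n")
  }
  invisible(x)
}
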