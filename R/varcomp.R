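#' Fit an animal model to repeated wealth records
#'
#' Decomposes phenotypic variance as `y = mu + a + pe + year + e`, where the
#' additive genetic values `a` have covariance `sigma2_a * K` (pedigree
#' A-matrix or genomic relationship matrix), `pe` is a permanent-environment
#' (individual identity) effect and `year` a random year intercept. Ratios
#' `h2`, `pe2` and `year2` are reported against the full phenotypic variance
#' (the sum of all components) with delta-method standard errors from the
#' inverse average-information matrix, and `h2_no_year` additionally gives
#' the additive fraction of `sigma2_a + sigma2_pe + sigma2_e` (the
#' denominator that excludes the shared year variance).
#'
#' @param records Data frame with columns `individual_id`, `wealth` and (when
#'   `"year"` is included) `year`.
#' @param K Relatedness matrix with individual ids as dimnames; every
#'   individual appearing in `records` must be indexed in `K`.
#' @param include Character subset of `c("pe", "year")` selecting the extra
#'   random components.
#' @return An object of class `animal_model`; see [tidy.animal_model()].
#' @export
fit_animal_model <- function(records, K, include = c("pe", "year")) {
  check_columns(records, c("individual_id", "wealth"), "records")
  if (length(include)) {
    include <- match.arg(include, c("pe", "year"), several.ok = TRUE)
  }
  ids <- as.character(records$individual_id)
  k_ids <- rownames(K)
  if (is.null(k_ids)) abort("`K` must carry individual ids as dimnames")
  missing <- setdiff(unique(ids), k_ids)
  if (length(missing)) {
    abort(sprintf("individuals with records but absent from K: %s%s",
                  paste(head(missing, 5), collapse = ", "),
                  if (length(missing) > 5) ", ..." else ""))
  }
  uids <- unique(ids)
  Ksub <- unclass(K)[uids, uids, drop = FALSE]
  fi <- factor(ids, levels = uids)
  Z <- model.matrix(~ 0 + fi)

  single_record <- !anyDuplicated(ids)
  random <- list(additive = list(Z = Z, K = Ksub))
  if ("pe" %in% include && !single_record) random$permanent_env <- fi
  if ("year" %in% include) {
    check_columns(records, "year", "records")
    if (length(unique(records$year)) > 1) random$year <- factor(records$year)
  }

  fit <- fit_lmm_reml(records$wealth, random = random)
  names(fit$sigma2)[1] <- "additive"
  ratios <- vc_ratios(fit)
  ratios$component <- sub("^additive$", "h2", ratios$component)
  ratios$component <- sub("^permanent_env$", "pe2", ratios$component)
  ratios$component <- sub("^year$", "year2", ratios$component)
  ratios$component <- sub("^residual$", "e2", ratios$component)

  th <- fit$sigma2
  no_year <- setdiff(names(th), "year")
  h2_no_year <- unname(th["additive"] / sum(th[no_year]))

  structure(list(
    vc = tibble::tibble(component = names(th), estimate = unname(th),
                        se = unname(fit$se_sigma2)),
    ratios = ratios,
    h2 = ratios$ratio[ratios$component == "h2"],
    h2_no_year = h2_no_year,
    fit = fit,
    n_records = nrow(records),
    n_individuals = length(uids)
  ), class = "animal_model")
}

#' Genomic heritability by REML from a relatedness matrix
#'
#' One phenotype value per individual: `y ~ N(X b, sigma2_a K + sigma2_e I)`,
#' solved exactly through the spectral decomposition of `K`.
#'
#' @param K Relatedness matrix (ids as dimnames, or aligned with `y`).
#' @param y Phenotype vector, one value per row of `K`.
#' @param X Optional fixed-effect design (intercept by default).
#' @return An `animal_model` object with the `h2` ratio.
#' @export
fit_genomic_h2 <- function(K, y, X = NULL) {
  if (length(y) != nrow(K)) abort("`y` must have one value per row of `K`")
  ids <- rownames(K) %||% as.character(seq_along(y))
  records <- tibble::tibble(individual_id = ids, wealth = as.numeric(y))
  Km <- unclass(K)
  rownames(Km) <- colnames(Km) <- ids
  fit <- fit_lmm_reml(as.numeric(y), X = X, random = list(additive = Km))
  ratios <- vc_ratios(fit)
  ratios$component <- sub("^additive$", "h2", ratios$component)
  ratios$component <- sub("^residual$", "e2", ratios$component)
  structure(list(
    vc = tibble::tibble(component = names(fit$sigma2),
                        estimate = unname(fit$sigma2),
                        se = unname(fit$se_sigma2)),
    ratios = ratios,
    h2 = ratios$ratio[ratios$component == "h2"],
    h2_no_year = ratios$ratio[ratios$component == "h2"],
    fit = fit,
    n_records = length(y),
    n_individuals = length(y)
  ), class = "animal_model")
}

#' Haseman-Elston regression estimate of heritability
#'
#' Moment estimator: the phenotype is standardised, the products `y_i * y_j`
#' over all pairs `i < j` are regressed (with intercept) on the relatedness
#' coefficients `K_ij`, and the slope estimates `h2`. The standard error is a
#' leave-one-individual-out jackknife.
#'
#' @param K Relatedness matrix.
#' @param y Phenotype vector, one value per individual in `K` order.
#' @return A list of class `he_fit` with `h2`, `se`, `n`.
#' @export
haseman_elston <- function(K, y) {
  n <- length(y)
  if (nrow(K) != n) abort("`y` must have one value per row of `K`")
  if (n < 3) abort("need at least 3 individuals")
  z <- as.numeric(scale(y))
  Km <- unclass(K)
  up <- upper.tri(Km)
  x <- Km[up]
  if (sd(x) == 0) abort("no relatedness contrast: K off-diagonals are constant")
  zz_x <- outer(z, z)                 # pair products
  X2 <- Km^2; XY <- Km * zz_x
  n_pairs <- n * (n - 1) / 2

  tot <- c(sx = sum(x), sy = sum(zz_x[up]), sxx = sum(X2[up]),
           sxy = sum(XY[up]), p = n_pairs)
  slope_of <- function(sx, sy, sxx, sxy, p) {
    (sxy - sx * sy / p) / (sxx - sx^2 / p)
  }
  h2 <- slope_of(tot["sx"], tot["sy"], tot["sxx"], tot["sxy"], tot["p"])

  # leave-one-individual-out via per-individual pair sums (off-diagonal rows)
  rs <- function(M) rowSums(M) - diag(M)
  sx_i <- rs(Km); sy_i <- rs(zz_x); sxx_i <- rs(X2); sxy_i <- rs(XY)
  loo <- slope_of(tot["sx"] - sx_i, tot["sy"] - sy_i,
                  tot["sxx"] - sxx_i, tot["sxy"] - sxy_i,
                  tot["p"] - (n - 1))
  se <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  structure(list(h2 = unname(h2), se = se, n = n, n_pairs = n_pairs),
            class = "he_fit")
}

#' Between-year repeatability of individual wealth
#'
#' Gaussian random-intercept model (`wealth ~ 1 + (1 | individual)`) fitted
#' by REML through lme4; `R = sigma2_ind / (sigma2_ind + sigma2_e)`. The
#' confidence interval comes from a parametric bootstrap: `n_boot` data sets
#' are simulated from the fitted model and refitted, and the 2.5% and 97.5%
#' quantiles of the refitted `R` are reported.
#'
#' @param records Data frame with columns `individual_id` and `wealth`.
#' @param n_boot Number of parametric bootstrap resamples (default 1000).
#' @param seed Optional integer seed for the bootstrap.
#' @return A list of class `repeatability_fit` with `R`, `ci`, `n_boot`.
#' @export
repeatability <- function(records, n_boot = 1000, seed = NULL) {
  check_columns(records, c("individual_id", "wealth"), "records")
  counts <- table(records$individual_id)
  if (sum(counts >= 2) < 2) {
    abort("repeatability needs at least two individuals with two or more records")
  }
  if (!is.null(seed)) set.seed(seed)
  dat <- data.frame(w = records$wealth, id = factor(records$individual_id))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(w ~ 1 + (1 | id), data = dat, REML = TRUE)))
  r_of <- function(m) {
    vc <- as.data.frame(lme4::VarCorr(m))
    vi <- vc$vcov[vc$grp == "id"]
    ve <- vc$vcov[vc$grp == "Residual"]
    vi / (vi + ve)
  }
  R <- r_of(fit)
  boot <- rep(NA_real_, n_boot)
  if (n_boot > 0) {
    sims <- simulate(fit, nsim = n_boot)
    boot <- vapply(seq_len(n_boot), function(b) {
      m <- suppressMessages(suppressWarnings(lme4::refit(fit, sims[[b]])))
      r_of(m)
    }, numeric(1))
  }
  ci <- if (n_boot > 0) unname(quantile(boot, c(0.025, 0.975))) else c(NA_real_, NA_real_)
  structure(list(R = R, ci = ci, n_boot = n_boot, boot = boot,
                 n_individuals = length(counts), n_records = nrow(records)),
            class = "repeatability_fit")
}

#' @export
print.animal_model <- function(x, ...) {
  cat("Animal model (", x$n_records, "records,", x$n_individuals, "individuals )\n")
  print(as.data.frame(x$ratios), row.names = FALSE)
  cat("h2 (denominator without year variance):", round(x$h2_no_year, 4), "\n")
  invisible(x)
}

#' @export
print.he_fit <- function(x, ...) {
  cat("Haseman-Elston regression: h2 =", round(x$h2, 4),
      "( se =", round(x$se, 4), ", n =", x$n, ")\n")
  invisible(x)
}

#' @export
print.repeatability_fit <- function(x, ...) {
  cat("Repeatability R =", round(x$R, 4), " 95% CI [",
      round(x$ci[1], 4), ",", round(x$ci[2], 4), "] (", x$n_boot, "bootstraps )\n")
  invisible(x)
}
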