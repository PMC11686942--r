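# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a REML mixed-model fit
#' @param x An `lmm_fit`. @param ... Ignored.
#' @return Tibble of variance components with standard errors.
#' @export
tidy.lmm_fit <- function(x, ...) {
  tibble::tibble(component = names(x$sigma2), estimate = unname(x$sigma2),
                 se = unname(x$se_sigma2))
}

#' @export
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, iterations = x$iterations,
                 converged = x$converged, n = x$n, method = x$method)
}

#' Tidy an animal model: variance ratios (h2, pe2, year2)
#' @param x An `animal_model`.
#' @param type `"ratios"` (default) or `"components"`. @param ... Ignored.
#' @return A tibble.
#' @export
tidy.animal_model <- function(x, type = c("ratios", "components"), ...) {
  type <- match.arg(type)
  if (type == "ratios") x$ratios else x$vc
}

#' @export
glance.animal_model <- function(x, ...) {
  tibble::tibble(h2 = x$h2, h2_no_year = x$h2_no_year,
                 logLik = x$fit$loglik, converged = x$fit$converged,
                 n_records = x$n_records, n_individuals = x$n_individuals)
}

#' @export
tidy.he_fit <- function(x, ...) {
  tibble::tibble(term = "h2", estimate = x$h2, se = x$se)
}

#' @export
glance.he_fit <- function(x, ...) {
  tibble::tibble(h2 = x$h2, se = x$se, n = x$n, n_pairs = x$n_pairs)
}

#' @export
tidy.repeatability_fit <- function(x, ...) {
  tibble::tibble(term = "R", estimate = x$R,
                 lower = x$ci[1], upper = x$ci[2])
}

#' @export
glance.repeatability_fit <- function(x, ...) {
  tibble::tibble(R = x$R, lower = x$ci[1], upper = x$ci[2],
                 n_boot = x$n_boot, n_individuals = x$n_individuals,
                 n_records = x$n_records)
}

#' @export
tidy.similarity_fit <- function(x, ...) x$coefficients

#' @export
glance.similarity_fit <- function(x, ...) {
  tibble::tibble(F = x$F, df1 = x$df1, df2 = x$df2,
                 p_interaction = x$p_interaction, lrt_chisq = x$lrt_chisq,
                 short_slope = x$slopes$slope[x$slopes$stratum == "short"],
                 long_slope = x$slopes$slope[x$slopes$stratum == "long"],
                 n = x$n)
}

#' @export
tidy.crossfoster_fit <- function(x, ...) {
  tibble::tibble(
    term = c("genetic_wealth", "foster_wealth"),
    estimate = c(x$genetic$slope, x$foster$slope),
    se = c(x$genetic$se, x$foster$se),
    statistic = c(x$genetic$chisq, x$foster$chisq),
    df = 1,
    p = c(x$genetic$p, x$foster$p)
  )
}

#' @export
glance.crossfoster_fit <- function(x, ...) {
  tibble::tibble(foster_chisq = x$foster$chisq, foster_p = x$foster$p,
                 genetic_chisq = x$genetic$chisq, genetic_p = x$genetic$p,
                 r_genetic_foster = x$r_genetic_foster, n = x$n)
}

#' @export
tidy.dispersal_fit <- function(x, ...) x$coefficients

#' @export
glance.dispersal_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, se = x$se, F = x$F, df1 = x$df1,
                 df2 = x$df2, p = x$p, n = x$n)
}

#' @export
tidy.trait_wealth_fit <- function(x, ...) {
  dplyr::left_join(x$coefficients,
                   dplyr::rename(x$vif, term = "predictor"),
                   by = "term")
}

#' @export
glance.trait_wealth_fit <- function(x, ...) {
  tibble::tibble(kappa = x$kappa, n = x$n)
}

#' @export
tidy.spatial_null <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$slopes), slope = x$slopes)
}

#' @export
glance.spatial_null <- function(x, ...) {
  tibble::tibble(observed_slope = x$observed_slope,
                 envelope_lower = x$envelope[1],
                 envelope_upper = x$envelope[2],
                 prop_ge = x$prop_ge, n_sim = x$n_sim,
                 n_kept_observed = x$n_kept_observed)
}
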