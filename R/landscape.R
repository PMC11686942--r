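#' Generate a map of nest-box territories
#'
#' Places `n` territories on a square study area of side `extent` metres,
#' optionally clustered into forest patches, with a hard minimum spacing
#' between any two territories (sequential rejection sampling).
#'
#' @param n Number of territories.
#' @param extent Side length of the square study area, metres.
#' @param min_spacing Minimum distance allowed between two territories, metres.
#' @param n_patches Number of patch centres territories cluster around; `1`
#'   gives a spatially uniform layout.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `territory_id`, `x`, `y`, `patch_id`.
#' @examples
#' map <- generate_territories(50, extent = 3000, min_spacing = 100, seed = 1)
#' @export
generate_territories <- function(n, extent = 5000, min_spacing = 150,
                                 n_patches = 1, seed = NULL) {
  check_number(n, "n", lower = 1)
  check_number(extent, "extent", lower = 0)
  check_number(min_spacing, "min_spacing", lower = 0)
  check_number(n_patches, "n_patches", lower = 1)
  if (extent <= min_spacing) abort("`extent` must exceed `min_spacing`")
  if (!is.null(seed)) set.seed(seed)

  centres_x <- runif(n_patches, 0.15 * extent, 0.85 * extent)
  centres_y <- runif(n_patches, 0.15 * extent, 0.85 * extent)
  patch_sd <- extent / (2 * sqrt(n_patches) + 1)

  xs <- numeric(n); ys <- numeric(n); patch <- integer(n)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 500L * n
  while (placed < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    if (n_patches > 1 && attempts <= max_attempts / 2) {
      p <- sample.int(n_patches, 1L)
      cand_x <- rnorm(1, centres_x[p], patch_sd)
      cand_y <- rnorm(1, centres_y[p], patch_sd)
      if (cand_x < 0 || cand_x > extent || cand_y < 0 || cand_y > extent) next
    } else {
      cand_x <- runif(1, 0, extent)
      cand_y <- runif(1, 0, extent)
    }
    if (placed > 0L && min_spacing > 0) {
      d2 <- (xs[seq_len(placed)] - cand_x)^2 + (ys[seq_len(placed)] - cand_y)^2
      if (min(d2) < min_spacing^2) next
    }
    placed <- placed + 1L
    xs[placed] <- cand_x
    ys[placed] <- cand_y
    patch[placed] <- if (n_patches > 1) {
      which.min((centres_x - cand_x)^2 + (centres_y - cand_y)^2)
    } else 1L
  }
  if (placed < n) {
    abort(sprintf(
      "could only place %d of %d territories at min_spacing = %g within extent %g; density infeasible",
      placed, n, min_spacing, extent))
  }
  tibble::tibble(territory_id = seq_len(n), x = xs, y = ys, patch_id = patch)
}

#' Parameters of the wealth landscape model
#'
#' The per-year wealth surface is `mean + year shift + spatial field + nugget
#' noise`, truncated below at `floor`. The spatial field is a zero-mean
#' Gaussian process with exponential covariance `sill * exp(-d / range)` and
#' AR(1) persistence `persistence` between successive years; the year shift is
#' a shared normal deviate with standard deviation `year_sd`.
#'
#' Defaults give territory wealth with mean 1.31 and standard deviation 0.35
#' (`sqrt(sill + nugget + year_sd^2)`) and, together with perfect adult site
#' fidelity, a between-year individual repeatability of about 0.74.
#'
#' @param mean Mean wealth (caterpillar-biomass index).
#' @param sill Marginal variance of the spatial field, wealth units squared.
#' @param range Correlation length of the exponential covariance, metres.
#' @param nugget Independent per-territory-per-year noise variance.
#' @param year_sd Standard deviation of the shared yearly shift.
#' @param persistence AR(1) correlation of the spatial field between years,
#'   in `[0, 1]`.
#' @param floor Lower truncation bound for wealth.
#' @return A list of class `field_params`.
#' @export
field_params <- function(mean = 1.31, sill = 0.10, range = 500, nugget = 0.015,
                         year_sd = 0.087, persistence = 0.95, floor = 0.05) {
  check_number(mean, "mean")
  check_number(sill, "sill", lower = 0)
  check_number(range, "range")
  if (range <= 0) abort("`range` must be > 0")
  check_number(nugget, "nugget", lower = 0)
  check_number(year_sd, "year_sd", lower = 0)
  check_number(persistence, "persistence", lower = 0, upper = 1)
  check_number(floor, "floor", lower = 0)
  structure(list(mean = mean, sill = sill, range = range, nugget = nugget,
                 year_sd = year_sd, persistence = persistence, floor = floor),
            class = "field_params")
}

#' Simulate per-territory, per-year wealth values
#'
#' Draws a spatially autocorrelated wealth surface over the territories of
#' `map` for `years` consecutive years (see [field_params()] for the model).
#'
#' @param map A territory map from [generate_territories()].
#' @param params A [field_params()] object.
#' @param years Number of years to simulate.
#' @param start_year Label of the first year.
#' @param seed Optional integer seed.
#' @return A tibble with columns `territory_id`, `year`, `wealth`.
#' @export
simulate_wealth_field <- function(map, params = field_params(), years = 20,
                                  start_year = 1, seed = NULL) {
  check_columns(map, c("territory_id", "x", "y"), "map")
  if (nrow(map) < 1) abort("`map` must contain at least one territory")
  if (!inherits(params, "field_params")) abort("`params` must come from field_params()")
  check_number(years, "years", lower = 1)
  if (!is.null(seed)) set.seed(seed)

  n <- nrow(map)
  phi <- params$persistence
  if (params$sill > 0) {
    D <- dist_xy(map$x, map$y)
    C <- params$sill * exp(-D / params$range)
    L <- chol_jitter(C, "spatial covariance matrix")
  } else {
    L <- NULL
  }
  draw_field <- function() if (is.null(L)) numeric(n) else drop(mvn_from_chol(L))

  out <- vector("list", years)
  f <- draw_field()
  for (t in seq_len(years)) {
    if (t > 1) f <- phi * f + sqrt(max(0, 1 - phi^2)) * draw_field()
    year_shift <- rnorm(1, 0, params$year_sd)
    w <- params$mean + year_shift + f + rnorm(n, 0, sqrt(params$nugget))
    w <- pmax(w, params$floor)
    out[[t]] <- tibble::tibble(
      territory_id = map$territory_id,
      year = start_year + t - 1L,
      wealth = w
    )
  }
  dplyr::bind_rows(out)
}

#' Empirical distance correlogram of a wealth field
#'
#' Pearson correlation of wealth between territory pairs, pooled over years,
#' within distance bins. Pairs are entered symmetrically so the estimate does
#' not depend on pair ordering. Empty bins or bins with degenerate variance
#' are reported as `NA`, not zero.
#'
#' @param field A wealth field from [simulate_wealth_field()].
#' @param map The matching territory map.
#' @param breaks Increasing vector of distance bin edges, metres.
#' @return A tibble with `bin_mid`, `correlation`, `n_pairs` (distinct
#'   territory pairs in the bin), of class `wealth_correlogram`.
#' @export
empirical_correlogram <- function(field, map,
                                  breaks = seq(0, 3000, by = 250)) {
  check_columns(field, c("territory_id", "year", "wealth"), "field")
  check_columns(map, c("territory_id", "x", "y"), "map")
  if (nrow(map) < 2) abort("need at least two territories")
  if (is.unsorted(breaks, strictly = TRUE)) abort("`breaks` must be strictly increasing")

  W <- tidyr::pivot_wider(field, id_cols = "territory_id", names_from = "year",
                          values_from = "wealth")
  ord <- match(map$territory_id, W$territory_id)
  Wm <- as.matrix(W[ord, -1, drop = FALSE])
  D <- dist_xy(map$x, map$y)
  ij <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[ij]
  bin <- cut(d, breaks = breaks, include.lowest = TRUE)

  res <- purrr::map_dfr(seq_len(length(breaks) - 1L), function(b) {
    lab <- levels(bin)[b]
    sel <- which(!is.na(bin) & bin == lab)
    mid <- (breaks[b] + breaks[b + 1]) / 2
    if (!length(sel)) {
      return(tibble::tibble(bin_mid = mid, correlation = NA_real_, n_pairs = 0L))
    }
    a <- as.vector(Wm[ij[sel, 1], , drop = FALSE])
    bvec <- as.vector(Wm[ij[sel, 2], , drop = FALSE])
    xx <- c(a, bvec); yy <- c(bvec, a)  # symmetrize
    r <- if (sd(xx) == 0 || sd(yy) == 0) NA_real_ else cor(xx, yy)
    tibble::tibble(bin_mid = mid, correlation = r, n_pairs = length(sel))
  })
  class(res) <- c("wealth_correlogram", class(res))
  res
}
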