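#' First-breeding table of locally born recruits
#'
#' One row per recruited, locally born bird (non-founder) with its first
#' breeding record: breeding wealth, natal wealth (wealth of the genetic
#' natal territory in the birth year), foster/rearing wealth, dispersal
#' distance (from the rearing nest, i.e. the nest the bird fledged from, to
#' the first breeding nest) and nest identifiers. This is the input to
#' [similarity_by_distance()], [dispersal_vs_natal_wealth()] and
#' [spatial_null_simulation()].
#'
#' @param sim A `wealth_sim` object from [run_simulation()].
#' @return A tibble with columns `individual_id`, `breeding_year`,
#'   `territory_id`, `breeding_wealth`, `natal_wealth`, `rearing_wealth`,
#'   `dispersal_distance`, `birth_nest`, `natal_territory`,
#'   `rearing_territory`, `birth_year`, `sex`.
#' @export
recruit_records <- function(sim) {
  ind <- sim$individuals
  rec <- sim$records
  first <- rec |>
    dplyr::arrange(.data$year) |>
    dplyr::distinct(.data$individual_id, .keep_all = TRUE)
  born <- ind[!is.na(ind$dam_id), ]
  out <- dplyr::inner_join(first, born, by = c(individual_id = "id"))
  ti_r <- match(out$rearing_territory_id, sim$map$territory_id)
  ti_n <- match(out$natal_territory_id, sim$map$territory_id)
  tibble::tibble(
    individual_id = out$individual_id,
    breeding_year = out$year,
    territory_id = out$territory_id,
    breeding_wealth = out$wealth,
    natal_wealth = sim$W[cbind(ti_n, out$birth_year + 1L)],
    rearing_wealth = sim$W[cbind(ti_r, out$birth_year + 1L)],
    dispersal_distance = out$dispersal_distance,
    birth_nest = paste0(out$rearing_territory_id, "_", out$birth_year),
    natal_territory = out$natal_territory_id,
    rearing_territory = out$rearing_territory_id,
    birth_year = out$birth_year,
    sex = out$sex
  )
}

#' Cross-fostered recruit table
#'
#' Recruits whose brood took part in a cross-fostering exchange, with the
#' wealth of their genetic and foster parents' territories in the birth year
#' and both nest identifiers -- the input to [crossfoster_analysis()]. Both
#' moved nestlings and their stay-home (half-sib design) brood mates are
#' included; for the latter the genetic and foster values coincide.
#'
#' @param sim A `wealth_sim` object.
#' @param swapped_only If `TRUE`, keep only birds actually reared away from
#'   their genetic nest.
#' @return A tibble with `individual_id`, `breeding_wealth`,
#'   `genetic_wealth`, `foster_wealth`, `genetic_nest`, `foster_nest`.
#' @export
crossfoster_records <- function(sim, swapped_only = TRUE) {
  rr <- recruit_records(sim)
  ind <- sim$individuals
  info <- ind[match(rr$individual_id, ind$id), ]
  moved <- !is.na(info$foster_dam_id) & !is.na(info$dam_id) &
    (info$foster_dam_id != info$dam_id)
  keep <- if (swapped_only) moved else {
    swapped_nests <- unique(c(
      paste0(sim$crossfoster_log$terr_a, "_", sim$crossfoster_log$year),
      paste0(sim$crossfoster_log$terr_b, "_", sim$crossfoster_log$year)
    ))
    moved | paste0(rr$natal_territory, "_", rr$birth_year) %in% swapped_nests
  }
  tibble::tibble(
    individual_id = rr$individual_id[keep],
    breeding_wealth = rr$breeding_wealth[keep],
    genetic_wealth = rr$natal_wealth[keep],
    foster_wealth = rr$rearing_wealth[keep],
    genetic_nest = paste0(rr$natal_territory, "_", rr$birth_year)[keep],
    foster_nest = paste0(rr$rearing_territory, "_", rr$birth_year)[keep]
  )
}

#' Per-individual mean wealth, optionally adjusted for year effects
#'
#' Averages each breeder's wealth over its records. With
#' `adjust_year = TRUE` (the default) each record is first centred on its
#' year's mean across breeders, removing shared annual shifts -- the
#' analogue of the year term that the association and animal models carry.
#' Without the adjustment, relatives that breed in the same years look
#' similar through the shared year effect alone, which would leak cohort
#' variance into heritability estimates.
#'
#' @param records Breeding records (`individual_id`, `year`, `wealth`).
#' @param adjust_year Remove per-year means first?
#' @return A tibble `individual_id`, `wealth`, `n_records`.
#' @export
individual_mean_wealth <- function(records, adjust_year = TRUE) {
  check_columns(records, c("individual_id", "year", "wealth"), "records")
  w <- if (adjust_year) {
    records$wealth - stats::ave(records$wealth, records$year)
  } else {
    records$wealth
  }
  tibble::tibble(individual_id = records$individual_id, w = w) |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(wealth = mean(.data$w), n_records = dplyr::n(),
                     .groups = "drop")
}

#' Pedigree table of a simulation
#'
#' @param sim A `wealth_sim` object.
#' @return Tibble with `id`, `sire`, `dam` (plus foster fields, sex, birth
#'   year, natal territory), suitable for [compute_A_matrix()].
#' @export
sim_pedigree <- function(sim) {
  ind <- sim$individuals
  tibble::tibble(
    id = ind$id, sire = ind$sire_id, dam = ind$dam_id,
    foster_sire = ind$foster_sire_id, foster_dam = ind$foster_dam_id,
    sex = ind$sex, birth_year = ind$birth_year,
    natal_territory = ind$natal_territory_id
  )
}
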