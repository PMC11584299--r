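#' Fixed-CO2 counterfactual drivers
#'
#' Replaces the CO2 column by a constant — by default the first week's value,
#' the concentration at the start of the study period — leaving every other
#' column untouched. Idempotent.
#'
#' @param drivers Driver tibble.
#' @param value Constant CO2 in ppm, or `"first-week"` (default) to read it
#'   from the table.
#' @return Transformed driver tibble.
#' @export
#' @examples
#' drv <- generate_drivers(site_config(n_years = 2, seed = 1))
#' unique(fixed_co2_drivers(drv)$co2_ppm)
fixed_co2_drivers <- function(drivers, value = "first-week") {
  if (nrow(drivers) == 0) stop("drivers must be non-empty")
  if (identical(value, "first-week")) value <- drivers$co2_ppm[1]
  if (!is.numeric(value) || value <= 0) stop("CO2 value must be > 0")
  dplyr::mutate(drivers, co2_ppm = value)
}

#' Fixed-climate (weekly climatology) counterfactual drivers
#'
#' Removes interannual variation in every meteorological driver except
#' atmospheric CO2 by replacing each week-of-year value with its mean across
#' the years present (mean of week 1 over all years, week 2, and so on).
#' Idempotent; requires complete years.
#'
#' @param drivers Driver tibble.
#' @return Transformed driver tibble.
#' @export
fixed_climate_drivers <- function(drivers) {
  counts <- table(drivers$year)
  if (length(unique(counts)) != 1) {
    stop("ragged years: every year must contain the same number of weeks")
  }
  clim_cols <- c("tmin_C", "tmax_C", "swrad_MJm2d", "precip_mm", "daylength_h")
  drivers |>
    dplyr::group_by(week) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(clim_cols), mean)) |>
    dplyr::ungroup()
}

#' Re-simulate a posterior ensemble under (counterfactual) drivers
#'
#' Runs every ensemble member's parameter vector through the forward model
#' under the supplied driver table. Under the factual drivers this reproduces
#' each member's calibrated trajectory exactly.
#'
#' @param ensemble A `fen_ensemble` tibble of parameter vectors.
#' @param drivers Driver tibble (factual or transformed).
#' @param constants ACM coefficient set.
#' @param engine Forward engine; see [simulate_dalec()].
#' @return A `fen_trajectories` tibble: `member` plus the weekly columns of
#'   [simulate_dalec()] for every member.
#' @export
run_experiment <- function(ensemble, drivers, constants = acm_constants(),
                           engine = "cpp") {
  if (nrow(ensemble) == 0) stop("ensemble is empty")
  pn <- intersect(.param_names(), names(ensemble))
  out <- purrr::map_dfr(seq_len(nrow(ensemble)), function(i) {
    params <- unlist(ensemble[i, pn])
    sim <- simulate_dalec(params, drivers, engine = engine,
                          constants = constants)
    dplyr::bind_cols(tibble::tibble(member = ensemble$member[i],
                                    .rows = nrow(sim)), sim)
  })
  class(out) <- c("fen_trajectories", class(out))
  out
}

#' Decompose a CO2-driven GPP change into direct and LAI-mediated parts
#'
#' The direct fertilisation effect is isolated by driving the canopy
#' photosynthesis submodel alone with factual versus counterfactual CO2 while
#' holding each member's factual LAI trajectory fixed; the indirect effect
#' (through the change in leaf area) is the remainder, so the two components
#' sum to the total member-wise change exactly.
#'
#' @param ensemble A `fen_ensemble`.
#' @param factual_drivers,counterfactual_drivers Aligned driver tibbles.
#' @param constants ACM coefficient set.
#' @return Tibble `member`, `t`, `year`, `week`, `total`, `direct`,
#'   `indirect` — weekly GPP differences (factual minus counterfactual),
#'   gC m-2 d-1.
#' @export
decompose_co2_effect <- function(ensemble, factual_drivers,
                                 counterfactual_drivers,
                                 constants = acm_constants()) {
  if (nrow(factual_drivers) != nrow(counterfactual_drivers)) {
    stop("factual and counterfactual drivers are misaligned")
  }
  pn <- intersect(.param_names(), names(ensemble))
  purrr::map_dfr(seq_len(nrow(ensemble)), function(i) {
    params <- unlist(ensemble[i, pn])
    fact <- simulate_dalec(params, factual_drivers, constants = constants)
    cf <- simulate_dalec(params, counterfactual_drivers,
                         constants = constants)
    # LAI entering GPP at each step is the start-of-week foliage
    lai_in <- c(attr(fact, "init")[["c_fol"]],
                fact$c_fol[-nrow(fact)]) / params[["lma"]]
    g_fact <- acm_gpp(lai_in, factual_drivers, params[["c_eff"]], constants,
                      dl_coef = params[["dl_coef"]])
    g_cf_direct <- acm_gpp(lai_in, counterfactual_drivers, params[["c_eff"]],
                           constants, dl_coef = params[["dl_coef"]])
    total <- fact$gpp - cf$gpp
    direct <- g_fact - g_cf_direct
    tibble::tibble(member = ensemble$member[i], t = seq_len(nrow(fact)),
                   year = fact$year, week = fact$week,
                   total = total, direct = direct, indirect = total - direct)
  })
}

#' Change in annual summaries relative to a base year
#'
#' Subtracts the base-year value from every year, separately for the median
#' and both confidence bounds; the base year itself maps to zero.
#'
#' @param annual An annual-summary tibble from [annual_summary()].
#' @param base_year Reference year (must be present).
#' @return Tibble of the same shape with differenced `lower`, `median`,
#'   `upper`.
#' @export
relative_change <- function(annual, base_year) {
  if (!base_year %in% annual$year) {
    stop("base year ", base_year, " not present in the summary")
  }
  annual |>
    dplyr::group_by(variable) |>
    dplyr::mutate(
      lower = lower - lower[year == base_year],
      median = median - median[year == base_year],
      upper = upper - upper[year == base_year]
    ) |>
    dplyr::ungroup()
}
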