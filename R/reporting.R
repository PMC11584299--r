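flux_vars <- c("gpp", "ra", "npp", "rh", "reco", "nee")
state_vars <- c("lai", pool_names)

#' Annual ensemble summary at the standard quantiles
#'
#' Per member and year, flux rates are aggregated to annual totals
#' (gC m-2 yr-1, rate times the 7-day step summed over weeks) and states
#' (pools, LAI) to annual means; quantiles are then taken across members.
#' The 95% interval uses fractional quantiles 0.025, 0.5 and 0.975 with the
#' linear-interpolation (type 7) estimator so values are reproducible
#' bit-exactly.
#'
#' @param trajectories A `fen_trajectories` tibble from [run_experiment()]
#'   (must contain at least 2 members).
#' @param quantiles Lower, median, upper quantile fractions.
#' @param dt Step length in days used for flux totals.
#' @return Tibble `year`, `variable`, `lower`, `median`, `upper`.
#' @export
annual_summary <- function(trajectories, quantiles = c(0.025, 0.5, 0.975),
                           dt = 7) {
  if (nrow(trajectories) == 0) stop("empty ensemble trajectories")
  if (length(unique(trajectories$member)) < 2) {
    stop("annual_summary needs at least 2 ensemble members")
  }
  per_member <- trajectories |>
    dplyr::group_by(member, year) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(flux_vars), ~ sum(.x) * dt),
      dplyr::across(dplyr::all_of(state_vars), mean),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(dplyr::all_of(c(flux_vars, state_vars)),
                        names_to = "variable")
  per_member |>
    dplyr::group_by(year, variable) |>
    dplyr::summarise(
      lower = stats::quantile(value, quantiles[1], type = 7, names = FALSE),
      median = stats::quantile(value, quantiles[2], type = 7, names = FALSE),
      upper = stats::quantile(value, quantiles[3], type = 7, names = FALSE),
      .groups = "drop"
    )
}

#' Carbon use efficiency
#'
#' The NPP:GPP ratio. Vectorised; errors if any GPP is non-positive.
#'
#' @param annual_npp,annual_gpp Annual NPP and GPP, gC m-2 yr-1.
#' @return CUE fraction.
#' @export
#' @examples
#' cue(286.5, 543.9)
cue <- function(annual_npp, annual_gpp) {
  if (any(annual_gpp <= 0)) stop("CUE undefined: annual GPP must be > 0")
  annual_npp / annual_gpp
}

#' Mean residence time of a carbon pool
#'
#' Stock divided by outflux. Zero or negative outflux gives `NA` (missing,
#' not infinite) with a warning.
#'
#' @param mean_stock Mean stock, gC m-2.
#' @param mean_outflux Mean outflux, gC m-2 yr-1.
#' @return Residence time in years.
#' @export
residence_time <- function(mean_stock, mean_outflux) {
  out <- ifelse(mean_outflux > 0, mean_stock / mean_outflux, NA_real_)
  if (any(is.na(out))) {
    warning("zero outflux: residence time reported as missing")
  }
  out
}

#' Per-member residence times of the carbon pools
#'
#' For each ensemble member, the mean stock of each pool divided by its mean
#' annual outflux, summarised across members at the standard quantiles.
#'
#' @param trajectories A `fen_trajectories` tibble.
#' @param quantiles Quantile fractions for the summary.
#' @param dt Step length, days.
#' @return Tibble `pool`, `lower`, `median`, `upper` (years).
#' @export
residence_times <- function(trajectories, quantiles = c(0.025, 0.5, 0.975),
                            dt = 7) {
  outflux <- list(
    c_lab = "labile_release", c_fol = "leaf_fall", c_root = "root_mort",
    c_wood = "wood_mort", c_lit = c("rh_lit", "dec_lit2som"),
    c_som = "rh_som"
  )
  per <- trajectories |>
    dplyr::group_by(member) |>
    dplyr::group_modify(function(df, key) {
      n_years <- nrow(df) * dt / 365
      tibble::tibble(
        pool = names(outflux),
        rt = vapply(names(outflux), function(p) {
          stock <- mean(df[[p]])
          out <- sum(rowSums(as.matrix(df[outflux[[p]]])) * dt) / n_years
          if (out > 0) stock / out else NA_real_
        }, numeric(1))
      )
    }) |>
    dplyr::ungroup()
  per |>
    dplyr::group_by(pool) |>
    dplyr::summarise(
      lower = stats::quantile(rt, quantiles[1], na.rm = TRUE, names = FALSE),
      median = stats::quantile(rt, quantiles[2], na.rm = TRUE, names = FALSE),
      upper = stats::quantile(rt, quantiles[3], na.rm = TRUE, names = FALSE),
      .groups = "drop"
    )
}

#' NPP allocation fractions per ensemble member
#'
#' The fractions of NPP destined for foliage (direct allocation plus the
#' labile route), the structural pool and fine roots. The three fractions
#' partition NPP and sum to one exactly.
#'
#' @param trajectories A `fen_trajectories` tibble.
#' @return Tibble `member`, `foliage`, `wood`, `root`.
#' @export
allocation_fractions <- function(trajectories) {
  out <- trajectories |>
    dplyr::group_by(member) |>
    dplyr::summarise(
      npp_tot = sum(npp),
      foliage = (sum(alloc_fol) + sum(alloc_lab)) / npp_tot,
      wood = sum(alloc_wood) / npp_tot,
      root = sum(alloc_root) / npp_tot,
      .groups = "drop"
    )
  if (any(out$npp_tot <= 0)) {
    stop("allocation fractions undefined: a member has zero total NPP")
  }
  dplyr::select(out, member, foliage, wood, root)
}

#' Ordinary least-squares fit of y on x
#'
#' Simple linear regression with the standard adjusted R-squared, slope
#' t-test p-value and residual standard error.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return One-row tibble: `slope`, `intercept`, `adj_r_squared`, `p_value`,
#'   `sigma`, `df_residual`, `n`.
#' @export
#' @examples
#' linear_fit(1:10, 2 * (1:10))
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 points (adjusted R2 undefined below)")
  if (stats::sd(x) == 0) stop("singular design: x is constant")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    adj_r_squared = sm$adj.r.squared,
    p_value = unname(sm$coefficients[2, 4]),
    sigma = sm$sigma,
    df_residual = unname(sm$df[2]),
    n = length(x)
  )
}

#' Carbon-budget bookkeeping table
#'
#' Median (with 95% interval) annual fluxes and mean stocks across the
#' ensemble, in the units the field reports: gC m-2 yr-1 for fluxes and
#' gC m-2 for stocks, plus carbon use efficiency computed per member and then
#' summarised.
#'
#' @param trajectories A `fen_trajectories` tibble.
#' @param dt Step length, days.
#' @return Tibble `quantity`, `unit`, `lower`, `median`, `upper`.
#' @export
budget_table <- function(trajectories, dt = 7) {
  n_years <- length(unique(trajectories$year))
  per <- trajectories |>
    dplyr::group_by(member) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(c(flux_vars, "alloc_fol", "alloc_lab",
                                    "alloc_root", "alloc_wood")),
                    ~ sum(.x) * dt / n_years),
      dplyr::across(dplyr::all_of(state_vars), mean),
      .groups = "drop"
    ) |>
    dplyr::mutate(cue = npp / gpp)
  q <- function(v) stats::quantile(v, c(0.025, 0.5, 0.975), type = 7,
                                   names = FALSE)
  vars <- setdiff(names(per), "member")
  purrr::map_dfr(vars, function(v) {
    qs <- q(per[[v]])
    unit <- if (v %in% state_vars) {
      if (v == "lai") "m2 m-2" else "gC m-2"
    } else if (v == "cue") "fraction" else "gC m-2 yr-1"
    tibble::tibble(quantity = v, unit = unit, lower = qs[1], median = qs[2],
                   upper = qs[3])
  })
}
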