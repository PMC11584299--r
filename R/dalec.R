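#' Exponential temperature rate modifier
#'
#' Dimensionless multiplier \eqn{\exp(\theta \bar{T})} applied to the base
#' mineralisation/decomposition rates.
#'
#' @param theta Temperature sensitivity, per degree C.
#' @param t_mean Mean air temperature of the step, degrees C.
#' @return Strictly positive factor; 1 at `t_mean = 0` or `theta = 0`.
#' @export
temperature_rate_modifier <- function(theta, t_mean) {
  if (any(!is.finite(theta)) || any(!is.finite(t_mean))) {
    stop("theta and t_mean must be finite")
  }
  exp(theta * t_mean)
}

#' Daily phenology weights (wrapped Gaussian day-of-year bell)
#'
#' A circular Gaussian bell over the 365-day year, normalised to sum to one.
#' Weights drive labile release (leaf-out) and leaf fall; their weekly sums
#' feed [release_fraction()] so the configured annual completeness is exact.
#'
#' @param d_center Day-of-year centre of the bell, in `[1, n_days]`.
#' @param width Standard deviation of the bell, days (> 0).
#' @param n_days Days in the phenological year (365).
#' @return Numeric vector of `n_days` non-negative weights summing to 1.
#' @export
phenology_weights <- function(d_center, width, n_days = 365) {
  if (!is.finite(width) || width <= 0) stop("width must be > 0")
  if (!is.finite(d_center) || d_center < 1 || d_center > n_days) {
    stop("d_center must lie in [1, n_days]")
  }
  d <- seq_len(n_days)
  w <- rep(0, n_days)
  for (k in -2:2) {
    w <- w + exp(-0.5 * ((d - d_center + k * n_days) / width)^2)
  }
  w / sum(w)
}

#' Per-step pool release fraction from annual completeness
#'
#' Converts an annual release completeness `F` and the phenology weight mass
#' falling in the step into the survival-consistent per-step fraction
#' \eqn{1 - (1 - F)^{w}}. With no inflows the product of survival fractions
#' over a full year is exactly `1 - F`.
#'
#' @param completeness Annual fraction released, in `[0, 1)`.
#' @param weight_sum_over_step Phenology weight mass in the step, in `[0, 1]`.
#' @return Fraction of the pool released this step.
#' @export
release_fraction <- function(completeness, weight_sum_over_step) {
  if (any(completeness < 0) || any(completeness >= 1)) {
    stop("completeness must lie in [0, 1); cap it below 1")
  }
  if (any(weight_sum_over_step < 0) || any(weight_sum_over_step > 1)) {
    stop("weight_sum_over_step must lie in [0, 1]")
  }
  1 - (1 - completeness)^weight_sum_over_step
}

#' Leaf area index from foliage carbon
#' @param c_fol Foliage carbon, gC m-2.
#' @param lma Leaf mass per area, gC m-2 (> 0).
#' @return LAI in m2 m-2.
#' @export
lai_from_foliage <- function(c_fol, lma) {
  if (any(!is.finite(lma)) || any(lma <= 0)) stop("lma must be > 0")
  c_fol / lma
}

# Days of year covered by each model week: 52 weeks of 7 days, week 52
# absorbing days 358-365 so the weeks partition the 365-day phenology grid.
week_days <- function(w) {
  if (w < 52) ((w - 1L) * 7L + 1L):(w * 7L) else 358:365
}

# Weekly sums of daily phenology weights; length-52 vector.
phenology_week_sums <- function(d_center, width, n_days = 365) {
  wts <- phenology_weights(d_center, width, n_days)
  vapply(1:52, function(w) sum(wts[week_days(w)]), numeric(1))
}

wrap_doy <- function(d, n_days = 365) ((d - 1) %% n_days) + 1

flux_names <- c("gpp", "ra", "npp", "alloc_lab", "alloc_fol", "alloc_root",
                "alloc_wood", "labile_release", "leaf_fall", "root_mort",
                "wood_mort", "dec_lit2som", "rh_lit", "rh_som", "rh",
                "reco", "nee", "nbe")

pool_names <- c("c_lab", "c_fol", "c_root", "c_wood", "c_lit", "c_som")

# One mass-balance update. pools: named vector; wsum_on/wsum_fall: phenology
# weight mass in this step; returns list(pools, fluxes (per-day rates),
# clamped). Kept free of tibble overhead: step() and the R simulation engine
# both call it.
.step_core <- function(pools, params, met, dt, wsum_on, wsum_fall,
                       constants, dl_coef) {
  p <- params
  t_mean <- (met$tmin_C + met$tmax_C) / 2
  f_t <- exp(p[["theta"]] * t_mean)
  f_t_lit <- exp(p[["theta_lit"]] * t_mean)

  lai0 <- pools[["c_fol"]] / p[["lma"]]
  gpp <- acm_gpp(lai0, met, p[["c_eff"]], constants, dl_coef = dl_coef)
  ra <- p[["f_auto"]] * gpp
  npp <- gpp - ra

  a_lab <- p[["f_lab"]] * npp * dt
  a_fol <- p[["f_fol"]] * npp * dt
  a_root <- p[["f_root"]] * npp * dt
  a_wood <- (1 - p[["f_fol"]] - p[["f_lab"]] - p[["f_root"]]) * npp * dt

  release <- release_fraction(p[["big_f_onset"]], wsum_on) * pools[["c_lab"]]
  fall <- release_fraction(p[["big_f_fall"]], wsum_fall) * pools[["c_fol"]]

  root_mort <- min(1, p[["t_root"]] * dt) * pools[["c_root"]]
  wood_mort <- min(1, p[["t_wood"]] * dt) * pools[["c_wood"]]
  wood2som <- p[["f_wood2som"]] * wood_mort
  wood2lit <- wood_mort - wood2som

  fr_rh <- p[["r_lit"]] * f_t_lit * dt
  fr_dec <- p[["d_lit2som"]] * f_t_lit * dt
  tot <- fr_rh + fr_dec
  if (tot > 1) {
    fr_rh <- fr_rh / tot
    fr_dec <- fr_dec / tot
  }
  rh_lit <- fr_rh * pools[["c_lit"]]
  dec <- fr_dec * pools[["c_lit"]]
  rh_som <- min(1, p[["r_som"]] * f_t * dt) * pools[["c_som"]]

  new <- c(
    c_lab = pools[["c_lab"]] + a_lab - release,
    c_fol = pools[["c_fol"]] + a_fol + release - fall,
    c_root = pools[["c_root"]] + a_root - root_mort,
    c_wood = pools[["c_wood"]] + a_wood - wood_mort,
    c_lit = pools[["c_lit"]] + fall + root_mort + wood2lit - rh_lit - dec,
    c_som = pools[["c_som"]] + dec + wood2som - rh_som
  )
  clamped <- any(new < 0)
  if (clamped) new[new < 0] <- 0

  rh <- (rh_lit + rh_som) / dt
  fluxes <- c(gpp = gpp, ra = ra, npp = npp,
              alloc_lab = a_lab / dt, alloc_fol = a_fol / dt,
              alloc_root = a_root / dt, alloc_wood = a_wood / dt,
              labile_release = release / dt, leaf_fall = fall / dt,
              root_mort = root_mort / dt, wood_mort = wood_mort / dt,
              dec_lit2som = dec / dt, rh_lit = rh_lit / dt,
              rh_som = rh_som / dt, rh = rh, reco = ra + rh,
              nee = ra + rh - gpp, nbe = ra + rh - gpp)
  list(pools = new, fluxes = fluxes, clamped = clamped)
}

#' Advance the carbon pools by one weekly step
#'
#' Photosynthesis enters through the aggregated canopy model with
#' `lai = c_fol / lma`; autotrophic respiration is a fixed fraction of GPP and
#' the NPP remainder is allocated by fixed fractions (structural pool takes the
#' residual). Labile-to-foliage release and foliage-to-litter fall follow the
#' day-of-year phenology; root mortality feeds litter, structural mortality is
#' split between SOM and litter; litter mineralisation, litter-to-SOM
#' decomposition and SOM mineralisation scale with the exponential temperature
#' modifier of the weekly mean of `(tmin + tmax) / 2`. Per-step pool losses use
#' the discrete fraction `min(1, rate * f_T * dt)`, so pools cannot go
#' negative beyond round-off (they are clamped and flagged if they do).
#'
#' @param pools Named vector `c_lab, c_fol, c_root, c_wood, c_lit, c_som`
#'   (gC m-2, all >= 0).
#' @param params Named parameter vector; see [param_registry()].
#' @param met One-row data frame of weekly drivers with columns `week`, `doy`,
#'   `tmin_C`, `tmax_C`, `swrad_MJm2d`, `co2_ppm`, `daylength_h`.
#' @param dt Step length, days (default 7).
#' @param constants ACM coefficient set.
#' @return List with `pools` (end-of-step, named vector), `fluxes` (named
#'   vector of per-day rates, gC m-2 d-1) and `clamped` (logical).
#' @export
dalec_step <- function(pools, params, met, dt = 7,
                       constants = acm_constants()) {
  validate_params(params)
  if (any(pools < 0) || any(!is.finite(pools))) {
    stop("pools must be finite and >= 0")
  }
  w <- met$week
  on_center <- wrap_doy(params[["d_onset"]] + params[["lab_lag"]])
  wsum_on <- sum(phenology_weights(on_center, params[["r_onset"]])[week_days(w)])
  wsum_fall <- sum(phenology_weights(params[["d_fall"]],
                                     params[["r_fall"]])[week_days(w)])
  .step_core(pools[pool_names], params, met, dt, wsum_on, wsum_fall,
             constants, params[["dl_coef"]])
}

check_contiguous <- function(drivers) {
  w <- drivers$week
  y <- drivers$year
  if (nrow(drivers) > 1) {
    dw <- diff(w)
    dy <- diff(y)
    ok <- (dw == 1 & dy == 0) | (dw == -51 & dy == 1 & w[-length(w)] == 52)
    if (any(!ok)) {
      i <- which(!ok)[1]
      stop(sprintf("drivers are not contiguous: gap after year %d week %d",
                   y[i], w[i]))
    }
  }
  invisible(drivers)
}

#' Run the six-pool model over a weekly driver record
#'
#' Iterates [dalec_step()] over the driver table. Deterministic given
#' `(params, drivers, init)`. The compiled engine (`"cpp"`, default) and the
#' reference R engine (`"r"`) implement the identical update and agree to
#' near machine precision.
#'
#' @param params Named parameter vector (28 calibrated quantities).
#' @param drivers Driver tibble with columns `year`, `week`, `doy`, `tmin_C`,
#'   `tmax_C`, `swrad_MJm2d`, `precip_mm`, `co2_ppm`, `daylength_h`;
#'   contiguous weeks.
#' @param init Optional named initial pool vector; defaults to the initial
#'   pools carried in `params`.
#' @param engine `"cpp"` or `"r"`.
#' @param constants ACM coefficient set.
#' @param dt Step length in days (default 7).
#' @return A `fen_sim` tibble with one row per week: `year`, `week`, `doy`,
#'   end-of-week pools, `lai` (= `c_fol / lma`), and per-day flux rates.
#'   Attributes: `init`, `params`, `clamped`, `dt`.
#' @export
#' @examples
#' drv <- generate_drivers(site_config(n_years = 1, seed = 1))
#' sim <- simulate_dalec(default_truth_params(), drv)
#' dplyr::summarise(sim, annual_gpp = sum(gpp * 7))
simulate_dalec <- function(params, drivers, init = NULL,
                           engine = c("cpp", "r"),
                           constants = acm_constants(), dt = 7) {
  engine <- match.arg(engine)
  validate_params(params)
  if (nrow(drivers) == 0) stop("drivers must be non-empty")
  check_contiguous(drivers)
  if (is.null(init)) init <- initial_pools(params)
  init <- init[pool_names]
  if (any(init < 0) || any(!is.finite(init))) {
    stop("initial pools must be finite and >= 0")
  }

  if (engine == "cpp") {
    dmat <- cbind(week = drivers$week, tmin = drivers$tmin_C,
                  tmax = drivers$tmax_C, swrad = drivers$swrad_MJm2d,
                  co2 = drivers$co2_ppm, dayl = drivers$daylength_h)
    cvec <- unlist(constants[c(paste0("e", 1:10), "psi_d", "r_tot")])
    out <- dalec_run_cpp(unname(params[.param_names()]), dmat, unname(init),
                         cvec, dt)
    pools_m <- out$pools
    flux_m <- out$fluxes
    clamped <- out$clamped
  } else {
    on_center <- wrap_doy(params[["d_onset"]] + params[["lab_lag"]])
    wsum_on <- phenology_week_sums(on_center, params[["r_onset"]])
    wsum_fall <- phenology_week_sums(params[["d_fall"]], params[["r_fall"]])
    n <- nrow(drivers)
    pools_m <- matrix(NA_real_, n, 6)
    flux_m <- matrix(NA_real_, n, length(flux_names))
    pools <- init
    clamped <- FALSE
    for (i in seq_len(n)) {
      met <- list(tmin_C = drivers$tmin_C[i], tmax_C = drivers$tmax_C[i],
                  swrad_MJm2d = drivers$swrad_MJm2d[i],
                  co2_ppm = drivers$co2_ppm[i],
                  daylength_h = drivers$daylength_h[i])
      w <- drivers$week[i]
      st <- .step_core(pools, params, met, dt, wsum_on[w], wsum_fall[w],
                       constants, params[["dl_coef"]])
      pools <- st$pools
      pools_m[i, ] <- pools
      flux_m[i, ] <- st$fluxes
      clamped <- clamped || st$clamped
    }
  }
  colnames(pools_m) <- pool_names
  colnames(flux_m) <- flux_names
  res <- tibble::as_tibble(cbind(
    tibble::tibble(year = drivers$year, week = drivers$week,
                   doy = drivers$doy),
    tibble::as_tibble(pools_m),
    tibble::tibble(lai = pools_m[, "c_fol"] / params[["lma"]]),
    tibble::as_tibble(flux_m)
  ))
  attr(res, "init") <- init
  attr(res, "params") <- params
  attr(res, "clamped") <- clamped
  attr(res, "dt") <- dt
  class(res) <- c("fen_sim", class(res))
  res
}

#' Per-step carbon mass-balance residual
#'
#' For each week, the change in total carbon minus the net ecosystem input
#' `(gpp - ra - rh) * dt`. Conservation by construction implies residuals at
#' round-off level; this is the test instrument that proves it.
#'
#' @param result A `fen_sim` tibble from [simulate_dalec()].
#' @return Numeric vector of residuals, gC m-2 per step.
#' @export
mass_balance_residual <- function(result) {
  init <- attr(result, "init")
  dt <- attr(result, "dt") %||% 7
  tot <- rowSums(as.matrix(result[, pool_names]))
  prev <- c(sum(init), tot[-length(tot)])
  (tot - prev) - (result$gpp - result$ra - result$rh) * dt
}
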