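#' Site configuration for the synthetic driver generator
#'
#' Defaults emulate the study conditions of a sub-arctic rich fen: seven years
#' of weekly records starting in 2014 at 64.82 deg N, a 2014-2020 mean annual
#' air temperature of -0.95 deg C, strongly seasonal shortwave radiation,
#' log-normal weekly precipitation, and an atmospheric CO2 record that starts
#' at 400.584 ppm in the first week and trends upward so its multi-year mean
#' is ~432 ppm (a tower-measured record, higher than the marine background).
#'
#' @param latitude Degrees north.
#' @param n_years Number of simulated years.
#' @param start_year First calendar year.
#' @param mat Mean annual air temperature target, deg C.
#' @param temp_amplitude Seasonal half-amplitude of mean temperature, deg C.
#' @param temp_noise_sd Weekly white-noise SD on mean temperature, deg C.
#' @param diurnal_range Mean weekly (tmax - tmin), deg C.
#' @param range_noise_sd Weekly SD of the diurnal range, deg C.
#' @param sw_peak,sw_winter Midsummer and midwinter shortwave radiation,
#'   MJ m-2 d-1.
#' @param sw_noise_sd Lognormal noise SD (log scale) on radiation.
#' @param precip_meanlog,precip_sdlog Lognormal weekly precipitation (mm).
#' @param co2_start First-week CO2, ppm.
#' @param co2_mean_target Multi-year mean CO2 the linear trend is tuned to,
#'   ppm.
#' @param co2_seasonal_amp Seasonal CO2 half-amplitude, ppm.
#' @param co2_noise_sd Weekly CO2 noise SD, ppm.
#' @param seed Integer seed; all outputs are pure functions of the config.
#' @return A list of class `fen_site_config`.
#' @export
site_config <- function(latitude = 64.82, n_years = 7, start_year = 2014,
                        mat = -0.95, temp_amplitude = 19, temp_noise_sd = 2,
                        diurnal_range = 9, range_noise_sd = 1.5,
                        sw_peak = 21, sw_winter = 0.3, sw_noise_sd = 0.25,
                        precip_meanlog = log(6), precip_sdlog = 0.8,
                        co2_start = 400.584, co2_mean_target = 432,
                        co2_seasonal_amp = 4, co2_noise_sd = 0.5,
                        seed = 42) {
  stopifnot(n_years >= 1, co2_start > 0, abs(latitude) <= 90)
  structure(as.list(environment()), class = "fen_site_config")
}

#' Observation error model
#'
#' Stream uncertainties used both to corrupt synthetic truth and as the
#' default likelihood sigmas: NEE 0.58 gC m-2 d-1; ecosystem respiration
#' 1 gC m-2 d-1 (NEE uncertainty plus flux-partitioning mismatch, inflated);
#' LAI fractional uncertainty floored at 0.5 m2 m-2, available April-September
#' (model weeks 14-39) only; sparse stock uncertainties for SOC (5000),
#' fine-root (140.86) and aboveground (49.165) carbon, gC m-2.
#'
#' @param nee_sigma,reco_sigma Flux sigmas, gC m-2 d-1.
#' @param lai_frac Fractional LAI sigma before flooring.
#' @param lai_floor Minimum LAI sigma, m2 m-2.
#' @param lai_weeks Model weeks-of-year with LAI coverage.
#' @param soc_sigma,root_sigma,agb_sigma Stock sigmas, gC m-2.
#' @return A list of class `fen_error_model`.
#' @export
error_model <- function(nee_sigma = 0.58, reco_sigma = 1.0, lai_frac = 0.2,
                        lai_floor = 0.5, lai_weeks = 14:39,
                        soc_sigma = 5000, root_sigma = 140.86,
                        agb_sigma = 49.165) {
  stopifnot(nee_sigma > 0, reco_sigma > 0, lai_floor > 0,
            soc_sigma > 0, root_sigma > 0, agb_sigma > 0)
  structure(as.list(environment()), class = "fen_error_model")
}

#' Generate a weekly synthetic driver table
#'
#' Sinusoidal seasonal cycles with white noise for temperature and radiation,
#' log-normal weekly precipitation, astronomical day length from the site
#' latitude, and a CO2 series anchored exactly at `co2_start` in the first
#' week whose linear trend is set so the deterministic multi-year mean equals
#' `co2_mean_target`. Deterministic given `config$seed`.
#'
#' @param config A [site_config()].
#' @return Driver tibble with columns `year`, `week`, `doy`, `tmin_C`,
#'   `tmax_C`, `swrad_MJm2d`, `precip_mm`, `co2_ppm`, `daylength_h`
#'   (`n_years * 52` rows).
#' @export
#' @examples
#' drv <- generate_drivers(site_config(n_years = 2, seed = 7))
#' mean((drv$tmin_C + drv$tmax_C) / 2)
generate_drivers <- function(config = site_config()) {
  cf <- config
  n <- cf$n_years * 52L
  week <- rep(1:52, cf$n_years)
  year <- rep(as.integer(cf$start_year) + seq_len(cf$n_years) - 1L,
              each = 52L)
  doy <- ifelse(week < 52, (week - 1) * 7 + 4, 361.5)

  withr::with_seed(cf$seed, {
    tmean <- cf$mat + cf$temp_amplitude * cos(2 * pi * (doy - 197) / 365) +
      stats::rnorm(n, 0, cf$temp_noise_sd)
    rng <- pmax(2, cf$diurnal_range + stats::rnorm(n, 0, cf$range_noise_sd))
    sw_season <- cf$sw_winter + (cf$sw_peak - cf$sw_winter) *
      pmax(0, cos(2 * pi * (doy - 172) / 365))^1.3
    swrad <- sw_season * exp(stats::rnorm(n, 0, cf$sw_noise_sd))
    precip <- stats::rlnorm(n, cf$precip_meanlog, cf$precip_sdlog)
    seas <- cf$co2_seasonal_amp * cos(2 * pi * (doy - 130) / 365)
    seas <- seas - seas[1]
    slope <- 2 * (cf$co2_mean_target - cf$co2_start - mean(seas)) / (n - 1)
    noise <- stats::rnorm(n, 0, cf$co2_noise_sd)
    co2 <- cf$co2_start + slope * (seq_len(n) - 1) + seas + (noise - noise[1])
  })

  tibble::tibble(
    year = year, week = week, doy = doy,
    tmin_C = tmean - rng / 2, tmax_C = tmean + rng / 2,
    swrad_MJm2d = swrad, precip_mm = precip, co2_ppm = co2,
    daylength_h = day_length(cf$latitude, pmin(doy, 365))
  )
}

#' Simulate a truth trajectory for twin experiments
#'
#' Runs the forward model at a known parameter vector and attaches that vector
#' for later recovery scoring. Warns if the truth violates the ecological and
#' dynamical constraints, since recovery tests require a feasible truth.
#'
#' @param params Truth parameter vector; defaults to the documented
#'   [default_truth_params()].
#' @param drivers Driver tibble.
#' @param ... Passed to [simulate_dalec()].
#' @return A `fen_sim` tibble with attribute `truth_params`.
#' @export
generate_truth <- function(params = default_truth_params(), drivers, ...) {
  res <- simulate_dalec(params, drivers, ...)
  edc <- check_edcs(params, res)
  if (!edc$pass) {
    warning("truth parameters violate EDCs: ",
            paste(edc$violated, collapse = ", "))
  }
  attr(res, "truth_params") <- params
  res
}

#' Corrupt a truth trajectory into a synthetic observation set
#'
#' NEE, ecosystem respiration and LAI observations are the truth plus
#' independent Gaussian noise at the stream sigma; LAI is present only inside
#' the April-September availability window; stock observations are placed in
#' the first week (SOC and fine-root stocks constraining the initial pools,
#' and a single aboveground stock point, foliage plus structural carbon).
#' The assimilation mask flags alternating years for calibration, holding the
#' remaining years out for validation.
#'
#' @param truth A `fen_sim` from [generate_truth()].
#' @param errors An [error_model()].
#' @param seed Integer seed for the observation noise.
#' @param assimilate_years Calendar years whose observations are assimilated.
#' @param noise If `FALSE`, observations equal truth exactly where present.
#' @return A `fen_obs` object: list with tibbles `streams` (`t`, `year`,
#'   `week`, `stream`, `value`, `sigma`, `present`, `assimilate`) and `stocks`
#'   (`pool`, `t`, `value`, `sigma`), plus `n_weeks`.
#' @export
sample_observations <- function(truth, errors = error_model(), seed = 1,
                                assimilate_years = c(2014, 2016, 2018, 2020),
                                noise = TRUE) {
  n <- nrow(truth)
  init <- attr(truth, "init")
  lai_present <- truth$week %in% errors$lai_weeks
  lai_sigma <- pmax(errors$lai_floor, errors$lai_frac * truth$lai)
  assim <- assimilation_mask(truth, assimilate_years)

  withr::with_seed(seed, {
    nee_obs <- truth$nee + if (noise) stats::rnorm(n, 0, errors$nee_sigma) else 0
    reco_obs <- truth$reco + if (noise) stats::rnorm(n, 0, errors$reco_sigma) else 0
    lai_obs <- truth$lai + if (noise) stats::rnorm(n, 0, lai_sigma) else 0
    stock_noise <- if (noise) {
      stats::rnorm(3, 0, c(errors$soc_sigma, errors$root_sigma,
                           errors$agb_sigma))
    } else rep(0, 3)
  })

  streams <- dplyr::bind_rows(
    tibble::tibble(t = seq_len(n), year = truth$year, week = truth$week,
                   stream = "nee", value = nee_obs, sigma = errors$nee_sigma,
                   present = TRUE, assimilate = assim),
    tibble::tibble(t = seq_len(n), year = truth$year, week = truth$week,
                   stream = "reco", value = reco_obs,
                   sigma = errors$reco_sigma, present = TRUE,
                   assimilate = assim),
    tibble::tibble(t = seq_len(n), year = truth$year, week = truth$week,
                   stream = "lai", value = lai_obs, sigma = lai_sigma,
                   present = lai_present, assimilate = assim & lai_present)
  )
  stocks <- tibble::tibble(
    pool = c("c_som", "c_root", "agb"),
    t = 1L,
    value = c(init[["c_som"]], init[["c_root"]],
              init[["c_fol"]] + init[["c_wood"]]) + stock_noise,
    sigma = c(errors$soc_sigma, errors$root_sigma, errors$agb_sigma)
  )
  structure(list(streams = streams, stocks = stocks, n_weeks = n),
            class = "fen_obs")
}

#' Assimilation mask from calendar years
#'
#' @param weeks Data frame with a `year` column (one row per week).
#' @param assimilate_years Years whose weeks are assimilated; the rest are
#'   held out for validation.
#' @return Logical vector, `TRUE` where the week's year is in the list.
#' @export
assimilation_mask <- function(weeks, assimilate_years) {
  weeks$year %in% assimilate_years
}

#' @export
print.fen_obs <- function(x, ...) {
  cat("<fen_obs> ", x$n_weeks, " weeks; streams: ",
      paste(unique(x$streams$stream), collapse = ", "),
      "; stock points: ", nrow(x$stocks), "\n", sep = "")
  invisible(x)
}
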