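driver_cols <- c("year", "week", "doy", "tmin_C", "tmax_C", "swrad_MJm2d",
                 "precip_mm", "co2_ppm", "daylength_h")

# write doubles at 17 significant digits so every value round-trips bit-exactly
write_csv_exact <- function(df, path) {
  num <- vapply(df, function(v) is.double(v) && !inherits(v, "Date"),
                logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  readr::write_csv(df, path)
}

#' Write / read the weekly driver table
#'
#' CSV with header `year,week,doy,tmin_C,tmax_C,swrad_MJm2d,precip_mm,
#' co2_ppm,daylength_h`. Values round-trip bit-exactly.
#'
#' @param drivers Driver tibble.
#' @param path File path.
#' @return `write_driver_csv` returns `path` invisibly; `read_driver_csv`
#'   returns the driver tibble.
#' @export
write_driver_csv <- function(drivers, path) {
  stopifnot(all(driver_cols %in% names(drivers)))
  write_csv_exact(drivers[driver_cols], path)
  invisible(path)
}

#' @rdname write_driver_csv
#' @export
read_driver_csv <- function(path) {
  # base strtod parsing is correctly rounded, so values round-trip bit-exactly
  df <- utils::read.csv(path, colClasses = c(year = "integer",
                                             week = "integer"))
  tibble::as_tibble(df)
}

#' Write / read an observation set
#'
#' CSV with header `week_start,stream,value,sigma`; flux/LAI streams are
#' `nee`, `reco`, `lai` and sparse stocks are `stock:<pool>` rows. Only
#' present observations are written. Assimilation masks are not stored in the
#' file; they are derived from the year list on read.
#'
#' @param obs A `fen_obs`.
#' @param path File path.
#' @param assimilate_years Years flagged for assimilation on read.
#' @return `write_obs_csv` returns `path` invisibly; `read_obs_csv` a
#'   `fen_obs`.
#' @export
write_obs_csv <- function(obs, path) {
  s <- obs$streams[obs$streams$present, ]
  flux <- tibble::tibble(
    week_start = as.Date(paste0(s$year, "-01-01")) + (s$week - 1) * 7,
    stream = s$stream, value = s$value, sigma = s$sigma
  )
  years <- sort(unique(obs$streams$year))
  st_year <- years[ceiling(obs$stocks$t / 52)]
  st_week <- ((obs$stocks$t - 1) %% 52) + 1
  stocks <- tibble::tibble(
    week_start = as.Date(paste0(st_year, "-01-01")) + (st_week - 1) * 7,
    stream = paste0("stock:", obs$stocks$pool),
    value = obs$stocks$value, sigma = obs$stocks$sigma
  )
  write_csv_exact(dplyr::arrange(dplyr::bind_rows(flux, stocks), week_start,
                                 stream), path)
  invisible(path)
}

#' @rdname write_obs_csv
#' @export
read_obs_csv <- function(path, assimilate_years = c(2014, 2016, 2018, 2020)) {
  raw <- utils::read.csv(path, colClasses = c(week_start = "Date",
                                              stream = "character"))
  year <- as.integer(format(raw$week_start, "%Y"))
  yday <- as.integer(format(raw$week_start, "%j"))
  week <- pmin(52L, (yday - 1L) %/% 7L + 1L)
  y0 <- min(year)
  t <- (year - y0) * 52L + week
  is_stock <- startsWith(raw$stream, "stock:")
  yr <- year[!is_stock]
  streams <- tibble::tibble(
    t = t[!is_stock], year = yr, week = week[!is_stock],
    stream = raw$stream[!is_stock], value = raw$value[!is_stock],
    sigma = raw$sigma[!is_stock], present = TRUE,
    assimilate = yr %in% assimilate_years
  )
  stocks <- tibble::tibble(
    pool = sub("^stock:", "", raw$stream[is_stock]),
    t = t[is_stock], value = raw$value[is_stock], sigma = raw$sigma[is_stock]
  )
  structure(list(streams = streams, stocks = stocks,
                 n_weeks = (max(year) - y0 + 1L) * 52L),
            class = "fen_obs")
}

#' Write / read a posterior ensemble as a flat CSV of parameter vectors
#'
#' @param ensemble A `fen_ensemble` tibble.
#' @param path File path.
#' @return `write_ensemble_csv` returns `path` invisibly; `read_ensemble_csv`
#'   the ensemble tibble.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  write_csv_exact(ensemble, path)
  invisible(path)
}

#' @rdname write_ensemble_csv
#' @export
read_ensemble_csv <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, colClasses = c(
    member = "integer", chain = "integer", draw = "integer")))
  class(out) <- c("fen_ensemble", class(out))
  out
}

#' Write a simulated trajectory as tidy CSV
#'
#' @param result A `fen_sim` tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_sim_csv <- function(result, path) {
  write_csv_exact(tibble::as_tibble(result), path)
  invisible(path)
}
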