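#' Aggregated canopy model coefficients
#'
#' Loads the empirical coefficient set (`e1`..`e10`), the maximum soil-leaf
#' water potential difference `psi_d` (MPa) and the total plant-soil hydraulic
#' resistance `r_tot` for the aggregated canopy photosynthesis model. The
#' canonical published coefficient set ships with the package as a versioned
#' YAML file whose md5 checksum is recorded in the returned object, so a run
#' can be tied bit-exactly to the coefficient vintage it used.
#'
#' @param path Path to a YAML file mapping `e1`..`e10`, `psi_d`, `r_tot`.
#'   Defaults to the packaged set.
#' @return A named list of coefficients with attributes `version` and
#'   `checksum`.
#' @export
#' @examples
#' acm_constants()$e7
acm_constants <- function(path = system.file("extdata", "acm_constants.yaml",
                                             package = "fenfusion")) {
  raw <- yaml::read_yaml(path)
  need <- c(paste0("e", 1:10), "psi_d", "r_tot")
  missing <- setdiff(need, names(raw$coefficients))
  if (length(missing) > 0) {
    stop("ACM constants file lacks: ", paste(missing, collapse = ", "))
  }
  out <- lapply(raw$coefficients[need], as.numeric)
  if (!all(is.finite(unlist(out)))) stop("non-finite ACM coefficient")
  if (out$e7 <= 0 || out$e9 <= 0) stop("e7 and e9 must be positive")
  attr(out, "version") <- raw$version
  attr(out, "checksum") <- unname(tools::md5sum(path))
  out
}

#' Day length from solar geometry
#'
#' Standard sunrise-equation day length: solar declination
#' \eqn{\delta = -23.44 \cos(2\pi (d + 10)/365)} degrees and hour angle from
#' \eqn{\cos H_0 = (\sin(-0.833^\circ) - \sin\phi \sin\delta) /
#' (\cos\phi \cos\delta)} (sun centre 0.833 degrees below the horizon at
#' rise/set, accounting for refraction and the solar disc), clipped to polar
#' day/night.
#'
#' @param latitude Degrees north, in `[-90, 90]`.
#' @param doy Day of year, in `[1, 366]`. Vectorised.
#' @return Day length in hours, in `[0, 24]`.
#' @export
#' @examples
#' day_length(64.82, 172) # midsummer at the fen, ~21.8 h
day_length <- function(latitude, doy) {
  if (!all(is.finite(latitude)) || any(abs(latitude) > 90)) {
    stop("latitude must be finite and within [-90, 90]")
  }
  if (!all(is.finite(doy)) || any(doy < 1 | doy > 366)) {
    stop("doy must be within [1, 366]")
  }
  phi <- latitude * pi / 180
  decl <- -23.44 * pi / 180 * cos(2 * pi * (doy + 10) / 365)
  cos_h0 <- (sin(-0.833 * pi / 180) - sin(phi) * sin(decl)) /
    (cos(phi) * cos(decl))
  cos_h0 <- pmin(1, pmax(-1, cos_h0))
  24 * acos(cos_h0) / pi
}

#' Internal CO2 concentration of the canopy model
#'
#' Solves the canopy-scale CO2 drawdown quadratic
#' \eqn{c_i = \tfrac12\left(c_a + q - p + \sqrt{(c_a + q - p)^2
#' - 4(c_a q - p\,e_3)}\right)} where \eqn{q = e_3 - e_4} and \eqn{p}
#' aggregates assimilation capacity over conductance. As \eqn{p \to 0}
#' (no assimilation) \eqn{c_i \to c_a} and the drawdown vanishes.
#'
#' @param ca Atmospheric CO2, ppm (> 0). Vectorised.
#' @param pp Capacity/conductance aggregate (dimensionless in ppm units).
#' @param qq `e3 - e4`.
#' @param e3 Coefficient `e3` of the constants set.
#' @return Internal CO2, ppm; strictly below `ca` whenever `pp > 0`.
#' @export
internal_co2 <- function(ca, pp, qq, e3) {
  if (any(ca <= 0)) stop("ca must be > 0")
  b <- ca + qq - pp
  disc <- b^2 - 4 * (ca * qq - pp * e3)
  if (any(disc < 0)) {
    stop(sprintf(
      "negative discriminant in internal CO2 quadratic (ca=%g, pp=%g, qq=%g, e3=%g)",
      ca[which(disc < 0)[1]], pp[which(disc < 0)[1]][1], qq[1], e3[1]))
  }
  0.5 * (b + sqrt(disc))
}

#' Canopy gross primary productivity
#'
#' Daily GPP (gC m-2 d-1) from leaf area, weekly meteorology and the canopy
#' efficiency scalar, following the aggregated canopy model: hydraulically
#' limited canopy conductance \eqn{g_c = |\psi_d|^{e_{10}} / (e_6 r_{tot} +
#' 0.5\,(T_{max}-T_{min}))}, capacity term
#' \eqn{p = L\,c_{eff}\,e_1 e^{e_8 T_{max}} / g_c}, CO2 drawdown via
#' [internal_co2()], light response \eqn{e_0 = e_7 L^2/(L^2 + e_9)}, the
#' co-limited rate \eqn{e_0 I g_c (c_a - c_i) / (e_0 I + g_c (c_a - c_i))}
#' and the day-length correction \eqn{(e_2 D + e_5)}.
#'
#' @param lai Leaf area index, m2 m-2 (>= 0). Vectorised with `met`.
#' @param met Data frame (or one-row slice) of weekly drivers with columns
#'   `tmin_C`, `tmax_C`, `swrad_MJm2d`, `co2_ppm`, `daylength_h`.
#' @param c_eff Canopy photosynthetic efficiency scalar (foliar nitrogen is
#'   folded into this calibrated quantity).
#' @param constants ACM coefficient set; see [acm_constants()].
#' @param dl_coef Optional calibrated day-length coefficient overriding `e2`.
#' @return GPP in gC m-2 d-1, non-negative; 0 when `lai = 0` or radiation is 0.
#' @export
#' @examples
#' met <- tibble::tibble(tmin_C = 8, tmax_C = 18, swrad_MJm2d = 18,
#'                       co2_ppm = 410, daylength_h = 20)
#' acm_gpp(2.5, met, c_eff = 1.1)
acm_gpp <- function(lai, met, c_eff, constants = acm_constants(),
                    dl_coef = NULL) {
  if (any(!is.finite(lai)) || any(lai < 0)) stop("lai must be finite and >= 0")
  cn <- constants
  e2 <- if (is.null(dl_coef)) cn$e2 else dl_coef
  trange <- met$tmax_C - met$tmin_C
  if (any(trange < 0)) stop("tmax_C must be >= tmin_C")
  gc <- abs(cn$psi_d)^cn$e10 / (cn$e6 * cn$r_tot + 0.5 * trange)
  pp <- lai * c_eff * cn$e1 * exp(cn$e8 * met$tmax_C) / gc
  qq <- cn$e3 - cn$e4
  ci <- internal_co2(met$co2_ppm, pp, qq, cn$e3)
  e0 <- cn$e7 * lai^2 / (lai^2 + cn$e9)
  draw <- gc * (met$co2_ppm - ci)
  denom <- e0 * met$swrad_MJm2d + draw
  core <- ifelse(denom > 0, e0 * met$swrad_MJm2d * draw / denom, 0)
  gpp <- core * (e2 * met$daylength_h + cn$e5)
  # exact zeros at the degenerate limits (no leaves, no light, no capacity)
  gpp[lai <= 0 | met$swrad_MJm2d <= 0 | c_eff <= 0] <- 0
  pmax(0, gpp)
}
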