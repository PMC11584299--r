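#' Registry of the calibrated quantities
#'
#' The model is calibrated over 28 free quantities: 18 process parameters
#' governing allocation, phenology, turnover and canopy efficiency; 6 initial
#' carbon pools; and 4 auxiliary quantities (a separate litter temperature
#' sensitivity, the day-length scaling coefficient of the canopy model, a
#' labile release-to-growth lag, and the fraction of structural mortality
#' routed directly to soil organic matter). Each row carries the uniform prior
#' bounds, the sampling scale (linear or log-uniform) and a documented default
#' "truth" value used by the synthetic-data generator.
#'
#' The registry is data, not code: alternative identities or bounds can be
#' supplied to every downstream function that takes a `registry` argument.
#'
#' @return A tibble with columns `name`, `group` (`process`, `initial`,
#'   `auxiliary`), `lower`, `upper`, `scale` (`"linear"` or `"log"`), `truth`
#'   and `description`.
#' @export
#' @examples
#' param_registry()
param_registry <- function() {
  tibble::tribble(
    ~name,        ~group,      ~lower, ~upper, ~scale,   ~truth, ~description,
    "f_auto",     "process",    0.2,    0.8,   "linear",  0.47,  "fraction of GPP respired autotrophically",
    "f_fol",      "process",    0.01,   0.6,   "linear",  0.25,  "NPP fraction allocated directly to foliage",
    "f_lab",      "process",    0.01,   0.6,   "linear",  0.25,  "NPP fraction allocated to the labile pool",
    "f_root",     "process",    0.01,   0.6,   "linear",  0.20,  "NPP fraction allocated to fine roots",
    "d_onset",    "process",   60,    185,     "linear", 140,    "day-of-year centre of labile release (leaf-out)",
    "r_onset",    "process",    5,     60,     "linear",  21,    "width of the leaf-out release window (days)",
    "big_f_onset","process",    0.2,    0.999, "linear",   0.95, "annual completeness of labile release",
    "d_fall",     "process",  200,    330,     "linear", 265,    "day-of-year centre of leaf fall",
    "r_fall",     "process",    5,     60,     "linear",  28,    "width of the leaf-fall window (days)",
    "big_f_fall", "process",    0.2,    0.999, "linear",   0.95, "annual completeness of leaf fall",
    "t_root",     "process",    1e-4,   5e-3,  "log",      5.9e-4, "fine-root turnover rate (per day)",
    "t_wood",     "process",    2e-5,   4e-3,  "log",      4.5e-4, "structural (wood) turnover rate (per day)",
    "r_lit",      "process",    1e-4,   0.1,   "log",      5e-3, "litter mineralisation base rate (per day)",
    "d_lit2som",  "process",    1e-6,   1e-2,  "log",      2e-4, "litter-to-SOM decomposition base rate (per day)",
    "r_som",      "process",    1e-8,   1e-4,  "log",      2.5e-6, "SOM mineralisation base rate (per day)",
    "theta",      "process",    0.01,   0.15,  "linear",   0.08, "temperature sensitivity of SOM decomposition (per deg C)",
    "c_eff",      "process",    0.1,   20,     "log",      1.0,  "canopy photosynthetic efficiency scalar",
    "lma",        "process",   10,    150,     "log",     50,    "leaf mass per area (gC per m2)",
    "theta_lit",  "auxiliary",  0.01,   0.15,  "linear",   0.09, "temperature sensitivity of litter processes (per deg C)",
    "dl_coef",    "auxiliary",  0.005,  0.05,  "linear",   0.0142, "day-length coefficient of the canopy model",
    "lab_lag",    "auxiliary",  0,     21,     "linear",   5,    "lag from labile release centre to leaf-out (days)",
    "f_wood2som", "auxiliary",  0.5,    1,     "linear",   0.9,  "fraction of structural mortality routed to SOM",
    "c_lab0",     "initial",    5,    300,     "log",     70,    "initial labile carbon (gC per m2)",
    "c_fol0",     "initial",    0.5,   60,     "log",      2,    "initial foliage carbon (gC per m2)",
    "c_root0",    "initial",   50,    800,     "log",    247,    "initial fine-root carbon (gC per m2)",
    "c_wood0",    "initial",   50,    900,     "log",    280,    "initial structural carbon (gC per m2)",
    "c_lit0",     "initial",    5,   1000,     "log",    100,    "initial litter carbon (gC per m2)",
    "c_som0",     "initial", 40000, 90000,     "linear", 64055,  "initial soil organic carbon (gC per m2)"
  )
}

#' Canonical parameter order used by the simulation engines
#' @keywords internal
.param_names <- function() param_registry()$name

#' Default truth parameter vector for synthetic experiments
#'
#' The documented truth used by the synthetic-data generator. Values are
#' chosen to yield fluxes and stocks of the magnitude observed at a sub-arctic
#' rich fen: annual GPP of some hundreds of gC m-2 yr-1, carbon use efficiency
#' near 0.5, peak leaf area index near 2.5 m2 m-2, a soil organic carbon stock
#' of 64055 gC m-2, and NPP partitioned roughly 50/30/20 between foliage
#' (direct plus labile), structural and fine-root pools.
#'
#' @param registry Parameter registry tibble; see [param_registry()].
#' @return Named numeric vector of length 28.
#' @export
default_truth_params <- function(registry = param_registry()) {
  stats::setNames(registry$truth, registry$name)
}

#' Validate a parameter vector against the registry
#'
#' Checks completeness, finiteness, bounds, the allocation-sum constraint
#' (`f_fol + f_lab + f_root <= 1`) and positivity of rates and `lma`.
#'
#' @param params Named numeric vector of calibrated quantities.
#' @param registry Parameter registry tibble.
#' @param check_bounds If `TRUE`, also require every value inside its prior
#'   bounds.
#' @return `params`, invisibly, on success; errors otherwise.
#' @export
validate_params <- function(params, registry = param_registry(),
                            check_bounds = FALSE) {
  missing <- setdiff(registry$name, names(params))
  if (length(missing) > 0) {
    stop("parameter vector is missing: ", paste(missing, collapse = ", "))
  }
  x <- params[registry$name]
  if (any(!is.finite(x))) {
    stop("non-finite parameter value(s): ",
         paste(registry$name[!is.finite(x)], collapse = ", "))
  }
  fr <- x[c("f_auto", "f_fol", "f_lab", "f_root", "big_f_onset", "big_f_fall",
            "f_wood2som")]
  if (any(fr <= 0 | fr >= 1)) {
    stop("fraction parameters must lie strictly in (0, 1)")
  }
  if (x[["f_fol"]] + x[["f_lab"]] + x[["f_root"]] > 1) {
    stop("allocation fractions f_fol + f_lab + f_root exceed 1")
  }
  rates <- x[c("t_root", "t_wood", "r_lit", "d_lit2som", "r_som")]
  if (any(rates <= 0)) stop("turnover/mineralisation rates must be > 0")
  if (x[["lma"]] <= 0) stop("lma must be > 0")
  if (check_bounds && any(x < registry$lower | x > registry$upper)) {
    bad <- registry$name[x < registry$lower | x > registry$upper]
    stop("parameter(s) outside prior bounds: ", paste(bad, collapse = ", "))
  }
  invisible(params)
}

#' Initial pools from a parameter vector
#' @param params Named parameter vector.
#' @return Named numeric vector `c_lab, c_fol, c_root, c_wood, c_lit, c_som`.
#' @export
initial_pools <- function(params) {
  c(c_lab = unname(params[["c_lab0"]]), c_fol = unname(params[["c_fol0"]]),
    c_root = unname(params[["c_root0"]]), c_wood = unname(params[["c_wood0"]]),
    c_lit = unname(params[["c_lit0"]]), c_som = unname(params[["c_som0"]]))
}

# Map between natural parameter space and the unit hypercube in which the
# sampler operates. Log-scale rows map through log-space, so a uniform draw on
# the cube is log-uniform in the natural space.
params_to_unit <- function(params, registry = param_registry()) {
  x <- as.numeric(params[registry$name])
  lo <- ifelse(registry$scale == "log", log(registry$lower), registry$lower)
  hi <- ifelse(registry$scale == "log", log(registry$upper), registry$upper)
  v <- ifelse(registry$scale == "log", log(x), x)
  stats::setNames((v - lo) / (hi - lo), registry$name)
}

unit_to_params <- function(z, registry = param_registry()) {
  lo <- ifelse(registry$scale == "log", log(registry$lower), registry$lower)
  hi <- ifelse(registry$scale == "log", log(registry$upper), registry$upper)
  v <- lo + as.numeric(z) * (hi - lo)
  x <- ifelse(registry$scale == "log", exp(v), v)
  stats::setNames(x, registry$name)
}
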