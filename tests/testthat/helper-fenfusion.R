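# Shared fixtures: all generated in code, nothing read from disk.

# short driver records keep unit tests fast
drivers_1yr <- generate_drivers(site_config(n_years = 1, seed = 11))
drivers_2yr <- generate_drivers(site_config(n_years = 2, seed = 11))
drivers_7yr <- generate_drivers(site_config(seed = 11))

truth_params <- default_truth_params()

# jitter a feasible parameter vector into an EDC-feasible synthetic ensemble
jitter_ensemble <- function(params, drivers, n = 40, seed = 5, sd = 0.03) {
  reg <- param_registry()
  z0 <- fenfusion:::params_to_unit(params, reg)
  members <- list()
  withr::with_seed(seed, {
    while (length(members) < n) {
      z <- pmin(0.999, pmax(0.001, z0 + stats::rnorm(length(z0), 0, sd)))
      cand <- fenfusion:::unit_to_params(z, reg)
      if (cand[["f_fol"]] + cand[["f_lab"]] + cand[["f_root"]] > 1) next
      sim <- simulate_dalec(cand, drivers)
      if (check_edcs(cand, sim)$pass) members[[length(members) + 1]] <- cand
    }
  })
  out <- tibble::as_tibble(do.call(rbind, members))
  out <- tibble::add_column(out, member = seq_len(n), chain = 1L,
                            draw = seq_len(n), .before = 1)
  class(out) <- c("fen_ensemble", class(out))
  out
}

# a minimal fen_sim-shaped fixture for constraint/bookkeeping tests
fake_sim <- function(pools_start, pools_end, n = 2, clamped = FALSE) {
  pm <- matrix(rep(pools_end, each = n), n,
               dimnames = list(NULL, fenfusion:::pool_names))
  res <- tibble::as_tibble(pm)
  res <- dplyr::bind_cols(
    tibble::tibble(year = 2014L, week = seq_len(n), doy = (seq_len(n) - 1) * 7 + 4),
    res,
    tibble::tibble(lai = 0, gpp = 0, ra = 0, npp = 0, rh = 0, reco = 0,
                   nee = 0, nbe = 0)
  )
  attr(res, "init") <- stats::setNames(pools_start, fenfusion:::pool_names)
  attr(res, "clamped") <- clamped
  attr(res, "dt") <- 7
  class(res) <- c("fen_sim", class(res))
  res
}
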