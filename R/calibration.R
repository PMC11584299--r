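#' Observation log-likelihood with square-root normalisation
#'
#' Independent-Gaussian misfit per stream, \eqn{-\tfrac12 \sum ((m - o)/\sigma)^2},
#' over assimilated, present points. Model observables are: ecosystem
#' respiration `reco = ra + rh`, `nee = reco - gpp`, and `lai = c_fol / lma`;
#' stock observations are compared to the named pool at the start of the named
#' week (`"agb"` maps to foliage plus structural carbon). The stream sums are
#' each multiplied by `normalisation`; the default 0.5 implements the
#' square-root likelihood weighting that balances the dense flux streams
#' against the sparse field observations.
#'
#' @param result A `fen_sim` trajectory aligned with the observations.
#' @param obs A `fen_obs` observation set.
#' @param normalisation Per-stream multiplier on the Gaussian log-misfit.
#' @param agb_pools Pools summed to form the aboveground-stock observable.
#' @return Log-density (<= 0); 0 with a warning if no observation is used.
#' @export
log_likelihood <- function(result, obs, normalisation = 0.5,
                           agb_pools = c("c_fol", "c_wood")) {
  if (nrow(result) != obs$n_weeks) {
    stop("result has ", nrow(result), " weeks but observations have ",
         obs$n_weeks)
  }
  model <- list(nee = result$nee, reco = result$reco, lai = result$lai)
  s <- obs$streams[obs$streams$present & obs$streams$assimilate, ]
  total <- 0
  n_used <- 0L
  for (st in unique(s$stream)) {
    rows <- s[s$stream == st, ]
    m <- model[[st]][rows$t]
    total <- total + normalisation * (-0.5 * sum(((m - rows$value) / rows$sigma)^2))
    n_used <- n_used + nrow(rows)
  }
  if (nrow(obs$stocks) > 0) {
    init <- attr(result, "init")
    pm <- as.matrix(result[, pool_names])
    start_pool <- function(pool, t) {
      if (t == 1) {
        if (pool == "agb") sum(init[agb_pools]) else init[[pool]]
      } else {
        if (pool == "agb") sum(pm[t - 1, agb_pools]) else pm[t - 1, pool]
      }
    }
    m <- mapply(start_pool, obs$stocks$pool, obs$stocks$t)
    total <- total + normalisation *
      (-0.5 * sum(((m - obs$stocks$value) / obs$stocks$sigma)^2))
    n_used <- n_used + nrow(obs$stocks)
  }
  if (n_used == 0L) {
    warning("no present, assimilated observations; log-likelihood is 0")
    return(0)
  }
  total
}

#' Uniform / log-uniform prior log-density
#'
#' Box prior over the registry bounds: 0 (up to a constant) inside for linear
#' quantities, `-log(value)` for log-uniform quantities, `-Inf` outside.
#' The joint support also requires `f_fol + f_lab + f_root <= 1` when those
#' quantities are present.
#'
#' @param params Named parameter vector.
#' @param priors Registry tibble with `name`, `lower`, `upper`, `scale`.
#' @return Log-density.
#' @export
log_prior <- function(params, priors = param_registry()) {
  missing <- setdiff(priors$name, names(params))
  if (length(missing) > 0) {
    stop("no prior-covered value for: ", paste(missing, collapse = ", "))
  }
  x <- as.numeric(params[priors$name])
  if (any(x < priors$lower | x > priors$upper)) return(-Inf)
  al <- c("f_fol", "f_lab", "f_root")
  if (all(al %in% priors$name) && sum(params[al]) > 1) return(-Inf)
  -sum(log(x[priors$scale == "log"]))
}

#' Ecological and dynamical constraint configuration
#'
#' @param growth_factor_bound Quasi-steady-state bound: each pool may change
#'   by at most this factor (either direction) over the run.
#' @param f_auto_range Open interval for the autotrophic fraction.
#' @param enabled Constraint ids switched on.
#' @param pool_floor Floor (gC m-2) applied before the pool ratio to avoid
#'   log-of-zero on seasonally empty pools.
#' @return List of class `fen_edc_config`.
#' @export
edc_config <- function(growth_factor_bound = 10, f_auto_range = c(0.2, 0.8),
                       enabled = c("E1", "E2", "E3", "E4", "E5"),
                       pool_floor = 1e-3) {
  structure(as.list(environment()), class = "fen_edc_config")
}

#' Check ecological and dynamical constraints
#'
#' E1: SOM turns over more slowly than litter (`r_som < r_lit`).
#' E2: fine roots turn over faster than structural carbon (`t_root > t_wood`).
#' E3: quasi-steady state — no pool changes by more than the configured factor
#' over the run. E4: no negative-pool clamping occurred. E5: the autotrophic
#' fraction lies in its plausible interval. All violated ids are returned,
#' not just the first.
#'
#' @param params Named parameter vector.
#' @param result A `fen_sim` trajectory from those parameters.
#' @param config An [edc_config()].
#' @return List with `pass` (logical) and `violated` (character ids).
#' @export
check_edcs <- function(params, result, config = edc_config()) {
  v <- character(0)
  en <- config$enabled
  if ("E1" %in% en && params[["r_som"]] >= params[["r_lit"]]) v <- c(v, "E1")
  if ("E2" %in% en && params[["t_root"]] <= params[["t_wood"]]) v <- c(v, "E2")
  if ("E3" %in% en) {
    init <- pmax(attr(result, "init"), config$pool_floor)
    final <- pmax(as.numeric(result[nrow(result), pool_names]), config$pool_floor)
    if (any(abs(log(final / init)) > log(config$growth_factor_bound))) {
      v <- c(v, "E3")
    }
  }
  if ("E4" %in% en && isTRUE(attr(result, "clamped"))) v <- c(v, "E4")
  if ("E5" %in% en) {
    fa <- params[["f_auto"]]
    if (fa <= config$f_auto_range[1] || fa >= config$f_auto_range[2]) {
      v <- c(v, "E5")
    }
  }
  list(pass = length(v) == 0, violated = v)
}

#' Multivariate-normal proposal
#'
#' Draws `current + scale * L z` with `L` the lower Cholesky factor of
#' `covariance` and `z` standard normal. Falls back to independent
#' diagonal jitter (with a warning) if the covariance is not positive
#' semi-definite.
#'
#' @param current Numeric state vector.
#' @param covariance Proposal covariance matrix.
#' @param scale Scalar jump scale; 0 returns `current` unchanged.
#' @return Candidate vector; deterministic given the RNG state.
#' @export
propose <- function(current, covariance, scale = 1) {
  d <- length(current)
  z <- stats::rnorm(d)
  L <- tryCatch(t(chol(covariance)), error = function(e) NULL)
  if (is.null(L)) {
    warning("proposal covariance not positive definite; using diagonal jitter")
    sd <- sqrt(pmax(diag(covariance), 1e-12))
    return(current + scale * sd * z)
  }
  current + scale * as.vector(L %*% z)
}

#' MCMC configuration
#'
#' Adaptive-proposal Metropolis settings. The study-scale algorithm assesses
#' vastly more proposals per chain; the desk default of `1e5` runs the
#' identical algorithm at tractable cost.
#'
#' @param n_chains Number of independent chains (default 3).
#' @param n_proposals Proposals per chain.
#' @param burn_in Fraction of each chain discarded before summaries.
#' @param adapt_interval Proposals between covariance adaptations (burn-in
#'   phase only).
#' @param proposal_scale Initial jump scale; default `2.38^2 / d` enters
#'   through the adapted covariance, this is a multiplier on it.
#' @param per_chain Posterior subsamples drawn from each chain.
#' @param seed Master seed; per-chain seeds are derived from it.
#' @return List of class `fen_mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_proposals = 1e5, burn_in = 0.5,
                        adapt_interval = 1000, proposal_scale = 1,
                        per_chain = 100, seed = 1) {
  stopifnot(n_chains >= 1, n_proposals >= 10, burn_in > 0, burn_in < 1)
  structure(as.list(environment()), class = "fen_mcmc_config")
}

# Fast DALEC log-posterior closure over the unit cube. Precomputes driver and
# observation arrays once; each evaluation is one compiled forward run plus
# vectorised misfit sums and EDC checks. Used by run_mcmc().
make_dalec_logpost <- function(obs, drivers, priors, constants,
                               normalisation = 0.5,
                               edc = edc_config(), dt = 7) {
  dmat <- cbind(week = drivers$week, tmin = drivers$tmin_C,
                tmax = drivers$tmax_C, swrad = drivers$swrad_MJm2d,
                co2 = drivers$co2_ppm, dayl = drivers$daylength_h)
  cvec <- unlist(constants[c(paste0("e", 1:10), "psi_d", "r_tot")])
  lo <- ifelse(priors$scale == "log", log(priors$lower), priors$lower)
  hi <- ifelse(priors$scale == "log", log(priors$upper), priors$upper)
  logm <- priors$scale == "log"
  nm <- priors$name
  idx <- function(p) match(p, nm)
  i_ffol <- idx("f_fol"); i_flab <- idx("f_lab"); i_froot <- idx("f_root")
  i_rsom <- idx("r_som"); i_rlit <- idx("r_lit")
  i_troot <- idx("t_root"); i_twood <- idx("t_wood")
  i_fauto <- idx("f_auto"); i_lma <- idx("lma")
  i_init <- idx(c("c_lab0", "c_fol0", "c_root0", "c_wood0", "c_lit0", "c_som0"))

  s <- obs$streams[obs$streams$present & obs$streams$assimilate, ]
  sp <- split(s[c("t", "value", "sigma")], s$stream)
  st <- obs$stocks
  stock_pool_idx <- match(st$pool, pool_names) # NA for "agb"
  log_gfb <- log(edc$growth_factor_bound)
  en <- edc$enabled
  nwk <- nrow(dmat)

  function(z) {
    if (any(z < 0) || any(z > 1)) return(-Inf)
    v <- lo + z * (hi - lo)
    x <- v
    x[logm] <- exp(v[logm])
    if (x[i_ffol] + x[i_flab] + x[i_froot] > 1) return(-Inf)
    if ("E1" %in% en && x[i_rsom] >= x[i_rlit]) return(-Inf)
    if ("E2" %in% en && x[i_troot] <= x[i_twood]) return(-Inf)
    if ("E5" %in% en &&
        (x[i_fauto] <= edc$f_auto_range[1] ||
         x[i_fauto] >= edc$f_auto_range[2])) return(-Inf)
    out <- dalec_run_cpp(x, dmat, x[i_init], cvec, dt)
    if ("E4" %in% en && out$clamped) return(-Inf)
    pools <- out$pools
    if ("E3" %in% en) {
      ratio <- log(pmax(pools[nwk, ], edc$pool_floor) /
                   pmax(x[i_init], edc$pool_floor))
      if (any(abs(ratio) > log_gfb)) return(-Inf)
    }
    fl <- out$fluxes
    ll <- 0
    if (!is.null(sp$nee)) {
      ll <- ll - 0.5 * sum(((fl[sp$nee$t, 17] - sp$nee$value) / sp$nee$sigma)^2)
    }
    if (!is.null(sp$reco)) {
      ll <- ll - 0.5 * sum(((fl[sp$reco$t, 16] - sp$reco$value) / sp$reco$sigma)^2)
    }
    if (!is.null(sp$lai)) {
      lai <- pools[sp$lai$t, 2] / x[i_lma]
      ll <- ll - 0.5 * sum(((lai - sp$lai$value) / sp$lai$sigma)^2)
    }
    if (nrow(st) > 0) {
      for (k in seq_len(nrow(st))) {
        m <- if (st$t[k] == 1) {
          if (is.na(stock_pool_idx[k])) x[i_init[2]] + x[i_init[4]]
          else x[i_init[stock_pool_idx[k]]]
        } else {
          if (is.na(stock_pool_idx[k])) pools[st$t[k] - 1, 2] + pools[st$t[k] - 1, 4]
          else pools[st$t[k] - 1, stock_pool_idx[k]]
        }
        ll <- ll - 0.5 * ((m - st$value[k]) / st$sigma[k])^2
      }
    }
    normalisation * ll
  }
}

# Split-chain potential scale reduction factor, one value per parameter.
rhat_split <- function(chains) {
  halves <- list()
  for (ch in chains) {
    n <- nrow(ch)
    h <- floor(n / 2)
    halves <- c(halves, list(ch[1:h, , drop = FALSE]),
                list(ch[(n - h + 1):n, , drop = FALSE]))
  }
  m <- length(halves)
  n <- nrow(halves[[1]])
  vapply(seq_len(ncol(chains[[1]])), function(j) {
    means <- vapply(halves, function(h) mean(h[, j]), numeric(1))
    vars <- vapply(halves, function(h) stats::var(h[, j]), numeric(1))
    b <- n * stats::var(means)
    w <- mean(vars)
    if (w <= 0) return(1)
    sqrt(((n - 1) / n * w + b / n) / w)
  }, numeric(1))
}

#' Adaptive-proposal Metropolis calibration
#'
#' Samples the 28 calibrated quantities by Metropolis MCMC over the unit-cube
#' reparameterisation of the uniform/log-uniform priors. The proposal is
#' multivariate normal whose covariance adapts to the accumulated chain history
#' (scaled by `2.38^2 / d`) at a fixed interval during burn-in, with a
#' Robbins-Monro tweak of the global scale towards the 23.4% optimal
#' acceptance rate; adaptation freezes after burn-in. Candidates violating the
#' ecological and dynamical constraints receive `-Inf` posterior density.
#' Chains are independent, each seeded from the master seed, so reruns are
#' bitwise identical.
#'
#' @param obs A `fen_obs` observation set (ignored when `log_posterior` is
#'   supplied).
#' @param drivers Driver tibble (ignored when `log_posterior` is supplied).
#' @param priors Registry tibble with prior bounds and scales.
#' @param config An [mcmc_config()].
#' @param log_posterior Optional function of a named parameter vector
#'   returning a log-density, replacing the built-in likelihood and EDCs
#'   (used for toy-problem validation).
#' @param normalisation Likelihood normalisation factor; see
#'   [log_likelihood()].
#' @param edc An [edc_config()].
#' @param constants ACM coefficient set.
#' @return A `fen_mcmc` object: post-burn-in states per chain (natural
#'   parameter space), log-posteriors, acceptance rates, split-chain potential
#'   scale reduction factors, and the configuration. A warning is raised if
#'   any factor exceeds 1.2.
#' @export
run_mcmc <- function(obs = NULL, drivers = NULL, priors = param_registry(),
                     config = mcmc_config(), log_posterior = NULL,
                     normalisation = 0.5, edc = edc_config(),
                     constants = acm_constants()) {
  d <- nrow(priors)
  lo <- ifelse(priors$scale == "log", log(priors$lower), priors$lower)
  hi <- ifelse(priors$scale == "log", log(priors$upper), priors$upper)
  logm <- priors$scale == "log"
  to_x <- function(z) {
    v <- lo + z * (hi - lo)
    v[logm] <- exp(v[logm])
    v
  }
  if (is.null(log_posterior)) {
    if (is.null(obs) || is.null(drivers)) {
      stop("supply either (obs, drivers) or a log_posterior function")
    }
    lp_fun <- make_dalec_logpost(obs, drivers, priors, constants,
                                 normalisation, edc)
  } else {
    lp_fun <- function(z) {
      if (any(z < 0) || any(z > 1)) return(-Inf)
      log_posterior(stats::setNames(to_x(z), priors$name))
    }
  }

  n <- as.integer(config$n_proposals)
  n_burn <- as.integer(floor(config$burn_in * n))
  base_cov <- diag(0.01, d)
  chains <- vector("list", config$n_chains)
  lps <- vector("list", config$n_chains)
  acc_rates <- numeric(config$n_chains)

  for (k in seq_len(config$n_chains)) {
    set.seed(config$seed * 8L + k)
    z <- NULL
    for (try in 1:5000) {
      cand <- stats::runif(d)
      if (is.finite(lp_fun(cand))) { z <- cand; break }
    }
    if (is.null(z)) {
      stop("no feasible starting point found; revise priors or constraints")
    }
    lp <- lp_fun(z)
    hist_z <- matrix(NA_real_, n, d)
    lp_trace <- numeric(n)
    L <- t(chol(base_cov))
    lambda <- config$proposal_scale * 2.38 / sqrt(d)
    n_acc <- 0L
    acc_window <- 0L
    adapt_count <- 0L
    for (i in seq_len(n)) {
      zc <- z + lambda * as.vector(L %*% stats::rnorm(d))
      lpc <- lp_fun(zc)
      if (is.finite(lpc) && (lpc >= lp || log(stats::runif(1)) < lpc - lp)) {
        z <- zc
        lp <- lpc
        n_acc <- n_acc + 1L
        acc_window <- acc_window + 1L
      }
      hist_z[i, ] <- z
      lp_trace[i] <- lp
      if (i <= n_burn && i %% config$adapt_interval == 0L && i >= 200L) {
        adapt_count <- adapt_count + 1L
        cv <- stats::cov(hist_z[seq_len(i), , drop = FALSE])
        cv <- cv + diag(1e-10, d)
        Lnew <- tryCatch(t(chol(cv)), error = function(e) NULL)
        if (!is.null(Lnew)) L <- Lnew
        rate <- acc_window / config$adapt_interval
        lambda <- lambda * exp((rate - 0.234) / sqrt(adapt_count))
        acc_window <- 0L
      }
    }
    keep <- (n_burn + 1L):n
    zk <- hist_z[keep, , drop = FALSE]
    xk <- zk
    for (j in seq_len(d)) {
      v <- lo[j] + zk[, j] * (hi[j] - lo[j])
      xk[, j] <- if (logm[j]) exp(v) else v
    }
    colnames(xk) <- priors$name
    chains[[k]] <- xk
    lps[[k]] <- lp_trace[keep]
    acc_rates[k] <- n_acc / n
  }
  if (all(acc_rates == 0)) {
    stop("no proposals accepted in any chain; revise priors or proposal scale")
  }
  rh <- rhat_split(chains)
  names(rh) <- priors$name
  if (any(rh > 1.2)) {
    warning("potential scale reduction factor above 1.2 for: ",
            paste(priors$name[rh > 1.2], collapse = ", "))
  }
  structure(list(chains = chains, log_post = lps, accept_rate = acc_rates,
                 rhat = rh, config = config, priors = priors),
            class = "fen_mcmc")
}

#' Draw the pooled posterior ensemble from calibrated chains
#'
#' Evenly spaced (thinned) draws from each chain's post-burn-in states,
#' pooled; with the defaults of 3 chains and 100 subsamples each the ensemble
#' has 300 members.
#'
#' @param fit A `fen_mcmc` object.
#' @param per_chain Subsamples per chain.
#' @return A `fen_ensemble` tibble: `member`, `chain`, `draw` and one column
#'   per calibrated quantity.
#' @export
extract_ensemble <- function(fit, per_chain = fit$config$per_chain) {
  if (per_chain == 0) {
    warning("per_chain = 0 gives an empty ensemble")
    out <- tibble::tibble(member = integer(0), chain = integer(0),
                          draw = integer(0))
    class(out) <- c("fen_ensemble", class(out))
    return(out)
  }
  avail <- min(vapply(fit$chains, nrow, integer(1)))
  if (per_chain > avail) {
    stop("per_chain = ", per_chain, " exceeds the ", avail,
         " post-burn-in states available per chain")
  }
  rows <- lapply(seq_along(fit$chains), function(k) {
    idx <- unique(floor(seq(1, nrow(fit$chains[[k]]), length.out = per_chain)))
    stopifnot(length(idx) == per_chain)
    cbind(chain = k, draw = idx, fit$chains[[k]][idx, , drop = FALSE])
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  out <- tibble::add_column(out, member = seq_len(nrow(out)), .before = 1)
  class(out) <- c("fen_ensemble", class(out))
  out
}
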