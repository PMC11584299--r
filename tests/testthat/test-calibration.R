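test_that("log-likelihood is zero at a perfect fit and scores residuals", {
  tr <- generate_truth(truth_params, drivers_2yr)
  obs <- sample_observations(tr, seed = 1, noise = FALSE)
  expect_equal(log_likelihood(tr, obs), 0, tolerance = 1e-9)

  # a single NEE residual of one sigma under the square-root rule
  one <- obs
  one$streams <- one$streams[one$streams$stream == "nee", ][1, ]
  one$streams$value <- one$streams$value + one$streams$sigma
  one$stocks <- one$stocks[0, ]
  expect_equal(log_likelihood(tr, one, normalisation = 0.5), -0.25,
               tolerance = 1e-12)
  # square-root normalisation halves the log-misfit exactly
  expect_equal(log_likelihood(tr, one, normalisation = 1), -0.5,
               tolerance = 1e-12)

  # widening every sigma with fixed residuals raises the log-likelihood
  noisy <- sample_observations(tr, seed = 2)
  wider <- noisy
  wider$streams$sigma <- wider$streams$sigma * 2
  wider$stocks$sigma <- wider$stocks$sigma * 2
  expect_gt(log_likelihood(tr, wider), log_likelihood(tr, noisy))
})

test_that("log-likelihood guards alignment and emptiness", {
  tr <- generate_truth(truth_params, drivers_2yr)
  obs <- sample_observations(tr, seed = 1)
  tr1 <- generate_truth(truth_params, drivers_1yr)
  expect_error(log_likelihood(tr1, obs), "weeks")
  empty <- obs
  empty$streams$present <- FALSE
  empty$stocks <- empty$stocks[0, ]
  expect_warning(val <- log_likelihood(tr, empty), "no present")
  expect_identical(val, 0)
})

test_that("stock observations constrain the named pool at the named week", {
  tr <- generate_truth(truth_params, drivers_2yr)
  obs <- sample_observations(tr, seed = 1, noise = FALSE)
  obs$streams$present <- FALSE
  # shift the SOC point by one sigma: log-likelihood drops by 0.25
  obs$stocks$value[obs$stocks$pool == "c_som"] <-
    obs$stocks$value[obs$stocks$pool == "c_som"] + 5000
  expect_equal(suppressWarnings(log_likelihood(tr, obs)), -0.25,
               tolerance = 1e-9)
})

test_that("the box prior handles bounds and log-uniform densities", {
  reg <- param_registry()
  mid <- stats::setNames((reg$lower + reg$upper) / 2, reg$name)
  expect_true(is.finite(log_prior(mid, reg)))
  low <- mid
  low["theta"] <- reg$lower[reg$name == "theta"] - 1e-3
  expect_identical(log_prior(low, reg), -Inf)
  over <- mid
  over[c("f_fol", "f_lab", "f_root")] <- 0.4 # allocation sum above 1
  expect_identical(log_prior(over, reg), -Inf)

  one <- tibble::tibble(name = "k", lower = 0.1, upper = 10, scale = "log")
  expect_equal(log_prior(c(k = 1), one), 0)
  expect_equal(log_prior(c(k = exp(1)), one), -1)
  expect_error(log_prior(c(other = 1), one), "prior")
})

test_that("ecological and dynamical constraints report every violation", {
  p <- truth_params
  sim <- simulate_dalec(p, drivers_2yr)
  expect_true(check_edcs(p, sim)$pass)

  bad <- p
  bad["r_som"] <- bad["r_lit"] * 2
  bad["t_root"] <- bad["t_wood"] / 2
  bad["f_auto"] <- 0.85
  chk <- check_edcs(bad, sim)
  expect_false(chk$pass)
  expect_setequal(chk$violated, c("E1", "E2", "E5"))

  # 20-fold SOM growth against the default 10-fold quasi-steady bound
  pools0 <- c(70, 2, 247, 280, 100, 100)
  pools1 <- c(70, 2, 247, 280, 100, 2000)
  grown <- fake_sim(pools0, pools1)
  expect_true("E3" %in% check_edcs(p, grown)$violated)
  # clamping is a violation on its own
  clamped <- fake_sim(pools0, pools0, clamped = TRUE)
  expect_identical(check_edcs(p, clamped)$violated, "E4")
  # constraints can be switched off through the registry config
  cfg <- edc_config(enabled = c("E1", "E2"))
  expect_true(check_edcs(p, grown, cfg)$pass)
})

test_that("proposals are deterministic, centred and correctly scaled", {
  cur <- c(1, -2, 3)
  S <- matrix(c(2, 0.5, 0.1, 0.5, 1, -0.2, 0.1, -0.2, 0.5), 3, 3)
  set.seed(1)
  a <- propose(cur, S, scale = 0.7)
  set.seed(1)
  b <- propose(cur, S, scale = 0.7)
  expect_identical(a, b)
  set.seed(2)
  expect_identical(propose(cur, S, scale = 0), cur)

  # Monte-Carlo oracle: sample covariance approaches scale^2 * covariance
  set.seed(3)
  n <- 20000
  draws <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) draws[i, ] <- propose(cur, S, scale = 0.5)
  emp <- stats::cov(draws)
  expect_lt(max(abs(emp - 0.25 * S)) / max(abs(0.25 * S)), 0.05)

  # non-PSD covariance falls back to diagonal jitter
  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_warning(propose(c(0, 0), bad), "positive definite")
})

test_that("the sampler recovers a closed-form Gaussian toy posterior", {
  mu <- 3
  sd_true <- 2
  toy <- tibble::tibble(name = "mu", lower = -10, upper = 16,
                        scale = "linear")
  fit <- run_mcmc(priors = toy,
                  config = mcmc_config(n_chains = 3, n_proposals = 1e4,
                                       seed = 7),
                  log_posterior = function(x) {
                    stats::dnorm(x[["mu"]], mu, sd_true, log = TRUE)
                  })
  pooled <- do.call(rbind, fit$chains)[, "mu"]
  # batch-means Monte-Carlo standard error
  nb <- 50
  bm <- colMeans(matrix(pooled, ncol = nb))
  mcse <- stats::sd(bm) / sqrt(nb)
  expect_lt(abs(mean(pooled) - mu), 3 * mcse)
  expect_equal(stats::sd(pooled), sd_true, tolerance = 0.15)
  expect_equal(length(fit$chains), 3)
})

test_that("chains replay bitwise identically under a fixed master seed", {
  tr <- generate_truth(truth_params, drivers_1yr)
  obs <- sample_observations(tr, seed = 1, assimilate_years = 2014)
  cfg <- mcmc_config(n_chains = 2, n_proposals = 2000, seed = 3)
  f1 <- suppressWarnings(run_mcmc(obs, drivers_1yr, config = cfg))
  f2 <- suppressWarnings(run_mcmc(obs, drivers_1yr, config = cfg))
  expect_identical(f1$chains, f2$chains)
  expect_identical(f1$accept_rate, f2$accept_rate)
})

test_that("the fast posterior path agrees with the exposed operations", {
  tr <- generate_truth(truth_params, drivers_2yr)
  obs <- sample_observations(tr, seed = 6)
  reg <- param_registry()
  lp <- fenfusion:::make_dalec_logpost(obs, drivers_2yr, reg, acm_constants())
  set.seed(8)
  checked <- 0
  while (checked < 5) {
    z <- stats::runif(28)
    x <- fenfusion:::unit_to_params(z, reg)
    if (x[["f_fol"]] + x[["f_lab"]] + x[["f_root"]] > 1) next
    sim <- simulate_dalec(x, drivers_2yr)
    expected <- if (check_edcs(x, sim)$pass) {
      log_likelihood(sim, obs, normalisation = 0.5)
    } else -Inf
    expect_equal(lp(z), expected, tolerance = 1e-8)
    checked <- checked + 1
  }
})

test_that("ensemble extraction pools evenly spaced draws per chain", {
  tr <- generate_truth(truth_params, drivers_1yr)
  obs <- sample_observations(tr, seed = 1, assimilate_years = 2014)
  cfg <- mcmc_config(n_chains = 3, n_proposals = 2000, per_chain = 100,
                     seed = 2)
  fit <- suppressWarnings(run_mcmc(obs, drivers_1yr, config = cfg))
  ens <- extract_ensemble(fit)
  expect_equal(nrow(ens), 300)
  expect_equal(unname(table(ens$chain)), rep(100L, 3), ignore_attr = TRUE)
  expect_true(all(fenfusion:::.param_names() %in% names(ens)))
  # every member inside the prior box and EDC-feasible by construction
  reg <- param_registry()
  for (j in seq_len(nrow(reg))) {
    expect_true(all(ens[[reg$name[j]]] >= reg$lower[j] - 1e-12))
    expect_true(all(ens[[reg$name[j]]] <= reg$upper[j] + 1e-12))
  }
  expect_warning(e0 <- extract_ensemble(fit, per_chain = 0), "empty")
  expect_equal(nrow(e0), 0)
  expect_error(extract_ensemble(fit, per_chain = 1e6), "exceeds")
  # deterministic thinning indices
  ens2 <- extract_ensemble(fit)
  expect_identical(ens, ens2)
})
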