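---
title: "Model-data fusion for a boreal rich-fen carbon cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-data fusion for a boreal rich-fen carbon cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fenfusion)
```

## The problem

Northern peatlands store a large share of the global soil carbon pool, and
whether a given fen is gaining or losing carbon under a changing climate is
rarely decidable from flux measurements alone: eddy-covariance towers see net
exchange, satellites see leaf area, and field campaigns see a handful of
stocks, each with its own uncertainty. `fenfusion` implements the standard
answer to that fragmentation — Bayesian model-data fusion. A
six-pool carbon mass-balance model of intermediate complexity is calibrated
against all observation streams simultaneously, and every downstream quantity
(fluxes, stocks, allocation fractions, residence times, counterfactual
experiments) is reported as an ensemble with full uncertainty.

## The forward model

Carbon is tracked weekly through six pools: labile, foliage, fine root,
structural (wood, including coarse roots), litter and soil organic matter
(SOM). Per step of `dt = 7` days:

* **Photosynthesis.** GPP comes from an aggregated canopy model: canopy
  conductance limited by the temperature range and fixed hydraulic constants,
  a CO2 drawdown solved from a quadratic for internal CO2, a light response
  saturating in leaf area index (LAI = foliage carbon / leaf mass per area),
  and a day-length correction. The canopy efficiency scalar `c_eff` (foliar
  nitrogen folded in) and the day-length coefficient are calibrated; the ten
  empirical coefficients ship as a versioned, checksummed YAML file
  (`inst/extdata/acm_constants.yaml`) and are data, not code.
* **Respiration and allocation.** Autotrophic respiration is a fixed
  calibrated fraction `f_auto` of GPP; the NPP remainder is allocated to
  labile, foliage and fine roots by fixed fractions, with wood taking the
  residual.
* **Phenology.** Leaf-out (labile-to-foliage release) and senescence
  (foliage-to-litter fall) follow a day-of-year model: a wrapped-Gaussian
  daily weight bell over a 365-day grid, summed per week, with the per-step
  release fraction `1 - (1 - F)^w`. This survival-exponent form makes the
  configured annual completeness `F` exact: with inflows disabled, a pool
  loses exactly the fraction `F` per year, which the tests verify to 1e-9.
* **Turnover and decomposition.** First-order root and wood mortality;
  litter either mineralises to heterotrophic respiration or decomposes to
  SOM; SOM mineralises. All three decomposition pathways scale with
  `exp(theta * T)` on the weekly mean of `(tmin + tmax)/2` (litter carries
  its own sensitivity `theta_lit`). Per-step losses use the discrete fraction
  `min(1, rate * f_T * dt)`, matching the difference-equation family this
  model belongs to; the analytic fixed-point test in the suite relies on this
  documented rule.

Mass balance is exact by construction: the change in total carbon equals
`(GPP - Ra - Rh) * dt` to round-off every week, and
`mass_balance_residual()` is the shipped instrument that proves it.

Design choices worth knowing about: wood mortality routes (by a calibrated
fraction, default 0.9) directly to SOM, the rest to litter, consistent with
a direct structural-to-SOC pathway in the site's carbon budget; the calendar
is 52 model weeks with week 52 absorbing days 358-365 of the 365-day
phenology grid, while flux bookkeeping uses a uniform 7-day step; negative
pools cannot arise from the update rule, but any clamping is flagged and
treated as an ecological-constraint violation during calibration.

## The calibrated quantities

`param_registry()` lists the 28 free quantities: 18 process parameters, the
6 initial pools, and 4 auxiliaries (litter temperature sensitivity, the
day-length coefficient, a labile release-to-growth lag, and the wood-to-SOM
routing fraction). Bounds are deliberately broad uniform (log-uniform for
rates and stocks spanning decades) because the exact prior table of the
original analysis is not reproduced here; the registry is config-driven so
identities and bounds can be swapped without touching code.

## Calibration

`run_mcmc()` is an adaptive-proposal Metropolis sampler over the unit-cube
reparameterisation of the priors (uniform in the cube is exactly the
uniform/log-uniform box prior in natural units). The proposal covariance
adapts to the accumulated chain history every 1000 proposals during the
burn-in half of the chain, scaled by the classic `2.38^2/d` factor, with a
Robbins-Monro nudge of the global scale towards 23.4% acceptance; adaptation
freezes after burn-in. Three independent chains are run (the field's
convention), each seeded from the master seed, so results replay bitwise.

The likelihood is independent-Gaussian per stream — NEE (sigma 0.58 gC m-2
d-1), ecosystem respiration (1 gC m-2 d-1), LAI (product uncertainty floored
at 0.5 m2 m-2, available April-September only, model weeks 14-39) — plus
sparse stock constraints (SOC 64055 +/- 5000, fine roots 247.06 +/- 140.86,
and a single aboveground point, foliage plus wood, 282 +/- 49.165 gC m-2, in
the first week). Each stream's log-misfit is multiplied by 0.5: the
square-root likelihood weighting that stops the dense flux record from
drowning the sparse field data. Observations from alternating years (2014,
2016, 2018, 2020) are assimilated; the others are held out.

Ecological and dynamical constraints (EDCs) reject implausible candidates
outright: SOM must turn over more slowly than litter, fine roots faster than
wood, no pool may drift more than 10-fold over the run (a quasi-steady-state
condition replacing centuries of spin-up), no negative-pool clamping, and
the autotrophic fraction stays within (0.2, 0.8). The EDC set is a registry
with per-constraint switches (`edc_config()`).

The study-scale algorithm assesses 1e8 proposals per chain; the desk default
is 1e5 — the identical algorithm at a cost that keeps the full twin
experiment under ten minutes on one core. At that length the chains are not
fully converged (the split potential-scale-reduction diagnostic regularly
warns above its 1.2 threshold, reported but deliberately not fatal), so
posterior intervals are wide; the twin-experiment acceptance check is
therefore about calibrated coverage, not about precision. Pooling 100
evenly-spaced subsamples from each of the 3 chains yields the standard
300-member ensemble on which all summaries are computed.

## The synthetic site

`generate_drivers()` emulates a sub-arctic rich fen at 64.82 degrees north for
seven years (2014-2020) at weekly resolution: sinusoidal air temperature with
a -0.95 degree C annual mean and +/-19 degree C seasonal half-amplitude
(white weekly noise, SD 2 degrees C — no attempt at autocorrelated weather),
strongly seasonal shortwave radiation peaking at 21 MJ m-2 d-1, log-normal
weekly precipitation (median 6 mm), astronomical day length, and a CO2 record
anchored at exactly 400.584 ppm in the first week with a linear trend tuned
so the deterministic seven-year mean is 432 ppm (a tower record, well above
marine background), plus a small seasonal cycle. The documented truth
parameter vector (`default_truth_params()`) was chosen once to produce
fluxes and stocks of the observed magnitude — annual GPP near 540 gC m-2
yr-1, CUE near 0.53, peak LAI near 2.5, NPP split roughly 50/30/20 between
foliage (direct plus labile), wood and fine roots — and is not adjusted.

What the generator does *not* emulate: autocorrelated or extreme weather,
flooding, snow, the actual Earth-observation LAI retrieval, or any soil
moisture control (the model has none). Passing twin experiments therefore
demonstrate that the machinery recovers known parameters under the stated
noise model; they do not certify performance on real tower data, which can
violate the Gaussian-independent error assumption.

## Counterfactual experiments

Two driver transforms isolate what drives interannual productivity change:

* `fixed_co2_drivers()` pins CO2 at the first week's value (400.584 ppm by
  default), leaving all else untouched.
* `fixed_climate_drivers()` replaces every non-CO2 driver by its
  week-of-year mean across the years present, removing interannual weather
  variability while the CO2 trend survives.

Both transforms are idempotent and column-isolated (tested byte-for-byte).
The calibrated ensemble is re-simulated under transformed drivers
(`run_experiment()`); the experiments do not re-run the MCMC — re-simulation
of calibrated members is the reading adopted here, with full re-calibration
available by simply calling `run_mcmc()` on transformed drivers if wanted.
`decompose_co2_effect()` splits the CO2-driven GPP change into a direct
fertilisation part — the canopy submodel driven alone with factual versus
counterfactual CO2 at fixed (factual) LAI — and an indirect part through the
leaf-area response, defined as the remainder so the two sum to the total
exactly.

## Reporting conventions

Annual summaries use quantiles 0.025 / 0.5 / 0.975 with the
linear-interpolation (type 7) estimator, fixed so confidence bounds are
bit-reproducible. Fluxes are summed to annual totals (gC m-2 yr-1, 52 weeks
of 7 days), states averaged — the split that matches the units the field
prints. Carbon use efficiency is computed per member and then summarised
(the ratio-of-members route); `budget_table()` also reports it. Residence
times are mean stock over mean annual outflux per member, reported missing
(not infinite) when a pool has no outflux. Allocation fractions count the
labile route towards foliage and partition NPP exactly.

## Worked example

```{r example, eval = FALSE}
drivers <- generate_drivers(site_config(seed = 1))
truth <- generate_truth(default_truth_params(), drivers)
obs <- sample_observations(truth, seed = 2)

fit <- run_mcmc(obs, drivers, config = mcmc_config(seed = 1))
ensemble <- extract_ensemble(fit) # 300 members
trajectories <- run_experiment(ensemble, drivers)

budget_table(trajectories)
annual_summary(trajectories) |> relative_change(2014)

counterfactual <- run_experiment(ensemble, fixed_co2_drivers(drivers))
decompose_co2_effect(ensemble, drivers, fixed_co2_drivers(drivers))
```

## Numerical notes and limitations

* The internal-CO2 quadratic takes the upper root, so zero assimilation
  capacity gives zero drawdown (`ci -> ca`) and GPP is exactly zero at zero
  leaf area, zero radiation or zero canopy efficiency.
* Simultaneous litter mineralisation and decomposition fractions are
  rescaled proportionally in the (unphysical-parameter) case where their sum
  would exceed 1, so pools cannot overdraw.
* CSV writers emit 17 significant digits and readers use correctly rounded
  base-R parsing, so all file round-trips are bit-exact. NetCDF output is
  not provided; the tidy CSV formats carry the same content.
* The compiled and reference-R simulation engines implement the identical
  update and are cross-checked to ~1e-13 relative; the sampler uses the
  compiled path.
* Problem sizes used throughout the test-suite and the acceptance script —
  7-year weekly records, 3 chains of 1e5 proposals, 300-member ensembles —
  are the package's desk-scale defaults; every knob scales up by
  configuration.
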