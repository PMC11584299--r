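#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of a calibration
#'
#' @param x A `fen_mcmc` fit.
#' @param conf_level Width of the posterior interval.
#' @param ... Unused.
#' @return Tibble `term`, `estimate` (posterior median), `conf.low`,
#'   `conf.high`, `rhat`.
#' @export
tidy.fen_mcmc <- function(x, conf_level = 0.95, ...) {
  a <- (1 - conf_level) / 2
  pooled <- do.call(rbind, x$chains)
  tibble::tibble(
    term = colnames(pooled),
    estimate = apply(pooled, 2, stats::median),
    conf.low = apply(pooled, 2, stats::quantile, probs = a, names = FALSE),
    conf.high = apply(pooled, 2, stats::quantile, probs = 1 - a,
                      names = FALSE),
    rhat = unname(x$rhat)
  )
}

#' One-row diagnostics of a calibration
#'
#' @param x A `fen_mcmc` fit.
#' @param ... Unused.
#' @return Tibble `n_chains`, `n_kept`, `mean_accept`, `max_rhat`.
#' @export
glance.fen_mcmc <- function(x, ...) {
  tibble::tibble(
    n_chains = length(x$chains),
    n_kept = sum(vapply(x$chains, nrow, integer(1))),
    mean_accept = mean(x$accept_rate),
    max_rhat = max(x$rhat)
  )
}

#' Tidy posterior summaries of an ensemble
#'
#' @param x A `fen_ensemble` tibble.
#' @param conf_level Width of the posterior interval.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`, `conf.low`, `conf.high`.
#' @export
tidy.fen_ensemble <- function(x, conf_level = 0.95, ...) {
  a <- (1 - conf_level) / 2
  pn <- setdiff(names(x), c("member", "chain", "draw"))
  purrr::map_dfr(pn, function(p) {
    tibble::tibble(
      term = p,
      estimate = stats::median(x[[p]]),
      conf.low = stats::quantile(x[[p]], a, names = FALSE),
      conf.high = stats::quantile(x[[p]], 1 - a, names = FALSE)
    )
  })
}

#' @export
print.fen_mcmc <- function(x, ...) {
  cat("<fen_mcmc> ", length(x$chains), " chains x ",
      nrow(x$chains[[1]]), " kept states; mean acceptance ",
      sprintf("%.3f", mean(x$accept_rate)), "; max split-Rhat ",
      sprintf("%.3f", max(x$rhat)), "\n", sep = "")
  invisible(x)
}
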