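#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a growth-model fit
#'
#' @param x A `growth_fit` from any of the five fitting pathways.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `conf.low`, `conf.high`, plus posterior columns (`mean`, `sd`, `rhat`,
#'   `ess`) for Bayesian fits.
#' @method tidy growth_fit
#' @export
tidy.growth_fit <- function(x, ...) {
  x$estimates
}

#' Glance at a growth-model fit
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `mode`, `n`, `sigma`, `converged`,
#'   and `rn` (ELEFAN score) where applicable.
#' @method glance growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method, mode = x$mode, n = x$n,
    sigma = x$sigma, converged = x$converged,
    rn = if (is.null(x$extra$rn)) NA_real_ else x$extra$rn
  )
}
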