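#' Von Bertalanffy growth parameter set
#'
#' Bundles the parameters of the von Bertalanffy growth model
#' \eqn{L(t) = L_\infty (1 - e^{-K (t - t_0)})} together with the residual
#' standard deviation of the additive normal error used by the stochastic
#' simulators and the likelihoods.
#'
#' @param l_inf Mean asymptotic length in mm; must be positive.
#' @param k Brody growth coefficient in 1/year; must be positive.
#' @param t0 Nominal age (years) at which expected length is zero. Defaults to
#'   0; the Fabens increment model has no `t0` and simply ignores it.
#' @param sigma Standard deviation (mm) of the normal error term; must be
#'   non-negative. 0 gives deterministic curves.
#'
#' @return An object of class `growth_params`: a named list with elements
#'   `l_inf`, `k`, `t0`, `sigma`.
#' @examples
#' growth_params(l_inf = 536.82, k = 0.38)
#' @export
growth_params <- function(l_inf, k, t0 = 0, sigma = 0) {
  stopifnot(
    "l_inf must be a single finite positive number" =
      is.numeric(l_inf) && length(l_inf) == 1 && is.finite(l_inf) && l_inf > 0,
    "k must be a single finite positive number" =
      is.numeric(k) && length(k) == 1 && is.finite(k) && k > 0,
    "t0 must be a single finite number" =
      is.numeric(t0) && length(t0) == 1 && is.finite(t0),
    "sigma must be a single finite non-negative number" =
      is.numeric(sigma) && length(sigma) == 1 && is.finite(sigma) && sigma >= 0
  )
  structure(
    list(l_inf = as.numeric(l_inf), k = as.numeric(k),
         t0 = as.numeric(t0), sigma = as.numeric(sigma)),
    class = "growth_params"
  )
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf(
    "<growth_params> L_inf = %.2f mm, K = %.3f 1/yr, t0 = %.3f yr, sigma = %.2f mm\n",
    x$l_inf, x$k, x$t0, x$sigma
  ))
  invisible(x)
}

as_growth_params <- function(x) {
  if (inherits(x, "growth_params")) return(x)
  if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    return(growth_params(
      l_inf = x$l_inf, k = x$k,
      t0 = if (is.null(x$t0)) 0 else x$t0,
      sigma = if (is.null(x$sigma)) 0 else x$sigma
    ))
  }
  stop("cannot interpret `params` as growth parameters", call. = FALSE)
}
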