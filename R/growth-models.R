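#' Expected length at age under the von Bertalanffy growth model
#'
#' Evaluates the deterministic part of the growth curve,
#' \eqn{L(t) = L_\infty (1 - e^{-K (t - t_0)})}. Ages below `t0` give negative
#' expected lengths; these are returned as-is (they are legitimate residual
#' territory for fitting) and truncation is left to the caller.
#'
#' @param params A [growth_params()] object (or coercible list).
#' @param age Numeric vector of decimal ages in years; must be finite.
#' @return Numeric vector of expected total lengths in mm.
#' @examples
#' p <- growth_params(524.46, 0.21)
#' vbgm_length(p, 0:7)
#' @seealso [vbgm_inverse_age()], [fabens_expected_recapture()]
#' @export
vbgm_length <- function(params, age) {
  p <- as_growth_params(params)
  if (!is.numeric(age) || anyNA(age) || any(!is.finite(age))) {
    stop("`age` must be finite numeric", call. = FALSE)
  }
  p$l_inf * (1 - exp(-p$k * (age - p$t0)))
}

#' Age at which the growth curve reaches a given length
#'
#' Inverts the von Bertalanffy curve:
#' \eqn{t = t_0 - \log(1 - L / L_\infty) / K}. Only defined for lengths
#' strictly below the asymptote.
#'
#' @inheritParams vbgm_length
#' @param length Numeric vector of lengths in mm, each in `[0, l_inf)`.
#' @return Numeric vector of decimal ages in years; round-trips with
#'   [vbgm_length()] to numerical tolerance.
#' @export
vbgm_inverse_age <- function(params, length) {
  p <- as_growth_params(params)
  if (!is.numeric(length) || anyNA(length) || any(!is.finite(length))) {
    stop("`length` must be finite numeric", call. = FALSE)
  }
  if (any(length < 0)) stop("`length` must be non-negative", call. = FALSE)
  if (any(length >= p$l_inf)) {
    stop("`length` must be strictly below l_inf; age is undefined at or above the asymptote",
         call. = FALSE)
  }
  p$t0 - log(1 - length / p$l_inf) / p$k
}

#' Expected recapture length under the Fabens increment model
#'
#' The Fabens reparameterization of the von Bertalanffy model predicts length
#' at recapture from length at marking and elapsed time:
#' \eqn{L_r = L_m + (L_\infty - L_m)(1 - e^{-K \Delta t})}. Individual ages
#' are never needed, which is what makes the model usable on mark-recapture
#' data. Mean growth increment declines linearly with marking length and is
#' zero at the asymptote.
#'
#' @param l_m Numeric vector of lengths at marking, mm.
#' @param params A [growth_params()] object; `t0` is not used.
#' @param dt Numeric vector of elapsed times in years; must be non-negative.
#' @return Numeric vector of expected recapture lengths, mm.
#' @examples
#' fabens_expected_recapture(300, growth_params(536.82, 0.38), 1)
#' @export
fabens_expected_recapture <- function(l_m, params, dt) {
  p <- as_growth_params(params)
  if (!is.numeric(l_m) || anyNA(l_m) || any(!is.finite(l_m))) {
    stop("`l_m` must be finite numeric", call. = FALSE)
  }
  if (!is.numeric(dt) || anyNA(dt) || any(!is.finite(dt))) {
    stop("`dt` must be finite numeric", call. = FALSE)
  }
  if (any(dt < 0)) stop("`dt` must be non-negative", call. = FALSE)
  l_m + (p$l_inf - l_m) * (1 - exp(-p$k * dt))
}

#' Tabulate a growth curve over an age grid
#'
#' Evaluates [vbgm_length()] over a grid of ages, optionally forcing `t0` to
#' zero. Zeroing `t0` is the convention used when overlaying curves from
#' methods that estimate `t0` on different scales (or not at all), so that
#' all curves start at the origin and only `l_inf` and `k` shape them.
#'
#' @inheritParams vbgm_length
#' @param age_grid Sorted ascending numeric vector of ages in years; must be
#'   non-empty.
#' @param zero_t0 Logical; if `TRUE`, the curve is evaluated with `t0 = 0`
#'   regardless of `params$t0`.
#' @param label Character tag identifying the method that produced the
#'   parameters (e.g. `"vBGM-Bayes"`, `"Fabens-freq"`, `"ELEFAN"`).
#' @return A tibble with columns `age` (years), `length` (mm), `label`.
#' @export
growth_curve_table <- function(params, age_grid, zero_t0 = FALSE, label = "vBGM") {
  p <- as_growth_params(params)
  if (length(age_grid) == 0) stop("`age_grid` must be non-empty", call. = FALSE)
  if (is.unsorted(age_grid)) stop("`age_grid` must be sorted ascending", call. = FALSE)
  if (isTRUE(zero_t0)) p$t0 <- 0
  tibble::tibble(
    age = as.numeric(age_grid),
    length = vbgm_length(p, age_grid),
    label = label
  )
}
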