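#' Fit the von Bertalanffy growth model by nonlinear least squares
#'
#' Minimizes the residual sum of squares of length about the growth curve
#' over `(l_inf, k, t0)` with the Levenberg-Marquardt algorithm
#' ([minpack.lm::nlsLM()]). The vBGM objective is multimodal under weak
#' designs (few old fish), so unless a start is supplied the fit is
#' multi-started from `l_inf = 1.1 * max(length)` crossed with
#' `k in {0.1, 0.3, 0.6}` and `t0 = 0`, keeping the lowest-SSE solution.
#' No box constraints are applied by default: when the data cannot identify
#' the asymptote the fit is allowed to run to the huge `l_inf` / tiny `k`
#' corner that such designs genuinely imply. `bounded = TRUE` restricts
#' `l_inf` to at most 3x the observed maximum for production use.
#'
#' @param data Data frame with columns `age` (years) and `length` (mm);
#'   at least 4 rows spanning at least 3 distinct ages.
#' @param start Optional [growth_params()] (or named list) starting values;
#'   suppresses the multi-start.
#' @param ci_method `"profile"` (profile likelihood, the default) or
#'   `"wald"`; profiling falls back to Wald with a warning when it fails.
#' @param level Confidence level for the parameter intervals.
#' @param bounded Apply the loose production bounds described above.
#' @param max_iter,tol Optimizer iteration cap and relative-offset tolerance.
#' @return An object of class `c("nls_fit", "growth_fit")`: point estimates,
#'   intervals, residual SD, convergence flag, and the underlying `nls`
#'   object in `$extra$fit`.
#' @examples
#' d <- simulate_age_length(growth_params(524.46, 0.21, sigma = 35),
#'                          n = 122, seed = 1)
#' fit_vbgm_nls(d)
#' @export
fit_vbgm_nls <- function(data, start = NULL, ci_method = c("profile", "wald"),
                         level = 0.95, bounded = FALSE,
                         max_iter = 500, tol = 1e-8) {
  ci_method <- match.arg(ci_method)
  stopifnot(is.data.frame(data))
  if (!all(c("age", "length") %in% names(data))) {
    stop("`data` needs columns `age` and `length`", call. = FALSE)
  }
  if (nrow(data) < 4) stop("need at least 4 records", call. = FALSE)
  if (length(unique(data$age)) < 3) {
    stop("need at least 3 distinct ages; the curve is unidentifiable", call. = FALSE)
  }
  starts <- if (!is.null(start)) {
    s <- as_growth_params(start)
    list(list(l_inf = s$l_inf, k = s$k, t0 = s$t0))
  } else {
    l0 <- 1.1 * max(data$length)
    lapply(c(0.1, 0.3, 0.6), function(k0) list(l_inf = l0, k = k0, t0 = 0))
  }
  lower <- if (bounded) c(l_inf = 1e-3, k = 1e-4, t0 = -10) else c(-Inf, -Inf, -Inf)
  upper <- if (bounded) c(l_inf = 3 * max(data$length), k = 5, t0 = 10) else c(Inf, Inf, Inf)
  best <- multistart_nls(
    length ~ l_inf * (1 - exp(-k * (age - t0))), data, starts,
    lower = lower, upper = upper, max_iter = max_iter, tol = tol
  )
  finish_nls_fit(best, data, method = "vBGM", ci_method = ci_method,
                 level = level, n_par = 3L)
}

#' Fit the Fabens increment model by nonlinear least squares
#'
#' Minimizes the residual sum of squares of recapture length about the Fabens
#' expectation over `(l_inf, k)`; there is no `t0` in this parameterization.
#' Multi-start and options mirror [fit_vbgm_nls()].
#'
#' @param data Data frame with columns `l_m`, `l_r` (mm) and `dt` (years);
#'   at least 3 pairs with non-constant design.
#' @inheritParams fit_vbgm_nls
#' @return An object of class `c("nls_fit", "growth_fit")`.
#' @examples
#' d <- simulate_mark_recapture(growth_params(538.85, 0.37, sigma = 15),
#'                              n = 121, seed = 1)
#' fit_fabens_nls(d)
#' @export
fit_fabens_nls <- function(data, start = NULL, ci_method = c("profile", "wald"),
                           level = 0.95, bounded = FALSE,
                           max_iter = 500, tol = 1e-8) {
  ci_method <- match.arg(ci_method)
  stopifnot(is.data.frame(data))
  if (!all(c("l_m", "l_r", "dt") %in% names(data))) {
    stop("`data` needs columns `l_m`, `l_r`, `dt`", call. = FALSE)
  }
  if (nrow(data) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(data$l_m) == 0 && stats::sd(data$dt) == 0) {
    stop("degenerate design: `l_m` and `dt` are both constant", call. = FALSE)
  }
  starts <- if (!is.null(start)) {
    s <- as_growth_params(start)
    list(list(l_inf = s$l_inf, k = s$k))
  } else {
    l0 <- 1.1 * max(c(data$l_m, data$l_r))
    lapply(c(0.1, 0.3, 0.6), function(k0) list(l_inf = l0, k = k0))
  }
  lower <- if (bounded) c(l_inf = 1e-3, k = 1e-4) else c(-Inf, -Inf)
  upper <- if (bounded) c(l_inf = 3 * max(data$l_r), k = 5) else c(Inf, Inf)
  best <- multistart_nls(
    l_r ~ l_m + (l_inf - l_m) * (1 - exp(-k * dt)), data, starts,
    lower = lower, upper = upper, max_iter = max_iter, tol = tol
  )
  finish_nls_fit(best, data, method = "Fabens", ci_method = ci_method,
                 level = level, n_par = 2L)
}

# Run nlsLM from each start, keep the lowest-SSE converged fit; if nothing
# converges keep the best non-converged attempt and flag it.
multistart_nls <- function(formula, data, starts, lower, upper, max_iter, tol) {
  attempts <- lapply(starts, function(s) {
    tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        formula, data = data, start = s,
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(
          maxiter = max_iter, ftol = tol, ptol = tol)
      )),
      error = function(e) NULL
    )
  })
  attempts <- attempts[!vapply(attempts, is.null, TRUE)]
  if (length(attempts) == 0) {
    stop("all optimizer starts failed", call. = FALSE)
  }
  sse <- vapply(attempts, function(f) sum(stats::residuals(f)^2), 0)
  attempts[[which.min(sse)]]
}

finish_nls_fit <- function(fit, data, method, ci_method, level, n_par) {
  est <- stats::coef(fit)
  n <- nrow(data)
  rss <- sum(stats::residuals(fit)^2)
  sigma <- sqrt(rss / (n - n_par))
  converged <- isTRUE(fit$convInfo$isConv)
  ints <- nls_intervals(fit, level = level, method = ci_method)
  estimates <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    conf.low = ints$lower[names(est)],
    conf.high = ints$upper[names(est)]
  )
  params <- growth_params(
    l_inf = est[["l_inf"]], k = max(est[["k"]], .Machine$double.eps),
    t0 = if ("t0" %in% names(est)) est[["t0"]] else 0,
    sigma = sigma
  )
  new_growth_fit(
    method = method, mode = "frequentist", params = params,
    estimates = estimates, n = n, sigma = sigma, converged = converged,
    extra = list(fit = fit, ci_method = ints$method, rss = rss),
    class = "nls_fit"
  )
}

nls_intervals <- function(fit, level, method) {
  est <- stats::coef(fit)
  wald <- function() {
    se <- sqrt(diag(stats::vcov(fit)))
    z <- stats::qnorm(1 - (1 - level) / 2)
    list(lower = est - z * se, upper = est + z * se, method = "wald")
  }
  if (method == "profile") {
    ci <- tryCatch(
      suppressWarnings(suppressMessages(stats::confint(fit, level = level))),
      error = function(e) NULL
    )
    ok <- !is.null(ci) && !anyNA(ci)
    if (ok) {
      if (is.null(dim(ci))) ci <- matrix(ci, 1, 2, dimnames = list(names(est), NULL))
      return(list(lower = stats::setNames(ci[, 1], rownames(ci)),
                  upper = stats::setNames(ci[, 2], rownames(ci)),
                  method = "profile"))
    }
    warning("profile intervals failed; falling back to Wald", call. = FALSE)
  }
  wald()
}

#' Recompute parameter intervals for a least-squares fit
#'
#' @param fit An `nls_fit` object from [fit_vbgm_nls()] or [fit_fabens_nls()];
#'   must have converged.
#' @param level Confidence level.
#' @param method `"profile"` or `"wald"`.
#' @return The fit with its `estimates` table's interval columns replaced.
#' @export
confidence_intervals <- function(fit, level = 0.95,
                                 method = c("profile", "wald")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "nls_fit"))
  if (!fit$converged) {
    stop("cannot compute intervals for a non-converged fit", call. = FALSE)
  }
  ints <- nls_intervals(fit$extra$fit, level = level, method = method)
  fit$estimates$conf.low <- ints$lower[fit$estimates$term]
  fit$estimates$conf.high <- ints$upper[fit$estimates$term]
  fit$extra$ci_method <- ints$method
  fit
}
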