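# Shared container for all five fitting pathways. `estimates` is a broom-shaped
# tibble (term, estimate, conf.low, conf.high, ...); `extra` holds
# pathway-specific payload (nls object, posterior draws, GA trace, ...).
new_growth_fit <- function(method, mode, params, estimates, n, sigma,
                           converged, extra = list(), class = character()) {
  stopifnot(is.data.frame(estimates), n >= 0)
  bad <- with(estimates,
              !is.na(conf.low) & !is.na(conf.high) &
                (conf.low > estimate | estimate > conf.high))
  if (any(bad)) {
    stop("interval bounds do not bracket the point estimate for: ",
         paste(estimates$term[bad], collapse = ", "), call. = FALSE)
  }
  structure(
    list(method = method, mode = mode, params = params,
         estimates = tibble::as_tibble(estimates), n = as.integer(n),
         sigma = sigma, converged = isTRUE(converged), extra = extra),
    class = c(class, "growth_fit")
  )
}

#' @export
print.growth_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<%s fit, %s> n = %d, residual SD = %s, %s\n",
              x$method, x$mode, x$n,
              formatC(x$sigma, digits = digits, format = "fg"),
              if (x$converged) "converged" else "NOT CONVERGED"))
  print(x$estimates, digits = digits)
  invisible(x)
}

#' Growth curve implied by a fitted model
#'
#' @param fit A `growth_fit` object.
#' @param age_grid Ages (years) to evaluate at.
#' @param zero_t0 Zero the `t0` parameter before evaluating (the convention
#'   for cross-method overlays).
#' @return A tibble `age`, `length`, `label` (see [growth_curve_table()]).
#' @export
fitted_growth_curve <- function(fit, age_grid = seq(0, 10, by = 0.1),
                                zero_t0 = TRUE) {
  stopifnot(inherits(fit, "growth_fit"))
  label <- if (fit$method == "ELEFAN") "ELEFAN" else
    paste0(fit$method, "-", abbreviate_mode(fit$mode))
  growth_curve_table(fit$params, age_grid, zero_t0 = zero_t0, label = label)
}

abbreviate_mode <- function(mode) {
  switch(mode, Bayesian = "Bayes", frequentist = "freq", Frequentist = "freq", mode)
}
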