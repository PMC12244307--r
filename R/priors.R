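#' Literature growth-parameter table for European grayling
#'
#' Published von Bertalanffy parameter estimates for European grayling
#' populations (FishBase plus studies from Wales, Norway and historical
#' European data). These are the default inputs from which informative normal
#' priors are built: a population in a large alpine river should be broadly
#' comparable to these stocks.
#'
#' @return A tibble with columns `reference`, `l_inf` (mm), `k` (1/yr),
#'   `t0` (yr), `locality`; 11 rows.
#' @export
grayling_prior_table <- function() {
  tibble::tribble(
    ~reference,                ~l_inf,   ~k,    ~t0,    ~locality,
    "FishBase",                375.00, 0.214, -0.080, "Kanin Peninsula (Russia)",
    "Guillaud et al. 2023",    544.00, 0.190, -1.400, "Historical data from Europe",
    "Woolland & Jones 1975a",  575.00, 0.223,  0.115, "Llyn Tegid (1946-52) (Wales)",
    "Woolland & Jones 1975b",  456.00, 0.386,  0.222, "Llyn Tegid (1962-68) (Wales)",
    "Woolland & Jones 1975c",  389.00, 0.424,  0.149, "Upper Dee (Wales)",
    "Woolland & Jones 1975d",  417.00, 0.484,  0.281, "Corwen (Wales)",
    "Giri 2021a",              437.80, 0.238,  0.540, "Valaae (Norway)",
    "Giri 2021b",              438.80, 0.238,  0.488, "Steinbekken (Norway)",
    "Giri 2021c",              393.33, 0.292,  0.557, "Sandbekken (Norway)",
    "Giri 2021d",              418.12, 0.241,  0.490, "Shyrjon (Norway)",
    "Giri 2021e",              456.41, 0.220,  0.520, "Soerskottaae (Norway)"
  )
}

#' Build normal priors from a table of literature estimates
#'
#' Each growth parameter gets a normal prior whose mean and SD are the sample
#' mean and sample SD of the corresponding column of literature estimates.
#' `l_inf` and `k` priors are truncated to the positive half-line (physical
#' support); `t0` is untruncated. The residual SD `sigma` gets a
#' half-normal prior, weakly informative on the mm scale.
#'
#' @param literature Data frame with numeric columns `l_inf` and `k` and
#'   optionally `t0`; at least 2 rows. Defaults to the packaged
#'   [grayling_prior_table()].
#' @param sigma_scale Scale (mm) of the half-normal prior on `sigma`.
#' @return An object of class `prior_spec`: a list with per-parameter
#'   `mean`/`sd`, truncation `bounds`, and the `sigma_scale`.
#' @examples
#' build_priors()
#' @export
build_priors <- function(literature = grayling_prior_table(), sigma_scale = 50) {
  stopifnot(is.data.frame(literature))
  if (nrow(literature) < 2) {
    stop("`literature` needs at least 2 rows: a prior SD is undefined from one study",
         call. = FALSE)
  }
  if (!all(c("l_inf", "k") %in% names(literature))) {
    stop("`literature` needs numeric columns `l_inf` and `k`", call. = FALSE)
  }
  col_prior <- function(x, name) {
    m <- mean(x)
    s <- stats::sd(x)
    if (!is.finite(s) || s <= 0) {
      stop("degenerate `", name, "` column: prior SD is zero or undefined",
           call. = FALSE)
    }
    list(mean = m, sd = s)
  }
  spec <- list(
    l_inf = col_prior(literature$l_inf, "l_inf"),
    k = col_prior(literature$k, "k"),
    t0 = if ("t0" %in% names(literature)) col_prior(literature$t0, "t0") else NULL,
    sigma_scale = sigma_scale,
    bounds = list(l_inf = c(0, Inf), k = c(0, Inf), t0 = c(-Inf, Inf),
                  sigma = c(0, Inf))
  )
  structure(spec, class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("<prior_spec>\n")
  cat(sprintf("  l_inf ~ Normal(%.2f, %.2f) truncated > 0\n",
              x$l_inf$mean, x$l_inf$sd))
  cat(sprintf("  k     ~ Normal(%.3f, %.3f) truncated > 0\n", x$k$mean, x$k$sd))
  if (!is.null(x$t0)) {
    cat(sprintf("  t0    ~ Normal(%.3f, %.3f)\n", x$t0$mean, x$t0$sd))
  }
  cat(sprintf("  sigma ~ Half-Normal(0, %.1f)\n", x$sigma_scale))
  invisible(x)
}
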