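#' Pooled mean age from repeated scale readings
#'
#' Each fish is typically aged by two readers on three scales, yielding up to
#' six independent annulus counts. The working age is the plain arithmetic
#' mean of all readings, readers pooled equally; no modal-age or re-read
#' protocol is applied.
#'
#' @param annuli Numeric vector of non-negative integer annulus counts for one
#'   fish (all readers and scales pooled). Must be non-empty.
#' @return Mean age in years (pre-hatch-date fraction).
#' @examples
#' mean_age(c(3, 3, 4, 3, 3, 4))
#' @export
mean_age <- function(annuli) {
  if (length(annuli) == 0) stop("`annuli` must be non-empty", call. = FALSE)
  if (!is.numeric(annuli) || anyNA(annuli) || any(annuli < 0) ||
      any(annuli != round(annuli))) {
    stop("`annuli` must be non-negative integer counts", call. = FALSE)
  }
  mean(annuli)
}

#' Decimal age from annulus count and capture date
#'
#' Converts an integer (or mean) annulus count into a decimal age by assuming
#' a nominal hatching date within the year and adding the elapsed fraction of
#' the year between the most recent hatching anniversary on or before the
#' capture date and the capture itself, using 365.25 days per year. Grayling
#' spawn in March-April, hence the April 1 default.
#'
#' @param mean_annuli Numeric vector of annulus counts (possibly fractional
#'   means across readings).
#' @param capture_date `Date` (or string coercible to `Date`) of capture,
#'   recycled against `mean_annuli`.
#' @param hatch_month_day Nominal hatching date as `"MM-DD"`; default April 1.
#' @return Decimal ages in years; always in `[mean_annuli, mean_annuli + 1)`.
#' @examples
#' fractional_age(2, as.Date("2022-09-15"))
#' @export
fractional_age <- function(mean_annuli, capture_date, hatch_month_day = "04-01") {
  capture_date <- tryCatch(as.Date(capture_date),
                           error = function(e) stop("invalid `capture_date`", call. = FALSE))
  if (anyNA(capture_date)) stop("invalid `capture_date`", call. = FALSE)
  yr <- as.integer(format(capture_date, "%Y"))
  anniv <- as.Date(paste0(yr, "-", hatch_month_day))
  # capture before this year's hatch date: fraction counts from previous year
  anniv <- dplyr::if_else(capture_date < anniv,
                          as.Date(paste0(yr - 1L, "-", hatch_month_day)),
                          anniv)
  frac <- as.numeric(capture_date - anniv) / 365.25
  mean_annuli + frac
}

#' Per-cohort length summary
#'
#' Summarizes lengths per integer age class (the floor of the decimal age,
#' matching the "0+ ... 7+" labelling of cohorts). Empty classes are omitted.
#'
#' @param records Data frame with columns `age` (decimal years) and `length`
#'   (mm), one row per fish. Must be non-empty.
#' @return A tibble with one row per age class: `age_class`, `n`, `min`,
#'   `max`, `range`, `mean`, `sd` of length (sd is `NA` for singleton
#'   classes).
#' @examples
#' cohort_summary(data.frame(age = c(2.4, 2.6, 3.1), length = c(204, 410, 300)))
#' @export
cohort_summary <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) stop("`records` must be non-empty", call. = FALSE)
  if (!all(c("age", "length") %in% names(records))) {
    stop("`records` needs columns `age` and `length`", call. = FALSE)
  }
  records |>
    dplyr::mutate(age_class = floor(.data$age)) |>
    dplyr::group_by(.data$age_class) |>
    dplyr::summarise(
      n = dplyr::n(),
      min = min(.data$length),
      max = max(.data$length),
      range = max(.data$length) - min(.data$length),
      mean = mean(.data$length),
      sd = stats::sd(.data$length),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$age_class)
}

#' Decimal ages from a table of raw scale readings
#'
#' Collapses a long table of per-reader, per-scale annulus counts into one
#' decimal age per fish: readings are pooled with [mean_age()] and the
#' within-year fraction added with [fractional_age()].
#'
#' @param readings Data frame with columns `fish_id`, `annuli`, `capture_date`
#'   (columns `reader` and `scale_index` may be present and are ignored beyond
#'   pooling).
#' @inheritParams fractional_age
#' @return A tibble with one row per fish: `fish_id`, `n_readings`,
#'   `mean_annuli`, `capture_date`, `age`.
#' @export
assign_ages <- function(readings, hatch_month_day = "04-01") {
  stopifnot(is.data.frame(readings))
  need <- c("fish_id", "annuli", "capture_date")
  if (!all(need %in% names(readings))) {
    stop("`readings` needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  readings |>
    dplyr::group_by(.data$fish_id) |>
    dplyr::summarise(
      n_readings = dplyr::n(),
      mean_annuli = mean_age(.data$annuli),
      capture_date = as.Date(.data$capture_date[1]),
      .groups = "drop"
    ) |>
    dplyr::mutate(age = fractional_age(.data$mean_annuli, .data$capture_date,
                                       hatch_month_day))
}
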