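# Shared validation helper: `checks` is a named list of logical vectors,
# TRUE = bad row; failing rows are reported with their file line numbers
# (line 1 is the header).
reject_rows <- function(df, checks, path) {
  msgs <- character()
  for (nm in names(checks)) {
    bad <- which(checks[[nm]])
    if (length(bad)) {
      msgs <- c(msgs, paste0(nm, " on line(s) ",
                             paste(bad + 1L, collapse = ", ")))
    }
  }
  if (length(msgs)) {
    stop("invalid rows in ", path, ":\n  ", paste(msgs, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(df)
}

need_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(path, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
}

# optional `unit` column: "cm" rows are converted to mm on ingest
apply_units <- function(df, length_cols) {
  if (!"unit" %in% names(df)) return(df)
  fac <- ifelse(tolower(df$unit) == "cm", 10, 1)
  for (cc in length_cols) df[[cc]] <- df[[cc]] * fac
  df$unit <- NULL
  df
}

#' Read an age-at-length CSV
#'
#' Expected columns: `fish_id`, `age` (decimal years), `length` (mm; an
#' optional `unit` column with values `mm`/`cm` converts on ingest).
#' Malformed rows are rejected with their line numbers.
#'
#' @param path CSV file path.
#' @return A tibble `fish_id`, `age`, `length`.
#' @export
read_age_length_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need_cols(df, c("fish_id", "age", "length"), path)
  df <- apply_units(df, "length")
  reject_rows(df, list(
    "non-numeric or missing age" = !is.finite(df$age),
    "negative age" = is.finite(df$age) & df$age < 0,
    "non-positive or missing length" = !is.finite(df$length) | df$length <= 0
  ), path)
  tibble::as_tibble(df[c("fish_id", "age", "length")])
}

#' Read a mark-recapture CSV
#'
#' Expected columns: `fish_id`, `l_m`, `l_r` (mm, `unit` column honoured) and
#' either `dt` (years) or ISO dates `marking_date` and `recapture_date`, from
#' which `dt` is computed at 365.25 days/year. Rows whose recapture date is
#' not after the marking date are rejected with line numbers.
#'
#' @param path CSV file path.
#' @return A tibble `fish_id`, `l_m`, `l_r`, `dt`.
#' @export
read_mark_recapture_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need_cols(df, c("fish_id", "l_m", "l_r"), path)
  df <- apply_units(df, c("l_m", "l_r"))
  if (!"dt" %in% names(df)) {
    need_cols(df, c("marking_date", "recapture_date"), path)
    md <- as.Date(df$marking_date)
    rd <- as.Date(df$recapture_date)
    reject_rows(df, list(
      "unparseable date" = is.na(md) | is.na(rd),
      "recapture date not after marking date" =
        !is.na(md) & !is.na(rd) & rd <= md
    ), path)
    df$dt <- as.numeric(rd - md) / 365.25
  }
  reject_rows(df, list(
    "non-positive or missing marking length" = !is.finite(df$l_m) | df$l_m <= 0,
    "non-positive or missing recapture length" = !is.finite(df$l_r) | df$l_r <= 0,
    "non-positive elapsed time" = !is.finite(df$dt) | df$dt <= 0
  ), path)
  tibble::as_tibble(df[c("fish_id", "l_m", "l_r", "dt")])
}

#' Read and write length-frequency CSVs
#'
#' The on-disk format is long: one row per `(date, bin)` cell with columns
#' `date` (ISO-8601), `bin_mid_mm` and `count` (an optional `unit = "cm"`
#' column scales bin mids by 10). [read_lfq_csv()] returns the binned
#' `lfq_matrix`; [write_lfq_csv()] writes one, including empty cells so the
#' matrix shape round-trips.
#'
#' @param path CSV file path.
#' @return For the reader, an `lfq_matrix`; the writer returns `path`
#'   invisibly.
#' @export
read_lfq_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if ("bin_mid_cm" %in% names(df) && !"bin_mid_mm" %in% names(df)) {
    df$bin_mid_mm <- df$bin_mid_cm * 10
    df$bin_mid_cm <- NULL
  }
  need_cols(df, c("date", "bin_mid_mm", "count"), path)
  if ("unit" %in% names(df)) {
    df$bin_mid_mm <- df$bin_mid_mm * ifelse(tolower(df$unit) == "cm", 10, 1)
    df$unit <- NULL
  }
  dd <- as.Date(df$date)
  reject_rows(df, list(
    "unparseable date" = is.na(dd),
    "non-positive bin midpoint" = !is.finite(df$bin_mid_mm) | df$bin_mid_mm <= 0,
    "negative or non-integer count" =
      !is.finite(df$count) | df$count < 0 | df$count != round(df$count)
  ), path)
  df$date <- dd
  dates <- sort(unique(dd))
  mids <- sort(unique(df$bin_mid_mm))
  w <- if (length(mids) > 1) min(diff(mids)) else mids[1] * 2
  full_mids <- seq(min(mids), max(mids), by = w)
  counts <- matrix(0L, length(full_mids), length(dates))
  bi <- round((df$bin_mid_mm - min(mids)) / w) + 1L
  di <- match(df$date, dates)
  for (r in seq_len(nrow(df))) {
    counts[bi[r], di[r]] <- counts[bi[r], di[r]] + as.integer(df$count[r])
  }
  new_lfq_matrix(dates, full_mids, counts, w)
}

#' @rdname read_lfq_csv
#' @param lfq An `lfq_matrix` to write.
#' @export
write_lfq_csv <- function(lfq, path) {
  stopifnot(inherits(lfq, "lfq_matrix"))
  long <- tidyr::expand_grid(
    date = lfq$dates, bin_mid_mm = lfq$bin_mids
  ) |>
    dplyr::arrange(.data$date, .data$bin_mid_mm)
  long$count <- as.vector(lfq$counts[
    cbind(match(long$bin_mid_mm, lfq$bin_mids), match(long$date, lfq$dates))])
  readr::write_csv(long, path)
  invisible(path)
}

#' Serialize a fit result to JSON
#'
#' Writes the method/mode tags, the estimate table and the fit statistics of
#' a `growth_fit` in a stable schema (version 1).
#'
#' @param fit A `growth_fit`.
#' @param path Output path; `NULL` returns the JSON string.
#' @export
write_fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "growth_fit"))
  obj <- list(
    schema = "trigrowth/fit-result/v1",
    method = fit$method,
    mode = fit$mode,
    estimates = fit$estimates,
    fit_stats = list(n = fit$n, sigma = fit$sigma, converged = fit$converged)
  )
  if (!is.null(fit$extra$rn)) obj$fit_stats$rn <- fit$extra$rn
  if (is.null(path)) {
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null"))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
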