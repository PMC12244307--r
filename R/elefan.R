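new_lfq_matrix <- function(dates, bin_mids, counts, bin_width) {
  dates <- as.Date(dates)
  stopifnot(
    "dates must be strictly increasing" = !is.unsorted(dates, strictly = TRUE),
    "counts must be a bins x dates matrix" =
      is.matrix(counts) && nrow(counts) == length(bin_mids) &&
      ncol(counts) == length(dates),
    "counts must be non-negative" = all(counts >= 0),
    "bin_width must be positive" = bin_width > 0
  )
  if (length(bin_mids) > 1 &&
      max(abs(diff(bin_mids) - bin_width)) > 1e-8) {
    stop("bin mids must be equally spaced at `bin_width`", call. = FALSE)
  }
  structure(
    list(dates = dates, bin_mids = as.numeric(bin_mids),
         counts = counts, bin_width = as.numeric(bin_width)),
    class = "lfq_matrix"
  )
}

#' @export
print.lfq_matrix <- function(x, ...) {
  cat(sprintf(
    "<lfq_matrix> %d sampling dates (%s .. %s), %d bins of %g mm (%g .. %g mm), %d fish\n",
    length(x$dates), min(x$dates), max(x$dates), length(x$bin_mids),
    x$bin_width, min(x$bin_mids), max(x$bin_mids), sum(x$counts)))
  invisible(x)
}

#' Bin individual lengths into a length-frequency matrix
#'
#' Counts fish per length bin per sampling date. Bins are half-open,
#' lower-inclusive intervals `[mid - w/2, mid + w/2)` with mids at odd
#' multiples of `w/2`, so a 154 mm fish with 10 mm bins lands in the bin
#' centred at 155 mm.
#'
#' @param samples Data frame with columns `date` and `length` (mm), one row
#'   per fish (e.g. from [simulate_length_frequency()]).
#' @param bin_width Bin width in mm; default 10 (the 1 cm resolution of the
#'   monitoring data).
#' @return An `lfq_matrix`: sampling dates, bin midpoints, and a bins x dates
#'   count matrix.
#' @examples
#' lf <- simulate_length_frequency(growth_params(436.5, 0.12), seed = 1)
#' bin_lengths(lf, 10)
#' @export
bin_lengths <- function(samples, bin_width = 10) {
  stopifnot(is.data.frame(samples))
  if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
  if (nrow(samples) == 0) stop("`samples` is empty", call. = FALSE)
  if (!all(c("date", "length") %in% names(samples))) {
    stop("`samples` needs columns `date` and `length`", call. = FALSE)
  }
  dates <- sort(unique(as.Date(samples$date)))
  idx_all <- floor(samples$length / bin_width)
  mids <- (seq(min(idx_all), max(idx_all))) * bin_width + bin_width / 2
  counts <- matrix(0L, length(mids), length(dates))
  di <- match(as.Date(samples$date), dates)
  bi <- idx_all - min(idx_all) + 1L
  for (r in seq_along(di)) counts[bi[r], di[r]] <- counts[bi[r], di[r]] + 1L
  new_lfq_matrix(dates, mids, counts, bin_width)
}

#' Restructure a length-frequency matrix
#'
#' The classic moving-average restructuring that turns histogram modes into
#' positive scores and troughs into negative ones, applied per sampling date:
#' (1) a centred moving average of the counts over `ma_window` bins (at the
#' edges, the mean of the in-range bins of the window); (2) raw score
#' `count/MA - 1` where the MA is positive, 0 otherwise; (3) de-emphasis of
#' isolated peaks: each positive score is multiplied by
#' `1 - nz/(ma_window - 1)` where `nz` counts the zero-count neighbours
#' (bins beyond the matrix edge count as zero); (4) negative scores are
#' rescaled so the positive and negative sums balance, then floored at -1.
#'
#' @param lfq An [bin_lengths()] result.
#' @param ma_window Odd moving-average span in bins, at least 3; default 5.
#' @return A `restructured_lfq`: same shape as `lfq` with a real-valued
#'   `scores` matrix replacing the counts.
#' @export
restructure <- function(lfq, ma_window = 5) {
  stopifnot(inherits(lfq, "lfq_matrix"))
  if (ma_window < 3 || ma_window %% 2 == 0) {
    stop("`ma_window` must be odd and >= 3", call. = FALSE)
  }
  half <- (ma_window - 1) / 2
  nb <- length(lfq$bin_mids)
  scores <- matrix(0, nb, ncol(lfq$counts))
  for (j in seq_len(ncol(lfq$counts))) {
    x <- lfq$counts[, j]
    if (all(x == 0)) next
    s <- numeric(nb)
    nz_neigh <- numeric(nb)
    for (i in seq_len(nb)) {
      win <- max(1, i - half):min(nb, i + half)
      ma <- mean(x[win])
      s[i] <- if (ma > 0) x[i] / ma - 1 else 0
      # neighbours outside the matrix count as zero-count bins
      neigh <- setdiff((i - half):(i + half), i)
      nz_neigh[i] <- sum(neigh < 1 | neigh > nb) +
        sum(x[neigh[neigh >= 1 & neigh <= nb]] == 0)
    }
    pos <- s > 0
    s[pos] <- s[pos] * (1 - nz_neigh[pos] / (ma_window - 1))
    possum <- sum(s[s > 0])
    negsum <- -sum(s[s < 0])
    if (negsum > 0) s[s < 0] <- s[s < 0] * possum / negsum
    s[s < -1] <- -1
    scores[, j] <- s
  }
  structure(
    list(dates = lfq$dates, bin_mids = lfq$bin_mids, scores = scores,
         bin_width = lfq$bin_width, ma_window = as.integer(ma_window)),
    class = "restructured_lfq"
  )
}

#' @export
print.restructured_lfq <- function(x, ...) {
  cat(sprintf("<restructured_lfq> %d dates x %d bins, MA window %d, score range [%.2f, %.2f]\n",
              length(x$dates), length(x$bin_mids), x$ma_window,
              min(x$scores), max(x$scores)))
  invisible(x)
}

# decimal calendar year of a Date, on the 365.25 d/yr convention
date_to_decimal_year <- function(d) {
  d <- as.Date(d)
  yr <- as.integer(format(d, "%Y"))
  yr + as.numeric(d - as.Date(paste0(yr, "-01-01"))) / 365.25
}

# peak bookkeeping for one restructured matrix: peaks are maximal runs of
# adjacent positive-score bins within a date column; a peak's value is its
# highest score. Returns per-cell peak ids (0 = not in a peak) and peak values.
flag_peaks <- function(scores) {
  nb <- nrow(scores)
  peak_id <- matrix(0L, nb, ncol(scores))
  peak_val <- numeric(0)
  npk <- 0L
  for (j in seq_len(ncol(scores))) {
    pos <- scores[, j] > 0
    r <- rle(pos)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (g in which(r$values)) {
      npk <- npk + 1L
      idx <- starts[g]:ends[g]
      peak_id[idx, j] <- npk
      peak_val[npk] <- max(scores[idx, j])
    }
  }
  list(id = peak_id, value = peak_val, n = npk)
}

#' Score a growth-curve family against a restructured matrix
#'
#' Traces one von Bertalanffy curve per birth cohort present in the survey
#' span (all cohorts share `l_inf`, `k` and the within-year anchor
#' `t_anchor`) through the restructured matrix and sums the scores of the
#' cells the family crosses. A flagged peak (maximal run of positive bins
#' within a date) is credited at most once, with its best score; crossed
#' trough cells contribute their (negative) score once each. ASP is the total
#' score available if every peak were hit; `Rn = 10^(ESP/ASP) / 10` is the
#' goodness-of-fit maximized by the genetic algorithm, so `Rn = 1` means
#' every peak is crossed and no trough.
#'
#' @param r A [restructure()] result.
#' @param params List or named vector with `l_inf` (mm), `k` (1/yr) and
#'   `t_anchor` (fraction of year in `[0, 1)`).
#' @param max_age Oldest cohort age (years) traced through the matrix.
#' @return A list with elements `esp`, `asp`, `rn`.
#' @export
score_growth_curve <- function(r, params, max_age = 50) {
  stopifnot(inherits(r, "restructured_lfq"))
  p <- as.list(params)
  if (is.null(p$l_inf) || is.null(p$k) || is.null(p$t_anchor)) {
    stop("`params` must name l_inf, k, t_anchor", call. = FALSE)
  }
  if (p$l_inf <= 0 || p$k <= 0 || p$t_anchor < 0 || p$t_anchor >= 1) {
    stop("invalid ELEFAN parameters", call. = FALSE)
  }
  pk <- flag_peaks(r$scores)
  asp <- sum(pk$value)
  if (pk$n == 0 || asp <= 0) {
    stop("ASP is zero: no positive peaks to fit", call. = FALSE)
  }
  nb <- length(r$bin_mids)
  lower_edge <- r$bin_mids[1] - r$bin_width / 2
  top_edge <- r$bin_mids[nb] + r$bin_width / 2
  t_dec <- date_to_decimal_year(r$dates)
  yrs <- as.integer(format(r$dates, "%Y"))
  # oldest birth year still small enough to appear in the matrix
  age_top <- if (top_edge >= p$l_inf) max_age else
    min(max_age, -log(1 - top_edge / p$l_inf) / p$k)
  births <- seq(floor(min(yrs) - age_top), max(yrs)) + p$t_anchor

  ages <- outer(t_dec, births, "-")          # dates x cohorts
  ok <- ages > 0
  lens <- p$l_inf * (1 - exp(-p$k * ages))
  # predicted lengths pass through the same recording operator as the data
  # (lengths measured to the bin resolution) before the bin lookup
  bins <- floor((round(lens / r$bin_width) * r$bin_width - lower_edge) /
                  r$bin_width) + 1
  ok <- ok & bins >= 1 & bins <= nb
  if (!any(ok)) {
    return(list(esp = 0, asp = asp, rn = 10^0 / 10))
  }
  date_idx <- row(ages)[ok]
  bin_idx <- bins[ok]
  cells <- unique(cbind(bin_idx, date_idx))
  cell_scores <- r$scores[cells]
  cell_peaks <- pk$id[cells]
  esp <- sum(pk$value[unique(cell_peaks[cell_peaks > 0L])]) +
    sum(cell_scores[cell_peaks == 0L & cell_scores < 0])
  list(esp = esp, asp = asp, rn = 10^(esp / asp) / 10)
}
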