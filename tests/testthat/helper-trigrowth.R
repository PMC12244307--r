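# Published parameter estimates used as generating truths across the suite
# (asymptotic length mm, growth coefficient 1/yr).
tbl_vbgm_bayes <- list(l_inf = 524.46, k = 0.21)
tbl_fabens_bayes <- list(l_inf = 536.82, k = 0.38)
tbl_fabens_freq <- list(l_inf = 538.85, k = 0.37)
tbl_elefan <- list(l_inf = 436.50, k = 0.12)

# The 11 literature study rows the default priors are built from, inlined so
# prior statistics can be recomputed by hand arithmetic independent of the
# packaged table.
lit_l_inf <- c(375.00, 544.00, 575.00, 456.00, 389.00, 417.00,
               437.80, 438.80, 393.33, 418.12, 456.41)
lit_k <- c(0.214, 0.190, 0.223, 0.386, 0.424, 0.484,
           0.238, 0.238, 0.292, 0.241, 0.220)
lit_t0 <- c(-0.080, -1.400, 0.115, 0.222, 0.149, 0.281,
            0.540, 0.488, 0.557, 0.490, 0.520)

# a small clean length-frequency fixture: quarterly survey, tight cohorts,
# no size selectivity, strong recruitment
make_clean_lfq <- function(seed = 11, l_inf = 450, k = 0.4) {
  survey <- seq(as.Date("2016-01-15"), as.Date("2018-12-15"), by = "quarter")
  lf <- simulate_length_frequency(
    growth_params(l_inf, k), survey = survey, cohort_sd = 6,
    recruits_per_year = 3000, max_age = 8, survival = 0.6,
    catchability = 0.15, selectivity = NULL, seed = seed
  )
  bin_lengths(lf, 10)
}

# build a restructured matrix directly from a score matrix (bins x dates)
as_restructured <- function(scores, bin_width = 10,
                            dates = as.Date("2020-01-01") + 90 * (seq_len(ncol(scores)) - 1),
                            first_mid = bin_width / 2 + 100) {
  structure(
    list(dates = as.Date(dates),
         bin_mids = first_mid + bin_width * (seq_len(nrow(scores)) - 1),
         scores = scores, bin_width = bin_width, ma_window = 5L),
    class = "restructured_lfq"
  )
}

# Brute-force traversal oracle for the ELEFAN score, written as plain loops
# and set bookkeeping, independent of the vectorized implementation.
naive_elefan_score <- function(r, p, max_age = 50) {
  w <- r$bin_width
  nb <- length(r$bin_mids)
  # peaks: scan every column for runs of positive scores
  peak_of <- matrix(0L, nb, ncol(r$scores))
  peak_best <- numeric(0)
  np <- 0L
  for (j in seq_len(ncol(r$scores))) {
    i <- 1L
    while (i <= nb) {
      if (r$scores[i, j] > 0) {
        start <- i
        while (i <= nb && r$scores[i, j] > 0) i <- i + 1L
        np <- np + 1L
        peak_of[start:(i - 1L), j] <- np
        peak_best[np] <- max(r$scores[start:(i - 1L), j])
      } else {
        i <- i + 1L
      }
    }
  }
  asp <- sum(peak_best)
  yrs <- as.integer(format(r$dates, "%Y"))
  t_dec <- yrs + as.numeric(r$dates - as.Date(paste0(yrs, "-01-01"))) / 365.25
  cells <- character(0)
  for (by in seq(floor(min(yrs) - max_age), max(yrs))) {
    birth <- by + p$t_anchor
    for (j in seq_along(r$dates)) {
      age <- t_dec[j] - birth
      if (age <= 0 || age > max_age) next
      len <- p$l_inf * (1 - exp(-p$k * age))
      rec <- round(len / w) * w
      b <- NA_integer_
      for (i in seq_len(nb)) {
        if (rec >= r$bin_mids[i] - w / 2 && rec < r$bin_mids[i] + w / 2) b <- i
      }
      if (!is.na(b)) cells <- c(cells, paste(b, j))
    }
  }
  cells <- unique(cells)
  esp <- 0
  hit <- integer(0)
  for (cl in cells) {
    ij <- as.integer(strsplit(cl, " ")[[1]])
    pk <- peak_of[ij[1], ij[2]]
    sc <- r$scores[ij[1], ij[2]]
    if (pk > 0L) {
      if (!(pk %in% hit)) {
        hit <- c(hit, pk)
        esp <- esp + peak_best[pk]
      }
    } else if (sc < 0) {
      esp <- esp + sc
    }
  }
  list(esp = esp, asp = asp, rn = 10^(esp / asp) / 10)
}

# independently coded log posterior for the oracle comparison
naive_log_posterior <- function(th, data, model, pr) {
  if (th[["l_inf"]] <= 0 || th[["k"]] <= 0 || th[["sigma"]] <= 0) return(-Inf)
  dens <- function(x, m, s) -log(s) - 0.5 * log(2 * pi) - (x - m)^2 / (2 * s^2)
  lp <- dens(th[["l_inf"]], pr$l_inf$mean, pr$l_inf$sd) +
    dens(th[["k"]], pr$k$mean, pr$k$sd) +
    log(2) + dens(th[["sigma"]], 0, pr$sigma_scale)
  if (model == "vbgm") {
    lp <- lp + dens(th[["t0"]], pr$t0$mean, pr$t0$sd)
    mu <- th[["l_inf"]] * (1 - exp(-th[["k"]] * (data$age - th[["t0"]])))
    y <- data$length
  } else {
    mu <- data$l_m + (th[["l_inf"]] - data$l_m) * (1 - exp(-th[["k"]] * data$dt))
    y <- data$l_r
  }
  if (!is.null(data) && nrow(data) > 0) {
    for (i in seq_along(y)) lp <- lp + dens(y[i], mu[i], th[["sigma"]])
  }
  lp
}
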