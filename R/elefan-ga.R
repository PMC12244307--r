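#' Genetic-algorithm settings for the ELEFAN search
#'
#' @param pop_size Individuals per generation.
#' @param generations Number of generations.
#' @param crossover_prob Blend-crossover probability.
#' @param mutation_prob Per-gene Gaussian mutation probability.
#' @param bounds Named list of `c(lower, upper)` per parameter
#'   (`l_inf`, `k`, `t_anchor`); `NULL` uses the data-driven defaults of
#'   [ga_optimize()].
#' @param seed Optional integer seed; runs are bit-reproducible under it.
#' @return An object of class `ga_settings`.
#' @export
ga_settings <- function(pop_size = 50, generations = 100,
                        crossover_prob = 0.8, mutation_prob = 0.1,
                        bounds = NULL, seed = NULL) {
  stopifnot(
    pop_size >= 4, generations >= 1,
    crossover_prob >= 0, crossover_prob <= 1,
    mutation_prob >= 0, mutation_prob <= 1
  )
  if (!is.null(bounds)) {
    for (b in bounds) {
      if (length(b) != 2 || !(b[1] < b[2])) {
        stop("each bound must be an ordered pair", call. = FALSE)
      }
    }
  }
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 bounds = bounds, seed = seed),
            class = "ga_settings")
}

#' Fit ELEFAN growth parameters with a real-coded genetic algorithm
#'
#' Restructures the length-frequency matrix once, then maximizes the ELEFAN
#' score `Rn` over `(l_inf, k, t_anchor)` with a real-coded GA: binary
#' tournament selection, BLX-0.5 blend crossover, Gaussian mutation (SD 10%
#' of each parameter's range, reflected into the bounds) and elitism of one,
#' so the best fitness never decreases across generations. Default search
#' bounds are `l_inf` in `(0.8, 1.5) x` the largest observed length, `k` in
#' `(0.01, 1)` and `t_anchor` in `[0, 1)`.
#'
#' @param lfq An [bin_lengths()] result.
#' @param settings A [ga_settings()] object.
#' @param ma_window Restructuring span, passed to [restructure()].
#' @return An object of class `c("elefan_fit", "growth_fit")`; `$extra`
#'   carries `rn`, `t_anchor`, the per-generation best-fitness trace and the
#'   settings. Intervals are `NA` until [bootstrap_elefan()] fills them.
#' @examples
#' \donttest{
#' lf <- simulate_length_frequency(growth_params(436.5, 0.12), seed = 1)
#' fit <- ga_optimize(bin_lengths(lf), ga_settings(pop_size = 30, generations = 40, seed = 1))
#' }
#' @export
ga_optimize <- function(lfq, settings = ga_settings(), ma_window = 5) {
  stopifnot(inherits(lfq, "lfq_matrix"), inherits(settings, "ga_settings"))
  r <- restructure(lfq, ma_window)
  lmax <- max(lfq$bin_mids[rowSums(lfq$counts) > 0]) + lfq$bin_width / 2
  bounds <- settings$bounds %||% list(
    l_inf = c(0.8 * lmax, 1.5 * lmax),
    k = c(0.01, 1),
    t_anchor = c(0, 1 - 1e-9)
  )
  bounds <- bounds[c("l_inf", "k", "t_anchor")]
  if (any(vapply(bounds, is.null, TRUE))) {
    stop("`bounds` must name l_inf, k, t_anchor", call. = FALSE)
  }
  lo <- vapply(bounds, `[`, 0, 1)
  hi <- vapply(bounds, `[`, 0, 2)
  if (any(!(lo < hi))) stop("degenerate bounds", call. = FALSE)

  fitness <- function(theta) {
    score_growth_curve(
      r, list(l_inf = theta[1], k = theta[2], t_anchor = theta[3]))$rn
  }

  local_seed(settings$seed)
  d <- 3L
  np <- settings$pop_size
  # stratified (Latin-hypercube) initial population: one draw per row stratum
  # per gene, covering the box far more evenly than plain uniform sampling
  pop <- vapply(seq_len(d), function(j) {
    lo[j] + (hi[j] - lo[j]) *
      (sample.int(np) - stats::runif(np)) / np
  }, numeric(np))
  fit <- apply(pop, 1, fitness)
  trace <- numeric(settings$generations)
  for (g in seq_len(settings$generations)) {
    elite_i <- which.max(fit)
    new_pop <- matrix(NA_real_, np, d)
    new_pop[1, ] <- pop[elite_i, ]
    i <- 2L
    while (i <= np) {
      # binary tournament picks each parent
      c1 <- sample.int(np, 2); c2 <- sample.int(np, 2)
      p1 <- pop[c1[which.max(fit[c1])], ]
      p2 <- pop[c2[which.max(fit[c2])], ]
      if (stats::runif(1) < settings$crossover_prob) {
        # BLX-0.5: children uniform on the parent interval extended by half
        lo_g <- pmin(p1, p2); hi_g <- pmax(p1, p2)
        ext <- 0.5 * (hi_g - lo_g)
        ch1 <- stats::runif(d, lo_g - ext, hi_g + ext)
        ch2 <- stats::runif(d, lo_g - ext, hi_g + ext)
      } else {
        ch1 <- p1; ch2 <- p2
      }
      for (ch in list(ch1, ch2)) {
        if (i > np) break
        mut <- stats::runif(d) < settings$mutation_prob
        ch[mut] <- ch[mut] + stats::rnorm(sum(mut)) * 0.1 * (hi - lo)[mut]
        ch <- reflect_into(ch, lo, hi)
        new_pop[i, ] <- ch
        i <- i + 1L
      }
    }
    # random immigrant in the last slot keeps exploration alive
    new_pop[np, ] <- lo + stats::runif(d) * (hi - lo)
    pop <- new_pop
    fit <- apply(pop, 1, fitness)
    # slot 1 carries the previous elite, so the best never slips
    trace[g] <- max(fit)
  }
  best <- pop[which.max(fit), ]
  best_rn <- max(fit)
  params <- growth_params(l_inf = best[1], k = best[2], t0 = 0)
  estimates <- tibble::tibble(
    term = c("l_inf", "k", "t_anchor"),
    estimate = best,
    conf.low = NA_real_,
    conf.high = NA_real_
  )
  new_growth_fit(
    method = "ELEFAN", mode = "frequentist", params = params,
    estimates = estimates, n = sum(lfq$counts), sigma = NA_real_,
    converged = TRUE,
    extra = list(rn = best_rn, t_anchor = best[3], trace = trace,
                 settings = settings, ma_window = ma_window),
    class = "elefan_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

reflect_into <- function(x, lo, hi) {
  for (j in seq_along(x)) {
    while (x[j] < lo[j] || x[j] > hi[j]) {
      if (x[j] < lo[j]) x[j] <- 2 * lo[j] - x[j]
      if (x[j] > hi[j]) x[j] <- 2 * hi[j] - x[j]
    }
  }
  x
}

#' Bootstrap confidence intervals for ELEFAN parameters
#'
#' Resamples individual fish within each sampling date with replacement,
#' rebins, reruns the GA per replicate, and reports 95% percentile intervals.
#' Replicates whose restructured matrix has no peaks (ASP = 0) are dropped
#' with a warning; more than 20% drops is an error.
#'
#' @param lfq An [bin_lengths()] result.
#' @param B Number of bootstrap replicates, at least 2.
#' @param settings GA settings used for each replicate (scale these down for
#'   large `B`).
#' @param ma_window Restructuring span.
#' @param seed Integer seed; replicate `b` resamples and runs under
#'   `seed + b`.
#' @param level Interval level.
#' @param point_fit Optional precomputed full-data [ga_optimize()] fit to use
#'   for the point estimates (avoids refitting).
#' @return An `elefan_fit` whose `estimates` carry percentile intervals and,
#'   in `$extra$replicates`, the per-replicate parameter draws.
#' @export
bootstrap_elefan <- function(lfq, B = 200, settings = ga_settings(),
                             ma_window = 5, seed = NULL, level = 0.95,
                             point_fit = NULL) {
  stopifnot(inherits(lfq, "lfq_matrix"))
  if (B < 2) stop("`B` must be at least 2", call. = FALSE)
  if (is.null(point_fit)) {
    point_fit <- ga_optimize(lfq, settings, ma_window)
  }
  n_per_date <- colSums(lfq$counts)
  reps <- vector("list", B)
  dropped <- 0L
  for (b in seq_len(B)) {
    rs <- seed
    if (!is.null(seed)) rs <- seed + b
    local_seed(rs)
    counts_b <- lfq$counts
    for (j in seq_len(ncol(counts_b))) {
      n_j <- n_per_date[j]
      if (n_j == 0) next
      draw <- sample.int(nrow(counts_b), n_j, replace = TRUE,
                         prob = lfq$counts[, j])
      counts_b[, j] <- tabulate(draw, nbins = nrow(counts_b))
    }
    lfq_b <- new_lfq_matrix(lfq$dates, lfq$bin_mids, counts_b, lfq$bin_width)
    st_b <- settings
    st_b$seed <- if (is.null(seed)) NULL else seed + b
    fit_b <- tryCatch(ga_optimize(lfq_b, st_b, ma_window),
                      error = function(e) NULL)
    if (is.null(fit_b)) {
      dropped <- dropped + 1L
      next
    }
    reps[[b]] <- stats::setNames(fit_b$estimates$estimate, fit_b$estimates$term)
  }
  if (dropped > 0) {
    warning(dropped, " bootstrap replicate(s) dropped (no peaks after resampling)",
            call. = FALSE)
    if (dropped / B > 0.2) {
      stop("more than 20% of bootstrap replicates failed", call. = FALSE)
    }
  }
  rep_mat <- do.call(rbind, reps)
  a <- (1 - level) / 2
  est <- point_fit$estimates
  qs <- apply(rep_mat[, est$term, drop = FALSE], 2, stats::quantile,
              probs = c(a, 1 - a))
  # percentile bounds; expanded to the point estimate in the rare unstable case
  est$conf.low <- pmin(qs[1, est$term], est$estimate)
  est$conf.high <- pmax(qs[2, est$term], est$estimate)
  out <- point_fit
  out$estimates <- est
  out$extra$replicates <- tibble::as_tibble(as.data.frame(rep_mat))
  out$extra$B <- B
  out$extra$dropped <- dropped
  out$extra$level <- level
  out
}
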