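# Seed handling: seeded simulators set the RNG locally and restore the
# caller's stream on exit, so a seeded call is a pure function of its
# arguments and leaves no trace on the session RNG.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  restore <- if (is.null(old)) {
    quote(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  } else {
    bquote(assign(".Random.seed", .(old), globalenv()))
  }
  do.call(base::on.exit, list(restore, add = TRUE), envir = envir)
  set.seed(seed)
  invisible(NULL)
}

# draw from Normal(mean, sd) truncated to (0, Inf) by rejection
rnorm_pos <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= 0)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean[bad], sd)
    bad <- bad[out[bad] <= 0]
  }
  out
}

#' Simulate age-at-length records
#'
#' Draws fish ages from a truncated-geometric distribution over the integer
#' age classes (young cohorts dominate riverine electrofishing catches), adds
#' the within-year fraction implied by an April-1 hatch date and the capture
#' date, and generates lengths as the von Bertalanffy expectation plus
#' additive normal noise truncated to positive values.
#'
#' @param params [growth_params()]; `sigma` is the residual SD of length
#'   about the growth curve (mm).
#' @param n Number of fish; must be positive.
#' @param age_range Integer age classes as `c(min, max)`; default 0 to 7.
#' @param capture_date Capture date used for the year fraction (a single
#'   autumn survey by default).
#' @param decay Geometric decay ratio of cohort abundance per year of age;
#'   0.6 keeps most fish in ages 0-3.
#' @param seed Optional integer for reproducibility; the caller's RNG state
#'   is untouched.
#' @return A tibble with columns `fish_id`, `age` (decimal years), `length`
#'   (mm, to the nearest mm).
#' @examples
#' p <- growth_params(524.46, 0.21, sigma = 35)
#' simulate_age_length(p, n = 122, seed = 1)
#' @export
simulate_age_length <- function(params, n, age_range = c(0, 7),
                                capture_date = "2022-09-15",
                                decay = 0.6, seed = NULL) {
  p <- as_growth_params(params)
  if (!is.numeric(n) || length(n) != 1 || n <= 0) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  n <- as.integer(n)
  local_seed(seed)
  classes <- seq(age_range[1], age_range[2])
  w <- decay^(classes - age_range[1])
  age_class <- sample(classes, n, replace = TRUE, prob = w / sum(w))
  frac <- fractional_age(0, capture_date)
  age <- age_class + frac
  mu <- vbgm_length(p, age)
  length <- if (p$sigma > 0) rnorm_pos(n, mu, p$sigma) else mu
  tibble::tibble(
    fish_id = sprintf("AL%04d", seq_len(n)),
    age = age,
    length = round(length)
  )
}

#' Simulate mark-recapture pairs
#'
#' Marking lengths are uniform over `lm_range` (truncated below the
#' asymptote), elapsed times uniform over `dt_range`, and recapture lengths
#' follow the Fabens expectation plus normal noise truncated to positive
#' values.
#'
#' @param params [growth_params()]; `sigma` is the recapture-length residual
#'   SD (mm); `t0` is unused.
#' @param n Number of pairs.
#' @param lm_range Range of marking lengths, mm.
#' @param dt_range Range of elapsed times, years.
#' @param seed Optional integer seed.
#' @return A tibble with columns `fish_id`, `l_m`, `l_r` (mm, nearest mm),
#'   `dt` (years).
#' @examples
#' p <- growth_params(536.82, 0.38, sigma = 15)
#' simulate_mark_recapture(p, n = 121, seed = 1)
#' @export
simulate_mark_recapture <- function(params, n, lm_range = c(119, 503),
                                    dt_range = c(0.09, 1.01), seed = NULL) {
  p <- as_growth_params(params)
  if (!is.numeric(n) || length(n) != 1 || n <= 0) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  if (lm_range[1] >= p$l_inf) {
    stop("`lm_range` lies entirely at or above l_inf", call. = FALSE)
  }
  n <- as.integer(n)
  local_seed(seed)
  upper <- min(lm_range[2], p$l_inf * (1 - 1e-9))
  l_m <- stats::runif(n, lm_range[1], upper)
  dt <- stats::runif(n, dt_range[1], dt_range[2])
  mu <- fabens_expected_recapture(l_m, p, dt)
  l_r <- if (p$sigma > 0) rnorm_pos(n, mu, p$sigma) else mu
  tibble::tibble(
    fish_id = sprintf("MR%04d", seq_len(n)),
    l_m = round(l_m),
    l_r = round(l_r),
    dt = dt
  )
}

#' Default seasonal monitoring survey
#'
#' 25 electrofishing events spanning autumn 2013 through spring 2022:
#' spring/summer/autumn in most years, winter samplings in 2019 and 2021,
#' and only a summer sampling in 2020.
#'
#' @return A `Date` vector of length 25, strictly increasing.
#' @export
default_lfq_survey <- function() {
  d <- c(
    "2013-10-01",
    as.vector(outer(c("-05-01", "-07-15", "-10-01"), 2014:2018,
                    function(md, y) paste0(y, md))),
    "2019-01-15", "2019-05-01", "2019-07-15", "2019-10-01",
    "2020-07-15",
    "2021-01-15", "2021-05-01", "2021-10-01",
    "2022-05-01"
  )
  sort(as.Date(d))
}

#' Logistic capture selectivity
#'
#' Probability that a fish of a given length is retained by the gear;
#' ascending logistic with 50% retention at `l50`.
#'
#' @param length Lengths, mm.
#' @param l50 Length at 50% retention, mm.
#' @param steepness Slope parameter, mm (smaller = sharper).
#' @return Retention probabilities in (0, 1).
#' @export
logistic_selectivity <- function(length, l50 = 80, steepness = 10) {
  1 / (1 + exp(-(length - l50) / steepness))
}

#' Simulate a length-frequency time series
#'
#' For each sampling event, every living cohort (one per birth year, hatched
#' April 1) contributes fish whose lengths are normal about the von
#' Bertalanffy mean at the cohort's current age. Cohort abundance decays with
#' a constant annual survival, so old (large) fish are rare; optional
#' logistic size selectivity additionally thins small fish, emulating
#' electrofishing gear. Lengths are recorded to the nearest centimetre, the
#' resolution of the monitoring data.
#'
#' @param params [growth_params()] generating truth; `sigma` is unused here
#'   (within-cohort spread is controlled by `cohort_sd`).
#' @param survey Vector of sampling dates; default [default_lfq_survey()].
#' @param cohort_sd Within-cohort length SD: a single number (mm) or a
#'   function of mean length. The default scales with mean length
#'   (7% of the cohort mean, floor 5 mm), reflecting the roughly
#'   proportional spread of length at age in salmonids.
#' @param recruits_per_year Cohort size at age 0.
#' @param max_age Oldest cohort simulated, years.
#' @param survival Annual survival rate in (0, 1].
#' @param catchability Per-event capture probability applied on top of
#'   selectivity.
#' @param selectivity `NULL` for none, or a function of length returning
#'   retention probability (default [logistic_selectivity()]).
#' @param hatch_month_day Nominal hatch date, `"MM-DD"`.
#' @param seed Optional integer seed.
#' @return A tibble with columns `date`, `length` (mm, rounded to the nearest
#'   10 mm), one row per captured fish.
#' @examples
#' p <- growth_params(436.50, 0.12)
#' lf <- simulate_length_frequency(p, seed = 1)
#' dplyr::count(lf, date)
#' @export
simulate_length_frequency <- function(params,
                                      survey = default_lfq_survey(),
                                      cohort_sd = NULL,
                                      recruits_per_year = 650,
                                      max_age = 12,
                                      survival = 0.5,
                                      catchability = 0.25,
                                      selectivity = logistic_selectivity,
                                      hatch_month_day = "04-01",
                                      seed = NULL) {
  p <- as_growth_params(params)
  if (length(survey) == 0) stop("`survey` must be non-empty", call. = FALSE)
  survey <- sort(as.Date(survey))
  sd_fun <- if (is.null(cohort_sd)) {
    function(mu) pmax(5, 0.07 * mu)
  } else if (is.function(cohort_sd)) {
    cohort_sd
  } else {
    if (cohort_sd <= 0) stop("`cohort_sd` must be positive", call. = FALSE)
    function(mu) rep(cohort_sd, length(mu))
  }
  local_seed(seed)

  years <- as.integer(format(survey, "%Y"))
  birth_years <- seq(floor(min(years) - max_age), max(years))
  out <- vector("list", length(survey))
  for (i in seq_along(survey)) {
    ev <- survey[i]
    hatch <- as.Date(paste0(birth_years, "-", hatch_month_day))
    ages <- as.numeric(ev - hatch) / 365.25
    alive <- which(ages > 0 & ages <= max_age)
    lens <- list()
    for (j in alive) {
      a <- ages[j]
      mu <- vbgm_length(p, a)
      if (mu <= 0) next
      lambda <- recruits_per_year * survival^a * catchability
      m <- stats::rpois(1, lambda)
      if (m == 0) next
      l <- rnorm_pos(m, rep(mu, m), sd_fun(mu))
      if (!is.null(selectivity)) {
        keep <- stats::runif(m) < selectivity(l)
        l <- l[keep]
      }
      if (length(l)) lens[[length(lens) + 1]] <- l
    }
    lens <- unlist(lens)
    out[[i]] <- tibble::tibble(
      date = rep(ev, length(lens)),
      length = round(lens / 10) * 10
    )
  }
  dplyr::bind_rows(out) |> dplyr::filter(.data$length > 0)
}

#' Write a set of synthetic CSV fixtures
#'
#' Generates one or all of the three dataset types with study-like defaults
#' (generating parameters taken from the package's comparison baseline) and
#' writes them, plus a JSON manifest recording the generating parameters and
#' seed, in the CSV dialects read by [read_age_length_csv()],
#' [read_mark_recapture_csv()] and [read_lfq_csv()].
#'
#' @param output_dir Directory to write into (created if missing).
#' @param scenario One of `"age_length"`, `"mark_recapture"`,
#'   `"length_frequency"`, `"all"`.
#' @param seed Integer master seed; sub-seeds are derived per dataset.
#' @param n_age,n_recapture Record counts for datasets 1 and 2.
#' @return Invisibly, a character vector of the files written.
#' @export
write_fixtures <- function(output_dir, scenario = "all", seed = 1,
                           n_age = 122, n_recapture = 121) {
  scenario <- match.arg(scenario,
                        c("all", "age_length", "mark_recapture", "length_frequency"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- list(
    age_length = list(l_inf = 524.46, k = 0.21, t0 = 0, sigma = 35),
    mark_recapture = list(l_inf = 536.82, k = 0.38, sigma = 15),
    length_frequency = list(l_inf = 436.50, k = 0.12)
  )
  files <- character()
  if (scenario %in% c("all", "age_length")) {
    d <- simulate_age_length(gen$age_length, n = n_age, seed = seed + 1L)
    f <- file.path(output_dir, "age_length.csv")
    readr::write_csv(d, f)
    files <- c(files, f)
  }
  if (scenario %in% c("all", "mark_recapture")) {
    d <- simulate_mark_recapture(gen$mark_recapture, n = n_recapture,
                                 seed = seed + 2L)
    f <- file.path(output_dir, "mark_recapture.csv")
    readr::write_csv(d, f)
    files <- c(files, f)
  }
  if (scenario %in% c("all", "length_frequency")) {
    d <- simulate_length_frequency(gen$length_frequency, seed = seed + 3L)
    lfq <- bin_lengths(d, bin_width = 10)
    f <- file.path(output_dir, "lfq.csv")
    write_lfq_csv(lfq, f)
    files <- c(files, f)
  }
  manifest <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(
    list(scenario = scenario, seed = seed,
         generating_parameters = gen[setdiff(names(gen), switch(
           scenario, all = character(), age_length = c("mark_recapture", "length_frequency"),
           mark_recapture = c("age_length", "length_frequency"),
           length_frequency = c("age_length", "mark_recapture")))]),
    manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(c(files, manifest))
}
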