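test_that("age-at-length generator hits the design contract", {
  p <- growth_params(tbl_vbgm_bayes$l_inf, tbl_vbgm_bayes$k, sigma = 35)
  d <- simulate_age_length(p, n = 122, seed = 1)
  expect_equal(nrow(d), 122)
  expect_true(all(floor(d$age) %in% 0:7))
  expect_true(all(d$length > 0))
  # noiseless draws sit on the curve (up to mm recording)
  p0 <- growth_params(tbl_vbgm_bayes$l_inf, tbl_vbgm_bayes$k, sigma = 0)
  d0 <- simulate_age_length(p0, n = 50, seed = 2)
  expect_equal(d0$length, round(vbgm_length(p0, d0$age)))
  expect_error(simulate_age_length(p, n = 0), "positive")
})

test_that("age-at-length noise reproduces the generating sigma", {
  p <- growth_params(tbl_vbgm_bayes$l_inf, tbl_vbgm_bayes$k, sigma = 35)
  d <- simulate_age_length(p, n = 10000, seed = 3)
  # restrict to cohorts whose mean is far from the positivity truncation
  d2 <- d[d$age >= 2, ]
  resid <- d2$length - vbgm_length(p, d2$age)
  expect_equal(sd(resid), 35, tolerance = 0.02)
})

test_that("mark-recapture generator follows the Fabens expectation", {
  p <- growth_params(tbl_fabens_bayes$l_inf, tbl_fabens_bayes$k, sigma = 0)
  one <- simulate_mark_recapture(p, n = 1, lm_range = c(300, 300),
                                 dt_range = c(0.5, 0.5), seed = 1)
  expect_equal(one$l_r, round(fabens_expected_recapture(300, p, 0.5)))
  d <- simulate_mark_recapture(
    growth_params(tbl_fabens_bayes$l_inf, tbl_fabens_bayes$k, sigma = 15),
    n = 121, seed = 4)
  expect_equal(nrow(d), 121)
  expect_true(all(d$l_m >= 119 & d$l_m <= 503))
  expect_true(all(d$dt >= 0.09 & d$dt <= 1.01))
  expect_error(
    simulate_mark_recapture(growth_params(200, 0.3), 10, lm_range = c(250, 400)),
    "l_inf")
})

test_that("mean simulated increment matches the model expectation", {
  p <- growth_params(tbl_fabens_bayes$l_inf, tbl_fabens_bayes$k, sigma = 15)
  d <- simulate_mark_recapture(p, n = 20000, lm_range = c(300, 300),
                               dt_range = c(1, 1), seed = 5)
  # MC standard error ~ 15/sqrt(20000) ~ 0.11 mm, plus mm rounding
  expect_equal(mean(d$l_r - d$l_m), 74.8679, tolerance = 0.02)
})

test_that("length-frequency generator emulates the seasonal survey", {
  expect_length(default_lfq_survey(), 25)
  lf <- simulate_length_frequency(growth_params(tbl_elefan$l_inf, tbl_elefan$k),
                                  seed = 6)
  expect_setequal(as.character(unique(lf$date)),
                  as.character(default_lfq_survey()))
  expect_true(all(lf$length > 0))
  expect_true(all(lf$length %% 10 == 0)) # recorded to the cm
  # a single young cohort with vanishing spread collapses to one length
  one <- simulate_length_frequency(
    growth_params(450, 0.4), survey = as.Date("2020-10-01"),
    cohort_sd = 1e-9, recruits_per_year = 500, max_age = 0.9,
    survival = 1, catchability = 1, selectivity = NULL, seed = 7)
  expect_equal(length(unique(one$length)), 1)
  expect_error(
    simulate_length_frequency(growth_params(450, 0.4), cohort_sd = 0),
    "positive")
})

test_that("cohort abundance decays with age", {
  # distinct cohorts are identifiable by length when spread is tiny
  lf <- simulate_length_frequency(
    growth_params(450, 0.4), survey = as.Date("2020-10-01"),
    cohort_sd = 1e-9, recruits_per_year = 5000, max_age = 6,
    survival = 0.5, catchability = 1, selectivity = NULL, seed = 8)
  counts <- dplyr::count(lf, length) |> dplyr::arrange(length)
  expect_true(all(diff(counts$n) < 0)) # longer (older) cohorts are rarer
})

test_that("modal progression between seasons tracks the growth increments", {
  p <- growth_params(tbl_elefan$l_inf, tbl_elefan$k)
  survey <- as.Date(c("2018-10-01", "2019-10-01"))
  lf <- simulate_length_frequency(
    p, survey = survey, cohort_sd = 4, recruits_per_year = 5000,
    max_age = 1.6, survival = 0.9, catchability = 0.8,
    selectivity = NULL, seed = 9)
  mode_of <- function(x) as.numeric(names(which.max(table(x))))
  # follow the 2018 cohort: below 50 mm on date 1, above 50 mm a year later
  age1 <- as.numeric(survey[1] - as.Date("2018-04-01")) / 365.25
  m1 <- mode_of(lf$length[lf$date == survey[1] & lf$length < 50])
  m2 <- mode_of(lf$length[lf$date == survey[2] & lf$length > 50])
  predicted_shift <- vbgm_length(p, age1 + 1) - vbgm_length(p, age1)
  expect_lt(abs((m2 - m1) - predicted_shift), 20) # within 2 bins
})

test_that("all generators are deterministic under a seed", {
  p <- growth_params(500, 0.3, sigma = 20)
  expect_identical(simulate_age_length(p, 40, seed = 10),
                   simulate_age_length(p, 40, seed = 10))
  expect_identical(simulate_mark_recapture(p, 40, seed = 10),
                   simulate_mark_recapture(p, 40, seed = 10))
  expect_identical(
    simulate_length_frequency(p, seed = 10),
    simulate_length_frequency(p, seed = 10))
  # and the caller's RNG stream is left untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_age_length(p, 10, seed = 1)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("write_fixtures writes a deterministic file set", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- write_fixtures(d1, "all", seed = 1)
  expect_length(f1, 4) # three CSVs + manifest
  expect_true(all(file.exists(f1)))
  write_fixtures(d2, "all", seed = 1)
  for (f in basename(f1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  d3 <- withr::local_tempdir()
  write_fixtures(d3, "mark_recapture", seed = 2, n_recapture = 121)
  mr <- readr::read_csv(file.path(d3, "mark_recapture.csv"),
                        show_col_types = FALSE)
  expect_equal(nrow(mr), 121)
})
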