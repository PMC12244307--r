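test_that("bin_lengths follows the half-open lower-inclusive convention", {
  s <- tibble::tibble(date = as.Date("2020-05-01"), length = 154)
  lfq <- bin_lengths(s, 10)
  expect_equal(lfq$bin_mids, 155)
  expect_equal(sum(lfq$counts), 1)
  # edge value belongs to the upper bin
  s2 <- tibble::tibble(date = as.Date("2020-05-01"), length = c(149.9, 150))
  lfq2 <- bin_lengths(s2, 10)
  expect_equal(lfq2$counts[match(c(145, 155), lfq2$bin_mids), 1], c(1L, 1L))
  # total count conservation on a larger sample
  lf <- simulate_length_frequency(growth_params(436.5, 0.12), seed = 50)
  lfq3 <- bin_lengths(lf, 10)
  expect_equal(sum(lfq3$counts), nrow(lf))
  expect_equal(ncol(lfq3$counts), 25)
  expect_error(bin_lengths(lf[0, ]), "empty")
})

test_that("restructuring matches the hand-computed toy column", {
  cnt <- matrix(c(0, 0, 2, 6, 2, 0, 0), ncol = 1)
  lfq <- trigrowth:::new_lfq_matrix(as.Date("2020-01-01"), 105 + 10 * (0:6),
                                    cnt, 10)
  r <- restructure(lfq, 5)
  expect_equal(r$scores[, 1], c(-0.25, -0.25, 0, 1, 0, -0.25, -0.25))
  # a fully isolated spike is de-emphasized away entirely
  cnt2 <- matrix(c(0, 0, 0, 5, 0, 0, 0), ncol = 1)
  lfq2 <- trigrowth:::new_lfq_matrix(as.Date("2020-01-01"), 105 + 10 * (0:6),
                                     cnt2, 10)
  expect_equal(restructure(lfq2, 5)$scores[, 1], rep(0, 7))
  # uniform counts leave nothing to emphasize
  cnt3 <- matrix(3, nrow = 9, ncol = 2)
  lfq3 <- trigrowth:::new_lfq_matrix(as.Date("2020-01-01") + c(0, 90),
                                     105 + 10 * (0:8), cnt3, 10)
  expect_equal(restructure(lfq3, 5)$scores, matrix(0, 9, 2))
  expect_error(restructure(lfq3, 4), "odd")
})

test_that("restructured columns are zero-sum and floored at -1", {
  for (s in 1:10) {
    cnt <- withr::with_seed(s, matrix(
      rpois(30 * 5, rep(c(0.5, 3, 8, 3, 0.5), each = 6)), 30, 5))
    lfq <- trigrowth:::new_lfq_matrix(as.Date("2020-01-01") + 90 * (0:4),
                                      105 + 10 * (0:29), cnt, 10)
    r <- restructure(lfq)
    expect_lt(max(abs(colSums(r$scores))), 1e-9)
    expect_gte(min(r$scores), -1)
  }
})

test_that("score ceiling and floor behave as the Rn definition implies", {
  # two dates, one clean peak each; other bins zero along the curve
  sc <- matrix(0, 10, 2)
  sc[3, 1] <- 0.8
  sc[5, 2] <- 0.6
  r <- as_restructured(sc, bin_width = 10, first_mid = 105,
                       dates = as.Date(c("2020-05-01", "2020-11-01")))
  # find a curve family through both peaks by brute scanning
  hit_both <- NULL
  for (li in seq(200, 400, 10)) for (k in seq(0.1, 0.9, 0.05)) {
    s <- score_growth_curve(r, list(l_inf = li, k = k, t_anchor = 0.25))
    if (s$esp == s$asp) { hit_both <- s; break }
  }
  expect_false(is.null(hit_both))
  expect_equal(hit_both$rn, 1)
  # a family crossing only zero-score bins scores the Rn floor for ESP = 0
  sc2 <- matrix(0, 10, 2)
  sc2[10, 1] <- 0.5 # peak far above any curve with a tiny l_inf
  r2 <- as_restructured(sc2, bin_width = 10, first_mid = 105,
                        dates = as.Date(c("2020-05-01", "2020-11-01")))
  s2 <- score_growth_curve(r2, list(l_inf = 120, k = 0.05, t_anchor = 0))
  expect_equal(s2$esp, 0)
  expect_equal(s2$rn, 0.1)
  # no peaks at all is an error
  expect_error(
    score_growth_curve(as_restructured(matrix(-0.1, 5, 2)),
                       list(l_inf = 300, k = 0.3, t_anchor = 0)),
    "ASP")
})

test_that("a hand-traced two-date toy matrix gives the hand-summed ESP", {
  # bins mid 105..155; peak run rows 1-2 on date 1 (best 0.9), row 4 on date 2
  sc <- matrix(0, 6, 2)
  sc[1, 1] <- 0.4; sc[2, 1] <- 0.9; sc[4, 1] <- -0.3
  sc[4, 2] <- 0.7; sc[6, 2] <- -0.5
  dates <- as.Date(c("2020-07-01", "2021-07-01"))
  r <- as_restructured(sc, bin_width = 10, first_mid = 105, dates = dates)
  p <- list(l_inf = 200, k = 0.4, t_anchor = 0.5)
  s <- score_growth_curve(r, p)
  # peaks: the run over rows 1-2 on date 1 (best 0.9) and row 4 on date 2
  expect_equal(s$asp, 0.9 + 0.7)
  # the loop-and-set traversal oracle hand-walks every cohort's crossings
  oracle <- naive_elefan_score(r, p)
  expect_equal(s$esp, oracle$esp)
  expect_equal(s$rn, oracle$rn)
})

test_that("scoring agrees with the brute-force traversal oracle", {
  for (case in 1:60) {
    sc <- withr::with_seed(600 + case, {
      m <- matrix(runif(30, -1, 1), 10, 3)
      m[abs(m) < 0.3] <- 0
      m
    })
    if (!any(sc > 0)) next
    r <- as_restructured(sc, bin_width = 10, first_mid = 55,
                         dates = as.Date("2019-04-01") + c(0, 150, 400))
    p <- withr::with_seed(700 + case, list(
      l_inf = runif(1, 100, 250), k = runif(1, 0.05, 0.9),
      t_anchor = runif(1)))
    got <- score_growth_curve(r, p)
    want <- naive_elefan_score(r, p)
    expect_equal(got$esp, want$esp, tolerance = 1e-12, label = paste("case", case))
    expect_equal(got$asp, want$asp, tolerance = 1e-12)
    expect_true(got$rn > 0 && got$rn <= 1)
    expect_lte(got$esp, got$asp)
  }
})

test_that("the genetic algorithm is reproducible and monotone", {
  lfq <- make_clean_lfq(seed = 11)
  st <- ga_settings(pop_size = 20, generations = 12, seed = 5)
  f1 <- ga_optimize(lfq, st)
  f2 <- ga_optimize(lfq, st)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$extra$trace, f2$extra$trace)
  expect_true(all(diff(f1$extra$trace) >= 0)) # elitism
  expect_error(ga_optimize(lfq, ga_settings(bounds = list(
    l_inf = c(500, 400), k = c(0.01, 1), t_anchor = c(0, 1)))),
    "ordered pair")
})

test_that("clean strongly-structured data are recovered by the GA", {
  lfq <- make_clean_lfq(seed = 11, l_inf = 450, k = 0.4)
  fit <- ga_optimize(lfq, ga_settings(pop_size = 40, generations = 60, seed = 12))
  est <- stats::setNames(fit$estimates$estimate, fit$estimates$term)
  expect_lt(abs(est[["l_inf"]] / 450 - 1), 0.10)
  expect_lt(abs(est[["k"]] / 0.4 - 1), 0.15)
  expect_gt(fit$extra$rn, 0.5)
})

test_that("removing the largest fish lowers the recovered asymptotic length", {
  lfq <- make_clean_lfq(seed = 11)
  st <- ga_settings(pop_size = 30, generations = 40, seed = 13)
  full <- ga_optimize(lfq, st)
  keep <- lfq$bin_mids <= 350
  trunc <- trigrowth:::new_lfq_matrix(lfq$dates, lfq$bin_mids[keep],
                                      lfq$counts[keep, ], lfq$bin_width)
  cut <- ga_optimize(trunc, st)
  expect_lt(cut$params$l_inf, full$params$l_inf)
})

test_that("bootstrap produces percentile intervals around the point fit", {
  lfq <- make_clean_lfq(seed = 11)
  st <- ga_settings(pop_size = 30, generations = 50, seed = 6)
  point <- ga_optimize(lfq, st)
  bs <- bootstrap_elefan(lfq, B = 2, settings = st, seed = 8,
                         point_fit = point)
  expect_equal(nrow(bs$extra$replicates), 2)
  bs2 <- bootstrap_elefan(lfq, B = 12, settings = st, seed = 8,
                          point_fit = point)
  est <- bs2$estimates
  expect_true(all(est$conf.low <= est$estimate & est$estimate <= est$conf.high))
  expect_equal(est$estimate, point$estimates$estimate)
  # replicate fits scatter along the l_inf/k ridge of the score surface, but
  # their centre tracks the generating asymptote on clean data
  expect_lt(abs(median(bs2$extra$replicates$l_inf) / 450 - 1), 0.10)
  expect_error(bootstrap_elefan(lfq, B = 1), "at least 2")
})
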