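test_that("priors are the column mean and SD of the literature table", {
  pr <- build_priors()
  expect_equal(pr$l_inf$mean, mean(lit_l_inf))
  expect_equal(pr$l_inf$sd, sd(lit_l_inf))
  expect_equal(pr$k$mean, mean(lit_k))
  expect_equal(pr$k$sd, sd(lit_k))
  expect_equal(pr$t0$mean, mean(lit_t0))
  expect_equal(pr$t0$sd, sd(lit_t0))
  # frozen reference values for the packaged table
  expect_equal(pr$l_inf$mean, 445.4964, tolerance = 1e-6)
  expect_equal(pr$l_inf$sd, 62.65148, tolerance = 1e-6)
  expect_equal(pr$k$mean, 0.2863636, tolerance = 1e-6)
  expect_equal(pr$k$sd, 0.09881323, tolerance = 1e-6)
})

test_that("degenerate literature tables are rejected", {
  expect_error(build_priors(grayling_prior_table()[1, ]), "at least 2 rows")
  two_same <- grayling_prior_table()[c(1, 1), ]
  expect_error(build_priors(two_same), "degenerate")
})

test_that("log_posterior matches an independently coded density", {
  pr <- build_priors()
  # no data: prior only
  th <- c(l_inf = 450, k = 0.3, t0 = 0.1, sigma = 20)
  expect_equal(log_posterior(th, NULL, "vbgm", pr),
               naive_log_posterior(th, NULL, "vbgm", pr), tolerance = 1e-12)
  # one observation exactly on the curve adds the Gaussian mode density
  d1 <- tibble::tibble(age = 2, length = vbgm_length(list(l_inf = 450, k = 0.3, t0 = 0.1), 2))
  expect_equal(
    log_posterior(th, d1, "vbgm", pr) - log_posterior(th, NULL, "vbgm", pr),
    -log(20 * sqrt(2 * pi)), tolerance = 1e-12)
  # oracle agreement on random points for both models
  al <- simulate_age_length(growth_params(500, 0.25, sigma = 30), 15, seed = 31)
  mr <- simulate_mark_recapture(growth_params(540, 0.4, sigma = 12), 15, seed = 32)
  pts <- withr::with_seed(33, replicate(5, c(
    l_inf = runif(1, 300, 700), k = runif(1, 0.05, 0.9),
    t0 = runif(1, -1, 1), sigma = runif(1, 5, 60)), simplify = FALSE))
  for (th in pts) {
    expect_equal(log_posterior(th, al, "vbgm", pr),
                 naive_log_posterior(th, al, "vbgm", pr), tolerance = 1e-10)
    expect_equal(log_posterior(th, mr, "fabens", pr),
                 naive_log_posterior(th, mr, "fabens", pr), tolerance = 1e-10)
  }
  # outside the truncation bounds
  expect_identical(log_posterior(c(l_inf = -1, k = 0.3, t0 = 0, sigma = 5),
                                 NULL, "vbgm", pr), -Inf)
  expect_identical(log_posterior(c(l_inf = 400, k = 0.3, sigma = -5),
                                 NULL, "fabens", pr), -Inf)
  al$length[1] <- NA
  expect_error(log_posterior(th, al, "vbgm", pr), "non-finite")
})

test_that("the retained-draw contract holds exactly", {
  s <- mcmc_settings(1000, 400, 7, chains = 2, seed = 1)
  d <- suppressWarnings(sample_posterior("fabens", NULL, settings = s))
  expect_equal(vapply(d$draws, nrow, 0L), rep((1000L - 400L) %/% 7L, 2))
  expect_error(mcmc_settings(1000, 1000, 1), "burn_in")
  expect_error(mcmc_settings(1000, 100, 0), "thin")
})

test_that("sampling without data recovers the prior", {
  s <- mcmc_settings(20000, 5000, 5, chains = 2, seed = 7)
  d <- sample_posterior("fabens", NULL, settings = s)
  pr <- build_priors()
  all_li <- unlist(lapply(d$draws, function(m) m[, "l_inf"]))
  se <- sd(all_li) / sqrt(d$ess[["l_inf"]])
  expect_lt(abs(mean(all_li) - pr$l_inf$mean), 4 * se)
  expect_equal(sd(all_li), pr$l_inf$sd, tolerance = 0.15)
  # truncation bounds respected in every retained draw
  expect_true(all(unlist(lapply(d$draws, function(m) m[, "k"])) > 0))
})

test_that("abundant precise data dominate the prior", {
  p <- growth_params(tbl_fabens_bayes$l_inf, tbl_fabens_bayes$k, sigma = 5)
  mr <- simulate_mark_recapture(p, n = 800, seed = 41)
  nls_fit <- fit_fabens_nls(mr, ci_method = "wald")
  bay <- fit_fabens_bayes(mr, settings = mcmc_settings(8000, 4000, 4,
                                                       chains = 2, seed = 42))
  expect_equal(bay$params$l_inf, nls_fit$params$l_inf, tolerance = 0.02)
  expect_equal(bay$params$k, nls_fit$params$k, tolerance = 0.02)
})

test_that("posterior intervals tighten as data accumulate", {
  p <- growth_params(536.82, 0.38, sigma = 15)
  big <- simulate_mark_recapture(p, n = 400, seed = 43)
  width <- function(n) {
    f <- suppressWarnings(fit_fabens_bayes(
      big[seq_len(n), ], settings = mcmc_settings(6000, 3000, 3, chains = 2,
                                                  seed = 44)))
    est <- f$estimates
    est$conf.high[est$term == "l_inf"] - est$conf.low[est$term == "l_inf"]
  }
  expect_gt(width(40), width(400))
})

test_that("summarize_posterior reports medians and equal-tailed intervals", {
  mk_draws <- function(m) {
    structure(list(draws = list(m), param_names = colnames(m),
                   model = "fabens", acceptance = 0.3,
                   rhat = stats::setNames(rep(1, ncol(m)), colnames(m)),
                   ess = stats::setNames(rep(nrow(m), ncol(m)), colnames(m)),
                   n_obs = 10L, settings = mcmc_settings(100, 50, 1, 1)),
              class = "posterior_draws")
  }
  z <- withr::with_seed(45, rnorm(10000))
  m <- cbind(l_inf = 500 + 50 * z, k = rep(0.4, 10000), sigma = rep(10, 10000))
  s <- summarize_posterior(mk_draws(m))
  est <- s$estimates
  li <- est[est$term == "l_inf", ]
  expect_equal(li$estimate, li$mean, tolerance = 0.01)
  expect_equal(li$conf.low, 500 - 1.96 * 50, tolerance = 0.05 * 50)
  expect_equal(li$conf.high, 500 + 1.96 * 50, tolerance = 0.05 * 50)
  # constant draws give a zero-width interval
  kk <- est[est$term == "k", ]
  expect_equal(kk$conf.low, kk$conf.high)
  expect_equal(kk$conf.low, 0.4)
})

test_that("split-Rhat flags unmixed chains", {
  good <- withr::with_seed(46, lapply(1:4, function(i) rnorm(500)))
  expect_lt(trigrowth:::split_rhat(good), 1.02)
  bad <- withr::with_seed(47, lapply(1:4, function(i) rnorm(500, mean = i * 3)))
  expect_gt(trigrowth:::split_rhat(bad), 1.5)
})

test_that("posterior covers the generating values across replicates", {
  p <- growth_params(536.82, 0.38, sigma = 15)
  pr <- build_priors()
  hits <- vapply(1:100, function(s) {
    mr <- simulate_mark_recapture(p, n = 121, seed = 1000 + s)
    # short single chains trip the mixing warning by design; silence it
    f <- suppressWarnings(fit_fabens_bayes(
      mr, pr, mcmc_settings(2500, 1000, 2, chains = 1, seed = s)))
    est <- f$estimates
    li <- est[est$term == "l_inf", ]
    kk <- est[est$term == "k", ]
    (li$conf.low <= 536.82 && 536.82 <= li$conf.high) &&
      (kk$conf.low <= 0.38 && 0.38 <= kk$conf.high)
  }, TRUE)
  expect_gte(sum(hits), 90)
})
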