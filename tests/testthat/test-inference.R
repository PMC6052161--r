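test_that("log-likelihood of a perfect fit is the Gaussian normalizer", {
  f <- flat_forcing(do_init = 10)
  p <- list(gpp = 2, er = -1, sigma = 1)
  obs <- simulate_do(p, f)[1:144]
  expect_equal(log_likelihood(p, f, obs), -72 * log(2 * pi),
               tolerance = 1e-9)
  expect_equal(-72 * log(2 * pi), -132.3271, tolerance = 1e-4)
  # noise-free data: truth beats a perturbed GPP
  p2 <- list(gpp = 12, er = -1, sigma = 1)
  expect_gt(log_likelihood(p, f, obs), log_likelihood(p2, f, obs))
  expect_error(log_likelihood(list(gpp = 2, er = -1, sigma = 0), f, obs),
               "sigma")
  expect_error(log_likelihood(p, f, obs[1:100]), "144")
})

test_that("doubling residuals lowers the log-likelihood by 3x the quadratic", {
  f <- day_forcing(par = rep(1, 3), temperature = rep(5, 3), ki = rep(0, 3),
                   o_sat = rep(10, 3), zmix = 1, open_fraction = 0,
                   delta_t = 1 / 3, do_init = 10)
  p <- list(gpp = 0, er = 0, sigma = 0.4)
  mod <- simulate_do(p, f)[1:3]
  r <- c(0.1, -0.25, 0.3)
  quad <- sum(r^2) / (2 * 0.4^2)
  expect_equal(log_likelihood(p, f, mod + r) - log_likelihood(p, f, mod + 2 * r),
               3 * quad, tolerance = 1e-10)
})

test_that("log posterior adds the prior and respects its support", {
  f <- flat_forcing()
  obs <- simulate_do(list(gpp = 2, er = -3), f)[1:144]
  expect_identical(log_posterior(list(gpp = 2, er = -3, sigma = -1), f, obs),
                   -Inf)
  # near-flat priors: posterior differences equal likelihood differences
  flat <- prior_config(gpp_sd = 1e6, er_sd = 1e6, sigma_sd = 1e6)
  p1 <- list(gpp = 2, er = -3, sigma = 0.3)
  p2 <- list(gpp = 2.4, er = -2.2, sigma = 0.3)
  expect_equal(
    log_posterior(p1, f, obs, flat) - log_posterior(p2, f, obs, flat),
    log_likelihood(p1, f, obs) - log_likelihood(p2, f, obs),
    tolerance = 1e-6)
  # prior ratio against a direct density computation
  pri <- prior_config()
  lr <- log_posterior(p1, f, obs, pri) - log_posterior(p2, f, obs, pri) -
    (log_likelihood(p1, f, obs) - log_likelihood(p2, f, obs))
  oracle <- dnorm(2, 3, 10, log = TRUE) + dnorm(-3, -5, 10, log = TRUE) -
    dnorm(2.4, 3, 10, log = TRUE) - dnorm(-2.2, -5, 10, log = TRUE)
  expect_equal(lr, oracle, tolerance = 1e-10)
})

test_that("a flat target accepts every proposal", {
  cfg <- mcmc_config(iterations = 500, burn_in = 0,
                     proposal_sd = c(a = 1), init = c(a = 0),
                     seed = 4, tune = FALSE)
  chain <- metropolis_sample(cfg, function(th) 0)
  expect_equal(chain$acceptance_rate, 1)
})

test_that("the sampler is bit-reproducible under a fixed seed", {
  cfg <- mcmc_config(iterations = 2000, burn_in = 200,
                     proposal_sd = c(x = 0.5), init = c(x = 1), seed = 11)
  target <- function(th) -0.5 * th[[1]]^2
  c1 <- metropolis_sample(cfg, target)
  c2 <- metropolis_sample(cfg, target)
  expect_identical(c1$samples, c2$samples)
  expect_identical(c1$log_posterior, c2$log_posterior)
})

test_that("the sampler reproduces a standard normal target", {
  cfg <- mcmc_config(iterations = 50000, burn_in = 1000,
                     proposal_sd = c(x = 2.4), init = c(x = 0), seed = 2,
                     tune = FALSE)
  chain <- metropolis_sample(cfg, function(th) -0.5 * th[[1]]^2)
  kept <- chain$samples[-(1:1000), 1]
  expect_equal(mean(kept), 0, tolerance = 0.05)
  expect_equal(sd(kept), 1, tolerance = 0.05)
})

test_that("initialization outside the target support is an error", {
  cfg <- mcmc_config(iterations = 100, burn_in = 10,
                     proposal_sd = c(x = 1), init = c(x = -2), seed = 1)
  expect_error(metropolis_sample(cfg, function(th) {
    if (th[[1]] < 0) -Inf else 0
  }), "initialization")
})

test_that("chain summaries: medians, quantiles and split R-hat", {
  # degenerate chain: undefined R-hat, flagged as unconverged
  flatchain <- matrix(5, nrow = 100, ncol = 1, dimnames = list(NULL, "gpp"))
  s <- summarize_chain(flatchain, burn_in = 10)
  expect_equal(s$median, 5)
  expect_true(is.na(s$rhat))
  expect_false(attr(s, "converged"))
  # arithmetic check
  s2 <- summarize_chain(matrix(1:1000, ncol = 1), burn_in = 0)
  expect_equal(s2$median, 500.5)
  # quantiles against an independent sort-based (type-7) computation
  withr::local_seed(6)
  x <- matrix(rnorm(4000), ncol = 2, dimnames = list(NULL, c("a", "b")))
  s3 <- summarize_chain(x, burn_in = 500)
  kept <- x[501:2000, ]
  type7 <- function(v, p) {
    v <- sort(v)
    h <- (length(v) - 1) * p + 1
    lo <- floor(h)
    v[lo] + (h - lo) * (v[min(lo + 1, length(v))] - v[lo])
  }
  for (j in 1:2) {
    expect_equal(s3$lower[j], type7(kept[, j], 0.025), tolerance = 1e-12)
    expect_equal(s3$median[j], type7(kept[, j], 0.5), tolerance = 1e-12)
    expect_equal(s3$upper[j], type7(kept[, j], 0.975), tolerance = 1e-12)
  }
  expect_error(summarize_chain(flatchain, burn_in = 100), "burn_in")
})

test_that("summaries ignore whatever happened during burn-in", {
  withr::local_seed(13)
  post <- matrix(rnorm(3000), ncol = 3,
                 dimnames = list(NULL, c("gpp", "er", "sigma")))
  garbled <- post
  garbled[1:200, ] <- 1e6
  expect_equal(summarize_chain(post, 200), summarize_chain(garbled, 200))
})

test_that("fit_day recovers known parameters with calibrated intervals", {
  f <- sunny_forcing()
  truth <- list(gpp = 3, er = -4, sigma = 0.05)
  obs <- simulate_do_noisy(truth, f, seed = 31)[1:144]
  fit <- fit_day(f, obs, mcmc_config(seed = 5), pond_id = "P1",
                 date = as.Date("2016-04-01"))
  expect_s3_class(fit, "day_fit")
  expect_gt(fit$gpp, 2.7)
  expect_lt(fit$gpp, 3.3)
  expect_gt(fit$er, -4.4)
  expect_lt(fit$er, -3.6)
  expect_true(fit$retained)
  expect_gt(fit$r2, 0.9)
  # bit-reproducible under the same seed
  fit2 <- fit_day(f, obs, mcmc_config(seed = 5), pond_id = "P1",
                  date = as.Date("2016-04-01"))
  expect_identical(fit$summary, fit2$summary)
})

test_that("fit_day's fast likelihood agrees with the direct log posterior", {
  f <- sunny_forcing(open_fraction = 0.5)
  obs <- simulate_do_noisy(list(gpp = 2, er = -3, sigma = 0.05), f,
                           seed = 44)[1:144]
  fit <- fit_day(f, obs, fast_mcmc(seed = 3), keep_chain = TRUE)
  # replay a handful of visited states through the public log_posterior
  f$do_init <- obs[1]
  rows <- seq(400, 1400, by = 250)
  for (i in rows) {
    th <- fit$chain$samples[i, ]
    f2 <- f
    f2$do_init <- th[["do_init"]]
    direct <- log_posterior(list(gpp = th[["gpp"]], er = th[["er"]],
                                 sigma = th[["sigma"]]), f2, obs)
    expect_equal(fit$chain$log_posterior[i], direct, tolerance = 1e-6)
  }
})

test_that("a dark day leaves GPP prior-dominated and wide", {
  f <- flat_forcing(par = rep(0, 144), ki = rep(1, 144),
                    o_sat = rep(12, 144), do_init = 11)
  obs <- simulate_do_noisy(list(gpp = 0, er = -2, sigma = 0.05), f,
                           seed = 17)[1:144]
  fit <- fit_day(f, obs, mcmc_config(seed = 2))
  s <- fit$summary
  width <- s$upper[s$parameter == "gpp"] - s$lower[s$parameter == "gpp"]
  # an order of magnitude wider than an identifiable day (~0.2), and the
  # convergence flag governs whether such a day is retained
  expect_gt(width, 2)
  if (!fit$converged) expect_true("no_convergence" %in% fit$qc_flags)
  expect_equal(fit$retained, length(fit$qc_flags) == 0)
})

test_that("quality filters flag and drop days exactly at the documented rules", {
  f <- sunny_forcing()
  obs <- simulate_do_noisy(list(gpp = 3, er = -4, sigma = 0.05), f,
                           seed = 8)[1:144]
  fit <- fit_day(f, obs, fast_mcmc(seed = 4))
  qc <- qc_config()
  # negative posterior-median GPP is removed
  neg <- fit
  neg$gpp <- -0.5
  neg <- filter_day(neg, qc)
  expect_true("negative_gpp" %in% neg$qc_flags)
  expect_false(neg$retained)
  # boundary values are kept (inclusive thresholds)
  edge <- fit
  edge$r2 <- qc$r2_min
  edge$rmse <- qc$rmse_max
  edge <- filter_day(edge, qc)
  expect_false("poor_fit" %in% edge$qc_flags)
  bad <- fit
  bad$r2 <- 0.49
  bad <- filter_day(bad, qc)
  expect_true("poor_fit" %in% bad$qc_flags)
  # healthy fit is retained
  good <- filter_day(fit, qc)
  expect_true(good$retained)
  expect_gt(good$r2, 0.95)
})
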