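make_ac <- function(values, lags = 10:100, max_lag = 100) {
  r <- numeric(max_lag)
  r[lags] <- values
  structure(list(r = r, lags = seq_len(max_lag), fit_lags = as.integer(lags),
                 sigma = stats::sd(values), n_points = 195L),
            class = "autocorr_series")
}

test_that("the damped sine evaluates its closed-form fixed points", {
  expect_equal(damped_sine(0, 11, 0.8, 30), 0.8)
  expect_equal(damped_sine(20, 20, 1, 20), 0.5)      # one cycle, one half-life
  expect_equal(damped_sine(10, 20, 1, 1e12), -1, tolerance = 1e-6)
  expect_error(damped_sine(5, -1, 1, 10), "positive")
  expect_error(damped_sine(5, 10, 1, 0), "positive")
})

test_that("autocorrelation matches per-lag Pearson correlation and flags degenerate input", {
  set.seed(8)
  v <- rpois(195, 40)
  ac <- autocorrelate(structure(v, spacings = 6:200, class = "smoothed_series"))
  expect_length(ac$r, 100L)
  expect_true(all(abs(ac$r) <= 1))
  expect_identical(ac$fit_lags, 10:100)
  for (x in c(1, 7, 33, 100))
    expect_equal(ac$r[x], cor(v[1:(195 - x)], v[(1 + x):195]), label = x)
  # cosine self-similarity peaks at its own period
  vc <- cos(2 * pi * (6:200) / 11)
  acc <- autocorrelate(structure(vc, spacings = 6:200, class = "smoothed_series"))
  expect_equal(which.max(acc$r[8:14]) + 7L, 11L)
  expect_error(autocorrelate(rep(3, 195)), "constant")
})

test_that("the grid fit recovers an on-grid damped sine exactly", {
  x <- 10:100
  f <- fit_damped_sine(make_ac(damped_sine(x, 11, 0.40, 50)))
  expect_equal(coef(f), c(period = 11, amplitude = 0.40, half_life = 50))
  expect_lt(f$chi2, 1e-10)
  expect_lt(f$gdf, 1e-8)
  expect_true(f$significant)
})

test_that("the grid fit reaches grid resolution on an off-schedule curve", {
  # HL = 30 is on the coarse grid but the coarse amplitude cap (120% of the
  # observed maximum) undershoots the true A, so refinement re-approaches the
  # truth at the resolution of the refinement steps
  x <- 10:100
  f <- fit_damped_sine(make_ac(damped_sine(x, 11, 0.40, 30)))
  expect_lt(abs(f$period - 11), 0.011)
  expect_lt(abs(f$amplitude - 0.40), 0.021)
  expect_lt(abs(f$half_life - 30), 0.8)
  expect_lt(f$gdf, 0.01)
})

test_that("goodness of fit is chi^2 / sigma with quadratic residual scaling", {
  set.seed(2)
  obs <- rnorm(50); pred <- rnorm(50); sigma <- 0.3
  expect_equal(goodness_of_fit(obs, obs, sigma), 0)
  g1 <- goodness_of_fit(obs, pred, sigma)
  expect_equal(g1, sum((obs - pred)^2) / sigma)
  g2 <- goodness_of_fit(obs, obs + 2 * (pred - obs), sigma)
  expect_equal(g2, 4 * g1)
  expect_error(goodness_of_fit(obs, pred, 0), "positive")
})

test_that("strength is ln(GdF/A), missing when undefined", {
  expect_equal(periodicity_strength(1, 1), 0)
  expect_equal(periodicity_strength(exp(1), 1), 1)
  expect_true(is.na(periodicity_strength(1, 0)))
  expect_true(is.na(periodicity_strength(0, 1)))
})

test_that("the significance threshold is a strict GdF < 3.0", {
  expect_true(is_periodic(0.539))
  expect_false(is_periodic(5.15))
  expect_false(is_periodic(3.0))
})

test_that("period-constrained fits never beat the free fit", {
  set.seed(77)
  x <- 10:100
  for (rep in 1:5) {
    obs <- damped_sine(x, 9 + 3 * runif(1), 0.4, 30) + rnorm(91, sd = 0.05)
    ac <- make_ac(obs)
    free <- fit_damped_sine(ac)
    at_free <- fit_damped_sine(ac, lambda = free$period)
    expect_equal(at_free$chi2, free$chi2, tolerance = 1e-9)
    fixed <- fit_damped_sine(ac, lambda = free$period + 0.7)
    expect_gte(fixed$chi2, free$chi2)
  }
})

test_that("scaling the series scales the amplitude and keeps the period", {
  set.seed(13)
  x <- 10:100
  obs <- damped_sine(x, 10.5, 0.3, 35) + rnorm(91, sd = 0.03)
  f1 <- fit_damped_sine(make_ac(obs))
  f2 <- fit_damped_sine(make_ac(2 * obs))
  expect_equal(f2$period, f1$period, tolerance = 0.02)
  expect_lt(abs(f2$amplitude - 2 * f1$amplitude), 0.1)
})

test_that("grid refinement never increases chi^2", {
  set.seed(21)
  x <- 10:100
  for (rep in 1:10) {
    obs <- rnorm(91, sd = 0.1)
    f <- periodscope:::fit_core(obs, x)
    expect_lte(f$chi2, f$coarse$chi2 + 1e-12)
  }
})

test_that("model methods are mutually consistent on a fitted genome", {
  fit <- planted_strong()$fit
  expect_equal(unname(coef(fit)["period"]), fit$period)
  expect_equal(fitted(fit),
               damped_sine(10:100, fit$period, fit$amplitude, fit$half_life))
  expect_equal(residuals(fit) + fitted(fit), fit$autocorr$r[10:100])
  expect_equal(fit$gdf, sum(residuals(fit)^2) / fit$sigma)
  expect_output(print(fit), "period")
  expect_output(print(summary(fit)), "residuals")
  sims <- simulate(fit, nsim = 2, seed = 3, length = 2e4)
  expect_length(sims, 2L)
  expect_equal(sims[[1]]$truth$period, fit$period)
})

test_that("the permutation null is reproducible, Gaussian-summarized, and separates signal from noise", {
  fit <- planted_strong()$fit
  n1 <- randomization_null(fit, n_iter = 150, seed = 5)
  n2 <- randomization_null(fit, n_iter = 150, seed = 5)
  expect_identical(n1$samples, n2$samples)
  expect_gt(n1$sd, 0)
  expect_gt(n1$p_gaussian, 0); expect_lt(n1$p_gaussian, 1)
  expect_gt(n1$p_empirical, 0); expect_lte(n1$p_empirical, 1)
  # a strongly planted genome beats every permutation
  expect_true(all(n1$samples > fit$gdf))
  expect_lt(n1$p_gaussian, 1e-6)
  expect_error(randomization_null(fit, n_iter = 1), ">= 2")
  # a non-periodic random genome never reaches the null's significant tail:
  # the genuine series carries serial correlation from the 3-bp smoothing
  # that permutation destroys, so its GdF is, if anything, inflated relative
  # to the null and the test is conservative
  rfit <- period_fit(random_genome(1e5, seed = 41))
  rn <- randomization_null(rfit, n_iter = 150, seed = 6)
  expect_gt(rfit$gdf, quantile(rn$samples, 0.01))
  expect_false(rfit$significant)
})
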