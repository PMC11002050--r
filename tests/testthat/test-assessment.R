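# Conventional metrics, Z-score charts and tolerance-interval
# classification.

test_that("metrics reproduce a hand-evaluated example", {
  p <- prediction_set(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
  m <- compute_metrics(p)
  # frozen values from direct evaluation of the defining formulas
  expect_equal(m$rmse, sqrt(0.1 / 4), tolerance = 1e-10)   # 0.1581139
  expect_equal(m$r2, 0.98, tolerance = 1e-10)
  expect_equal(m$rpd, sqrt(5 / 3) / sqrt(0.1 / 4), tolerance = 1e-6)
  expect_equal(round(m$rpd, 4), 8.165)
})

test_that("perfect prediction flags RPD as undefined", {
  m <- compute_metrics(prediction_set(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(m$rmse, 0)
  expect_equal(m$r2, 1)
  expect_false(m$rpd_defined)
  m2 <- compute_metrics(prediction_set(c(2, 2, 2), c(1, 2, 3)))
  expect_false(m2$r2_defined)
  expect_true(is.na(m2$r2))
})

test_that("RPD times RMSE equals the reference SD on random instances", {
  for (seed in 1:1000) {
    p <- random_prediction_set(n = 5 + seed %% 20, seed = seed)
    m <- compute_metrics(p)
    expect_equal(m$rpd * m$rmse, stats::sd(p$actual), tolerance = 1e-10)
  }
})

test_that("sigma_max reproduces the policy table's worked values", {
  specs <- default_tolerance_specs()
  expect_equal(sigma_max(2.0, specs$N), 0.25)
  expect_equal(sigma_max(30, specs$N), 3.0)
  expect_equal(sigma_max(0.4, specs$P2O5), 0.075)
  expect_equal(sigma_max(10, specs$P2O5), 1.5)
  # vectorised, with the threshold included in the constant regime
  expect_equal(sigma_max(c(2.5, 2.6), specs$N), c(0.25, 0.26))
})

test_that("linear-mode Z-scores follow the defining formula", {
  specs <- default_tolerance_specs()
  z <- compute_zscores(prediction_set(30, 33), specs$N, mode = "linear")
  expect_equal(z$z, 1.0)
  zp <- compute_zscores(prediction_set(c(10, 20), c(10, 20)), specs$N)
  expect_equal(zp$z, c(0, 0))
  expect_equal(zp$fraction_inside, 1)
  expect_equal(z$coverage_factor, 1.96)
  expect_equal(z$limits_sigma, c(2, 3))
})

test_that("log2-mode Z-scores use the delta-method sigma transfer", {
  specs <- default_tolerance_specs()
  y <- c(10, 30); yp <- c(11, 28)
  z <- compute_zscores(prediction_set(y, yp), specs$N, mode = "log2")
  sig_lin <- sigma_max(y, specs$N)
  oracle <- (log2(yp) - log2(y)) / (sig_lin / (y * log(2)))
  expect_equal(z$z, oracle, tolerance = 1e-12)
  expect_error(compute_zscores(prediction_set(c(1, -2), c(1, 1)), specs$N,
                               mode = "log2"), "indices: 2")
})

test_that("the empirical 95% band uses the 1.96 coverage factor", {
  p <- random_prediction_set(50, seed = 99)
  z <- compute_zscores(p, default_tolerance_specs()$N)
  expect_equal(z$limit_95, 1.96 * stats::sd(z$z), tolerance = 1e-12)
  expect_equal(z$inside, abs(z$z) <= z$limit_95)
  expect_equal(z$fraction_inside, mean(z$inside))
})

test_that("tolerance bands reproduce the nitrogen worked example", {
  spec_n <- default_tolerance_specs()$N
  r <- tolerance_bands(prediction_set(30, 32), spec_n)
  expect_equal(r$epsilon, 3.0)
  expect_equal(r$all, 27)
  expect_equal(r$aul, 33)
  expect_true(r$inside)
})

test_that("35 of 37 inside gives the published 94.6 percent", {
  # 35 predictions well inside their band, 2 far outside
  y <- rep(30, 37)
  yp <- c(rep(31, 35), 40, 40)
  r <- tolerance_bands(prediction_set(y, yp), default_tolerance_specs()$N)
  expect_equal(r$n_inside, 35)
  expect_equal(round(r$percent_inside, 1), 94.6)
})

test_that("bands are symmetric and scale-invariant in the proportional regime", {
  spec_n <- default_tolerance_specs()$N
  p <- random_prediction_set(60, seed = 5)
  r <- tolerance_bands(p, spec_n)
  expect_equal(r$aul - p$actual, r$epsilon)
  expect_equal(p$actual - r$all, r$epsilon)
  expect_equal(p$actual[r$order], sort(p$actual))
  # epsilon strictly increases with the actual value above the threshold
  y_hi <- sort(p$actual[p$actual > spec_n$c0])
  eps_hi <- ifelse(y_hi <= spec_n$c0, spec_n$eps_low, spec_n$k_eps * y_hi)
  expect_true(all(diff(eps_hi) > 0))
  # rescaling (Yi, Yi') by a positive constant keeps the classification,
  # provided everything stays in the proportional regime
  hi <- p$actual > spec_n$c0 * 2
  p_hi <- prediction_set(p$actual[hi], p$predicted[hi])
  scaled <- prediction_set(3.7 * p$actual[hi], 3.7 * p$predicted[hi])
  expect_equal(tolerance_bands(scaled, spec_n)$inside,
               tolerance_bands(p_hi, spec_n)$inside)
})

test_that("band edges are inside and a degenerate band needs exact equality", {
  spec_n <- default_tolerance_specs()$N
  y <- c(2, 30)
  r_edge <- tolerance_bands(prediction_set(y, y + c(0.5, 3.0)), spec_n)
  expect_true(all(r_edge$inside))  # predictions exactly at AUL
  spec0 <- tolerance_spec("N", c0 = 2.5, eps_low = 1e-300, k_eps = 1e-300,
                          sigma_low = 0.25, sigma_coef = 0.1)
  r0 <- tolerance_bands(prediction_set(c(2, 30), c(2, 30.001)), spec0)
  expect_equal(r0$inside, c(TRUE, FALSE))
})

test_that("vectorised classification agrees with the brute-force oracle", {
  spec_n <- default_tolerance_specs()$N
  for (seed in 1:1000) {
    p <- random_prediction_set(n = 3 + seed %% 40, seed = seed,
                               spread = 1 + (seed %% 5))
    expect_identical(tolerance_bands(p, spec_n)$n_inside,
                     as.integer(classification_oracle(p, spec_n)))
  }
  empty <- prediction_set(numeric(0), numeric(0))
  expect_equal(classification_oracle(empty, spec_n), 0L)
  expect_equal(tolerance_bands(empty, spec_n)$n_inside, 0L)
})

test_that("Z-score and tolerance classifications agree at 1.96 sigma bands", {
  specs <- default_tolerance_specs()$N
  wide <- tolerance_spec("N", c0 = 2.5, eps_low = 1.96 * 0.25,
                         k_eps = 1.96 * 0.1, sigma_low = 0.25,
                         sigma_coef = 0.1)
  for (seed in c(3, 17, 88)) {
    p <- random_prediction_set(80, seed = seed)
    z <- compute_zscores(p, specs, mode = "linear")
    t <- tolerance_bands(p, wide)
    expect_equal(abs(z$z) <= 1.96, t$inside)
  }
})

test_that("tolerance_spec rejects nonpositive limits", {
  expect_error(tolerance_spec("N", c0 = 0, eps_low = 1, k_eps = 0.1,
                              sigma_low = 0.1, sigma_coef = 0.1), "> 0")
  expect_error(tolerance_spec("N", c0 = 1, eps_low = -1, k_eps = 0.1,
                              sigma_low = 0.1, sigma_coef = 0.1), "> 0")
})
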