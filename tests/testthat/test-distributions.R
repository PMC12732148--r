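test_that("interval normalization repairs the corrupted published rows", {
  # consistent printed interval kept verbatim
  expect_equal(normalize_interval(0.833, 0.750, 0.916), c(0.750, 0.916))
  # inverted bounds with the mean repeated as "lower"
  expect_equal(normalize_interval(0.30, 0.30, 0.27), c(0.27, 0.33))
  expect_equal(normalize_interval(0.128, 0.128, 0.115),
               c(0.115, 0.128 * 1.1))
  # bounds copied from an adjacent row, both below the mean
  expect_equal(normalize_interval(0.17, 0.128, 0.115), c(0.115, 0.187))
  # clerical row discards the printed bounds entirely
  expect_equal(normalize_interval(400, 29042, 35496, clerical = TRUE),
               c(360, 440))
  # result always brackets the mean
  for (i in seq_len(nrow(bp$uncertainty))) {
    r <- bp$uncertainty[i, ]
    b <- normalize_interval(r$mean, r$lower, r$upper, r$clerical)
    expect_true(b[1] <= r$mean && r$mean <= b[2], info = r$parameter_id)
  }
})

test_that("beta fit matches the mean and the 95% interval width", {
  # symmetric case forces alpha == beta
  sh <- fit_beta_from_interval(0.5, 0.4, 0.6)
  expect_equal(unname(sh["alpha"]), unname(sh["beta"]))
  expect_equal(unname(sh["alpha"] / sum(sh)), 0.5, tolerance = 1e-12)

  # PET/CT sensitivity row: mean and sd recovered exactly
  sh <- fit_beta_from_interval(0.833, 0.750, 0.916)
  m <- sh["alpha"] / sum(sh)
  v <- prod(sh) / (sum(sh)^2 * (sum(sh) + 1))
  expect_equal(unname(m), 0.833, tolerance = 1e-9)
  expect_equal(unname(sqrt(v)), 0.166 / 3.92, tolerance = 1e-9)

  # a wide interval near the support edge implies more variance than a
  # beta with this mean can carry
  expect_error(fit_beta_from_interval(0.01, 0, 0.4), "infeasible")
  expect_error(fit_beta_from_interval(1, 0.9, 1), "fixed")
  expect_error(fit_beta_from_interval(0.5, 0.5, 0.5), "fixed")
})

test_that("fitted quantiles land near the normalized bounds (beta rows)", {
  rows <- bp$uncertainty[bp$uncertainty$family == "beta", ]
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    b <- normalize_interval(r$mean, r$lower, r$upper, r$clerical)
    sh <- fit_beta_from_interval(r$mean, b[1], b[2])
    # oracle: numerical CDF inversion of the fitted distribution
    expect_lt(abs(qbeta(0.025, sh["alpha"], sh["beta"]) - b[1]), 0.03,
              label = paste(r$parameter_id, "lower quantile gap"))
    expect_lt(abs(qbeta(0.975, sh["alpha"], sh["beta"]) - b[2]), 0.03,
              label = paste(r$parameter_id, "upper quantile gap"))
  }
})

test_that("lognormal fit is moment-matched on the natural scale", {
  ls <- fit_lognormal_from_interval(580, 522, 638)
  expect_equal(unname(exp(ls["mu"] + ls["sigma"]^2 / 2)), 580,
               tolerance = 1e-6)
  # zero-variance limit degenerates to the mean
  ls0 <- fit_lognormal_from_interval(400, 400, 400)
  expect_equal(unname(ls0["sigma"]), 0)
  expect_equal(unname(exp(ls0["mu"])), 400)
  expect_error(fit_lognormal_from_interval(-1, 1, 2), "positive mean")

  # Monte-Carlo oracle: sample mean over 1e6 draws within 0.5%
  ls <- fit_lognormal_from_interval(24604, 22144, 27064)
  set.seed(2024)
  draws <- rlnorm(1e6, ls["mu"], ls["sigma"])
  expect_equal(mean(draws), 24604, tolerance = 0.005)
  expect_true(all(draws > 0))
})

test_that("every published distribution row refits to its printed mean", {
  unc <- bp$uncertainty
  for (i in seq_len(nrow(unc))) {
    r <- unc[i, ]
    b <- normalize_interval(r$mean, r$lower, r$upper, r$clerical)
    analytic_mean <- switch(r$family,
      beta = {
        sh <- fit_beta_from_interval(r$mean, b[1], b[2])
        unname(sh["alpha"] / sum(sh))
      },
      lognormal = {
        ls <- fit_lognormal_from_interval(r$mean, b[1], b[2])
        unname(exp(ls["mu"] + ls["sigma"]^2 / 2))
      },
      uniform = mean(b),
      fixed = r$mean)
    expect_equal(analytic_mean, r$mean, tolerance = 1e-6,
                 info = r$parameter_id)
  }
})

test_that("sampled draws respect distribution support", {
  sh <- fit_beta_from_interval(0.17, 0.153, 0.187)
  set.seed(7)
  d <- rbeta(1e5, sh["alpha"], sh["beta"])
  expect_true(all(d >= 0 & d <= 1))
  ls <- fit_lognormal_from_interval(32269, 29042, 35496)
  d <- rlnorm(1e5, ls["mu"], ls["sigma"])
  expect_true(all(d > 0))
})
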