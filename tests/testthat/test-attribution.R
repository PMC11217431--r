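test_that("closed-form attributable fractions are honoured", {
  m <- fixture_fixed_model(mmt = 40)
  # all lags at the reference: zero retained sum, AF = 0
  af0 <- case_af(m, rep(40, 3))
  expect_equal(af0$af, 0, tolerance = 1e-12)
  expect_equal(af0$retained_sum, 0, tolerance = 1e-12)
  # AF = 1 - exp(-s): s = ln 2 -> 1/2; s = ln 0.9 -> 1 - 1/0.9 (protective)
  expect_equal(1 - exp(-log(2)), 0.5)
  s <- case_af(m, c(75, 80, 85))$retained_sum
  expect_equal(case_af(m, c(75, 80, 85))$af, 1 - exp(-s), tolerance = 1e-15)
})

test_that("case AF matches the brute-force reconstruction (Eq.-level oracle)", {
  m <- fixture_fixed_model(mmt = 40, seed = 31)
  set.seed(32)
  X <- matrix(runif(1000 * 3, 0, 100), 1000, 3)
  for (r in seq_len(nrow(X))) {
    expect_equal(case_af(m, X[r, ])$af, oracle_case_af(m, X[r, ]),
                 tolerance = 1e-12)
  }
  # per-lag restricted variants against the same oracle
  for (r in sample(1000, 50)) {
    expect_equal(case_af(m, X[r, ], "heat", restrict_by = "per_lag")$af,
                 oracle_case_af(m, X[r, ], side = "heat"), tolerance = 1e-12)
    expect_equal(case_af(m, X[r, ], "cold", restrict_by = "per_lag")$af,
                 oracle_case_af(m, X[r, ], side = "cold"), tolerance = 1e-12)
  }
})

test_that("a single hand-computed case matches to machine precision", {
  spec <- cross_basis_spec()
  beta <- seq(0.01, 0.06, by = 0.01)
  m <- exposure_response_model(spec, beta, diag(1e-4, 6), mmt_percentile = 50)
  x <- c(90, 10, 55)
  # hand computation: sum over lags of the centered tensor contraction
  V0 <- ns_basis(50, spec$var_spec)
  G <- ns_basis(0:2, spec$lag_basis_spec)
  s <- 0
  for (k in 1:3) {
    v <- ns_basis(x[k], spec$var_spec) - V0
    for (i in 1:2) for (j in 1:3) s <- s + beta[(j - 1) * 2 + i] * v[i] * G[k, j]
  }
  expect_equal(case_af(m, x)$af, unname(1 - exp(-s)), tolerance = 1e-12)
})

test_that("burden components decompose exactly under case-day assignment", {
  m <- fixture_fixed_model(mmt = 45, seed = 33)
  set.seed(34)
  X <- matrix(runif(600 * 3, 0, 100), 600, 3)
  b <- burden_from_exposures(m, X)
  tab <- setNames(b$table$an, b$table$component)
  expect_identical(unname(tab["heat"] + tab["cold"]), unname(tab["total"]))
  expect_identical(unname(tab["mild_heat"] + tab["moderate_heat"] +
                            tab["extreme_heat"]), unname(tab["heat"]))
  expect_identical(unname(tab["extreme_cold"] + tab["moderate_cold"] +
                            tab["mild_cold"]), unname(tab["cold"]))
  expect_identical(unname(attr(b, "additivity_gap")), 0)
})

test_that("one-sided cases are exactly additive under per-lag zeroing too", {
  m <- fixture_fixed_model(mmt = 45, seed = 35)
  set.seed(36)
  Xh <- matrix(runif(200 * 3, 50, 100), 200, 3)   # all lags above the MMT
  b <- burden_from_exposures(m, Xh, restrict_by = "per_lag")
  tab <- setNames(b$table$an, b$table$component)
  expect_equal(unname(tab["heat"]), unname(tab["total"]), tolerance = 1e-12)
  expect_identical(unname(tab["cold"]), 0)
  # mixed cases: the signed discrepancy is reported, not hidden
  Xm <- matrix(runif(200 * 3, 0, 100), 200, 3)
  bm <- burden_from_exposures(m, Xm, restrict_by = "per_lag")
  expect_true(is.finite(attr(bm, "additivity_gap")))
})

test_that("a null model attributes nothing in either scenario", {
  spec <- cross_basis_spec()
  m <- exposure_response_model(spec, rep(0, 6), diag(0, 6),
                               mmt_percentile = 50)
  X <- matrix(runif(50 * 3, 0, 100), 50, 3)
  bf <- burden_from_exposures(m, X, "factual")
  bc <- burden_from_exposures(m, X, "counterfactual")
  expect_true(all(bf$table$an == 0))
  ex <- climate_excess(bf, bc)
  expect_true(all(ex$table$an_excess == 0))
})

test_that("identical scenarios difference to exactly zero", {
  m <- fixture_fixed_model(mmt = 40, seed = 37)
  set.seed(38)
  X <- matrix(runif(300 * 3, 0, 100), 300, 3)
  ex <- climate_excess(burden_from_exposures(m, X, "factual"),
                       burden_from_exposures(m, X, "counterfactual"))
  expect_true(all(ex$table$an_excess == 0))
  expect_true(all(ex$table$af_excess == 0))
})

test_that("scope mismatches between scenarios are refused", {
  m <- fixture_fixed_model(mmt = 40)
  X <- matrix(runif(30 * 3, 0, 100), 30, 3)
  bf <- burden_from_exposures(m, X, "factual", outcome = "neonatal")
  bc <- burden_from_exposures(m, X[-1, ], "counterfactual",
                              outcome = "neonatal")
  expect_error(climate_excess(bf, bc), "mismatched")
})

test_that("the share identity links burden increase and attributable share", {
  # factual heat burden 1.46x the counterfactual implies a 31.5% share
  expect_equal(1 - 1 / 1.46, 0.315, tolerance = 0.001)
  m <- fixture_fixed_model(mmt = 40, seed = 39)
  set.seed(40)
  X <- matrix(runif(400 * 3, 0, 100), 400, 3)
  Xc <- pmax(X - 4, 0.01)   # uniformly cooler counterfactual
  ex <- climate_excess(burden_from_exposures(m, X, "factual"),
                       burden_from_exposures(m, Xc, "counterfactual"))
  t <- ex$table
  i <- t$component == "heat"
  expect_equal(t$share_of_factual[i],
               1 - t$an_counterfactual[i] / t$an_factual[i],
               tolerance = 1e-12)
})

test_that("attributable rates scale the mortality rate by the fraction", {
  rates <- data.frame(country = c("SYN", "OTH"),
                      births = c(1e6, 2e6),
                      neonatal_mortality_rate = c(2000, 3000),
                      very_early_share = c(0.375, 0.4))
  expect_equal(attributable_rate(0.01, rates, "SYN"), 20)
  expect_equal(attributable_rate(0, rates, "SYN"), 0)
  expect_equal(attributable_rate(0.01, rates, "SYN", "very_early"), 7.5)
  expect_error(attributable_rate(0.01, rates, "NOPE"), "not in rate table")
})

test_that("Monte Carlo collapses to the point estimate with zero covariance", {
  spec <- cross_basis_spec()
  set.seed(41)
  beta <- rnorm(6, 0, 0.2)
  m <- exposure_response_model(spec, beta, diag(0, 6), mmt_percentile = 50)
  X <- matrix(runif(100 * 3, 0, 100), 100, 3)
  Xc <- pmax(X - 3, 0.01)
  mc <- monte_carlo_ui(m, list(factual = X, counterfactual = Xc),
                       n_draws = 200, seed = 5)
  expect_equal(mc$an_lo, mc$an, tolerance = 1e-10)
  expect_equal(mc$an_hi, mc$an, tolerance = 1e-10)
  # and the point estimate equals the deterministic burden
  bf <- burden_from_exposures(m, X, "factual")
  expect_equal(mc$an[mc$quantity == "factual.total"],
               bf$table$an[bf$table$component == "total"], tolerance = 1e-10)
})

test_that("Monte Carlo draws are seed-reproducible", {
  m <- fixture_fixed_model(mmt = 45, seed = 43)
  set.seed(44)
  X <- matrix(runif(80 * 3, 0, 100), 80, 3)
  Xc <- pmax(X - 3, 0.01)
  a <- monte_carlo_ui(m, list(factual = X, counterfactual = Xc),
                      n_draws = 500, seed = 11)
  b <- monte_carlo_ui(m, list(factual = X, counterfactual = Xc),
                      n_draws = 500, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- monte_carlo_ui(m, list(factual = X, counterfactual = Xc),
                       n_draws = 500, seed = 12)
  expect_false(identical(a$af_lo, c2$af_lo))
})

test_that("draws pool across datasets with equal weight", {
  m1 <- fixture_fixed_model(mmt = 45, seed = 45)
  m2 <- fixture_fixed_model(mmt = 45, seed = 46)
  set.seed(47)
  X <- matrix(runif(60 * 3, 0, 100), 60, 3)
  ex <- list(factual = X, counterfactual = pmax(X - 3, 0.01))
  pooled <- monte_carlo_ui(list(a = m1, b = m2), list(a = ex, b = ex),
                           n_draws = 2000, seed = 13)
  q <- "factual.total"
  # equal-weight pooling: the point estimate approaches the average of the
  # two models' deterministic burdens as draws accumulate
  an1 <- burden_from_exposures(m1, X)$table$an[1]
  an2 <- burden_from_exposures(m2, X)$table$an[1]
  got <- pooled$an[pooled$quantity == q]
  expect_equal(got, (an1 + an2) / 2, tolerance = 0.1)
})
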