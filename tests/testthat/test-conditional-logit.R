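test_that("MLE matches brute-force grid search on a tiny 1-D instance", {
  set.seed(21)
  sizes <- c(4, 5, 4, 5, 4)
  set <- rep(seq_along(sizes), sizes)
  case <- unlist(lapply(sizes, function(s) c(TRUE, rep(FALSE, s - 1))))
  x <- matrix(rnorm(length(set)), ncol = 1)
  fit <- clogit_fit(x, set, case)
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, oracle_clogit_loglik, numeric(1), x = x, set = set,
               case = case)
  expect_lt(abs(fit$beta - grid[which.max(ll)]), 1e-4 + 1e-9)
  expect_equal(fit$loglik, max(ll), tolerance = 1e-8)
})

test_that("log-likelihood at beta = 0 is minus the sum of log set sizes", {
  set.seed(22)
  sizes <- sample(4:5, 30, replace = TRUE)
  set <- rep(seq_along(sizes), sizes)
  case <- unlist(lapply(sizes, function(s) c(TRUE, rep(FALSE, s - 1))))
  x <- matrix(rnorm(2 * length(set)), ncol = 2)
  at0 <- clogit_fit(x, set, case, init = c(0, 0), max_iter = 0)
  expect_identical(at0$loglik, -sum(log(sizes)))
})

test_that("an antisymmetric design has its MLE exactly at zero", {
  # pair every set with its sign-flipped twin: the score at 0 vanishes by
  # construction and the likelihood is symmetric around 0
  d <- c(1.3, -0.4, 2.2)
  x <- matrix(c(rbind(d, -d), rbind(-d, d)), ncol = 1)
  set <- rep(1:6, each = 2)
  case <- rep(c(TRUE, FALSE), 6)
  fit <- clogit_fit(x, set, case)
  expect_lt(abs(fit$beta), 1e-8)
})

test_that("uninformative designs and separation are reported as errors", {
  x <- matrix(rep(c(1, 1, 1, 1), 3), ncol = 1)
  set <- rep(1:3, each = 4)
  case <- rep(c(TRUE, FALSE, FALSE, FALSE), 3)
  expect_error(clogit_fit(x, set, case), "uninformative")

  # perfectly separated: the case always has the largest covariate; the
  # small scale keeps the likelihood climbing past the divergence guard
  xs <- matrix(rep(c(0.08, 0, 0, 0), 40), ncol = 1)
  sets <- rep(1:40, each = 4)
  cases <- rep(c(TRUE, FALSE, FALSE, FALSE), 40)
  expect_error(clogit_fit(xs, sets, cases), "no finite MLE")
})

test_that("the likelihood is invariant to set-constant covariate shifts", {
  set.seed(23)
  sizes <- sample(4:5, 40, replace = TRUE)
  set <- rep(seq_along(sizes), sizes)
  case <- unlist(lapply(sizes, function(s) c(TRUE, rep(FALSE, s - 1))))
  x <- matrix(rnorm(2 * length(set)), ncol = 2)
  shift <- matrix(rnorm(2 * length(sizes), 0, 5), ncol = 2)[set, ]
  f1 <- clogit_fit(x, set, case)
  f2 <- clogit_fit(x + shift, set, case)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-7)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-9)
})

test_that("1:1 matching equals no-intercept logistic regression on differences", {
  set.seed(24)
  n <- 120
  xc <- rnorm(n); xk <- rnorm(n)
  x <- matrix(as.vector(rbind(xc, xk)), ncol = 1)
  set <- rep(seq_len(n), each = 2)
  case <- rep(c(TRUE, FALSE), n)
  fit <- clogit_fit(x, set, case)
  d <- xc - xk
  glm_fit <- stats::glm(rep(1, n) ~ d - 1, family = stats::binomial())
  expect_equal(unname(fit$beta), unname(stats::coef(glm_fit)),
               tolerance = 1e-6)
})

test_that("fit agrees with survival::clogit on multi-covariate data", {
  skip_if_not_installed("survival")
  library(survival)   # clogit() expands to a coxph() call
  set.seed(25)
  sizes <- sample(4:5, 150, replace = TRUE)
  set <- rep(seq_along(sizes), sizes)
  case <- unlist(lapply(sizes, function(s) c(TRUE, rep(FALSE, s - 1))))
  x <- matrix(rnorm(3 * length(set)), ncol = 3)
  fit <- clogit_fit(x, set, case)
  ref <- survival::clogit(case ~ x[, 1] + x[, 2] + x[, 3] +
                            survival::strata(set))
  expect_equal(unname(fit$beta), unname(stats::coef(ref)), tolerance = 1e-7)
  expect_equal(unname(fit$vcov), unname(stats::vcov(ref)), tolerance = 1e-7)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-9)
})

test_that("AIC selection prefers the generating model and breaks ties first", {
  small <- cross_basis_spec(var_knots = 20)
  large <- cross_basis_spec(var_knots = c(15, 40, 60, 85))
  set.seed(26)
  beta <- rnorm(small$ncoef, 0, 0.3)
  wins <- 0L
  for (r in 1:50) {
    sets <- simulate_sets_from_model(120, small, beta, seed = 1000 + r)
    sel <- aic_select(list(small, large), sets)
    if (identical(sel$best_spec, small)) wins <- wins + 1L
  }
  expect_gt(wins, 25L)

  # duplicate candidates tie exactly; the first wins
  sets <- simulate_sets_from_model(100, small, beta, seed = 3)
  sel <- aic_select(list(small, cross_basis_spec(var_knots = 20)), sets)
  expect_identical(which.min(sel$table$aic), 1L)
})

test_that("a singular candidate is skipped with a log entry", {
  small <- cross_basis_spec(var_knots = 20)
  set.seed(27)
  sets <- simulate_sets_from_model(80, small, rnorm(small$ncoef, 0, 0.2),
                                   seed = 4)
  # boundary knots far below the data put every exposure on the linear
  # extrapolation, making the two spline columns affinely dependent
  degenerate <- cross_basis_spec(var_knots = 0.5, var_boundary = c(0, 1))
  expect_message(sel <- aic_select(list(small, degenerate), sets),
                 "skipped")
  expect_identical(sel$table$error[1], "")
  expect_false(sel$table$error[2] == "")
  expect_identical(sel$best_spec, small)
})
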