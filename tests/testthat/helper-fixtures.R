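# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

# small synthetic study: 3 locations, enough deaths for a stable fit
fixture_world <- function() {
  if (is.null(.fixtures$world)) {
    cfg <- world_config(n_locations = 3L, births_per_location = 30000L,
                        seed = 42L)
    .fixtures$world <- simulate_world(cfg)
  }
  .fixtures$world
}

# factual/counterfactual percentile series of the fixture world
fixture_pct <- function() {
  if (is.null(.fixtures$pct)) {
    w <- fixture_world()
    pf <- do.call(rbind, lapply(w$series, function(p) {
      pm <- fit_percentile_map(p$factual)
      map_series(pm, p$factual)
    }))
    pc <- do.call(rbind, lapply(w$series, function(p) {
      pm <- fit_percentile_map(p$factual)
      map_series(pm, p$counterfactual)
    }))
    .fixtures$pct <- list(factual = pf, counterfactual = pc)
  }
  .fixtures$pct
}

# deaths + matched sets + fitted exposure-response model on the fixture
fixture_fit <- function() {
  if (is.null(.fixtures$fit)) {
    w <- fixture_world()
    pct <- fixture_pct()
    deaths <- select_deaths(w$records, "neonatal", 15)
    sets <- build_matched_sets(deaths, pct$factual)
    model <- fit_exposure_response(sets)
    .fixtures$fit <- list(deaths = deaths, sets = sets, model = model)
  }
  .fixtures$fit
}

# an arbitrary (non-fitted) model with known coefficients, for oracle tests
fixture_fixed_model <- function(mmt = 40, seed = 7) {
  spec <- cross_basis_spec()
  set.seed(seed)
  beta <- stats::rnorm(spec$ncoef, 0, 0.2)
  v <- matrix(stats::rnorm(spec$ncoef^2, 0, 0.02), spec$ncoef)
  exposure_response_model(spec, beta, crossprod(v), mmt_percentile = mmt)
}

# independent brute-force evaluation of the backward attributable fraction:
# rebuilds lag-specific contrasts from raw spline basis matrices with
# explicit loops, sharing no code path with the package internals
oracle_case_af <- function(model, x_lags, side = NULL) {
  spec <- model$spec
  vs <- spec$var_spec
  ls <- spec$lag_basis_spec
  nsv <- function(x) {
    splines::ns(x, knots = vs$internal_knots,
                Boundary.knots = vs$boundary_knots, intercept = vs$intercept)
  }
  nsl <- function(l) {
    splines::ns(l, knots = ls$internal_knots,
                Boundary.knots = ls$boundary_knots, intercept = ls$intercept)
  }
  lags <- seq(spec$lag$l0, spec$lag$L)
  total <- 0
  for (k in seq_along(lags)) {
    if (!is.null(side)) {
      is_heat <- x_lags[k] > model$mmt_percentile
      if (side == "heat" && !is_heat) next
      if (side == "cold" && is_heat) next
    }
    v <- as.numeric(nsv(x_lags[k])) - as.numeric(nsv(model$mmt_percentile))
    g <- as.numeric(nsl(lags[k]))
    for (i in seq_len(spec$df_var)) {
      for (j in seq_len(spec$df_lag)) {
        total <- total + model$beta[(j - 1) * spec$df_var + i] * v[i] * g[j]
      }
    }
  }
  1 - exp(-total)
}

# independent conditional log-likelihood (plain loops over sets)
oracle_clogit_loglik <- function(beta, x, set, case) {
  x <- as.matrix(x)
  eta <- drop(x %*% beta)
  ll <- 0
  for (s in unique(set)) {
    in_s <- set == s
    ll <- ll + eta[in_s & case] - log(sum(exp(eta[in_s])))
  }
  ll
}

# simulated matched sets drawn from a known cross-basis model (no world):
# random lagged exposures, case chosen within set by conditional probability
simulate_sets_from_model <- function(n_sets, spec, beta, seed,
                                     set_size = 4L) {
  set.seed(seed)
  nl <- spec$lag$L - spec$lag$l0 + 1L
  n <- n_sets * set_size
  xl <- matrix(stats::runif(n * nl, 0, 100), n, nl)
  X <- cross_basis_rows(xl, spec)
  eta <- drop(X %*% beta)
  set <- rep(seq_len(n_sets), each = set_size)
  case <- logical(n)
  for (s in seq_len(n_sets)) {
    rows <- which(set == s)
    p <- exp(eta[rows]); p <- p / sum(p)
    case[sample(rows, 1L, prob = p)] <- TRUE
  }
  out <- data.frame(set_id = set, role = ifelse(case, "case", "control"))
  for (k in seq_len(nl)) out[[paste0("lag", spec$lag$l0 + k - 1L)]] <- xl[, k]
  class(out) <- c("matched_sets", "data.frame")
  out
}
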