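
# ---- internal machinery ----------------------------------------------------

# per-lag log-RR contributions relative to the model reference x0:
# C[r, l] = (ns_var(x_{r,l}) - ns_var(x0)) x ns_lag(l) . beta
lag_contributions <- function(model, x_lags, beta = model$beta) {
  spec <- model$spec
  x0 <- model$mmt_percentile
  if (is.na(x0)) stopf("model reference (MMT percentile) is unset; run find_mmt()")
  if (is.null(dim(x_lags))) x_lags <- matrix(x_lags, nrow = 1L)
  nl <- n_lags(spec$lag)
  if (ncol(x_lags) != nl) stopf("lagged exposures have wrong width")
  n <- nrow(x_lags)
  G <- lag_basis_matrix(spec)
  V0 <- ns_basis(x0, spec$var_spec)
  if (length(beta) != spec$ncoef) stopf("beta length mismatch")
  bmat <- matrix(beta, spec$df_var, spec$df_lag)
  out <- matrix(0, n, nl)
  for (k in seq_len(nl)) {
    Vd <- ns_basis(x_lags[, k], spec$var_spec) -
      V0[rep(1L, n), , drop = FALSE]
    # cross-basis contrast restricted to lag k, times beta
    out[, k] <- drop(Vd %*% (bmat %*% G[k, ]))
  }
  out
}

# contrast matrix A such that A %*% beta gives the retained log-RR sum per
# case; `lagmask` (n x nl logical) zeroes out-of-range lag contributions
masked_contrast_matrix <- function(model, x_lags, lagmask = NULL) {
  spec <- model$spec
  x0 <- model$mmt_percentile
  if (is.null(dim(x_lags))) x_lags <- matrix(x_lags, nrow = 1L)
  n <- nrow(x_lags)
  nl <- n_lags(spec$lag)
  G <- lag_basis_matrix(spec)
  V0 <- ns_basis(x0, spec$var_spec)
  A <- matrix(0, n, spec$ncoef)
  for (k in seq_len(nl)) {
    Vd <- ns_basis(x_lags[, k], spec$var_spec) - V0[rep(1L, n), , drop = FALSE]
    if (!is.null(lagmask)) Vd <- Vd * lagmask[, k]
    for (j in seq_len(spec$df_lag)) {
      cols <- (j - 1L) * spec$df_var + seq_len(spec$df_var)
      A[, cols] <- A[, cols] + Vd * G[k, j]
    }
  }
  A
}

# classify exposures into side and severity bin relative to x0.
# side: heat iff x > x0. bins partition each side:
#   cold: extreme (<=2.5), moderate (2.5,25], mild (rest of the cold side)
#   heat: mild (up to 75], moderate (75,97.5], extreme (>97.5)
classify_exposure <- function(x, x0, cuts = c(2.5, 25, 75, 97.5)) {
  heat <- x > x0
  bin <- ifelse(heat,
                ifelse(x > cuts[4], "extreme_heat",
                       ifelse(x > cuts[3], "moderate_heat", "mild_heat")),
                ifelse(x <= cuts[1], "extreme_cold",
                       ifelse(x <= cuts[2], "moderate_cold", "mild_cold")))
  list(heat = heat, bin = bin)
}

range_components <- function() {
  c("extreme_cold", "moderate_cold", "mild_cold",
    "mild_heat", "moderate_heat", "extreme_heat")
}

#' Lagged exposure matrix for a set of case days
#'
#' Looks up, for every case day, the percentile exposures over the lag
#' window from a percentile series. Unlike [build_matched_sets], coverage
#' gaps are an error here: the same case set must be evaluable under every
#' scenario.
#'
#' @param deaths data frame with `location_id` and `death_date`.
#' @param pct_series percentile series (`location_id`, `date`, `pct`).
#' @param lag a [lag_spec].
#' @return Numeric matrix, cases by lags.
#' @export
exposure_matrix <- function(deaths, pct_series, lag) {
  locs <- sort(unique(pct_series$location_id))
  key <- function(loc, day) {
    match(loc, locs) * 1e7 + as.double(as.integer(as.Date(day)))
  }
  skey <- key(pct_series$location_id, pct_series$date)
  lags <- seq(lag$l0, lag$L)
  cdate <- as.Date(deaths$death_date)
  X <- matrix(NA_real_, nrow(deaths), length(lags))
  for (k in seq_along(lags)) {
    i <- match(key(deaths$location_id, cdate - lags[k]), skey)
    X[, k] <- pct_series$pct[i]
  }
  if (anyNA(X)) {
    bad <- unique(format(cdate[rowSums(is.na(X)) > 0]))
    stopf("exposure coverage gap for case day(s): %s",
          paste(utils::head(bad, 5), collapse = ", "))
  }
  X
}

# ---- user-facing operations ------------------------------------------------

#' Backward attributable fraction for one case day
#'
#' Computes the attributable fraction `AF = 1 - exp(-sum_l beta_{x_{t-l},l})`
#' for a single case's lagged exposure vector, where each lag contributes
#' the lag-specific log relative risk of its exposure versus the reference
#' percentile `x0` (the model's MMT). Negative values (net protective
#' exposure histories) are meaningful and retained.
#'
#' Heat/cold and severity-range restriction supports two conventions:
#' `"case_day"` (default) assigns the whole case AF to the side/range of the
#' lag-0 exposure, so components add exactly; `"per_lag"` zeroes individual
#' out-of-range lag contributions inside the exponent, which is exactly
#' additive only for cases whose retained lags all fall on one side.
#'
#' @param model an [exposure_response_model] with `mmt_percentile` set.
#' @param x_lags lagged exposure vector (percentiles), length `L - l0 + 1`.
#' @param restrict `"all"`, `"heat"`, `"cold"`, or one of the six severity
#'   ranges (`"extreme_cold"`, ..., `"extreme_heat"`).
#' @param restrict_by restriction convention, see Details.
#' @return List: `af`, `retained_sum` (the retained log-RR sum),
#'   `contributions` (per-lag log-RR contributions), `side` and `bin` of
#'   each lag's exposure.
#' @export
case_af <- function(model, x_lags,
                    restrict = c("all", "heat", "cold", range_components()),
                    restrict_by = c("case_day", "per_lag")) {
  restrict <- match.arg(restrict)
  restrict_by <- match.arg(restrict_by)
  x_lags <- as.numeric(x_lags)
  contrib <- drop(lag_contributions(model, x_lags))
  cls <- classify_exposure(x_lags, model$mmt_percentile)
  side <- ifelse(cls$heat, "heat", "cold")
  keep <- if (restrict == "all") {
    rep(TRUE, length(x_lags))
  } else if (restrict_by == "case_day") {
    tag <- if (restrict %in% c("heat", "cold")) side[1L] else cls$bin[1L]
    rep(tag == restrict, length(x_lags))
  } else {
    if (restrict %in% c("heat", "cold")) side == restrict else cls$bin == restrict
  }
  s <- sum(contrib[keep])
  list(af = 1 - exp(-s), retained_sum = s, contributions = contrib,
       side = side, bin = cls$bin)
}

#' Attributable burden of a death series under one temperature scenario
#'
#' Applies the backward attributable-fraction formula to every case day and
#' aggregates: the attributable number (AN) is the sum of per-case AFs, and
#' the attributable fraction the mean. Heat and cold components and the six
#' severity ranges (cut at the 2.5th, 25th, MMT, 75th, and 97.5th
#' percentiles) are reported alongside the total. The same case set must be
#' used under factual and counterfactual scenarios; only the exposure
#' series changes.
#'
#' @param model an [exposure_response_model] with `mmt_percentile` set.
#' @param deaths data frame with `location_id` and `death_date`.
#' @param pct_series percentile exposure series for the scenario (columns
#'   `location_id`, `date`, `pct`).
#' @param scenario label, `"factual"` or `"counterfactual"`.
#' @param restrict_by restriction convention, see [case_af].
#' @param outcome,dataset_id scope labels carried into the result.
#' @return An object of class `attribution_result`: scope fields plus a
#'   `table` with one row per component (`total`, `heat`, `cold`, and the
#'   six ranges) holding `an` and `af`. Attribute `additivity_gap` reports
#'   `heat + cold - total` (exactly 0 under the `"case_day"` convention).
#' @export
scenario_burden <- function(model, deaths, pct_series,
                            scenario = c("factual", "counterfactual"),
                            restrict_by = c("case_day", "per_lag"),
                            outcome = "neonatal", dataset_id = "synthetic") {
  scenario <- match.arg(scenario)
  restrict_by <- match.arg(restrict_by)
  X <- exposure_matrix(deaths, pct_series, model$spec$lag)
  burden_from_exposures(model, X, scenario = scenario,
                        restrict_by = restrict_by, outcome = outcome,
                        dataset_id = dataset_id)
}

#' @rdname scenario_burden
#' @param x_lags precomputed lagged exposure matrix (cases by lags), an
#'   alternative entry point when exposures are already assembled.
#' @export
burden_from_exposures <- function(model, x_lags,
                                  scenario = "factual",
                                  restrict_by = c("case_day", "per_lag"),
                                  outcome = "neonatal",
                                  dataset_id = "synthetic") {
  restrict_by <- match.arg(restrict_by)
  if (is.null(dim(x_lags))) x_lags <- matrix(x_lags, nrow = 1L)
  n <- nrow(x_lags)
  C <- lag_contributions(model, x_lags)
  cls <- classify_exposure(x_lags, model$mmt_percentile)
  af_total <- 1 - exp(-rowSums(C))
  comp <- c("total", "heat", "cold", range_components())
  an <- setNames(numeric(length(comp)), comp)
  an["total"] <- sum(af_total)
  if (restrict_by == "case_day") {
    bin1 <- matrix(cls$bin, n)[, 1L]
    for (b in range_components()) an[b] <- sum(af_total[bin1 == b])
    # sides and total aggregate their bins, so the decomposition identities
    # hold exactly, not merely to rounding
    an["heat"] <- an["mild_heat"] + an["moderate_heat"] + an["extreme_heat"]
    an["cold"] <- an["extreme_cold"] + an["moderate_cold"] + an["mild_cold"]
    an["total"] <- an["heat"] + an["cold"]
  } else {
    heat <- matrix(cls$heat, n)
    bin <- matrix(cls$bin, n)
    an["heat"] <- sum(1 - exp(-rowSums(C * heat)))
    an["cold"] <- sum(1 - exp(-rowSums(C * !heat)))
    for (b in range_components()) an[b] <- sum(1 - exp(-rowSums(C * (bin == b))))
  }
  tab <- data.frame(component = comp, an = unname(an),
                    af = unname(an) / n, stringsAsFactors = FALSE)
  structure(list(scenario = scenario, outcome = outcome,
                 dataset_id = dataset_id, restrict_by = restrict_by,
                 mmt_percentile = model$mmt_percentile,
                 n_cases = n, table = tab),
            class = "attribution_result",
            additivity_gap = unname(an["heat"] + an["cold"] - an["total"]))
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("<attribution_result> %s / %s / %s, %d cases (MMT pct %.1f, %s restriction)\n",
              x$outcome, x$dataset_id, x$scenario, x$n_cases,
              x$mmt_percentile, x$restrict_by))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Climate-change excess burden
#'
#' Differences the attributable burden between the factual and the
#' counterfactual scenario, component by component. Positive heat excess
#' means climate change added heat-related deaths; negative cold excess
#' means it averted cold-related deaths. `share_of_factual` expresses the
#' excess as a proportion of the factual component burden (e.g. "the share
#' of the heat-related burden attributable to climate change").
#'
#' @param factual,counterfactual [scenario_burden] results with matching
#'   scope (outcome, dataset, case count, restriction convention).
#' @return An object of class `climate_excess`: scope fields plus a `table`
#'   with `an_factual`, `an_counterfactual`, `an_excess`, `af_excess`, and
#'   `share_of_factual` per component.
#' @export
climate_excess <- function(factual, counterfactual) {
  stopifnot(inherits(factual, "attribution_result"),
            inherits(counterfactual, "attribution_result"))
  same <- identical(factual$outcome, counterfactual$outcome) &&
    identical(factual$dataset_id, counterfactual$dataset_id) &&
    identical(factual$restrict_by, counterfactual$restrict_by) &&
    factual$n_cases == counterfactual$n_cases
  if (!same) stopf("factual and counterfactual results have mismatched scopes")
  f <- factual$table; cf <- counterfactual$table
  tab <- data.frame(component = f$component,
                    an_factual = f$an,
                    an_counterfactual = cf$an,
                    an_excess = f$an - cf$an,
                    af_excess = f$af - cf$af,
                    share_of_factual = ifelse(f$an != 0, (f$an - cf$an) / f$an,
                                              NA_real_),
                    stringsAsFactors = FALSE)
  structure(list(outcome = factual$outcome, dataset_id = factual$dataset_id,
                 restrict_by = factual$restrict_by,
                 n_cases = factual$n_cases, table = tab),
            class = "climate_excess")
}

#' @export
print.climate_excess <- function(x, ...) {
  cat(sprintf("<climate_excess> %s / %s, %d cases\n",
              x$outcome, x$dataset_id, x$n_cases))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Attributable mortality rate per 100,000 live births
#'
#' Converts a climate-change-attributable fraction into a rate by scaling
#' the country's neonatal mortality rate: `AR = m * AF_CC`. For the very
#' early outcome the rate is first scaled by the country's share of
#' neonatal deaths occurring on the day of birth.
#'
#' @param af_cc attributable fraction(s) of the outcome due to climate
#'   change.
#' @param rates a country rate table (see [read_country_rates]): columns
#'   `country`, `births`, `neonatal_mortality_rate` (per 100,000 live
#'   births), `very_early_share`.
#' @param country country identifier(s), recycled against `af_cc`.
#' @param outcome `"neonatal"` or `"very_early"`.
#' @return Attributable deaths per 100,000 live births.
#' @export
attributable_rate <- function(af_cc, rates, country,
                              outcome = c("neonatal", "very_early")) {
  outcome <- match.arg(outcome)
  i <- match(country, rates$country)
  if (anyNA(i)) {
    stopf("country not in rate table: %s",
          paste(unique(country[is.na(i)]), collapse = ", "))
  }
  m <- rates$neonatal_mortality_rate[i]
  if (outcome == "very_early") m <- m * rates$very_early_share[i]
  m * af_cc
}

#' Monte Carlo uncertainty intervals for the attributable burden
#'
#' Propagates coefficient uncertainty into the attributable numbers and
#' fractions by drawing cross-basis coefficients from a multivariate normal
#' centred at the fit, recomputing the factual and counterfactual burdens
#' and their difference for every draw, and pooling draws across the
#' temperature datasets with equal weight. Point estimates are the mean
#' over all pooled draws; uncertainty intervals are the empirical 2.5th and
#' 97.5th percentiles. The MMT of each fitted model is held fixed across
#' draws and scenarios.
#'
#' @param fits named list of [exposure_response_model]s, one per
#'   temperature dataset.
#' @param exposures named list parallel to `fits`; each element a list with
#'   `factual` and `counterfactual` lagged-exposure matrices for the same
#'   case days.
#' @param n_draws Monte Carlo sample size (default 10,000).
#' @param seed integer seed; draws are reproducible given the seed.
#' @param restrict_by restriction convention, see [case_af].
#' @param chunk draws processed per block (memory control).
#' @return An object of class `mc_ui`: data frame with one row per
#'   `quantity` (`factual`/`counterfactual`/`excess` x
#'   `total`/`heat`/`cold`) holding pooled `an` and `af` point estimates
#'   and their `lo`/`hi` interval bounds.
#' @export
monte_carlo_ui <- function(fits, exposures, n_draws = 10000L, seed = 1L,
                           restrict_by = c("case_day", "per_lag"),
                           chunk = 250L) {
  restrict_by <- match.arg(restrict_by)
  if (inherits(fits, "exposure_response_model")) fits <- list(dataset1 = fits)
  if (!is.null(exposures$factual)) exposures <- list(dataset1 = exposures)
  stopifnot(length(fits) == length(exposures))
  set.seed(as.integer(seed))
  comp <- c("total", "heat", "cold")
  draws <- list()  # per dataset: list of an/af draw vectors per quantity
  for (d in seq_along(fits)) {
    model <- fits[[d]]
    ex <- exposures[[d]]
    vc <- (model$vcov + t(model$vcov)) / 2
    ev <- eigen(vc, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10 * max(abs(ev), 1)) {
      stopf("covariance matrix is not positive semi-definite")
    }
    # PSD repair within tolerance: clip tiny negative eigenvalues
    if (min(ev) < 0) {
      es <- eigen(vc, symmetric = TRUE)
      vc <- es$vectors %*% (pmax(es$values, 0) * t(es$vectors))
      vc <- (vc + t(vc)) / 2
    }
    n <- nrow(ex$factual)
    A <- list()
    for (sc in c("factual", "counterfactual")) {
      X <- ex[[sc]]
      if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
      cls <- classify_exposure(X, model$mmt_percentile)
      heat <- matrix(cls$heat, nrow(X))
      if (restrict_by == "case_day") {
        hmask <- matrix(heat[, 1L], nrow(X), ncol(X))
      } else {
        hmask <- heat
      }
      A[[paste0(sc, ".total")]] <- masked_contrast_matrix(model, X)
      A[[paste0(sc, ".heat")]] <- masked_contrast_matrix(model, X, hmask)
      A[[paste0(sc, ".cold")]] <- masked_contrast_matrix(model, X, !hmask)
    }
    B <- MASS::mvrnorm(n_draws, mu = model$beta, Sigma = vc)
    if (is.null(dim(B))) B <- matrix(B, nrow = n_draws)
    an <- matrix(0, n_draws, length(A), dimnames = list(NULL, names(A)))
    done <- 0L
    while (done < n_draws) {
      take <- seq.int(done + 1L, min(done + chunk, n_draws))
      Bt <- t(B[take, , drop = FALSE])
      for (nm in names(A)) {
        an[take, nm] <- colSums(1 - exp(-(A[[nm]] %*% Bt)))
      }
      done <- done + length(take)
    }
    res <- list(n = n)
    for (cc in comp) {
      res[[paste0("factual.", cc)]] <- an[, paste0("factual.", cc)]
      res[[paste0("counterfactual.", cc)]] <- an[, paste0("counterfactual.", cc)]
      res[[paste0("excess.", cc)]] <-
        an[, paste0("factual.", cc)] - an[, paste0("counterfactual.", cc)]
    }
    draws[[d]] <- res
  }
  qty <- as.vector(outer(comp, c("factual", "counterfactual", "excess"),
                         function(a, b) paste(b, a, sep = ".")))
  rows <- lapply(qty, function(q) {
    an_pool <- unlist(lapply(draws, `[[`, q))
    af_pool <- unlist(lapply(draws, function(r) r[[q]] / r$n))
    data.frame(quantity = q,
               an = mean(an_pool),
               an_lo = unname(stats::quantile(an_pool, 0.025)),
               an_hi = unname(stats::quantile(an_pool, 0.975)),
               af = mean(af_pool),
               af_lo = unname(stats::quantile(af_pool, 0.025)),
               af_hi = unname(stats::quantile(af_pool, 0.975)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_draws") <- n_draws
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("mc_ui", "data.frame")
  out
}
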