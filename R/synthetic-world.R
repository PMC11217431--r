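
#' Ground-truth exposure-lag-response surface
#'
#' Defines the known U-shaped log relative-risk surface that drives deaths
#' in the synthetic world: a curve in percentile space with its minimum at
#' `mmt` (where the log-RR is exactly 0), distributed over lags by weights
#' summing to 1 (a separable surface).
#'
#' Two curve families are available. `"spline"` (default) constructs the
#' U inside the span of a natural cubic spline with one internal knot and
#' boundary knots at 0/100 -- the same function space the default fitted
#' model uses -- so recovery tests measure estimation error rather than
#' spline-approximation error. `"quadratic"` is an asymmetric piecewise
#' quadratic, useful for studying misspecification.
#'
#' @param type curve family.
#' @param mmt true minimum-mortality percentile.
#' @param cold_logrr log relative risk at percentile 0 (cold end). The
#'   default 0.35 (RR about 1.42) is on the scale reported for neonatal
#'   temperature-mortality associations.
#' @param heat_logrr log RR at percentile 100; for the spline family this
#'   is implied by the construction and the argument is ignored.
#' @param lag_weights per-lag fractions over lags `0..L`; normalised to sum
#'   to 1. Default `c(0.5, 0.3, 0.2)`: the effect is strongest on the day
#'   of death and decays over two lag days.
#' @param knot,boundary exposure-spline geometry for the `"spline"` family.
#' @return An object of class `true_exposure_response` with elements
#'   `fun` (vectorised percentile -> log RR), `true_mmt_percentile`,
#'   `lag_weights`, `type`.
#' @export
true_exposure_response <- function(type = c("spline", "quadratic"),
                                   mmt = 50, cold_logrr = 0.35,
                                   heat_logrr = 0.25,
                                   lag_weights = c(0.5, 0.3, 0.2),
                                   knot = 20, boundary = c(0, 100)) {
  type <- match.arg(type)
  if (mmt <= 0 || mmt >= 100) stopf("true MMT percentile must be in (0, 100)")
  if (any(lag_weights < 0) || sum(lag_weights) <= 0) {
    stopf("lag weights must be non-negative with positive sum")
  }
  lag_weights <- lag_weights / sum(lag_weights)
  if (type == "spline") {
    sp <- spline_spec(knot, boundary, intercept = FALSE)
    h <- 1e-4
    d <- (ns_basis(mmt + h, sp) - ns_basis(mmt - h, sp)) / (2 * h)
    gamma <- c(d[2], -d[1])              # orthogonal to the gradient at mmt
    bm <- ns_basis(mmt, sp)
    f0 <- function(p) drop((ns_basis(p, sp) -
                              bm[rep(1L, length(p)), , drop = FALSE]) %*% gamma)
    v0 <- f0(boundary[1])
    if (v0 == 0) stopf("degenerate spline truth; move the knot or the MMT")
    gamma <- gamma * cold_logrr / v0
    fun <- function(p) drop((ns_basis(p, sp) -
                               bm[rep(1L, length(p)), , drop = FALSE]) %*% gamma)
    if (fun(boundary[2]) <= 0 || min(fun(seq(1, 99))) < -1e-8) {
      stopf("spline truth is not U-shaped for this knot/MMT combination")
    }
  } else {
    fun <- function(p) {
      ifelse(p < mmt, cold_logrr * ((mmt - p) / mmt)^2,
             heat_logrr * ((p - mmt) / (100 - mmt))^2)
    }
  }
  structure(list(type = type, fun = fun, true_mmt_percentile = mmt,
                 lag_weights = lag_weights,
                 cold_logrr = cold_logrr,
                 heat_logrr = if (type == "spline") fun(boundary[2]) else heat_logrr),
            class = "true_exposure_response")
}

#' @export
print.true_exposure_response <- function(x, ...) {
  cat(sprintf("<true_exposure_response> %s U-curve, MMT pct %.1f, logRR %.3f (cold end) / %.3f (heat end), lag weights %s\n",
              x$type, x$true_mmt_percentile, x$cold_logrr, x$heat_logrr,
              paste(signif(x$lag_weights, 3), collapse = "/")))
  invisible(x)
}

#' Synthetic study configuration
#'
#' Describes a fully synthetic study: several locations with distinct
#' seasonal climates, a counterfactual daily temperature series per
#' location, a factual series derived from it by adding a linear warming
#' ramp, and a birth cohort whose neonatal deaths are driven by a known
#' exposure-lag-response surface. Defaults mirror the observational design
#' being emulated: a 2001--2019 study window, 0.9 degC total warming over
#' the window, and a 15-year maternal recall window.
#'
#' @param n_locations number of locations.
#' @param study_period length-2 character/Date, start and end day.
#' @param baseline_climates optional data frame (`location_id`, `lat`,
#'   `lon`, `mean_temp`, `amplitude`, `noise_sd`, `ar1`); a default
#'   spanning temperate-to-tropical climates is generated when omitted.
#' @param warming total warming (degC) added to the factual series by the
#'   end of the period.
#' @param births_per_location cohort size per location.
#' @param baseline_hazard daily death hazard at the optimal temperature.
#'   The default 0.0012 yields a 28-day cumulative mortality near 3.5%,
#'   typical of high-mortality settings.
#' @param true_surface a [true_exposure_response].
#' @param very_early_surface optional second surface driving day-0 deaths;
#'   defaults to `true_surface`.
#' @param recall_years maternal recall window in years.
#' @param seed integer master seed.
#' @return An object of class `world_config`.
#' @export
world_config <- function(n_locations = 5L,
                         study_period = c("2001-01-01", "2019-12-31"),
                         baseline_climates = NULL,
                         warming = 0.9,
                         births_per_location = 20000L,
                         baseline_hazard = 0.0012,
                         true_surface = true_exposure_response(),
                         very_early_surface = NULL,
                         recall_years = 15,
                         seed = 1L) {
  study_period <- as.Date(study_period)
  if (anyNA(study_period) || length(study_period) != 2L ||
      study_period[1] >= study_period[2]) {
    stopf("invalid study period")
  }
  if (as.numeric(study_period[2] - study_period[1]) < 2 * 365) {
    stopf("study period must span at least 2 full years")
  }
  if (warming < 0) stopf("warming must be non-negative")
  if (births_per_location < 0) stopf("births_per_location must be non-negative")
  if (baseline_hazard <= 0 || baseline_hazard >= 1) {
    stopf("baseline hazard must be in (0, 1)")
  }
  stopifnot(inherits(true_surface, "true_exposure_response"))
  if (is.null(baseline_climates)) {
    i <- seq_len(n_locations)
    baseline_climates <- data.frame(
      location_id = sprintf("L%02d", i),
      lat = 5.25 + 0.5 * (i - 1),
      lon = 10.25 + 0.5 * (i - 1),
      mean_temp = seq(15, 28, length.out = max(n_locations, 2))[i],
      amplitude = seq(10, 3, length.out = max(n_locations, 2))[i],
      noise_sd = rep(2.5, n_locations),
      ar1 = rep(0.7, n_locations),
      stringsAsFactors = FALSE)
  }
  need <- c("location_id", "lat", "lon", "mean_temp", "amplitude",
            "noise_sd", "ar1")
  if (!all(need %in% names(baseline_climates))) {
    stopf("baseline_climates lacks columns: %s",
          paste(setdiff(need, names(baseline_climates)), collapse = ", "))
  }
  if (nrow(baseline_climates) != n_locations) {
    stopf("baseline_climates must have one row per location")
  }
  structure(list(n_locations = as.integer(n_locations),
                 study_period = study_period,
                 baseline_climates = baseline_climates,
                 warming = warming,
                 births_per_location = as.integer(births_per_location),
                 baseline_hazard = baseline_hazard,
                 true_surface = true_surface,
                 very_early_surface = very_early_surface,
                 recall_years = recall_years,
                 seed = as.integer(seed)),
            class = "world_config")
}

#' @export
print.world_config <- function(x, ...) {
  cat(sprintf("<world_config> %d locations, %s..%s, warming %.2f degC, %d births/location, seed %d\n",
              x$n_locations, format(x$study_period[1]),
              format(x$study_period[2]), x$warming,
              x$births_per_location, x$seed))
  invisible(x)
}

#' Generate a factual/counterfactual daily temperature pair
#'
#' The counterfactual series is a seasonal cycle plus AR(1) weather noise;
#' the factual series adds a linear warming ramp rising from 0 at the start
#' of the study period to `cfg$warming` degC at its end. Because the ramp
#' is additive, the two series share their weather variability and the
#' day-rank timing of warm and cold spells is preserved by construction.
#'
#' @param cfg a [world_config].
#' @param location location id or index.
#' @return List with elements `factual` and `counterfactual`, both
#'   [scenario_series] on identical calendars.
#' @export
generate_temperature_pair <- function(cfg, location = 1L) {
  stopifnot(inherits(cfg, "world_config"))
  bc <- cfg$baseline_climates
  idx <- if (is.character(location)) match(location, bc$location_id) else as.integer(location)
  if (is.na(idx) || idx < 1L || idx > nrow(bc)) stopf("unknown location: %s", location)
  row <- bc[idx, ]
  dates <- seq(cfg$study_period[1], cfg$study_period[2], by = "day")
  n <- length(dates)
  doy <- as.POSIXlt(dates)$yday
  seasonal <- row$mean_temp + row$amplitude * cos(2 * pi * (doy - 196) / 365.25)
  set.seed(derive_seed(cfg$seed, "temperature", idx))
  innov <- stats::rnorm(n, 0, row$noise_sd * sqrt(1 - row$ar1^2))
  noise <- as.numeric(stats::filter(innov, row$ar1, method = "recursive"))
  cfact <- seasonal + noise
  ramp <- if (n > 1L) cfg$warming * (seq_len(n) - 1L) / (n - 1L) else 0
  list(
    factual = scenario_series(row$location_id, dates, cfact + ramp,
                              scenario = "factual"),
    counterfactual = scenario_series(row$location_id, dates, cfact,
                                     scenario = "counterfactual"))
}

# per-calendar-day death-hazard multiplier exp(sum_l w_l f(pct[t-l]));
# NA for the first L days where the lag window is incomplete
day_multiplier <- function(surface, pct) {
  w <- surface$lag_weights
  f <- surface$fun(pct)
  n <- length(f)
  s <- rep(0, n)
  for (l in seq_along(w) - 1L) {
    shifted <- c(rep(NA_real_, l), f[seq_len(n - l)])
    s <- s + w[l + 1L] * shifted
  }
  exp(s)
}

#' Generate a synthetic birth cohort with temperature-driven deaths
#'
#' Births are uniform over the study period (clipped so that every child's
#' 28 neonatal days and the lag window are covered by the temperature
#' series). Survival is simulated day by day over days of life 0--28 with
#' a baseline hazard multiplied by the true relative risk for that calendar
#' day, `exp(sum_l w_l f(pct_{t-l}))`, evaluated on the *factual* percentile
#' scale (deaths happen in the factual world). Interview dates are set to
#' the day after the period ends, so recall filtering is exercised purely
#' through the `recall_years` parameter.
#'
#' @param cfg a [world_config].
#' @param series list of per-location temperature pairs (from
#'   [generate_temperature_pair]) or factual [scenario_series].
#' @return A birth-record data frame: `child_id`, `psu_id`, `birth_date`,
#'   `age_at_death_days` (`NA` for survivors), `interview_date`,
#'   `psu_lat`, `psu_lon`, `location_id`.
#' @export
generate_cohort <- function(cfg, series) {
  stopifnot(inherits(cfg, "world_config"))
  bc <- cfg$baseline_climates
  surface <- cfg$true_surface
  surface0 <- cfg$very_early_surface %||% surface
  nlw <- length(surface$lag_weights)
  out <- vector("list", nrow(bc))
  for (idx in seq_len(nrow(bc))) {
    loc <- bc$location_id[idx]
    fact <- series[[idx]]
    if (!inherits(fact, "scenario_series") && !is.null(fact$factual)) {
      fact <- fact$factual
    }
    if (fact$location_id[1] != loc) stopf("series order does not match locations")
    pmap <- fit_percentile_map(fact)
    pct <- map_percentile(pmap, fact$tmean)
    mult <- day_multiplier(surface, pct)
    mult0 <- if (is.null(cfg$very_early_surface)) mult else day_multiplier(surface0, pct)
    pk <- max(c(mult, mult0), na.rm = TRUE) * cfg$baseline_hazard
    if (pk > 1) stopf("baseline hazard too high (daily death probability %.3f > 1)", pk)
    nb <- cfg$births_per_location
    if (nb == 0L) { out[idx] <- list(NULL); next }
    ndays <- nrow(fact)
    set.seed(derive_seed(cfg$seed, "cohort", idx))
    bidx <- sample.int(ndays - 28L - nlw + 1L, nb, replace = TRUE) + nlw - 1L
    alive <- rep(TRUE, nb)
    age <- rep(NA_integer_, nb)
    for (d in 0:28) {
      m <- if (d == 0L) mult0 else mult
      p <- cfg$baseline_hazard * m[bidx + d]
      die <- alive & stats::runif(nb) < p
      age[die] <- d
      alive[die] <- FALSE
    }
    out[[idx]] <- data.frame(
      child_id = sprintf("%s-%06d", loc, seq_len(nb)),
      psu_id = loc,
      birth_date = fact$date[bidx],
      age_at_death_days = age,
      interview_date = cfg$study_period[2] + 1L,
      psu_lat = bc$lat[idx], psu_lon = bc$lon[idx],
      location_id = loc,
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(child_id = character(0), psu_id = character(0),
                      birth_date = as.Date(character(0)),
                      age_at_death_days = integer(0),
                      interview_date = as.Date(character(0)),
                      psu_lat = numeric(0), psu_lon = numeric(0),
                      location_id = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: generates temperature pairs for every location, the
#' birth cohort, and a ground-truth record (true MMT, lag weights, and the
#' true log-RR curve on an integer percentile grid) for recovery tests.
#'
#' @param cfg a [world_config].
#' @return List of class `synthetic_world`: `config`, `records`, `series`
#'   (per-location factual/counterfactual pairs), `truth`.
#' @export
simulate_world <- function(cfg) {
  stopifnot(inherits(cfg, "world_config"))
  series <- lapply(seq_len(cfg$n_locations), function(i) {
    generate_temperature_pair(cfg, i)
  })
  names(series) <- cfg$baseline_climates$location_id
  records <- generate_cohort(cfg, series)
  grid <- 0:100
  truth <- list(true_mmt_percentile = cfg$true_surface$true_mmt_percentile,
                lag_weights = cfg$true_surface$lag_weights,
                curve_type = cfg$true_surface$type,
                log_rr_grid = data.frame(percentile = grid,
                                         log_rr = cfg$true_surface$fun(grid)))
  structure(list(config = cfg, records = records, series = series,
                 truth = truth),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  nd <- sum(!is.na(x$records$age_at_death_days) &
              x$records$age_at_death_days <= 28)
  cat(sprintf("<synthetic_world> %d locations, %d births, %d neonatal deaths\n",
              x$config$n_locations, nrow(x$records), nd))
  invisible(x)
}

#' Write a synthetic world to disk
#'
#' Emits the same flat files the ingestion side consumes: `births.csv`,
#' `temps.csv` (long format, both scenarios), `country_rates.csv` (the
#' synthetic study pooled as one country), and `truth.yaml` with the
#' ground-truth surface for recovery tests.
#'
#' @param world a [simulate_world] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_birth_records(world$records, file.path(dir, "births.csv"))
  temps <- do.call(rbind, lapply(world$series, function(pair) {
    rbind(as.data.frame(pair$factual), as.data.frame(pair$counterfactual))
  }))
  rownames(temps) <- NULL
  utils::write.csv(temps, file.path(dir, "temps.csv"), row.names = FALSE)
  rec <- world$records
  ne <- sum(!is.na(rec$age_at_death_days) & rec$age_at_death_days <= 28)
  ve <- sum(!is.na(rec$age_at_death_days) & rec$age_at_death_days == 0)
  rates <- data.frame(country = "SYN", births = nrow(rec),
                      neonatal_mortality_rate = 1e5 * ne / max(nrow(rec), 1),
                      very_early_share = if (ne > 0) ve / ne else 0.375)
  utils::write.csv(rates, file.path(dir, "country_rates.csv"), row.names = FALSE)
  yaml::write_yaml(list(
    true_mmt_percentile = world$truth$true_mmt_percentile,
    lag_weights = as.numeric(world$truth$lag_weights),
    curve_type = world$truth$curve_type,
    log_rr_grid = list(percentile = world$truth$log_rr_grid$percentile,
                       log_rr = world$truth$log_rr_grid$log_rr)),
    file.path(dir, "truth.yaml"))
  invisible(dir)
}
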