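
#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (or YAML file) with either a
#' `simulate` block (synthetic-world parameters, see [world_config]) or a
#' `paths` block (`births`, `temps`, optionally `country_rates` and
#' `grid`), plus analysis settings: `outcome` (`"neonatal"` or
#' `"very_early"`), `recall_years`, `lag` (`l0`, `L`), `candidates` (list
#' of exposure-knot vectors for AIC selection), `n_draws`, `seed`,
#' `output_dir`.
#'
#' @param config named list or path to a YAML file.
#' @return The normalised configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("config must be a list or a YAML file path")
  if (is.null(config$simulate) && is.null(config$paths)) {
    stopf("invalid config: needs either a 'simulate' block or a 'paths' block")
  }
  if (!is.null(config$paths)) {
    if (is.null(config$paths$births) || is.null(config$paths$temps)) {
      stopf("invalid config: paths block needs 'births' and 'temps'")
    }
  }
  config$outcome <- match.arg(config$outcome %||% "neonatal",
                              c("neonatal", "very_early"))
  config$recall_years <- config$recall_years %||% 15
  lg <- config$lag %||% list(l0 = 0L, L = 2L)
  config$lag <- lag_spec(lg$l0 %||% 0L, lg$L %||% 2L)
  config$candidates <- config$candidates %||% list(10, 20, c(25, 75))
  config$n_draws <- as.integer(config$n_draws %||% 10000L)
  config$seed <- as.integer(config$seed %||% 1L)
  config
}

config_hash <- function(config) {
  flat <- jsonlite::toJSON(rapply(config, function(x) {
    if (inherits(x, "Date")) format(x) else x
  }, how = "replace"), auto_unbox = TRUE, digits = NA, force = TRUE)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(flat), tf)
  unname(tools::md5sum(tf))
}

stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

# percentile exposure series for every location/dataset under one scenario,
# always through the *factual* reference map
percentile_series_table <- function(temps, scenario) {
  out <- list()
  combos <- unique(temps[, c("location_id", "dataset_id")])
  for (i in seq_len(nrow(combos))) {
    loc <- combos$location_id[i]; ds <- combos$dataset_id[i]
    ref <- temps[temps$location_id == loc & temps$dataset_id == ds &
                   temps$scenario == "factual", , drop = FALSE]
    tgt <- temps[temps$location_id == loc & temps$dataset_id == ds &
                   temps$scenario == scenario, , drop = FALSE]
    if (!nrow(ref)) stopf("no factual reference series for %s/%s", loc, ds)
    if (!nrow(tgt)) next
    pm <- fit_percentile_map(ref)
    tgt$pct <- map_percentile(pm, tgt$tmean)
    out[[length(out) + 1L]] <- tgt
  }
  do.call(rbind, out)
}

#' Run the full attribution pipeline
#'
#' Executes every stage end to end: simulate or ingest; percentile
#' standardisation (factual reference); outcome/recall death selection;
#' time-stratified matching; AIC selection over candidate exposure knots;
#' conditional-logistic DLNM fit and MMT location; factual and
#' counterfactual attributable burdens and their climate-change excess per
#' temperature dataset; Monte Carlo uncertainty pooled across datasets;
#' optional conversion to rates per 100,000 live births. All randomness
#' derives from `config$seed`.
#'
#' @param config run configuration (list or YAML path), see
#'   [validate_config].
#' @param output_dir optional output directory; when given, writes
#'   `burden.csv`, `curve.csv`, `aic_table.csv`, `model.json` and
#'   `run_metadata.json` there.
#' @return List of class `pipeline_result`: `config`, `models` (per
#'   dataset), `burdens`, `excess`, `mc`, `burden_table`, `curve`,
#'   `aic_table`, `truth` (synthetic runs only).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  config <- validate_config(config)
  output_dir <- output_dir %||% config$output_dir
  hash <- config_hash(config)

  truth <- NULL
  rates <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    cfg <- world_config(
      n_locations = sim$n_locations %||% 5L,
      study_period = sim$study_period %||% c("2001-01-01", "2019-12-31"),
      warming = sim$warming %||% 0.9,
      births_per_location = sim$births_per_location %||% 20000L,
      baseline_hazard = sim$baseline_hazard %||% 0.0012,
      recall_years = config$recall_years,
      seed = sim$seed %||% config$seed)
    stage_msg("simulate", "%d locations x %d births, warming %.2f degC",
              cfg$n_locations, cfg$births_per_location, cfg$warming)
    world <- simulate_world(cfg)
    records <- world$records
    truth <- world$truth
    temps <- do.call(rbind, lapply(world$series, function(pair) {
      rbind(as.data.frame(pair$factual), as.data.frame(pair$counterfactual))
    }))
    rownames(temps) <- NULL
    ne <- sum(!is.na(records$age_at_death_days) &
                records$age_at_death_days <= 28)
    ve <- sum(!is.na(records$age_at_death_days) &
                records$age_at_death_days == 0)
    rates <- data.frame(country = "SYN", births = nrow(records),
                        neonatal_mortality_rate = 1e5 * ne / max(nrow(records), 1),
                        very_early_share = if (ne > 0) ve / ne else 0.375)
  } else {
    stage_msg("ingest", "reading %s", config$paths$births)
    records <- read_birth_records(config$paths$births)
    temps <- read_temperature_series(config$paths$temps)
    if (!is.null(config$paths$country_rates)) {
      rates <- read_country_rates(config$paths$country_rates)
    }
    if (!"location_id" %in% names(records)) {
      if (is.null(config$paths$grid)) {
        stopf("records lack location_id and no grid file is configured")
      }
      grid <- utils::read.csv(config$paths$grid, stringsAsFactors = FALSE)
      records <- link_to_grid(records, grid)
    }
  }

  stage_msg("exposure", "building factual-reference percentile series")
  pct_fact <- percentile_series_table(temps, "factual")
  pct_cfact <- percentile_series_table(temps, "counterfactual")

  deaths_all <- select_deaths(records, config$outcome, config$recall_years)
  stage_msg("select", "%d %s deaths within %g-year recall",
            nrow(deaths_all), config$outcome, config$recall_years)
  if (!nrow(deaths_all)) stopf("no deaths to analyse")

  datasets <- sort(unique(temps$dataset_id))
  candidates <- lapply(config$candidates, function(k) {
    cross_basis_spec(var_knots = unlist(k), lag = config$lag)
  })

  models <- list(); burdens <- list(); excess <- list()
  exposures <- list(); aic_tabs <- list()
  for (ds in datasets) {
    pf <- pct_fact[pct_fact$dataset_id == ds, , drop = FALSE]
    pc <- pct_cfact[pct_cfact$dataset_id == ds, , drop = FALSE]
    deaths <- deaths_all[deaths_all$location_id %in% unique(pf$location_id), ,
                         drop = FALSE]
    stage_msg("match", "[%s] building matched sets for %d deaths", ds,
              nrow(deaths))
    sets <- build_matched_sets(deaths, pf, config$lag)
    if (length(candidates) >= 2L) {
      sel <- aic_select(candidates, sets)
      model <- sel$best_model
      aic_tabs[[ds]] <- cbind(dataset_id = ds, sel$table)
    } else {
      model <- fit_exposure_response(sets, candidates[[1L]])
      aic_tabs[[ds]] <- data.frame(dataset_id = ds, candidate = 1L,
                                   ncoef = model$spec$ncoef,
                                   var_knots = paste(model$spec$var_spec$internal_knots,
                                                     collapse = ";"),
                                   loglik = model$loglik, aic = model$aic,
                                   error = "")
    }
    stage_msg("fit", "[%s] AIC %.1f, MMT percentile %.1f", ds, model$aic,
              model$mmt_percentile)
    models[[ds]] <- model
    xf <- exposure_matrix(deaths, pf, config$lag)
    xc <- exposure_matrix(deaths, pc, config$lag)
    exposures[[ds]] <- list(factual = xf, counterfactual = xc)
    bf <- burden_from_exposures(model, xf, "factual",
                                outcome = config$outcome, dataset_id = ds)
    bc <- burden_from_exposures(model, xc, "counterfactual",
                                outcome = config$outcome, dataset_id = ds)
    burdens[[ds]] <- list(factual = bf, counterfactual = bc)
    excess[[ds]] <- climate_excess(bf, bc)
    stage_msg("attribute", "[%s] factual AF %.3f%%, excess heat AN %.1f", ds,
              100 * bf$table$af[1], excess[[ds]]$table$an_excess[2])
  }

  stage_msg("mc", "%d Monte Carlo draws across %d dataset(s)",
            config$n_draws, length(datasets))
  mc <- monte_carlo_ui(models, exposures, n_draws = config$n_draws,
                       seed = derive_seed(config$seed, "mc"))

  # flat burden table
  rows <- list()
  for (ds in datasets) {
    for (sc in c("factual", "counterfactual")) {
      tb <- burdens[[ds]][[sc]]$table
      rows[[length(rows) + 1L]] <-
        data.frame(outcome = config$outcome, dataset_id = ds, scenario = sc,
                   component = tb$component, an = tb$an, af = tb$af,
                   ar = NA_real_, stringsAsFactors = FALSE)
    }
    te <- excess[[ds]]$table
    ar <- rep(NA_real_, nrow(te))
    if (!is.null(rates)) {
      ar <- attributable_rate(te$af_excess, rates,
                              rep(rates$country[1L], nrow(te)),
                              outcome = config$outcome)
    }
    rows[[length(rows) + 1L]] <-
      data.frame(outcome = config$outcome, dataset_id = ds,
                 scenario = "excess", component = te$component,
                 an = te$an_excess, af = te$af_excess, ar = ar,
                 stringsAsFactors = FALSE)
  }
  burden_table <- do.call(rbind, rows)
  curve <- cumulative_rr(models[[1L]])
  curve$dataset_id <- datasets[1L]
  curve$centered_at <- attr(curve, "centered_at")

  result <- structure(list(config = config, config_hash = hash,
                           models = models, burdens = burdens,
                           excess = excess, mc = mc,
                           burden_table = burden_table, curve = curve,
                           aic_table = do.call(rbind, aic_tabs),
                           rates = rates, truth = truth),
                      class = "pipeline_result")

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(burden_table, file.path(output_dir, "burden.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(mc), file.path(output_dir, "uncertainty.csv"),
                     row.names = FALSE)
    utils::write.csv(curve, file.path(output_dir, "curve.csv"),
                     row.names = FALSE)
    utils::write.csv(result$aic_table, file.path(output_dir, "aic_table.csv"),
                     row.names = FALSE)
    m1 <- models[[1L]]
    jsonlite::write_json(
      list(dataset_id = datasets[1L],
           beta = m1$beta, vcov = m1$vcov,
           mmt_percentile = m1$mmt_percentile,
           loglik = m1$loglik, aic = m1$aic,
           var_knots = m1$spec$var_spec$internal_knots,
           lag = c(m1$spec$lag$l0, m1$spec$lag$L)),
      file.path(output_dir, "model.json"), digits = NA, auto_unbox = TRUE)
    jsonlite::write_json(
      list(seed = config$seed, config_hash = hash,
           outcome = config$outcome,
           n_deaths = nrow(deaths_all),
           datasets = datasets,
           r_version = paste(R.version$major, R.version$minor, sep = "."),
           package_version = as.character(utils::packageVersion("neonatclim"))),
      file.path(output_dir, "run_metadata.json"), digits = NA,
      auto_unbox = TRUE)
    stage_msg("report", "artifacts written to %s", output_dir)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> outcome %s, %d dataset(s), config %s\n",
              x$config$outcome, length(x$models), substr(x$config_hash, 1, 8)))
  ex <- x$mc[x$mc$quantity %in%
               c("excess.total", "excess.heat", "excess.cold"), ]
  print(ex, row.names = FALSE)
  invisible(x)
}
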