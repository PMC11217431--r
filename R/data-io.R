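
birth_record_columns <- c("child_id", "psu_id", "birth_date",
                          "age_at_death_days", "interview_date",
                          "psu_lat", "psu_lon")

#' Read birth records
#'
#' Reads a flat CSV of birth records (one child per row) with ISO-8601
#' dates. Rows violating the record invariants -- unparseable dates,
#' negative age at death, birth after interview -- are rejected, not
#' repaired; a row-numbered report is attached as attribute `rejected` and
#' summarised in a message.
#'
#' @param path CSV file with a header containing at least the columns
#'   `child_id`, `psu_id`, `birth_date`, `age_at_death_days` (empty for
#'   survivors), `interview_date`, `psu_lat`, `psu_lon`.
#' @return Data frame of typed records; attribute `rejected` holds a data
#'   frame with `row` and `reason` for each dropped line.
#' @export
read_birth_records <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  missing <- setdiff(birth_record_columns, names(raw))
  if (length(missing)) {
    stopf("birth record schema error: missing mandatory column(s) %s",
          paste(missing, collapse = ", "))
  }
  n <- nrow(raw)
  bd <- as_date_strict(raw$birth_date)
  iv <- as_date_strict(raw$interview_date)
  age <- suppressWarnings(as.integer(raw$age_at_death_days))
  age[!nzchar(trimws(raw$age_at_death_days))] <- NA_integer_
  has_age_text <- nzchar(trimws(raw$age_at_death_days))
  reason <- rep(NA_character_, n)
  reason[is.na(bd)] <- "unparseable birth_date"
  reason[is.na(iv) & is.na(reason)] <- "unparseable interview_date"
  reason[has_age_text & is.na(age) & is.na(reason)] <- "unparseable age_at_death_days"
  reason[!is.na(age) & age < 0 & is.na(reason)] <- "negative age_at_death_days"
  reason[!is.na(bd) & !is.na(iv) & bd > iv & is.na(reason)] <- "birth_date after interview_date"
  bad <- !is.na(reason)
  rec <- data.frame(child_id = raw$child_id, psu_id = raw$psu_id,
                    birth_date = bd, age_at_death_days = age,
                    interview_date = iv,
                    psu_lat = as.numeric(raw$psu_lat),
                    psu_lon = as.numeric(raw$psu_lon),
                    stringsAsFactors = FALSE)
  if ("location_id" %in% names(raw)) rec$location_id <- raw$location_id
  rec <- rec[!bad, , drop = FALSE]
  rownames(rec) <- NULL
  rej <- data.frame(row = which(bad), reason = reason[bad],
                    stringsAsFactors = FALSE)
  if (nrow(rej)) {
    message(sprintf("read_birth_records: rejected %d of %d row(s) (%s)",
                    nrow(rej), n,
                    paste(unique(rej$reason), collapse = "; ")))
  }
  attr(rec, "rejected") <- rej
  rec
}

#' Write birth records
#'
#' @param records birth-record data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_birth_records <- function(records, path) {
  out <- records
  out$birth_date <- format(as.Date(out$birth_date))
  out$interview_date <- format(as.Date(out$interview_date))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read long-format daily temperature series
#'
#' Reads a long CSV (`location_id`, `date`, `tmean`, optional `dataset_id`
#' and `scenario`) and validates that each location/dataset/scenario series
#' is a complete, strictly increasing daily calendar.
#'
#' @param path CSV path.
#' @return Data frame with columns `location_id`, `dataset_id`, `scenario`,
#'   `date`, `tmean`, sorted by series and date.
#' @export
read_temperature_series <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("location_id", "date", "tmean")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stopf("temperature schema error: missing mandatory column(s) %s",
          paste(missing, collapse = ", "))
  }
  raw$date <- as_date_strict(raw$date)
  if (anyNA(raw$date)) stopf("temperature file contains unparseable dates")
  if (anyNA(raw$tmean)) stopf("temperature file contains missing tmean values")
  if (is.null(raw$dataset_id)) raw$dataset_id <- "default"
  if (is.null(raw$scenario)) raw$scenario <- "factual"
  raw <- raw[order(raw$location_id, raw$dataset_id, raw$scenario, raw$date), ,
             drop = FALSE]
  gid <- paste(raw$location_id, raw$dataset_id, raw$scenario, sep = "\r")
  for (g in unique(gid)) {
    d <- raw$date[gid == g]
    if (length(d) > 1L && any(diff(as.integer(d)) != 1L)) {
      stopf("temperature series %s has missing or duplicated days",
            gsub("\r", "/", g))
    }
  }
  rownames(raw) <- NULL
  raw[, c("location_id", "dataset_id", "scenario", "date", "tmean")]
}

#' Read a country rate table
#'
#' @param path CSV with columns `country`, `births` (live births over the
#'   study period), `neonatal_mortality_rate` (deaths per 100,000 live
#'   births), `very_early_share` (fraction of neonatal deaths on day 0).
#' @return Validated data frame.
#' @export
read_country_rates <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("country", "births", "neonatal_mortality_rate", "very_early_share")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stopf("country rate schema error: missing mandatory column(s) %s",
          paste(missing, collapse = ", "))
  }
  if (any(raw$neonatal_mortality_rate <= 0)) {
    stopf("neonatal mortality rates must be positive")
  }
  if (any(raw$very_early_share <= 0 | raw$very_early_share >= 1)) {
    stopf("very_early_share must lie strictly between 0 and 1")
  }
  raw
}

#' Select death records for an outcome window
#'
#' Keeps deaths within the outcome's age window -- `"neonatal"`: age at
#' death 0--28 days; `"very_early"`: day of birth only -- and drops deaths
#' reported longer than `recall_years` before the interview, mirroring the
#' restriction of self-reported birth histories to a maternal recall
#' window. The death date is reconstructed as `birth_date +
#' age_at_death_days`.
#'
#' @param records birth-record data frame.
#' @param window outcome window.
#' @param recall_years recall restriction in years (365.25-day years).
#' @return The death rows, with a `death_date` column added.
#' @export
select_deaths <- function(records, window = c("neonatal", "very_early"),
                          recall_years = 15) {
  window <- match.arg(window)
  age <- records$age_at_death_days
  keep <- !is.na(age) & if (window == "neonatal") age >= 0 & age <= 28 else age == 0
  out <- records[keep, , drop = FALSE]
  out$death_date <- as.Date(out$birth_date) + out$age_at_death_days
  cutoff <- as.Date(out$interview_date) - round(recall_years * 365.25)
  out <- out[out$death_date >= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Link records to the nearest temperature grid location
#'
#' Assigns each PSU the grid location whose cell centre is nearest by
#' great-circle distance (or, with `method = "containing"`, the 0.5-degree
#' cell containing the PSU). Ties resolve to the lexicographically lowest
#' `location_id`, so the assignment is deterministic and invariant to the
#' row order of the input.
#'
#' @param records birth-record data frame with `psu_id`, `psu_lat`,
#'   `psu_lon`.
#' @param grid data frame of cell centres: `location_id`, `lat`, `lon`.
#' @param max_distance_km PSUs farther than this from every centre are an
#'   error (listed by id).
#' @param method `"nearest"` centre or `"containing"` 0.5-degree cell.
#' @return `records` with a `location_id` column.
#' @export
link_to_grid <- function(records, grid, max_distance_km = 100,
                         method = c("nearest", "containing")) {
  method <- match.arg(method)
  stopifnot(all(c("psu_id", "psu_lat", "psu_lon") %in% names(records)),
            all(c("location_id", "lat", "lon") %in% names(grid)))
  psu <- unique(records[, c("psu_id", "psu_lat", "psu_lon")])
  if (anyNA(psu$psu_lat) || anyNA(psu$psu_lon)) {
    stopf("PSU(s) without coordinates: %s",
          paste(psu$psu_id[is.na(psu$psu_lat) | is.na(psu$psu_lon)],
                collapse = ", "))
  }
  grid <- grid[order(grid$location_id), , drop = FALSE]
  if (method == "containing") {
    centre_lat <- floor(psu$psu_lat / 0.5) * 0.5 + 0.25
    centre_lon <- floor(psu$psu_lon / 0.5) * 0.5 + 0.25
    gkey <- paste(grid$lat, grid$lon)
    i <- match(paste(centre_lat, centre_lon), gkey)
    if (anyNA(i)) {
      stopf("no grid cell contains PSU(s): %s",
            paste(psu$psu_id[is.na(i)], collapse = ", "))
    }
    assigned <- grid$location_id[i]
  } else {
    dm <- geosphere::distm(cbind(psu$psu_lon, psu$psu_lat),
                           cbind(grid$lon, grid$lat)) / 1000
    # nearest centre; distance ties go to the lowest location_id, which
    # comes first because grid is sorted by id
    best <- apply(dm, 1L, function(r) which(r <= min(r) + 1e-9)[1L])
    dist <- dm[cbind(seq_len(nrow(dm)), best)]
    far <- dist > max_distance_km
    if (any(far)) {
      stopf("PSU(s) farther than %g km from any grid cell: %s",
            max_distance_km, paste(psu$psu_id[far], collapse = ", "))
    }
    assigned <- grid$location_id[best]
  }
  records$location_id <- assigned[match(records$psu_id, psu$psu_id)]
  records
}
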