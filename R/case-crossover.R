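
#' Control days for a time-stratified case-crossover design
#'
#' For a case day, returns every other day in the same calendar month and
#' year that falls on the same day of the week. Month/year strata with the
#' same weekday always contain 4 or 5 such days, so each case receives 3 or
#' 4 controls.
#'
#' @param date a `Date` (vectorised).
#' @return For a single date, a `Date` vector of controls; for several, a
#'   list of such vectors.
#' @examples
#' control_days(as.Date("2015-06-17")) # the other Wednesdays of June 2015
#' @export
control_days <- function(date) {
  date <- as.Date(date)
  one <- function(d) {
    dom <- as.integer(format(d, "%d"))
    first <- dom %% 7L
    if (first == 0L) first <- 7L
    fom <- as.Date(format(d, "%Y-%m-01"))
    last <- as.integer(format(seq(fom, by = "month", length.out = 2L)[2L] - 1L,
                              "%d"))
    doms <- seq(first, last, by = 7L)
    ctrl <- d + (doms - dom)
    ctrl[ctrl != d]
  }
  if (length(date) == 1L) one(date) else lapply(date, one)
}

#' Build time-stratified matched sets with lagged exposures
#'
#' Matches every death day to its same-weekday control days within the same
#' calendar month and year, and attaches the lagged percentile exposure
#' vector to each case and control day. Sets for which any required
#' exposure day is missing from the series are dropped (with a count
#' reported), never filled.
#'
#' @param deaths data frame with columns `location_id` and `death_date`
#'   (plus any id columns, which are carried through).
#' @param pct_series data frame with columns `location_id`, `date`, `pct`
#'   (one scenario), e.g. from [map_series].
#' @param lag a [lag_spec].
#' @return Long data frame of class `matched_sets`: one row per case or
#'   control day with columns `set_id`, `role` (`"case"`/`"control"`),
#'   `location_id`, `date`, and `lag0 ... lagL` percentile columns.
#'   Attribute `n_dropped` counts sets lost to exposure coverage.
#' @export
build_matched_sets <- function(deaths, pct_series, lag = lag_spec()) {
  stopifnot(is.data.frame(deaths), is.data.frame(pct_series))
  if (!all(c("location_id", "death_date") %in% names(deaths))) {
    stopf("deaths must have location_id and death_date columns")
  }
  n <- nrow(deaths)
  if (n == 0L) {
    out <- data.frame(set_id = integer(0), role = character(0),
                      location_id = character(0), date = as.Date(character(0)))
    for (l in seq(lag$l0, lag$L)) out[[paste0("lag", l)]] <- numeric(0)
    attr(out, "n_dropped") <- 0L
    class(out) <- c("matched_sets", "data.frame")
    return(out)
  }
  cdate <- as.Date(deaths$death_date)
  ctrl <- control_days(cdate)
  if (n == 1L) ctrl <- list(ctrl)
  nctrl <- lengths(ctrl)
  set_id <- seq_len(n)
  long <- data.frame(
    set_id = c(set_id, rep(set_id, nctrl)),
    role = c(rep("case", n), rep("control", sum(nctrl))),
    location_id = as.character(c(deaths$location_id,
                                 rep(deaths$location_id, nctrl))),
    date = c(cdate, as.Date(unlist(ctrl), origin = "1970-01-01")),
    stringsAsFactors = FALSE)

  # lagged exposures via a keyed lookup on (location, day)
  locs <- sort(unique(pct_series$location_id))
  key <- function(loc, day) {
    match(loc, locs) * 1e7 + as.double(as.integer(as.Date(day)))
  }
  skey <- key(pct_series$location_id, pct_series$date)
  lags <- seq(lag$l0, lag$L)
  ok <- rep(TRUE, nrow(long))
  for (l in lags) {
    i <- match(key(long$location_id, long$date - l), skey)
    long[[paste0("lag", l)]] <- pct_series$pct[i]
    ok <- ok & !is.na(i)
  }
  bad_sets <- unique(long$set_id[!ok])
  n_dropped <- length(bad_sets)
  if (n_dropped) {
    message(sprintf("build_matched_sets: dropped %d set(s) lacking exposure coverage",
                    n_dropped))
    long <- long[!(long$set_id %in% bad_sets), , drop = FALSE]
  }
  # renumber sets consecutively, preserving input order
  long$set_id <- match(long$set_id, sort(unique(long$set_id)))
  long <- long[order(long$set_id, long$role != "case", long$date), , drop = FALSE]
  rownames(long) <- NULL
  attr(long, "n_dropped") <- n_dropped
  class(long) <- c("matched_sets", "data.frame")
  long
}

# lagged-exposure matrix (cases/controls in row order) and bookkeeping
matched_design <- function(sets, spec) {
  lags <- seq(spec$lag$l0, spec$lag$L)
  cols <- paste0("lag", lags)
  if (!all(cols %in% names(sets))) {
    stopf("matched sets lack lag columns %s",
          paste(setdiff(cols, names(sets)), collapse = ", "))
  }
  list(x_lags = as.matrix(sets[, cols, drop = FALSE]),
       set = sets$set_id,
       case = sets$role == "case")
}
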