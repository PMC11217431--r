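make_records <- function() {
  data.frame(child_id = c("c1", "c2", "c3"),
             psu_id = c("p1", "p1", "p2"),
             birth_date = as.Date(c("2015-03-01", "2016-07-10", "2017-01-05")),
             age_at_death_days = c(0L, 12L, NA),
             interview_date = as.Date("2019-06-01"),
             psu_lat = c(5.25, 5.25, 6.75),
             psu_lon = c(10.25, 10.25, 11.25),
             stringsAsFactors = FALSE)
}

test_that("birth records round-trip losslessly through CSV", {
  rec <- make_records()
  path <- tempfile(fileext = ".csv")
  write_birth_records(rec, path)
  back <- read_birth_records(path)
  attr(back, "rejected") <- NULL
  expect_equal(back, rec)
  # write -> read -> write is byte-stable
  path2 <- tempfile(fileext = ".csv")
  write_birth_records(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("schema violations name the missing column", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(child_id = "c1", psu_id = "p1"), path,
            row.names = FALSE)
  expect_error(read_birth_records(path), "birth_date")
})

test_that("invalid rows are rejected with a row-numbered report", {
  rec <- make_records()
  raw <- data.frame(lapply(rec, as.character), stringsAsFactors = FALSE)
  raw$age_at_death_days[1] <- "-1"
  raw$birth_date[2] <- "not-a-date"
  path <- tempfile(fileext = ".csv")
  write.csv(raw, path, row.names = FALSE, na = "")
  expect_message(out <- read_birth_records(path), "rejected 2 of 3")
  expect_identical(nrow(out), 1L)
  rej <- attr(out, "rejected")
  expect_setequal(rej$row, c(1L, 2L))
  expect_true(any(grepl("negative age", rej$reason)))
  expect_true(any(grepl("birth_date", rej$reason)))
})

test_that("an empty file with a header reads as an empty table", {
  path <- tempfile(fileext = ".csv")
  writeLines(paste(c("child_id", "psu_id", "birth_date", "age_at_death_days",
                     "interview_date", "psu_lat", "psu_lon"), collapse = ","),
             path)
  out <- read_birth_records(path)
  expect_identical(nrow(out), 0L)
})

test_that("death selection applies age windows and the recall restriction", {
  rec <- data.frame(child_id = paste0("c", 1:5), psu_id = "p",
                    birth_date = as.Date("2010-06-01"),
                    age_at_death_days = c(0L, 5L, 28L, 29L, NA),
                    interview_date = as.Date("2019-01-01"),
                    psu_lat = 0.25, psu_lon = 0.25,
                    stringsAsFactors = FALSE)
  neo <- select_deaths(rec, "neonatal", 15)
  expect_setequal(neo$age_at_death_days, c(0L, 5L, 28L))
  ve <- select_deaths(rec, "very_early", 15)
  expect_identical(ve$age_at_death_days, 0L)
  # a death 6 years before the interview is outside a 5-year recall
  rec$interview_date <- as.Date("2016-07-01")
  expect_identical(nrow(select_deaths(rec, "neonatal", 5)), 0L)
  expect_identical(nrow(select_deaths(rec, "neonatal", 10)), 3L)
  # death date reconstruction
  expect_identical(neo$death_date, neo$birth_date + neo$age_at_death_days)
})

test_that("temperature series reader enforces complete calendars", {
  s <- data.frame(location_id = "A",
                  date = format(as.Date("2010-01-01") + 0:4),
                  tmean = 20 + 1:5)
  path <- tempfile(fileext = ".csv")
  write.csv(s, path, row.names = FALSE)
  out <- read_temperature_series(path)
  expect_identical(nrow(out), 5L)
  expect_identical(out$scenario, rep("factual", 5))
  write.csv(s[-3, ], path, row.names = FALSE)
  expect_error(read_temperature_series(path), "missing or duplicated days")
})

test_that("country rate tables are validated", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(country = "X", births = 10, neonatal_mortality_rate = 0,
                       very_early_share = 0.3), path, row.names = FALSE)
  expect_error(read_country_rates(path), "positive")
  write.csv(data.frame(country = "X", births = 10,
                       neonatal_mortality_rate = 2000,
                       very_early_share = 1.2), path, row.names = FALSE)
  expect_error(read_country_rates(path), "very_early_share")
})

test_that("grid linkage picks the nearest cell with a deterministic tie-break", {
  grid <- data.frame(location_id = c("cellA", "cellB"),
                     lat = c(5.25, 5.75), lon = c(10.25, 10.25))
  rec <- make_records()
  rec$psu_lat <- c(5.25, 5.50, 5.75)   # row 2 exactly equidistant
  rec$psu_lon <- 10.25
  out <- link_to_grid(rec, grid)
  expect_identical(out$location_id, c("cellA", "cellA", "cellB"))

  # idempotent and invariant to row order
  out2 <- link_to_grid(out, grid)
  expect_identical(out2$location_id, out$location_id)
  rev_out <- link_to_grid(rec[3:1, ], grid)
  expect_identical(rev_out$location_id, rev(out$location_id))
})

test_that("PSUs beyond the maximum distance raise a listing error", {
  grid <- data.frame(location_id = "cellA", lat = 5.25, lon = 10.25)
  rec <- make_records()
  rec$psu_lat <- c(5.25, 5.25, 45)     # c3 is thousands of km away
  expect_error(link_to_grid(rec, grid, max_distance_km = 100), "p2")
})

test_that("containing-cell linkage maps to the enclosing half-degree cell", {
  grid <- data.frame(location_id = c("cellA", "cellB"),
                     lat = c(5.25, 5.75), lon = c(10.25, 10.25))
  rec <- make_records()
  rec$psu_lat <- c(5.10, 5.40, 5.60)
  rec$psu_lon <- 10.30
  out <- link_to_grid(rec, grid, method = "containing")
  expect_identical(out$location_id, c("cellA", "cellA", "cellB"))
})

test_that("a synthetic world round-trips through its flat files", {
  cfg <- world_config(n_locations = 2, births_per_location = 500, seed = 55)
  w <- simulate_world(cfg)
  dir <- tempfile()
  write_world(w, dir)
  rec <- read_birth_records(file.path(dir, "births.csv"))
  expect_identical(nrow(rec), nrow(w$records))
  expect_equal(rec$birth_date, w$records$birth_date)
  temps <- read_temperature_series(file.path(dir, "temps.csv"))
  expect_setequal(unique(temps$scenario), c("factual", "counterfactual"))
  tru <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_equal(tru$true_mmt_percentile, 50)
  rates <- read_country_rates(file.path(dir, "country_rates.csv"))
  expect_identical(rates$births, nrow(w$records))
})
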