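test_that("parser maps dialect columns and keeps every data line", {
  expect_equal(nrow(parse_speedometer_log(make_log())), 0L)

  rows <- parse_speedometer_log(make_log(
    log_line(0, 10), "", log_line(1, 12), "", log_line(2, 14)
  ))
  expect_equal(nrow(rows), 5L)            # blanks carried forward, not filtered
  expect_equal(rows$line_number, 1:5)
  expect_equal(rows$speed_mph[c(1, 3, 5)], c("10", "12", "14"))
  expect_equal(rows$speed_mph[2], "")
})

test_that("parser rejects mismatched headers and empty streams", {
  bad <- sub("speed (mph)", "velocity", make_log(log_line(0, 10)), fixed = TRUE)
  err <- expect_error(parse_speedometer_log(bad), class = "motoprofile_dialect_error")
  expect_match(conditionMessage(err), "speed_mph")
  expect_error(parse_speedometer_log(""), class = "motoprofile_dialect_error")
})

test_that("parser accepts a renamed export through a custom dialect", {
  cols <- c(duration = "secs", time = "clock", distance_miles = "dist",
            speed_mph = "spd", lat_wgs84 = "lat", lon_wgs84 = "lon",
            altitude_feet = "alt", lat_bd09 = "latb", lon_bd09 = "lonb")
  txt <- c("secs,clock,dist,spd,lat,lon,alt,latb,lonb",
           "0,08:00:00,0,31.07,3.7,101.5,200,3.706,101.5065")
  rows <- parse_speedometer_log(txt, gps_dialect(columns = cols))
  expect_equal(rows$speed_mph, "31.07")
})

test_that("unit conversion uses the exact international constants", {
  expect_equal(convert_units(0, 0, 0), list(speed_kmh = 0, distance_km = 0, altitude_m = 0))
  expect_equal(convert_units(50, 0, 0)$speed_kmh, 80.4672)
  expect_equal(convert_units(0, 0, 100)$altitude_m, 30.48)
  expect_error(convert_units(-1, 0, 0), class = "motoprofile_domain_error")
})

test_that("unit conversion is linear", {
  a <- runif(20, 0, 100); b <- runif(20, 0, 100)
  expect_equal(convert_units(a, a, a)$speed_kmh + convert_units(b, b, b)$speed_kmh,
               convert_units(a + b, a + b, a + b)$speed_kmh)
})

test_that("cleaning coerces, converts and logs one primary reason per drop", {
  txt <- make_log(vapply(0:9, function(i) log_line(i, 10 + i), character(1)))
  got <- clean_records(parse_speedometer_log(txt))
  expect_equal(got$report$rows_dropped, 0L)
  expect_equal(nrow(got$records), 10L)
  expect_equal(got$records$speed, (10:19) * 1.609344)

  txt <- make_log(
    log_line(0, 10),
    "",                                      # empty_row
    sub(",11,", ",n/a,", log_line(1, 11)),   # non_numeric speed cell
    log_line(2, 12),
    log_line(7, 13),
    log_line(7, 14),                         # duplicate_timestamp (first wins)
    log_line(5, 15)                          # non_monotonic_time
  )
  # 4 of 7 rows drop here, so the high-drop-rate diagnostic also fires
  got <- suppressWarnings(clean_records(parse_speedometer_log(txt)))
  expect_equal(got$report$rows_read, 7L)
  expect_equal(got$report$rows_kept, 3L)
  expect_equal(got$report$reasons$reason,
               c("empty_row", "non_numeric", "duplicate_timestamp",
                 "non_monotonic_time"))
  expect_equal(got$records$t, c(0, 2, 7))
  expect_equal(got$records$speed[3], 13 * 1.609344)  # first occurrence kept
})

test_that("cleaning flags high drop rates and refuses empty trips", {
  txt <- make_log(log_line(0, 10), "", "", "")
  expect_warning(got <- clean_records(parse_speedometer_log(txt)), "50%")
  expect_true(got$report$high_drop_rate)
  expect_error(
    suppressWarnings(clean_records(parse_speedometer_log(make_log("", "")))),
    class = "motoprofile_data_error"
  )
})

test_that("cleaning conserves row counts under fuzzing", {
  set.seed(404)
  for (rep in 1:20) {
    n <- sample(1:40, 1)
    lines <- vapply(seq_len(n), function(i) {
      r <- runif(1)
      if (r < 0.15) {
        ""
      } else if (r < 0.3) {
        sub(",3.7,", ",oops,", log_line(i, runif(1, 0, 60)))
      } else {
        log_line(sample(0:n, 1), runif(1, 0, 60))
      }
    }, character(1))
    got <- tryCatch(
      suppressWarnings(clean_records(parse_speedometer_log(make_log(lines)))),
      motoprofile_data_error = function(e) NULL
    )
    if (!is.null(got)) {
      expect_identical(got$report$rows_read,
                       got$report$rows_kept + got$report$rows_dropped)
      expect_equal(got$report$rows_dropped, nrow(got$report$reasons))
    }
  }
})
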