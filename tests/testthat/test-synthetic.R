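test_that("a degenerate spec yields a constant-speed trip with all-zero samples", {
  spec <- trip_spec(duration = 60, base_speed = 50, speed_noise_sd = 0,
                    maneuver_rate = 0, seed = 5)
  sim <- simulate_trip(spec)
  expect_equal(nrow(sim$trip$records), 60L)
  expect_true(all(sim$trip$records$speed == 50))
  expect_true(all(sim$ledger$event_label == "zero"))
  expect_true(all(sim$ledger$speed_label == "normal_speed"))
})

test_that("the same spec and seed reproduce byte-identical logs", {
  spec <- trip_spec(duration = 120, seed = 99,
                    injected_events = list(
                      list(label = "aggressive_accel", count = 3,
                           magnitude = c(1.4, 2.4))
                    ))
  a <- write_log(simulate_trip(spec)$trip)
  b <- write_log(simulate_trip(spec)$trip)
  expect_identical(a, b)
  c <- write_log(simulate_trip(trip_spec(duration = 120, seed = 100))$trip)
  expect_false(identical(a, c))
})

test_that("injected events appear in the ledger and are recovered by the classifier", {
  spec <- trip_spec(duration = 400, base_speed = 70, speed_noise_sd = 0,
                    maneuver_rate = 0, seed = 17,
                    injected_events = list(
                      list(label = "dangerous_accel", count = 10,
                           magnitude = c(3, 5)),
                      list(label = "aggressive_decel", count = 4,
                           magnitude = c(6.5, 9))
                    ))
  sim <- simulate_trip(spec)
  inj <- sim$ledger$injected
  expect_equal(sum(inj$label == "dangerous_accel"), 10L)
  expect_equal(sum(inj$label == "aggressive_decel"), 4L)
  lab <- classify_sample(sim$ledger$a, threshold_preset("methods"))
  expect_equal(which(lab == "dangerous_accel"),
               sort(inj$index[inj$label == "dangerous_accel"]))
  expect_equal(as.character(lab), as.character(sim$ledger$event_label))
})

test_that("injection ranges inconsistent with the thresholds are rejected", {
  spec <- trip_spec(duration = 60, seed = 1,
                    injected_events = list(
                      list(label = "dangerous_accel", count = 1,
                           magnitude = c(2.0, 2.2))   # inside the aggressive band
                    ))
  expect_error(simulate_trip(spec), class = "motoprofile_config_error")
  too_many <- trip_spec(duration = 10, seed = 1,
                        injected_events = list(
                          list(label = "aggressive_accel", count = 50,
                               magnitude = c(1.4, 2.4))
                        ))
  expect_error(simulate_trip(too_many), class = "motoprofile_config_error")
})

test_that("write_log round-trips numerically at the dialect precision", {
  sim <- simulate_trip(trip_spec(duration = 100, seed = 23,
                                 over_speed_segments = list(
                                   list(start = 30, length = 20, target = 95)
                                 )))
  lines <- write_log(sim$trip)
  expect_equal(length(lines), 101L)  # header + 100 records
  back <- read_trip(paste(lines, collapse = "\n"), "D1", "T1")
  expect_equal(back$report$rows_dropped, 0L)
  tol_kmh <- 0.5 * 1e-4 * 1.609344   # half an ulp of a 4-decimal mph cell
  expect_equal(back$trip$records$t, sim$trip$records$t)
  expect_lt(max(abs(back$trip$records$speed - sim$trip$records$speed)), tol_kmh)
  expect_lt(max(abs(back$trip$records$distance - sim$trip$records$distance)),
            0.5 * 1e-4 * 1.609344)
  expect_lt(max(abs(back$trip$records$altitude - sim$trip$records$altitude)),
            0.5 * 1e-4 * 0.3048)

  empty <- trip("D1", "T0", tibble::tibble(t = numeric(0), speed = numeric(0)))
  expect_equal(write_log(empty), log_header)
})

test_that("cohorts have per-driver sub-seeds and exact sample arithmetic", {
  specs <- cohort_trip_specs(3, 3, trip_spec(duration = 1200), seed = 7)
  seeds <- unlist(lapply(specs, function(p) vapply(p, `[[`, integer(1), "seed")))
  expect_equal(anyDuplicated(seeds), 0L)

  cohort <- simulate_cohort(specs)
  expect_equal(nrow(cohort$index), 9L)
  expect_true(all(cohort$index$n_records == 1200L))
  # per driver: 3 trips x 1199 samples
  labs <- split(cohort$ledgers, cohort$index$driver_id)
  totals <- vapply(labs, function(ls) sum(lengths(lapply(ls, `[[`, "a"))),
                   numeric(1))
  expect_true(all(totals == 3 * 1199))

  expect_error(simulate_cohort(list()), class = "motoprofile_config_error")
  dup <- specs; names(dup) <- c("D1", "D1", "D3")
  expect_error(simulate_cohort(dup), class = "motoprofile_config_error")
})

test_that("over-speed segments generate dangerous and over-speed readings", {
  spec <- trip_spec(duration = 600, base_speed = 60, seed = 31,
                    maneuver_rate = 0.3,
                    over_speed_segments = list(
                      list(start = 100, length = 200, target = 105)
                    ))
  sim <- simulate_trip(spec)
  tab <- table(sim$ledger$speed_label)
  expect_gt(tab[["over_speed"]], 0)
  expect_gt(tab[["dangerous_speed"]], 0)
  expect_gt(tab[["normal_speed"]], tab[["over_speed"]])
})
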