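# synthetic_data: seeded trip generator with ground-truth label ledgers.

INJECTABLE_LABELS <- c("aggressive_accel", "dangerous_accel",
                       "aggressive_decel", "dangerous_decel")

#' Synthetic trip recipe
#'
#' Describes one generated trip: its duration and cadence, the cruise speed
#' the controller holds, per-step speed jitter, the Gaussian magnitude
#' models for ordinary throttle and braking maneuvers, deliberately
#' injected severe events, and over-speed excursions. Defaults emulate the
#' study conditions the generator stands in for: 20-minute (1200 s) trips
#' at 1 Hz, cruising around 60 km/h on an 80 km/h road, with maneuver
#' magnitudes drawn so that most samples are small speed jitter and severe
#' events are rare.
#'
#' @param duration Trip length in seconds, > 0.
#' @param dt Sampling interval in seconds, > 0 (the app logs near 1 Hz).
#' @param base_speed Cruise target in km/h.
#' @param speed_noise_sd Per-step speed jitter standard deviation in km/h
#'   (converted internally to an acceleration noise of
#'   `speed_noise_sd / 3.6 / dt` m/s²).
#' @param accel_burst_model,decel_burst_model Length-2 numeric
#'   `c(mean, sd)` in m/s²: the Gaussian from which ordinary maneuver
#'   magnitudes are drawn (non-positive draws rejected; a magnitude must be
#'   positive).
#' @param maneuver_rate Per-sample probability of an ordinary maneuver.
#' @param band Half width in km/h of the cruise band the controller holds
#'   around the current target speed.
#' @param injected_events List of `list(label =, count =, magnitude = c(lo, hi))`
#'   entries; labels from `"aggressive_accel"`, `"dangerous_accel"`,
#'   `"aggressive_decel"`, `"dangerous_decel"`. Magnitude ranges must be
#'   consistent with their label under the active threshold set (checked at
#'   simulation time).
#' @param over_speed_segments List of `list(start =, length =, target =)`
#'   entries (seconds, seconds, km/h): windows during which the controller
#'   targets `target` instead of `base_speed`.
#' @param seed Integer RNG seed; the same spec always yields bit-identical
#'   output.
#' @param start_lat,start_lon,altitude Track origin (WGS84 degrees) and
#'   constant altitude in m, used only for format completeness; the track
#'   is dead-reckoned due north.
#' @return A `trip_spec`.
#' @export
trip_spec <- function(duration = 1200, dt = 1, base_speed = 60,
                      speed_noise_sd = 0.5,
                      accel_burst_model = c(mean = 1.0, sd = 0.6),
                      decel_burst_model = c(mean = 1.2, sd = 0.8),
                      maneuver_rate = 0.05, band = 5,
                      injected_events = NULL, over_speed_segments = NULL,
                      seed = 1L) {
  check_number(duration, "duration", min = 0, strict = TRUE)
  check_number(dt, "dt", min = 0, strict = TRUE)
  check_number(base_speed, "base_speed", min = 0)
  check_number(speed_noise_sd, "speed_noise_sd", min = 0)
  check_number(maneuver_rate, "maneuver_rate", min = 0)
  check_number(band, "band", min = 0)
  for (m in list(accel_burst_model, decel_burst_model)) {
    if (length(m) != 2L || any(!is.finite(m)) || m[[2L]] < 0) {
      stop_config("burst models must be c(mean, sd) with sd >= 0")
    }
  }
  if (!is.null(injected_events)) {
    for (ev in injected_events) {
      if (!all(c("label", "count", "magnitude") %in% names(ev)) ||
          !ev$label %in% INJECTABLE_LABELS ||
          ev$count < 0 || length(ev$magnitude) != 2L ||
          ev$magnitude[[1L]] <= 0 || ev$magnitude[[1L]] > ev$magnitude[[2L]]) {
        stop_config(paste0(
          "each injected event needs label in {",
          paste(INJECTABLE_LABELS, collapse = ", "),
          "}, count >= 0 and magnitude = c(lo, hi) with 0 < lo <= hi"
        ))
      }
    }
  }
  if (!is.null(over_speed_segments)) {
    for (sg in over_speed_segments) {
      if (!all(c("start", "length", "target") %in% names(sg)) ||
          sg$start < 0 || sg$length <= 0 || sg$target < 0) {
        stop_config("over-speed segments need start >= 0, length > 0, target >= 0")
      }
    }
  }
  structure(
    list(duration = duration, dt = dt, base_speed = base_speed,
         speed_noise_sd = speed_noise_sd,
         accel_burst_model = unname(accel_burst_model),
         decel_burst_model = unname(decel_burst_model),
         maneuver_rate = maneuver_rate, band = band,
         injected_events = injected_events,
         over_speed_segments = over_speed_segments,
         seed = as.integer(seed)),
    class = "trip_spec"
  )
}

# positive-truncated Gaussian draw (a maneuver magnitude must be positive)
draw_magnitude <- function(model) {
  if (model[[2L]] == 0) return(max(model[[1L]], 0))
  repeat {
    x <- rnorm(1L, model[[1L]], model[[2L]])
    if (x > 0) return(x)
  }
}

check_injection_range <- function(label, lo, hi, thresholds) {
  ok <- switch(label,
    aggressive_accel = lo > thresholds$accel_t1 && hi <= thresholds$accel_t2,
    dangerous_accel  = lo > thresholds$accel_t2,
    aggressive_decel = lo > -thresholds$decel_t1 && hi <= -thresholds$decel_t2,
    dangerous_decel  = lo > -thresholds$decel_t2
  )
  if (!ok) {
    stop_config(sprintf(
      "injected %s magnitude range [%g, %g] is not consistent with the active thresholds",
      label, lo, hi
    ))
  }
}

#' Simulate one trip with its ground-truth label ledger
#'
#' Builds an acceleration sequence sample by sample — Gaussian speed jitter
#' by default, an ordinary throttle/braking maneuver with probability
#' `maneuver_rate` (direction chosen by a controller holding the cruise
#' band, magnitude drawn from the burst model), and injected severe events
#' spliced at seeded, non-overlapping random indices — then integrates it
#' into the speed trace, clipping at standstill (a clipped step is re-zeroed
#' in both the trace and the ledger so they stay consistent). Because speed
#' is integrated from the constructed accelerations, the ledger's labels
#' are exact by construction: each event label is the classification of the
#' constructed acceleration under the supplied thresholds, each speed label
#' the classification of the constructed speed under the policy.
#'
#' @param spec A [trip_spec()].
#' @param thresholds [threshold_set()] the ledger (and injection-range
#'   validation) uses.
#' @param policy [speed_policy()] for ground-truth speed labels.
#' @param zero_eps Zero-band half width in m/s².
#' @param driver_id,trip_id Labels stamped on the generated trip.
#' @return A list: `trip` (a [trip()] with metric records), `ledger` (list
#'   with per-sample `event_label`, per-record `speed_label`, the exact
#'   constructed accelerations `a`, and an `injected` index tibble).
#' @export
#' @examples
#' sim <- simulate_trip(trip_spec(duration = 60, seed = 7), driver_id = "D1")
#' head(sim$trip$records)
simulate_trip <- function(spec, thresholds = threshold_preset("methods"),
                          policy = speed_policy(), zero_eps = 0,
                          driver_id = "D1", trip_id = "T1") {
  stopifnot(inherits(spec, "trip_spec"), inherits(thresholds, "threshold_set"))
  # a trip of `duration` seconds at cadence dt holds duration/dt readings,
  # hence one fewer kinematic samples
  n <- as.integer(round(spec$duration / spec$dt)) - 1L
  if (n < 1L) stop_config("spec yields no kinematic samples")

  inj_label <- character(n)   # "" = not injected
  inj_range <- vector("list", n)
  total_inject <- 0L
  with_seed(spec$seed, {
    if (!is.null(spec$injected_events)) {
      total_inject <- sum(vapply(spec$injected_events, `[[`, numeric(1), "count"))
      if (total_inject > n) {
        stop_config(sprintf("injected events (%d) exceed available samples (%d)",
                            total_inject, n))
      }
      for (ev in spec$injected_events) {
        check_injection_range(ev$label, ev$magnitude[[1L]], ev$magnitude[[2L]],
                              thresholds)
      }
      pool <- which(inj_label == "")
      for (ev in spec$injected_events) {
        if (ev$count == 0) next
        pick <- pool[sample.int(length(pool), ev$count)]
        inj_label[pick] <- ev$label
        for (j in pick) inj_range[[j]] <- ev$magnitude
        pool <- setdiff(pool, pick)
      }
    }

    noise_a <- (spec$speed_noise_sd / 3.6) / spec$dt
    seg_target <- rep(spec$base_speed, n)
    if (!is.null(spec$over_speed_segments)) {
      t_start <- (seq_len(n) - 1L) * spec$dt
      for (sg in spec$over_speed_segments) {
        inside <- t_start >= sg$start & t_start < sg$start + sg$length
        seg_target[inside] <- sg$target
      }
    }

    v <- numeric(n + 1L)
    v[1L] <- spec$base_speed
    a <- numeric(n)
    for (i in seq_len(n)) {
      if (inj_label[i] != "") {
        mag <- runif(1L, inj_range[[i]][[1L]], inj_range[[i]][[2L]])
        ai <- if (grepl("accel$", inj_label[i])) mag else -mag
      } else if (runif(1L) < spec$maneuver_rate) {
        target <- seg_target[i]
        dir <- if (v[i] > target + spec$band) {
          -1
        } else if (v[i] < target - spec$band) {
          1
        } else if (runif(1L) < 0.5) 1 else -1
        mag <- draw_magnitude(
          if (dir > 0) spec$accel_burst_model else spec$decel_burst_model
        )
        ai <- dir * mag
      } else {
        ai <- if (noise_a > 0) rnorm(1L, 0, noise_a) else 0
      }
      vn <- v[i] + ai * spec$dt * 3.6
      if (vn < 0) {       # standstill clip: re-zero the step in the ledger too
        vn <- v[i]
        ai <- 0
        inj_label[i] <- ""
      }
      v[i + 1L] <- vn
      a[i] <- ai
    }
  })

  t <- (0:n) * spec$dt
  dist <- c(0, cumsum((v[-1L] + v[-(n + 1L)]) / 2 * spec$dt / 3600))
  lat <- 3.7 + dist / 110.574          # dead-reckoned due north
  lon <- rep(101.52, n + 1L)
  records <- tibble::tibble(
    t = t, speed = v, distance = dist, lat = lat, lon = lon,
    altitude = rep(60, n + 1L),
    time = format(as.POSIXct("2020-08-01 08:00:00", tz = "UTC") + t,
                  "%H:%M:%S"),
    lat_bd09 = sprintf("%.6f", lat + 0.0060),
    lon_bd09 = sprintf("%.6f", lon + 0.0065)
  )
  tr <- trip(driver_id, trip_id, records)
  inj_idx <- which(inj_label != "")
  ledger <- list(
    event_label = classify_sample(a, thresholds, zero_eps),
    speed_label = classify_speed(v, policy),
    a = a,
    injected = tibble::tibble(index = inj_idx, label = inj_label[inj_idx])
  )
  list(trip = tr, ledger = ledger)
}

#' Build per-driver trip specs for a cohort
#'
#' Derives one deterministic sub-seed per (driver, trip) from the master
#' seed so cohorts are reproducible end to end.
#'
#' @param n_drivers,trips_per_driver Cohort shape (the emulated study used
#'   16 riders with at least three trips each).
#' @param base A [trip_spec()] whose fields (other than `seed`) every trip
#'   copies.
#' @param seed Master integer seed.
#' @return Named list (driver id -> list of `trip_spec`s) for
#'   [simulate_cohort()].
#' @export
cohort_trip_specs <- function(n_drivers = 16, trips_per_driver = 3,
                              base = trip_spec(), seed = 1L) {
  stopifnot(inherits(base, "trip_spec"), n_drivers >= 1, trips_per_driver >= 1)
  specs <- list()
  for (d in seq_len(n_drivers)) {
    per <- list()
    for (k in seq_len(trips_per_driver)) {
      s <- base
      s$seed <- as.integer((as.numeric(seed) + 1000003 * d + 7919 * k) %%
                             2147483647)
      per[[paste0("T", k)]] <- s
    }
    specs[[paste0("D", d)]] <- per
  }
  specs
}

#' Simulate a cohort of drivers
#'
#' Runs [simulate_trip()] for every (driver, trip) spec and returns the
#' trips with their ledgers and an index.
#'
#' @param specs Named list: driver id -> list of [trip_spec()]s (see
#'   [cohort_trip_specs()]). Driver ids must be unique and non-empty.
#' @inheritParams simulate_trip
#' @return A list with `trips` (list of [trip()]s), `ledgers` (parallel
#'   list), and `index` (tibble `driver_id`, `trip_id`, `n_records`).
#' @export
simulate_cohort <- function(specs, thresholds = threshold_preset("methods"),
                            policy = speed_policy(), zero_eps = 0) {
  if (!is.list(specs) || length(specs) == 0L) {
    stop_config("`specs` must be a non-empty named list of per-driver spec lists")
  }
  ids <- names(specs)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids)) {
    stop_config("driver ids must be unique, non-empty names of `specs`")
  }
  trips <- list()
  ledgers <- list()
  idx <- list()
  for (d in ids) {
    per <- specs[[d]]
    trip_ids <- names(per) %||% paste0("T", seq_along(per))
    for (k in seq_along(per)) {
      sim <- simulate_trip(per[[k]], thresholds = thresholds, policy = policy,
                           zero_eps = zero_eps, driver_id = d,
                           trip_id = trip_ids[[k]])
      key <- paste(d, trip_ids[[k]], sep = "/")
      trips[[key]] <- sim$trip
      ledgers[[key]] <- sim$ledger
      idx[[key]] <- tibble::tibble(driver_id = d, trip_id = trip_ids[[k]],
                                   n_records = nrow(sim$trip$records))
    }
  }
  list(trips = trips, ledgers = ledgers, index = dplyr::bind_rows(idx))
}

#' Write a trip back out in the app's log dialect
#'
#' Inverse of [parse_speedometer_log()] + [clean_records()]: metric fields
#' are converted back to the dialect's native units (mph, miles, feet) and
#' printed at the dialect's decimal precision, so a parse + clean round
#' trip reproduces the trip numerically at that precision.
#'
#' @param trip A [trip()].
#' @param dialect A [gps_dialect()].
#' @param path Optional file path; `NULL` returns the CSV text as a
#'   character vector of lines.
#' @return The lines, invisibly when written to `path`.
#' @export
write_log <- function(trip, dialect = gps_dialect(), path = NULL) {
  stopifnot(inherits(trip, "trip"))
  rec <- trip$records
  delim <- dialect$delim %||% ","
  fmt <- function(x) formatC(x, format = "f", digits = dialect$decimals)
  n <- nrow(rec)
  col_or <- function(name, default) {
    if (name %in% names(rec)) rec[[name]] else rep(default, n)
  }
  # optional fields default to plausible constants so minimal (t, speed)
  # trips still serialize; distance falls back to the speed integral
  dist <- if ("distance" %in% names(rec)) {
    rec$distance
  } else if (n > 1) {
    c(0, cumsum((rec$speed[-1L] + rec$speed[-n]) / 2 * diff(rec$t) / 3600))
  } else {
    rep(0, n)
  }
  lat <- col_or("lat", 3.7)
  lon <- col_or("lon", 101.52)
  cols <- list(
    duration       = fmt(rec$t),
    time           = col_or("time", ""),
    distance_miles = fmt(dist / MILES_TO_KM),
    speed_mph      = fmt(rec$speed / MILES_TO_KM),
    lat_wgs84      = fmt(lat),
    lon_wgs84      = fmt(lon),
    altitude_feet  = fmt(col_or("altitude", 60) / FEET_TO_M),
    lat_bd09       = if ("lat_bd09" %in% names(rec)) rec$lat_bd09 else fmt(lat + 0.0060),
    lon_bd09       = if ("lon_bd09" %in% names(rec)) rec$lon_bd09 else fmt(lon + 0.0065)
  )
  header <- paste(unname(dialect$columns), collapse = delim)
  body <- if (n > 0) do.call(paste, c(cols, sep = delim)) else character(0)
  lines <- c(header, body)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
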