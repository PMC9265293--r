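# cli_reporting: configuration, end-to-end runs and table artifacts.

#' Pipeline configuration
#'
#' Validated bundle of every knob the end-to-end run uses. Threshold modes:
#' `"pooled"` learns one cut-off set from all drivers' samples together
#' (the default: the cohort defines its own normality), `"per-driver"`
#' learns one per driver, `"preset"` uses a frozen published set (see
#' [threshold_preset()]), and `"frozen"` uses the [threshold_set()] passed
#' in `thresholds`.
#'
#' @param dialect A [gps_dialect()].
#' @param zero_eps Zero-band half width in m/s².
#' @param k1,k2 Sigma multipliers, `0 < k1 < k2`.
#' @param threshold_mode One of `"pooled"`, `"per-driver"`, `"preset"`,
#'   `"frozen"`.
#' @param preset Preset name when `threshold_mode = "preset"`.
#' @param thresholds Frozen [threshold_set()] when `threshold_mode = "frozen"`.
#' @param policy A [speed_policy()].
#' @param seed Integer seed recorded in run manifests (the profiling run
#'   itself is deterministic; the seed feeds simulation commands).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(dialect = gps_dialect(), zero_eps = 0,
                            k1 = 1, k2 = 2,
                            threshold_mode = c("pooled", "per-driver",
                                               "preset", "frozen"),
                            preset = "methods", thresholds = NULL,
                            policy = speed_policy(), seed = 1L) {
  threshold_mode <- match.arg(threshold_mode)
  check_k(k1, k2)
  check_number(zero_eps, "zero_eps", min = 0)
  stopifnot(inherits(dialect, "gps_dialect"), inherits(policy, "speed_policy"))
  if (threshold_mode == "frozen" && !inherits(thresholds, "threshold_set")) {
    stop_config('threshold_mode = "frozen" requires a threshold_set in `thresholds`')
  }
  if (threshold_mode == "preset") {
    thresholds <- threshold_preset(preset)
  }
  structure(
    list(dialect = dialect, zero_eps = zero_eps, k1 = k1, k2 = k2,
         threshold_mode = threshold_mode, preset = preset,
         thresholds = thresholds, policy = policy, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

config_hash <- function(config) {
  rlang::hash(unclass(config))
}

write_table_csv <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full profiling pipeline
#'
#' Two-phase end-to-end run over a set of trips: first learn (or load) the
#' severity thresholds, then classify every kinematic sample and speed
#' reading and aggregate the per-driver and cohort tables. Input is either
#' a tibble of log files (`path`, `driver_id`, optional `trip_id`) parsed
#' through the configured dialect, or a list of ready [trip()] objects.
#'
#' @param logs Tibble with columns `path`, `driver_id` (optionally
#'   `trip_id`), or a list of [trip()]s.
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory; when given, the tables, cleaning
#'   report, threshold set and a run manifest are written there as CSV/JSON.
#' @return A list: `thresholds` (the set actually used; named list of sets
#'   in per-driver mode), `profiles`, `ratios`, `cohort`
#'   ([cohort_summary()]), `speed` ([speed_summary()]), `labeled` (list of
#'   per-trip label streams), `cleaning` (list of cleaning reports, for
#'   file input), and `manifest`.
#' @export
run_profile <- function(logs, config = pipeline_config(), output_dir = NULL) {
  trips <- list()
  cleaning <- list()
  if (is.data.frame(logs)) {
    if (!all(c("path", "driver_id") %in% names(logs)) || nrow(logs) == 0L) {
      stop_data("`logs` needs at least one row with columns path and driver_id")
    }
    for (i in seq_len(nrow(logs))) {
      trip_id <- if ("trip_id" %in% names(logs)) logs$trip_id[i] else paste0("T", i)
      got <- read_trip(logs$path[i], logs$driver_id[i], trip_id,
                       dialect = config$dialect)
      key <- paste(logs$driver_id[i], trip_id, sep = "/")
      trips[[key]] <- got$trip
      cleaning[[key]] <- got$report
    }
  } else if (is.list(logs) && length(logs) > 0 &&
             all(vapply(logs, inherits, logical(1), "trip"))) {
    for (tr in logs) {
      trips[[paste(tr$driver_id, tr$trip_id, sep = "/")]] <- tr
    }
  } else {
    stop_data("`logs` must be a path tibble or a non-empty list of trips")
  }

  series <- lapply(trips, derive_kinematics)
  drivers <- vapply(trips, `[[`, character(1), "driver_id")
  pooled_a <- unlist(lapply(series, `[[`, "a"), use.names = FALSE)

  thresholds <- switch(config$threshold_mode,
    pooled = learn_thresholds(pooled_a, config$k1, config$k2, config$zero_eps),
    `per-driver` = {
      by_driver <- split(series, drivers)
      lapply(by_driver, function(ss) {
        learn_thresholds(unlist(lapply(ss, `[[`, "a"), use.names = FALSE),
                         config$k1, config$k2, config$zero_eps)
      })
    },
    preset = ,
    frozen = config$thresholds
  )

  labeled <- lapply(names(trips), function(key) {
    th <- if (config$threshold_mode == "per-driver") {
      thresholds[[trips[[key]]$driver_id]]
    } else {
      thresholds
    }
    label_trip(series[[key]], trips[[key]]$records, th, config$policy,
               config$zero_eps)
  })
  names(labeled) <- names(trips)

  event_by_driver <- split(
    lapply(labeled, function(l) as.character(l$events$event_label)), drivers
  )
  speed_by_driver <- split(
    lapply(labeled, function(l) as.character(l$speeds$speed_label)), drivers
  )
  ids <- unique(drivers)
  profiles <- dplyr::bind_rows(lapply(ids, function(d) {
    build_driver_profile(unlist(event_by_driver[[d]], use.names = FALSE), d)
  }))
  speed_profiles <- dplyr::bind_rows(lapply(ids, function(d) {
    build_speed_profile(unlist(speed_by_driver[[d]], use.names = FALSE), d)
  }))

  ratios <- event_ratios(profiles)
  cohort <- cohort_summary(profiles, n_trips = length(trips))
  speed <- speed_summary(speed_profiles)

  manifest <- list(
    n_trips = length(trips),
    n_drivers = length(ids),
    drivers = ids,
    threshold_mode = config$threshold_mode,
    thresholds = if (config$threshold_mode == "per-driver") {
      lapply(thresholds, unclass)
    } else {
      unclass(thresholds)
    },
    config_hash = config_hash(config),
    rows_dropped = sum(vapply(cleaning, function(r) r$rows_dropped, numeric(1)) %||% 0)
  )

  result <- list(thresholds = thresholds, profiles = profiles, ratios = ratios,
                 cohort = cohort, speed = speed, labeled = labeled,
                 cleaning = cleaning, manifest = manifest)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_table_csv(profiles, output_dir, "driver_profiles")
    write_table_csv(ratios, output_dir, "event_ratios")
    write_table_csv(speed$per_driver, output_dir, "speed_profiles")
    cohort_df <- tibble::tibble(
      feature = c("sample_size", "n_trips", names(cohort$mean_counts),
                  "grand_total", "normal_share_pct"),
      value = c(cohort$n_drivers, cohort$n_trips, unname(cohort$mean_counts),
                cohort$grand_total, cohort$normal_share_pct)
    )
    write_table_csv(cohort_df, output_dir, "cohort_summary")
    if (config$threshold_mode != "per-driver") {
      thresholds_to_json(thresholds, file.path(output_dir, "thresholds.json"))
    }
    writeLines(
      jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA),
      file.path(output_dir, "run_manifest.json")
    )
    if (length(cleaning) > 0) {
      writeLines(
        jsonlite::toJSON(lapply(cleaning, unclass), dataframe = "rows",
                         auto_unbox = TRUE, pretty = TRUE),
        file.path(output_dir, "cleaning_report.json")
      )
    }
  }
  result
}

#' Replay published count tables through the aggregation stages
#'
#' Fixture mode: takes per-driver event-count and speed-count tables (for
#' example the bundled [motorcycle_cohort_events()] /
#' [motorcycle_cohort_speeds()]) and regenerates the ratio table, cohort
#' summary and speed summary without any traces.
#'
#' @param profiles Event-count profile tibble.
#' @param speed_profiles Optional speed-count profile tibble.
#' @param n_trips Trip-count metadata for the cohort summary.
#' @return A list with `ratios`, `pooled_ratios` (ratios of the summed
#'   cohort profile), `cohort`, and `speed` (when given).
#' @export
#' @examples
#' rep <- replay_tables(motorcycle_cohort_events(),
#'                      motorcycle_cohort_speeds(), n_trips = 116)
#' rep$cohort
replay_tables <- function(profiles, speed_profiles = NULL,
                          n_trips = NA_integer_) {
  profiles <- bind_profiles(profiles)
  pooled <- dplyr::summarise(
    profiles,
    driver_id = "pooled",
    dplyr::across(dplyr::all_of(c(EVENT_LABELS, "total")), sum)
  )
  list(
    ratios = event_ratios(profiles),
    pooled_ratios = event_ratios(pooled),
    cohort = cohort_summary(profiles, n_trips = n_trips),
    speed = if (!is.null(speed_profiles)) speed_summary(speed_profiles)
  )
}

#' Simulate trips and write them as app-dialect logs
#'
#' Delegates to the synthetic generator and writes one CSV per trip plus a
#' ground-truth ledger JSON per trip and a manifest listing every file
#' written, under one directory per driver.
#'
#' @param specs Named list of per-driver [trip_spec()] lists (see
#'   [cohort_trip_specs()]).
#' @param output_dir Directory to populate.
#' @param config A [pipeline_config()] (supplies dialect, policy, zero_eps;
#'   preset/frozen thresholds are used for the ledgers, otherwise the
#'   `"methods"` preset).
#' @return The manifest (list), invisibly; `manifest$files` is a tibble of
#'   `driver_id`, `trip_id`, `log`, `ledger` paths.
#' @export
run_simulate <- function(specs, output_dir, config = pipeline_config()) {
  thresholds <- config$thresholds %||% threshold_preset("methods")
  cohort <- simulate_cohort(specs, thresholds = thresholds,
                            policy = config$policy,
                            zero_eps = config$zero_eps)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (key in names(cohort$trips)) {
    tr <- cohort$trips[[key]]
    led <- cohort$ledgers[[key]]
    ddir <- file.path(output_dir, tr$driver_id)
    dir.create(ddir, showWarnings = FALSE)
    log_path <- file.path(ddir, paste0(tr$trip_id, ".csv"))
    write_log(tr, config$dialect, log_path)
    ledger_path <- file.path(ddir, paste0(tr$trip_id, "_ledger.json"))
    writeLines(
      jsonlite::toJSON(
        list(event_label = as.character(led$event_label),
             speed_label = as.character(led$speed_label),
             a = led$a, injected = led$injected),
        dataframe = "rows", auto_unbox = TRUE, digits = NA
      ),
      ledger_path
    )
    rows[[key]] <- tibble::tibble(driver_id = tr$driver_id,
                                  trip_id = tr$trip_id,
                                  log = log_path, ledger = ledger_path)
  }
  manifest <- list(
    files = dplyr::bind_rows(rows),
    thresholds = unclass(thresholds),
    config_hash = config_hash(config)
  )
  writeLines(
    jsonlite::toJSON(manifest, dataframe = "rows", auto_unbox = TRUE,
                     pretty = TRUE, digits = NA),
    file.path(output_dir, "simulate_manifest.json")
  )
  invisible(manifest)
}
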