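# trace_io: parse, clean and unit-convert speedometer-app CSV logs.

MILES_TO_KM <- 1.609344   # international mile
FEET_TO_M   <- 0.3048     # international foot

CANONICAL_COLUMNS <- c(
  "duration", "time", "distance_miles", "speed_mph",
  "lat_wgs84", "lon_wgs84", "altitude_feet", "lat_bd09", "lon_bd09"
)

# columns that must coerce to finite numbers for a row to survive cleaning;
# `time` is a wall-clock string and is carried through untouched, and the
# BD09 pair is parsed but never used analytically.
NUMERIC_COLUMNS <- c(
  "duration", "distance_miles", "speed_mph",
  "lat_wgs84", "lon_wgs84", "altitude_feet"
)

#' Log file dialect for speedometer app exports
#'
#' Describes how a particular app export maps its header names onto the
#' canonical fields (`duration`, `time`, `distance_miles`, `speed_mph`,
#' `lat_wgs84`, `lon_wgs84`, `altitude_feet`, `lat_bd09`, `lon_bd09`), which
#' delimiter it uses, and at how many decimals numeric cells are printed.
#' The default matches the Android speedometer app's export: imperial units
#' (miles, mph, feet) and positions in both WGS84 and BD09.
#'
#' @param columns Named character vector mapping canonical field names to the
#'   header names found in the file. Must cover every canonical field.
#' @param delim Field delimiter; `NULL` auto-detects comma vs tab from the
#'   header line.
#' @param decimals Number of decimals used when writing numeric cells (see
#'   [write_log()]); the app's own precision is unknown, 4 is the default.
#' @return A `gps_dialect` object.
#' @export
#' @examples
#' gps_dialect()
gps_dialect <- function(columns = NULL, delim = NULL, decimals = 4) {
  default <- c(
    duration       = "duration",
    time           = "time",
    distance_miles = "distance (miles)",
    speed_mph      = "speed (mph)",
    lat_wgs84      = "latitude (WGS84)",
    lon_wgs84      = "longitude (WGS84)",
    altitude_feet  = "altitude (feet)",
    lat_bd09       = "latitude (BD09)",
    lon_bd09       = "longitude (BD09)"
  )
  columns <- columns %||% default
  missing <- setdiff(CANONICAL_COLUMNS, names(columns))
  if (length(missing) > 0) {
    stop_config(paste0(
      "dialect column map is missing canonical fields: ",
      paste(missing, collapse = ", ")
    ))
  }
  if (!is.null(delim) && !delim %in% c(",", "\t", ";")) {
    stop_config('`delim` must be one of "," "\\t" ";"')
  }
  check_number(decimals, "decimals", min = 0)
  structure(
    list(columns = columns[CANONICAL_COLUMNS], delim = delim,
         decimals = as.integer(decimals)),
    class = "gps_dialect"
  )
}

#' @export
print.gps_dialect <- function(x, ...) {
  cat("<gps_dialect>\n")
  cat("  delimiter:", if (is.null(x$delim)) "auto" else deparse(x$delim), "\n")
  cat("  decimals: ", x$decimals, "\n")
  for (k in names(x$columns)) {
    cat(sprintf("  %-14s <- %s\n", k, deparse(unname(x$columns[[k]]))))
  }
  invisible(x)
}

detect_delim <- function(header_line) {
  if (grepl("\t", header_line, fixed = TRUE)) "\t" else ","
}

#' Parse a speedometer-app log into raw rows
#'
#' Reads delimited text (a file path, a connection, or the text itself) with
#' one header line, maps the header onto the dialect's canonical fields and
#' returns one raw row per data line, in file order, with every cell kept as
#' uncoerced text. Blank lines are carried forward so that [clean_records()]
#' can account for them; the parser itself filters nothing.
#'
#' @param stream A file path, connection, or character vector of lines (a
#'   single string may contain embedded newlines).
#' @param dialect A [gps_dialect()].
#' @return A tibble with `line_number` (1-based data-line index) and one
#'   character column per canonical field.
#' @export
#' @examples
#' txt <- c(
#'   "duration,time,distance (miles),speed (mph),latitude (WGS84),longitude (WGS84),altitude (feet),latitude (BD09),longitude (BD09)",
#'   "0,08:00:00,0,0,3.7,101.5,200,3.706,101.5065",
#'   "1,08:00:01,0.005,31.07,3.7001,101.5,200,3.7061,101.5065"
#' )
#' parse_speedometer_log(txt)
parse_speedometer_log <- function(stream, dialect = gps_dialect()) {
  lines <- if (inherits(stream, "connection")) {
    readLines(stream, warn = FALSE)
  } else if (is.character(stream) && length(stream) == 1L &&
             !grepl("\n", stream, fixed = TRUE) && file.exists(stream)) {
    readLines(stream, warn = FALSE)
  } else if (is.character(stream)) {
    # strsplit maps "" to character(0); keep blank lines as blank rows
    unlist(lapply(strsplit(stream, "\n", fixed = TRUE),
                  function(x) if (length(x) == 0L) "" else x),
           use.names = FALSE)
  } else {
    stop_data("`stream` must be a file path, connection, or character text")
  }
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    abort("empty stream: no header line found",
          class = "motoprofile_dialect_error")
  }
  delim <- dialect$delim %||% detect_delim(lines[[1L]])
  header <- trimws(strsplit(lines[[1L]], delim, fixed = TRUE)[[1L]])
  idx <- match(unname(dialect$columns), header)
  if (anyNA(idx)) {
    missing <- names(dialect$columns)[is.na(idx)]
    abort(
      paste0(
        "header does not match dialect; missing columns: ",
        paste(sprintf("%s (expected header %s)", missing,
                      sQuote(dialect$columns[missing])), collapse = ", ")
      ),
      class = "motoprofile_dialect_error"
    )
  }
  data_lines <- lines[-1L]
  cells <- lapply(data_lines, function(l) trimws(strsplit(l, delim, fixed = TRUE)[[1L]]))
  grab <- function(j) {
    vapply(cells, function(cc) if (j <= length(cc)) cc[[j]] else "", character(1))
  }
  out <- lapply(idx, grab)
  names(out) <- names(dialect$columns)
  tibble::as_tibble(c(list(line_number = seq_along(data_lines)), out))
}

#' Convert imperial log units to metric
#'
#' Applies the exact international definitions 1 mile = 1.609344 km and
#' 1 foot = 0.3048 m, with no rounding. All three arguments are vectorized
#' and recycled by the usual rules.
#'
#' @param speed_mph,distance_miles,altitude_feet Finite non-negative numerics.
#' @return A list with `speed_kmh`, `distance_km`, `altitude_m`.
#' @export
#' @examples
#' convert_units(50, 10, 100)  # 80.4672 km/h, 16.09344 km, 30.48 m
convert_units <- function(speed_mph, distance_miles, altitude_feet) {
  vals <- list(speed_mph = speed_mph, distance_miles = distance_miles,
               altitude_feet = altitude_feet)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      stop_domain(sprintf("`%s` must be finite numeric", nm))
    }
    if (any(v < 0)) {
      stop_domain(sprintf("`%s` must be non-negative", nm))
    }
  }
  list(
    speed_kmh   = speed_mph * MILES_TO_KM,
    distance_km = distance_miles * MILES_TO_KM,
    altitude_m  = altitude_feet * FEET_TO_M
  )
}

#' Clean raw log rows into metric GPS records
#'
#' Coerces each raw row to numeric, converts to metric units and enforces a
#' strictly increasing timeline. Every dropped row is logged with exactly one
#' primary reason, checked in this order: `empty_row` (all cells blank),
#' `non_numeric` (a required cell fails numeric coercion), `negative_value`
#' (speed, distance or duration below zero), `duplicate_timestamp` (same
#' timestamp as the last kept row), `non_monotonic_time` (timestamp earlier
#' than the last kept row). First occurrence wins on timestamp conflicts.
#'
#' @param rows Raw rows from [parse_speedometer_log()].
#' @return A list with `records` (tibble: `t` seconds, `speed` km/h,
#'   `distance` km, `lat`, `lon` degrees WGS84, `altitude` m, `time`,
#'   `lat_bd09`, `lon_bd09` carried as text) and `report`, a
#'   `cleaning_report` with `rows_read`, `rows_kept`, `rows_dropped`, a
#'   per-row `reasons` tibble and a `high_drop_rate` flag set when more than
#'   half the rows were dropped.
#' @export
clean_records <- function(rows) {
  stopifnot(is.data.frame(rows))
  n <- nrow(rows)
  reasons <- character(0)
  reason_lines <- integer(0)
  keep <- logical(n)
  num <- matrix(NA_real_, nrow = n, ncol = length(NUMERIC_COLUMNS),
                dimnames = list(NULL, NUMERIC_COLUMNS))
  last_t <- -Inf
  for (i in seq_len(n)) {
    cells <- vapply(CANONICAL_COLUMNS, function(k) as.character(rows[[k]][i]),
                    character(1))
    drop_reason <- NULL
    if (all(!nzchar(cells) | is.na(cells))) {
      drop_reason <- "empty_row"
    } else {
      vals <- suppressWarnings(setNames(as.numeric(cells[NUMERIC_COLUMNS]),
                                        NUMERIC_COLUMNS))
      if (anyNA(vals)) {
        drop_reason <- "non_numeric"
      } else if (vals[["speed_mph"]] < 0 || vals[["distance_miles"]] < 0 ||
                 vals[["duration"]] < 0) {
        drop_reason <- "negative_value"
      } else if (vals[["duration"]] == last_t) {
        drop_reason <- "duplicate_timestamp"
      } else if (vals[["duration"]] < last_t) {
        drop_reason <- "non_monotonic_time"
      } else {
        keep[i] <- TRUE
        num[i, ] <- vals
        last_t <- vals[["duration"]]
      }
    }
    if (!is.null(drop_reason)) {
      reasons <- c(reasons, drop_reason)
      reason_lines <- c(reason_lines, rows$line_number[i])
    }
  }
  kept <- which(keep)
  if (length(kept) == 0L) {
    stop_data("no rows survived cleaning: empty trip")
  }
  metric <- convert_units(
    speed_mph      = num[kept, "speed_mph"],
    distance_miles = num[kept, "distance_miles"],
    altitude_feet  = abs(num[kept, "altitude_feet"])
  )
  # altitude below sea level is physically possible; convert sign-preserving
  altitude_m <- num[kept, "altitude_feet"] * FEET_TO_M
  records <- tibble::tibble(
    t        = num[kept, "duration"],
    speed    = metric$speed_kmh,
    distance = metric$distance_km,
    lat      = num[kept, "lat_wgs84"],
    lon      = num[kept, "lon_wgs84"],
    altitude = altitude_m,
    time     = as.character(rows$time[kept]),
    lat_bd09 = as.character(rows$lat_bd09[kept]),
    lon_bd09 = as.character(rows$lon_bd09[kept])
  )
  report <- structure(
    list(
      rows_read = n,
      rows_kept = length(kept),
      rows_dropped = n - length(kept),
      reasons = tibble::tibble(line_number = reason_lines, reason = reasons),
      high_drop_rate = (n - length(kept)) > n / 2
    ),
    class = "cleaning_report"
  )
  if (report$high_drop_rate) {
    warn(sprintf("cleaning dropped %d of %d rows (> 50%%)",
                 report$rows_dropped, report$rows_read))
  }
  list(records = records, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("<cleaning_report> read %d, kept %d, dropped %d\n",
              x$rows_read, x$rows_kept, x$rows_dropped))
  if (x$rows_dropped > 0) {
    tab <- table(x$reasons$reason)
    for (r in names(tab)) cat(sprintf("  %-20s %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Serialize a cleaning report to JSON
#'
#' @param report A `cleaning_report` from [clean_records()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON text (invisibly, when written to a file).
#' @export
cleaning_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "cleaning_report"))
  js <- jsonlite::toJSON(unclass(report), dataframe = "rows", auto_unbox = TRUE,
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Construct a trip
#'
#' A trip is one driver's contiguous recording: an ordered set of cleaned,
#' metric GPS records. Kinematic derivation requires at least two records.
#'
#' @param driver_id,trip_id Labels.
#' @param records Tibble of cleaned records as returned by [clean_records()]
#'   (at minimum columns `t` and `speed`; `t` strictly increasing).
#' @return A `trip` object.
#' @export
trip <- function(driver_id, trip_id, records) {
  stopifnot(is.data.frame(records), all(c("t", "speed") %in% names(records)))
  if (nrow(records) > 1 && any(diff(records$t) <= 0)) {
    stop_data("trip records must have strictly increasing timestamps")
  }
  if (any(records$speed < 0)) {
    stop_data("trip speeds must be non-negative")
  }
  structure(
    list(driver_id = as.character(driver_id), trip_id = as.character(trip_id),
         records = tibble::as_tibble(records)),
    class = "trip"
  )
}

#' @export
print.trip <- function(x, ...) {
  cat(sprintf("<trip> driver %s, trip %s: %d records over %.0f s\n",
              x$driver_id, x$trip_id, nrow(x$records),
              diff(range(x$records$t))))
  invisible(x)
}

#' Read a log file straight into a trip
#'
#' Convenience wrapper chaining [parse_speedometer_log()] and
#' [clean_records()].
#'
#' @inheritParams parse_speedometer_log
#' @inheritParams trip
#' @return A list with `trip` and the `cleaning_report`.
#' @export
read_trip <- function(stream, driver_id, trip_id, dialect = gps_dialect()) {
  cleaned <- clean_records(parse_speedometer_log(stream, dialect))
  list(trip = trip(driver_id, trip_id, cleaned$records),
       report = cleaned$report)
}
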