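# profiling: per-driver and cohort aggregation tables.

#' Build a driver profile from an event-label stream
#'
#' Counts each of the seven event labels over everything the driver was
#' labeled with (typically the concatenation of all their trips). An empty
#' stream yields an all-zero profile. Profiles are additive: the profile of
#' two concatenated streams is the sum of the per-stream profiles.
#'
#' @param labels Factor or character vector of [event_labels()].
#' @param driver_id Driver label.
#' @return A one-row tibble: `driver_id`, one count column per event label,
#'   and `total`.
#' @export
#' @examples
#' build_driver_profile(c("normal_accel", "normal_accel", "zero"), "D1")
build_driver_profile <- function(labels, driver_id) {
  labels <- factor(as.character(labels), levels = EVENT_LABELS)
  if (anyNA(labels)) {
    stop_domain("unknown event label in stream")
  }
  counts <- as.integer(table(labels))
  out <- tibble::as_tibble(as.list(setNames(counts, EVENT_LABELS)))
  tibble::add_column(out, driver_id = as.character(driver_id), .before = 1) |>
    dplyr::mutate(total = sum(counts))
}

#' Assemble a driver profile directly from known counts
#'
#' Used to replay published count tables through the aggregation stages
#' without the underlying traces.
#'
#' @param driver_id Driver label.
#' @param normal_accel,aggressive_accel,dangerous_accel Throttle-side counts.
#' @param normal_decel,aggressive_decel,dangerous_decel Braking-side counts.
#' @param zero Zero-band count.
#' @return A one-row profile tibble as from [build_driver_profile()].
#' @export
driver_profile_from_counts <- function(driver_id, normal_accel,
                                       aggressive_accel, dangerous_accel,
                                       normal_decel, aggressive_decel,
                                       dangerous_decel, zero) {
  counts <- c(normal_accel, aggressive_accel, dangerous_accel,
              normal_decel, aggressive_decel, dangerous_decel, zero)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_domain("event counts must be non-negative integers")
  }
  tibble::tibble(
    driver_id = as.character(driver_id),
    normal_accel = normal_accel, aggressive_accel = aggressive_accel,
    dangerous_accel = dangerous_accel, normal_decel = normal_decel,
    aggressive_decel = aggressive_decel, dangerous_decel = dangerous_decel,
    zero = zero, total = sum(counts)
  )
}

#' Per-second event ratios for a driver
#'
#' Divides each event count by the driver's total sample count (zero events
#' included), giving the share of recorded seconds spent in each severity
#' band. Full precision is retained; rendering at table precision is left to
#' the caller.
#'
#' @param profile One-row profile tibble (possibly several rows; each is
#'   converted independently).
#' @return A tibble with `driver_id` and one ratio column per event label;
#'   ratios sum to 1 per row.
#' @export
event_ratios <- function(profile) {
  stopifnot(is.data.frame(profile))
  if (any(profile$total == 0)) {
    stop_data("event ratios are undefined for a driver with zero samples")
  }
  out <- profile[, c("driver_id", EVENT_LABELS)]
  out[EVENT_LABELS] <- out[EVENT_LABELS] / profile$total
  tibble::as_tibble(out)
}

#' Cohort summary of driver profiles
#'
#' Unweighted per-driver means of each event count, the grand totals, and
#' the cohort's normal-driving share: the pooled fraction of samples labeled
#' normal (throttle or braking side), rendered as a whole percent.
#'
#' @param profiles Profile tibble (one row per driver) or list of one-row
#'   profiles.
#' @param n_trips Optional trip count metadata carried into the summary.
#' @return A `cohort_summary` list: `n_drivers`, `n_trips`, `mean_counts`
#'   (named, one per label plus `total`), `grand_total`,
#'   `normal_share_pct` (whole percent) and `normal_share_raw` (exact).
#' @export
cohort_summary <- function(profiles, n_trips = NA_integer_) {
  profiles <- bind_profiles(profiles)
  if (nrow(profiles) == 0L) {
    stop_data("cohort summary needs at least one driver profile")
  }
  mean_counts <- colMeans(profiles[, c(EVENT_LABELS, "total")])
  grand_total <- sum(profiles$total)
  share <- sum(profiles$normal_accel + profiles$normal_decel) / grand_total * 100
  structure(
    list(
      n_drivers = nrow(profiles),
      n_trips = n_trips,
      mean_counts = mean_counts,
      grand_total = grand_total,
      normal_share_raw = share,
      normal_share_pct = round_half_away(share)
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d drivers, %s trips, %d samples\n",
              x$n_drivers, ifelse(is.na(x$n_trips), "?", x$n_trips),
              x$grand_total))
  for (nm in names(x$mean_counts)) {
    cat(sprintf("  mean %-17s %.4f\n", nm, x$mean_counts[[nm]]))
  }
  cat(sprintf("  normal-driving share: %d%%\n", as.integer(x$normal_share_pct)))
  invisible(x)
}

bind_profiles <- function(profiles) {
  if (is.data.frame(profiles)) {
    tibble::as_tibble(profiles)
  } else {
    dplyr::bind_rows(profiles)
  }
}

#' Build a speed profile from a speed-label stream
#'
#' @param labels Factor or character vector of [speed_labels()].
#' @param driver_id Driver label.
#' @return One-row tibble of per-label counts with `total` and exact
#'   per-label `_ratio` columns.
#' @export
build_speed_profile <- function(labels, driver_id) {
  labels <- factor(as.character(labels), levels = SPEED_LABELS)
  if (anyNA(labels)) {
    stop_domain("unknown speed label in stream")
  }
  counts <- as.integer(table(labels))
  speed_profile_from_counts(driver_id, counts[1L], counts[2L], counts[3L])
}

#' @rdname build_speed_profile
#' @param normal_speed,over_speed,dangerous_speed Reading counts per label.
#' @export
speed_profile_from_counts <- function(driver_id, normal_speed, over_speed,
                                      dangerous_speed) {
  counts <- c(normal_speed, over_speed, dangerous_speed)
  if (any(counts < 0)) stop_domain("speed counts must be non-negative")
  total <- sum(counts)
  tibble::tibble(
    driver_id = as.character(driver_id),
    normal_speed = normal_speed, over_speed = over_speed,
    dangerous_speed = dangerous_speed, total = total,
    normal_speed_ratio = if (total > 0) normal_speed / total else NA_real_,
    over_speed_ratio = if (total > 0) over_speed / total else NA_real_,
    dangerous_speed_ratio = if (total > 0) dangerous_speed / total else NA_real_
  )
}

#' Cohort speed-behavior table
#'
#' Per-driver over-speed shares plus cohort averages: the unweighted mean of
#' the per-driver ratios over the drivers that contributed any readings,
#' rendered both exactly and at whole percent. Drivers with zero readings
#' are excluded with a warning.
#'
#' @param speed_profiles Tibble (one row per driver) or list of one-row
#'   speed profiles from [build_speed_profile()].
#' @return A `speed_summary` list: `per_driver` tibble, `mean_counts`,
#'   `mean_ratios` (exact fractions) and `mean_ratios_pct` (whole-percent
#'   rendering, half away from zero).
#' @export
speed_summary <- function(speed_profiles) {
  per <- bind_profiles(speed_profiles)
  if (nrow(per) == 0L) {
    stop_data("speed summary needs at least one driver")
  }
  empty <- per$total == 0
  if (any(empty)) {
    warn(sprintf("excluding %d driver(s) with zero speed readings: %s",
                 sum(empty), paste(per$driver_id[empty], collapse = ", ")))
    per <- per[!empty, , drop = FALSE]
    if (nrow(per) == 0L) stop_data("no driver has any speed readings")
  }
  ratio_cols <- paste0(SPEED_LABELS, "_ratio")
  mean_ratios <- colMeans(per[, ratio_cols])
  structure(
    list(
      per_driver = per,
      mean_counts = colMeans(per[, SPEED_LABELS]),
      mean_ratios = mean_ratios,
      mean_ratios_pct = round_half_away(mean_ratios * 100)
    ),
    class = "speed_summary"
  )
}

#' @export
print.speed_summary <- function(x, ...) {
  cat(sprintf("<speed_summary> %d drivers\n", nrow(x$per_driver)))
  cat(sprintf("  mean shares: normal %g%%, over %g%%, dangerous %g%%\n",
              x$mean_ratios_pct[[1L]], x$mean_ratios_pct[[2L]],
              x$mean_ratios_pct[[3L]]))
  invisible(x)
}

#' Render a fraction as a table percent
#'
#' Whole-percent rendering with half rounded away from zero, falling back to
#' one decimal only where whole-percent rounding would saturate — a non-zero
#' share that would print as 0%, or a share below 100% that would print as
#' 100% (so a 0.14% share prints as 0.1% against a 99.9% complement, while
#' 99.4% still prints as 99%).
#'
#' @param ratio Fractions in `[0, 1]`.
#' @return Character vector like `"75%"`, `"0.1%"`, `"0"`.
#' @export
#' @examples
#' render_percent(c(0.7497, 0.00139, 0))
render_percent <- function(ratio) {
  pct <- ratio * 100
  vapply(pct, function(p) {
    if (is.na(p)) return(NA_character_)
    if (p == 0) return("0")
    whole <- round_half_away(p)
    if ((whole == 0 && p > 0) || (whole == 100 && p < 100)) {
      return(sprintf("%.1f%%", round_half_away(p, 1)))
    }
    sprintf("%d%%", as.integer(whole))
  }, character(1))
}

#' Bundled 16-rider naturalistic cohort tables
#'
#' The per-driver event-count and speed-count tables from a published
#' 16-rider naturalistic motorcycle study (the only form in which that
#' cohort's data are available; raw traces were not deposited). The speed
#' table covers 15 of the 16 riders. These fixtures let the aggregation
#' stages be replayed exactly.
#'
#' @return `motorcycle_cohort_events()`: a 16-row profile tibble.
#'   `motorcycle_cohort_speeds()`: a 15-row speed-profile tibble.
#' @export
motorcycle_cohort_events <- function() {
  path <- system.file("extdata", "cohort_event_counts.csv",
                      package = "motoprofile", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  dplyr::bind_rows(lapply(seq_len(nrow(raw)), function(i) {
    do.call(driver_profile_from_counts, as.list(raw[i, ]))
  }))
}

#' @rdname motorcycle_cohort_events
#' @export
motorcycle_cohort_speeds <- function() {
  path <- system.file("extdata", "cohort_speed_counts.csv",
                      package = "motoprofile", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  dplyr::bind_rows(lapply(seq_len(nrow(raw)), function(i) {
    do.call(speed_profile_from_counts, as.list(raw[i, ]))
  }))
}

#' Bar chart of cohort event counts by label
#'
#' The standard cohort figure: mean event counts per severity label, split
#' by throttle/braking side.
#'
#' @param profiles Profile tibble as from [build_driver_profile()] rows.
#' @return A ggplot object.
#' @export
plot_event_counts <- function(profiles) {
  profiles <- bind_profiles(profiles)
  means <- colMeans(profiles[, EVENT_LABELS])
  df <- tibble::tibble(
    label = factor(EVENT_LABELS, levels = EVENT_LABELS),
    side = c(rep("acceleration", 3), rep("deceleration", 3), "zero"),
    severity = c(rep(c("normal", "aggressive", "dangerous"), 2), "zero"),
    mean_count = as.numeric(means)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$severity, y = .data$mean_count,
                                   fill = .data$side)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "mean events per driver", fill = NULL) +
    ggplot2::theme_minimal()
}
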