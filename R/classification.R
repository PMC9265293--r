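# event_classification: per-sample severity labels and per-reading speed
# labels.

#' Road speed policy
#'
#' The posted limit and the multiplier that separates mere over-speed from
#' dangerous speed. Readings at or below the limit are normal ("over" means
#' strictly above the limit); readings above `limit * dangerous_factor` are
#' dangerous. The study road's limit is 80 km/h; no dangerous tier is
#' defined for it anywhere in the source material, so the 1.25 factor
#' (100 km/h on an 80 km/h road) is a package policy default and is fully
#' configurable.
#'
#' @param limit Posted limit in km/h, > 0.
#' @param dangerous_factor Multiplier > 1.
#' @return A `speed_policy`.
#' @export
speed_policy <- function(limit = 80, dangerous_factor = 1.25) {
  check_number(limit, "limit", min = 0, strict = TRUE)
  check_number(dangerous_factor, "dangerous_factor", min = 1, strict = TRUE)
  structure(list(limit = limit, dangerous_factor = dangerous_factor),
            class = "speed_policy")
}

#' @export
print.speed_policy <- function(x, ...) {
  cat(sprintf("<speed_policy> limit %g km/h, dangerous above %g km/h\n",
              x$limit, x$limit * x$dangerous_factor))
  invisible(x)
}

#' Classify kinematic samples against a threshold set
#'
#' Vectorized over `a`. The zero band is evaluated first (`|a| <= zero_eps`
#' is `zero`); positive samples are `normal_accel` up to and including
#' `accel_t1`, `aggressive_accel` up to and including `accel_t2`, and
#' `dangerous_accel` above; braking samples mirror this on the negative
#' side: `normal_decel` down to and including `decel_t1`,
#' `aggressive_decel` down to and including `decel_t2`, `dangerous_decel`
#' below. Boundaries are closed on the less severe side throughout.
#'
#' @param a Signed accelerations in m/s².
#' @param thresholds A [threshold_set()].
#' @param zero_eps Zero-band half width in m/s².
#' @return A factor with levels [event_labels()].
#' @export
#' @examples
#' th <- threshold_preset("methods")
#' classify_sample(c(1.3, 3.0, -7.0, 0), th)
classify_sample <- function(a, thresholds, zero_eps = 0) {
  stopifnot(inherits(thresholds, "threshold_set"))
  check_number(zero_eps, "zero_eps", min = 0)
  lab <- character(length(a))
  zero <- abs(a) <= zero_eps
  lab[zero] <- "zero"
  pos <- !zero & a > 0
  lab[pos & a <= thresholds$accel_t1] <- "normal_accel"
  lab[pos & a > thresholds$accel_t1 & a <= thresholds$accel_t2] <- "aggressive_accel"
  lab[pos & a > thresholds$accel_t2] <- "dangerous_accel"
  neg <- !zero & a < 0
  lab[neg & a >= thresholds$decel_t1] <- "normal_decel"
  lab[neg & a < thresholds$decel_t1 & a >= thresholds$decel_t2] <- "aggressive_decel"
  lab[neg & a < thresholds$decel_t2] <- "dangerous_decel"
  factor(lab, levels = EVENT_LABELS)
}

#' Classify speed readings against a road policy
#'
#' Vectorized over `v`: `v <= limit` is `normal_speed`,
#' `limit < v <= limit * dangerous_factor` is `over_speed`, and anything
#' above is `dangerous_speed`.
#'
#' @param v Speeds in km/h, non-negative.
#' @param policy A [speed_policy()].
#' @return A factor with levels [speed_labels()].
#' @export
#' @examples
#' classify_speed(c(80, 81, 120), speed_policy(80))
classify_speed <- function(v, policy = speed_policy()) {
  stopifnot(inherits(policy, "speed_policy"))
  if (!is.numeric(v) || any(!is.finite(v))) {
    stop_domain("`v` must be finite numeric")
  }
  if (any(v < 0)) {
    stop_domain("speeds must be non-negative")
  }
  hi <- policy$limit * policy$dangerous_factor
  lab <- ifelse(v <= policy$limit, "normal_speed",
                ifelse(v <= hi, "over_speed", "dangerous_speed"))
  factor(lab, levels = SPEED_LABELS)
}

#' Label a whole trip
#'
#' Fans the two classifiers out over a trip: one event label per kinematic
#' sample and one speed label per GPS reading. The series must have been
#' derived from the records it is paired with (one sample per consecutive
#' record pair).
#'
#' @param series A `kinematic_series` from [derive_kinematics()].
#' @param records The trip's record tibble (column `speed`).
#' @param thresholds A [threshold_set()].
#' @param policy A [speed_policy()].
#' @param zero_eps Zero-band half width in m/s².
#' @return A list with `events` (tibble `t, v, a, dt, event_label`) and
#'   `speeds` (tibble `t, v, speed_label`).
#' @export
label_trip <- function(series, records, thresholds, policy = speed_policy(),
                       zero_eps = 0) {
  stopifnot(is.data.frame(series), is.data.frame(records))
  if (nrow(records) != nrow(series) + 1L && !(nrow(records) == 0 && nrow(series) == 0)) {
    stop_data(sprintf(
      "length mismatch: %d records should yield %d kinematic samples, got %d",
      nrow(records), max(nrow(records) - 1L, 0L), nrow(series)
    ))
  }
  events <- tibble::as_tibble(series[, c("t", "v", "a", "dt")])
  events$event_label <- classify_sample(series$a, thresholds, zero_eps)
  speeds <- tibble::tibble(
    t = records$t,
    v = records$speed,
    speed_label = classify_speed(records$speed, policy)
  )
  list(events = events, speeds = speeds)
}
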