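# kinematics: per-interval acceleration from the speed series.

KMH_TO_MS <- 1 / 3.6

#' Derive per-interval acceleration from a trip's speed series
#'
#' For every pair of consecutive records the signed acceleration over the
#' interval is `a = ((v_i - v_(i-1)) / 3.6) / (t_i - t_(i-1))` in m/s²: the
#' speed difference converted from km/h to m/s, divided by the actual gap.
#' App logs are nominally 1 Hz but gaps are not assumed uniform. Each sample
#' is attached to the interval-ending timestamp. No smoothing is applied by
#' default; `smooth_window > 1` replaces the speed series with a centred
#' moving average of that (odd) width before differencing, for noisier
#' sources.
#'
#' @param trip A [trip()] with at least two records.
#' @param smooth_window Odd integer moving-average width; 1 = no smoothing.
#' @return A `kinematic_series`: tibble with `t` (s, interval end), `v`
#'   (km/h, speed at interval end), `a` (m/s²), `dt` (s), carrying
#'   `driver_id`/`trip_id` attributes.
#' @export
#' @examples
#' tr <- trip("D1", "T1", tibble::tibble(t = 0:2, speed = c(0, 36, 36)))
#' derive_kinematics(tr)  # a = 10, 0 m/s2
derive_kinematics <- function(trip, smooth_window = 1L) {
  stopifnot(inherits(trip, "trip"))
  rec <- trip$records
  if (nrow(rec) < 2L) {
    stop_data("kinematic derivation needs at least 2 records")
  }
  dt <- diff(rec$t)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1L]
    stop_data(sprintf(
      "non-positive time gap between t=%g and t=%g (cleaning should have removed it)",
      rec$t[bad], rec$t[bad + 1L]
    ))
  }
  v <- rec$speed
  if (smooth_window > 1L) {
    if (smooth_window %% 2L == 0L) {
      stop_config("`smooth_window` must be odd")
    }
    v <- stats::filter(v, rep(1 / smooth_window, smooth_window), sides = 2)
    v <- as.numeric(v)
    # keep endpoints unsmoothed where the window does not fit
    v[is.na(v)] <- rec$speed[is.na(v)]
  }
  a <- (diff(v) * KMH_TO_MS) / dt
  out <- tibble::tibble(
    t = rec$t[-1L],
    v = rec$speed[-1L],
    a = a,
    dt = dt
  )
  attr(out, "driver_id") <- trip$driver_id
  attr(out, "trip_id") <- trip$trip_id
  class(out) <- c("kinematic_series", class(out))
  out
}

#' Partition kinematic samples by sign of acceleration
#'
#' Splits a series into accelerations (`a > zero_eps`), decelerations
#' (`a < -zero_eps`) and zero-band samples (`|a| <= zero_eps`). With the
#' default `zero_eps = 0` only exact zeros land in the zero band, which
#' matches the handful of zero events seen in app-precision speed logs.
#'
#' @param series A `kinematic_series` (or any tibble with column `a`).
#' @param zero_eps Zero-band half width in m/s², `>= 0`.
#' @return A list of three tibbles: `accelerations`, `decelerations`,
#'   `zeros`; together they partition the input rows.
#' @export
partition_samples <- function(series, zero_eps = 0) {
  check_number(zero_eps, "zero_eps", min = 0)
  stopifnot(is.data.frame(series), "a" %in% names(series))
  a <- series$a
  zero <- abs(a) <= zero_eps
  list(
    accelerations = series[!zero & a > 0, , drop = FALSE],
    decelerations = series[!zero & a < 0, , drop = FALSE],
    zeros         = series[zero, , drop = FALSE]
  )
}
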