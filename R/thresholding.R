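# thresholding: empirical mean/SD summaries and the mean + k*sd severity
# cut-offs for acceleration and braking.

#' Summarize an empirical acceleration distribution
#'
#' Arithmetic mean and sample standard deviation (N-1 denominator) of a set
#' of kinematic magnitudes, the two moments from which the severity
#' thresholds are built.
#'
#' @param values Numeric vector, at least two finite values, in m/s².
#' @return A `distribution_summary` with `mean`, `sdev`, `n`.
#' @export
#' @examples
#' summarize_distribution(c(1, 2, 3))  # mean 2, sdev 1
summarize_distribution <- function(values) {
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop_domain("`values` must be finite numerics")
  }
  if (length(values) < 2L) {
    stop_data("need at least 2 values to estimate a standard deviation")
  }
  structure(
    list(mean = mean(values), sdev = sd(values), n = length(values)),
    class = "distribution_summary"
  )
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf("<distribution_summary> n=%d mean=%.4f sdev=%.4f\n",
              x$n, x$mean, x$sdev))
  invisible(x)
}

as_summary <- function(x) {
  if (inherits(x, "distribution_summary")) return(x)
  if (is.list(x) && all(c("mean", "sdev") %in% names(x))) {
    return(structure(list(mean = x$mean, sdev = x$sdev, n = x$n %||% NA_integer_),
                     class = "distribution_summary"))
  }
  stop_domain("expected a distribution_summary (or list with mean and sdev)")
}

check_k <- function(k1, k2) {
  check_number(k1, "k1", min = 0, strict = TRUE)
  check_number(k2, "k2")
  if (k1 >= k2) stop_config(sprintf("k1 (%g) must be < k2 (%g)", k1, k2))
}

#' Derive acceleration severity cut-offs from a distribution summary
#'
#' The positive (throttle) side of the empirical distribution yields two
#' cut-offs: `t1 = mean + k1*sdev` bounds normal accelerations and
#' `t2 = mean + k2*sdev` separates aggressive from dangerous ones, so that
#' normal is `a <= t1`, aggressive `t1 < a <= t2`, dangerous `a > t2`. With
#' the defaults `k1 = 1, k2 = 2` the bands mirror the one- and two-sigma
#' coverage of a Gaussian.
#'
#' @param summary A [summarize_distribution()] of the positive acceleration
#'   samples (the deceleration variant expects braking magnitudes `|a|`).
#' @param k1,k2 Sigma multipliers, `0 < k1 < k2`.
#' @return Named numeric `c(accel_t1, accel_t2)` (or
#'   `c(decel_t1, decel_t2)`, both negative, for the braking side).
#' @export
#' @examples
#' s <- list(mean = 0.1, sdev = 1.2, n = 1000)
#' derive_acceleration_thresholds(s)   # 1.3, 2.5
derive_acceleration_thresholds <- function(summary, k1 = 1, k2 = 2) {
  check_k(k1, k2)
  s <- as_summary(summary)
  if (s$sdev == 0) {
    warn("degenerate thresholds: sdev = 0 so t1 = t2 and the aggressive band is empty")
  }
  c(accel_t1 = s$mean + k1 * s$sdev, accel_t2 = s$mean + k2 * s$sdev)
}

#' @rdname derive_acceleration_thresholds
#' @export
#' @examples
#' derive_deceleration_thresholds(list(mean = 2.48, sdev = 3.53))  # -6.01, -9.54
derive_deceleration_thresholds <- function(summary, k1 = 1, k2 = 2) {
  pos <- derive_acceleration_thresholds(summary, k1, k2)
  c(decel_t1 = -unname(pos[1L]), decel_t2 = -unname(pos[2L]))
}

#' Severity threshold set
#'
#' Bundles the four learned cut-offs: `accel_t1 < accel_t2` on the throttle
#' side and `decel_t2 < decel_t1 < 0` on the braking side (more negative =
#' more severe). Braking cut-offs are learned on magnitudes `|a|` and then
#' negated, so a braking sample is normal when `a >= decel_t1`, aggressive
#' when `decel_t2 <= a < decel_t1` and dangerous when `a < decel_t2`.
#'
#' @param accel_t1,accel_t2 Throttle-side cut-offs in m/s², `t1 <= t2`.
#' @param decel_t1,decel_t2 Braking-side cut-offs in m/s², negative,
#'   `decel_t2 <= decel_t1 < 0`.
#' @param k1,k2 The sigma multipliers the set was built with (metadata).
#' @param source Free-text provenance label.
#' @return A `threshold_set`.
#' @export
threshold_set <- function(accel_t1, accel_t2, decel_t1, decel_t2,
                          k1 = 1, k2 = 2, source = "manual") {
  for (nm in c("accel_t1", "accel_t2", "decel_t1", "decel_t2")) {
    check_number(get(nm), nm, finite = TRUE)
  }
  if (accel_t1 > accel_t2) {
    stop_config("accel_t1 must be <= accel_t2")
  }
  if (!(decel_t2 <= decel_t1 && decel_t1 < 0)) {
    stop_config("need decel_t2 <= decel_t1 < 0 (braking cut-offs are negative)")
  }
  structure(
    list(accel_t1 = accel_t1, accel_t2 = accel_t2,
         decel_t1 = decel_t1, decel_t2 = decel_t2,
         k1 = k1, k2 = k2, source = source),
    class = "threshold_set"
  )
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("<threshold_set>", x$source, "\n")
  cat(sprintf("  acceleration: normal <= %.4g < aggressive <= %.4g < dangerous\n",
              x$accel_t1, x$accel_t2))
  cat(sprintf("  braking:      normal >= %.4g > aggressive >= %.4g > dangerous\n",
              x$decel_t1, x$decel_t2))
  invisible(x)
}

#' Published threshold presets
#'
#' Two frozen cut-off sets reported for the 16-rider motorcycle cohort:
#' `"methods"` carries the acceleration pair (1.3, 2.5) from the stepwise
#' threshold derivation, `"conclusions"` the pair (4.73, 7.48) from the
#' concluding stratification; both share the braking pair (-6.01, -9.54).
#' The two acceleration pairs are mutually inconsistent in the source
#' material; they are shipped as alternative dataset-dependent presets and
#' the package asserts nothing about which is correct.
#'
#' @param name `"methods"` or `"conclusions"`.
#' @return A [threshold_set()].
#' @export
#' @examples
#' threshold_preset("methods")
threshold_preset <- function(name = c("methods", "conclusions")) {
  name <- match.arg(name)
  switch(name,
    methods = threshold_set(1.3, 2.5, -6.01, -9.54, source = "preset:methods"),
    conclusions = threshold_set(4.73, 7.48, -6.01, -9.54,
                                source = "preset:conclusions")
  )
}

#' Learn a threshold set from pooled kinematic samples
#'
#' Splits the signed accelerations at the zero band, summarizes the positive
#' side and the braking magnitudes separately, and derives mean + k*sd
#' cut-offs for each. Pooling all drivers' samples is the default (the
#' cohort defines what is "normal" for its population); pass one driver's
#' samples for a per-driver set.
#'
#' @param a Signed accelerations in m/s² (pooled over trips/drivers).
#' @param k1,k2 Sigma multipliers, `0 < k1 < k2`.
#' @param zero_eps Zero-band half width used to exclude zero samples.
#' @return A [threshold_set()] with source `"learned"`.
#' @export
learn_thresholds <- function(a, k1 = 1, k2 = 2, zero_eps = 0) {
  check_k(k1, k2)
  check_number(zero_eps, "zero_eps", min = 0)
  if (!is.numeric(a) || any(!is.finite(a))) {
    stop_domain("`a` must be finite numerics")
  }
  pos <- a[a > zero_eps]
  neg <- abs(a[a < -zero_eps])
  if (length(pos) < 2L || length(neg) < 2L) {
    stop_data("need at least 2 samples on each side of zero to learn thresholds")
  }
  at <- derive_acceleration_thresholds(summarize_distribution(pos), k1, k2)
  dt <- derive_deceleration_thresholds(summarize_distribution(neg), k1, k2)
  threshold_set(at[["accel_t1"]], at[["accel_t2"]],
                dt[["decel_t1"]], dt[["decel_t2"]],
                k1 = k1, k2 = k2, source = "learned")
}

#' Empirical Gaussian coverage
#'
#' Fraction of values inside `mean +/- k*sd`, using the sample moments. On
#' large Gaussian samples this approaches 68.27% (k=1), 95.45% (k=2) and
#' 99.73% (k=3), the coverage identities motivating the mean + k*sd cut-off
#' construction.
#'
#' @param values Numeric vector, n >= 2.
#' @param k Non-negative sigma multiplier.
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' gaussian_coverage(c(-1, 0, 1), 1)  # 1
gaussian_coverage <- function(values, k) {
  check_number(k, "k", min = 0)
  s <- summarize_distribution(values)
  mean(values >= s$mean - k * s$sdev & values <= s$mean + k * s$sdev)
}

#' Freeze or thaw a threshold set as JSON
#'
#' Learned cut-offs can be written to a JSON block and reloaded for reuse on
#' another cohort.
#'
#' @param thresholds A [threshold_set()].
#' @param path Optional file path; `NULL` returns the JSON text.
#' @export
thresholds_to_json <- function(thresholds, path = NULL) {
  stopifnot(inherits(thresholds, "threshold_set"))
  js <- jsonlite::toJSON(unclass(thresholds), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname thresholds_to_json
#' @param json JSON text or a file path containing it.
#' @export
thresholds_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  threshold_set(x$accel_t1, x$accel_t2, x$decel_t1, x$decel_t2,
                k1 = x$k1 %||% 1, k2 = x$k2 %||% 2,
                source = x$source %||% "json")
}
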