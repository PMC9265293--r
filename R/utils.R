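# Internal helpers shared across modules.

# round half away from zero at d decimals (base round() is round-half-even,
# which does not match how percentage cells are conventionally rendered)
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_config <- function(msg, ...) {
  abort(msg, class = "motoprofile_config_error", ...)
}

stop_domain <- function(msg, ...) {
  abort(msg, class = "motoprofile_domain_error", ...)
}

stop_data <- function(msg, ...) {
  abort(msg, class = "motoprofile_data_error", ...)
}

check_number <- function(x, name, finite = TRUE, min = NULL, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_domain(sprintf("`%s` must be a single number", name))
  }
  if (finite && !is.finite(x)) {
    stop_domain(sprintf("`%s` must be finite", name))
  }
  if (!is.null(min)) {
    bad <- if (strict) x <= min else x < min
    if (bad) {
      stop_domain(sprintf(
        "`%s` must be %s %s (got %g)",
        name, if (strict) ">" else ">=", format(min), x
      ))
    }
  }
  invisible(x)
}
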