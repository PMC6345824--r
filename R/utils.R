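#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can distinguish data problems ("zeu_below_profile",
# "profile_too_shallow", ...) from programming errors.
bp_stop <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "bloomphen_error", "error")))
}

bp_warn <- function(class, msg) {
  warning(warningCondition(msg, class = c(class, "bloomphen_warning", "warning")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# clamp(x) to [0, 1]; used for linear ramps in the synthetic fields
ramp01 <- function(x) pmin(pmax(x, 0), 1)

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Trapezoidal integral of the piecewise-linear interpolant of (z, y) over
# [z0, z1]. Boundary values are linearly interpolated; if z0 is shallower than
# the shallowest sample the profile is extended upward with a constant value
# (floats rarely sample the top metre). Callers must check z1 <= max(z).
trap_integral <- function(z, y, z0, z1) {
  stopifnot(z1 > z0, z1 <= max(z))
  if (z0 < z[1]) {
    z <- c(z0, z)
    y <- c(y[1], y)
  }
  y0 <- stats::approx(z, y, xout = z0)$y
  y1 <- stats::approx(z, y, xout = z1)$y
  inside <- z > z0 & z < z1
  zz <- c(z0, z[inside], z1)
  yy <- c(y0, y[inside], y1)
  pracma::trapz(zz, yy)
}
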