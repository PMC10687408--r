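# MilkBot lactation-curve mathematics.
#
# The four-parameter MilkBot model describes daily milk yield (kg/day) at
# days in milk t as
#
#   Y(t) = a * (1 - exp((c - t)/b) / 2) * exp(-d * t)
#
# with magnitude a (kg/day, overall scale), ramp b (days, time constant of
# the early-lactation rise), offset c (days, time shift of the ramp) and
# decay d (1/day, exponential decline rate).  Persistency -- the half-life
# of milk production in the declining stage -- is 0.693/d days.

# Half-life constant kept literally as 0.693 (not log(2)) so the field's
# printed worked examples reproduce exactly.
HALF_LIFE_CONSTANT <- 0.693

#' Lactation curve characteristics
#'
#' Bundle the four MilkBot parameters (and, once fitted, the fit RMSE) into
#' a light-weight descriptor used throughout the package.
#'
#' @param magnitude Overall scale of the curve `a`, kg/day; must be > 0.
#' @param ramp Time constant of the early-lactation rise `b`, days; > 0.
#' @param offset Time shift of the ramp `c`, days.
#' @param decay Exponential decline rate `d`, 1/day.  Negative values are
#'   representable (they arise transiently during fitting) but are rejected
#'   by the persistency transform and filtered out of analysis cohorts.
#' @param fit_rmse Root mean squared error of the fit that produced these
#'   parameters, kg; `NA` until fitted.
#'
#' @return An object of class `"lcc"`: a named list with the five fields.
#' @examples
#' curve <- lcc(magnitude = 38.2, ramp = 28.2, offset = -0.5, decay = 1.4e-3)
#' milk_yield(curve, t = 100)
#' @export
lcc <- function(magnitude, ramp, offset, decay, fit_rmse = NA_real_) {
  assert_finite(c(magnitude, ramp, offset, decay), "magnitude/ramp/offset/decay")
  if (magnitude <= 0) stop("`magnitude` must be > 0", call. = FALSE)
  if (ramp <= 0) stop("`ramp` must be > 0", call. = FALSE)
  structure(
    list(magnitude = magnitude, ramp = ramp, offset = offset, decay = decay,
         fit_rmse = fit_rmse),
    class = "lcc"
  )
}

#' @export
print.lcc <- function(x, ...) {
  cat(sprintf(
    "<lcc> magnitude %.2f kg/d, ramp %.2f d, offset %.3f d, decay %.4g /d",
    x$magnitude, x$ramp, x$offset, x$decay))
  if (is.finite(x$decay) && x$decay > 0) {
    cat(sprintf(" (persistency %.0f d)", persistency_from_decay(x$decay)))
  }
  cat("\n")
  invisible(x)
}

# Vectorised raw curve (no floor); internal workhorse.
mb_yield_raw <- function(t, a, b, c, d) {
  a * (1 - exp((c - t) / b) / 2) * exp(-d * t)
}

#' Evaluate the MilkBot curve
#'
#' Daily milk yield (kg/day) at days in milk `t`, floored at 0 kg: the raw
#' curve is negative for t far below the offset, which is unphysical.
#'
#' @param curve An [lcc()] object.
#' @param t Days in milk, numeric vector, each >= 0.
#' @return Numeric vector of yields, kg/day.
#' @export
milk_yield <- function(curve, t) {
  stopifnot(inherits(curve, "lcc"))
  assert_finite(t, "t")
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  pmax(0, mb_yield_raw(t, curve$magnitude, curve$ramp, curve$offset, curve$decay))
}

#' Persistency from decay, and back
#'
#' Persistency is the half-life of milk production in the declining stage
#' of lactation: the number of days it takes daily yield to halve,
#' `0.693 / d`.  The inverse transform returns the decay implied by a
#' persistency.  Both are strictly decreasing bijections on the positive
#' half-line and round-trip exactly.
#'
#' @param d Decay, 1/day; all elements must be > 0.
#' @return Persistency in days.
#' @examples
#' persistency_from_decay(1.55e-3)  # ~447 days
#' decay_from_persistency(300)      # 2.31e-3 per day
#' @export
persistency_from_decay <- function(d) {
  assert_finite(d, "d")
  if (any(d <= 0)) stop("`d` must be > 0 (negative-decay records are filtered upstream)",
                        call. = FALSE)
  HALF_LIFE_CONSTANT / d
}

#' @rdname persistency_from_decay
#' @param p Persistency, days; all elements must be > 0.
#' @export
decay_from_persistency <- function(p) {
  assert_finite(p, "p")
  if (any(p <= 0)) stop("`p` must be > 0", call. = FALSE)
  HALF_LIFE_CONSTANT / p
}

#' Declining-phase half-life projection
#'
#' Pure exponential-decline approximation (ramp factor treated as 1): the
#' yield `elapsed` days after a reference point with yield `y_peak`, for a
#' cow with the given persistency.  A cow at 40 kg with persistency 300
#' days is at 20 kg another 300 days later.
#'
#' @param y_peak Reference daily yield, kg/day.
#' @param p Persistency, days; > 0.
#' @param elapsed Days since the reference point; >= 0.
#' @return Projected daily yield, kg/day.
#' @export
half_life_decline <- function(y_peak, p, elapsed) {
  assert_finite(c(y_peak, p, elapsed), "y_peak/p/elapsed")
  if (any(p <= 0)) stop("`p` must be > 0", call. = FALSE)
  if (any(elapsed < 0)) stop("`elapsed` must be >= 0", call. = FALSE)
  y_peak * exp(-(HALF_LIFE_CONSTANT / p) * elapsed)
}

# Vectorised closed-form integral of the raw curve from 0 to t.
# Valid where the raw curve is nonnegative on [0, t] (always true for the
# parameter ranges this package fits, where c - b*log(2) < 0).
mb_cumulative <- function(t, a, b, c, d) {
  term1 <- ifelse(abs(d) < 1e-12, a * t, a * (1 - exp(-d * t)) / d)
  k <- 1 / b + d
  term2 <- -(a / 2) * exp(c / b) * (1 - exp(-t * k)) / k
  term1 + term2
}

#' Cumulative milk production
#'
#' Closed-form integral of the MilkBot curve over `[0, t]`, kg.
#'
#' @inheritParams milk_yield
#' @export
milk_cumulative <- function(curve, t) {
  stopifnot(inherits(curve, "lcc"))
  assert_finite(t, "t")
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  mb_cumulative(t, curve$magnitude, curve$ramp, curve$offset, curve$decay)
}

# Vectorised 305-day production in the printed closed form.
mb_m305 <- function(a, b, c, d) {
  term1 <- ifelse(abs(d) < 1e-12, a * 305, (a - a * exp(-305 * d)) / d)
  term2 <- a * b * exp(c / b) * (-1 + exp(-305 * (1 / b + d))) / (2 + 2 * b * d)
  term1 + term2
}

#' 305-day milk production
#'
#' Cumulative yield over the first 305 days of lactation (M305, kg), using
#' the closed-form expression
#' `a(1 - e^(-305 d))/d + a b e^(c/b) (-1 + e^(-305(1/b + d))) / (2 + 2 b d)`,
#' which equals the integral of the curve over `[0, 305]`.  The `d = 0`
#' limit of the first term (`305 a`) is used rather than dividing by zero.
#'
#' @param curve An [lcc()] object with `ramp > 0`.
#' @return M305 in kg.
#' @export
m305 <- function(curve) {
  stopifnot(inherits(curve, "lcc"))
  mb_m305(curve$magnitude, curve$ramp, curve$offset, curve$decay)
}

#' Locate the lactation peak
#'
#' Numerically locates the maximum of the MilkBot curve on days in milk
#' 0--500 by a dense grid (step 0.1 day) followed by local refinement.
#' Note that the ramp parameter is a time *constant*, not the peak day:
#' the true argmax depends on all four parameters and is reported here.
#' When `decay = 0` the curve is monotone nondecreasing and the "peak" day
#' is reported as the first day yield reaches 99.9% of the magnitude.
#'
#' @param curve An [lcc()] object with `decay >= 0`.
#' @return A list with `peak_dim` (days) and `peak_yield` (kg/day).
#' @export
peak_summary <- function(curve) {
  stopifnot(inherits(curve, "lcc"))
  if (curve$decay < 0) stop("`decay` must be >= 0 for peak location", call. = FALSE)
  grid <- seq(0, 500, by = 0.1)
  y <- milk_yield(curve, grid)
  if (curve$decay == 0) {
    hit <- which(y >= 0.999 * curve$magnitude)
    peak_dim <- if (length(hit)) grid[hit[1]] else 500
    return(list(peak_dim = peak_dim, peak_yield = milk_yield(curve, peak_dim)))
  }
  i <- which.max(y)
  lo <- grid[max(1L, i - 2L)]
  hi <- grid[min(length(grid), i + 2L)]
  opt <- stats::optimize(function(t) milk_yield(curve, t),
                         interval = c(lo, hi), maximum = TRUE, tol = 1e-8)
  list(peak_dim = opt$maximum, peak_yield = opt$objective)
}
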