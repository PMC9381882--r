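# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
tdx_error <- function(subclass, message, call = sys.call(-1), ...) {
  stop(structure(
    class = c(paste0("torsadex_", subclass), "torsadex_error",
              "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

assert_that <- function(ok, subclass, message) {
  if (!isTRUE(ok)) tdx_error(subclass, message, call = sys.call(-2))
  invisible(TRUE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Savitzky-Golay derivative filter coefficients
#'
#' Least-squares local polynomial fit of given order over an odd window;
#' returns convolution weights for the requested derivative.
#' @noRd
sg_coefficients <- function(window, order = 2L, deriv = 0L) {
  stopifnot(window %% 2L == 1L, window > order)
  m <- (window - 1L) %/% 2L
  A <- outer(-m:m, 0:order, `^`)
  # row (deriv+1) of the pseudo-inverse gives the filter, scaled by deriv!
  H <- solve(crossprod(A), t(A))
  H[deriv + 1L, ] * factorial(deriv)
}

#' Smoothed first derivative of a uniformly sampled signal, in units/ms.
#' Edges use one-sided differences. `window_ms` is rounded to the nearest
#' odd number of samples.
#' @noRd
sg_derivative <- function(x, fs_hz = 1000, window_ms = 15) {
  n <- length(x)
  dt_ms <- 1000 / fs_hz
  w <- max(3L, round(window_ms / dt_ms))
  if (w %% 2L == 0L) w <- w + 1L
  if (w >= n) w <- if (n %% 2L == 1L) n else n - 1L
  if (w < 3L) return(c(diff(x) / dt_ms, 0))
  cf <- rev(sg_coefficients(w, order = 2L, deriv = 1L)) # rev for convolution
  d <- stats::filter(x, cf, sides = 2) / dt_ms
  d <- as.numeric(d)
  m <- (w - 1L) %/% 2L
  d[seq_len(m)] <- (x[seq_len(m) + 1L] - x[seq_len(m)]) / dt_ms
  d[(n - m + 1L):n] <- (x[(n - m + 1L):n] - x[(n - m):(n - 1L)]) / dt_ms
  d
}

#' Linear interpolation of the time at which a sampled signal crosses `level`
#' between samples i and i+1 (times in ms, 0-based sample indexing).
#' @noRd
interp_crossing_ms <- function(i, v_i, v_next, level, fs_hz = 1000) {
  dt_ms <- 1000 / fs_hz
  frac <- (level - v_i) / (v_next - v_i)
  (i + frac) * dt_ms
}

#' Simulate a repolarization-duration series with AR(1) beat-to-beat noise
#'
#' The duration series is `mean_ms` plus a stationary AR(1) process whose
#' innovation SD is chosen in closed form so that the expected short-term
#' variability (sqrt2-mode STV, i.e. mean absolute successive difference
#' divided by sqrt(2)) equals `stv_target`. Under AR(1) with coefficient
#' `phi` and innovation SD `s`, successive differences are Gaussian with
#' SD `sd_diff = s * sqrt(2/(1+phi))`, and E|diff| = sd_diff*sqrt(2/pi),
#' so E[STV] = sd_diff/sqrt(pi). The realized series is re-centred so its
#' mean equals `mean_ms` exactly.
#'
#' @param n number of beats
#' @param mean_ms series mean in ms
#' @param stv_target expected STV in ms (>= 0)
#' @param phi AR(1) coefficient in [0, 1)
#' @param trend_ms optional length-n additive trend (e.g. a drug ramp)
#' @return numeric vector of durations (ms)
#' @export
simulate_duration_series <- function(n, mean_ms, stv_target, phi = 0.5,
                                     trend_ms = NULL) {
  assert_that(is_number(n) && n >= 1, "spec", "n must be a positive count")
  assert_that(is_number(stv_target) && stv_target >= 0, "spec",
              "stv_target must be >= 0")
  assert_that(is_number(phi) && phi >= 0 && phi < 1, "spec",
              "phi must lie in [0, 1)")
  sd_diff <- stv_target * sqrt(pi)
  s_innov <- sd_diff * sqrt((1 + phi) / 2)
  x <- numeric(n)
  if (s_innov > 0 && n > 1) {
    x[1] <- stats::rnorm(1, 0, s_innov / sqrt(1 - phi^2))
    for (i in 2:n) x[i] <- phi * x[i - 1] + stats::rnorm(1, 0, s_innov)
    x <- x - mean(x)
  }
  out <- mean_ms + x
  if (!is.null(trend_ms)) {
    stopifnot(length(trend_ms) == n)
    out <- out + trend_ms
  }
  out
}

#' Closed-form expected STV of the AR(1) duration model
#' @param stv_target the configured target (the model is calibrated to it)
#' @return the expectation, identical to the target by construction
#' @export
expected_stv_ar1 <- function(stv_target) stv_target

# round half away from zero (for reporting only; internals keep full precision)
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
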