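#' Zero-phase low-pass Butterworth filtering
#'
#' Standard biomechanics pre-processing of angle/position time series:
#' a low-pass Butterworth filter applied forward and backward
#' (zero net phase shift); the effective magnitude response is the square of
#' the single-pass response, \eqn{|H(f)|^2 = 1 / (1 + (f/f_c)^{2 \cdot order})}.
#'
#' @param x Numeric time series (evenly sampled).
#' @param cutoff_hz Cutoff frequency (Hz); default 15.
#' @param order Filter order of the single pass (even); default 4.
#' @param rate_hz Sampling rate (Hz); must exceed `2 * cutoff_hz`.
#' @return Filtered series, same length as `x`.
#' @examples
#' t <- seq(0, 2, by = 1 / 240)
#' noisy <- sin(2 * pi * 1 * t) + 0.2 * sin(2 * pi * 60 * t)
#' smooth <- butterworth_filter(noisy, cutoff_hz = 15, rate_hz = 240)
#' @export
butterworth_filter <- function(x, cutoff_hz = 15, order = 4, rate_hz) {
  assert_that(is.numeric(x) && all(is.finite(x)), "`x` must be finite numeric.")
  assert_that(order >= 2 && order %% 2 == 0, "`order` must be an even integer >= 2.")
  assert_that(rate_hz > 2 * cutoff_hz,
              "`rate_hz` must exceed twice `cutoff_hz` (Nyquist).")
  if (length(x) <= 3 * order) {
    abort(sprintf("signal too short to filter: length %d <= 3 * order (%d).",
                  length(x), 3 * order))
  }
  bf <- signal::butter(order, 2 * cutoff_hz / rate_hz, type = "low")
  # odd-reflection padding so the zero-initial-condition passes settle before
  # the data start; pad covers several filter time constants
  n <- length(x)
  padlen <- min(n - 1, max(3 * (order + 1), ceiling(10 * rate_hz / cutoff_hz)))
  pre <- 2 * x[1] - x[seq(padlen + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - padlen)]
  y <- as.numeric(signal::filtfilt(bf, c(pre, x, post)))
  y[seq(padlen + 1, padlen + n)]
}
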