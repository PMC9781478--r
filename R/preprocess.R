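#' Zero-phase Butterworth bandpass filter
#'
#' Filters a single-channel waveform with 4th-order Butterworth high-pass and
#' low-pass stages in cascade, each applied forward and backward, so the net
#' phase response is zero and landmark timing (and hence pulse arrival times)
#' is not shifted. The cascade form is used instead of a single bandpass
#' design because physiological bands (e.g. 0.5-15 Hz at 1000 Hz sampling)
#' are numerically ill-conditioned as one narrow-band section.
#'
#' @param x Numeric vector of samples.
#' @param fs Sampling rate in Hz.
#' @param low_cut,high_cut Band edges in Hz; must satisfy
#'   `0 < low_cut < high_cut < fs/2`.
#' @param order Butterworth order of the one-pass prototype (default 4).
#' @return Numeric vector of the same length as `x`.
#' @examples
#' fs <- 250
#' t <- seq(0, 2, by = 1 / fs)
#' x <- sin(2 * pi * 10 * t) + 2    # 10 Hz tone on a DC pedestal
#' y <- bandpass_filter(x, fs, 0.5, 30)
#' abs(mean(y)) < 0.05              # DC removed
#' @export
bandpass_filter <- function(x, fs, low_cut, high_cut, order = 4) {
  stopifnot(is.numeric(x), fs > 0)
  if (!(low_cut > 0 && low_cut < high_cut && high_cut < fs / 2)) {
    stop("invalid filter spec: need 0 < low_cut < high_cut < fs/2")
  }
  if (length(x) <= 3 * (2 * order + 1)) {
    stop("signal too short for the requested filter order")
  }
  hp <- signal::butter(order, low_cut / (fs / 2), type = "high")
  lp <- signal::butter(order, high_cut / (fs / 2), type = "low")
  ## odd-reflection padding suppresses start/end transients of the long
  ## high-pass impulse response
  n <- length(x)
  pad <- min(n - 1, round(2 * fs / low_cut))
  left <- 2 * x[1] - x[seq(pad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - pad)]
  xp <- c(left, x, right)
  y <- signal::filtfilt(hp, xp)
  y <- as.numeric(signal::filtfilt(lp, y))
  y[(pad + 1):(pad + n)]
}

#' Z-score normalization of a signal segment
#'
#' Centers to zero mean and scales to unit standard deviation. The sample SD
#' of the whole segment is used, so the map is affine and order-preserving;
#' normalizing an already-normalized segment is a no-op.
#'
#' @param x Numeric vector, length >= 2, non-constant.
#' @param population Logical; use the population SD (divide by n) instead of
#'   the sample SD (divide by n - 1). Default `FALSE`.
#' @return Numeric vector with mean 0 and SD 1.
#' @export
zscore_normalize <- function(x, population = FALSE) {
  stopifnot(is.numeric(x))
  if (length(x) < 2) stop("need at least 2 samples to normalize")
  s <- stats::sd(x)
  if (population) s <- s * sqrt((length(x) - 1) / length(x))
  if (!is.finite(s) || s == 0) stop("degenerate signal: zero standard deviation")
  (x - mean(x)) / s
}

#' Centered moving-average smoother
#'
#' Mean over an odd, centered window; near the edges the window shrinks
#' symmetrically so the output has the same length as the input and no
#' phase shift is introduced.
#'
#' @param x Numeric vector.
#' @param window Odd positive integer window length in samples,
#'   `window <= length(x)`.
#' @return Smoothed numeric vector, same length as `x`.
#' @export
moving_average <- function(x, window) {
  stopifnot(is.numeric(x))
  if (length(window) != 1 || window < 1 || window %% 2 == 0) {
    stop("window must be a positive odd integer")
  }
  if (window > length(x)) stop("window longer than signal")
  if (window == 1) return(x)
  n <- length(x)
  h <- (window - 1) / 2
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  # shrink symmetrically at the edges so the window stays centered
  half <- pmin(i - lo, hi - i)
  lo <- i - half
  hi <- i + half
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Convert a smoothing window from milliseconds to an odd sample count
#' @param ms Window length in milliseconds.
#' @param fs Sampling rate in Hz.
#' @return Odd integer number of samples (at least 1).
#' @keywords internal
ms_to_odd_samples <- function(ms, fs) {
  w <- max(1L, as.integer(round(ms * fs / 1000)))
  if (w %% 2 == 0) w <- w + 1L
  w
}
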