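# Zero-phase IIR filtering with steady-state initial conditions.
#
# signal::filtfilt() starts both passes from zero state, which leaves large
# edge transients for signals with nonzero baseline (a pure DC input comes
# out with ~0.3 amplitude ringing at a 0.75 Hz corner). The forward pass
# here initializes the recursion at the steady-state response to the first
# sample and adds short odd-reflection padding, the same strategy MATLAB's
# and scipy's filtfilt use, so a constant input maps to its exact
# steady-state output with no transient.

# one causal ARMA pass assuming the signal was at x[1] for all past time
.filterPass <- function(b, a, x) {
  b <- b / a[1L]
  a <- a / a[1L]
  nb <- length(b)
  na <- length(a)
  xpad <- c(rep(x[1L], nb - 1L), x)
  u <- stats::filter(xpad, b, method = "convolution", sides = 1L)
  u <- as.numeric(u[nb:length(u)])
  if (na > 1L) {
    y0 <- x[1L] * sum(b) / sum(a)
    y <- stats::filter(u, -a[-1L], method = "recursive",
                       init = rep(y0, na - 1L))
    as.numeric(y)
  } else u
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies an IIR filter forward and then backward so the cascade has zero
#' phase (no group delay) and the squared magnitude response of the design.
#' Initial conditions are matched to the steady state of the edge samples
#' and the edges are padded by odd reflection, so baseline offsets do not
#' ring.
#'
#' @param filt a filter as returned by \code{signal::butter} (or any object
#'   with \code{b} and \code{a} coefficients).
#' @param x numeric signal.
#' @return the filtered signal, same length as \code{x}.
#' @examples
#' bw <- signal::butter(4, 2 / 1024, "low")
#' y <- zeroPhaseFilter(bw, sin(seq(0, 20, by = 1 / 2048)))
#' @export
zeroPhaseFilter <- function(filt, x) {
  b <- as.numeric(filt$b)
  a <- as.numeric(filt$a)
  n <- length(x)
  p <- min(n - 1L, 3L * (max(length(a), length(b)) - 1L))
  ext <- c(2 * x[1L] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
  y <- .filterPass(b, a, ext)
  y <- rev(.filterPass(b, a, rev(y)))
  y[(p + 1L):(p + n)]
}

#' Condition a signal into the common fluctuation band
#'
#' Restricts a CST, torque or fascicle trace to the band in which their
#' common fluctuations are compared: a 4th-order Butterworth lowpass at the
#' upper corner followed by a 4th-order Butterworth highpass at the lower
#' corner, both applied forward-backward (zero phase), so conditioning
#' introduces no delay between signals. The default band is 0.75-2 Hz.
#'
#' A raw summed binary spike train can be conditioned directly: the 2 Hz
#' lowpass performs the smoothing, no separate pre-smoothing is applied.
#'
#' @param x numeric trace, or a \linkS4class{CumulativeSpikeTrain}.
#' @param fs sampling rate in Hz (taken from the object if available).
#' @param band numeric (highpass, lowpass) corner frequencies in Hz.
#' @param label source label used in pairing names ("CST", "torque",
#'   "fascicle", ...).
#' @param min_duration_s guard against edge effects: the trace must span at
#'   least this many seconds (default 10).
#' @return a \linkS4class{ConditionedSignal}.
#' @examples
#' fs <- 2048
#' x <- sin(2 * pi * 1.2 * seq(0, 15, by = 1 / fs))
#' cs <- conditionSignal(x, fs)
#' @export
conditionSignal <- function(x, fs = NULL, band = c(0.75, 2),
                            label = "signal", min_duration_s = 10) {
  if (is(x, "CumulativeSpikeTrain")) {
    if (is.null(fs)) fs <- x@fs
    if (missing(label)) label <- "CST"
    x <- as.numeric(x@counts)
  }
  if (is.null(fs)) stop("fs is required for a plain numeric trace")
  if (fs <= 2 * band[2L])
    stop("sampling rate must exceed twice the lowpass corner")
  if (length(x) < min_duration_s * fs)
    stop(sprintf("trace must span at least %g s at %g Hz", min_duration_s, fs))
  lp <- signal::butter(4, band[2L] / (fs / 2), type = "low")
  hp <- signal::butter(4, band[1L] / (fs / 2), type = "high")
  y <- zeroPhaseFilter(hp, zeroPhaseFilter(lp, x))
  new("ConditionedSignal", samples = y, fs = as.numeric(fs),
      band = as.numeric(band), label = label)
}

# unit-area Hann window of the given width in ms (odd length >= 1)
.hannKernel <- function(fs, width_ms) {
  m <- max(1L, round(fs * width_ms / 1000))
  if (m %% 2L == 0L) m <- m + 1L
  if (m == 1L) return(1)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(m) / (m + 1L))
  w / sum(w)
}

# centred same-length convolution with edge zero-padding
.convSame <- function(x, k) {
  m <- length(k)
  h <- (m - 1L) %/% 2L
  xp <- c(rep(0, h), x, rep(0, h))
  y <- stats::filter(xp, k, method = "convolution", sides = 2L)
  as.numeric(y[(h + 1L):(h + length(x))])
}

# centred moving average over width_ms (edges use shrinking windows)
.movingAverage <- function(x, fs, width_ms) {
  m <- max(1L, round(fs * width_ms / 1000))
  if (m %% 2L == 0L) m <- m + 1L
  if (m == 1L) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  h <- (m - 1L) %/% 2L
  lo <- pmax(0L, seq_len(n) - h - 1L)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}
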