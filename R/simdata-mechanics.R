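# delay a trace by an integer number of samples, padding with its first value
.shiftTrace <- function(x, k) {
  n <- length(x)
  if (k == 0L) return(x)
  if (k >= n) stop("delay shift exceeds trace length")
  c(rep(x[1L], k), x[seq_len(n - k)])
}

# band-shaped unit-variance noise: white noise filtered to band_hz (scalar
# = lowpass corner, length 2 = bandpass), rescaled to unit sd -- places
# noise power at physiological fluctuation frequencies
.shapedNoise <- function(n, fs, band_hz) {
  z <- stats::rnorm(n)
  band_hz <- band_hz[is.finite(band_hz) & band_hz < fs / 2]
  if (length(band_hz) >= 1L) {
    lp <- signal::butter(2, max(band_hz) / (fs / 2), type = "low")
    z <- zeroPhaseFilter(lp, z)
    if (length(band_hz) == 2L) {
      hp <- signal::butter(2, min(band_hz) / (fs / 2), type = "high")
      z <- zeroPhaseFilter(hp, z)
    }
    z <- z / stats::sd(z)
  }
  z
}

#' Synthesize fascicle kinematics and torque from a drive
#'
#' Maps neural drive to the two mechanical outputs with exact, configurable
#' latencies. The drive is either the zero-phase-smoothed cumulative spike
#' train of a \linkS4class{SpikeTrainSet} (so the stochastic firing
#' fluctuations propagate into the mechanics, carrying the injected delays
#' into the band the analysis correlates) or any numeric trace in
#' %MVC-equivalent units. When built from spikes the smoothed train is
#' rescaled so its plateau mean equals the protocol target, making the
#' calibration exact: a sustained 20 %MVC plateau shortens the fascicle by
#' \code{shortening_at_20pct} on average.
#'
#' In \code{"pure-shift"} mode the delays are integer-sample time shifts, so
#' the injected latencies are exact ground truth for cross-correlation lag
#' recovery. In \code{"causal-kernel"} mode the shifts are replaced by a
#' causal critically damped kernel \eqn{(t/\tau^2)\,e^{-t/\tau}} with
#' \eqn{\tau} = delay/2 per stage; its effective band-limited group delay
#' must be measured, not assumed.
#'
#' Outputs: fascicle length \code{rest_length - A * s(t - Df)} (sampled per
#' frame, with per-frame noise), pennation increasing affinely with
#' shortening, and torque \code{B * s(t - Df - Dt)} with lowpass-shaped
#' additive noise.
#'
#' @param x a \linkS4class{SpikeTrainSet} or a numeric drive (%MVC) at
#'   \code{protocol$fs}.
#' @param mech a \code{\link{mechanicsConfig}}.
#' @param protocol the \code{\link{protocolConfig}} the drive realizes.
#' @param noise logical; add measurement noise (default TRUE). Ground-truth
#'   checks use \code{noise = FALSE}.
#' @param seed integer seed for the noise streams.
#' @return a list with elements \code{fascicle}
#'   (\linkS4class{FascicleTrace} at the imaging rate), \code{torque_pct},
#'   \code{torque_nm}, \code{drive_pct} (the noiseless calibrated drive),
#'   \code{frame_samples} (sample index of each frame) and
#'   \code{length_mm_fs}/\code{delta_mm_fs} (noiseless fascicle views on the
#'   signal clock, useful as ground truth).
#' @examples
#' prot <- protocolConfig(plateau_s = 5)
#' e <- generateExcitation(prot)
#' m <- synthesizeMechanics(e, mechanicsConfig(), prot, noise = FALSE)
#' range(m$torque_pct)
#' @export
synthesizeMechanics <- function(x, mech = mechanicsConfig(),
                                protocol = protocolConfig(), noise = TRUE,
                                seed = 1L) {
  if (!inherits(mech, "MechanicsConfig")) stop("mech must be a mechanicsConfig()")
  fs <- protocol$fs
  if (is(x, "SpikeTrainSet")) {
    cst <- cumulativeSpikeTrain(x)
    s <- .convSame(as.numeric(cst@counts), .hannKernel(fs, mech$smoothing_tau))
    seg <- NULL
    n_rest <- round(fs * protocol$rest_s)
    n_ramp <- round(fs * protocol$target_level / protocol$ramp_rate)
    n_plat <- round(fs * protocol$plateau_s)
    plat <- (n_rest + n_ramp + 1L):(n_rest + n_ramp + n_plat)
    plat <- plat[plat <= length(s)]
    mu <- mean(s[plat])
    if (!is.finite(mu) || mu <= 0)
      stop("cannot calibrate drive: no activity in the nominal plateau")
    s <- s * protocol$target_level / mu
  } else {
    s <- as.numeric(x)
  }
  n <- length(s)
  kf <- round(mech$delay_drive_to_fascicle * fs / 1000)
  kt <- round(mech$delay_fascicle_to_torque * fs / 1000)
  if (mech$mode == "pure-shift") {
    s_f <- .shiftTrace(s, kf)
    s_t <- .shiftTrace(s_f, kt)
  } else {
    s_f <- .causalKernelDelay(s, fs, mech$delay_drive_to_fascicle / 2)
    s_t <- .causalKernelDelay(s_f, fs, mech$delay_fascicle_to_torque / 2)
  }
  short_per_pct <- mech$shortening_at_20pct / 20
  length_mm_fs <- mech$rest_length - short_per_pct * s_f
  torque_pct <- s_t
  # frame clock: one frame per nominal trigger period
  frame_step <- fs / protocol$frame_rate
  n_frames <- floor((n - 1L) / frame_step) + 1L
  frame_samples <- as.integer(round((seq_len(n_frames) - 1L) * frame_step) + 1L)
  len_frames <- length_mm_fs[frame_samples]
  pen_slope <- (mech$pennation_at_20pct - mech$rest_pennation) /
    mech$shortening_at_20pct
  if (noise) {
    force(seed)
    old <- .saveSeed()
    on.exit(.restoreSeed(old), add = TRUE)
    set.seed(as.integer(seed))
    torque_pct <- torque_pct +
      mech$noise_torque_pct * .shapedNoise(n, fs, mech$noise_band_hz)
    len_frames <- len_frames +
      mech$noise_fascicle_mm *
        .shapedNoise(n_frames, protocol$frame_rate, mech$noise_band_hz)
  }
  pen_frames <- mech$rest_pennation +
    pen_slope * (mech$rest_length - len_frames)
  fascicle <- fascicleTrace(len_frames, pen_frames, protocol$frame_rate,
                            rest_length_mm = mech$rest_length)
  list(fascicle = fascicle,
       torque_pct = torque_pct,
       torque_nm = torque_pct / 100 * mech$torque_mvc,
       drive_pct = s,
       frame_samples = frame_samples,
       length_mm_fs = length_mm_fs,
       delta_mm_fs = mech$rest_length - length_mm_fs)
}

# causal critically damped second-order kernel (t/tau^2) exp(-t/tau),
# truncated at 8 tau and renormalized to unit area
.causalKernelDelay <- function(x, fs, tau_ms) {
  if (tau_ms <= 0) return(x)
  tau <- tau_ms / 1000
  tt <- seq(0, 8 * tau, by = 1 / fs)
  k <- (tt / tau^2) * exp(-tt / tau)
  k <- k / sum(k)
  m <- length(k)
  xpad <- c(rep(x[1L], m - 1L), x)
  y <- stats::filter(xpad, k, method = "convolution", sides = 1L)
  as.numeric(y[m:length(xpad)])
}
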