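#' Motoneuron pool configuration
#'
#' Parameters of the simulated motoneuron pool. Recruitment excitations are
#' exponentially spaced over a configurable range (many-fold more
#' low-threshold than high-threshold units), the classic pool construction
#' for simulating graded voluntary drive. Defaults describe the pool the
#' analysis expects to see in a dorsiflexion experiment: about 7
#' simultaneously detectable units whose pooled plateau discharge rate at a
#' 20 %MVC target is ~15 Hz.
#'
#' @param n_units number of motor units (default 7).
#' @param recruitment_range ratio of the highest to the lowest recruitment
#'   excitation (default 30).
#' @param threshold_max excitation (%MVC-equivalent drive) at which the last
#'   unit is recruited (default 15, so the whole pool is active below a
#'   20 %MVC target).
#' @param min_rate discharge rate at recruitment, Hz (default 8).
#' @param rate_gain rate increase per unit excitation, Hz per %MVC (default
#'   0.46, which calibrates the pooled plateau mean at 20 %MVC to ~15 Hz for
#'   the default pool).
#' @param peak_rate saturation rate, Hz (default 35).
#' @param isi_cv coefficient of variation of the inter-spike-interval jitter
#'   (default 0.15).
#' @param derecruit_frac fraction of the recruitment excitation at which a
#'   unit stops firing on the descending ramp (default 1 = stops exactly at
#'   its recruitment excitation; values < 1 add motoneuron de-recruitment
#'   hysteresis).
#' @return a list of class \code{"PoolConfig"}.
#' @examples
#' poolConfig(n_units = 5)
#' @export
poolConfig <- function(n_units = 7, recruitment_range = 30,
                       threshold_max = 15, min_rate = 8, rate_gain = 0.46,
                       peak_rate = 35, isi_cv = 0.15, derecruit_frac = 1) {
  if (n_units < 1) stop("n_units must be >= 1")
  if (recruitment_range <= 1) stop("recruitment_range must exceed 1")
  if (isi_cv < 0) stop("isi_cv must be >= 0")
  if (min_rate <= 0 || peak_rate < min_rate)
    stop("need 0 < min_rate <= peak_rate")
  if (derecruit_frac <= 0 || derecruit_frac > 1)
    stop("derecruit_frac must be in (0, 1]")
  structure(list(n_units = as.integer(n_units),
                 recruitment_range = recruitment_range,
                 threshold_max = threshold_max, min_rate = min_rate,
                 rate_gain = rate_gain, peak_rate = peak_rate,
                 isi_cv = isi_cv, derecruit_frac = derecruit_frac),
            class = "PoolConfig")
}

#' Contraction protocol configuration
#'
#' Describes one trapezoidal (ramp-hold-ramp) isometric contraction,
#' optionally with a sinusoidal torque target during the plateau. Defaults
#' follow the reference protocol: 10 %MVC/s ramps, a 30 s plateau at 20 or
#' 40 %MVC, 0.5 Hz / +-2.5 %MVC plateau oscillation in sinusoidal mode,
#' 2048 Hz signal sampling and 80 frames/s imaging.
#'
#' @param target_level plateau target in %MVC (20 or 40 in the reference
#'   protocol; any positive value is accepted).
#' @param ramp_rate ramp slope, %MVC per second (default 10).
#' @param plateau_s plateau duration, seconds (default 30).
#' @param mode "sustained" or "sinusoidal".
#' @param sin_freq plateau oscillation frequency, Hz (default 0.5).
#' @param sin_amp plateau oscillation amplitude, %MVC (default 2.5, i.e. a
#'   20 %MVC target varies between 17.5 and 22.5 %MVC).
#' @param fs signal sampling rate, Hz (default 2048).
#' @param frame_rate imaging frame rate, Hz (default 80).
#' @param rest_s quiet lead-in/lead-out before and after the trapezoid,
#'   seconds (default 2).
#' @param common_noise_pct standard deviation (%MVC) of the shared
#'   low-frequency drive fluctuation added to the commanded profile during
#'   the contraction (default 1.5, calibrated together with
#'   \code{common_noise_hz} so the band-limited CST-torque correlation of
#'   the default trial sits near the ~0.7 reported for voluntary
#'   dorsiflexion). This is the common synaptic noise that makes neural
#'   drive, fascicle length and torque co-fluctuate at all; set 0 for a
#'   fully deterministic profile.
#' @param common_noise_hz corner(s) shaping the common fluctuation: a
#'   (high, low) pair gives a bandpass (default c(0.4, 2.5) Hz, the
#'   physiological force-fluctuation band the muscle transmits).
#' @return a list of class \code{"ProtocolConfig"}.
#' @examples
#' protocolConfig(target_level = 40)
#' protocolConfig(mode = "sinusoidal")
#' @export
protocolConfig <- function(target_level = 20, ramp_rate = 10, plateau_s = 30,
                           mode = c("sustained", "sinusoidal"),
                           sin_freq = 0.5, sin_amp = 2.5, fs = 2048,
                           frame_rate = 80, rest_s = 2,
                           common_noise_pct = 1.5,
                           common_noise_hz = c(0.4, 2.5)) {
  mode <- match.arg(mode)
  if (target_level <= 0) stop("target_level must be positive")
  if (ramp_rate <= 0) stop("ramp_rate must be positive")
  if (plateau_s <= 0) stop("plateau duration must be positive")
  if (fs <= 0 || frame_rate <= 0) stop("rates must be positive")
  structure(list(target_level = target_level, ramp_rate = ramp_rate,
                 plateau_s = plateau_s, mode = mode, sin_freq = sin_freq,
                 sin_amp = sin_amp, fs = fs, frame_rate = frame_rate,
                 rest_s = rest_s, common_noise_pct = common_noise_pct,
                 common_noise_hz = common_noise_hz),
            class = "ProtocolConfig")
}

#' Muscle mechanics configuration
#'
#' Parameters of the delayed, calibrated mapping from neural drive to
#' fascicle shortening and torque. The two delays are pure time shifts by
#' default so that the injected electromechanical latencies are exact ground
#' truth for the lag estimators: ~75 ms from drive to fascicle shortening
#' and a further ~75 ms from shortening to measured torque. Geometry and
#' torque anchors default to a tibialis anterior at the short muscle length
#' (60.2 mm rest fascicle length, 15.2 deg rest pennation, 7.5 mm shortening
#' and 19.2 deg pennation at a 20 %MVC plateau, 25.2 N m MVC); see
#' \code{mechanicsPresets} for the long-length values.
#'
#' @param delay_drive_to_fascicle ms, drive-to-fascicle latency (default 75).
#' @param delay_fascicle_to_torque ms, additional fascicle-to-torque latency
#'   (default 75, i.e. drive-to-torque is ~150 ms).
#' @param smoothing_tau ms, width of the zero-phase Hann kernel that turns
#'   a summed spike train into a smooth drive when the mechanics are driven
#'   from spikes (default 400, a twitch-fusion-scale lowpass; unused for an
#'   excitation drive).
#' @param rest_length mm, fascicle rest length (default 60.2).
#' @param shortening_at_20pct mm of shortening at a sustained 20 %MVC
#'   plateau (default 7.5); other drive levels scale linearly.
#' @param rest_pennation deg at rest (default 15.2).
#' @param pennation_at_20pct deg at the 20 %MVC plateau (default 19.2);
#'   pennation is affine in shortening between these anchors.
#' @param torque_mvc N m at 100 %MVC (default 25.2).
#' @param noise_torque_pct %MVC standard deviation of the additive torque
#'   noise (default 0.3, a typical force-steadiness scale at 20 %MVC).
#' @param noise_fascicle_mm mm standard deviation of the per-frame fascicle
#'   noise (default 0.1, a typical speckle-tracking jitter).
#' @param noise_band_hz Hz, the noise is lowpass-shaped below this corner so
#'   it has realistic power at physiological fluctuation frequencies
#'   (default 5).
#' @param mode "pure-shift" (default; delays are exact sample shifts) or
#'   "causal-kernel" (critically damped impulse response
#'   \eqn{(t/\tau^2) e^{-t/\tau}}; more physiological but its effective
#'   band-limited group delay must be measured, not assumed).
#' @return a list of class \code{"MechanicsConfig"}.
#' @examples
#' mechanicsConfig()
#' mechanicsConfig(delay_fascicle_to_torque = 0)
#' @export
mechanicsConfig <- function(delay_drive_to_fascicle = 75,
                            delay_fascicle_to_torque = 75,
                            smoothing_tau = 400, rest_length = 60.2,
                            shortening_at_20pct = 7.5, rest_pennation = 15.2,
                            pennation_at_20pct = 19.2, torque_mvc = 25.2,
                            noise_torque_pct = 0.3, noise_fascicle_mm = 0.1,
                            noise_band_hz = 5,
                            mode = c("pure-shift", "causal-kernel")) {
  mode <- match.arg(mode)
  if (delay_drive_to_fascicle < 0 || delay_fascicle_to_torque < 0)
    stop("delays must be >= 0")
  if (shortening_at_20pct <= 0) stop("shortening amplitude must be positive")
  if (rest_length <= shortening_at_20pct * 5)
    stop("rest_length must exceed the shortening at any drive level")
  structure(list(delay_drive_to_fascicle = delay_drive_to_fascicle,
                 delay_fascicle_to_torque = delay_fascicle_to_torque,
                 smoothing_tau = smoothing_tau, rest_length = rest_length,
                 shortening_at_20pct = shortening_at_20pct,
                 rest_pennation = rest_pennation,
                 pennation_at_20pct = pennation_at_20pct,
                 torque_mvc = torque_mvc,
                 noise_torque_pct = noise_torque_pct,
                 noise_fascicle_mm = noise_fascicle_mm,
                 noise_band_hz = noise_band_hz, mode = mode),
            class = "MechanicsConfig")
}

#' Mechanics presets for the two muscle lengths
#'
#' Convenience constructors for the short (0 deg plantar flexion) and long
#' (30 deg plantar flexion) tibialis anterior geometries used throughout the
#' worked examples: rest fascicle length 60.2 vs 74.5 mm, rest pennation
#' 15.2 vs 12.0 deg, MVC torque 25.2 vs 51.8 N m.
#'
#' @param length "short" or "long".
#' @param ... further arguments passed to \code{\link{mechanicsConfig}}.
#' @return a \code{"MechanicsConfig"} list.
#' @examples
#' mechanicsPresets("long")
#' @export
mechanicsPresets <- function(length = c("short", "long"), ...) {
  length <- match.arg(length)
  if (length == "short") {
    mechanicsConfig(rest_length = 60.2, rest_pennation = 15.2,
                    pennation_at_20pct = 19.2, torque_mvc = 25.2, ...)
  } else {
    mechanicsConfig(rest_length = 74.5, rest_pennation = 12.0,
                    shortening_at_20pct = 8.2, pennation_at_20pct = 16.9,
                    torque_mvc = 51.8, ...)
  }
}

#' Ultrasound renderer configuration
#'
#' Geometry of the synthetic B-mode frames. The pixel scale follows the
#' probe's field of view divided by the image width.
#'
#' @param width_px image width in pixels (default 256).
#' @param height_px image height in pixels (default 128).
#' @param fov_mm lateral field of view in mm (default 60).
#' @param apo_y_px image row of the (horizontal) central aponeurosis
#'   (default 112).
#' @param insertion_x_px image column of the fascicle insertion into the
#'   aponeurosis (default \code{width_px - 4}).
#' @param speckle_sigma_px Gaussian blur radius of the speckle background
#'   (default 1.5).
#' @return a list of class \code{"ImagingConfig"} including the derived
#'   \code{mm_per_px}.
#' @examples
#' imagingConfig()
#' @export
imagingConfig <- function(width_px = 256, height_px = 128, fov_mm = 60,
                          apo_y_px = 112, insertion_x_px = width_px - 4,
                          speckle_sigma_px = 1.5) {
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px), fov_mm = fov_mm,
                 mm_per_px = fov_mm / width_px, apo_y_px = apo_y_px,
                 insertion_x_px = insertion_x_px,
                 speckle_sigma_px = speckle_sigma_px),
            class = "ImagingConfig")
}
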