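#' Simulate one complete trial
#'
#' Runs the whole generator: excitation drive for the protocol, spike trains
#' from the motoneuron pool, delayed calibrated mechanics (fascicle
#' kinematics + torque), multichannel EMG, the imaging trigger and
#' (optionally) rendered speckle frames. One master seed fans out into named
#' sub-streams (spikes, mechanics noise, EMG templates, EMG noise, speckle)
#' so the components can be varied independently while the whole bundle is
#' reproducible bit-for-bit.
#'
#' @param protocol a \code{\link{protocolConfig}}.
#' @param pool_cfg a \code{\link{poolConfig}}.
#' @param mech a \code{\link{mechanicsConfig}}.
#' @param seed master seed.
#' @param render logical, render ultrasound frames (default FALSE; the
#'   ground-truth \linkS4class{FascicleTrace} is always present).
#' @param imaging an \code{\link{imagingConfig}} used when rendering.
#' @param emg logical, synthesize the EMG matrix (default TRUE).
#' @param noise logical, add measurement noise to mechanics (default TRUE).
#' @param emg_noise_sd white-noise sd of the EMG channels.
#' @return a \linkS4class{TrialRecording}.
#' @examples
#' tr <- simulateTrial(protocolConfig(plateau_s = 5), seed = 7, emg = FALSE)
#' tr
#' @export
simulateTrial <- function(protocol = protocolConfig(),
                          pool_cfg = poolConfig(), mech = mechanicsConfig(),
                          seed = 1L, render = FALSE,
                          imaging = imagingConfig(), emg = TRUE,
                          noise = TRUE, emg_noise_sd = 0.05) {
  seeds <- .fanSeeds(seed, c("drive", "spikes", "mech", "templates", "emg",
                             "speckle"))
  pool <- buildPool(pool_cfg)
  excitation <- generateExcitation(protocol,
                                   seed = if (noise) seeds[["drive"]])
  fs <- protocol$fs
  spikes <- sampleSpikes(pool, excitation, fs, seed = seeds[["spikes"]])
  # the mechanics transduce the whole-pool common drive (the excitation,
  # shared fluctuations included), not the few detected units' summed
  # train: renewal noise of the undetected majority averages out in vivo
  mx <- synthesizeMechanics(as.numeric(excitation), mech, protocol,
                            noise = noise, seed = seeds[["mech"]])
  n <- length(mx$torque_pct)
  if (emg) {
    templates <- muapTemplateLibrary(pool_cfg$n_units, fs = fs,
                                     seed = seeds[["templates"]])
    emg_mat <- synthesizeEmg(spikes, templates, noise_sd = emg_noise_sd,
                             seed = seeds[["emg"]])
  } else {
    emg_mat <- matrix(numeric(0), 0, 0)
  }
  frames <- list()
  if (render) {
    r <- renderUltrasound(mx$fascicle, imaging, fs = fs,
                          seed = seeds[["speckle"]])
    frames <- r$frames
    trigger <- numeric(n)
    m <- min(n, length(r$trigger))
    trigger[seq_len(m)] <- r$trigger[seq_len(m)]
    edges <- r$edges
  } else {
    edges <- mx$frame_samples
    pulse <- max(2L, round(fs / protocol$frame_rate / 2))
    trigger <- numeric(n)
    for (e in edges) trigger[e:min(n, e + pulse - 1L)] <- 1
  }
  new("TrialRecording", emg = emg_mat, torque_nm = mx$torque_nm,
      torque_pct = mx$torque_pct, drive_pct = mx$drive_pct,
      spikes = spikes, truth_fascicle = mx$fascicle, trigger = trigger,
      frames = frames, fs = fs, frame_rate = protocol$frame_rate,
      delays_ms = c(drive_to_fascicle = mech$delay_drive_to_fascicle,
                    fascicle_to_torque = mech$delay_fascicle_to_torque),
      config = list(protocol = protocol, pool = pool_cfg, mechanics = mech),
      seed = as.integer(seed))
}
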