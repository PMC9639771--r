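#' Segment a trapezoidal contraction into ramp-up, plateau, ramp-down
#'
#' Boundary criteria: contraction onset is the first sample where torque
#' exceeds \code{onset_pct} (%MVC) sustained for \code{sustain_ms}; the
#' plateau is the longest run in which the torque stays within
#' \code{plateau_tol} (fraction) of the target while the smoothed torque
#' slope stays below \code{slope_max} %MVC/s; offset is symmetric on the
#' falling side. The ±25% default plateau band accommodates the sinusoidal
#' protocol (target ± amplitude) within the same code path. The slope is
#' computed on a \code{smooth_ms} moving average; with noisy torque this
#' biases the plateau edges outward by up to half the smoothing width —
#' set \code{smooth_ms = 0} for exact edges on noiseless traces.
#'
#' @param torque_pct torque trace in %MVC.
#' @param target_pct plateau target (%MVC).
#' @param fs sampling rate, Hz.
#' @param opts list: \code{onset_pct} (2), \code{sustain_ms} (100),
#'   \code{plateau_tol} (0.25), \code{slope_max} (2 %MVC/s),
#'   \code{smooth_ms} (500), \code{bridge_ms} (1000: interior criterion
#'   dropouts shorter than this are bridged, so brief fluctuation
#'   excursions do not fragment a physiologically continuous plateau).
#' @return a \linkS4class{ContractionSegments}.
#' @examples
#' prot <- protocolConfig(plateau_s = 5)
#' e <- generateExcitation(prot)
#' seg <- segmentContraction(e, 20, fs = prot$fs, opts = list(smooth_ms = 0))
#' @export
segmentContraction <- function(torque_pct, target_pct, fs, opts = list()) {
  onset_pct <- if (is.null(opts$onset_pct)) 2 else opts$onset_pct
  sustain_ms <- if (is.null(opts$sustain_ms)) 100 else opts$sustain_ms
  tol <- if (is.null(opts$plateau_tol)) 0.25 else opts$plateau_tol
  slope_max <- if (is.null(opts$slope_max)) 2 else opts$slope_max
  smooth_ms <- if (is.null(opts$smooth_ms)) 500 else opts$smooth_ms
  bridge_ms <- if (is.null(opts$bridge_ms)) 1000 else opts$bridge_ms
  n <- length(torque_pct)
  sustain <- max(1L, round(sustain_ms * fs / 1000))
  above <- torque_pct > onset_pct
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts_run <- ends - runs$lengths + 1L
  ok <- which(runs$values & runs$lengths >= sustain)
  if (!length(ok)) stop("no sustained contraction found")
  onset <- starts_run[ok[1L]]
  offset <- ends[ok[length(ok)]]
  sm <- if (smooth_ms > 0) .movingAverage(torque_pct, fs, smooth_ms)
        else torque_pct
  slope <- c(0, diff(sm)) * fs
  in_band <- abs(torque_pct - target_pct) < tol * target_pct &
    abs(slope) < slope_max
  # bridge brief interior dropouts of the criterion
  bridge <- round(bridge_ms * fs / 1000)
  if (bridge > 0L) {
    rb <- rle(in_band)
    eb <- cumsum(rb$lengths)
    sb <- eb - rb$lengths + 1L
    short <- which(!rb$values & rb$lengths < bridge)
    short <- short[short > 1L & short < length(rb$values)]
    for (j in short) in_band[sb[j]:eb[j]] <- TRUE
  }
  runs2 <- rle(in_band)
  ends2 <- cumsum(runs2$lengths)
  starts2 <- ends2 - runs2$lengths + 1L
  ok2 <- which(runs2$values)
  if (!length(ok2)) stop("no qualifying plateau found")
  best <- ok2[which.max(runs2$lengths[ok2])]
  p0 <- starts2[best]
  p1 <- ends2[best]
  if (p0 <= onset || p1 >= offset)
    stop("plateau must lie strictly inside the contraction")
  new("ContractionSegments",
      ramp_up = c(as.integer(onset), as.integer(p0 - 1L)),
      plateau = c(as.integer(p0), as.integer(p1)),
      ramp_down = c(as.integer(p1 + 1L), as.integer(offset)),
      target_pct = as.numeric(target_pct))
}

#' Recruitment and de-recruitment thresholds in two coordinate systems
#'
#' For every unit with at least one discharge, reads the torque (%MVC) and
#' the fascicle shortening (mm, rest minus current length) at the instant
#' of its first discharge (recruitment) and of its last discharge
#' (de-recruitment), at the discharge sample itself with no local
#' averaging. Units that first fire after the end of the ramp-up (i.e.
#' recruited during the plateau) or last fire before the start of the
#' ramp-down are flagged, as are tonic units already firing before the
#' contraction onset.
#'
#' @param spikes a \linkS4class{SpikeTrainSet}.
#' @param torque_pct torque trace (%MVC) on the spike clock.
#' @param delta_mm fascicle shortening trace (mm) on the spike clock (NA
#'   allowed outside the imaging span).
#' @param segments a \linkS4class{ContractionSegments}.
#' @return data.frame with one row per unit holding \code{unit_id},
#'   \code{rt_pct}, \code{drt_pct}, \code{rt_delta_mm}, \code{drt_delta_mm},
#'   the discharge samples used, and logical flags
#'   \code{recruited_in_plateau}, \code{derecruited_in_plateau},
#'   \code{tonic}. Units without discharges are excluded (with a message).
#' @examples
#' prot <- protocolConfig(plateau_s = 5)
#' tr <- simulateTrial(prot, seed = 2, emg = FALSE, noise = FALSE)
#' seg <- segmentContraction(tr@torque_pct, 20, prot$fs,
#'                           opts = list(smooth_ms = 0))
#' rs <- resampleToEmg(tr@truth_fascicle, which(diff(c(0, tr@trigger)) > 0))
#' thresholdRecords(tr@spikes, tr@torque_pct, rs$delta_mm, seg)
#' @export
thresholdRecords <- function(spikes, torque_pct, delta_mm, segments) {
  if (length(torque_pct) < spikes@n_samples)
    stop("torque trace shorter than the spike clock")
  delta_full <- rep(NA_real_, spikes@n_samples)
  delta_full[seq_len(min(length(delta_mm), spikes@n_samples))] <-
    delta_mm[seq_len(min(length(delta_mm), spikes@n_samples))]
  rows <- list()
  for (i in seq_along(spikes@units)) {
    d <- spikes@units[[i]]
    if (!length(d)) {
      message("unit ", spikes@unit_ids[i], " has no discharges; excluded")
      next
    }
    f <- d[1L]
    l <- d[length(d)]
    rows[[length(rows) + 1L]] <- data.frame(
      unit_id = spikes@unit_ids[i],
      rt_pct = torque_pct[f], drt_pct = torque_pct[l],
      rt_delta_mm = delta_full[f], drt_delta_mm = delta_full[l],
      rt_sample = f, drt_sample = l,
      recruited_in_plateau = f > segments@ramp_up[2L],
      derecruited_in_plateau = l < segments@ramp_down[1L],
      tonic = f < segments@ramp_up[1L],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no unit with discharges")
  do.call(rbind, rows)
}
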