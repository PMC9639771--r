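#' @import methods
NULL

#' Set of motor unit spike trains
#'
#' Holds the discharge times (integer sample indices on a common clock) of one
#' or more decomposed motor units, together with the sampling rate of that
#' clock and the length of the recording they live in. This is the neural
#' input of the whole pipeline: everything downstream (cumulative spike
#' trains, discharge-rate statistics, recruitment thresholds) consumes it.
#'
#' @slot units list of integer vectors, one per motor unit, each strictly
#'   increasing discharge sample indices (1-based).
#' @slot unit_ids character vector of unit identifiers, parallel to
#'   \code{units}.
#' @slot fs sampling rate in Hz.
#' @slot n_samples length of the recording in samples; all discharge indices
#'   must lie in \code{[1, n_samples]}.
#' @export
setClass("SpikeTrainSet",
  representation(units = "list", unit_ids = "character",
                 fs = "numeric", n_samples = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@units) != length(object@unit_ids))
      msg <- c(msg, "units and unit_ids must have equal length")
    if (length(object@fs) != 1L || object@fs <= 0)
      msg <- c(msg, "fs must be a single positive number")
    for (u in object@units) {
      if (length(u) == 0L) next
      if (any(u < 1L) || any(u > object@n_samples))
        msg <- c(msg, "discharge indices must lie in [1, n_samples]")
      if (is.unsorted(u, strictly = TRUE))
        msg <- c(msg, "discharge indices must be strictly increasing")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a SpikeTrainSet
#'
#' @param units list of integer vectors of discharge sample indices.
#' @param fs sampling rate (Hz).
#' @param n_samples recording length in samples.
#' @param unit_ids optional character ids; defaults to \code{"MU1"}, ...
#' @return a \linkS4class{SpikeTrainSet}.
#' @examples
#' spikeTrainSet(list(c(100L, 300L), c(150L)), fs = 2048, n_samples = 1000)
#' @export
spikeTrainSet <- function(units, fs, n_samples, unit_ids = NULL) {
  units <- lapply(units, function(u) as.integer(sort(u)))
  if (is.null(unit_ids))
    unit_ids <- if (length(units)) paste0("MU", seq_along(units))
                else character(0)
  new("SpikeTrainSet", units = units, unit_ids = as.character(unit_ids),
      fs = as.numeric(fs), n_samples = as.integer(n_samples))
}

#' Cumulative spike train (CST)
#'
#' Per-sample sum of the binary discharge trains of all units in a
#' \linkS4class{SpikeTrainSet}; the conventional proxy for the net neural
#' drive to the muscle.
#'
#' @slot counts integer vector of per-sample discharge counts.
#' @slot fs sampling rate in Hz.
#' @slot n_units number of motor units summed.
#' @export
setClass("CumulativeSpikeTrain",
  representation(counts = "integer", fs = "numeric", n_units = "integer"),
  validity = function(object) {
    if (any(object@counts < 0L)) "counts must be nonnegative" else TRUE
  })

#' Fascicle kinematics trace
#'
#' Fascicle length and pennation angle per imaging frame, with the rest
#' length used to express shortening. The shortening convention follows the
#' field: delta = rest length minus current length, positive while the
#' muscle contracts concentrically.
#'
#' @slot length_mm fascicle length per frame (mm).
#' @slot pennation_deg pennation angle per frame (degrees).
#' @slot frame_rate imaging frame rate (Hz).
#' @slot rest_length_mm scalar rest length (mm) used for the delta view.
#' @export
setClass("FascicleTrace",
  representation(length_mm = "numeric", pennation_deg = "numeric",
                 frame_rate = "numeric", rest_length_mm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@length_mm) != length(object@pennation_deg))
      msg <- c(msg, "length_mm and pennation_deg must be parallel")
    if (object@frame_rate <= 0) msg <- c(msg, "frame_rate must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a FascicleTrace
#'
#' @param length_mm per-frame fascicle length (mm).
#' @param pennation_deg per-frame pennation angle (deg).
#' @param frame_rate frame rate (Hz).
#' @param rest_length_mm rest length; defaults to the first frame's length.
#' @return a \linkS4class{FascicleTrace}.
#' @export
fascicleTrace <- function(length_mm, pennation_deg, frame_rate,
                          rest_length_mm = length_mm[1L]) {
  new("FascicleTrace", length_mm = as.numeric(length_mm),
      pennation_deg = as.numeric(pennation_deg),
      frame_rate = as.numeric(frame_rate),
      rest_length_mm = as.numeric(rest_length_mm))
}

#' Band-limited conditioned signal
#'
#' A signal restricted to the common fluctuation band (default 0.75-2 Hz) by
#' zero-phase Butterworth filtering, tagged with its provenance so pairing
#' labels in cross-correlation summaries are self-describing.
#'
#' @slot samples conditioned samples.
#' @slot fs sampling rate (Hz).
#' @slot band two-element numeric, (highpass, lowpass) corner frequencies.
#' @slot label source label, e.g. "CST", "torque", "fascicle".
#' @export
setClass("ConditionedSignal",
  representation(samples = "numeric", fs = "numeric",
                 band = "numeric", label = "character"))

#' Windowed cross-correlation summary
#'
#' Per-window peak correlation coefficients and lags for one signal pairing,
#' plus their arithmetic means. Positive lag means the first-named signal
#' leads the second.
#'
#' @slot pairing label such as "CST-torque".
#' @slot coef per-window peak coefficients.
#' @slot lag_ms per-window lags at the peak (ms).
#' @slot start per-window start samples.
#' @slot n_skipped number of windows skipped for zero variance.
#' @slot fs sampling rate of the input signals (Hz).
#' @export
setClass("XcorrSummary",
  representation(pairing = "character", coef = "numeric", lag_ms = "numeric",
                 start = "numeric", n_skipped = "integer", fs = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@coef) != length(object@lag_ms))
      msg <- c(msg, "coef and lag_ms must be parallel")
    if (any(abs(object@coef) > 1 + 1e-12))
      msg <- c(msg, "|coefficient| must not exceed 1")
    if (length(msg)) msg else TRUE
  })

#' Spike-triggered 2-D motor unit action potential template
#'
#' Spatio-temporal MUAP waveform over the electrode grid, obtained by
#' averaging EMG segments centred on a unit's discharges.
#'
#' @slot waveforms channels x samples matrix (arbitrary units).
#' @slot fs sampling rate (Hz).
#' @slot pre_ms window extent before the discharge instant (ms).
#' @slot post_ms window extent after the discharge instant (ms).
#' @slot n_averaged number of discharges averaged.
#' @export
setClass("MuapTemplate",
  representation(waveforms = "matrix", fs = "numeric",
                 pre_ms = "numeric", post_ms = "numeric",
                 n_averaged = "integer"),
  validity = function(object) {
    if (object@n_averaged < 1L) "n_averaged must be >= 1" else TRUE
  })

#' Decomposition-quality (SIL) result
#'
#' Silhouette-type score in [0, 1] contrasting the squared heights of the
#' source peaks at the proposed discharge times against the remaining local
#' maxima of the source, with the acceptance flag at a configurable gate
#' (default 0.86).
#'
#' @slot sil silhouette score in [0, 1].
#' @slot threshold acceptance gate.
#' @slot accepted TRUE iff \code{sil >= threshold}.
#' @export
setClass("SilResult",
  representation(sil = "numeric", threshold = "numeric", accepted = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@sil < 0 || object@sil > 1) msg <- c(msg, "sil must be in [0,1]")
    if (!identical(object@accepted, object@sil >= object@threshold))
      msg <- c(msg, "accepted must equal sil >= threshold")
    if (length(msg)) msg else TRUE
  })

#' Construct a SilResult
#' @param sil silhouette value in [0, 1].
#' @param threshold acceptance gate, default 0.86.
#' @return a \linkS4class{SilResult} with the acceptance flag derived from
#'   the gate.
#' @export
silResult <- function(sil, threshold = 0.86) {
  new("SilResult", sil = as.numeric(sil), threshold = as.numeric(threshold),
      accepted = as.numeric(sil) >= as.numeric(threshold))
}

#' Affine transform parameters (pixels)
#'
#' 2x2 linear part plus translation, mapping image coordinates (x, y) of one
#' frame into the next. Composable; the identity is
#' \code{affineParams()}.
#'
#' @slot A 2x2 linear part.
#' @slot t length-2 translation (px).
#' @slot converged TRUE unless the estimator flagged a failure.
#' @export
setClass("AffineParams",
  representation(A = "matrix", t = "numeric", converged = "logical"),
  validity = function(object) {
    msg <- character()
    if (!all(dim(object@A) == c(2L, 2L))) msg <- c(msg, "A must be 2x2")
    if (length(object@t) != 2L) msg <- c(msg, "t must have length 2")
    if (abs(det(object@A)) < .Machine$double.eps)
      msg <- c(msg, "linear part must be nonsingular")
    if (length(msg)) msg else TRUE
  })

#' @rdname AffineParams-class
#' @param A 2x2 linear part.
#' @param t translation (px).
#' @param converged estimator convergence flag.
#' @return an \linkS4class{AffineParams}.
#' @export
affineParams <- function(A = diag(2), t = c(0, 0), converged = TRUE) {
  new("AffineParams", A = A, t = as.numeric(t), converged = converged)
}

#' Fascicle geometry in image coordinates
#'
#' Endpoints of the tracked fascicle segment, the aponeurosis line it inserts
#' into, and the pixel scale. Image convention: x rightward, y downward,
#' origin at pixel (1, 1).
#'
#' @slot endpoints 2x2 matrix, columns are the two endpoints (x, y) in px;
#'   column 1 is the insertion on the aponeurosis.
#' @slot apo_point point on the aponeurosis line (px).
#' @slot apo_dir direction of the aponeurosis line (px, need not be unit).
#' @slot mm_per_px pixel scale (mm / px).
#' @export
setClass("FascicleGeometry",
  representation(endpoints = "matrix", apo_point = "numeric",
                 apo_dir = "numeric", mm_per_px = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(dim(object@endpoints) == c(2L, 2L)))
      msg <- c(msg, "endpoints must be a 2x2 matrix (columns = points)")
    if (sum((object@endpoints[, 1] - object@endpoints[, 2])^2) == 0)
      msg <- c(msg, "endpoints must be distinct")
    if (sum(object@apo_dir^2) == 0)
      msg <- c(msg, "aponeurosis direction must be nonzero")
    if (object@mm_per_px <= 0) msg <- c(msg, "mm_per_px must be > 0")
    if (length(msg)) msg else TRUE
  })

#' @rdname FascicleGeometry-class
#' @param endpoints 2x2 matrix of endpoint columns (x, y) px.
#' @param apo_point point on the aponeurosis (px).
#' @param apo_dir aponeurosis direction (px).
#' @param mm_per_px pixel scale (mm per px).
#' @return a \linkS4class{FascicleGeometry}.
#' @export
fascicleGeometry <- function(endpoints, apo_point, apo_dir, mm_per_px) {
  new("FascicleGeometry", endpoints = endpoints,
      apo_point = as.numeric(apo_point), apo_dir = as.numeric(apo_dir),
      mm_per_px = as.numeric(mm_per_px))
}

#' Contraction phase segmentation
#'
#' Sample ranges of the ramp-up, plateau and ramp-down phases of one
#' trapezoidal contraction, on the torque timeline.
#'
#' @slot ramp_up integer (start, end) samples.
#' @slot plateau integer (start, end) samples.
#' @slot ramp_down integer (start, end) samples.
#' @slot target_pct target torque (%MVC).
#' @export
setClass("ContractionSegments",
  representation(ramp_up = "integer", plateau = "integer",
                 ramp_down = "integer", target_pct = "numeric"),
  validity = function(object) {
    msg <- character()
    rng <- rbind(object@ramp_up, object@plateau, object@ramp_down)
    if (any(rng[, 1] > rng[, 2])) msg <- c(msg, "ranges must be nonempty")
    if (object@ramp_up[2] >= object@plateau[1] ||
        object@plateau[2] >= object@ramp_down[1])
      msg <- c(msg, "ranges must be ordered and disjoint")
    if (length(msg)) msg else TRUE
  })

#' Trigger-to-frame synchronization map
#'
#' Rising-edge sample indices of the imaging trigger on the EMG clock; frame
#' k corresponds to edge k.
#'
#' @slot edges strictly increasing edge sample indices.
#' @slot fs EMG sampling rate (Hz).
#' @slot frame_rate nominal imaging frame rate (Hz).
#' @slot gaps indices (into edges) after which a dropped-pulse gap was found.
#' @export
setClass("TriggerMap",
  representation(edges = "integer", fs = "numeric",
                 frame_rate = "numeric", gaps = "integer"),
  validity = function(object) {
    if (is.unsorted(object@edges, strictly = TRUE))
      "edges must be strictly increasing" else TRUE
  })

#' Paired contrast result
#'
#' Mean paired difference with its 95% confidence interval and two-sided
#' paired-t probability. With a single pair (as when contrasting printed
#' group means) the interval and probability are NA.
#'
#' @slot mean_diff mean of the paired differences.
#' @slot ci95 (lower, upper) 95% CI of the difference.
#' @slot p two-sided paired-t p-value.
#' @slot n number of pairs.
#' @export
setClass("ContrastResult",
  representation(mean_diff = "numeric", ci95 = "numeric",
                 p = "numeric", n = "integer"),
  validity = function(object) {
    ok <- anyNA(object@ci95) ||
      (object@ci95[1] <= object@mean_diff + 1e-12 &&
       object@mean_diff <= object@ci95[2] + 1e-12)
    if (!ok) "ci95 must bracket mean_diff" else TRUE
  })

#' One simulated trial bundle
#'
#' Everything one synthetic contraction produces, on a single time origin:
#' the multichannel EMG, torque in both units, the ground-truth fascicle
#' trace at the imaging rate, the frame trigger, the spike trains that drove
#' the mechanics, the injected delays, and the configuration snapshot.
#'
#' @slot emg samples x channels EMG matrix (a.u.).
#' @slot torque_nm torque trace (N m) at fs.
#' @slot torque_pct torque trace (%MVC) at fs.
#' @slot drive_pct the noiseless %MVC-equivalent drive the mechanics used.
#' @slot spikes \linkS4class{SpikeTrainSet}.
#' @slot truth_fascicle ground-truth \linkS4class{FascicleTrace}.
#' @slot trigger binary trigger trace at fs.
#' @slot frames list of image matrices (possibly empty).
#' @slot fs EMG/torque sampling rate (Hz).
#' @slot frame_rate imaging frame rate (Hz).
#' @slot delays_ms injected (drive->fascicle, fascicle->torque) delays (ms).
#' @slot config configuration snapshot (list of the three configs).
#' @slot seed master seed of the trial.
#' @export
setClass("TrialRecording",
  representation(emg = "matrix", torque_nm = "numeric", torque_pct = "numeric",
                 drive_pct = "numeric", spikes = "SpikeTrainSet",
                 truth_fascicle = "FascicleTrace", trigger = "numeric",
                 frames = "list", fs = "numeric", frame_rate = "numeric",
                 delays_ms = "numeric", config = "list", seed = "integer"))

setMethod("show", "SpikeTrainSet", function(object) {
  cnt <- vapply(object@units, length, integer(1))
  cat("SpikeTrainSet:", length(object@units), "units,",
      sum(cnt), "discharges,", object@n_samples, "samples @",
      object@fs, "Hz\n")
  if (length(cnt))
    cat("  discharges per unit:", paste(cnt, collapse = ", "), "\n")
})

setMethod("show", "CumulativeSpikeTrain", function(object) {
  cat("CumulativeSpikeTrain:", sum(object@counts), "discharges from",
      object@n_units, "units over", length(object@counts), "samples @",
      object@fs, "Hz\n")
})

setMethod("show", "FascicleTrace", function(object) {
  cat("FascicleTrace:", length(object@length_mm), "frames @",
      object@frame_rate, "Hz; rest", round(object@rest_length_mm, 2),
      "mm; range", paste(round(range(object@length_mm), 2), collapse = "-"),
      "mm\n")
})

setMethod("show", "XcorrSummary", function(object) {
  cat(sprintf("XcorrSummary [%s]: mean r = %.3f, mean lag = %.1f ms (%d windows",
              object@pairing, mean(object@coef), mean(object@lag_ms),
              length(object@coef)))
  if (object@n_skipped > 0L) cat(",", object@n_skipped, "skipped")
  cat(")\n")
})

setMethod("show", "SilResult", function(object) {
  cat(sprintf("SIL = %.3f (gate %.2f): %s\n", object@sil, object@threshold,
              if (object@accepted) "accepted" else "rejected"))
})

setMethod("show", "ContrastResult", function(object) {
  cat(sprintf("Paired contrast: mean diff %.4g, 95%% CI [%.4g, %.4g], p = %.4g, n = %d\n",
              object@mean_diff, object@ci95[1], object@ci95[2], object@p,
              object@n))
})

setMethod("show", "TrialRecording", function(object) {
  cat("TrialRecording:", length(object@torque_pct), "samples @", object@fs,
      "Hz;", length(object@truth_fascicle@length_mm), "frames @",
      object@frame_rate, "Hz;", length(object@spikes@units), "units;",
      "delays", paste(object@delays_ms, collapse = "/"), "ms; seed",
      object@seed, "\n")
})
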