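#' Number of motor units
#' @param x an object holding motor unit data.
#' @return integer count of units.
#' @export
setGeneric("nUnits", function(x) standardGeneric("nUnits"))

#' @rdname nUnits
#' @export
setMethod("nUnits", "SpikeTrainSet", function(x) length(x@units))

#' @rdname nUnits
#' @export
setMethod("nUnits", "CumulativeSpikeTrain", function(x) as.integer(x@n_units))

#' Sampling rate accessor
#' @param x an object with a sample clock.
#' @return sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "SpikeTrainSet", function(x) x@fs)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "CumulativeSpikeTrain", function(x) x@fs)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "ConditionedSignal", function(x) x@fs)

#' Discharge sample indices of one unit
#' @param x a \linkS4class{SpikeTrainSet}.
#' @param unit unit index or id.
#' @return integer vector of discharge sample indices.
#' @export
setGeneric("discharges", function(x, unit) standardGeneric("discharges"))

#' @rdname discharges
#' @export
setMethod("discharges", "SpikeTrainSet", function(x, unit) {
  if (is.character(unit)) unit <- match(unit, x@unit_ids)
  x@units[[unit]]
})

#' Per-sample counts of a cumulative spike train
#' @param x a \linkS4class{CumulativeSpikeTrain}.
#' @return integer vector of per-sample discharge counts.
#' @export
setGeneric("cstCounts", function(x) standardGeneric("cstCounts"))

#' @rdname cstCounts
#' @export
setMethod("cstCounts", "CumulativeSpikeTrain", function(x) x@counts)

#' Fascicle shortening relative to rest
#'
#' The delta view of a fascicle trace: rest length minus current length,
#' positive during concentric shortening.
#' @param x a \linkS4class{FascicleTrace}.
#' @return numeric vector of per-frame shortening (mm).
#' @export
setGeneric("deltaLength", function(x) standardGeneric("deltaLength"))

#' @rdname deltaLength
#' @export
setMethod("deltaLength", "FascicleTrace",
          function(x) x@rest_length_mm - x@length_mm)

#' Fascicle length accessor
#' @param x a \linkS4class{FascicleTrace}.
#' @return numeric vector of per-frame fascicle length (mm).
#' @export
setGeneric("fascicleLength", function(x) standardGeneric("fascicleLength"))

#' @rdname fascicleLength
#' @export
setMethod("fascicleLength", "FascicleTrace", function(x) x@length_mm)

#' Pennation accessor
#' @param x a \linkS4class{FascicleTrace}.
#' @return numeric vector of per-frame pennation angles (deg).
#' @export
setGeneric("pennation", function(x) standardGeneric("pennation"))

#' @rdname pennation
#' @export
setMethod("pennation", "FascicleTrace", function(x) x@pennation_deg)

#' Mean peak coefficient of a windowed cross-correlation
#' @param x an \linkS4class{XcorrSummary}.
#' @return arithmetic mean of the per-window peak coefficients.
#' @export
setGeneric("meanCoef", function(x) standardGeneric("meanCoef"))

#' @rdname meanCoef
#' @export
setMethod("meanCoef", "XcorrSummary", function(x) mean(x@coef))

#' Mean lag of a windowed cross-correlation
#' @param x an \linkS4class{XcorrSummary}.
#' @return arithmetic mean of the per-window lags (ms); positive when the
#'   first-named signal leads.
#' @export
setGeneric("meanLag", function(x) standardGeneric("meanLag"))

#' @rdname meanLag
#' @export
setMethod("meanLag", "XcorrSummary", function(x) mean(x@lag_ms))

#' Number of analysis windows
#' @param x an \linkS4class{XcorrSummary}.
#' @return number of retained windows.
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))

#' @rdname nWindows
#' @export
setMethod("nWindows", "XcorrSummary", function(x) length(x@coef))

#' Conditioned samples accessor
#' @param x a \linkS4class{ConditionedSignal}.
#' @return numeric vector of samples.
#' @export
setGeneric("signalSamples", function(x) standardGeneric("signalSamples"))

#' @rdname signalSamples
#' @export
setMethod("signalSamples", "ConditionedSignal", function(x) x@samples)

#' Trigger edge indices accessor
#' @param x a \linkS4class{TriggerMap}.
#' @return integer vector of rising-edge sample indices (frame k -> edge k).
#' @export
setGeneric("triggerEdges", function(x) standardGeneric("triggerEdges"))

#' @rdname triggerEdges
#' @export
setMethod("triggerEdges", "TriggerMap", function(x) x@edges)

#' Apply an affine transform to points
#' @param params an \linkS4class{AffineParams}.
#' @param pts 2 x m matrix of (x, y) columns.
#' @return 2 x m matrix of transformed points.
#' @export
applyAffine <- function(params, pts) {
  pts <- as.matrix(pts)
  params@A %*% pts + params@t
}

#' Compose two affine transforms
#'
#' \code{composeAffine(f, g)} is the transform applying \code{g} first and
#' then \code{f}.
#' @param f,g \linkS4class{AffineParams}.
#' @return the composed \linkS4class{AffineParams}.
#' @export
composeAffine <- function(f, g) {
  affineParams(A = f@A %*% g@A, t = as.numeric(f@A %*% g@t + f@t),
               converged = f@converged && g@converged)
}
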