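#' Clean a discharge train
#'
#' Deterministic replacement for the manual editing of decomposed spike
#' trains: discharges closer together than the refractory limit are
#' collapsed to the first of the cluster (duplicate firings assigned to a
#' single physiological discharge), and inter-spike intervals longer than
#' \code{long_isi_ms} are flagged as likely missing-pulse gaps. Gaps are
#' flagged only, never imputed: re-estimating pulses requires the
#' decomposition internals, which this package deliberately does not own.
#' The operation is idempotent and never increases the spike count.
#'
#' @param x a \linkS4class{SpikeTrainSet} or an integer vector of discharge
#'   sample indices.
#' @param fs sampling rate, Hz (taken from the object if available).
#' @param refractory_ms duplicates closer than this are collapsed
#'   (default 20).
#' @param long_isi_ms intervals longer than this are flagged (default 250).
#' @param unit unit index when \code{x} is a set (default: clean all units).
#' @return for a vector input, a list with \code{discharges},
#'   \code{n_duplicates_removed} and \code{gap_after} (indices into the
#'   cleaned train after which a long-ISI gap follows); for a set input, a
#'   cleaned \linkS4class{SpikeTrainSet} with per-unit flags in
#'   \code{attr(, "flags")}.
#' @examples
#' cleanDischarges(c(1000L, 1010L, 3000L), fs = 2048)
#' @export
cleanDischarges <- function(x, fs = NULL, refractory_ms = 20,
                            long_isi_ms = 250, unit = NULL) {
  if (is(x, "SpikeTrainSet")) {
    idx <- if (is.null(unit)) seq_along(x@units) else unit
    out <- x
    flags <- vector("list", length(x@units))
    names(flags) <- x@unit_ids
    for (i in idx) {
      cl <- cleanDischarges(x@units[[i]], fs = x@fs,
                            refractory_ms = refractory_ms,
                            long_isi_ms = long_isi_ms)
      out@units[[i]] <- cl$discharges
      flags[[i]] <- cl[c("n_duplicates_removed", "gap_after")]
    }
    validObject(out)
    attr(out, "flags") <- flags
    return(out)
  }
  if (is.null(fs)) stop("fs is required for a plain discharge vector")
  d <- as.integer(sort(x))
  refr <- refractory_ms * fs / 1000
  keep <- integer(0)
  last <- -Inf
  for (s in d) {
    if (s - last >= refr) {
      keep <- c(keep, s)
      last <- s
    }
  }
  isi_ms <- diff(keep) / fs * 1000
  list(discharges = as.integer(keep),
       n_duplicates_removed = length(d) - length(keep),
       gap_after = which(isi_ms > long_isi_ms))
}

#' Build the cumulative spike train
#'
#' Sums the binary discharge trains of all units into a per-sample count
#' trace: the cumulative spike train (CST), the conventional estimate of
#' the net neural drive. Spike count is conserved: the total of the counts
#' equals the summed per-unit discharge numbers, independent of unit order.
#'
#' @param spikes a \linkS4class{SpikeTrainSet}.
#' @param n_samples output length; defaults to the set's recording length.
#' @return a \linkS4class{CumulativeSpikeTrain}.
#' @examples
#' st <- spikeTrainSet(list(c(10L, 50L), c(50L)), fs = 2048, n_samples = 100)
#' sum(cstCounts(cumulativeSpikeTrain(st)))
#' @export
cumulativeSpikeTrain <- function(spikes, n_samples = spikes@n_samples) {
  n_samples <- as.integer(n_samples)
  counts <- integer(n_samples)
  for (u in spikes@units) {
    if (length(u) == 0L) next
    if (any(u > n_samples)) stop("discharge index beyond n_samples")
    tab <- tabulate(u, nbins = n_samples)
    counts <- counts + tab
  }
  new("CumulativeSpikeTrain", counts = counts, fs = spikes@fs,
      n_units = length(spikes@units))
}

#' Discharge-rate statistics of one unit
#'
#' Mean rate over a window plus a smoothed instantaneous-rate trace. The
#' mean uses (number of discharges - 1) divided by the span between the
#' first and last discharge inside the window, which is unbiased for sparse
#' trains; fewer than two discharges give 0. The smoothed trace is the
#' binary train convolved with a unit-area Hann kernel (default 400 ms,
#' wide enough to be smooth yet resolve a 0.5 Hz target modulation), scaled
#' to Hz, so its integral over time approximates the spike count.
#'
#' @param spikes a \linkS4class{SpikeTrainSet}.
#' @param unit unit index or id.
#' @param window integer (start, end) sample range; default whole recording.
#' @param smooth_ms Hann kernel width (default 400).
#' @return list with \code{mean_rate_hz}, \code{rate_trace_hz} (full-length,
#'   Hz) and \code{n_discharges} (inside the window).
#' @examples
#' st <- spikeTrainSet(list(seq(205L, 2048L, by = 205L)), fs = 2048,
#'                     n_samples = 2048L)
#' dischargeRateStats(st, 1)$mean_rate_hz
#' @export
dischargeRateStats <- function(spikes, unit, window = NULL, smooth_ms = 400) {
  fs <- spikes@fs
  if (is.null(window)) window <- c(1L, spikes@n_samples)
  if (window[1L] > window[2L] || window[1L] < 1L ||
      window[2L] > spikes@n_samples)
    stop("window must be a valid sample range inside the recording")
  d <- discharges(spikes, unit)
  inside <- d[d >= window[1L] & d <= window[2L]]
  mean_rate <- if (length(inside) >= 2L) {
    (length(inside) - 1L) / ((inside[length(inside)] - inside[1L]) / fs)
  } else 0
  train <- numeric(spikes@n_samples)
  train[d] <- 1
  trace <- .convSame(train, .hannKernel(fs, smooth_ms)) * fs
  list(mean_rate_hz = mean_rate, rate_trace_hz = trace,
       n_discharges = length(inside))
}
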