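#' Spike-triggered average 2-D MUAP template
#'
#' Averages EMG segments centred on a unit's discharges, channel by channel,
#' yielding the unit's spatio-temporal action potential over the grid.
#' Discharges whose window does not fit inside the recording are skipped and
#' excluded from \code{n_averaged}.
#'
#' @param emg samples x channels EMG matrix.
#' @param discharges integer discharge sample indices (or a
#'   \linkS4class{SpikeTrainSet} plus \code{unit}).
#' @param fs sampling rate, Hz.
#' @param window_ms (pre, post) window extents around the discharge in ms
#'   (default c(25, 25)).
#' @param unit unit index/id when passing a set.
#' @return a \linkS4class{MuapTemplate}.
#' @examples
#' st <- spikeTrainSet(list(c(500L, 900L)), fs = 2048, n_samples = 2048L)
#' tpl <- muapTemplateLibrary(1, seed = 3)
#' emg <- synthesizeEmg(st, tpl, noise_sd = 0)
#' staMuap(emg, st, unit = 1)
#' @export
staMuap <- function(emg, discharges, fs = NULL, window_ms = c(25, 25),
                    unit = 1L) {
  if (is(discharges, "SpikeTrainSet")) {
    st <- discharges
    fs <- st@fs
    if (is.character(unit)) unit <- match(unit, st@unit_ids)
    discharges <- st@units[[unit]]
  }
  if (is.null(fs)) stop("fs is required")
  pre <- round(window_ms[1L] * fs / 1000)
  post <- round(window_ms[2L] * fs / 1000)
  n <- nrow(emg)
  usable <- discharges[discharges - pre >= 1L & discharges + post <= n]
  if (!length(usable)) stop("no discharge fits the window inside the recording")
  acc <- matrix(0, ncol(emg), pre + post + 1L)
  for (d in usable)
    acc <- acc + t(emg[(d - pre):(d + post), , drop = FALSE])
  new("MuapTemplate", waveforms = acc / length(usable), fs = fs,
      pre_ms = window_ms[1L], post_ms = window_ms[2L],
      n_averaged = length(usable))
}

#' Match two MUAP templates by normalized cross-correlation
#'
#' Decides whether two templates (typically from two trials) belong to the
#' same motor unit: the channels are concatenated in fixed order and the
#' normalized cross-correlation is maximized over a global time shift of up
#' to \code{max_shift_ms} applied to all channels simultaneously. Templates
#' are regarded as the same unit when the peak coefficient exceeds 0.80.
#' The operation is symmetric: \code{matchMuaps(a, b)} equals
#' \code{matchMuaps(b, a)}.
#'
#' @param a,b \linkS4class{MuapTemplate}s with equal channel counts.
#' @param max_shift_ms maximal global shift (default 10).
#' @param match_threshold acceptance coefficient (default 0.80).
#' @return list with \code{coefficient} in [-1, 1], \code{shift_ms} at the
#'   peak, and \code{matched}.
#' @examples
#' st <- spikeTrainSet(list(c(500L, 900L)), fs = 2048, n_samples = 2048L)
#' tpl <- muapTemplateLibrary(1, seed = 4)
#' emg <- synthesizeEmg(st, tpl, noise_sd = 0)
#' m <- staMuap(emg, st, unit = 1)
#' matchMuaps(m, m)$coefficient
#' @export
matchMuaps <- function(a, b, max_shift_ms = 10, match_threshold = 0.80) {
  if (nrow(a@waveforms) != nrow(b@waveforms))
    stop("templates must have the same channel count")
  if (abs(a@fs - b@fs) > 1e-9) stop("templates must share the sampling rate")
  kmax <- round(max_shift_ms * a@fs / 1000)
  wa <- a@waveforms
  wb <- b@waveforms
  m <- min(ncol(wa), ncol(wb))
  wa <- wa[, seq_len(m), drop = FALSE]
  wb <- wb[, seq_len(m), drop = FALSE]
  best <- -Inf
  best_k <- 0L
  for (k in -kmax:kmax) {
    if (k >= 0) {
      xa <- wa[, seq_len(m - k), drop = FALSE]
      xb <- wb[, (1L + k):m, drop = FALSE]
    } else {
      xa <- wa[, (1L - k):m, drop = FALSE]
      xb <- wb[, seq_len(m + k), drop = FALSE]
    }
    r <- stats::cor(as.numeric(xa), as.numeric(xb))
    if (is.finite(r) && (r > best ||
        (r == best && abs(k) < abs(best_k)))) {
      best <- r
      best_k <- k
    }
  }
  list(coefficient = best, shift_ms = best_k * 1000 / a@fs,
       matched = best > match_threshold)
}
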