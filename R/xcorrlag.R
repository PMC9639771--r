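# full cross-products S(k) = sum_i a[i] * b[i+k] for k in -K..K via FFT
.crossProducts <- function(a, b, K) {
  m <- length(a)
  nfft <- stats::nextn(m + K, 2)
  fa <- stats::fft(c(a, numeric(nfft - m)))
  fb <- stats::fft(c(b, numeric(nfft - m)))
  cc <- Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / nfft
  # cc[k+1] = S(k) for k >= 0; cc[nfft+k+1] = S(k) for k < 0
  c(cc[(nfft - K + 1L):nfft], cc[1:(K + 1L)])
}

# per-lag Pearson correlation over the overlapping samples of one window
.lagPearson <- function(a, b, K) {
  m <- length(a)
  ca <- cumsum(a); ca2 <- cumsum(a^2)
  cb <- cumsum(b); cb2 <- cumsum(b^2)
  S <- .crossProducts(a, b, K)
  ks <- (-K):K
  len <- m - abs(ks)
  Sa <- Sb <- Sa2 <- Sb2 <- numeric(length(ks))
  pos <- ks >= 0
  kp <- ks[pos]
  Sa[pos] <- ca[m - kp]
  Sa2[pos] <- ca2[m - kp]
  cb0 <- c(0, cb)   # cb0[k + 1] = sum of b[1..k], defined for k = 0
  cb20 <- c(0, cb2)
  Sb[pos] <- cb[m] - cb0[kp + 1L]
  Sb2[pos] <- cb2[m] - cb20[kp + 1L]
  kn <- -ks[!pos]
  Sa[!pos] <- ca[m] - ca[kn]
  Sa2[!pos] <- ca2[m] - ca2[kn]
  Sb[!pos] <- cb[m - kn]
  Sb2[!pos] <- cb2[m - kn]
  va <- Sa2 - Sa^2 / len
  vb <- Sb2 - Sb^2 / len
  r <- (S - Sa * Sb / len) / sqrt(pmax(va, 0) * pmax(vb, 0))
  r[va <= 0 | vb <= 0] <- NA_real_
  list(lag = ks, r = r)
}

#' Windowed cross-correlation with lag estimation
#'
#' Splits two equally sampled signals into fixed-length windows (default
#' 5 s with 50% overlap, fully contained: a 30 s record yields 11 windows),
#' and in each window evaluates the Pearson correlation between the two
#' segments at every integer-sample lag within \code{±lag_max_ms}
#' (correlation recomputed over the overlapping samples at each lag). The
#' per-window peak coefficient is the maximum value and the lag is its
#' argument, with no sub-sample interpolation (at 2048 Hz the resolution,
#' 0.49 ms, is far below the effects of interest); exact ties resolve to
#' the smallest absolute lag. Positive lag means the first signal leads the
#' second. The summary reports the arithmetic means over windows; windows
#' in which either segment has zero variance are skipped and counted.
#'
#' @param a,b \linkS4class{ConditionedSignal}s or numeric vectors of equal
#'   length.
#' @param fs sampling rate, Hz (taken from conditioned inputs).
#' @param win_s window length in seconds (default 5).
#' @param overlap fractional window overlap (default 0.5).
#' @param lag_max_ms lag search half-range in ms (default 1000, covering
#'   every physiological electromechanical delay with a wide margin; note
#'   that for band-limited signals a search range approaching the band's
#'   fundamental period admits correlation sidelobes, so pipeline analyses
#'   of the 0.75-2 Hz band use 500 ms).
#' @param drop_boundary exclude windows whose maximum falls exactly on the
#'   search boundary — there a true interior peak was not resolved and the
#'   value is a failed detection; such windows are counted in
#'   \code{n_skipped} (default TRUE).
#' @param pairing label for the summary; defaults to the signal labels.
#' @return an \linkS4class{XcorrSummary}.
#' @examples
#' fs <- 256
#' x <- sin(2 * pi * 1.3 * seq(0, 30, by = 1 / fs))
#' s <- windowedXcorr(x, x, fs = fs)
#' nWindows(s)
#' meanLag(s)
#' @export
windowedXcorr <- function(a, b, fs = NULL, win_s = 5, overlap = 0.5,
                          lag_max_ms = 1000, drop_boundary = TRUE,
                          pairing = NULL) {
  la <- if (is(a, "ConditionedSignal")) a@label else "a"
  lb <- if (is(b, "ConditionedSignal")) b@label else "b"
  if (is(a, "ConditionedSignal")) { fs <- a@fs; a <- a@samples }
  if (is(b, "ConditionedSignal")) { fs <- if (is.null(fs)) b@fs else fs
                                    b <- b@samples }
  if (is.null(fs)) stop("fs is required for numeric inputs")
  if (length(a) != length(b)) stop("signals must have equal length")
  if (is.null(pairing)) pairing <- paste(la, lb, sep = "-")
  m <- round(win_s * fs)
  if (length(a) < m) stop("signals shorter than one window")
  step <- max(1L, round(m * (1 - overlap)))
  starts <- seq(1L, length(a) - m + 1L, by = step)
  K <- round(lag_max_ms * fs / 1000)
  K <- min(K, m - 2L)
  coefs <- lags <- numeric(0)
  kept <- numeric(0)
  skipped <- 0L
  for (s0 in starts) {
    aw <- a[s0:(s0 + m - 1L)]
    bw <- b[s0:(s0 + m - 1L)]
    if (stats::sd(aw) == 0 || stats::sd(bw) == 0) {
      skipped <- skipped + 1L
      next
    }
    lp <- .lagPearson(aw, bw, K)
    ok <- is.finite(lp$r)
    if (!any(ok)) { skipped <- skipped + 1L; next }
    rmax <- max(lp$r[ok])
    cand <- which(ok & lp$r == rmax)
    pick <- cand[which.min(abs(lp$lag[cand]))]
    if (drop_boundary && abs(lp$lag[pick]) == K) {
      skipped <- skipped + 1L
      next
    }
    coefs <- c(coefs, min(max(lp$r[pick], -1), 1))
    lags <- c(lags, lp$lag[pick] * 1000 / fs)
    kept <- c(kept, s0)
  }
  new("XcorrSummary", pairing = pairing, coef = coefs, lag_ms = lags,
      start = kept, n_skipped = skipped, fs = as.numeric(fs))
}

#' Delay matrix between CST, torque and fascicle shortening
#'
#' Runs the windowed cross-correlation for the three canonical pairings of
#' one trial: CST vs fascicle shortening, CST vs torque, and fascicle
#' shortening vs torque. The fascicle signal must be passed as shortening
#' (rest minus length) so that all correlations are positive-sense:
#' discharge rate rises when the fascicle shortens. Orientation is
#' consistent across pairings: a positive mean lag means the first-named
#' signal leads, so with a neural-to-fascicle latency of ~75 ms and a
#' further fascicle-to-torque latency of ~75 ms one expects lags of roughly
#' +75, +150 and +75 ms respectively.
#'
#' @param cst conditioned CST (\linkS4class{ConditionedSignal} or numeric).
#' @param torque conditioned torque.
#' @param fascicle_shortening conditioned fascicle shortening.
#' @param fs sampling rate for numeric inputs.
#' @param ... further arguments to \code{\link{windowedXcorr}}.
#' @return named list of three \linkS4class{XcorrSummary}:
#'   \code{cst_fascicle}, \code{cst_torque}, \code{fascicle_torque}.
#' @examples
#' fs <- 256
#' t <- seq(0, 30, by = 1 / fs)
#' x <- sin(2 * pi * 1.1 * t)
#' d <- delayMatrix(x, c(rep(0, 26), x[1:(length(x) - 26)]), x, fs = fs)
#' meanLag(d$cst_torque)
#' @export
delayMatrix <- function(cst, torque, fascicle_shortening, fs = NULL, ...) {
  n <- vapply(list(cst, torque, fascicle_shortening), function(x)
    if (is(x, "ConditionedSignal")) length(x@samples) else length(x),
    numeric(1))
  if (length(unique(n)) != 1L) stop("signals must have equal length")
  list(
    cst_fascicle = windowedXcorr(cst, fascicle_shortening, fs = fs,
                                 pairing = "CST-fascicle", ...),
    cst_torque = windowedXcorr(cst, torque, fs = fs,
                               pairing = "CST-torque", ...),
    fascicle_torque = windowedXcorr(fascicle_shortening, torque, fs = fs,
                                    pairing = "fascicle-torque", ...))
}
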