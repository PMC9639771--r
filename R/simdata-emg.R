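#' Generate a library of synthetic 2-D MUAP templates
#'
#' One spatio-temporal action potential template per unit over an 8 x 4
#' electrode grid (32 channels, row-major channel order): a Gaussian-windowed
#' oscillation whose amplitude decays with distance from a unit-specific
#' centre channel and whose latency shifts slightly along grid rows,
#' mimicking propagation. Each unit uses its own random draw, so templates
#' from different units are essentially uncorrelated.
#'
#' @param n_units number of templates.
#' @param fs sampling rate, Hz.
#' @param n_rows,n_cols electrode grid shape (default 8 x 4).
#' @param dur_ms template duration (default 15 ms).
#' @param seed integer seed.
#' @return list of channels x samples template matrices.
#' @examples
#' tpl <- muapTemplateLibrary(2, fs = 2048, seed = 1)
#' dim(tpl[[1]])
#' @export
muapTemplateLibrary <- function(n_units, fs = 2048, n_rows = 8, n_cols = 4,
                                dur_ms = 15, seed = 1L) {
  force(seed)
  old <- .saveSeed()
  on.exit(.restoreSeed(old), add = TRUE)
  set.seed(as.integer(seed))
  n_ch <- n_rows * n_cols
  m <- max(3L, round(fs * dur_ms / 1000))
  tt <- seq_len(m) - m / 2
  lapply(seq_len(n_units), function(i) {
    f0 <- stats::runif(1, 60, 280)          # Hz, MUAP spectral centre
    phase <- stats::runif(1, 0, 2 * pi)
    harm <- stats::runif(1, 0, 0.9)         # multiphasic admixture
    phase2 <- stats::runif(1, 0, 2 * pi)
    width <- stats::runif(1, 0.8, 4) / 1000 * fs    # envelope sd, samples
    r0 <- stats::runif(1, 1, n_rows)
    c0 <- stats::runif(1, 1, n_cols)
    shift_per_row <- stats::runif(1, -3, 3) / 1000 * fs    # samples/row
    amp <- stats::runif(1, 0.6, 1.4) * sample(c(-1, 1), 1)
    # spatial territory: sharp per-channel decay about a random centre
    spread <- stats::runif(1, 1, 2.5)
    w <- matrix(0, n_ch, m)
    for (ch in seq_len(n_ch)) {
      r <- (ch - 1L) %/% n_cols + 1L
      cc <- (ch - 1L) %% n_cols + 1L
      d2 <- (r - r0)^2 + (cc - c0)^2
      lat <- (r - r0) * shift_per_row
      w[ch, ] <- amp * exp(-d2 / spread) *
        exp(-((tt - lat)^2) / (2 * width^2)) *
        (sin(2 * pi * f0 * (tt - lat) / fs + phase) +
           harm * sin(2 * pi * 1.7 * f0 * (tt - lat) / fs + phase2))
    }
    w
  })
}

#' Synthesize a multichannel surface EMG recording
#'
#' Linear superposition model: each unit's template is added at every one of
#' its discharge instants, plus white Gaussian noise. The recording is
#' exactly the sum of the placed templates, so superposition holds by
#' construction.
#'
#' @param spikes a \linkS4class{SpikeTrainSet}.
#' @param templates list of channels x samples matrices, one per unit
#'   (see \code{\link{muapTemplateLibrary}}); templates are centred on the
#'   discharge instant.
#' @param noise_sd standard deviation of the additive white noise.
#' @param seed integer seed for the noise.
#' @return samples x channels EMG matrix.
#' @examples
#' st <- spikeTrainSet(list(c(500L, 900L)), fs = 2048, n_samples = 2048L)
#' tpl <- muapTemplateLibrary(1, seed = 2)
#' emg <- synthesizeEmg(st, tpl, noise_sd = 0)
#' @export
synthesizeEmg <- function(spikes, templates, noise_sd = 0.05, seed = 1L) {
  n <- spikes@n_samples
  if (length(templates) < length(spikes@units))
    stop("need one template per unit")
  n_ch <- nrow(templates[[1L]])
  m <- ncol(templates[[1L]])
  if (m > n) stop("template longer than the recording")
  half <- m %/% 2L
  emg <- matrix(0, n, n_ch)
  for (i in seq_along(spikes@units)) {
    w <- t(templates[[i]])                  # samples x channels
    for (d in spikes@units[[i]]) {
      i0 <- d - half
      j0 <- max(1L, i0)
      j1 <- min(n, i0 + m - 1L)
      emg[j0:j1, ] <- emg[j0:j1, ] + w[(j0 - i0 + 1L):(j1 - i0 + 1L), ]
    }
  }
  if (noise_sd > 0) {
    force(seed)
    old <- .saveSeed()
    on.exit(.restoreSeed(old), add = TRUE)
    set.seed(as.integer(seed))
    emg <- emg + matrix(stats::rnorm(n * n_ch, sd = noise_sd), n, n_ch)
  }
  emg
}
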