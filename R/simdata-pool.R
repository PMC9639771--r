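#' Build a motoneuron pool model
#'
#' Assigns each unit a recruitment excitation on an exponential ladder
#' spanning \code{recruitment_range} (normalized so the highest threshold is
#' \code{recruitment_range} times the lowest, with the highest placed at
#' \code{threshold_max} %MVC of drive), and a linear rate coding law: a unit
#' is silent below its recruitment excitation, fires at \code{min_rate}
#' exactly at it, and increases at \code{rate_gain} Hz per %MVC up to
#' \code{peak_rate}.
#'
#' @param cfg a \code{\link{poolConfig}}.
#' @return a list of class \code{"PoolModel"} with elements \code{rte}
#'   (per-unit recruitment excitations, %MVC, strictly increasing),
#'   \code{rte_stop} (excitation at which each unit de-recruits) and
#'   \code{cfg}.
#' @examples
#' pool <- buildPool(poolConfig())
#' pool$rte
#' @export
buildPool <- function(cfg = poolConfig()) {
  if (!inherits(cfg, "PoolConfig")) stop("cfg must be a poolConfig()")
  n <- cfg$n_units
  if (n < 1L) stop("n_units must be >= 1")
  if (n == 1L) {
    rte <- cfg$threshold_max
  } else {
    # exponential ladder exp(i * log(RR) / n), rescaled in log space so that
    # max = RR * min and max sits at threshold_max
    raw <- exp(seq_len(n) * log(cfg$recruitment_range) / n)
    lr <- log(raw)
    lr <- (lr - min(lr)) / (max(lr) - min(lr)) * log(cfg$recruitment_range)
    rte <- exp(lr) * cfg$threshold_max / cfg$recruitment_range
  }
  structure(list(rte = rte, rte_stop = rte * cfg$derecruit_frac, cfg = cfg),
            class = "PoolModel")
}

#' Discharge rate of one unit at a given excitation
#'
#' @param pool a \code{"PoolModel"} from \code{\link{buildPool}}.
#' @param excitation excitation in %MVC-equivalent drive (vectorized).
#' @param unit unit index.
#' @return discharge rate(s) in Hz; 0 below the unit's recruitment
#'   excitation, \code{min_rate} exactly at it.
#' @examples
#' pool <- buildPool(poolConfig())
#' rateAt(pool, pool$rte[1], 1)  # == min_rate
#' @export
rateAt <- function(pool, excitation, unit) {
  cfg <- pool$cfg
  r <- cfg$min_rate + cfg$rate_gain * (excitation - pool$rte[unit])
  r <- pmin(pmax(r, cfg$min_rate), cfg$peak_rate)
  r[excitation < pool$rte[unit]] <- 0
  r
}

#' Generate the excitation drive for a protocol
#'
#' Open-loop %MVC-equivalent drive: quiet lead-in, linear ramp up at
#' \code{ramp_rate}, plateau (constant, or sinusoidally modulated in
#' sinusoidal mode), linear ramp down, quiet lead-out. Ramp sample counts
#' are exact: \code{round(fs * target_level / ramp_rate)}.
#'
#' When \code{seed} is given and \code{protocol$common_noise_pct > 0}, a
#' band-limited common-drive fluctuation is superimposed during the
#' contraction (scaled by the commanded level so the rest phases stay
#' silent). This shared fluctuation is what the motoneuron pool, the
#' fascicle and the torque all inherit, and is the component the
#' cross-correlation analysis works on. Without a seed the commanded
#' profile is returned exactly.
#'
#' @param protocol a \code{\link{protocolConfig}}.
#' @param seed optional integer seed for the common-drive fluctuation.
#' @return numeric drive at \code{protocol$fs} with attribute
#'   \code{"segments"}: a list with 1-based (start, end) sample indices of
#'   \code{ramp_up}, \code{plateau} and \code{ramp_down}.
#' @examples
#' e <- generateExcitation(protocolConfig())
#' attr(e, "segments")$plateau
#' @export
generateExcitation <- function(protocol = protocolConfig(), seed = NULL) {
  if (!inherits(protocol, "ProtocolConfig"))
    stop("protocol must be a protocolConfig()")
  fs <- protocol$fs
  n_rest <- round(fs * protocol$rest_s)
  n_ramp <- round(fs * protocol$target_level / protocol$ramp_rate)
  n_plat <- round(fs * protocol$plateau_s)
  up <- protocol$target_level * seq_len(n_ramp) / n_ramp
  plat <- rep(protocol$target_level, n_plat)
  if (protocol$mode == "sinusoidal") {
    tt <- (seq_len(n_plat) - 1L) / fs
    plat <- plat + protocol$sin_amp * sin(2 * pi * protocol$sin_freq * tt)
  }
  x <- c(rep(0, n_rest), up, plat, rev(up), rep(0, n_rest))
  if (!is.null(seed) && protocol$common_noise_pct > 0) {
    force(seed)
    old <- .saveSeed()
    on.exit(.restoreSeed(old), add = TRUE)
    set.seed(as.integer(seed))
    cn <- .shapedNoise(length(x), fs, protocol$common_noise_hz)
    x <- pmax(0, x + protocol$common_noise_pct * cn *
                pmin(x / protocol$target_level, 1))
  }
  seg <- list(
    ramp_up = c(n_rest + 1L, n_rest + n_ramp),
    plateau = c(n_rest + n_ramp + 1L, n_rest + n_ramp + n_plat),
    ramp_down = c(n_rest + n_ramp + n_plat + 1L,
                  n_rest + 2L * n_ramp + n_plat))
  attr(x, "segments") <- seg
  attr(x, "fs") <- fs
  x
}

#' Sample motor unit spike trains from a pool and an excitation drive
#'
#' Renewal sampling per unit by time rescaling: the instantaneous rate
#' \code{rateAt(pool, E(t), i)} is integrated and a discharge is emitted
#' whenever the integrated rate since the previous discharge reaches a
#' jittered unit threshold \code{max(0.1, 1 + isi_cv * z)}, with z standard
#' normal (the 0.1 floor forbids nonphysiologically short intervals). Under
#' constant drive this reproduces exactly the classic sequential rule
#' "next interval = jitter / rate", i.e. intervals of mean \code{1/rate}
#' with coefficient of variation \code{isi_cv}; under varying drive the
#' discharge rate follows the excitation instantaneously instead of one
#' interval late, which matters when the trains are used to estimate
#' neuromechanical delays. A unit is silent while the excitation is below
#' its recruitment threshold; the first discharge of each recruitment
#' episode falls on the threshold crossing, and the unit stays active until
#' the excitation drops below its de-recruitment excitation
#' (\code{derecruit_frac * rte}).
#'
#' @param pool a \code{"PoolModel"}.
#' @param excitation numeric drive (%MVC-equivalent) at rate \code{fs}.
#' @param fs sampling rate of the drive, Hz.
#' @param seed integer seed; the trains are reproducible given
#'   (pool, excitation, seed).
#' @return a \linkS4class{SpikeTrainSet}.
#' @examples
#' pool <- buildPool(poolConfig(n_units = 3))
#' e <- generateExcitation(protocolConfig(plateau_s = 5))
#' sampleSpikes(pool, e, fs = 2048, seed = 1)
#' @export
sampleSpikes <- function(pool, excitation, fs, seed = 1L) {
  if (any(excitation < 0) || any(excitation > 100))
    stop("excitation must lie in [0, 100] %MVC")
  n <- length(excitation)
  force(seed)
  old <- .saveSeed()
  on.exit(.restoreSeed(old), add = TRUE)
  set.seed(as.integer(seed))
  cv <- pool$cfg$isi_cv
  units <- vector("list", pool$cfg$n_units)
  for (i in seq_along(units)) {
    rte <- pool$rte[i]
    stop_at <- pool$rte_stop[i]
    # per-sample rate, clamped to min_rate between the de-recruitment and
    # recruitment excitations (relevant only with hysteresis)
    r_t <- rateAt(pool, excitation, i)
    r_t[excitation >= stop_at & r_t <= 0] <- pool$cfg$min_rate
    C <- cumsum(r_t / fs)
    sp <- integer(0)
    pos <- 1L
    repeat {
      # next recruitment: excitation crosses rte at or after pos
      rec <- which(excitation[pos:n] >= rte)
      if (!length(rec)) break
      a <- pos + rec[1L] - 1L
      # active until excitation drops below the de-recruitment excitation
      der <- which(excitation[a:n] < stop_at)
      b <- if (length(der)) a + der[1L] - 2L else n
      sp <- c(sp, a)
      t_last <- a
      repeat {
        theta <- max(0.1, 1 + cv * stats::rnorm(1L))
        nxt <- findInterval(C[t_last] + theta, C) + 1L
        if (nxt > b) break
        sp <- c(sp, nxt)
        t_last <- nxt
      }
      if (b >= n) break
      pos <- b + 1L
    }
    units[[i]] <- as.integer(sp)
  }
  spikeTrainSet(units, fs = fs, n_samples = n)
}

# preserve the caller's RNG state around seeded sections
.saveSeed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restoreSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# deterministic fan-out of a master seed into named sub-stream seeds
.fanSeeds <- function(seed, names) {
  force(seed)
  old <- .saveSeed()
  on.exit(.restoreSeed(old), add = TRUE)
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max - 1L, length(names))
  names(s) <- names
  s
}
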