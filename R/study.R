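#' Map imaging trigger pulses to frames
#'
#' Detects rising edges of the analogue frame trigger by half-maximum
#' crossing; frame k corresponds to edge k. Gaps larger than 1.5x the
#' nominal pulse spacing are reported as dropped pulses.
#'
#' @param trigger trigger trace at \code{fs}.
#' @param fs sampling rate, Hz.
#' @param frame_rate nominal trigger rate, Hz (default 80).
#' @return a \linkS4class{TriggerMap}; dropped-pulse gap positions are in
#'   the \code{gaps} slot (index of the edge after which a gap follows).
#' @examples
#' tg <- rep(0, 2048)
#' for (e in round((0:79) * 25.6) + 1) tg[e:(e + 12)] <- 1
#' am <- alignTrigger(tg, 2048, 80)
#' length(triggerEdges(am))
#' @export
alignTrigger <- function(trigger, fs, frame_rate = 80) {
  thr <- (max(trigger) + min(trigger)) / 2
  if (max(trigger) == min(trigger)) stop("no edges in trigger")
  up <- trigger >= thr
  edges <- which(up & !c(TRUE, up[-length(up)]))
  if (trigger[1L] >= thr) edges <- c(1L, edges)
  if (length(edges) < 2L) stop("need at least 2 trigger edges")
  nominal <- fs / frame_rate
  gaps <- which(diff(edges) > 1.5 * nominal)
  if (abs(stats::median(diff(edges)) - nominal) > max(1, 0.01 * nominal))
    warning("median trigger spacing deviates >1% from nominal")
  new("TriggerMap", edges = as.integer(edges), fs = as.numeric(fs),
      frame_rate = as.numeric(frame_rate), gaps = as.integer(gaps))
}

#' Paired contrast with 95% confidence interval
#'
#' Mean paired difference \code{mean(x - y)}, its 95% confidence interval
#' \code{mean_diff ± t(0.975, n-1) * sd(x - y) / sqrt(n)}, and the
#' two-sided paired-t probability. Degenerate pairs with zero-variance
#' differences short-circuit: identical vectors give a difference of 0,
#' interval [0, 0] and p = 1.
#'
#' @param x,y equal-length paired observations (n >= 2).
#' @return a \linkS4class{ContrastResult}.
#' @examples
#' pairedContrast(c(60.2, 52.7), c(74.5, 66.3))
#' @export
pairedContrast <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs")
  d <- x - y
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    return(new("ContrastResult", mean_diff = md, ci95 = c(md, md),
               p = if (md == 0) 1 else 0, n = as.integer(n)))
  }
  se <- sdd / sqrt(n)
  tq <- stats::qt(0.975, n - 1L)
  tstat <- md / se
  new("ContrastResult", mean_diff = md,
      ci95 = c(md - tq * se, md + tq * se),
      p = 2 * stats::pt(-abs(tstat), n - 1L), n = as.integer(n))
}

#' Marginal (main) effect of one factor in a balanced condition table
#'
#' Collapses a condition table by averaging the metric over all other
#' factors within each subject, then contrasts the two levels of the named
#' factor pairwise across subjects. With a single subject row per cell (as
#' when the table holds printed group means) the mean difference is still
#' defined but the confidence interval and probability are NA.
#'
#' @param table data.frame with a subject column, factor columns and metric
#'   columns.
#' @param metric name of the metric column.
#' @param factor name of the factor column to contrast (must have exactly
#'   two levels after subsetting).
#' @param levels optional length-2 character vector fixing the order: the
#'   contrast is \code{levels[1] - levels[2]}.
#' @param subject name of the subject column (default "subject").
#' @return a \linkS4class{ContrastResult}.
#' @examples
#' tab <- data.frame(subject = "group",
#'                   length = c("short", "long", "short", "long"),
#'                   level = c(20, 20, 40, 40),
#'                   fl = c(52.7, 66.3, 50.8, 61.9))
#' marginalEffect(tab, "fl", "level", levels = c("40", "20"))
#' @export
marginalEffect <- function(table, metric, factor, levels = NULL,
                           subject = "subject") {
  stopifnot(all(c(subject, factor, metric) %in% names(table)))
  fac <- as.character(table[[factor]])
  if (is.null(levels)) levels <- unique(fac)
  levels <- as.character(levels)
  if (length(levels) != 2L) stop("factor must have exactly two levels")
  sub <- table[fac %in% levels, , drop = FALSE]
  fac <- as.character(sub[[factor]])
  agg <- stats::aggregate(sub[[metric]],
                          by = list(subject = as.character(sub[[subject]]),
                                    level = fac),
                          FUN = mean)
  counts <- table(as.character(sub[[subject]]), fac)
  if (length(unique(as.vector(counts))) != 1L)
    stop("design must be balanced across the other factors")
  w <- stats::reshape(agg, idvar = "subject", timevar = "level",
                      direction = "wide")
  x <- w[[paste0("x.", levels[1L])]]
  y <- w[[paste0("x.", levels[2L])]]
  if (anyNA(x) || anyNA(y)) stop("each subject needs both factor levels")
  if (length(x) == 1L) {
    return(new("ContrastResult", mean_diff = x - y, ci95 = c(NA_real_,
               NA_real_), p = NA_real_, n = 1L))
  }
  pairedContrast(x, y)
}

#' Bundled reference group means
#'
#' Ships two small plain-text tables of published group-mean values for the
#' tibialis anterior experiment the package's worked examples emulate
#' (n = 10 participants): muscle architecture (fascicle length and
#' pennation at rest and at the 20/40 %MVC plateaus, short and long muscle
#' lengths) and windowed cross-correlation coefficients for the three
#' signal pairings under sustained and sinusoidal contractions. These are
#' condition means only; they serve the table-arithmetic worked examples
#' and as calibration anchors for the simulator defaults.
#'
#' @param which "architecture" or "xcorr".
#' @return a data.frame with a leading \code{subject = "group"} column.
#' @examples
#' referenceGroupMeans("architecture")
#' @export
referenceGroupMeans <- function(which = c("architecture", "xcorr")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   if (which == "architecture")
                     "ta_architecture_group_means.csv"
                   else "ta_xcorr_group_means.csv",
                   package = "neuromech", mustWork = TRUE)
  tab <- utils::read.csv(f, stringsAsFactors = FALSE)
  cbind(subject = "group", tab, stringsAsFactors = FALSE)
}

#' Configuration for a simulated cohort run
#'
#' @param n_subjects number of simulated participants (default 10);
#'   subjects are simulation seeds with ±\code{jitter_frac} parameter
#'   jitter on rest length, delays and MVC torque so group dispersion is
#'   nonzero.
#' @param levels target torques, %MVC (default c(20, 40)).
#' @param lengths muscle lengths (default c("short", "long")).
#' @param modes contraction modes (default c("sustained", "sinusoidal")).
#' @param plateau_s plateau duration (default 30).
#' @param jitter_frac per-subject parameter jitter (default 0.1).
#' @param seed master seed.
#' @param pool_cfg pool configuration shared by all subjects.
#' @return a list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(n_subjects = 10, levels = c(20, 40),
                           lengths = c("short", "long"),
                           modes = c("sustained", "sinusoidal"),
                           plateau_s = 30, jitter_frac = 0.1, seed = 1L,
                           pool_cfg = poolConfig()) {
  structure(list(n_subjects = as.integer(n_subjects), levels = levels,
                 lengths = lengths, modes = modes, plateau_s = plateau_s,
                 jitter_frac = jitter_frac, seed = as.integer(seed),
                 pool_cfg = pool_cfg),
            class = "PipelineConfig")
}

# analyse one simulated trial: spikes -> CST -> conditioned signals ->
# delay matrix + thresholds + plateau discharge rates
.analyzeTrial <- function(trial, target_pct) {
  fs <- trial@fs
  clean <- cleanDischarges(trial@spikes)
  cst <- cumulativeSpikeTrain(clean)
  seg <- segmentContraction(trial@torque_pct, target_pct, fs)
  edges <- which(trial@trigger >= 0.5 &
                   !c(TRUE, trial@trigger[-length(trial@trigger)] >= 0.5))
  if (trial@trigger[1L] >= 0.5) edges <- c(1L, edges)
  rs <- resampleToEmg(trial@truth_fascicle, edges)
  pl <- seg@plateau[1L]:seg@plateau[2L]
  cst_c <- conditionSignal(as.numeric(cst@counts)[pl], fs, label = "CST")
  tor_c <- conditionSignal(trial@torque_pct[pl], fs, label = "torque")
  fas_c <- conditionSignal(rs$delta_mm[pl], fs, label = "fascicle")
  dm <- delayMatrix(cst_c, tor_c, fas_c, lag_max_ms = 350)
  thr <- thresholdRecords(clean, trial@torque_pct, rs$delta_mm, seg)
  rates <- vapply(seq_along(clean@units), function(i)
    dischargeRateStats(clean, i, window = seg@plateau)$mean_rate_hz,
    numeric(1))
  list(delays = dm, thresholds = thr, rates = rates, segments = seg,
       n_skipped = sum(vapply(dm, function(s) s@n_skipped, integer(1))))
}

#' Run the full simulated-cohort pipeline
#'
#' Simulates every cell of the condition grid (muscle length x target
#' torque x contraction mode) for every subject seed, runs the per-trial
#' analysis (spike cleaning, cumulative spike train, contraction
#' segmentation, signal conditioning, delay matrix, dual-coordinate
#' recruitment thresholds, plateau discharge rates) and aggregates
#' group-level tables and the standard marginal contrasts. Fully
#' reproducible from the master seed.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param progress print one line per trial (default FALSE).
#' @return a list of class \code{"PipelineReport"}: \code{xcorr}
#'   (per-trial-and-pairing coefficients and lags), \code{thresholds}
#'   (per-trial-and-unit records), \code{rates} (per-trial pooled plateau
#'   rates), \code{contrasts} (named \linkS4class{ContrastResult}s),
#'   \code{log} (per-trial notes) and \code{config}.
#' @examples
#' \donttest{
#' rep <- runPipeline(pipelineConfig(n_subjects = 2, plateau_s = 12,
#'                                   modes = "sustained"))
#' head(rep$xcorr)
#' }
#' @export
runPipeline <- function(config = pipelineConfig(), progress = FALSE) {
  sseeds <- .fanSeeds(config$seed,
                      paste0("subject", seq_len(config$n_subjects)))
  jseeds <- .fanSeeds(config$seed + 1L,
                      paste0("jitter", seq_len(config$n_subjects)))
  xc <- list(); th <- list(); ra <- list(); lg <- list()
  for (s in seq_len(config$n_subjects)) {
    old <- .saveSeed()
    set.seed(jseeds[[s]])
    jit <- stats::runif(4, -config$jitter_frac, config$jitter_frac)
    .restoreSeed(old)
    for (len in config$lengths) for (lev in config$levels)
      for (mode in config$modes) {
        prot <- protocolConfig(target_level = lev, mode = mode,
                               plateau_s = config$plateau_s)
        mech <- mechanicsPresets(len)
        mech$rest_length <- mech$rest_length * (1 + jit[1])
        mech$delay_drive_to_fascicle <-
          mech$delay_drive_to_fascicle * (1 + jit[2])
        mech$delay_fascicle_to_torque <-
          mech$delay_fascicle_to_torque * (1 + jit[3])
        mech$torque_mvc <- mech$torque_mvc * (1 + jit[4])
        trial_seed <- (sseeds[[s]] + 7L * match(len, config$lengths) +
                         13L * match(lev, config$levels) +
                         29L * match(mode, config$modes)) %%
          (.Machine$integer.max - 1L)
        res <- tryCatch({
          trial <- simulateTrial(prot, config$pool_cfg, mech,
                                 seed = trial_seed, emg = FALSE)
          suppressMessages(.analyzeTrial(trial, lev))
        }, error = function(e) e)
        tag <- sprintf("s%02d_%s_%d_%s", s, len, lev, mode)
        if (inherits(res, "error")) {
          lg[[tag]] <- paste("trial aborted:", conditionMessage(res))
          next
        }
        if (progress) message(tag, " ok")
        for (pn in names(res$delays)) {
          sm <- res$delays[[pn]]
          xc[[paste(tag, pn)]] <- data.frame(
            subject = s, length = len, level = lev, mode = mode,
            pairing = sm@pairing, coef = meanCoef(sm),
            lag_ms = meanLag(sm), n_windows = nWindows(sm))
        }
        th[[tag]] <- cbind(subject = s, length = len, level = lev,
                           mode = mode, res$thresholds)
        ra[[tag]] <- data.frame(subject = s, length = len, level = lev,
                                mode = mode,
                                mean_rate_hz = mean(res$rates[res$rates > 0]))
        lg[[tag]] <- sprintf("ok; %d skipped windows", res$n_skipped)
      }
  }
  xcorr <- do.call(rbind, xc)
  rownames(xcorr) <- NULL
  thresholds <- do.call(rbind, th)
  rownames(thresholds) <- NULL
  rates <- do.call(rbind, ra)
  rownames(rates) <- NULL
  contrasts <- list()
  if (length(unique(xcorr$length)) == 2L) {
    for (pn in unique(xcorr$pairing))
      contrasts[[paste0("length_effect_lag_", pn)]] <-
        marginalEffect(xcorr[xcorr$pairing == pn, ], "lag_ms", "length",
                       levels = c("short", "long"))
  }
  if (length(unique(xcorr$mode)) == 2L) {
    contrasts[["mode_effect_coef"]] <-
      marginalEffect(xcorr, "coef", "mode",
                     levels = c("sustained", "sinusoidal"))
  }
  if (length(unique(rates$level)) == 2L) {
    contrasts[["torque_effect_rate"]] <-
      marginalEffect(rates, "mean_rate_hz", "level",
                     levels = as.character(sort(unique(rates$level))))
  }
  agg_thr <- stats::aggregate(
    thresholds[, c("rt_pct", "drt_pct", "rt_delta_mm", "drt_delta_mm")],
    by = list(subject = thresholds$subject), FUN = mean, na.rm = TRUE)
  if (nrow(agg_thr) >= 2L) {
    contrasts[["recruit_vs_derecruit_pct"]] <-
      pairedContrast(agg_thr$rt_pct, agg_thr$drt_pct)
    contrasts[["recruit_vs_derecruit_delta_mm"]] <-
      pairedContrast(agg_thr$rt_delta_mm, agg_thr$drt_delta_mm)
  }
  structure(list(xcorr = xcorr, thresholds = thresholds, rates = rates,
                 contrasts = contrasts, log = lg, config = config),
            class = "PipelineReport")
}
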