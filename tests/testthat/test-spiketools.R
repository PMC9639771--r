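test_that("discharge cleaning collapses duplicates and flags long gaps", {
  # 1000 and 1010 at 2048 Hz are ~4.9 ms apart: below the 20 ms refractory
  cl <- cleanDischarges(c(1000L, 1010L, 3000L), fs = FS)
  expect_identical(cl$discharges, c(1000L, 3000L))
  expect_identical(cl$n_duplicates_removed, 1L)
  # a clean regular 10 Hz train is untouched
  reg <- seq(205L, 20000L, by = 205L)
  cl2 <- cleanDischarges(reg, fs = FS)
  expect_identical(cl2$discharges, reg)
  expect_identical(cl2$n_duplicates_removed, 0L)
  expect_length(cl2$gap_after, 0L)
  # one 300 ms interval: unchanged but flagged
  gap <- as.integer(c(1000L, 1000L + round(0.3 * FS),
                      1000L + round(0.3 * FS) + 205L))
  cl3 <- cleanDischarges(gap, fs = FS)
  expect_identical(cl3$discharges, gap)
  expect_identical(cl3$gap_after, 1L)
  # idempotent and never increasing the count
  cl4 <- cleanDischarges(cl$discharges, fs = FS)
  expect_identical(cl4$discharges, cl$discharges)
  expect_lte(length(cl$discharges), 3L)
})

test_that("cumulative spike train sums and conserves discharges", {
  empty <- spikeTrainSet(list(), FS, 100L)
  expect_identical(cstCounts(cumulativeSpikeTrain(empty)), integer(100))
  two <- spikeTrainSet(list(c(10L, 50L), 50L), FS, 100L)
  cst <- cumulativeSpikeTrain(two)
  expect_identical(cstCounts(cst)[50], 2L)
  expect_identical(sum(cstCounts(cst)), 3L)
  # invariant under unit reordering
  swapped <- spikeTrainSet(list(50L, c(10L, 50L)), FS, 100L)
  expect_identical(cstCounts(cumulativeSpikeTrain(swapped)), cstCounts(cst))
  expect_error(cumulativeSpikeTrain(two, n_samples = 20), "beyond")
  # simulated total count within Poisson-like bounds of n * rate * T
  st <- sampleSpikes(buildPool(poolConfig(n_units = 5, threshold_max = 12)),
                     rep(20, FS * 30), FS, seed = 8)
  total <- sum(cstCounts(cumulativeSpikeTrain(st)))
  expected <- 5 * 15 * 30
  expect_lt(abs(total - expected), 3 * sqrt(expected) + 0.15 * expected)
})

test_that("discharge-rate statistics match renewal arithmetic", {
  # regular 100 ms intervals -> 10 Hz
  reg <- spikeTrainSet(list(seq(205L, 20295L, by = 205L)), FS, 20500L)
  rs <- dischargeRateStats(reg, 1)
  expect_equal(rs$mean_rate_hz, FS / 205, tolerance = 1e-9)
  # smoothed trace integrates back to the spike count
  expect_equal(sum(rs$rate_trace_hz) / FS, rs$n_discharges, tolerance = 0.01)
  # single discharge: rate 0 by the (n-1)/span rule, unit integral
  single <- spikeTrainSet(list(5000L), FS, 20000L)
  rs1 <- dischargeRateStats(single, 1)
  expect_identical(rs1$mean_rate_hz, 0)
  expect_equal(sum(rs1$rate_trace_hz) / FS, 1, tolerance = 1e-6)
  expect_error(dischargeRateStats(reg, 1, window = c(100L, 50L)), "window")
})

test_that("simulated plateau discharge rates sit near the calibrated 15 Hz", {
  tr <- simulateTrial(quickProtocol(plateau_s = 15), seed = 3, emg = FALSE)
  seg <- segmentContraction(tr@torque_pct, 20, FS)
  rates <- vapply(1:7, function(i)
    dischargeRateStats(tr@spikes, i, window = seg@plateau)$mean_rate_hz,
    numeric(1))
  expect_true(all(abs(mean(rates) - 15) < 3))
})

test_that("SIL separates clean sources from noise and gates at 0.86", {
  set.seed(10)
  n <- FS * 10
  pk <- seq(500, n - 500, by = 140)
  src <- rnorm(n, sd = 0.05)
  src[pk] <- 1 + rnorm(length(pk), sd = 0.05)
  res <- computeSil(src, pk)
  expect_gte(res@sil, 0.95)
  expect_true(res@accepted)
  # pure noise with arbitrary claimed peaks scores low and is rejected
  noise <- rnorm(n, sd = 0.05)
  res0 <- computeSil(noise, pk)
  expect_lt(res0@sil, 0.5)
  expect_false(res0@accepted)
  # acceptance boundary is a closed threshold
  expect_true(silResult(0.86)@accepted)
  expect_false(silResult(0.859)@accepted)
  expect_error(computeSil(src, pk[1]), "2 peaks")
  # degenerate identical amplitudes
  flat <- rep(1, 1000)
  expect_identical(computeSil(flat, c(10L, 20L))@sil, 0)
})

test_that("SIL never improves as source noise grows", {
  sigmas <- c(0.02, 0.1, 0.25, 0.5, 0.9)
  med <- vapply(sigmas, function(s) {
    vals <- vapply(1:20, function(sd_) {
      set.seed(sd_)
      n <- FS * 4
      pk <- seq(300, n - 300, by = 140)
      src <- rnorm(n, sd = s)
      src[pk] <- 1 + rnorm(length(pk), sd = s)
      computeSil(src, pk)@sil
    }, numeric(1))
    median(vals)
  }, numeric(1))
  expect_true(all(diff(med) <= 1e-9))
})

test_that("spike-triggered averaging recovers the generating template", {
  tpl <- muapTemplateLibrary(1, fs = FS, seed = 12)
  d <- seq(500L, 9500L, by = 300L)
  st <- spikeTrainSet(list(d), FS, 10000L)
  emg <- synthesizeEmg(st, tpl, noise_sd = 0)
  m <- staMuap(emg, st, unit = 1, window_ms = c(5, 5))
  half <- round(0.005 * FS)
  ctr <- ncol(tpl[[1]]) %/% 2L + 1L
  span <- (ctr - half):(ctr + half)
  expect_lt(max(abs(m@waveforms - tpl[[1]][, span])), 1e-9)
  expect_identical(m@n_averaged, length(d))
  # a discharge too close to the start is skipped
  st2 <- spikeTrainSet(list(c(5L, d)), FS, 10000L)
  emg2 <- synthesizeEmg(st2, tpl, noise_sd = 0)
  m2 <- staMuap(emg2, st2, unit = 1, window_ms = c(25, 25))
  expect_identical(m2@n_averaged, length(d))
  # residual noise shrinks like sigma / sqrt(n)
  emg3 <- synthesizeEmg(st, tpl, noise_sd = 0.2, seed = 2)
  m3 <- staMuap(emg3, st, unit = 1, window_ms = c(5, 5))
  resid <- m3@waveforms - tpl[[1]][, span]
  expect_lt(sd(resid), 2 * 0.2 / sqrt(length(d)))
  expect_error(staMuap(emg, spikeTrainSet(list(2L), FS, 10000L), unit = 1),
               "window")
})

test_that("MUAP matching is shift-invariant, symmetric and selective", {
  tpl <- muapTemplateLibrary(2, fs = FS, seed = 20)
  mk <- function(w) new("MuapTemplate", waveforms = w, fs = FS, pre_ms = 7.5,
                        post_ms = 7.5, n_averaged = 1L)
  a <- mk(tpl[[1]])
  expect_equal(matchMuaps(a, a)$coefficient, 1, tolerance = 1e-12)
  expect_true(matchMuaps(a, a)$matched)
  # global shift by 8 samples (~3.9 ms), within the 10 ms search
  shifted <- mk(cbind(matrix(0, 32, 8), tpl[[1]][, 1:(ncol(tpl[[1]]) - 8)]))
  ms <- matchMuaps(a, shifted)
  expect_gt(ms$coefficient, 0.999)
  expect_true(ms$matched)
  b <- mk(tpl[[2]])
  expect_equal(matchMuaps(a, b)$coefficient, matchMuaps(b, a)$coefficient,
               tolerance = 1e-12)
  # independently seeded templates almost never match: ~95% of pairs stay
  # below 0.5 (binomial slack for the Monte-Carlo draw) and none reaches
  # the 0.80 match gate
  set.seed(99)
  lib_seeds <- sample.int(1e6, 100)
  pairs <- vapply(lib_seeds, function(sd_) {
    tt <- muapTemplateLibrary(2, fs = FS, seed = sd_)
    matchMuaps(mk(tt[[1]]), mk(tt[[2]]))$coefficient
  }, numeric(1))
  expect_gte(mean(pairs < 0.5), 0.93)
  expect_lte(mean(pairs > 0.8), 0.02)
  bad <- mk(tpl[[1]][1:16, ])
  expect_error(matchMuaps(a, bad), "channel")
})
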