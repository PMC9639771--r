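test_that("pool construction places recruitment thresholds on the ladder", {
  pool <- buildPool(poolConfig())
  expect_length(pool$rte, 7L)
  expect_true(all(diff(pool$rte) > 0))
  expect_equal(max(pool$rte) / min(pool$rte), 30, tolerance = 1e-9)
  expect_equal(max(pool$rte), 15, tolerance = 1e-9)
  # rate law: min_rate exactly at threshold, clipped at peak, silent below
  expect_equal(rateAt(pool, pool$rte[3], 3), 8)
  expect_equal(rateAt(pool, pool$rte[3] - 1e-9, 3), 0)
  expect_equal(rateAt(pool, 1e6, 3), 35)
  expect_error(poolConfig(n_units = 0), "n_units")
})

test_that("excitation drive realizes the protocol arithmetic", {
  prot <- protocolConfig(target_level = 20, plateau_s = 30, rest_s = 2,
                         common_noise_pct = 0)
  e <- generateExcitation(prot)
  seg <- attr(e, "segments")
  expect_equal(diff(seg$ramp_up) + 1L, round(FS * 2))       # 20 / 10 = 2 s
  expect_equal(diff(seg$plateau) + 1L, round(FS * 30))
  expect_equal(length(e), round(FS * (2 + 2 + 30 + 2 + 2)))
  e40 <- generateExcitation(protocolConfig(target_level = 40, rest_s = 0,
                                           common_noise_pct = 0))
  expect_equal(length(e40), round(FS * (4 + 30 + 4)))
  es <- generateExcitation(protocolConfig(mode = "sinusoidal",
                                          common_noise_pct = 0))
  segs <- attr(es, "segments")
  plat <- es[segs$plateau[1]:segs$plateau[2]]
  expect_equal(range(plat), c(17.5, 22.5), tolerance = 1e-6)
  expect_error(protocolConfig(plateau_s = 0), "plateau")
})

test_that("renewal sampling respects thresholds, regularity and the seed", {
  pool <- buildPool(poolConfig())
  st0 <- sampleSpikes(pool, rep(0, FS), FS, seed = 1)
  expect_true(all(vapply(seq_len(7), function(i)
    length(discharges(st0, i)) == 0L, logical(1))))
  # deterministic renewal: constant supra-threshold drive, 10 Hz, cv = 0
  p1 <- buildPool(poolConfig(n_units = 1, isi_cv = 0, threshold_max = 10,
                             min_rate = 10, rate_gain = 0))
  st1 <- sampleSpikes(p1, rep(20, FS * 3), FS, seed = 1)
  isis_ms <- diff(discharges(st1, 1)) / FS * 1000
  expect_true(all(abs(isis_ms - 100) <= 1000 / FS))
  # empirical ISI CV close to the configured 0.15
  st <- sampleSpikes(buildPool(poolConfig()), rep(20, FS * 30), FS, seed = 5)
  isis <- diff(discharges(st, 1))
  expect_gt(length(isis), 200)
  cv <- sd(isis) / mean(isis)
  expect_gt(cv, 0.12)
  expect_lt(cv, 0.18)
  # silent below threshold: highest-threshold unit at rte 15, drive 10
  sth <- sampleSpikes(buildPool(poolConfig()), rep(10, FS * 5), FS, seed = 2)
  expect_length(discharges(sth, 7), 0L)
  # reproducibility
  a <- sampleSpikes(pool, rep(20, FS * 5), FS, seed = 42)
  b <- sampleSpikes(pool, rep(20, FS * 5), FS, seed = 42)
  expect_identical(a@units, b@units)
})

test_that("pooled plateau rate calibration lands near 15 Hz at 20 %MVC", {
  rates <- vapply(1:10, function(sd_) {
    st <- sampleSpikes(buildPool(poolConfig()), rep(20, FS * 30), FS,
                       seed = sd_)
    mean(vapply(1:7, function(i)
      dischargeRateStats(st, i)$mean_rate_hz, numeric(1)))
  }, numeric(1))
  expect_gt(mean(rates), 14)
  expect_lt(mean(rates), 16)
})

test_that("pure-shift mechanics carry an impulse by exactly the delays", {
  prot <- protocolConfig(plateau_s = 1, rest_s = 0, common_noise_pct = 0)
  n <- round(FS * 2)
  drive <- numeric(n)
  drive[FS %/% 2] <- 1
  mech <- mechanicsConfig(delay_drive_to_fascicle = 75,
                          delay_fascicle_to_torque = 75)
  mx <- synthesizeMechanics(drive, mech, prot, noise = FALSE)
  k_f <- which.min(mx$length_mm_fs)  # shortening peak
  k_t <- which.max(mx$torque_pct)
  expect_equal((k_f - FS %/% 2) / FS * 1000, 75, tolerance = 0.5)
  expect_equal((k_t - FS %/% 2) / FS * 1000, 150, tolerance = 0.5)
  expect_error(
    synthesizeMechanics(drive[1:100],
                        mechanicsConfig(delay_drive_to_fascicle = 1000),
                        prot, noise = FALSE),
    "shift")
})

test_that("calibration recovery: 20 %MVC plateau shortening within 5%", {
  shorten <- vapply(1:10, function(sd_) {
    tr <- simulateTrial(quickProtocol(plateau_s = 10), seed = sd_,
                        emg = FALSE)
    fr <- tr@frame_rate
    plat_frames <- round((2 + 2 + 1) * fr):round((2 + 2 + 9) * fr)
    mean(deltaLength(tr@truth_fascicle)[plat_frames])
  }, numeric(1))
  expect_lt(abs(mean(shorten) - 7.5) / 7.5, 0.05)
})

test_that("trial generation is deterministic under a fixed master seed", {
  prot <- quickProtocol(plateau_s = 5)
  a <- simulateTrial(prot, seed = 31, emg = FALSE)
  b <- simulateTrial(prot, seed = 31, emg = FALSE)
  expect_identical(a@torque_pct, b@torque_pct)
  expect_identical(a@spikes@units, b@spikes@units)
  expect_identical(fascicleLength(a@truth_fascicle),
                   fascicleLength(b@truth_fascicle))
  # CST conservation against per-unit counts
  cst <- cumulativeSpikeTrain(a@spikes)
  expect_identical(sum(cstCounts(cst)),
                   sum(vapply(a@spikes@units, length, integer(1))))
})

test_that("EMG synthesis is a linear superposition of placed templates", {
  tpl <- muapTemplateLibrary(2, fs = FS, seed = 3)
  n <- 2048L
  none <- spikeTrainSet(list(integer(0), integer(0)), FS, n)
  emg0 <- synthesizeEmg(none, tpl, noise_sd = 0.05, seed = 1)
  expect_equal(mean(apply(emg0, 2, sd)), 0.05, tolerance = 0.01)
  one <- spikeTrainSet(list(600L, integer(0)), FS, n)
  emg1 <- synthesizeEmg(one, tpl, noise_sd = 0)
  m <- ncol(tpl[[1]])
  half <- m %/% 2L
  seg <- emg1[(600 - half):(600 - half + m - 1L), ]
  expect_equal(max(abs(t(seg) - tpl[[1]])), 0, tolerance = 1e-12)
  expect_equal(max(abs(emg1[-((600 - half):(600 - half + m - 1L)), ])), 0)
  both <- spikeTrainSet(list(600L, 605L), FS, n)
  emg2 <- synthesizeEmg(both, tpl, noise_sd = 0)
  sep <- synthesizeEmg(spikeTrainSet(list(600L, integer(0)), FS, n), tpl,
                       noise_sd = 0) +
    synthesizeEmg(spikeTrainSet(list(integer(0), 605L), FS, n), tpl,
                  noise_sd = 0)
  expect_equal(emg2, sep, tolerance = 1e-12)
  expect_error(synthesizeEmg(spikeTrainSet(list(5L), FS, 10L), tpl),
               "longer")
})

test_that("ultrasound renderer encodes the commanded geometry exactly", {
  cfg <- imagingConfig()
  tr_const <- fascicleTrace(rep(60.2, 5), rep(15.2, 5), frame_rate = 80)
  r <- renderUltrasound(tr_const, cfg, fs = FS, seed = 6)
  expect_length(r$frames, 5L)
  for (k in 2:5) expect_identical(r$frames[[k]], r$frames[[1]])
  # frame/trigger bookkeeping: 1 s at 80 fps
  tr1s <- fascicleTrace(seq(60.2, 55, length.out = 80), rep(15.2, 80), 80)
  r1 <- renderUltrasound(tr1s, cfg, fs = FS, seed = 6)
  expect_length(r1$frames, 80L)
  expect_length(r1$edges, 80L)
  expect_equal(sum(diff(c(0, r1$trigger)) > 0.5), 80L)
  # drawn endpoint separation reproduces the commanded length
  for (k in c(1L, 40L, 80L)) {
    d_px <- sqrt(sum((r1$endpoints[[k]][, 1] - r1$endpoints[[k]][, 2])^2))
    expect_equal(d_px * cfg$mm_per_px, fascicleLength(tr1s)[k],
                 tolerance = 0.1 * cfg$mm_per_px)
  }
  expect_error(
    renderUltrasound(fascicleTrace(rep(200, 3), rep(15, 3), 80), cfg),
    "outside")
})
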