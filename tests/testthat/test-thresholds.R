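test_that("an ideal trapezoid segments exactly with an unsmoothed slope", {
  prot <- protocolConfig(plateau_s = 30, common_noise_pct = 0)
  e <- generateExcitation(prot)
  seg <- segmentContraction(e, 20, FS, opts = list(smooth_ms = 0))
  truth <- attr(e, "segments")
  expect_lte(abs(seg@plateau[1] - truth$plateau[1]), 2)
  expect_lte(abs(seg@plateau[2] - truth$plateau[2]), 2)
  expect_equal(seg@ramp_up[1], truth$ramp_up[1], tolerance = 2)
  expect_error(segmentContraction(rep(0, FS * 10), 20, FS), "contraction")
})

test_that("default segmentation finds the ~30 s plateau of noisy trials", {
  tr <- simulateTrial(protocolConfig(), seed = 21, emg = FALSE)
  seg <- segmentContraction(tr@torque_pct, 20, FS)
  expect_gt(diff(seg@plateau) / FS, 28.5)
  expect_lt(diff(seg@plateau) / FS, 31.5)
})

test_that("the sinusoidal plateau stays inside the ±25% band in one piece", {
  prot <- protocolConfig(mode = "sinusoidal", plateau_s = 20,
                         common_noise_pct = 0)
  e <- generateExcitation(prot)
  seg <- segmentContraction(e, 20, FS)
  truth <- attr(e, "segments")
  expect_lte(seg@plateau[1], truth$plateau[1] + FS)
  expect_gte(seg@plateau[2], truth$plateau[2] - FS)
})

test_that("thresholds read the trace at the discharge instants", {
  # one unit recruited at 10 %MVC of drive, delay-free noiseless mechanics
  pool_cfg <- poolConfig(n_units = 1, threshold_max = 10)
  mech <- mechanicsConfig(delay_drive_to_fascicle = 0,
                          delay_fascicle_to_torque = 0)
  prot <- quickProtocol(plateau_s = 6, common_noise_pct = 0)
  tr <- simulateTrial(prot, pool_cfg, mech, seed = 4, emg = FALSE,
                      noise = FALSE)
  seg <- segmentContraction(tr@torque_pct, 20, FS,
                            opts = list(smooth_ms = 0))
  tg <- tr@trigger
  edges <- which(tg >= 0.5 & !c(TRUE, tg[-length(tg)] >= 0.5))
  edges <- c(1L, edges)
  rs <- resampleToEmg(tr@truth_fascicle, edges)
  th <- thresholdRecords(tr@spikes, tr@torque_pct, rs$delta_mm, seg)
  expect_equal(th$rt_pct, 10, tolerance = 0.5)
  expect_false(th$recruited_in_plateau)
  # excluded units are reported, not invented
  st2 <- spikeTrainSet(list(integer(0), c(18000L, 22000L)), FS,
                       tr@spikes@n_samples)
  expect_message(
    th2 <- thresholdRecords(st2, tr@torque_pct, rs$delta_mm, seg),
    "no discharges")
  expect_identical(nrow(th2), 1L)
})

test_that("with all delays zero both coordinates are symmetric to renewal
          resolution", {
  d <- thresholdDiffs(0, 0, seeds = 1:6, noise = FALSE)
  # the last discharge precedes the falling crossing by up to one interval
  # (~125 ms at the 8 Hz de-recruitment rate = 1.25 %MVC of ramp travel)
  expect_lt(abs(d["pct"]), 1.3)
  expect_lt(abs(d["mm"]), 0.5)
})

test_that("a fascicle-torque delay widens the torque-coordinate asymmetry
          while the fascicle coordinate stays put", {
  d75 <- thresholdDiffs(0, 75, seeds = 1:6)
  d150 <- thresholdDiffs(0, 150, seeds = 1:6)
  d0 <- thresholdDiffs(0, 0, seeds = 1:6)
  # asymmetry magnitude grows monotonically with the injected delay; under
  # the causal transmission model torque lags drive, so the torque read at
  # de-recruitment exceeds that at recruitment (rt - drt becomes more
  # negative as the delay grows)
  expect_gt(abs(d75["pct"]), abs(d0["pct"]))
  expect_gt(abs(d150["pct"]), abs(d75["pct"]))
  expect_true(d150["pct"] < d75["pct"])
  # fascicle-shortening thresholds are insensitive to that delay
  expect_lt(abs(d75["mm"]), 0.5)
  expect_lt(abs(d150["mm"]), 0.5)
})

test_that("threshold records are invariant to unit relabeling", {
  tr <- simulateTrial(quickProtocol(plateau_s = 6), seed = 13, emg = FALSE)
  seg <- segmentContraction(tr@torque_pct, 20, FS)
  tg <- tr@trigger
  edges <- which(tg >= 0.5 & !c(TRUE, tg[-length(tg)] >= 0.5))
  edges <- c(1L, edges)
  rs <- resampleToEmg(tr@truth_fascicle, edges)
  th <- suppressMessages(
    thresholdRecords(tr@spikes, tr@torque_pct, rs$delta_mm, seg))
  perm <- rev(seq_along(tr@spikes@units))
  st_perm <- spikeTrainSet(tr@spikes@units[perm], FS, tr@spikes@n_samples,
                           unit_ids = tr@spikes@unit_ids[perm])
  th_perm <- suppressMessages(
    thresholdRecords(st_perm, tr@torque_pct, rs$delta_mm, seg))
  ord <- order(th$unit_id)
  ord_p <- order(th_perm$unit_id)
  expect_equal(th$rt_pct[ord], th_perm$rt_pct[ord_p])
  expect_equal(th$drt_delta_mm[ord], th_perm$drt_delta_mm[ord_p])
})
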