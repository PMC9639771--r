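test_that("conditioning kills DC, passes the band and stops 5 Hz", {
  x <- rep(1, FS * 12)
  expect_lt(max(abs(signalSamples(conditionSignal(x, FS)))), 1e-6)
  t <- seq(0, 30, by = 1 / FS)
  mid <- (FS * 5):(FS * 25)
  y12 <- signalSamples(conditionSignal(sin(2 * pi * 1.2 * t), FS))
  expect_gt(max(abs(y12[mid])), 0.7)
  expect_lte(max(abs(y12[mid])), 1.0)
  # zero lag between a passband tone and its conditioned version; the
  # search must stay below the tone period (833 ms), where the
  # correlation of a periodic signal is ambiguous by construction
  w <- windowedXcorr(sin(2 * pi * 1.2 * t), y12, fs = FS,
                     lag_max_ms = 400)
  expect_lte(max(abs(w@lag_ms)), 2)
  # analytic cascade response at 5 Hz: two zero-phase 4th-order sections
  amp5 <- 1 / (1 + (5 / 2)^8) * 1 / (1 + (0.75 / 5)^8)
  y5 <- signalSamples(conditionSignal(sin(2 * pi * 5 * t), FS))
  expect_lt(max(abs(y5[mid])), 0.1)
  expect_lt(abs(max(abs(y5[mid])) - amp5), 0.25 * amp5)
  expect_error(conditionSignal(rnorm(100), fs = 3), "twice")
  expect_error(conditionSignal(rnorm(100), FS), "span")
  # post-highpass mean is small relative to amplitude (finite-length
  # residual of the 0.75 Hz highpass)
  zm <- signalSamples(conditionSignal(bandSignal(20, seed = 2) + 5, FS))
  expect_lt(abs(mean(zm)), 1e-3 * max(abs(zm)))
})

test_that("windowed cross-correlation nails identity, shifts and counts", {
  x <- bandSignal(30, seed = 7)
  w <- windowedXcorr(x, x, fs = FS)
  expect_equal(nWindows(w), 11L)
  expect_true(all(w@coef == 1))
  expect_true(all(w@lag_ms == 0))
  # truncated (circular-free) 100 ms shift
  k <- round(0.1 * FS)
  y <- c(rep(0, k), x[seq_len(length(x) - k)])
  w2 <- windowedXcorr(x, y, fs = FS)
  expect_equal(meanLag(w2), 100, tolerance = 0.5)
  expect_true(all(abs(w2@coef) <= 1 + 1e-12))
  # lag antisymmetry under argument swap
  w3 <- windowedXcorr(y, x, fs = FS)
  expect_identical(w2@lag_ms, -w3@lag_ms)
  # zero-variance windows are skipped, not fabricated
  z <- c(rep(0, FS * 6), bandSignal(9, seed = 3))
  wz <- windowedXcorr(z, z, fs = FS, win_s = 5)
  expect_gt(wz@n_skipped, 0L)
})

test_that("fast per-lag Pearson equals the brute-force oracle", {
  K <- round(0.25 * FS)
  for (sd_ in 1:20) {
    set.seed(sd_)
    n <- 3 * FS
    a <- rnorm(n)
    b <- rnorm(n)
    w <- windowedXcorr(a, b, fs = FS, win_s = 3, lag_max_ms = 250,
                       drop_boundary = FALSE)
    o <- oracleXcorr(a, b, K)
    expect_equal(w@coef, o$peak, tolerance = 1e-12)
    expect_identical(as.integer(round(w@lag_ms * FS / 1000)),
                     as.integer(o$lag))
  }
})

test_that("conditioning introduces no delay on random in-band signals", {
  lags <- vapply(1:20, function(sd_) {
    x <- bandSignal(12, seed = 100 + sd_)
    cx <- conditionSignal(x, FS)
    w <- windowedXcorr(x, signalSamples(cx), fs = FS, win_s = 12)
    meanLag(w)
  }, numeric(1))
  # each within the estimator's sample-scale resolution, no systematic
  # delay across signals
  expect_lte(max(abs(lags)), 5)
  expect_lte(abs(mean(lags)), 1)
})

test_that("delay matrix orients and adds up on noiseless shifts", {
  x <- bandSignal(30, seed = 5)
  kf <- round(0.075 * FS)
  kt <- round(0.150 * FS)
  fasc <- c(rep(0, kf), x[seq_len(length(x) - kf)])
  torq <- c(rep(0, kt), x[seq_len(length(x) - kt)])
  dm <- delayMatrix(x, torq, fasc, fs = FS, lag_max_ms = 500)
  expect_equal(meanLag(dm$cst_fascicle), 75, tolerance = 1)
  expect_equal(meanLag(dm$cst_torque), 150, tolerance = 1)
  expect_equal(meanLag(dm$fascicle_torque), 75, tolerance = 1)
  add_err <- meanLag(dm$cst_torque) - meanLag(dm$cst_fascicle) -
    meanLag(dm$fascicle_torque)
  expect_lt(abs(add_err), 10)
  expect_error(delayMatrix(x, torq[1:100], fasc, fs = FS), "length")
})

test_that("CST-torque coupling weakens monotonically with torque noise", {
  sig <- c(0.3, 1.5, 4)
  med <- vapply(sig, function(s) {
    median(vapply(1:5, function(sd_) {
      mech <- mechanicsConfig(noise_torque_pct = s)
      tr <- simulateTrial(quickProtocol(plateau_s = 12), mech = mech,
                          seed = sd_, emg = FALSE)
      an <- analyzeTrialFixture(tr, 20)
      meanCoef(an$dm$cst_torque)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) < 0))
})
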