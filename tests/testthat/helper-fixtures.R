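# shared fixtures: everything is generated in code at test time

FS <- 2048

# a short protocol for fast end-to-end runs
quickProtocol <- function(plateau_s = 10, ...) {
  protocolConfig(plateau_s = plateau_s, ...)
}

# random signal with power concentrated in the analysis band: a mixture of
# sinusoids drawn from 0.8-1.9 Hz plus a little wideband noise
bandSignal <- function(dur_s, fs = FS, seed = 1, n_comp = 8) {
  set.seed(seed)
  t <- seq(0, dur_s, by = 1 / fs)[- 1L]
  f <- runif(n_comp, 0.8, 1.9)
  a <- runif(n_comp, 0.5, 1)
  ph <- runif(n_comp, 0, 2 * pi)
  x <- rowSums(sapply(seq_len(n_comp), function(i)
    a[i] * sin(2 * pi * f[i] * t + ph[i])))
  x + 0.02 * rnorm(length(t))
}

# brute-force per-lag Pearson oracle: direct cor() at every lag, no FFT
oracleXcorr <- function(a, b, K) {
  lags <- (-K):K
  r <- vapply(lags, function(k) {
    m <- length(a)
    if (k >= 0) stats::cor(a[seq_len(m - k)], b[(1 + k):m])
    else stats::cor(a[(1 - k):m], b[seq_len(m + k)])
  }, numeric(1))
  pk <- which(r == max(r, na.rm = TRUE))
  pk <- pk[which.min(abs(lags[pk]))]
  list(peak = r[pk], lag = lags[pk])
}

# standard per-trial analysis used by several tests: segmentation,
# conditioning over the plateau, delay matrix, thresholds
analyzeTrialFixture <- function(trial, target, lag_max_ms = 350,
                                seg_opts = list()) {
  fs <- trial@fs
  seg <- segmentContraction(trial@torque_pct, target, fs, opts = seg_opts)
  tg <- trial@trigger
  edges <- which(tg >= 0.5 & !c(TRUE, tg[-length(tg)] >= 0.5))
  if (tg[1L] >= 0.5) edges <- c(1L, edges)
  rs <- resampleToEmg(trial@truth_fascicle, edges)
  pl <- seg@plateau[1L]:seg@plateau[2L]
  cst <- cumulativeSpikeTrain(cleanDischarges(trial@spikes))
  dm <- delayMatrix(
    conditionSignal(as.numeric(cstCounts(cst))[pl], fs, label = "CST"),
    conditionSignal(trial@torque_pct[pl], fs, label = "torque"),
    conditionSignal(rs$delta_mm[pl], fs, label = "fascicle"),
    lag_max_ms = lag_max_ms)
  list(seg = seg, dm = dm, delta_mm = rs$delta_mm, cst = cst)
}

# mean recruitment / de-recruitment differences over simulated seeds
thresholdDiffs <- function(df_ms, dt_ms, seeds, noise = TRUE,
                           plateau_s = 10) {
  out <- t(vapply(seeds, function(sd_) {
    mech <- mechanicsConfig(delay_drive_to_fascicle = df_ms,
                            delay_fascicle_to_torque = dt_ms)
    prot <- quickProtocol(plateau_s = plateau_s)
    tr <- simulateTrial(prot, mech = mech, seed = sd_, emg = FALSE,
                        noise = noise)
    seg <- segmentContraction(tr@torque_pct, 20, tr@fs,
                              opts = if (noise) list() else
                                list(smooth_ms = 0))
    tg <- tr@trigger
    edges <- which(tg >= 0.5 & !c(TRUE, tg[-length(tg)] >= 0.5))
    if (tg[1L] >= 0.5) edges <- c(1L, edges)
    rs <- resampleToEmg(tr@truth_fascicle, edges)
    th <- suppressMessages(
      thresholdRecords(tr@spikes, tr@torque_pct, rs$delta_mm, seg))
    c(pct = mean(th$rt_pct - th$drt_pct),
      mm = mean(th$rt_delta_mm - th$drt_delta_mm, na.rm = TRUE))
  }, numeric(2)))
  colMeans(out)
}

# initial tracker geometry for a rendered trial
renderInit <- function(truth, cfg = imagingConfig()) {
  ep <- neuromech:::.fascicleEndpoints(fascicleLength(truth)[1L],
                                       pennation(truth)[1L], cfg)
  fascicleGeometry(ep, c(1, cfg$apo_y_px), c(1, 0), cfg$mm_per_px)
}

# smooth synthetic speckle image for flow tests
speckleImage <- function(h = 140, w = 200, seed = 4, sigma = 1.5) {
  set.seed(seed)
  EBImage::gblur(matrix(rnorm(h * w), h, w), sigma)
}

# warp an image by an affine (x' = A (x - c) + c + t), bilinear
warpImage <- function(img, A, t, centre = c(0, 0)) {
  h <- nrow(img)
  w <- ncol(img)
  gx <- matrix(rep(seq_len(w), each = h), h)
  gy <- matrix(rep(seq_len(h), times = w), h)
  Ai <- solve(A)
  xr <- gx - centre[1] - t[1]
  yr <- gy - centre[2] - t[2]
  sx <- Ai[1, 1] * xr + Ai[1, 2] * yr + centre[1]
  sy <- Ai[2, 1] * xr + Ai[2, 2] * yr + centre[2]
  matrix(neuromech:::.bilinearSample(img, as.numeric(sx), as.numeric(sy)),
         h, w)
}
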