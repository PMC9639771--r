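test_that("trigger alignment maps pulses to frames and finds faults", {
  edges_true <- as.integer(round((0:799) * FS / 80) + 1)
  tg <- numeric(edges_true[800] + 13)
  for (e in edges_true) tg[e:(e + 12)] <- 1
  tm <- alignTrigger(tg, FS, 80)
  expect_length(triggerEdges(tm), 800L)
  expect_identical(triggerEdges(tm), edges_true)
  d <- diff(triggerEdges(tm))
  expect_true(all(d %in% c(25L, 26L)))
  expect_equal(mean(d), FS / 80, tolerance = 0.01)
  expect_length(tm@gaps, 0L)
  # frame -> sample -> frame round trip
  k <- c(1L, 250L, 800L)
  expect_identical(vapply(triggerEdges(tm)[k], function(s)
    which(triggerEdges(tm) == s), integer(1)), k)
  # a deleted pulse is reported exactly once
  tg2 <- tg
  tg2[edges_true[400]:(edges_true[400] + 12)] <- 0
  tm2 <- alignTrigger(tg2, FS, 80)
  expect_length(tm2@gaps, 1L)
  expect_length(triggerEdges(tm2), 799L)
  expect_error(alignTrigger(rep(0, 100), FS, 80), "edges")
})

test_that("paired contrasts handle degenerate and generic input", {
  x <- c(60.2, 52.7, 50.8)
  same <- pairedContrast(x, x)
  expect_identical(same@mean_diff, 0)
  expect_identical(same@ci95, c(0, 0))
  expect_identical(same@p, 1)
  a <- c(1, 2, 3, 4)
  b <- c(2, 2, 5, 3)
  f <- pairedContrast(a, b)
  g <- pairedContrast(b, a)
  expect_identical(f@mean_diff, -g@mean_diff)
  expect_equal(f@ci95, -rev(g@ci95))
  # agreement with the standard paired t machinery
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(f@p, tt$p.value)
  expect_equal(f@ci95, as.numeric(tt$conf.int), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(pairedContrast(1, 2), "2 pairs")
})

test_that("the 95% interval covers the true paired difference ~95% of the
          time", {
  set.seed(1234)
  hits <- vapply(1:1000, function(i) {
    x <- rnorm(10, mean = 1)
    y <- rnorm(10)
    cr <- pairedContrast(x, y)
    cr@ci95[1] <= 1 && 1 <= cr@ci95[2]
  }, logical(1))
  expect_gt(mean(hits), 0.93)
  expect_lt(mean(hits), 0.97)
})

test_that("marginal effects collapse balanced tables correctly", {
  tab <- expand.grid(subject = 1:6, length = c("short", "long"),
                     level = c("20", "40"))
  set.seed(2)
  tab$metric <- 5 + (tab$level == "40") * 2 + rnorm(nrow(tab), sd = 0.1)
  me <- marginalEffect(tab, "metric", "level", levels = c("40", "20"))
  expect_equal(me@mean_diff, 2, tolerance = 0.1)
  expect_identical(me@n, 6L)
  const <- tab
  const$metric <- 7
  me0 <- marginalEffect(const, "metric", "level")
  expect_identical(me0@mean_diff, 0)
  unb <- tab[-1, ]
  expect_error(marginalEffect(unb, "metric", "level"), "balanced")
})

test_that("published group-mean tables reproduce their printed contrasts", {
  arch <- referenceGroupMeans("architecture")
  rest <- arch[arch$condition == "rest", ]
  d_len <- marginalEffect(rest, "fascicle_length_mm", "length",
                          levels = c("short", "long"))
  expect_equal(d_len@mean_diff, -14.3, tolerance = 0.1)
  d_pen <- marginalEffect(rest, "pennation_deg", "length",
                          levels = c("short", "long"))
  expect_equal(d_pen@mean_diff, 3.2, tolerance = 0.1)
  m40 <- arch[arch$condition == "mvc40", ]
  expect_equal(marginalEffect(m40, "fascicle_length_mm", "length",
                              levels = c("short", "long"))@mean_diff,
               -11.1, tolerance = 0.1)
  contr <- arch[arch$condition != "rest", ]
  d_tor <- marginalEffect(contr, "fascicle_length_mm", "condition",
                          levels = c("mvc40", "mvc20"))
  expect_equal(d_tor@mean_diff, -3.2, tolerance = 0.1)
  xc <- referenceGroupMeans("xcorr")
  d_mode <- marginalEffect(xc, "coef", "mode",
                           levels = c("sustained", "sinusoidal"))
  expect_lt(abs(d_mode@mean_diff - (-0.11)), 0.01)
})

test_that("the cohort pipeline produces a complete, reproducible report", {
  cfg <- pipelineConfig(n_subjects = 2, plateau_s = 15,
                        modes = "sustained", seed = 5)
  rep1 <- runPipeline(cfg)
  expect_setequal(unique(rep1$xcorr$pairing),
                  c("CST-fascicle", "CST-torque", "fascicle-torque"))
  # 2 subjects x 2 lengths x 2 levels x 3 pairings
  expect_identical(nrow(rep1$xcorr), 2L * 2L * 2L * 3L)
  expect_true(all(c("rt_pct", "drt_pct", "rt_delta_mm", "drt_delta_mm")
                  %in% names(rep1$thresholds)))
  expect_true(all(rep1$xcorr$n_windows >= 3))
  expect_true(all(abs(rep1$xcorr$coef) <= 1))
  expect_s4_class(rep1$contrasts$recruit_vs_derecruit_pct, "ContrastResult")
  rep2 <- runPipeline(cfg)
  expect_identical(rep1$xcorr, rep2$xcorr)
  expect_identical(rep1$thresholds, rep2$thresholds)
  # report files round-trip through plain text
  dir <- tempfile("report")
  writePipelineReport(rep1, dir)
  back <- read.csv(file.path(dir, "xcorr.csv"))
  expect_equal(nrow(back), nrow(rep1$xcorr))
})

test_that("spike CSV export round-trips", {
  st <- spikeTrainSet(list(c(10L, 400L), 77L), FS, 1000L)
  f <- tempfile(fileext = ".csv")
  exportSpikesCsv(st, f)
  back <- readSpikesCsv(f)
  expect_identical(back@units, st@units)
  expect_identical(back@fs, st@fs)
})
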