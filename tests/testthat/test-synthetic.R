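# smaller grid keeps the generator tests fast
smallConfig <- function(...) {
  recordingConfig(layout = electrodeLayout(8L, 6L, 0.1), duration = 4,
                  stimTime = 1.2, ...)
}

test_that("identical seeds reproduce a recording bit for bit", {
  cfg <- smallConfig()
  a <- generateRecording(cfg, seed = 5)
  b <- generateRecording(cfg, seed = 5)
  expect_identical(lfp(a), lfp(b))
  expect_identical(spikeTimes(a), spikeTimes(b))
  c <- generateRecording(cfg, seed = 6)
  expect_false(identical(lfp(a), lfp(c)))
})

test_that("with noise off the LFP equals the closed-form windowed oscillation", {
  cfg <- smallConfig(singleModule = TRUE, noiseSd = 0)
  rec <- generateRecording(cfg, seed = 1)
  gt <- groundTruth(rec)
  tt <- lfpTimes(rec)
  mod <- cfg@modules[[1]]
  tau <- tt - gt$moduleOnsets[1]
  Tact <- cfg@nCycles / mod@frequency
  osc <- ifelse(tau >= 0 & tau <= Tact,
                sin(2 * pi * mod@frequency * tau) *
                  0.5 * (1 - cos(2 * pi * tau / Tact)), 0)
  # channel at the module centroid has footprint weight ~1; use actual weight
  lay <- recordingLayout(rec)
  cen <- colMeans(lay@positions)
  ch <- which.min(rowSums(sweep(lay@positions, 2, cen)^2))
  sig <- pmax(apply(lay@positions[mod@channels, , drop = FALSE], 2, sd),
              lay@pitch / 2) * mod@spreadFactor
  d <- lay@positions[ch, ] - colMeans(lay@positions[mod@channels, , drop = FALSE])
  w <- exp(-(d[1]^2 / sig[1]^2 + d[2]^2 / sig[2]^2) / 2)
  expect_equal(lfp(rec)[ch, ], w * mod@amplitude * osc, tolerance = 1e-12)
})

test_that("pre-stimulus LFP variance matches the configured noise power", {
  cfg <- smallConfig(noiseSd = 10)
  rec <- generateRecording(cfg, seed = 2)
  pre <- lfp(rec)[, seq_len(1000)]     # first second: pure noise
  expect_lt(abs(var(as.numeric(pre)) - 100) / 100, 0.1)
})

test_that("pooled spike phases lock to the preferred phase of the LFP", {
  cfg <- recordingConfig()     # full grid for enough spikes
  pooled <- c()
  for (s in 1:3) {
    rec <- generateRecording(cfg, seed = s)
    clean <- groundTruth(rec)$cleanLfp
    an <- analyticSignal(applyFilter(clean, sampleRate(rec), c(0, 2)))
    pl <- phaseLocking(spikeTimes(rec), an, lfpTimes(rec))
    pooled <- c(pooled, pl$phases)
  }
  expect_gt(length(pooled), 500)
  cm <- atan2(mean(sin(pooled)), mean(cos(pooled)))
  expect_lt(abs(cm - 0.53 * pi), 0.1 * pi)
  # modal histogram bin also within 0.1*pi of the target
  h <- hist(pooled, breaks = seq(-pi, pi, length.out = 37), plot = FALSE)
  expect_lt(abs(h$mids[which.max(h$counts)] - 0.53 * pi), 0.1 * pi)
})

test_that("trials are independent, reproducible, and average to the template", {
  cfg <- smallConfig(noiseSd = 20)
  tr <- generateTrials(cfg, 3, seed = 9)
  expect_false(identical(spikeTimes(tr[[1]]), spikeTimes(tr[[2]])))
  tr2 <- generateTrials(cfg, 3, seed = 9)
  expect_identical(lfp(tr[[3]]), lfp(tr2[[3]]))
  # trial-averaged LFP converges to the noiseless template ~ 1/sqrt(n)
  clean <- groundTruth(tr[[1]])$cleanLfp
  rmse <- function(n) {
    acc <- 0
    for (i in seq_len(n)) acc <- acc + lfp(generateRecording(cfg, seed = 100 + i))
    sqrt(mean((acc / n - clean)^2))
  }
  e <- c(rmse(4), rmse(16))
  expect_lt(e[2] / e[1], 0.7)          # expected 1/2, allow Monte-Carlo slack
})

test_that("the generative premise holds: graded unimodal LFP, modular spikes", {
  cfg <- recordingConfig(noiseSd = 0)
  rec <- generateRecording(cfg, seed = 3)
  lay <- recordingLayout(rec)
  an <- analyticSignal(applyFilter(lfp(rec), sampleRate(rec), c(0, 2)))
  cr <- detectPhaseCrossings(an, lfpTimes(rec), pi / 2, threshold = 2)
  cr <- cr[cr$time >= stimTimes(rec)[1], ]
  w <- selectWaves(clusterCrossings(cr, lay, 0.1), lay, "fraction")[[1]]
  plm <- computePLM(w, lay)
  # spatially graded: distinct latencies on (nearly) all channels
  expect_gt(length(unique(plm$latency)), 0.95 * nrow(plm))
  expect_gt(dipPValue(plm$latency, nBoot = 500, seed = 1)@pValue, 0.1)
  # spiking is modular: pooled first spikes are bimodal
  fs <- firstSpikesInWave(spikeTimes(rec), w)
  expect_lt(dipPValue(fs$onset, nBoot = 500, seed = 1)@pValue, 0.05)
  # and the two onset groups sit ~ interModuleDelay apart
  gt <- groundTruth(rec)
  g <- split(fs$onset, gt$moduleLabels[fs$channel])
  expect_lt(abs(diff(vapply(g, median, 0)) - gt$interModuleDelay), 0.1)
})

test_that("recordings survive the plain-text round trip", {
  cfg <- smallConfig()
  rec <- generateRecording(cfg, seed = 4)
  path <- file.path(tempdir(), "modwave-io-test")
  writeRecording(rec, path)
  rec2 <- readRecording(path)
  expect_equal(lfp(rec2), lfp(rec), tolerance = 1e-6)       # float32 precision
  expect_equal(spikeTimes(rec2), spikeTimes(rec), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sampleRate(rec2), sampleRate(rec))
  expect_equal(recordingLayout(rec2)@positions, recordingLayout(rec)@positions)
  # ground truth is optional on read
  file.remove(file.path(path, "ground_truth.json"))
  rec3 <- readRecording(path)
  expect_null(groundTruth(rec3))
  # a missing required dataset is a format error naming the file
  file.remove(file.path(path, "lfp.csv"))
  expect_error(readRecording(path), "lfp.csv")
  unlink(path, recursive = TRUE)
})
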