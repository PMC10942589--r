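test_that("zero-phase filtering preserves the passband and kills the stopband", {
  fs <- 1000
  t <- (0:2999) / fs
  # passband DC: unchanged away from the padding edges (the step against the
  # zero padding rings over ~1/corner-frequency at each end)
  dc <- rep(2.5, 10000)
  out <- applyFilter(dc, fs, c(0, 2))
  expect_lt(max(abs(out[3000:7000] - 2.5)), 0.01)
  mid <- 1000:2000
  # 1 Hz through a 2 Hz low pass: amplitude >= 0.9, peak shift < 1 sample
  s1 <- sin(2 * pi * 1 * t)
  y1 <- applyFilter(s1, fs, c(0, 2))
  expect_gt(max(y1[mid]), 0.9)
  cc <- vapply(-3:3, function(l) cor(s1[mid], y1[mid + l]), 0)
  expect_equal(which.max(cc), 4L)          # zero lag maximizes correlation
  # 30 Hz through the same low pass: residual < 1e-3.  A long trace keeps the
  # truncation-edge spectral leakage below the stopband floor being tested.
  tl <- (0:11999) / fs
  y30 <- applyFilter(sin(2 * pi * 30 * tl), fs, c(0, 2))
  expect_lt(max(abs(y30[3000:9000])), 1e-3)
  # band pass keeps in-band, rejects out-of-band
  yb <- applyFilter(sin(2 * pi * 20 * t) + sin(2 * pi * 1 * t), fs, c(12, 35))
  expect_gt(max(yb[mid]), 0.9)
  expect_lt(abs(cor(yb[mid], sin(2 * pi * 20 * t)[mid])), 1.0)
  # corners must lie below Nyquist
  expect_error(applyFilter(s1, fs, c(0, 600)), "Nyquist")
})

test_that("the analytic signal carries the textbook phase convention", {
  fs <- 1000
  t <- (0:2999) / fs
  a <- analyticSignal(cos(2 * pi * 1 * t))
  expect_lt(abs(a$phase[1]), 0.01)                       # 0 at the peak
  expect_lt(abs(a$phase[251] - pi / 2), 0.01)            # pi/2 a quarter later
  mid <- 500:2500
  expect_lt(max(abs(a$envelope[mid] - 1)), 0.01)
  a3 <- analyticSignal(3 * cos(2 * pi * 1 * t))
  expect_lt(max(abs(a3$envelope[mid] - 3)), 0.03)
  z <- analyticSignal(rep(0, 100))
  expect_true(all(is.na(z$phase)))
  expect_equal(z$zeroChannels, 1L)
})

test_that("phase crossings appear once per cycle at the right times", {
  fs <- 1000
  t <- (0:2999) / fs
  a <- analyticSignal(cos(2 * pi * 1 * t))
  cr <- detectPhaseCrossings(a, t)
  expect_equal(cr$time, c(0.25, 1.25, 2.25), tolerance = 1e-3)
  # crossing count ~ duration * frequency
  expect_lte(abs(nrow(cr) - 3), 1)
  # positive rescaling leaves crossing times untouched (above threshold)
  a5 <- analyticSignal(5 * cos(2 * pi * 1 * t))
  cr5 <- detectPhaseCrossings(a5, t, threshold = 1)
  expect_equal(cr5$time, cr$time, tolerance = 1e-9)
  # the amplitude threshold silences a weak trace
  aw <- analyticSignal(0.1 * cos(2 * pi * 1 * t))
  expect_equal(nrow(detectPhaseCrossings(aw, t, threshold = 1)), 0L)
})

test_that("the noise threshold rejects noise and scales with its amplitude", {
  cfgN <- recordingConfig(amplitude = 0, baselineRate = 0, peakRate = 0,
                          noiseSd = 10)
  recs <- generateTrials(cfgN, 6, seed = 11)
  thr <- estimateNoiseThreshold(recs, c(0, 2))
  tot <- 0; kept <- 0
  for (r in recs[4:6]) {
    a <- analyticSignal(applyFilter(lfp(r), sampleRate(r), c(0, 2)))
    tot <- tot + nrow(detectPhaseCrossings(a, lfpTimes(r), pi / 2, 0))
    kept <- kept + nrow(detectPhaseCrossings(a, lfpTimes(r), pi / 2, thr))
  }
  expect_gt(1 - kept / tot, 0.97)
  # doubling the noise sd approximately doubles the threshold
  cfg2 <- recordingConfig(amplitude = 0, baselineRate = 0, peakRate = 0,
                          noiseSd = 20)
  thr2 <- estimateNoiseThreshold(generateTrials(cfg2, 6, seed = 11), c(0, 2))
  expect_lt(abs(thr2 / thr - 2), 0.25)
  # zero-noise limit: the threshold collapses far below the signal scale and
  # the response crossings all survive it
  rec0 <- generateRecording(recordingConfig(noiseSd = 0), seed = 3)
  thr0 <- estimateNoiseThreshold(list(rec0), c(0, 2))
  expect_lt(thr0, 0.05 * 100)
  a0 <- analyticSignal(applyFilter(lfp(rec0), 1000, c(0, 2)))
  cr0 <- detectPhaseCrossings(a0, lfpTimes(rec0), pi / 2, 0)
  response <- cr0[cr0$amplitude > 20, ]
  crT <- detectPhaseCrossings(a0, lfpTimes(rec0), pi / 2, thr0)
  expect_true(all(response$time %in% crT$time))
})

test_that("Welch spectra localize narrowband power and sit flat for noise", {
  lay <- electrodeLayout(2L, 2L, 0.1)
  fs <- 1000; nt <- 5000
  tt <- (0:(nt - 1)) / fs
  mkRec <- function(mat) {
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(lfp = mat),
      rowData = S4Vectors::DataFrame(channel = 1:4,
                                     x = lay@positions[, 1],
                                     y = lay@positions[, 2]))
    S4Vectors::metadata(se) <- list(sampleRate = fs, stimTimes = 1.5,
                                    duration = 5, layout = lay,
                                    spikes = rep(list(numeric(0)), 4),
                                    groundTruth = NULL, seed = 0)
    as(se, "MEARecording")
  }
  sine <- mkRec(matrix(rep(sin(2 * pi * 1 * tt), each = 4), 4))
  psd <- welchPsd(sine)
  expect_equal(psd$freq[which.max(psd$power)], 1)
  set.seed(1)
  noise <- mkRec(matrix(rnorm(4 * nt), 4))
  pn <- welchPsd(noise)
  band <- pn$power[pn$freq >= 5 & pn$freq <= 450]
  expect_lt(sd(band) / mean(band), 0.5)     # flat within Monte-Carlo slack
  # the evoked synthetic recording is dominated by power below 2 Hz
  rec <- generateRecording(recordingConfig(), seed = 1)
  pr <- welchPsd(rec)
  expect_gt(sum(pr$power[pr$freq < 2]) / sum(pr$power), 0.5)
  expect_error(welchPsd(sine, window = c(0.25, 10)), "exceeds")
})
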