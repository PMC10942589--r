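test_that("flood fill chains crossings through neighbors within the window", {
  line <- electrodeLayout(1L, 3L, 0.1)
  # chained: 0, 90, 180 ms with a 100 ms window -> one wave of three
  w <- clusterCrossings(makeCrossings(1:3, c(0, 0.09, 0.18)), line, 0.1)
  expect_length(w, 1L)
  expect_equal(waveChannels(w[[1]]), 1:3)
  # too far apart in time: three singleton waves
  w <- clusterCrossings(makeCrossings(1:3, c(0, 0.15, 0.30)), line, 0.1)
  expect_length(w, 3L)
  # fully connected 2x2 grid
  grid2 <- electrodeLayout(2L, 2L, 0.1)
  w <- clusterCrossings(makeCrossings(1:4, c(0, 0.02, 0.04, 0.05)), grid2, 0.05)
  expect_length(w, 1L)
  expect_equal(waveChannels(w[[1]]), 1:4)
  # but not across a spatial break: diagonal-only contact is not adjacency
  w <- clusterCrossings(makeCrossings(c(1, 4), c(0, 0.01)), grid2, 0.05)
  expect_length(w, 2L)
})

test_that("the wave partition is independent of crossing order", {
  lay <- electrodeLayout(3L, 4L, 0.1)
  set.seed(8)
  cr <- makeCrossings(sample(1:12, 30, TRUE), runif(30, 0, 2))
  part <- function(cc) {
    ws <- clusterCrossings(cc, lay, 0.12)
    sig <- lapply(ws, function(w)
      paste(sort(paste(w@crossings$channel, round(w@crossings$time, 9))),
            collapse = "|"))
    sort(unlist(sig))
  }
  p1 <- part(cr)
  p2 <- part(cr[sample(nrow(cr)), ])
  expect_identical(p1, p2)
})

test_that("wave selection applies the recruitment criteria", {
  lay <- electrodeLayout(12L, 10L, 0.1)
  w80 <- makeWave(1:80, seq(0, 0.079, by = 0.001))
  w31 <- makeWave(1:31, seq(0, 0.030, by = 0.001))
  w30 <- makeWave(1:30, seq(0, 0.029, by = 0.001))
  expect_length(selectWaves(list(w80), lay, "fraction", fraction = 2/3), 1L)
  expect_length(selectWaves(list(w30), lay, "fraction", fraction = 2/3), 0L)
  expect_length(selectWaves(list(w31), lay, "count", minCount = 30), 1L)
  expect_length(selectWaves(list(w30), lay, "count", minCount = 30), 0L)
  expect_length(selectWaves(list(), lay, "fraction"), 0L)
})

test_that("the latency map keeps only first crossings, anchored at the start", {
  lay <- electrodeLayout(1L, 3L, 0.1)
  w <- makeWave(c(1, 2, 2, 3), c(0.00, 0.05, 0.30, 0.10))
  plm <- computePLM(w, lay)
  expect_equal(nrow(plm), 3L)
  expect_equal(plm$latency[plm$channel == 2], 0.05)   # first of the two
  expect_equal(attr(plm, "startChannel"), 1L)
  expect_equal(plm$distance, c(0, 0.1, 0.2))
  single <- computePLM(makeWave(5, 0.2), electrodeLayout(2L, 3L, 0.1))
  expect_equal(nrow(single), 1L)
})

test_that("PLDC is exact on ramps and invariant to affine rescaling", {
  d <- seq(0, 1, by = 0.1)
  expect_equal(computePLDC(2 + 3 * d, d), 1)
  expect_equal(computePLDC(2 - 3 * d, d), -1)
  set.seed(3)
  lat <- runif(30); dist <- runif(30)
  expect_equal(computePLDC(lat, dist),
               computePLDC(5 + 2 * lat, 1 + 0.1 * dist), tolerance = 1e-12)
  flat <- computePLDC(rep(1, 10), d[1:10])
  expect_true(is.na(flat))
  expect_match(attr(flat, "reason"), "variance")
  expect_true(is.na(computePLDC(c(1, 2), c(1, 2))))
})

test_that("the wave center path follows the amplitude-weighted center of mass", {
  lay <- electrodeLayout(1L, 5L, 0.1)
  # all crossings on one channel: constant path
  w1 <- makeWave(c(3, 3, 3), c(0.1, 0.2, 0.3))
  p1 <- computeWCP(w1, lay, 100)
  expect_true(all(abs(p1$x - 0.2) < 1e-12))
  # two equal-amplitude crossings at symmetric times: midpoint midway
  w2 <- makeWave(c(1, 5), c(0.0, 0.2))
  p2 <- computeWCP(w2, lay, 1000)
  midRow <- which.min(abs(p2$time - 0.1))
  expect_equal(p2$x[midRow], 0.2, tolerance = 1e-9)
  # endpoints approach the earliest/latest crossing electrodes once the
  # ramp's end width 2*dTbar is small against the wave span (many crossings)
  wd <- makeWave(rep(c(1, 3, 5), c(7, 7, 7)),
                 c(seq(0, .06, by = .01), seq(.2, .26, by = .01),
                   seq(.4, .46, by = .01)))
  pd <- computeWCP(wd, lay, 1000)
  expect_lt(abs(pd$x[1] - 0), 0.05)
  expect_lt(abs(pd$x[nrow(pd)] - 0.4), 0.05)
  # direct evaluation of the weighted-mean formula on a 5-crossing toy
  w5 <- makeWave(c(1, 2, 3, 4, 5), c(0.00, 0.03, 0.05, 0.09, 0.12),
                 amplitude = c(1, 2, 1.5, 0.5, 1))
  wcp <- computeWCP(w5, lay, 1000)
  cr <- w5@crossings
  pos <- lay@positions[cr$channel, , drop = FALSE]
  dTbar <- mean(diff(sort(cr$time)))
  ns <- nrow(wcp)
  for (k in c(1L, 17L, 61L, ns)) {
    i <- k - 1
    sig <- if (i < ns / 2) 2 * dTbar + 8 * dTbar * i / (ns / 2)
           else 10 * dTbar - 8 * dTbar * (i - ns / 2) / (ns / 2)
    wgt <- cr$amplitude * exp(-(wcp$time[k] - cr$time)^2 / (2 * sig^2))
    expect_equal(wcp$x[k], sum(pos[, 1] * wgt) / sum(wgt), tolerance = 1e-12)
    expect_equal(wcp$sigma[k], sig, tolerance = 1e-12)
  }
})

test_that("path speed is the fitted displacement rate along the main axis", {
  # uniform motion: 0.5 mm in 0.25 s -> 2 mm/s
  wcp <- data.frame(time = seq(0, 0.25, by = 0.01),
                    x = seq(0, 0.5, length.out = 26), y = 0)
  expect_equal(estimateSpeed(wcp), 2, tolerance = 1e-9)
  expect_equal(estimateSpeed(data.frame(time = 0:10, x = 1, y = 2)), 0)
})

test_that("wave speed recovers the module gap over the activation delay", {
  cfg <- speedTestConfig(delay = 0.28)
  lay <- cfg@layout
  rels <- vapply(1:3, function(s) {
    rec <- generateRecording(cfg, seed = s)
    a <- analyticSignal(applyFilter(lfp(rec), sampleRate(rec), c(0, 2)))
    cr <- detectPhaseCrossings(a, lfpTimes(rec), pi / 2, 3.4)
    cr <- cr[cr$time >= stimTimes(rec)[1], ]
    w <- selectWaves(clusterCrossings(cr, lay, 0.1), lay, "count",
                     minCount = 30)[[1]]
    speed <- estimateSpeed(computeWCP(w, lay, sampleRate(rec)))
    target <- moduleCentroidGap(rec) / groundTruth(rec)$interModuleDelay
    abs(speed - target) / target
  }, 0)
  expect_lt(median(rels), 0.25)
})
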