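test_that("the summed potential matches direct substitution and its symmetries", {
  p <- sourcePair(c(-0.5, 0.5), sigmaX = 1, t1 = -1, t2 = 1, sigmaT = 1)
  # both sources contribute exp(-(0.5^2)/2 - 1/2) = exp(-5/8) at the origin
  expect_equal(as.numeric(evaluatePotential(p, 0, 0)), 2 * exp(-0.625),
               tolerance = 1e-12)
  # Gaussian tails
  expect_lt(max(abs(evaluatePotential(p, c(-60, 60), 0))), 1e-300)
  # symmetric pair: V(x, t) = V(-x, 2*tbar - t), tbar = 0 here
  xs <- seq(-2, 2, by = 0.25); ts <- seq(-2, 2, by = 0.5)
  V <- evaluatePotential(p, xs, ts)
  Vr <- evaluatePotential(p, -xs, -ts)
  expect_equal(V, Vr, tolerance = 1e-12)
  # linear in amplitudes, additive over sources
  p2 <- sourcePair(c(-0.5, 0.5), sigmaX = 1, t1 = -1, t2 = 1, sigmaT = 1,
                   amplitudes = c(3, 3))
  expect_equal(evaluatePotential(p2, xs, ts), 3 * V, tolerance = 1e-12)
  only1 <- sourcePair(c(-0.5, 0.5), sigmaX = 1, t1 = -1, t2 = 1, sigmaT = 1,
                      amplitudes = c(1, 0))
  only2 <- sourcePair(c(-0.5, 0.5), sigmaX = 1, t1 = -1, t2 = 1, sigmaT = 1,
                      amplitudes = c(0, 1))
  expect_equal(evaluatePotential(only1, xs, ts) + evaluatePotential(only2, xs, ts),
               V, tolerance = 1e-12)
})

test_that("source-pair validity rejects degenerate inputs", {
  expect_error(sourcePair(c(0, 1), sigmaX = -1), "positive")
  expect_error(sourcePair(c(0, 1), sigmaX = 1, sigmaT = 0), "positive")
  expect_error(sourcePair(c(0, 1), mode = "periodic", freq = -2), "positive")
  bad <- matrix(c(1, 2, 0, 1), 2)   # asymmetric covariance
  expect_error(sourcePair(rbind(c(0, 0), c(1, 0)), sigmaX = list(bad, diag(2))),
               "symmetric")
})

test_that("peak tracking follows the moving maximum of the field", {
  p <- sourcePair(c(-0.5, 0.5), sigmaX = 1, t1 = -1, t2 = 1, sigmaT = 1)
  # symmetry: the peak sits at 0 at the mid time
  tr <- trackPeak(p, 0)
  expect_equal(tr$position, 0, tolerance = 1e-8)
  expect_false(tr$degenerate)
  # long before the first activation the peak sits at the first source
  tr <- trackPeak(p, -6)
  expect_lt(abs(tr$position - (-0.5)), 0.05)
  # agreement with a dense-grid argmax oracle for dx=1, sx=st=1, dt=2
  times <- seq(-0.8, 0.8, by = 0.1)
  tr <- trackPeak(p, times)
  grid <- seq(-4.5, 4.5, length.out = 10001L)
  argmax <- vapply(times, function(t)
    grid[which.max(evaluatePotential(p, grid, t))], 0)
  expect_lt(max(abs(tr$position - argmax)), diff(grid[1:2]) + 1e-9)
})

test_that("transient-model mid-point velocity matches its closed form", {
  expect_equal(peakVelocityGaussian(1, 1, 2, 1), 2 / 3, tolerance = 1e-12)
  expect_equal(peakVelocityGaussian(1, 1, 0, 1), 0)
  # strictly increasing toward the 2*sigma boundary
  v <- vapply(seq(0.2, 1.9, by = 0.1), peakVelocityGaussian,
              0, sigmaX = 1, dt = 1, sigmaT = 1)
  expect_true(all(diff(v) > 0))
  expect_error(peakVelocityGaussian(2, 1, 1, 1), "2\\*sigmaX")
  expect_error(peakVelocityGaussian(2.5, 1, 1, 1), "2\\*sigmaX")
  # reversing the activation order reverses the velocity
  expect_equal(peakVelocityGaussian(1, 1, -2, 1), -peakVelocityGaussian(1, 1, 2, 1))
  # oracle equivalence on random draws
  set.seed(101)
  for (i in 1:25) {
    sx <- runif(1, 0.5, 2); dx <- runif(1, 0.2, 1.8) * sx
    st <- runif(1, 0.5, 2); dt <- runif(1, 0.2, 2) * st
    v1 <- peakVelocityGaussian(dx, sx, dt, st)
    v2 <- oracleVelocityGaussian(dx, sx, dt, st)
    expect_lt(abs(v1 - v2) / abs(v2), 1e-3)
  }
})

test_that("periodic-model peak velocity matches the tracked-peak oracle", {
  # frozen oracle value for the reference parameter point
  # (x=0, dx=1, sx=1, f=1, dphi=pi/2): 2*pi*tan(pi/4)*0.5/0.75
  expect_equal(peakVelocityPeriodic(0, 1, 1, 1, pi / 2), 2 * pi * 0.5 / 0.75,
               tolerance = 1e-10)
  expect_equal(oracleVelocityPeriodic(0, 1, 1, 1, pi / 2), 2 * pi * 0.5 / 0.75,
               tolerance = 1e-5)
  expect_equal(peakVelocityPeriodic(0, 1, 1, 1, 0), 0)
  # sign flips with the phase-lag difference
  expect_equal(peakVelocityPeriodic(0.1, 1, 1, 1, -pi / 3),
               -peakVelocityPeriodic(0.1, 1, 1, 1, pi / 3), tolerance = 1e-12)
  expect_gt(peakVelocityPeriodic(0, 1, 1, 1, pi / 4), 0)
  # magnitude proportional to the frequency
  expect_equal(peakVelocityPeriodic(0.1, 1, 1, 3, pi / 4),
               3 * peakVelocityPeriodic(0.1, 1, 1, 1, pi / 4), tolerance = 1e-12)
  # domain errors
  expect_error(peakVelocityPeriodic(0.6, 1, 1, 1, pi / 4), "between")
  expect_error(peakVelocityPeriodic(0, 3, 1, 1, pi / 4), "concave")
  # oracle equivalence on random draws
  set.seed(202)
  for (i in 1:25) {
    sx <- runif(1, 0.7, 1.5); dx <- runif(1, 0.3, 1.7) * sx
    fr <- runif(1, 0.5, 2); dphi <- runif(1, 0.2, 2)
    x <- runif(1, -dx / 3, dx / 3)
    if (x^2 + sx^2 - (dx / 2)^2 <= 0) next
    v1 <- peakVelocityPeriodic(x, dx, sx, fr, dphi)
    v2 <- oracleVelocityPeriodic(x, dx, sx, fr, dphi)
    expect_lt(abs(v1 - v2) / abs(v2), 1e-3)
  }
})

test_that("mid-point concavity switches at twice the spatial scale", {
  expect_identical(classifyMidpointConcavity(1, 1), "concave")
  expect_identical(classifyMidpointConcavity(3, 1), "convex")
  expect_identical(classifyMidpointConcavity(0, 2), "concave")
  # the boundary itself (an inflection) counts as concave
  expect_identical(classifyMidpointConcavity(2, 1), "concave")
  # single transition on a coarse scan
  cls <- vapply(seq(0.5, 3.5, by = 0.01), classifyMidpointConcavity, "",
                sigmaX = 1)
  expect_equal(sum(cls[-1] != cls[-length(cls)]), 1L)
})

test_that("the mid-point trace splits into two temporal peaks at 2*sigmaT", {
  mk <- function(dt) sourcePair(c(-0.5, 0.5), 1, t1 = -dt / 2, t2 = dt / 2,
                                sigmaT = 1)
  expect_equal(countTemporalPeaks(mk(1)), 1L)
  expect_equal(countTemporalPeaks(mk(3)), 2L)
  expect_equal(countTemporalPeaks(mk(2)), 1L)   # plateau boundary
  b <- unimodalityBoundary(seq(1.8, 2.2, by = 1e-3))
  expect_lt(abs(b - 2), 1e-3)
})

test_that("pattern constructors realize the three wave geometries", {
  pl <- makePattern("plane")
  expect_equal(pl@centers[2, ] - pl@centers[1, ], c(2, 0))   # dx = 2*sigma
  expect_equal(pl@spatialScale[[1]], pl@spatialScale[[2]])
  ra <- makePattern("radial")
  expect_equal(ra@centers[1, ], ra@centers[2, ])
  expect_lt(sum(diag(ra@spatialScale[[1]])), sum(diag(ra@spatialScale[[2]])))
  sp <- makePattern("spiral_like")
  a1 <- eigen(sp@spatialScale[[1]])$vectors[, 1]
  a2 <- eigen(sp@spatialScale[[2]])$vectors[, 1]
  expect_lt(abs(sum(a1 * a2)), 1e-10)      # orthogonal major axes
  expect_error(makePattern("vortex"))
})

test_that("PLDC of the model stays high inside the concave regime", {
  g <- pldcScan(dxValues = 0.5, delayValues = 1)   # dx = 0.5*sx, dt = st
  expect_gt(g[1, 1], 0.9)
  # simultaneous activation has no directed gradient: the field is separable,
  # every point peaks at the same instant, and the PLDC is undefined
  g0 <- pldcScan(dxValues = 1, delayValues = 0)
  expect_true(is.na(g0[1, 1]))
})
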