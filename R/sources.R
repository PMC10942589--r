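#' Evaluate the two-source potential V(x, t)
#'
#' Sums the two sources' spatial Gaussians, each multiplied by its temporal
#' factor (a temporal Gaussian, or \eqn{\cos(2\pi f t - \phi_i)} in periodic
#' mode).  Linear in the source amplitudes and additive across sources.
#'
#' @param pair a [SourcePair-class].
#' @param x spatial sample points: numeric vector (1D pair) or a matrix with
#'   2 columns (2D pair).
#' @param t numeric vector of time points.
#' @return numeric matrix, `length(x)` (or `nrow(x)`) rows by `length(t)`
#'   columns.
#' @examples
#' p <- sourcePair(c(-0.5, 0.5), sigmaX = 1, t1 = -1, t2 = 1, sigmaT = 1)
#' evaluatePotential(p, 0, 0)   # 2 exp(-5/8)
#' @export
evaluatePotential <- function(pair, x, t) {
  stopifnot(is(pair, "SourcePair"))
  d <- ncol(pair@centers)
  if (d == 1L) {
    x <- as.numeric(x)
    spatial <- vapply(1:2, function(i)
      exp(-(x - pair@centers[i, 1])^2 / (2 * pair@spatialScale[[i]]^2)),
      numeric(length(x)))
    if (length(x) == 1L) spatial <- matrix(spatial, nrow = 1L)
  } else {
    if (!is.matrix(x) || ncol(x) != 2L)
      stop("a 2D pair needs x as a matrix with 2 columns")
    spatial <- vapply(1:2, function(i) {
      dc <- sweep(x, 2L, pair@centers[i, ])
      Sinv <- solve(pair@spatialScale[[i]])
      q <- rowSums((dc %*% Sinv) * dc)
      exp(-q / 2)
    }, numeric(nrow(x)))
    if (nrow(x) == 1L) spatial <- matrix(spatial, nrow = 1L)
  }
  temporal <- temporalFactors(pair, t)       # 2 x length(t)
  (pair@amplitudes[1] * spatial[, 1, drop = FALSE] %*% temporal[1, , drop = FALSE]) +
    (pair@amplitudes[2] * spatial[, 2, drop = FALSE] %*% temporal[2, , drop = FALSE])
}

# per-source temporal activation factors, 2 x length(t)
temporalFactors <- function(pair, t) {
  if (pair@temporalMode == "gaussian") {
    rbind(exp(-(t - pair@temporalCenters[1])^2 / (2 * pair@temporalScale^2)),
          exp(-(t - pair@temporalCenters[2])^2 / (2 * pair@temporalScale^2)))
  } else {
    rbind(cos(2 * pi * pair@frequency * t - pair@phases[1]),
          cos(2 * pi * pair@frequency * t - pair@phases[2]))
  }
}

# analytic spatial derivative of V for a 1D pair, vectorized over x (scalar t)
potentialDx <- function(pair, x, t) {
  tf <- temporalFactors(pair, t)
  out <- 0
  for (i in 1:2) {
    s <- pair@spatialScale[[i]]
    g <- exp(-(x - pair@centers[i, 1])^2 / (2 * s^2))
    out <- out - pair@amplitudes[i] * tf[i, 1] * (x - pair@centers[i, 1]) / s^2 * g
  }
  out
}

#' Track the moving peak of a 1D two-source potential
#'
#' At each time the peak position \eqn{x_p(t)} is the root of the analytic
#' spatial derivative \eqn{\partial V/\partial x}, bracketed between the two
#' source centers (bisection to 1e-9 of the spatial scale).  When no interior
#' root exists (spatially separated peaks, or both temporal factors
#' non-positive) the global argmax over a dense grid is returned instead and
#' the sample is flagged `degenerate`.  Peak velocities are central finite
#' differences of the positions.
#'
#' @param pair a 1D [SourcePair-class].
#' @param times numeric vector of times, ideally within the active epoch.
#' @return data.frame with columns `time`, `position`, `velocity`,
#'   `degenerate`.
#' @export
trackPeak <- function(pair, times) {
  stopifnot(is(pair, "SourcePair"), ncol(pair@centers) == 1L)
  x1 <- min(pair@centers[, 1]); x2 <- max(pair@centers[, 1])
  sx <- max(unlist(pair@spatialScale))
  tol <- 1e-9 * max(sx, 1)
  pos <- numeric(length(times))
  dg <- logical(length(times))
  grid <- seq(x1 - 4 * sx, x2 + 4 * sx, length.out = 2001L)
  for (k in seq_along(times)) {
    t <- times[k]
    lo <- x1 + 1e-12; hi <- x2 - 1e-12
    flo <- potentialDx(pair, lo, t); fhi <- potentialDx(pair, hi, t)
    if (is.finite(flo) && is.finite(fhi) && flo > 0 && fhi < 0) {
      # bisection on the bracketed derivative root
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (potentialDx(pair, mid, t) > 0) lo <- mid else hi <- mid
      }
      pos[k] <- (lo + hi) / 2
    } else {
      v <- evaluatePotential(pair, grid, t)
      pos[k] <- grid[which.max(v)]
      dg[k] <- TRUE
    }
  }
  vel <- rep(NA_real_, length(times))
  if (length(times) >= 3L) {
    vel[2:(length(times) - 1)] <-
      (pos[3:length(times)] - pos[1:(length(times) - 2)]) /
      (times[3:length(times)] - times[1:(length(times) - 2)])
  }
  if (length(times) >= 2L) {
    vel[1] <- (pos[2] - pos[1]) / (times[2] - times[1])
    vel[length(times)] <- (pos[length(times)] - pos[length(times) - 1]) /
      (times[length(times)] - times[length(times) - 1])
  }
  data.frame(time = times, position = pos, velocity = vel, degenerate = dg)
}

#' Mid-point peak velocity of the transient (Gaussian) two-source model
#'
#' Closed-form velocity of the traveling peak at the symmetry point
#' (\eqn{x = 0}, \eqn{t = \bar t}) of two identical spatial Gaussians
#' separated by `dx` and activated `dt` apart:
#' \deqn{v_p = \frac{\Delta t\, \sigma_x^2\, \Delta x}
#'              {\sigma_t^2\,(4\sigma_x^2 - \Delta x^2)}.}
#' Valid for \eqn{0 < \Delta x < 2\sigma_x} (the regime with a single concave
#' traveling peak); the formula diverges at \eqn{\Delta x = 2\sigma_x}.
#'
#' @param dx center separation \eqn{\Delta x > 0}.
#' @param sigmaX spatial standard deviation \eqn{\sigma_x > 0}.
#' @param dt activation delay \eqn{\Delta t}.
#' @param sigmaT temporal standard deviation \eqn{\sigma_t > 0}.
#' @return peak velocity (model units per time unit).
#' @examples
#' peakVelocityGaussian(1, 1, 2, 1)   # 2/3
#' @export
peakVelocityGaussian <- function(dx, sigmaX, dt, sigmaT) {
  stopifnot(sigmaX > 0, sigmaT > 0)
  if (dx <= 0 || dx >= 2 * sigmaX)
    stop("the mid-point velocity law requires 0 < dx < 2*sigmaX")
  dt * sigmaX^2 * dx / (sigmaT^2 * (4 * sigmaX^2 - dx^2))
}

#' Peak velocity of the periodic (oscillatory) two-source model
#'
#' Closed-form velocity of the traveling peak of two identical spatial
#' Gaussians with temporal factors \eqn{\cos(2\pi f t - \phi_i)}, evaluated at
#' the position `x` (origin midway between the centers).  Derived by implicit
#' differentiation of the peak condition \eqn{\partial V/\partial x = 0}:
#' with \eqn{a = \Delta x/2},
#' \deqn{v_p(x) = \frac{2\pi f \sin(\Delta\phi)\; \sigma_x^2 (a^2 - x^2)}
#'   {\left(\cos\Delta\phi + \cos 2\theta(x)\right)\, a\,
#'    (x^2 + \sigma_x^2 - a^2)}}
#' where \eqn{\rho(x) = \frac{x+a}{a-x} e^{-x \Delta x/\sigma_x^2}} and
#' \eqn{\tan\theta = \cot(\Delta\phi/2)\,(\rho-1)/(\rho+1)}.  The sign of
#' \eqn{v_p} is the sign of \eqn{\sin\Delta\phi} and the magnitude scales
#' with \eqn{f}.
#'
#' @param x evaluation position, strictly between the centers
#'   (\eqn{|x| < \Delta x/2}).
#' @param dx center separation \eqn{\Delta x > 0}.
#' @param sigmaX spatial standard deviation \eqn{\sigma_x > 0}.
#' @param freq oscillation frequency \eqn{f > 0}.
#' @param dphi phase-lag difference \eqn{\Delta\phi = \phi_2 - \phi_1}
#'   (radians, \eqn{|\Delta\phi| < \pi}).
#' @return peak velocity at the time the peak passes `x`.
#' @export
peakVelocityPeriodic <- function(x, dx, sigmaX, freq, dphi) {
  stopifnot(dx > 0, freq > 0, sigmaX > 0)
  a <- dx / 2
  if (abs(x) >= a)
    stop("x must lie strictly between the source centers (|x| < dx/2)")
  if (x^2 + sigmaX^2 - a^2 <= 0)
    stop("no concave traveling peak at this x: x^2 + sigmaX^2 - (dx/2)^2 <= 0")
  if (abs(dphi) >= pi)
    stop("|dphi| must be smaller than pi")
  if (dphi == 0) return(0)
  rho <- (x + a) / (a - x) * exp(-x * dx / sigmaX^2)
  theta <- atan((1 / tan(dphi / 2)) * (rho - 1) / (rho + 1))
  2 * pi * freq * sin(dphi) * sigmaX^2 * (a^2 - x^2) /
    ((cos(dphi) + cos(2 * theta)) * a * (x^2 + sigmaX^2 - a^2))
}

#' Concavity of the mid-time spatial profile
#'
#' For the symmetric transient pair, evaluates the sign of the second spatial
#' derivative of \eqn{V} at the mid point (\eqn{x = 0},
#' \eqn{t = \bar t = (t_1+t_2)/2}).  Since
#' \eqn{\partial^2 V/\partial x^2 \propto \Delta x^2 - 4\sigma_x^2} there, the
#' profile is a single concave traveling peak for
#' \eqn{\Delta x \le 2\sigma_x} and splits into a convex mid point (two
#' discernible sources) beyond; the boundary itself (an inflection) is
#' classified concave.
#'
#' @param dx center separation \eqn{\Delta x \ge 0}.
#' @param sigmaX spatial standard deviation \eqn{\sigma_x > 0}.
#' @return `"concave"` or `"convex"`.
#' @examples
#' classifyMidpointConcavity(1, 1)   # concave
#' classifyMidpointConcavity(3, 1)   # convex
#' @export
classifyMidpointConcavity <- function(dx, sigmaX) {
  stopifnot(dx >= 0, sigmaX > 0)
  # d2V/dx2(0, tbar) = 2 * exp(-dx^2/(8 sx^2) - dt^2/(8 st^2)) *
  #                    (dx^2 - 4 sx^2) / (4 sx^4); only the sign matters
  curv <- dx^2 - 4 * sigmaX^2
  if (curv <= 0) "concave" else "convex"
}

#' Count temporal peaks of the mid-point trace V(0, t)
#'
#' For the symmetric transient pair, counts strict local temporal maxima of
#' \eqn{V(0, t)} on a dense grid spanning \eqn{\bar t \pm 4\sigma_t}.  The
#' trace is unimodal (one peak) when the activations overlap enough,
#' \eqn{\Delta t \le 2\sigma_t}, and splits into two peaks beyond; the plateau
#' boundary \eqn{\Delta t = 2\sigma_t} counts as one.
#'
#' @param pair a symmetric 1D Gaussian-mode [SourcePair-class] (only
#'   \eqn{\Delta t} and \eqn{\sigma_t} matter at \eqn{x = 0}).
#' @param nGrid temporal grid resolution (default 2001).
#' @return integer number of strict local maxima.
#' @examples
#' countTemporalPeaks(sourcePair(c(-0.5, 0.5), 1, t1 = 0, t2 = 1, sigmaT = 1))  # 1
#' countTemporalPeaks(sourcePair(c(-0.5, 0.5), 1, t1 = 0, t2 = 3, sigmaT = 1))  # 2
#' @export
countTemporalPeaks <- function(pair, nGrid = 2001L) {
  stopifnot(is(pair, "SourcePair"), pair@temporalMode == "gaussian",
            ncol(pair@centers) == 1L)
  tbar <- mean(pair@temporalCenters)
  st <- pair@temporalScale
  t <- seq(tbar - 4 * st, tbar + 4 * st, length.out = nGrid)
  v <- as.numeric(evaluatePotential(pair, 0, t))
  s <- sign(diff(v))
  s <- s[s != 0]                      # plateaus collapse to one transition
  sum(s[-length(s)] > 0 & s[-1] < 0)
}

#' Locate the concavity boundary by scanning the separation ratio
#'
#' Scans \eqn{\Delta x/\sigma_x} and reports the ratio at which the mid-time
#' spatial profile switches from concave to convex (the midpoint of the
#' bracketing grid step).  The analytic boundary is exactly 2.
#'
#' @param ratios separation ratios to scan (default `seq(0.1, 4, by = 1e-3)`).
#' @param sigmaX spatial standard deviation (default 1).
#' @return the transition ratio, or `NA` if no transition occurs in the scan.
#' @export
concavityBoundary <- function(ratios = seq(0.1, 4, by = 1e-3), sigmaX = 1) {
  cls <- vapply(ratios, function(r)
    classifyMidpointConcavity(r * sigmaX, sigmaX), character(1))
  flip <- which(cls[-1] != cls[-length(cls)])
  if (!length(flip)) return(NA_real_)
  if (length(flip) > 1L) warning("multiple transitions found; using the first")
  mean(ratios[flip[1] + 0:1])
}

#' Locate the temporal unimodality boundary by scanning the delay ratio
#'
#' Scans \eqn{\Delta t/\sigma_t} and reports the ratio at which the number of
#' temporal peaks of \eqn{V(0, t)} changes from 1 to 2 (midpoint of the
#' bracketing grid step).  The analytic boundary is exactly 2.
#'
#' @param ratios delay ratios to scan (default `seq(0.1, 4, by = 1e-3)`).
#' @param sigmaT temporal standard deviation (default 1).
#' @param nGrid temporal grid resolution per evaluation.
#' @return the transition ratio, or `NA` if no transition occurs in the scan.
#' @export
unimodalityBoundary <- function(ratios = seq(0.1, 4, by = 1e-3), sigmaT = 1,
                                nGrid = 2001L) {
  npk <- vapply(ratios, function(r) {
    dt <- r * sigmaT
    p <- sourcePair(c(-0.5, 0.5), sigmaX = 1,
                    t1 = -dt / 2, t2 = dt / 2, sigmaT = sigmaT)
    countTemporalPeaks(p, nGrid = nGrid)
  }, integer(1))
  flip <- which(npk[-1] != npk[-length(npk)])
  if (!length(flip)) return(NA_real_)
  if (length(flip) > 1L) warning("multiple transitions found; using the first")
  mean(ratios[flip[1] + 0:1])
}
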