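# Independent oracles used to validate the package's closed forms and core
# statistics.  These deliberately avoid the package's own code paths.

# ---- numeric peak-velocity oracle, transient (Gaussian) model --------------
# root of dV/dx by uniroot on a locally defined derivative, then central
# finite differences of the tracked position around t = tbar (x = 0)
oracleVelocityGaussian <- function(dx, sx, dt, st, h = 1e-5) {
  dvdx <- function(x, t) {
    -((x + dx / 2) / sx^2) * exp(-(x + dx / 2)^2 / (2 * sx^2) - (t + dt / 2)^2 / (2 * st^2)) -
      ((x - dx / 2) / sx^2) * exp(-(x - dx / 2)^2 / (2 * sx^2) - (t - dt / 2)^2 / (2 * st^2))
  }
  peakAt <- function(t) stats::uniroot(dvdx, c(-dx / 2 + 1e-12, dx / 2 - 1e-12),
                                       t = t, tol = 1e-13)$root
  (peakAt(h) - peakAt(-h)) / (2 * h)
}

# ---- numeric peak-velocity oracle, periodic model --------------------------
# temporal factor cos(2*pi*f*t - phi_i), phi = -+dphi/2; velocity of the
# tracked peak at the time it passes position x
oracleVelocityPeriodic <- function(x, dx, sx, fr, dphi, h = 1e-7) {
  dvdx <- function(xx, t) {
    -cos(2 * pi * fr * t + dphi / 2) * ((xx + dx / 2) / sx^2) *
      exp(-(xx + dx / 2)^2 / (2 * sx^2)) -
      cos(2 * pi * fr * t - dphi / 2) * ((xx - dx / 2) / sx^2) *
      exp(-(xx - dx / 2)^2 / (2 * sx^2))
  }
  peakAt <- function(t) stats::uniroot(dvdx, c(-dx / 2 + 1e-12, dx / 2 - 1e-12),
                                       t = t, tol = 1e-14)$root
  tmax <- 0.8 * (pi / 2 - dphi / 2) / (2 * pi * fr)
  tstar <- stats::uniroot(function(t) peakAt(t) - x, c(-tmax, tmax),
                          tol = 1e-14)$root
  (peakAt(tstar + h) - peakAt(tstar - h)) / (2 * h)
}

# ---- exact dip oracle by linear programming --------------------------------
# Minimizes sup|F_n - G| over unimodal G: for every mode placement (an atom at
# a sample point, or a mode at mu inside an inter-sample gap on a grid, with
# the junction value p as an LP variable) the constraints on G's values at the
# unique sample points are linear in (g, [v or p], d).  Convexity holds up to
# the mode and concavity from it on, including through the gap segments.
# boot::simplex solutions are verified against the constraints and unreliable
# solves are dropped.  The mu grid makes the oracle an upper bound on the
# exact dip, tight to O(grid step).
oracleDipLP <- function(x, ngrid = 25) {
  stopifnot(requireNamespace("boot", quietly = TRUE))
  x <- sort(x); n <- length(x)
  y <- unique(x); m <- length(y)
  if (m == 1) return(0)
  N <- cumsum(tabulate(match(x, y), m)); C <- N / n; Cm <- c(0, C)[1:m]
  rowv <- function(nv, idx, val, dcoef = 0) {
    r <- rep(0, nv + 1); r[idx] <- val; r[nv + 1] <- dcoef; r
  }
  runlp <- function(nv, A1, b1, A2, b2) {
    res <- try(boot::simplex(a = c(rep(0, nv), 1), A1 = A1, b1 = b1,
                             A2 = A2, b2 = b2, maxi = FALSE), silent = TRUE)
    if (inherits(res, "try-error") || res$solved != 1) return(NA_real_)
    s <- res$soln
    if (!all(A1 %*% s <= b1 + 1e-7) || !all(A2 %*% s >= b2 - 1e-7))
      return(NA_real_)
    res$value
  }
  shape <- function(nv, ids, xs, i) {
    h1 <- xs[i] - xs[i - 1]; h2 <- xs[i + 1] - xs[i]
    rowv(nv, c(ids[i + 1], ids[i], ids[i - 1]), c(1 / h2, -1 / h2 - 1 / h1, 1 / h1))
  }
  vals <- c()
  # atom placements (left-limit value v is its own variable)
  for (j in 1:m) {
    nv <- m + 1; vpos <- m + 1
    A1 <- NULL; b1 <- NULL; A2 <- NULL; b2 <- NULL
    add <- function(r, b, leq) {
      if (leq) { A1 <<- rbind(A1, r); b1 <<- c(b1, b) }
      else { A2 <<- rbind(A2, r); b2 <<- c(b2, b) }
    }
    for (k in setdiff(1:m, j)) {
      add(rowv(nv, k, 1, 1), C[k], FALSE); add(rowv(nv, k, 1, -1), Cm[k], TRUE)
    }
    add(rowv(nv, j, 1, 1), C[j], FALSE); add(rowv(nv, j, 1, -1), C[j], TRUE)
    add(rowv(nv, vpos, 1, 1), Cm[j], FALSE); add(rowv(nv, vpos, 1, -1), Cm[j], TRUE)
    add(rowv(nv, m, 1), 1, TRUE)
    chain <- c(if (j > 1) 1:(j - 1), vpos, j:m)
    for (k in 1:(length(chain) - 1))
      add(rowv(nv, c(chain[k + 1], chain[k]), c(1, -1)), 0, FALSE)
    cvx <- c(if (j > 1) 1:(j - 1), vpos)
    if (j >= 3) for (i in 2:(j - 1)) add(shape(nv, cvx, y[1:j], i), 0, FALSE)
    if (m - j + 1 >= 3) for (i in (j + 1):(m - 1)) add(shape(nv, 1:m, y, i), 0, TRUE)
    vals <- c(vals, runlp(nv, A1, b1, A2, b2))
  }
  # in-gap mode placements
  if (m >= 2) for (j in 1:(m - 1)) {
    gapw <- y[j + 1] - y[j]
    for (mu in y[j] + gapw * seq(1, ngrid) / (ngrid + 1)) {
      nv <- m + 1; ppos <- m + 1
      A1 <- NULL; b1 <- NULL; A2 <- NULL; b2 <- NULL
      add <- function(r, b, leq) {
        if (leq) { A1 <<- rbind(A1, r); b1 <<- c(b1, b) }
        else { A2 <<- rbind(A2, r); b2 <<- c(b2, b) }
      }
      for (k in 1:m) {
        add(rowv(nv, k, 1, 1), C[k], FALSE); add(rowv(nv, k, 1, -1), Cm[k], TRUE)
      }
      add(rowv(nv, m, 1), 1, TRUE)
      add(rowv(nv, ppos, 1, 1), C[j], FALSE); add(rowv(nv, ppos, 1, -1), C[j], TRUE)
      ci <- c(1:j, ppos, (j + 1):m); cx <- c(y[1:j], mu, y[(j + 1):m])
      for (k in 1:(length(ci) - 1))
        add(rowv(nv, c(ci[k + 1], ci[k]), c(1, -1)), 0, FALSE)
      up <- j + 1; nc2 <- length(ci)
      if (up >= 3) for (i in 2:(up - 1)) add(shape(nv, ci, cx, i), 0, FALSE)
      if (nc2 - up + 1 >= 3) for (i in (up + 1):(nc2 - 1)) add(shape(nv, ci, cx, i), 0, TRUE)
      vals <- c(vals, runlp(nv, A1, b1, A2, b2))
    }
  }
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(NA_real_)
  min(vals)
}

# ---- small fixtures --------------------------------------------------------

# crossings data.frame
makeCrossings <- function(channel, time, amplitude = 1) {
  data.frame(channel = as.integer(channel), time = time,
             amplitude = rep_len(amplitude, length(time)))
}

# a Wave object built directly from crossing vectors
makeWave <- function(channel, time, amplitude = 1, window = 0.1) {
  cr <- makeCrossings(channel, time, amplitude)
  cr <- cr[order(cr$time), ]
  cr$first <- !duplicated(cr$channel)
  rownames(cr) <- NULL
  new("Wave", crossings = cr, window = window, band = c(0, 2))
}

# the canonical speed-recovery configuration: end-column blocks 0.7 mm apart
# with 4x footprints, so the recruited extent matches the module gap
speedTestConfig <- function(delay = 0.28) {
  lay <- electrodeLayout(12L, 10L, 0.1)
  col <- (seq_len(nChannels(lay)) - 1L) %% 10L + 1L
  recordingConfig(layout = lay, modules = list(
    moduleSpec(which(col <= 3), delay = 0, spreadFactor = 4),
    moduleSpec(which(col >= 8), delay = delay, spreadFactor = 4)))
}

# centroid gap (mm) between the two ground-truth modules of a recording
moduleCentroidGap <- function(rec) {
  gt <- groundTruth(rec)
  lay <- recordingLayout(rec)
  cen <- vapply(1:2, function(m)
    colMeans(lay@positions[which(gt$moduleLabels == m), , drop = FALSE]),
    numeric(2))
  sqrt(sum((cen[, 2] - cen[, 1])^2))
}
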