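#' Group phase crossings into waves by spatiotemporal flood fill
#'
#' Starting from the earliest unassigned crossing, a wave grows by closure:
#' any crossing joins if its channel is a rook neighbor of (or identical to)
#' a member channel and its time lies within `window` of any member crossing.
#' The process repeats until no further crossing is spatiotemporally
#' connected; each crossing belongs to at most one wave.  The result is
#' independent of the order in which candidates are examined (set closure).
#'
#' @param crossings data.frame from [detectPhaseCrossings()] (already
#'   amplitude-thresholded).
#' @param layout an [ElectrodeLayout-class].
#' @param window temporal window in s (conventions: 0.1 s for the 0--2 Hz
#'   band, 0.002 s for 12--35 Hz).
#' @param band analysis band recorded on the waves (annotation only).
#' @return list of [Wave-class] objects in start-time order.
#' @export
clusterCrossings <- function(crossings, layout, window = 0.1,
                             band = c(0, 2)) {
  stopifnot(window > 0)
  n <- nrow(crossings)
  if (!n) return(list())
  nb <- neighborList(layout)
  ord <- order(crossings$time)
  cr <- crossings[ord, , drop = FALSE]
  assigned <- rep(FALSE, n)
  waves <- list()
  repeat {
    seedIdx <- which(!assigned)
    if (!length(seedIdx)) break
    seedIdx <- seedIdx[which.min(cr$time[seedIdx])]
    member <- rep(FALSE, n)
    member[seedIdx] <- TRUE
    repeat {
      memCh <- unique(cr$channel[member])
      reach <- unique(c(memCh, unlist(nb[memCh])))
      memT <- cr$time[member]
      cand <- which(!member & !assigned & cr$channel %in% reach)
      if (!length(cand)) break
      ok <- vapply(cand, function(i)
        min(abs(cr$time[i] - memT)) <= window, logical(1))
      if (!any(ok)) break
      member[cand[ok]] <- TRUE
    }
    assigned[member] <- TRUE
    wcr <- cr[member, , drop = FALSE]
    wcr <- wcr[order(wcr$time), , drop = FALSE]
    wcr$first <- !duplicated(wcr$channel)
    rownames(wcr) <- NULL
    waves[[length(waves) + 1L]] <-
      new("Wave", crossings = wcr, window = window, band = band)
  }
  waves[order(vapply(waves, waveStartTime, 0))]
}

#' Filter waves by recruitment criterion
#'
#' Keeps waves recruiting enough channels: a fraction of the array (2/3 for
#' the 0--2 Hz band, 5/6 for 12--35 Hz) or an absolute count (more than 30
#' channels, the criterion used for sparse first-spike analyses).
#'
#' @param waves list of [Wave-class] objects.
#' @param layout an [ElectrodeLayout-class].
#' @param criterion `"fraction"` or `"count"`.
#' @param fraction minimal recruited fraction (default 2/3).
#' @param minCount count threshold; waves with strictly more channels pass
#'   (default 30).
#' @return the passing waves, with the criterion recorded in attribute
#'   `"criterion"`.
#' @export
selectWaves <- function(waves, layout, criterion = c("fraction", "count"),
                        fraction = 2 / 3, minCount = 30L) {
  criterion <- match.arg(criterion)
  keep <- vapply(waves, function(w) {
    nch <- length(waveChannels(w))
    if (criterion == "fraction") nch / nChannels(layout) >= fraction
    else nch > minCount
  }, logical(1))
  structure(waves[keep],
            criterion = if (criterion == "fraction")
              sprintf("fraction >= %.4g", fraction)
            else sprintf("count > %d", minCount))
}

#' Phase-latency map of a wave
#'
#' Per recruited channel, the latency is the time of the channel's first
#' phase crossing within the wave.  The reference start point is the position
#' of the earliest crossing (ties broken by lowest channel id), and distances
#' are Euclidean distances from it.
#'
#' @param wave a [Wave-class].
#' @param layout an [ElectrodeLayout-class].
#' @return data.frame with columns `channel`, `x`, `y`, `latency`,
#'   `distance`; attributes `startChannel` and `start` (position).
#' @export
computePLM <- function(wave, layout) {
  cr <- wave@crossings[wave@crossings$first, , drop = FALSE]
  tmin <- min(cr$time)
  startCh <- min(cr$channel[cr$time == tmin])
  pos <- layout@positions
  d <- sqrt((pos[cr$channel, 1] - pos[startCh, 1])^2 +
            (pos[cr$channel, 2] - pos[startCh, 2])^2)
  out <- data.frame(channel = cr$channel,
                    x = pos[cr$channel, 1], y = pos[cr$channel, 2],
                    latency = cr$time, distance = d)
  out <- out[order(out$channel), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "startChannel") <- startCh
  attr(out, "start") <- pos[startCh, ]
  out
}

#' Wave center path: amplitude- and time-weighted center of mass
#'
#' For every time sample t from the first to the last crossing, the path
#' position is
#' \deqn{X_{cm}(t) = \frac{\sum_i X_i A_i e^{-(t-t_i)^2/2\sigma(t)^2}}
#'                        {\sum_i A_i e^{-(t-t_i)^2/2\sigma(t)^2}}}
#' over all wave crossings i (position \eqn{X_i}, envelope amplitude
#' \eqn{A_i}, crossing time \eqn{t_i}).  To reduce edge bias, the temporal
#' width ramps linearly from \eqn{2\bar{\Delta T}} at the first sample to
#' \eqn{10\bar{\Delta T}} at the middle sample and back down to
#' \eqn{2\bar{\Delta T}} at the last, where \eqn{\bar{\Delta T}} is the mean
#' difference between consecutive sorted crossing times.
#'
#' @param wave a [Wave-class].
#' @param layout an [ElectrodeLayout-class].
#' @param sampleRate temporal sampling of the path in Hz (default 1000).
#' @return data.frame with columns `time`, `x`, `y`, `sigma`.
#' @export
computeWCP <- function(wave, layout, sampleRate = 1000) {
  cr <- wave@crossings
  pos <- layout@positions[cr$channel, , drop = FALSE]
  t0 <- min(cr$time); t1 <- max(cr$time)
  if (nrow(cr) == 1L || t1 == t0) {
    return(data.frame(time = t0, x = pos[1, 1], y = pos[1, 2], sigma = NA_real_))
  }
  ts <- sort(cr$time)
  dTbar <- mean(diff(ts))
  if (dTbar == 0) dTbar <- 1 / sampleRate
  tgrid <- seq(t0, t1, by = 1 / sampleRate)
  if (tgrid[length(tgrid)] < t1) tgrid <- c(tgrid, t1)
  ns <- length(tgrid)
  idx <- seq_len(ns) - 1L
  half <- ns / 2
  sigma <- ifelse(idx < half,
                  2 * dTbar + 8 * dTbar * idx / half,
                  10 * dTbar - 8 * dTbar * (idx - half) / half)
  out <- matrix(0, ns, 2L)
  for (k in seq_len(ns)) {
    w <- cr$amplitude * exp(-(tgrid[k] - cr$time)^2 / (2 * sigma[k]^2))
    sw <- sum(w)
    out[k, ] <- if (sw > 0) colSums(pos * w) / sw else colMeans(pos)
  }
  data.frame(time = tgrid, x = out[, 1], y = out[, 2], sigma = sigma)
}

#' Propagation speed of a wave center path
#'
#' Projects the path onto its principal displacement axis (first principal
#' component of the positions) and returns the magnitude of the slope of a
#' least-squares fit of that projection against time.
#'
#' @param wcp data.frame from [computeWCP()].
#' @return speed in mm/s (0 for a constant path).
#' @export
estimateSpeed <- function(wcp) {
  if (nrow(wcp) < 2L) return(0)
  P <- as.matrix(wcp[, c("x", "y")])
  if (max(apply(P, 2L, function(v) diff(range(v)))) == 0) return(0)
  pc <- prcomp(P, center = TRUE, scale. = FALSE)
  proj <- pc$x[, 1]
  abs(unname(coef(lm(proj ~ wcp$time))[2]))
}
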