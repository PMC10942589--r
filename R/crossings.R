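# unwrap a vector of phases in (-pi, pi] to a continuous phase
unwrapPhase <- function(p) {
  d <- diff(p)
  corr <- cumsum(ifelse(d > pi, -2 * pi, ifelse(d < -pi, 2 * pi, 0)))
  c(p[1], p[-1] + corr)
}

#' Detect amplitude-thresholded phase crossings
#'
#' Finds the times at which each channel's unwrapped instantaneous phase
#' crosses the target phase (modulo \eqn{2\pi}) in the upward direction --
#' one event per oscillation cycle.  Crossing times are refined below the
#' sample period by linear interpolation of the unwrapped phase, and events
#' whose interpolated envelope amplitude falls below `threshold` are
#' discarded (noise rejection; see [estimateNoiseThreshold()]).
#'
#' @param analytic output of [analyticSignal()] on band-filtered traces.
#' @param times numeric vector of sample times (s), e.g. [lfpTimes()].
#' @param targetPhase target phase in radians (default \eqn{\pi/2}).
#' @param threshold minimal envelope amplitude (uV); 0 disables rejection.
#' @return data.frame with columns `channel`, `time`, `amplitude`, sorted by
#'   time.
#' @examples
#' t <- (0:2999) / 1000
#' a <- analyticSignal(cos(2 * pi * 1 * t))
#' detectPhaseCrossings(a, t)$time   # 0.25, 1.25, 2.25
#' @export
detectPhaseCrossings <- function(analytic, times, targetPhase = pi / 2,
                                 threshold = 0) {
  ph <- analytic$phase
  env <- analytic$envelope
  if (is.null(dim(ph))) { ph <- matrix(ph, 1L); env <- matrix(env, 1L) }
  out <- vector("list", nrow(ph))
  for (ch in seq_len(nrow(ph))) {
    p <- ph[ch, ]
    if (anyNA(p)) { out[[ch]] <- NULL; next }
    u <- unwrapPhase(p)
    kmin <- ceiling((min(u) - targetPhase) / (2 * pi))
    kmax <- floor((max(u) - targetPhase) / (2 * pi))
    if (kmax < kmin) next
    ts <- c(); as <- c()
    n <- length(u)
    for (k in kmin:kmax) {
      target <- targetPhase + 2 * pi * k
      idx <- which(u[-n] < target & u[-1] >= target)
      if (!length(idx)) next
      frac <- (target - u[idx]) / (u[idx + 1] - u[idx])
      ts <- c(ts, times[idx] + frac * (times[idx + 1] - times[idx]))
      as <- c(as, env[ch, idx] + frac * (env[ch, idx + 1] - env[ch, idx]))
    }
    if (length(ts)) {
      keep <- as >= threshold
      if (any(keep))
        out[[ch]] <- data.frame(channel = ch, time = ts[keep],
                                amplitude = as[keep])
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(channel = integer(), time = numeric(),
                      amplitude = numeric())
  res[order(res$time), , drop = FALSE]
}

#' Estimate the noise amplitude threshold from pre-stimulus epochs
#'
#' Collects the envelope amplitudes of phase crossings occurring in the
#' pre-stimulus window of up to `nSampleTrials` randomly chosen trials and
#' returns `mean + 4*sd` of that distribution.  Crossings below this
#' threshold are treated as noise in subsequent analyses.
#'
#' @param trials list of [MEARecording-class] objects (or a single one).
#' @param band analysis band in Hz (default `c(0, 2)`).
#' @param preStimWindow numeric length 2: window before the stimulus, in s
#'   (default `c(0.5, 1.0)`, i.e. 0.5--1 s before stimulus onset).
#' @param nSampleTrials maximal number of trials sampled (default 100).
#' @param targetPhase target phase of the crossings (default \eqn{\pi/2}).
#' @param order Butterworth order (default 8).
#' @return threshold in uV, with the number of crossings used as attribute
#'   `"nCrossings"`.
#' @export
estimateNoiseThreshold <- function(trials, band = c(0, 2),
                                   preStimWindow = c(0.5, 1.0),
                                   nSampleTrials = 100L,
                                   targetPhase = pi / 2, order = 8L) {
  if (is(trials, "MEARecording")) trials <- list(trials)
  if (length(trials) > nSampleTrials)
    trials <- trials[sort(sample(length(trials), nSampleTrials))]
  amps <- unlist(lapply(trials, function(rec)
    preStimCrossingAmplitudes(rec, band, preStimWindow, targetPhase, order)))
  if (!length(amps))
    stop("no pre-stimulus phase crossings found; record a longer baseline")
  structure(mean(amps) + 4 * sd(amps), nCrossings = length(amps))
}

# envelope amplitudes of phase crossings inside the pre-stimulus window of
# one recording
preStimCrossingAmplitudes <- function(rec, band, preStimWindow, targetPhase,
                                      order = 8L) {
  stim <- stimTimes(rec)[1]
  filt <- applyFilter(lfp(rec), sampleRate(rec), band, order = order)
  an <- analyticSignal(filt)
  cr <- detectPhaseCrossings(an, lfpTimes(rec), targetPhase, threshold = 0)
  lo <- stim - preStimWindow[2]
  hi <- stim - preStimWindow[1]
  cr$amplitude[cr$time >= lo & cr$time <= hi]
}
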