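#' First spikes of each channel within a wave
#'
#' Using the wave's middle time T and width W, returns for every channel with
#' at least one spike in the interval \eqn{[T-W,\ T+W]} the earliest such
#' spike time (the channel's supra-threshold activation onset).  Channels
#' without spikes in the window are excluded; downstream comparisons restrict
#' the matching LFP sample to the same channel subset.
#'
#' @param spikes list of per-channel spike-time vectors (see [spikeTimes()]).
#' @param wave a [Wave-class].
#' @return data.frame with columns `channel`, `onset`; attribute `"window"`
#'   holds the interval used.
#' @export
firstSpikesInWave <- function(spikes, wave) {
  Tm <- waveMiddleTime(wave)
  W <- waveWidth(wave)
  lo <- Tm - W; hi <- Tm + W
  rows <- lapply(seq_along(spikes), function(ch) {
    s <- spikes[[ch]]
    s <- s[s >= lo & s <= hi]
    if (length(s)) data.frame(channel = ch, onset = min(s)) else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(channel = integer(), onset = numeric())
  structure(out, window = c(lo, hi))
}

#' Average local spiking activity (ALSA)
#'
#' A robust estimate of local supra-threshold excitability: each channel's
#' spike train is binned at the sample rate, convolved with a 100 ms boxcar,
#' smoothed with a Gaussian window of the same temporal width
#' (\eqn{\sigma} = 100 ms), and then averaged with its rook neighbors, each
#' neighbor carrying half the weight of the center channel:
#' \deqn{ALSA_i = \frac{S_i + \sum_{j \in nn(i)} S_j/2}{1 + \sum_{j \in nn(i)} 1/2}.}
#'
#' @param spikes list of per-channel spike-time vectors.
#' @param layout an [ElectrodeLayout-class].
#' @param duration recording duration in s.
#' @param sampleRate temporal resolution in Hz (default 1000).
#' @param boxcarMs boxcar width in ms (default 100).
#' @param gaussSigmaMs Gaussian sigma in ms (default 100).
#' @return matrix (channels x samples) of smoothed rates in spikes/s, with
#'   the smoothing parameters in attribute `"params"`.
#' @export
computeALSA <- function(spikes, layout, duration, sampleRate = 1000,
                        boxcarMs = 100, gaussSigmaMs = 100) {
  nch <- nChannels(layout)
  stopifnot(length(spikes) == nch)
  nt <- round(duration * sampleRate)
  wb <- max(1L, round(boxcarMs / 1000 * sampleRate))
  sg <- gaussSigmaMs / 1000 * sampleRate
  half <- ceiling(4 * sg)
  g <- exp(-((-half):half)^2 / (2 * sg^2))
  kern <- convolve(rep(1 / wb, wb) * sampleRate, rev(g / sum(g)), type = "open")
  S <- matrix(0, nch, nt)
  for (ch in seq_len(nch)) {
    s <- spikes[[ch]]
    if (!length(s)) next
    counts <- tabulate(pmin(pmax(floor(s * sampleRate) + 1L, 1L), nt), nt)
    sm <- convolve(counts, rev(kern), type = "open")
    off <- (length(kern) - 1L) %/% 2L
    S[ch, ] <- sm[off + seq_len(nt)]
  }
  nb <- neighborList(layout)
  out <- matrix(0, nch, nt)
  for (ch in seq_len(nch)) {
    nn <- nb[[ch]]
    out[ch, ] <- (S[ch, ] + colSums(S[nn, , drop = FALSE]) / 2) /
      (1 + length(nn) / 2)
  }
  out[out < 1e-9] <- 0     # clip fft-convolution round-off (rates ~1e-15)
  structure(out, params = list(sampleRate = sampleRate, boxcarMs = boxcarMs,
                               gaussSigmaMs = gaussSigmaMs))
}

#' ALSA onset times around a wave
#'
#' Per channel, the onset is the time of the first local maximum of its ALSA
#' trace within the window from half a wave duration before the wave start to
#' half a duration after its end, i.e. \eqn{[start - W/2,\ end + W/2]}.  A
#' local maximum is the first sample strictly greater than its predecessor
#' and not smaller than its successor (plateaus resolve to their first
#' sample).  Channels whose ALSA is flat zero in the window are excluded.
#'
#' @param alsa matrix from [computeALSA()].
#' @param wave a [Wave-class].
#' @param sampleRate temporal resolution of `alsa` in Hz (default taken from
#'   its `"params"` attribute).
#' @return data.frame with columns `channel`, `onset`; attribute `"window"`.
#' @export
alsaOnsets <- function(alsa, wave, sampleRate = NULL) {
  if (is.null(sampleRate)) sampleRate <- attr(alsa, "params")$sampleRate
  W <- waveWidth(wave)
  lo <- min(wave@crossings$time) - W / 2
  hi <- max(wave@crossings$time) + W / 2
  i0 <- max(1L, floor(lo * sampleRate) + 1L)
  i1 <- min(ncol(alsa), ceiling(hi * sampleRate))
  tt <- (seq(i0, i1) - 1L) / sampleRate
  rows <- lapply(seq_len(nrow(alsa)), function(ch) {
    v <- alsa[ch, i0:i1]
    if (all(v == 0)) return(NULL)
    n <- length(v)
    if (n < 3L) return(NULL)
    isMax <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
    if (!length(isMax)) return(NULL)
    i <- isMax[1]
    # sub-sample peak time by parabolic interpolation around the maximum
    den <- v[i - 1] - 2 * v[i] + v[i + 1]
    delta <- if (den < 0) 0.5 * (v[i - 1] - v[i + 1]) / den else 0
    delta <- max(-0.5, min(0.5, delta))
    data.frame(channel = ch, onset = tt[i] + delta / sampleRate)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(channel = integer(), onset = numeric())
  structure(out, window = c(lo, hi))
}

#' Spike-LFP phase locking
#'
#' Samples each channel's instantaneous LFP phase at its spike times, pools
#' the phases, and summarizes their distribution: a circular histogram, the
#' modal bin center, the circular mean and the resultant vector length R
#' (R near 0 for phases unrelated to the oscillation, near 1 for tight
#' locking).
#'
#' @param spikes list of per-channel spike-time vectors.
#' @param analytic output of [analyticSignal()] for the matching band.
#' @param times sample times of the analytic traces (s).
#' @param nBins histogram bins over \eqn{(-\pi, \pi]} (default 36).
#' @return list with `phases` (pooled, radians), `counts`, `binCenters`,
#'   `modalPhase`, `circularMean`, `resultantLength`, `n`.
#' @export
phaseLocking <- function(spikes, analytic, times, nBins = 36L) {
  ph <- analytic$phase
  if (is.null(dim(ph))) ph <- matrix(ph, 1L)
  pooled <- numeric(0)
  for (ch in seq_along(spikes)) {
    s <- spikes[[ch]]
    if (!length(s) || anyNA(ph[ch, ])) next
    # interpolate on the unit circle to avoid wrap artifacts
    re <- approx(times, cos(ph[ch, ]), xout = s, rule = 2)$y
    im <- approx(times, sin(ph[ch, ]), xout = s, rule = 2)$y
    pooled <- c(pooled, atan2(im, re))
  }
  breaks <- seq(-pi, pi, length.out = nBins + 1L)
  counts <- if (length(pooled))
    tabulate(findInterval(pooled, breaks, rightmost.closed = TRUE,
                          left.open = TRUE), nBins)
  else integer(nBins)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  n <- length(pooled)
  if (n) {
    mre <- mean(cos(pooled)); mim <- mean(sin(pooled))
    cm <- atan2(mim, mre); R <- sqrt(mre^2 + mim^2)
    modal <- centers[which.max(counts)]
  } else {
    cm <- NA_real_; R <- NA_real_; modal <- NA_real_
  }
  list(phases = pooled, counts = counts, binCenters = centers,
       modalPhase = modal, circularMean = cm, resultantLength = R, n = n)
}
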