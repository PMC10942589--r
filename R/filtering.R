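#' Zero-phase Butterworth filtering
#'
#' Filters each channel with the exact forward-backward (zero-phase)
#' Butterworth magnitude response, applied in the frequency domain after
#' symmetric zero padding of one trace length: the gain at frequency f is
#' \eqn{1/(1 + (f/f_c)^{2n})} for a low-pass corner \eqn{f_c} of order n
#' (squared magnitude of a single pass, i.e. the filtfilt response), and the
#' product of the high- and low-pass responses for a band-pass.  The phase
#' response is identically zero, so filtering introduces no frequency-
#' dependent delay -- a prerequisite for unbiased phase-latency maps.
#'
#' @param x numeric vector or matrix (channels x samples).
#' @param sampleRate sampling rate in Hz.
#' @param band numeric length 2: `c(0, fc)` is a low pass, `c(f1, f2)` with
#'   `f1 > 0` a band pass.  Corners must lie below the Nyquist frequency.
#' @param order Butterworth order per pass (default 8).
#' @param padFactor total zero padding as a multiple of the trace length
#'   (default 1, split evenly between the two ends).
#' @return filtered data with the same shape as `x`.
#' @examples
#' t <- (0:2999) / 1000
#' y <- applyFilter(sin(2 * pi * 1 * t), 1000, c(0, 2))
#' max(abs(y - sin(2 * pi * t)))   # passband: nearly unchanged
#' @export
applyFilter <- function(x, sampleRate, band = c(0, 2), order = 8L,
                        padFactor = 1) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  nyq <- sampleRate / 2
  if (band[2] >= nyq || band[2] <= 0)
    stop("upper corner must lie in (0, Nyquist)")
  if (band[1] < 0 || band[1] >= band[2])
    stop("band must satisfy 0 <= low < high")
  nt <- ncol(x)
  if (nt <= 3L * order) stop("trace too short for this filter order")
  npad <- ceiling(padFactor * nt / 2)
  ntot <- nt + 2L * npad
  X <- cbind(matrix(0, nrow(x), npad), x, matrix(0, nrow(x), npad))
  f <- c(seq_len(ceiling(ntot / 2)) - 1L,
         -rev(seq_len(floor(ntot / 2)))) * (sampleRate / ntot)
  af <- abs(f)
  gain <- 1 / (1 + (af / band[2])^(2 * order))
  if (band[1] > 0) {
    hp <- (af / band[1])^(2 * order)
    gain <- gain * hp / (1 + hp)
  }
  Fx <- stats::mvfft(t(X)) * gain            # ntot x channels; gain recycles
  Y <- t(Re(stats::mvfft(Fx, inverse = TRUE))) / ntot
  out <- Y[, npad + seq_len(nt), drop = FALSE]
  if (vec) out <- drop(out)
  out
}

#' Analytic signal: envelope and instantaneous phase
#'
#' Computes the analytic signal of each (band-limited) channel by the
#' frequency-domain Hilbert construction and returns the envelope (modulus)
#' and the wrapped instantaneous phase (argument).  Convention: for
#' \eqn{\cos(2\pi f t)} the phase is 0 at the peak and increases through
#' \eqn{\pi/2} a quarter period later.
#'
#' @param x numeric vector or matrix (channels x samples) of filtered traces.
#' @return list with `envelope` and `phase` (same shape as `x`; phase in
#'   \eqn{(-\pi, \pi]}), and `zeroChannels`, an integer vector of all-zero
#'   channels whose phase is undefined (their phase is set to `NA`).
#' @examples
#' t <- (0:999) / 1000
#' a <- analyticSignal(cos(2 * pi * 1 * t))
#' a$phase[1]          # 0 at the cosine peak
#' @export
analyticSignal <- function(x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  nt <- ncol(x)
  h <- numeric(nt)
  if (nt %% 2L == 0L) {
    h[1] <- 1; h[nt / 2 + 1] <- 1; h[2:(nt / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((nt + 1) / 2)] <- 2
  }
  A <- t(stats::mvfft(stats::mvfft(t(x)) * h, inverse = TRUE)) / nt
  env <- Mod(A)
  ph <- Arg(A)
  zero <- which(apply(x, 1L, function(r) all(r == 0)))
  if (length(zero)) ph[zero, ] <- NA_real_
  if (vec) {
    env <- drop(env); ph <- drop(ph)
  }
  list(envelope = env, phase = ph, zeroChannels = zero)
}

#' Welch power spectral density of evoked responses
#'
#' Estimates the PSD over a post-stimulus window by Welch's method: the
#' window is split into segments (1 s blocks with 0.5 s overlap by default),
#' each segment is Hamming-windowed and periodogram-averaged across segments,
#' channels and trials.
#'
#' @param trials an [MEARecording-class] or a list of them.
#' @param window numeric length 2: window relative to the stimulus, in s
#'   (default `c(0.25, 2.25)`).
#' @param segSeconds segment length in s (default 1).
#' @param overlapSeconds segment overlap in s (default 0.5).
#' @return data.frame with columns `freq` (Hz) and `power` (uV^2/Hz).
#' @export
welchPsd <- function(trials, window = c(0.25, 2.25), segSeconds = 1,
                     overlapSeconds = 0.5) {
  if (is(trials, "MEARecording")) trials <- list(trials)
  fs <- sampleRate(trials[[1]])
  nseg <- round(segSeconds * fs)
  step <- round((segSeconds - overlapSeconds) * fs)
  w <- 0.54 - 0.46 * cos(2 * pi * seq_len(nseg) / (nseg + 1))   # Hamming
  wnorm <- sum(w^2)
  acc <- NULL; nacc <- 0L
  for (rec in trials) {
    stim <- stimTimes(rec)[1]
    i0 <- round((stim + window[1]) * fs) + 1L
    i1 <- round((stim + window[2]) * fs)
    if (i1 > ncol(rec) || i0 < 1L)
      stop("analysis window exceeds the trial duration")
    seg0 <- seq(i0, i1 - nseg + 1L, by = step)
    if (!length(seg0)) stop("window shorter than one segment")
    X <- lfp(rec)
    for (s in seg0) {
      block <- X[, s:(s + nseg - 1L), drop = FALSE] * rep(w, each = nrow(X))
      P <- abs(stats::mvfft(t(block)))^2 / (wnorm * fs)
      keep <- seq_len(floor(nseg / 2) + 1L)
      P <- P[keep, , drop = FALSE]
      if (nseg %% 2L == 0L) P[c(-1L, -nrow(P)), ] <- 2 * P[c(-1L, -nrow(P)), ]
      else P[-1L, ] <- 2 * P[-1L, ]
      pseg <- rowMeans(P)
      acc <- if (is.null(acc)) pseg else acc + pseg
      nacc <- nacc + 1L
    }
  }
  freq <- (seq_len(floor(nseg / 2) + 1L) - 1L) * fs / nseg
  data.frame(freq = freq, power = acc / nacc)
}
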