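#' Pair of sequentially activated spatial Gaussian sources
#'
#' The elementary object of the analytic wave-like-pattern (WLP) model: two
#' spatial Gaussians (1D or 2D) whose amplitudes are modulated in time either
#' by temporal Gaussians (transient activation) or by a periodic factor
#' \eqn{\cos(2\pi f t - \phi_i)} (oscillatory activation with per-source phase
#' lag \eqn{\phi_i}).  The summed potential is
#' \deqn{V(x,t) = \sum_{i=1,2} a_i \, g_i(t) \,
#'   \exp\!\left(-\tfrac{(x-x_i)^2}{2\sigma_x^2}\right)}
#' with \eqn{g_i(t) = \exp(-(t-t_i)^2 / 2\sigma_t^2)} (Gaussian mode) or
#' \eqn{g_i(t) = \cos(2\pi f t - \phi_i)} (periodic mode).
#'
#' @slot centers numeric matrix, one source per row (1 or 2 columns).
#' @slot spatialScale list of length 2; per source either a positive scalar
#'   (1D standard deviation) or a 2x2 symmetric positive-definite covariance.
#' @slot temporalMode `"gaussian"` or `"periodic"`.
#' @slot temporalCenters numeric length 2 (\eqn{t_1}, \eqn{t_2}; Gaussian mode).
#' @slot temporalScale positive scalar \eqn{\sigma_t} (Gaussian mode).
#' @slot frequency positive scalar \eqn{f} in cycles per time unit
#'   (periodic mode).
#' @slot phases numeric length 2, per-source phase lags \eqn{\phi_i} in
#'   radians (periodic mode); the source with the larger lag activates later.
#' @slot amplitudes numeric length 2, dimensionless source amplitudes.
#' @seealso [sourcePair()], [evaluatePotential()], [trackPeak()]
#' @export
setClass("SourcePair",
  representation(
    centers = "matrix",
    spatialScale = "list",
    temporalMode = "character",
    temporalCenters = "numeric",
    temporalScale = "numeric",
    frequency = "numeric",
    phases = "numeric",
    amplitudes = "numeric"
  )
)

setValidity("SourcePair", function(object) {
  msg <- character()
  if (nrow(object@centers) != 2L)
    msg <- c(msg, "exactly two sources are required")
  if (!object@temporalMode %in% c("gaussian", "periodic"))
    msg <- c(msg, "temporalMode must be 'gaussian' or 'periodic'")
  d <- ncol(object@centers)
  for (i in 1:2) {
    s <- object@spatialScale[[i]]
    if (d == 1L) {
      if (!is.numeric(s) || length(s) != 1L || s <= 0)
        msg <- c(msg, "1D spatial scale must be a positive scalar")
    } else {
      if (!is.matrix(s) || any(dim(s) != c(2L, 2L)) ||
          max(abs(s - t(s))) > 1e-10 * max(abs(s), 1) ||
          any(eigen(s, symmetric = TRUE, only.values = TRUE)$values <= 0))
        msg <- c(msg, "2D spatial scale must be a symmetric positive-definite 2x2 covariance")
    }
  }
  if (object@temporalMode == "gaussian") {
    if (length(object@temporalCenters) != 2L)
      msg <- c(msg, "two temporal centers are required in gaussian mode")
    if (length(object@temporalScale) != 1L || object@temporalScale <= 0)
      msg <- c(msg, "temporalScale must be a positive scalar")
  } else {
    if (length(object@frequency) != 1L || object@frequency <= 0)
      msg <- c(msg, "frequency must be a positive scalar")
    if (length(object@phases) != 2L)
      msg <- c(msg, "two phases are required in periodic mode")
  }
  if (length(object@amplitudes) != 2L)
    msg <- c(msg, "two amplitudes are required")
  if (length(msg)) msg else TRUE
})

#' Construct a pair of sequentially activated Gaussian sources
#'
#' @param centers two source centers: numeric length 2 for a 1D model
#'   (positions \eqn{x_1}, \eqn{x_2}), or a 2x2 matrix (row per source) for 2D.
#' @param sigmaX spatial scale: a positive scalar shared by both sources, a
#'   numeric length 2, or (2D) a list of two 2x2 covariance matrices.
#' @param mode `"gaussian"` (transient activation at `t1`, `t2` with width
#'   `sigmaT`) or `"periodic"` (oscillation at `freq` with phase lags `phases`).
#' @param t1,t2 temporal activation centers (Gaussian mode).
#' @param sigmaT temporal standard deviation \eqn{\sigma_t} (Gaussian mode).
#' @param freq oscillation frequency \eqn{f} (periodic mode).
#' @param phases numeric length 2: per-source phase lags in radians (periodic
#'   mode).  The temporal factor is \eqn{\cos(2\pi f t - \phi_i)}, so the
#'   source with the larger \eqn{\phi} peaks later and
#'   \eqn{\Delta\phi = \phi_2 - \phi_1 > 0} yields forward propagation.
#' @param amplitudes numeric length 2, default `c(1, 1)`.
#' @return A [SourcePair-class] object.
#' @examples
#' p <- sourcePair(c(-0.5, 0.5), sigmaX = 1, t1 = -1, t2 = 1, sigmaT = 1)
#' evaluatePotential(p, x = 0, t = 0)   # 2 * exp(-0.625)
#' @export
sourcePair <- function(centers, sigmaX = 1,
                       mode = c("gaussian", "periodic"),
                       t1 = -1, t2 = 1, sigmaT = 1,
                       freq = 1, phases = c(0, pi / 4),
                       amplitudes = c(1, 1)) {
  mode <- match.arg(mode)
  if (is.matrix(centers)) {
    cen <- centers
  } else {
    stopifnot(length(centers) == 2L)
    cen <- matrix(centers, ncol = 1L)
  }
  d <- ncol(cen)
  if (is.list(sigmaX)) {
    sc <- sigmaX
  } else if (d == 1L) {
    s <- rep_len(as.numeric(sigmaX), 2L)
    sc <- list(s[1], s[2])
  } else {
    sc <- list(diag(sigmaX^2, 2L), diag(sigmaX^2, 2L))
  }
  new("SourcePair",
      centers = cen, spatialScale = sc, temporalMode = mode,
      temporalCenters = c(t1, t2), temporalScale = sigmaT,
      frequency = freq, phases = phases, amplitudes = amplitudes)
}

setMethod("show", "SourcePair", function(object) {
  d <- ncol(object@centers)
  cat(sprintf("SourcePair (%dD, %s temporal mode)\n", d, object@temporalMode))
  for (i in 1:2) {
    cat(sprintf("  source %d: center (%s), amplitude %g", i,
                paste(signif(object@centers[i, ], 4), collapse = ", "),
                object@amplitudes[i]))
    if (object@temporalMode == "gaussian")
      cat(sprintf(", t_i = %g, sigma_t = %g\n",
                  object@temporalCenters[i], object@temporalScale))
    else
      cat(sprintf(", f = %g, phase lag = %g rad\n",
                  object@frequency, object@phases[i]))
  }
  invisible(object)
})

#' Regular multi-electrode-array layout
#'
#' A planar rectangular grid of electrodes with fixed pitch, the geometry of
#' the recordings this package emulates (100 um pitch MEA).  Channels are
#' numbered row-major: channel of (row r, column c) is `(r-1)*nCols + c`.
#'
#' @slot nRows,nCols integer grid dimensions.
#' @slot pitch electrode spacing in mm.
#' @slot positions numeric matrix (channels x 2) of (x, y) positions in mm.
#' @seealso [electrodeLayout()], [neighborList()]
#' @export
setClass("ElectrodeLayout",
  representation(nRows = "integer", nCols = "integer",
                 pitch = "numeric", positions = "matrix"))

setValidity("ElectrodeLayout", function(object) {
  n <- object@nRows * object@nCols
  if (nrow(object@positions) != n)
    return("positions must have nRows*nCols rows")
  expected <- cbind(
    rep((seq_len(object@nCols) - 1) * object@pitch, times = object@nRows),
    rep((seq_len(object@nRows) - 1) * object@pitch, each = object@nCols))
  if (max(abs(object@positions - expected)) > 1e-9)
    return("positions inconsistent with rows x cols x pitch")
  TRUE
})

#' Construct a rectangular electrode layout
#'
#' @param nRows,nCols grid dimensions.
#' @param pitch electrode spacing in mm (default 0.1, i.e. 100 um).
#' @return An [ElectrodeLayout-class].
#' @examples
#' lay <- electrodeLayout(12, 10)
#' nChannels(lay)
#' @export
electrodeLayout <- function(nRows = 12L, nCols = 10L, pitch = 0.1) {
  nRows <- as.integer(nRows); nCols <- as.integer(nCols)
  pos <- cbind(
    x = rep((seq_len(nCols) - 1) * pitch, times = nRows),
    y = rep((seq_len(nRows) - 1) * pitch, each = nCols))
  new("ElectrodeLayout", nRows = nRows, nCols = nCols, pitch = pitch,
      positions = pos)
}

#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Number of channels
#' @param x an [ElectrodeLayout-class] or [MEARecording-class].
#' @return integer channel count.
#' @export
setMethod("nChannels", "ElectrodeLayout", function(x) x@nRows * x@nCols)

#' Rook-adjacency neighbor lists of a grid layout
#'
#' Each channel's neighbors are the up-to-four channels sharing a grid edge
#' (4 for interior channels, 3 on edges, 2 at corners), the adjacency used
#' both for wave flood-fill clustering and for the ALSA spatial weighting.
#'
#' @param layout an [ElectrodeLayout-class].
#' @return list of integer vectors, one per channel.
#' @export
neighborList <- function(layout) {
  nr <- layout@nRows; nc <- layout@nCols
  lapply(seq_len(nr * nc), function(ch) {
    r <- (ch - 1L) %/% nc + 1L
    c <- (ch - 1L) %% nc + 1L
    nb <- integer()
    if (r > 1L)  nb <- c(nb, ch - nc)
    if (r < nr)  nb <- c(nb, ch + nc)
    if (c > 1L)  nb <- c(nb, ch - 1L)
    if (c < nc)  nb <- c(nb, ch + 1L)
    nb
  })
}

setMethod("show", "ElectrodeLayout", function(object) {
  cat(sprintf("ElectrodeLayout: %d x %d grid, pitch %g mm (%d channels)\n",
              object@nRows, object@nCols, object@pitch, nChannels(object)))
  invisible(object)
})

#' Multi-electrode-array recording container
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with one assay `lfp`
#' (channels x samples, microvolts); `rowData` holds the electrode grid
#' coordinates, and `metadata` holds the sample rate, stimulus times, spike
#' trains (one sorted numeric vector of spike times per channel), the layout
#' object, the generator's ground truth (if synthetic) and the seed used.
#'
#' @seealso [generateRecording()], [writeRecording()], [readRecording()]
#' @export
setClass("MEARecording", contains = "SummarizedExperiment")

setValidity("MEARecording", function(object) {
  msg <- character()
  if (!"lfp" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'lfp' is required")
  else if (!all(is.finite(SummarizedExperiment::assay(object, "lfp"))))
    msg <- c(msg, "LFP must be finite")
  md <- metadata(object)
  for (f in c("sampleRate", "stimTimes", "duration", "spikes"))
    if (is.null(md[[f]])) msg <- c(msg, sprintf("metadata field '%s' is required", f))
  if (!is.null(md$spikes) && !is.null(md$duration)) {
    rng <- range(c(0, unlist(md$spikes, use.names = FALSE)))
    if (rng[1] < 0 || rng[2] > md$duration)
      msg <- c(msg, "spike times must lie within [0, duration]")
  }
  if (length(msg)) msg else TRUE
})

#' @export
setGeneric("lfp", function(x) standardGeneric("lfp"))
#' LFP matrix (channels x samples, microvolts)
#' @param x an [MEARecording-class].
#' @return numeric matrix.
#' @export
setMethod("lfp", "MEARecording", function(x) SummarizedExperiment::assay(x, "lfp"))

#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))
#' Per-channel spike time lists (seconds)
#' @param x an [MEARecording-class].
#' @return list of sorted numeric vectors, one per channel.
#' @export
setMethod("spikeTimes", "MEARecording", function(x) metadata(x)$spikes)

#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' Sampling rate in Hz
#' @param x an [MEARecording-class].
#' @return numeric scalar.
#' @export
setMethod("sampleRate", "MEARecording", function(x) metadata(x)$sampleRate)

#' @export
setGeneric("stimTimes", function(x) standardGeneric("stimTimes"))
#' Stimulus onset times (seconds)
#' @param x an [MEARecording-class].
#' @return numeric vector.
#' @export
setMethod("stimTimes", "MEARecording", function(x) metadata(x)$stimTimes)

#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' Generator ground truth (synthetic recordings)
#' @param x an [MEARecording-class].
#' @return list with module labels, onsets, inter-module delay and spike
#'   parameters, or `NULL` for recordings without ground truth.
#' @export
setMethod("groundTruth", "MEARecording", function(x) metadata(x)$groundTruth)

#' @export
setGeneric("recordingLayout", function(x) standardGeneric("recordingLayout"))
#' Electrode layout of a recording
#' @param x an [MEARecording-class].
#' @return [ElectrodeLayout-class].
#' @export
setMethod("recordingLayout", "MEARecording", function(x) metadata(x)$layout)

#' @describeIn nChannels channel count of a recording.
#' @export
setMethod("nChannels", "MEARecording", function(x) nrow(x))

#' @export
setGeneric("recordingDuration", function(x) standardGeneric("recordingDuration"))
#' Trial duration (seconds)
#' @param x an [MEARecording-class].
#' @return numeric scalar.
#' @export
setMethod("recordingDuration", "MEARecording", function(x) metadata(x)$duration)

#' Time axis of a recording
#' @param rec an [MEARecording-class].
#' @return numeric vector of sample times in seconds, starting at 0.
#' @export
lfpTimes <- function(rec) {
  (seq_len(ncol(rec)) - 1L) / sampleRate(rec)
}

setMethod("show", "MEARecording", function(object) {
  md <- metadata(object)
  cat(sprintf("MEARecording: %d channels x %d samples at %g Hz (%.2f s)\n",
              nrow(object), ncol(object), md$sampleRate, md$duration))
  cat(sprintf("  stimuli at %s s; %d spikes total%s\n",
              paste(signif(md$stimTimes, 4), collapse = ", "),
              length(unlist(md$spikes, use.names = FALSE)),
              if (!is.null(md$groundTruth)) "; ground truth attached" else ""))
  invisible(object)
})

#' A detected wave: spatiotemporally connected phase crossings
#'
#' A set of amplitude-thresholded phase crossings grouped by the flood-fill
#' rule (neighboring channels with crossings within the band-specific temporal
#' window).  The middle time is \eqn{T = (t_{first}+t_{last})/2} and the
#' width \eqn{W = t_{last}-t_{first}}; spike-based onset analyses use the
#' interval \eqn{[T-W, T+W]}.
#'
#' @slot crossings data.frame with columns `channel`, `time`, `amplitude`,
#'   `first` (logical, first crossing of its channel within the wave).
#' @slot window temporal flood-fill window (s).
#' @slot band numeric length 2, analysis band (Hz).
#' @export
setClass("Wave",
  representation(crossings = "data.frame", window = "numeric",
                 band = "numeric"))

setValidity("Wave", function(object) {
  cr <- object@crossings
  need <- c("channel", "time", "amplitude", "first")
  if (!all(need %in% names(cr)))
    return("crossings needs columns channel, time, amplitude, first")
  if (nrow(cr) < 1L) return("a wave holds at least one crossing")
  TRUE
})

#' @export
setGeneric("waveChannels", function(x) standardGeneric("waveChannels"))
#' Channels recruited by a wave
#' @param x a [Wave-class].
#' @return sorted integer vector of channel ids.
#' @export
setMethod("waveChannels", "Wave", function(x) sort(unique(x@crossings$channel)))

#' @export
setGeneric("waveStartTime", function(x) standardGeneric("waveStartTime"))
#' Earliest crossing time of a wave
#' @param x a [Wave-class].
#' @return numeric scalar (s).
#' @export
setMethod("waveStartTime", "Wave", function(x) min(x@crossings$time))

#' @export
setGeneric("waveWidth", function(x) standardGeneric("waveWidth"))
#' Wave width W = last - first crossing time
#' @param x a [Wave-class].
#' @return numeric scalar (s).
#' @export
setMethod("waveWidth", "Wave", function(x) diff(range(x@crossings$time)))

#' @export
setGeneric("waveMiddleTime", function(x) standardGeneric("waveMiddleTime"))
#' Wave middle time T = (first + last crossing time)/2
#' @param x a [Wave-class].
#' @return numeric scalar (s).
#' @export
setMethod("waveMiddleTime", "Wave", function(x) mean(range(x@crossings$time)))

setMethod("show", "Wave", function(object) {
  cat(sprintf("Wave: %d crossings on %d channels, t = [%.4f, %.4f] s (window %g s)\n",
              nrow(object@crossings), length(waveChannels(object)),
              min(object@crossings$time), max(object@crossings$time),
              object@window))
  invisible(object)
})

#' Dip-test result
#'
#' Hartigan's dip statistic for a one-dimensional sample together with its
#' bootstrap p-value under the uniform null (the worst-case unimodal
#' distribution).
#'
#' @slot statistic the dip, in \eqn{[1/(2n), 1/4]} for non-degenerate samples.
#' @slot pValue bootstrap p-value, floored at `1/(nBoot+1)`.
#' @slot n sample size.
#' @slot nBoot number of bootstrap draws (0 if no p-value was computed).
#' @slot seed seed used for the bootstrap (NA if none).
#' @seealso [dipStatistic()], [dipPValue()]
#' @export
setClass("DipResult",
  representation(statistic = "numeric", pValue = "numeric",
                 n = "integer", nBoot = "integer", seed = "numeric"))

setValidity("DipResult", function(object) {
  if (object@statistic < 0 || object@statistic > 0.25 + 1e-12)
    return("dip must lie in [0, 0.25]")
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    return("p-value must lie in [0, 1]")
  TRUE
})

setMethod("show", "DipResult", function(object) {
  cat(sprintf("DipResult: dip = %.5f (n = %d)", object@statistic, object@n))
  if (!is.na(object@pValue))
    cat(sprintf(", p = %.4g (%d uniform bootstrap draws, seed %s)",
                object@pValue, object@nBoot, format(object@seed)))
  cat("\n")
  invisible(object)
})
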