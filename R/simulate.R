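#' Specification of one activation module
#'
#' A module is a spatially contiguous set of channels that spikes together,
#' plus the (wider) LFP footprint its synaptic currents project onto the
#' array through volume conduction.  The footprint is an isotropic 2D
#' Gaussian centered on the module's centroid whose standard deviation is
#' `spreadFactor` times the spatial spread of the member channels, so LFP
#' from neighboring modules overlaps while spiking stays segregated.
#'
#' @slot channels integer vector of member channel ids (spiking membership).
#' @slot delay onset delay relative to stimulus + response latency (s).
#' @slot frequency oscillation frequency (Hz).
#' @slot amplitude oscillation amplitude (uV).
#' @slot spreadFactor LFP footprint sigma as a multiple of the module's
#'   spiking spatial spread.
#' @export
setClass("ModuleSpec",
  representation(channels = "integer", delay = "numeric",
                 frequency = "numeric", amplitude = "numeric",
                 spreadFactor = "numeric"))

setValidity("ModuleSpec", function(object) {
  msg <- character()
  if (length(object@channels) < 1L) msg <- c(msg, "a module needs channels")
  if (object@delay < 0) msg <- c(msg, "delay must be >= 0")
  if (object@frequency <= 0) msg <- c(msg, "frequency must be positive")
  if (object@amplitude < 0) msg <- c(msg, "amplitude must be >= 0")
  if (object@spreadFactor <= 0) msg <- c(msg, "spreadFactor must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a module specification
#'
#' @param channels integer vector of member channel ids.
#' @param delay onset delay relative to stimulus + response latency (s).
#' @param frequency oscillation frequency (Hz, default 1).
#' @param amplitude oscillation amplitude (uV, default 100).
#' @param spreadFactor LFP footprint spread multiple (default 2).
#' @return a [ModuleSpec-class].
#' @export
moduleSpec <- function(channels, delay = 0, frequency = 1, amplitude = 100,
                       spreadFactor = 2) {
  new("ModuleSpec", channels = as.integer(channels), delay = delay,
      frequency = frequency, amplitude = amplitude,
      spreadFactor = spreadFactor)
}

#' Configuration of a synthetic MEA recording
#'
#' Holds everything needed to generate one trial: the electrode layout, the
#' sampling and stimulus timing, the activation modules, the additive noise
#' level and the phase-locked spike model.  Defaults emulate visually evoked
#' responses of an ex vivo cortical preparation on a 100 um-pitch MEA:
#' responses start about 200 ms after the stimulus, last about 2 s (two
#' cycles at 1 Hz, dominant power below 2 Hz), and spikes lock to the LFP
#' with peak rate at phase `0.53*pi`.
#'
#' @slot layout an [ElectrodeLayout-class].
#' @slot sampleRate sampling rate (Hz).
#' @slot duration trial duration (s).
#' @slot stimTime stimulus time (s).
#' @slot responseLatency response latency after the stimulus (s).
#' @slot modules list of [ModuleSpec-class] objects.
#' @slot nCycles oscillation cycles per module activation.
#' @slot noiseSd white LFP noise standard deviation (uV).
#' @slot baselineRate,peakRate spike rates (Hz) at trough/preferred phase
#'   inside the module's active window.
#' @slot preferredPhase preferred LFP phase of spiking (radians).
#' @slot kappa von Mises phase concentration of the spike rate.
#' @export
setClass("RecordingConfig",
  representation(layout = "ElectrodeLayout", sampleRate = "numeric",
                 duration = "numeric", stimTime = "numeric",
                 responseLatency = "numeric", modules = "list",
                 nCycles = "numeric", noiseSd = "numeric",
                 baselineRate = "numeric", peakRate = "numeric",
                 preferredPhase = "numeric", kappa = "numeric"))

setValidity("RecordingConfig", function(object) {
  msg <- character()
  if (!length(object@modules)) msg <- c(msg, "at least one module is required")
  fmax <- max(vapply(object@modules, function(m) m@frequency, 0))
  if (object@sampleRate < 4 * fmax)
    msg <- c(msg, "sampleRate must be at least 4x the highest module frequency")
  tEnd <- object@stimTime + object@responseLatency +
    max(vapply(object@modules, function(m)
      m@delay + object@nCycles / m@frequency, 0))
  if (object@duration < tEnd)
    msg <- c(msg, "duration must cover stimulus + latency + module activations")
  nch <- nChannels(object@layout)
  for (m in object@modules)
    if (any(m@channels < 1L | m@channels > nch))
      msg <- c(msg, "module channels outside the layout")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@peakRate < object@baselineRate)
    msg <- c(msg, "peakRate must be >= baselineRate")
  if (object@kappa < 0) msg <- c(msg, "kappa must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a recording configuration
#'
#' With `modules = NULL` the layout is split into two spatially contiguous
#' half-array modules (left and right column blocks) activated `interModuleDelay`
#' apart -- the canonical two-module condition.  With `singleModule = TRUE`
#' one module spans the whole array (the continuous control condition).
#'
#' @param layout an [ElectrodeLayout-class] (default 12 x 10 grid at 0.1 mm).
#' @param sampleRate sampling rate in Hz (default 1000).
#' @param duration trial length in s (default 5).
#' @param stimTime stimulus time in s (default 1.5).
#' @param responseLatency response latency in s (default 0.2).
#' @param modules list of [ModuleSpec-class], or `NULL` for the defaults.
#' @param interModuleDelay delay between the two default modules in s
#'   (default 0.28).
#' @param obliqueSlope slope of the oblique split axis (y-weight relative to
#'   x) for the default two modules (default 1.15, roughly the array diagonal).  Cortical waves cross
#'   the array obliquely; an oblique axis also makes the per-channel
#'   latencies distinct rather than collapsing onto the few grid columns.
#' @param singleModule logical; build the one-module control instead.
#' @param frequency,amplitude,spreadFactor passed to the default modules.
#' @param nCycles oscillation cycles per activation (default 2).
#' @param noiseSd LFP noise sd in uV (default 10).
#' @param baselineRate,peakRate spike rates in Hz (defaults 0.2 and 20).
#' @param preferredPhase preferred spiking phase in radians
#'   (default `0.53 * pi`).
#' @param kappa von Mises concentration (default 4).
#' @return a [RecordingConfig-class].
#' @examples
#' cfg <- recordingConfig()
#' cfg
#' @export
recordingConfig <- function(layout = electrodeLayout(12L, 10L, 0.1),
                            sampleRate = 1000, duration = 5, stimTime = 1.5,
                            responseLatency = 0.2, modules = NULL,
                            interModuleDelay = 0.28, obliqueSlope = 1.15,
                            singleModule = FALSE,
                            frequency = 1, amplitude = 100, spreadFactor = 2,
                            nCycles = 2, noiseSd = 10,
                            baselineRate = 0.2, peakRate = 20,
                            preferredPhase = 0.53 * pi, kappa = 4) {
  if (is.null(modules)) {
    if (singleModule) {
      modules <- list(moduleSpec(seq_len(nChannels(layout)), delay = 0,
                                 frequency = frequency, amplitude = amplitude,
                                 spreadFactor = spreadFactor))
    } else {
      # split the array into two contiguous halves along an oblique axis
      q <- layout@positions[, 1] + obliqueSlope * layout@positions[, 2]
      first <- which(q <= stats::median(q))
      second <- setdiff(seq_len(nChannels(layout)), first)
      modules <- list(
        moduleSpec(first, delay = 0, frequency = frequency,
                   amplitude = amplitude, spreadFactor = spreadFactor),
        moduleSpec(second, delay = interModuleDelay, frequency = frequency,
                   amplitude = amplitude, spreadFactor = spreadFactor))
    }
  }
  new("RecordingConfig", layout = layout, sampleRate = sampleRate,
      duration = duration, stimTime = stimTime,
      responseLatency = responseLatency, modules = modules,
      nCycles = nCycles, noiseSd = noiseSd, baselineRate = baselineRate,
      peakRate = peakRate, preferredPhase = preferredPhase, kappa = kappa)
}

setMethod("show", "RecordingConfig", function(object) {
  cat(sprintf("RecordingConfig: %d modules on a %d x %d grid, %g Hz, %g s\n",
              length(object@modules), object@layout@nRows,
              object@layout@nCols, object@sampleRate, object@duration))
  for (i in seq_along(object@modules)) {
    m <- object@modules[[i]]
    cat(sprintf("  module %d: %d channels, delay %g s, %g Hz, %g uV\n",
                i, length(m@channels), m@delay, m@frequency, m@amplitude))
  }
  invisible(object)
})

# per-axis spatial spread (mm) of a set of channel positions
moduleSpatialSigma <- function(positions) {
  apply(positions, 2L, sd)
}

# windowed oscillation template: sin(2 pi f tau) under a Hann envelope over
# the active window [0, nCycles/f]; zero outside
oscTemplate <- function(tau, frequency, nCycles) {
  Tact <- nCycles / frequency
  inside <- tau >= 0 & tau <= Tact
  out <- numeric(length(tau))
  out[inside] <- sin(2 * pi * frequency * tau[inside]) *
    0.5 * (1 - cos(2 * pi * tau[inside] / Tact))
  out
}

# deterministic per-channel substream seed (< 2^31), so adding channels or
# trials never perturbs other draws
channelSeed <- function(seed, channel) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(channel)) %% 2147483587 + 1)
}

#' Generate one synthetic MEA recording
#'
#' Per channel, the clean LFP is the footprint-weighted sum of the modules'
#' windowed oscillations, each starting at
#' `stimTime + responseLatency + delay_m`; white Gaussian noise is added on
#' top.  Spikes are drawn (per 1-sample bin) as an inhomogeneous Bernoulli
#' approximation of a Poisson process whose rate is
#' `baseline + (peak - baseline) * exp(kappa * (cos(phi - preferredPhase) - 1))`
#' with `phi` the ideal instantaneous phase of the channel's own module
#' oscillation; the rate is zero outside the module's active window and on
#' channels outside the module.  Each channel consumes an independent RNG
#' substream derived from `seed`, so the same seed reproduces the recording
#' bit for bit.
#'
#' @param config a [RecordingConfig-class].
#' @param seed integer master seed for this trial.
#' @return an [MEARecording-class] with ground truth attached.
#' @examples
#' rec <- generateRecording(recordingConfig(), seed = 1)
#' rec
#' @export
generateRecording <- function(config, seed = 1L) {
  stopifnot(is(config, "RecordingConfig"))
  validObject(config)
  lay <- config@layout
  nch <- nChannels(lay)
  fs <- config@sampleRate
  nt <- round(config@duration * fs)
  tt <- (seq_len(nt) - 1L) / fs
  pos <- lay@positions

  nmod <- length(config@modules)
  onsets <- numeric(nmod)
  weights <- matrix(0, nch, nmod)     # LFP footprint weight per channel
  templates <- matrix(0, nt, nmod)    # windowed oscillation per module
  for (m in seq_len(nmod)) {
    mod <- config@modules[[m]]
    onsets[m] <- config@stimTime + config@responseLatency + mod@delay
    sigMod <- pmax(moduleSpatialSigma(pos[mod@channels, , drop = FALSE]),
                   lay@pitch / 2)
    sigLfp <- mod@spreadFactor * sigMod      # anisotropic footprint
    centroid <- colMeans(pos[mod@channels, , drop = FALSE])
    dx <- sweep(pos, 2L, centroid)
    weights[, m] <- exp(-(dx[, 1]^2 / sigLfp[1]^2 +
                          dx[, 2]^2 / sigLfp[2]^2) / 2)
    templates[, m] <- mod@amplitude *
      oscTemplate(tt - onsets[m], mod@frequency, config@nCycles)
  }
  clean <- weights %*% t(templates)   # channels x samples

  # module label per channel: first module whose spiking set contains it
  labels <- rep(NA_integer_, nch)
  for (m in seq_len(nmod))
    labels[config@modules[[m]]@channels[
      is.na(labels[config@modules[[m]]@channels])]] <- m

  lfpMat <- clean
  spikes <- vector("list", nch)
  dt <- 1 / fs
  for (ch in seq_len(nch)) {
    set.seed(channelSeed(seed, ch))
    if (config@noiseSd > 0)
      lfpMat[ch, ] <- lfpMat[ch, ] + rnorm(nt, sd = config@noiseSd)
    m <- labels[ch]
    if (!is.na(m)) {
      mod <- config@modules[[m]]
      tau <- tt - onsets[m]
      active <- tau >= 0 & tau <= config@nCycles / mod@frequency
      phi <- 2 * pi * mod@frequency * tau - pi / 2   # phase of sin()
      rate <- numeric(nt)
      rate[active] <- config@baselineRate +
        (config@peakRate - config@baselineRate) *
        exp(config@kappa * (cos(phi[active] - config@preferredPhase) - 1))
      p <- pmin(rate * dt, 1)
      hits <- which(runif(nt) < p)
      # a Poisson point is uniform within its bin given locally constant rate
      spikes[[ch]] <- sort(tt[hits] + runif(length(hits)) * dt)
    } else {
      spikes[[ch]] <- numeric(0)
    }
  }

  gt <- list(
    moduleLabels = labels,
    moduleOnsets = onsets,
    interModuleDelay = if (nmod >= 2L) diff(onsets[1:2]) else 0,
    spikeParams = list(baselineRate = config@baselineRate,
                       peakRate = config@peakRate,
                       preferredPhase = config@preferredPhase,
                       kappa = config@kappa),
    moduleFrequencies = vapply(config@modules, function(m) m@frequency, 0),
    cleanLfp = clean
  )
  se <- SummarizedExperiment(
    assays = list(lfp = lfpMat),
    rowData = DataFrame(channel = seq_len(nch),
                        x = pos[, 1], y = pos[, 2]))
  metadata(se) <- list(sampleRate = fs, stimTimes = config@stimTime,
                       duration = config@duration, spikes = spikes,
                       layout = lay, groundTruth = gt, seed = seed)
  as(se, "MEARecording")
}

#' Generate a list of independent trials
#'
#' Trial `i` uses the seed `seed + i - 1` (a counter off the master seed), so
#' the whole list is reproducible and each trial is independent.
#'
#' @param config a [RecordingConfig-class].
#' @param nTrials number of trials (>= 1).
#' @param seed master seed.
#' @return list of [MEARecording-class] objects.
#' @export
generateTrials <- function(config, nTrials, seed = 1L) {
  stopifnot(nTrials >= 1)
  lapply(seq_len(nTrials), function(i)
    generateRecording(config, seed = seed + i - 1L))
}
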