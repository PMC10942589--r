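#' Run a full synthetic-MEA experiment
#'
#' Orchestrates the complete analysis chain on freshly generated trials:
#' noise-threshold calibration from pre-stimulus epochs, band filtering,
#' analytic-signal phase, amplitude-thresholded pi/2 phase crossings,
#' flood-fill wave detection, recruitment-based wave selection,
#' phase-latency map and PLDC (plus a shuffled-latency control per trial),
#' wave center path and speed, ALSA onsets and first spikes, and the paired
#' LFP-vs-onset dip comparison.  Everything is reproducible from
#' `(config, seed)`: trial i uses seed `seed + i - 1`, and the analysis RNG
#' (shuffles, bootstrap) is derived from `seed`.
#'
#' @param config a [RecordingConfig-class].
#' @param nTrials number of trials (default 100).
#' @param band analysis band in Hz (default `c(0, 2)`).
#' @param windowS flood-fill window in s (default 0.1 for the 0--2 Hz band;
#'   use 0.002 for 12--35 Hz).
#' @param selectFraction minimal recruited channel fraction (default 2/3).
#' @param nBoot dip bootstrap draws (default 500).
#' @param seed master seed (default 1).
#' @param nThresholdTrials trials used for threshold calibration
#'   (default `min(nTrials, 100)`).
#' @return list with elements `trials` (per-trial data.frame: wave counts,
#'   PLDC, shuffled PLDC, speed), `dipSpikes` and `dipAlsa` (outputs of
#'   [pairedComparison()]), `threshold`, `nTrials`, `seed` and `band`.
#' @export
runExperiment <- function(config, nTrials = 100L, band = c(0, 2),
                          windowS = 0.1, selectFraction = 2 / 3,
                          nBoot = 500L, seed = 1L,
                          nThresholdTrials = min(nTrials, 100L)) {
  stopifnot(is(config, "RecordingConfig"), nTrials >= 1)
  lay <- config@layout

  # pass 1: noise threshold from the pre-stimulus epochs of the first trials
  amps <- unlist(lapply(seq_len(nThresholdTrials), function(i) {
    rec <- generateRecording(config, seed = seed + i - 1L)
    preStimCrossingAmplitudes(rec, band, c(0.5, 1.0), pi / 2)
  }))
  if (!length(amps))
    stop("no pre-stimulus phase crossings found; record a longer baseline")
  threshold <- mean(amps) + 4 * sd(amps)

  # pass 2: per-trial analysis (trials regenerated from their seeds)
  rows <- list()
  wavesKept <- list(); spikeOnsets <- list(); alsaOnsetsL <- list()
  for (i in seq_len(nTrials)) {
    rec <- generateRecording(config, seed = seed + i - 1L)
    filt <- applyFilter(lfp(rec), sampleRate(rec), band)
    an <- analyticSignal(filt)
    tt <- lfpTimes(rec)
    cross <- detectPhaseCrossings(an, tt, pi / 2, threshold)
    # restrict to the evoked epoch (noise crossings before the stimulus
    # cannot belong to the response)
    cross <- cross[cross$time >= stimTimes(rec)[1], , drop = FALSE]
    waves <- clusterCrossings(cross, lay, window = windowS, band = band)
    sel <- selectWaves(waves, lay, "fraction", fraction = selectFraction)
    if (!length(sel)) {
      rows[[i]] <- data.frame(trial = i, nWaves = length(waves),
                              nSelected = 0L, waveChannels = NA_integer_,
                              pldc = NA_real_, pldcShuffled = NA_real_,
                              speed = NA_real_)
      next
    }
    w <- sel[[1]]                      # first oscillation cycle
    plm <- computePLM(w, lay)
    pldc <- computePLDC(plm)
    set.seed(seed + 500003L + i)
    plmSh <- plm
    plmSh$latency <- sample(plmSh$latency)
    pldcSh <- computePLDC(plmSh)
    wcp <- computeWCP(w, lay, sampleRate = sampleRate(rec))
    spd <- estimateSpeed(wcp)
    alsa <- computeALSA(spikeTimes(rec), lay, metadata(rec)$duration,
                        sampleRate = sampleRate(rec))
    rows[[i]] <- data.frame(trial = i, nWaves = length(waves),
                            nSelected = length(sel),
                            waveChannels = length(waveChannels(w)),
                            pldc = pldc, pldcShuffled = pldcSh, speed = spd)
    k <- length(wavesKept) + 1L
    wavesKept[[k]] <- w
    spikeOnsets[[k]] <- firstSpikesInWave(spikeTimes(rec), w)
    alsaOnsetsL[[k]] <- alsaOnsets(alsa, w)
  }
  trialsDf <- do.call(rbind, rows)
  dipSpikes <- pairedComparison(wavesKept, spikeOnsets, nBoot = nBoot,
                                seed = seed + 900001L)
  dipAlsa <- pairedComparison(wavesKept, alsaOnsetsL, nBoot = nBoot,
                              seed = seed + 900002L)
  list(trials = trialsDf, dipSpikes = dipSpikes, dipAlsa = dipAlsa,
       threshold = threshold, nTrials = nTrials, seed = seed, band = band)
}

#' Run the analytic-model suite
#'
#' Executes the model-side analyses in one call: the concavity-boundary scan
#' (separation ratio at which the mid-time profile turns convex), the
#' temporal-unimodality scan (delay ratio at which the mid-point trace splits
#' into two peaks), the mid-point velocity curve against separation, the PLDC
#' grid over (separation, delay), and the three-pattern zoo with the PLDC of
#' the radial pattern.
#'
#' @param boundaryStep scan step for the two boundary scans (default 1e-3).
#' @param dxValues separations for the velocity curve and PLDC grid
#'   (defaults `seq(0.25, 3, by = 0.25)`).
#' @param delayValues delays for the PLDC grid (default `c(0.5, 1, 2)`).
#' @return list with `concavityBoundary`, `unimodalityBoundary`,
#'   `velocityCurve` (data.frame `dx`, `velocity`), `pldcGrid` (matrix),
#'   `patterns` (list of latency maps) and `radialPldc`.
#' @export
runModelSuite <- function(boundaryStep = 1e-3,
                          dxValues = seq(0.25, 3, by = 0.25),
                          delayValues = c(0.5, 1, 2)) {
  ratios <- seq(0.1, 4, by = boundaryStep)
  cb <- concavityBoundary(ratios)
  ub <- unimodalityBoundary(ratios)
  vdx <- dxValues[dxValues < 2]
  vel <- vapply(vdx, function(dx) peakVelocityGaussian(dx, 1, 1, 1), 0)
  grid <- pldcScan(dxValues, delayValues)
  pats <- lapply(c(plane = "plane", radial = "radial",
                   spiral_like = "spiral_like"), function(k)
    modelLatencyMap(makePattern(k),
                    distance = if (k == "radial") "radial" else "axis"))
  radialPldc <- computePLDC(pats$radial)
  list(concavityBoundary = cb, unimodalityBoundary = ub,
       velocityCurve = data.frame(dx = vdx, velocity = vel),
       pldcGrid = grid, patterns = pats, radialPldc = radialPldc)
}
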