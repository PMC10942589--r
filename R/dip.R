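#' Hartigan's dip statistic
#'
#' The dip of a one-dimensional sample is the minimum, over all unimodal
#' distribution functions G, of the maximum deviation between the empirical
#' CDF and G -- a measure of departure from unimodality.  It is invariant
#' under strictly monotone transformations of the sample and lies in
#' \eqn{[1/(2n), 1/4]} for samples with at least two distinct values.
#' Computed from the definition by the greatest-convex-minorant /
#' least-concave-majorant modal-interval iteration (compiled code).
#'
#' @param x numeric sample with at least 2 finite values.
#' @return the dip statistic.
#' @examples
#' dipStatistic(c(0, 1))                       # 0.25, the maximum
#' dipStatistic(seq(0, 1, length.out = 100))   # 0.005 = 1/(2n), the floor
#' @export
dipStatistic <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x))) stop("sample must be finite")
  if (length(x) < 2L) stop("the dip requires at least 2 observations")
  .dip_sorted_cpp(sort(x))
}

#' Dip test with a uniform bootstrap null
#'
#' Compares the observed dip against `nBoot` dips of uniform(0,1) samples of
#' the same size (the uniform is the worst-case unimodal null).  The p-value
#' is the proportion of bootstrap dips at least as large as the observed one,
#' floored at `1/(nBoot + 1)` (the resolution of a finite bootstrap).
#'
#' @param x numeric sample (n >= 2; n >= 4 recommended).
#' @param nBoot bootstrap draws (default 500).
#' @param seed optional integer seed for reproducibility.
#' @param nullDips optional precomputed vector of null dips for this sample
#'   size (e.g. shared across tests at the same n); when supplied, `nBoot`
#'   and `seed` are ignored for the null.
#' @return a [DipResult-class].
#' @examples
#' r <- dipPValue(c(rnorm(50), rnorm(50, 10)), nBoot = 200, seed = 1)
#' r
#' @export
dipPValue <- function(x, nBoot = 500L, seed = NULL, nullDips = NULL) {
  d <- dipStatistic(x)
  n <- length(x)
  if (is.null(nullDips)) {
    if (!is.null(seed)) set.seed(seed)
    nullDips <- .dip_unif_boot_cpp(n, as.integer(nBoot))
  }
  nb <- length(nullDips)
  p <- max(mean(nullDips >= d), 1 / (nb + 1))
  new("DipResult", statistic = d, pValue = p, n = as.integer(n),
      nBoot = as.integer(nb),
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

#' Paired LFP-vs-onset dip comparison across waves
#'
#' For each wave, runs the dip test on the channel-wise LFP first-crossing
#' times and on the matching spike (or ALSA) onset times, both restricted to
#' the common channel subset (only channels with an onset enter either
#' sample).  Waves with fewer than `minChannels` common channels are skipped
#' with a recorded reason.  Null dip distributions are computed once per
#' distinct sample size and shared.
#'
#' @param waves list of [Wave-class] objects.
#' @param onsetsList list (same length) of onset data.frames with columns
#'   `channel`, `onset` (from [firstSpikesInWave()] or [alsaOnsets()]).
#' @param nBoot bootstrap draws per test (default 500).
#' @param seed integer seed (bootstrap reproducibility).
#' @param minChannels minimal common channels per wave (default 4).
#' @return list with `perWave` (data.frame: `wave`, `n`, `dipLfp`, `pLfp`,
#'   `dipOnset`, `pOnset`, `pDiff`), `medians` (named vector),
#'   `fracLfpGreater` (fraction of waves with `pLfp > pOnset`) and
#'   `skipped` (data.frame of skipped waves and reasons).
#' @export
pairedComparison <- function(waves, onsetsList, nBoot = 500L, seed = 1L,
                             minChannels = 4L) {
  stopifnot(length(waves) == length(onsetsList))
  set.seed(seed)
  nullCache <- new.env(parent = emptyenv())
  nullFor <- function(n) {
    key <- as.character(n)
    if (is.null(nullCache[[key]]))
      nullCache[[key]] <- .dip_unif_boot_cpp(n, as.integer(nBoot))
    nullCache[[key]]
  }
  rows <- list(); skipped <- list()
  for (i in seq_along(waves)) {
    w <- waves[[i]]
    ons <- onsetsList[[i]]
    firsts <- w@crossings[w@crossings$first, , drop = FALSE]
    common <- intersect(firsts$channel, ons$channel)
    if (length(common) < minChannels) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        wave = i, reason = sprintf("only %d common channels", length(common)))
      next
    }
    lfpSample <- firsts$time[match(common, firsts$channel)]
    onsetSample <- ons$onset[match(common, ons$channel)]
    nd <- nullFor(length(common))
    dl <- dipStatistic(lfpSample)
    dn <- dipStatistic(onsetSample)
    pl <- max(mean(nd >= dl), 1 / (length(nd) + 1))
    pn <- max(mean(nd >= dn), 1 / (length(nd) + 1))
    rows[[length(rows) + 1L]] <- data.frame(
      wave = i, n = length(common), dipLfp = dl, pLfp = pl,
      dipOnset = dn, pOnset = pn, pDiff = pl - pn)
  }
  perWave <- do.call(rbind, rows)
  if (is.null(perWave))
    perWave <- data.frame(wave = integer(), n = integer(), dipLfp = numeric(),
                          pLfp = numeric(), dipOnset = numeric(),
                          pOnset = numeric(), pDiff = numeric())
  med <- if (nrow(perWave)) c(
    dipLfp = median(perWave$dipLfp), pLfp = median(perWave$pLfp),
    dipOnset = median(perWave$dipOnset), pOnset = median(perWave$pOnset),
    pDiff = median(perWave$pDiff)) else
    c(dipLfp = NA, pLfp = NA, dipOnset = NA, pOnset = NA, pDiff = NA)
  skippedDf <- do.call(rbind, skipped)
  if (is.null(skippedDf))
    skippedDf <- data.frame(wave = integer(), reason = character())
  list(perWave = perWave, medians = med,
       fracLfpGreater = if (nrow(perWave))
         mean(perWave$pLfp > perWave$pOnset) else NA_real_,
       skipped = skippedDf)
}
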