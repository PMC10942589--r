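---
title: "Wave-like patterns from sequentially activated modules: models, synthetic data, and the analysis chain"
author: "modwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wave-like patterns from sequentially activated modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modwave)
```

## The scientific problem

Phase-latency analyses of field potentials are the standard evidence for
cortical traveling waves: band-filter the signal, take the analytic phase,
mark when each channel crosses a reference phase, and observe latencies that
increase smoothly along the array. The difficulty is that smoothly increasing
latencies are also produced when two *discrete*, spatially fixed neural
modules activate one after the other and their fields blend — through volume
conduction, wide measurement point-spread, averaging, or narrow-band
filtering. At the electrode the blend of two delayed deflections crosses any
reference phase at a time that interpolates between the two activation times
in proportion to the local mixing ratio, so a spatial gradient of mixing
masquerades as propagation. `modwave` packages (i) an analytic model that
makes this masquerade precise, (ii) a ground-truthed synthetic
multi-electrode-array (MEA) generator embodying it, and (iii) the full
analysis chain needed to expose it, whose discriminating statistic is the
unimodality (dip) test on channel onset times: blended field potentials give
graded, unimodal crossing times while the underlying spiking onsets stay
bimodal.

## The analytic model

Two spatial Gaussians (centers $x_{1,2}$, common width $\sigma_x$) are
activated in sequence, either transiently,
$V(x,t)=\sum_i \exp\left(-\frac{(x-x_i)^2}{2\sigma_x^2}
-\frac{(t-t_i)^2}{2\sigma_t^2}\right)$, or periodically with per-source phase
lags, $g_i(t) = \cos(2\pi f t - \phi_i)$. Three closed-form results organize
the phenomenology (all verified in the test suite against brute-force
oracles):

* **Concavity boundary.** At the mid time the spatial profile has
  $\partial^2 V/\partial x^2(0,\bar t) \propto \Delta x^2 - 4\sigma_x^2$: for
  $\Delta x \le 2\sigma_x$ there is a single concave peak that drifts from
  $x_1$ to $x_2$ — one apparent wave; beyond, a convex mid point betrays two
  sources. `classifyMidpointConcavity()` evaluates the sign;
  `concavityBoundary()` locates the transition by scanning
  $\Delta x/\sigma_x$ (it brackets 2.000 at the scan resolution).
* **Temporal unimodality.** The mid-point trace $V(0,t)$ keeps a single
  temporal maximum while $\Delta t \le 2\sigma_t$ (`countTemporalPeaks()`,
  `unimodalityBoundary()`), so temporal smoothing (e.g. narrow-band
  filtering, which effectively raises $\sigma_t$) merges discrete events.
* **Velocity laws.** The apparent peak velocity at the mid point is
  $v_p = \Delta t\,\sigma_x^2 \Delta x\,/\,(\sigma_t^2(4\sigma_x^2-\Delta
  x^2))$: linear in $\Delta x$ when modules are close, divergent as
  $\Delta x \to 2\sigma_x$. For the periodic model we derived the velocity by
  implicit differentiation of the peak condition
  $\partial V/\partial x = 0$; with $a = \Delta x/2$,
  $\rho(x) = \frac{x+a}{a-x}e^{-x\Delta x/\sigma_x^2}$ and
  $\tan\theta = \cot(\Delta\phi/2)\,\frac{\rho-1}{\rho+1}$,
  $$v_p(x) = \frac{2\pi f \sin(\Delta\phi)\,\sigma_x^2\,(a^2-x^2)}
  {\left(\cos\Delta\phi+\cos 2\theta(x)\right)\,a\,(x^2+\sigma_x^2-a^2)}.$$
  Its sign follows $\sin\Delta\phi$ and its magnitude scales with $f$ —
  apparent wave direction flips with small phase-lag changes and faster
  bands "propagate" faster. We adopted this derived form after checking it
  against the independent tracked-peak oracle (bisection on the analytic
  spatial derivative plus finite differences) to relative error below
  $10^{-9}$; published renderings of this formula differ between sources in
  grouping and normalization, so the numeric oracle was treated as the
  ground truth, and the package's tests freeze oracle-computed values (for
  example $v_p(0)$ at $\Delta x = \sigma_x = f = 1$,
  $\Delta\phi = \pi/2$ equals $2\pi\tan(\pi/4)\cdot 0.5/0.75 \approx 4.19$).

**Phase convention.** The periodic temporal factor is
$\cos(2\pi f t - \phi_i)$ with $\phi$ a phase *lag*: the source with the
larger $\phi$ activates later, so $\Delta\phi = \phi_2 - \phi_1 > 0$ means
forward propagation and positive $v_p$. This keeps the sign law
$\mathrm{sign}(v_p) = \mathrm{sign}(\sin\Delta\phi)$ under the natural
definition of $\Delta\phi$.

Two-source arrangements in 2D (`makePattern()`) reproduce the classic wave
taxonomy: a **plane**-like pattern (equal isotropic covariances,
$\Delta x = 2\sigma_x$), a **radial** pattern (concentric sources, the first
narrower: $\sigma_1 = 0.5$, $\sigma_2 = 1.5$), and a **spiral-like** pattern
(anisotropic covariances $\mathrm{diag}(2^2, 0.5^2)$ and
$\mathrm{diag}(0.5^2, 2^2)$ with orthogonal major axes, centers offset by one
unit per axis). These numeric defaults are the package's own choices — the
qualitative geometries (side-by-side, nested, orthogonally crossed) are what
matters. Latency maps for model fields use the *first field maximum* per
grid point (`modelLatencyMap()`), the convention for simulated sensor data
where instantaneous phase is not defined.

**Sensor window for pattern maps.** The pattern latency maps are evaluated on
a window extending 0.8 of the widest source scale beyond the centers. This
mimics a sensor patch covering the active region; on much wider windows the
far field is dominated by the later source everywhere, latencies saturate at
its activation time, and any latency-distance correlation is diluted by a
zero-gradient plateau. With this window the radial pattern's PLDC is ≈ 0.96
— comfortably in the "traveling wave" reading, although the source never
moves. The 1D scans (`pldcScan()`) use a grid spanning
$[\min x_i - 4\sigma_x,\ \max x_i + 4\sigma_x]$ with 2001 points (boundary
scans resolve $10^{-3}$ at negligible cost); PLDC exceeds 0.9 throughout the
$\Delta x < 2\sigma_x$ regime and degrades only slowly beyond.

## The synthetic MEA generator

`recordingConfig()` + `generateRecording()` emulate visually evoked
responses of an ex vivo cortical preparation flattened on a 100 µm-pitch MEA:

* **Geometry.** A 12 × 10 grid (120 channels, 0.1 mm pitch). The default two
  modules split the array into contiguous halves along an oblique axis
  ($x + 1.15y$, roughly the array diagonal). Obliqueness is doing two jobs:
  evoked cortical waves cross arrays diagonally, and an axis-aligned split
  would collapse the noiseless channel latencies onto ~10 distinct column
  values — a grid artifact that the dip test would read as strong
  multimodality however smooth the underlying gradation.
* **Timing.** 5 s trials sampled at 1 kHz, stimulus at 1.5 s, response
  latency 0.2 s, two oscillation cycles at 1 Hz per module (responses start
  ~200 ms post-stimulus, last ~2 s, dominant power below 2 Hz), inter-module
  delay 0.28 s. 1 kHz comfortably resolves the ≤ 35 Hz analysis bands while
  keeping hundred-trial experiments desk-scale.
* **LFP.** Each module contributes an amplitude-windowed oscillation
  (sin under a Hann envelope) starting at stimulus + latency + delay,
  projected onto every channel through a Gaussian *footprint* whose per-axis
  standard deviation is twice the module's spiking extent — the
  volume-conduction premise: LFP mixes across module boundaries while
  spiking stays segregated. White Gaussian noise (sd 10 µV against 100 µV
  oscillations) is added per channel; white noise suffices because the
  threshold rule only needs a stationary pre-stimulus amplitude
  distribution.
* **Spikes.** Inside its module's active window a channel fires as an
  inhomogeneous Poisson process with rate
  $r(t) = r_0 + (r_{peak}-r_0)\exp(\kappa(\cos(\varphi(t)-\varphi^*)-1))$,
  $\varphi$ the ideal phase of the module's own oscillation,
  $\varphi^* = 0.53\pi$, $\kappa = 4$, $r_0 = 0.2$ Hz, $r_{peak} = 20$ Hz;
  the rate is zero outside the window and off-module, so "first spikes" are
  well defined per wave. Spike times are placed uniformly within their 1 ms
  bin — the correct conditional distribution of a Poisson point, and
  essential because grid-quantized spike times create ties that the dip test
  reads as spurious multimodality. Amplitudes and rates are free parameters
  (the emulated preparation's values are not published); the defaults above
  were fixed once as plausible for extracellular cortical recordings.
* **Reproducibility.** One master seed; each trial uses seed + trial counter
  and each channel an arithmetic substream of the trial seed, so identical
  seeds give bit-identical recordings and adding channels or trials never
  perturbs other draws. Ground truth (module labels, onsets, delay, spike
  parameters, the noiseless LFP) travels with the recording.

What the generator does *not* emulate: biophysical membrane/conductance
dynamics, spike waveforms and sorting (synthetic spikes arrive
channel-assigned; for real data the contract is that spikes have been
assigned to their maximal-amplitude channel upstream), retinal input
statistics, trial-to-trial response variability in amplitude or latency, and
non-white (pink) noise. Passing tests on synthetic data therefore validate
the analysis chain's correctness and calibration, not the biological
fidelity of any particular parameter value.

Recordings round-trip through a plain-text bundle (`writeRecording()` /
`readRecording()`): CSV for layout and LFP (float32 precision), JSON for
metadata, spikes (float64) and optional ground truth.

## The analysis chain and its numerical choices

* **Filtering** (`applyFilter()`): zero-phase Butterworth applied in the
  frequency domain after symmetric zero padding of one trace length, with
  gain $1/(1+(f/f_c)^{2n})$, $n = 8$ — the exact squared-magnitude
  (forward–backward) response. Zero phase is non-negotiable here: a causal
  filter's frequency-dependent group delay would *fabricate* latency
  gradients, the very artifact this package studies. The frequency-domain
  route was chosen because transfer-function (filtfilt) realizations of an
  order-8 Butterworth at a 2 Hz corner and 1 kHz sampling are numerically
  unstable, while the frequency-domain operator is exact and
  unconditionally stable.
* **Analytic signal** (`analyticSignal()`): FFT Hilbert construction;
  convention: $\cos(2\pi f t)$ has phase 0 at its peak, crossing $\pi/2$ a
  quarter period later. All-zero traces are flagged, their phase is NA.
* **Phase crossings** (`detectPhaseCrossings()`): upward crossings of the
  target phase (one per cycle) on the unwrapped phase, with sub-sample
  linear interpolation; events below the amplitude threshold are discarded.
  The threshold (`estimateNoiseThreshold()`) is mean + 4 sd of the envelope
  amplitudes of pre-stimulus crossings (0.5–1.0 s before the stimulus, up to
  100 trials). In the zero-noise limit the threshold collapses to the tiny
  acausal pre-ring of the zero-phase filter (≈ 1.5 µV against 100 µV
  signals) and all response crossings survive.
* **Wave detection** (`clusterCrossings()`): seeded flood fill — starting
  from the earliest unassigned crossing, any crossing joins whose channel is
  a rook neighbor of (or identical to) a member channel and whose time lies
  within the band window (100 ms for 0–2 Hz, 2 ms for 12–35 Hz) of *any*
  member crossing, iterated to closure. Closure makes the partition
  independent of processing order. Rook adjacency matches the ALSA
  neighborhood — one grid topology throughout. Selection
  (`selectWaves()`) keeps waves recruiting ≥ 2/3 of channels (5/6 for the
  fast band) or, for sparse spike analyses, more than 30 channels.
* **Latency maps and PLDC** (`computePLM()`, `computePLDC()`): first
  crossing per channel; start point = earliest crossing (ties to the lowest
  channel id); Pearson correlation of latency against Euclidean distance
  from the start (against the propagation-axis position for model grids).
  Degenerate inputs return NA with an explicit reason, never a silent 0.
* **Wave center path** (`computeWCP()`): amplitude-weighted center of mass
  with Gaussian temporal weights whose width ramps linearly from
  $2\bar{\Delta T}$ at the path ends to $10\bar{\Delta T}$ at the middle
  ($\bar{\Delta T}$ = mean spacing of sorted crossing times), so the path
  endpoints stay anchored to the first/last crossings while the middle
  averages broadly. `estimateSpeed()` fits the path's projection on its
  principal displacement axis against time and reports the slope magnitude
  (the estimator behind any single speed number is rarely published; this
  package states its convention explicitly). Note a systematic property of
  any such estimator under module blending: the path traverses the
  *recruited extent*, while the latency span contracts toward the blend's
  interpolation range, so apparent speeds exceed
  (module gap)/(activation delay) when footprints overlap strongly — an
  instance of the model's velocity blow-up near $\Delta x = 2\sigma_x$, and
  a caution against interpreting wave speeds literally.
* **ALSA** (`computeALSA()`): per-channel spike counts at the sample rate,
  boxcar-convolved (100 ms), Gaussian-smoothed (σ = 100 ms; the reference
  description reuses "the same temporal width", which we read as σ equal to
  the boxcar length — exposed as a parameter), then neighbor-averaged with
  half-weights: $ALSA_i = (S_i + \sum_{nn} S_j/2)/(1 + n_{nn}/2)$. Onsets
  (`alsaOnsets()`) are first local maxima within
  [start − W/2, end + W/2] of the wave, refined by parabolic interpolation
  (again: sample-grid ties would otherwise fake multimodality). First local
  maximum = first sample strictly above its predecessor and not below its
  successor; plateaus resolve to their first sample.
* **Dip test** (`dipStatistic()`, `dipPValue()`): Hartigan's dip — the
  minimum over unimodal distribution functions of the maximum deviation from
  the empirical CDF — implemented from the definition (greatest convex
  minorant / least concave majorant modal-interval iteration, compiled).
  It is validated in the tests against an exact linear-programming oracle
  that solves the band-feasibility problem directly for every mode placement
  (atoms at sample points; in-gap modes with the junction value as an LP
  variable), plus closed-form anchors: dip({0,1}) = 1/4,
  dip({0,0,1}) = 1/6, the $1/(2n)$ floor for regularly spaced samples.
  P-values compare against `nBoot` (default 500) uniform samples of the same
  size — the worst-case unimodal null — and are floored at 1/(nBoot+1), the
  resolution of a finite bootstrap; reported significance below that floor
  would be fictitious, which is why the floor convention, not 0, is
  reported even where finer granularity is quoted elsewhere.
* **Paired comparison** (`pairedComparison()`): per wave, the dip test runs
  on the LFP first-crossing times and on the spike (or ALSA) onsets of the
  *same* channel subset (channels with onsets); waves with fewer than 4
  common channels are skipped with a logged reason. Null dip distributions
  are computed once per sample size and shared — the null depends only on n.

`runExperiment()` chains everything (threshold calibration pass, then
per-trial analysis regenerated from counter seeds to keep memory flat) and
`runModelSuite()` runs the analytic scans. A default 100-trial experiment
takes about two and a half minutes on one CPU.

## What the synthetic experiments show

With all defaults (100 trials): LFP phase latencies of the first oscillation
cycle are smooth and graded — PLDC concentrated near 0.9, collapsing to ~0
under latency shuffling — and their dip p-values sit near 1 (no evidence
against unimodality). The spike and ALSA onsets on the same channels are
bimodal: median dip p at the bootstrap floor, and the LFP p exceeds the
onset p in essentially every wave. ALSA onset clusters recover the
configured 0.28 s inter-module delay within a few percent (cluster locations
taken as group medians: channels at the module border inherit the earlier
module's bump through the ALSA spatial kernel, which biases group means
low). This is the
package's core demonstration: a measurement chain that any practitioner
would read as a traveling LFP wave, generated by — and diagnosable as — two
discrete modules.

The single-module control deserves a caveat recorded here deliberately. In
a perfectly synchronous control, detected "waves" have widths of only
10–30 ms, so the onset windows [T−W, T+W] are an order of magnitude below
the 100 ms ALSA smoothing scale. The LFP crossing sample is then pure
Gaussian measurement jitter — *more* unimodal than the uniform null, with
p-values near 1 — while first-event times inside a narrow window are
quasi-uniform, with p-values near 0.5. Neither sample shows modularity
(median onset p ≫ 0.05, the substantive negative-control property), but the
*paired difference* of p-values stays systematically positive (~0.15–0.35)
because the two sample types have different null shapes, not because
modularity is detected. Paired dip p-value differences should therefore be
interpreted against a matched control of the same sample type, not against
zero.

## Known limitations

* The generator's modules share one frequency and amplitude and activate
  with deterministic onsets; real preparations show trial-to-trial latency
  and amplitude variability that would widen all onset distributions.
* PLDC, as a Pearson correlation, is blind to nonlinearity: saturating
  latency profiles (radial far fields) dilute it even when propagation reads
  clearly in the map.
* The dip test is extremely sensitive to tied values; any discretization of
  onset times (sampling grids, binned estimators) must be undone (sub-sample
  interpolation, within-bin placement) before it is applied, or ties will
  register as multimodality.
* `estimateSpeed()` reports a single straight-line rate; rotational
  (spiral-like) paths are out of its scope, as is any optical-flow style
  velocity field.
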