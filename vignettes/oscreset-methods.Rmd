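---
title: "Phase-reset analysis of oscillating electroreceptors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-reset analysis of oscillating electroreceptors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscreset)
```

# The scientific problem

Mormyrid weakly electric fish communicate with electric organ discharges
(EODs) emitted at variable interpulse intervals (IPIs). Two kinds of
electroreceptor (knollenorgan) physiology exist across species: receptors
that fire a single, time-locked spike to an electric pulse edge, and
receptors grouped into head rosettes that oscillate spontaneously at 1-3 kHz
and respond to stimuli by *resetting the phase* of their ongoing
oscillation. Phase resets transiently synchronize the receptor population
(each receptor then drifts apart again at its own intrinsic frequency),
which can signal stimulus timing and polarity — but not waveform details.

`oscreset` implements the complete measurement chain for both receptor
types — circular statistics, spontaneous-activity characterization,
phase-independence tests between simultaneously recorded receptors,
stimulus-evoked reset quantification, frequency tuning, IPI statistics of
single fish and groups, and behavioral playback metrics — together with a
synthetic-data module that generates every input the analyses consume, so
the whole chain is testable without any recorded data.

# Measurement conventions

* Oscillating-receptor traces are median filtered (0.1 ms width,
  `median_filter_trace()`, backed by `stats::runmed`) before peak detection.
* The first seven oscillatory peaks after stimulus offset give the first six
  poststimulus periods. If the first period is < 85% or > 115% of the mean
  of the following five, the first peak is treated as artifact-contaminated
  and the *second* peak is designated for all measurements.
* The reset angle is computed from the designated peak's latency `lat`
  (relative to stimulus offset) and the poststimulus period `p`. The source
  convention `phi = lat / p` "in radians" cannot span the circle, and the
  vector-strength formula requires full-circle angles, so the package
  deliberately uses `phi = 2 * pi * (lat mod p) / p`.
* Vector strength `r = sqrt((sum cos phi / n)^2 + (sum sin phi / n)^2)` is
  computed across stimulus repetitions.
* The opposite-polarity phase difference is
  `delta_phi = (lat_N - lat_P) / ((p_N + p_P) / 2) * 360` degrees, measured
  on across-sweep *averaged* traces, reported raw and reduced to
  (-180, 180].
* Evoked oscillation amplitude is the mean voltage of the first two
  designated poststimulus peaks minus the intervening trough; spontaneous
  amplitude is each trough subtracted from the *preceding* peak. Both
  definitions are implemented as written; they differ on purpose.
* The spontaneous frequency is the argmax of the magnitude FFT averaged
  across five repeated recordings. Magnitudes (not complex spectra) are
  averaged because oscillation phase is random across recordings; complex
  averaging would cancel the peak.
* A receptor's spontaneous activity is measurable when its amplitude is at
  least `max(2.5 * noise_floor, 0.1 mV)`.
* EOD events in tank recordings are rising crossings of the rectified
  potential above 0.6 mV, with a 0.25-ms dead time (the dead time must pass
  genuine ~0.5-ms group IPIs while suppressing double counts on multiphasic
  EODs; the source procedure states none).
* Behavioral EOD rates use a Gaussian spike-density function. "Gaussian of
  200-ms width" is interpreted as sigma = 200 ms (the usual SDF
  convention); it is a configurable parameter. Baseline is the mean rate
  4.8-0.2 s before stimulus onset; response extrema are taken from 0.2 s
  before onset to 1.2 s after offset, on the repetition-averaged SDF.

# The synthetic world

## Oscillating receptors

An oscillating receptor is a stochastically perturbed Stuart-Landau
(normal-form supercritical Hopf) oscillator with additive stimulus forcing:

    dz/dt = (mu + i * 2 * pi * f0 - |z|^2) z + (kappa / g) a(t) s(t) + noise

recorded as `V = g * Re(z)` plus measurement noise, where
`g = spont_amp / (2 * sqrt(mu))` maps the unit limit cycle to the receptor's
spontaneous peak-to-trough amplitude. Integration uses a fixed-step
*exponential* Euler-Maruyama scheme at the recording rate (97.7 kHz): the
rotation/relaxation factor `exp((mu - |z|^2 + i * omega) * dt)` is applied
exactly per step. A plain Euler step at this rate inflates the limit-cycle
radius by `O(omega^2 dt)` and biases the frequency; the exponential step
removes both while keeping the scheme fixed-step and stochastic.

`a(t)` is a coupling-depletion resource in [0, 1]:

    da/dt = (1 - a) / tau_rec - a * max(|s| - s0, 0) / q_dep

with `tau_rec = 1.5 ms`, `q_dep = 0.3 nA*ms`, and threshold `s0 = 2 nA`.
This stage exists because a purely additive coupling re-entrains the phase
on *every* pulse at *any* interval: the cubic term collapses the previous
kick's radius to at most ~2.35 limit-cycle radii within a tenth of a
millisecond, while a fresh kick is unbounded, so a plain Stuart-Landau
oscillator tracks even 0.3-ms IPIs — which the modeled receptors
demonstrably do not (interoscillation intervals plateau near the intrinsic
period below ~1 ms). With depletion, a saturating pulse consumes the
coupling; a second pulse within the sub-millisecond range cannot re-reset,
and the interval measurement plateaus, while recovery over a few
milliseconds restores accurate interval coding at 3 ms and beyond. Weak
(sub-threshold-intensity) stimuli leave the coupling intact, which is the
regime used for resonance and tuning demonstrations.

Two canonical parameterizations are used throughout tests and demos:

* **Reset regime** (`mu = 1`, `kappa = 7`, `noise_sd = 0.15`, stimuli at
  10 nA): strong, reliable resets; vector strength > 0.9; opposite
  polarities reset ~180 degrees apart; interoscillation intervals match
  IPIs >= ~1 ms and fail below.
* **Resonance regime** (`mu = 0.35`, `kappa = 7`, `noise_sd = 0.45`,
  stimuli at 0.8 nA): slower amplitude relaxation (~1.4 ms) and an
  oscillation coherence time of a few milliseconds. A weak pulse pair at an
  IPI equal to the intrinsic period adds its kicks in phase while the first
  kick's contribution is still present, so the paired-pulse amplitude
  (normalized to the single-pulse response) is maximal at one period among
  {1/4, 1/2, 1, 2, 4, 8} periods and decays toward 1 as coherence is lost.
  The measured effect is a ~10% amplitude modulation on top of a noisy
  baseline, so the corresponding test averages 60 sweeps per condition
  across four receptors and uses common random numbers between the pair and
  single-pulse simulations; quantitative amplitude-vs-duration shapes are
  otherwise treated as qualitative.

## Spiking receptors

Spiking receptors respond to inward current transients — the onset of a
positive square pulse and the offset of a negative one — with a single
spike at `edge + latency + jitter`, emitted with probability given by a
steep sigmoid of the transient charge (`intensity * min(duration, 0.1 ms)`
for pulse edges), and suppressed within an absolute refractory period
(default 1 ms). Sine bursts drive the receptor through a resonant gain
centred on `f0_khz` with quality `q_factor`, producing one phase-locked
spike candidate per cycle. Exact event times are carried alongside the
rendered traces (the biphasic 0.5-ms spike waveform is cosmetic; analyses
may detect from the trace or use the embedded events).

## Trains and behavior

Single fish emit EODs as a renewal process with shifted-gamma IPIs
(`IPI = 8 ms + Gamma(2, 60 ms)`, mean 128 ms), so one fish never produces
an IPI below its ~8-ms physiological floor; a group's pooled train contains
sub-millisecond intervals purely through chance coincidence across
independent fish (concerted signaling is deliberately not modeled).
Behavioral sessions draw EOD times from an inhomogeneous gamma-renewal
process (shape 4, i.e. more regular than Poisson) whose rate is baseline
plus unit-peak alpha-function (or box) increase/decrease kernels.

## What the generator does not emulate

Real rosette geometry and receptor mapping, electric-field geometry of the
fish's body, biophysical transduction, EOD waveform diversity beyond a
calibrated windowed-sine surrogate (`synth_eod()` is labelled synthetic),
and concerted group signaling. A green test therefore establishes that the
*measurement chain* behaves as specified on data with the stated
statistical structure — not that the generative model reproduces any
particular species' physiology quantitatively.

# Statistical choices

* **Angular S.E.M.**: the circular standard deviation `sqrt(-2 log r)`
  divided by `sqrt(n)`; the source names no formula, and this is the
  standard dispersion-based choice.
* **Paired second-order Hotelling test** (Zar's formulation): per-pair
  rectangular difference vectors `(cos a - cos b, sin a - sin b)` are
  tested for zero mean via the bivariate one-sample statistic referred to
  F(2, n-2). At alpha = 0.05 and n = 6 pairs the critical value is
  `qf(0.95, 2, 4) = 6.94`. Note the test detects a *consistent* difference
  vector: with uniformly scattered base angles, `b = a + pi` produces
  difference vectors that cancel around the circle, so power calculations
  must use clustered base angles (as reset phases are).
* **Circular correlation**: the Jammalamadaka-SenGupta sine-product
  estimator about the sample circular means; when a sample's resultant is
  numerically zero (mean undefined, e.g. evenly spaced angles) the
  equivalent mean-free pairwise form is used instead.
* **Wilcoxon matched-pairs, repeated-measures ANOVA, F quantiles** are
  delegated to `stats::wilcox.test`, `stats::aov` (with an `Error(fish/ipi)`
  stratum), and `stats::qf`; these are standard routines, not contributions
  of this package.
* **Welch PSD and the analytic signal** are implemented in-package (Hann
  window, 4096-sample segments, 50% overlap; frequency-domain Hilbert
  transform) because no pre-installed R package provides them. Waves
  shorter than one segment are zero-padded to at least twice their length
  and estimated from a single untapered segment — tapering a single-cycle
  wave biases its spectral peak upward, and the single-cycle peak is
  specified to fall *below* the inverse duration.

# Numerical details and degenerate inputs

* Peak times are refined by parabolic interpolation around local maxima;
  the 0.1-ms median filter flattens sine peaks into short plateaus, which
  biases detected peak positions by up to ~2 samples and attenuates
  measured peak-trough amplitudes by ~4%; tests account for both.
* Surrogate pairings for the phase-independence analysis are exactly the
  (first, fifth) and (fifth, first) segment combinations.
* Tuning-curve ties break toward the lower frequency and are logged; when
  the two polarities' best frequencies disagree, the receptor's best
  frequency is their mean.
* The total-duration criterion (first/last points where |waveform| exceeds
  0.5% of the maximum peak-to-peak amplitude) uses inclusive sample counts,
  so a rectangle of width w measures exactly w.
* Degenerate inputs error loudly: empty angle samples, constant traces
  (phase undefined), zero reference amplitudes, unbalanced ANOVA designs,
  thresholds below the noise floor.
* All simulators take explicit integer seeds and are bit-reproducible;
  there is no hidden global RNG state beyond the seed passed in.

# Scaled-down replicate counts

The null-calibration properties (100 phase-independence replicates of 14
receptor pairs, 200-replicate Hotelling type-I check, ANOVA power checks)
run on reduced segment lengths (150 ms at 19.54 kHz instead of 1 s at
97.7 kHz) so the full suite stays within its time budget; replicate counts
and decision thresholds are unchanged. Phase-correlation magnitudes on
shorter segments are larger in absolute terms than the source's 1-s values,
but the tests assert the calibration properties (type-I error, fraction
non-significant), which are length-invariant under the null.

# Known limitations

* The oscillator's amplitude-versus-duration curve for square pulses is
  qualitative; no quantitative model of amplitude enhancement versus
  duration is attempted.
* The spiking receptor's sine-burst pathway models tuning as a static
  resonant gain; it does not produce damped subthreshold oscillations.
* `nA` in the synthetic world is a per-receptor effective drive scale, not
  a calibrated stimulation current; comparisons to printed stimulus
  intensities are by regime (sub- vs supra-saturating), not by value.
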