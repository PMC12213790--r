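---
title: "Quantal analysis of miniature EPSPs by genetic-algorithm distribution fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantal analysis of miniature EPSPs by genetic-algorithm distribution fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minisfit)
```

## The problem

Miniature excitatory postsynaptic potentials (minis, mEPSPs) are the
somatic voltage responses to spontaneous release of single
neurotransmitter vesicles. In large pyramidal neurons most minis are
strongly attenuated by the cell's membrane capacitance by the time they
reach a somatic electrode, so a large fraction is indistinguishable from
background noise, and naive amplitude histograms of *detected* events
overestimate the quantal size while underestimating the incidence rate.
Direct subtraction of a noise-alone event histogram (recorded from the
same cell after pharmacological blockade of synaptic events) does not
solve this: larger minis overshadow smaller ones and noise fluctuations,
producing negative low-amplitude bins in the difference.

`minisfit` implements the simulation-based alternative: superimpose
*simulated* minis, drawn from a parametric source distribution, on the
real noise-alone recording; detect events in the composite trace with
exactly the same detector settings used on the real recording; and let a
genetic algorithm (GA) adjust the source distribution until the
amplitude and 10–90% rise-time histograms of detected events are
statistically indistinguishable from the real ones. Detection biases
(missed events, overshadowing, summation) then affect both sides
equally and cancel in aggregate. The fitted source distribution yields
the cell's mean mini amplitude and incidence rate; across cells, mean
amplitude against inverse total capacitance gives the population mean
injected charge per mini, `Q = ΔV / Δ(1/C)`.

## Waveform model

Simulated mEPSP waveforms are the analytical response of a passive
uniform cable (electrotonic length `L`, default 1, sealed at both ends,
recording at the origin) to a double-exponential synaptic current
`I(t) ∝ e^{-t/τ₂} − e^{-t/τ₁}` injected at electrotonic distance `X`.
The somatic voltage is a truncated series of 100 equalization modes
with time constants `τ_k = τ_m / (1 + (kπ/L)²)` convolved with the
current (`simulate_psp()`). Two limits anchor the implementation and
are asserted in the tests: at `L → 0` the response reduces to the
closed-form RC convolution, and for brief currents with slow membranes
the peak tends to `Q/C_total` — the capacitor law the downstream charge
regression relies on. `τ₁` ranges over 0.15–3 ms and `τ₂` is fixed at
2 ms; `X` and the injected charge are the two shape degrees of freedom,
mapped to a requested (amplitude, rise time) pair by a monotone root
find (`calibrate_shape()`).

Inside the fitting loop per-event root finding would be prohibitive, so
the loop uses a precomputed table of rise time as a function of
`(X, τ₁, τ_m)` and caches unit-peak waveforms on a quantized
`(τ₁, τ_m)` grid (0.05 ms and 0.25 ms steps). The quantization is far
below the 0.5 ms rise-time bin width, so it does not affect which bin a
simulated event lands in.

## Source model

The source distribution is a mixture of four rotated bivariate normals
in (amplitude, rise time), each with six parameters
(`μ_X, σ_X, μ_Y, σ_Y, ρ, n`). The first component has a non-negative
count scale; the other three may be negative, *sculpting* the base
shape. The distribution is realized on a fixed grid (10 µV × 0.5 ms
bins); negative totals are zeroed, as are bins below the amplitude
lower limit or at negative rise times. Realized counts are interpreted
as events per 100 s of recording, so the GA controls the incidence rate
through the count scales. With `τ₁` and `τ_m` (constrained to ±10% of
its pulse-derived estimate) this gives the GA's 26-parameter genome.

Bin masses are computed as the exact normal mass of the amplitude bin
times the exact conditional rise-time mass evaluated at the amplitude
bin midpoint. This is exact for `ρ = 0` and accurate to well below a
percent at the 10 µV amplitude bin width otherwise; a full bivariate
rectangle integral would require a 2-D normal CDF for no practical
gain at this grid resolution.

Shape constraints are evaluated on the *realized* (post-zeroing)
distribution: it must be unimodal (local-maxima count of the 3×3
smoothed grid, secondary peaks above 5% of the maximum), its rise-time
mean must not exceed 5 ms, the rise-time mean must exceed the median by
at least 0.25 standard deviations (the skew observed in real minis),
and the amplitude marginal must not begin with a sharp cliff (first
non-zero bin above half the modal bin). The median is interpolated
within its bin; reading it at a bin center would quantize the skew
statistic by up to half a bin width and mis-flag genuinely skewed
distributions.

## Detection

The detector is deliberately simple and symmetric: boxcar smoothing
(0.5 ms), local maxima (ties to the earliest sample), a walk back down
the rising phase to the nearest preceding local minimum (at most the
10 ms rise gap), a baseline mean over 2 ms ending there, and an
amplitude filter (0.02–10 mV). The *nearest* local minimum matters: a
window minimum would measure noise bumps riding on an event's decay
against the decay's floor, inflating their amplitudes by the decay drop
across the window. Events touching excluded segments are dropped
entirely. A 1 ms refractory suppresses duplicate maxima within one
smoothing width. The effective decay time constant (time to fall to 1/e
of the value 8 ms after the peak) is reported for quality control but
not scored, so the fitting loop skips it.

The specific parameter values are less important than the symmetry:
identical settings are applied to real and simulated traces, which is
what lets detection bias cancel between them.

## Cost function

Candidate distributions are scored against a selected reference real
histogram through 15 discrepancy scores: sums of absolute deviations
(SAD) and maximal absolute deviations (MAD) over six views (all
amplitudes; the top-50%, top-10% and top-2% amplitude tails; all rise
times; the joint 2-D histogram), and signed sums (SSD, simulated minus
real) over the three tails, which must be non-negative so the fitted
tail is never lighter than the real one. Counts in each view are first
divided by the view's average bin count over the real set, which
up-weights the sparse tails. Tail boundaries come from the reference
distribution's empirical quantiles so that all candidates are scored on
the same bins.

Cutoffs for the SAD/MAD scores implement the "15-score combined 50th
centile": the smallest integer percentile whose per-score cutoffs are
satisfied *simultaneously* by at least half of all real-real file
pairings. The centile is estimated from single-sweep pairings and then
applied to the pairwise scores of the full-length comparison files.
Percentiles use R's type-7 (linear interpolation) definition; with `n`
pairings, pass counts can only change at multiples of `100/(n-1)`, so
isolated percentile values require enough pairings — the test suite
constructs an 11-pairing table whose smallest working centile is
exactly 90.

A further 15 envelope-deviation scores measure how far the candidate
leaves the bin-wise min–max band of the real histograms, in the same
views; the candidate must not exceed the worst (leave-one-out,
per-score maximum) envelope scores of the real distributions
themselves — it must not be pickable as the "worst outlier". With the
four shape penalties this gives 34 fitness components. A fit satisfying
all 34 is `best_possible`; one satisfying all amplitude SAD/MAD
cutoffs, all SSDs, and unimodality is `acceptable`.

The scalar cost driving the GA is the sum of normalized excesses over
cutoffs, SSD shortfalls, envelope excesses over the worst-real
baseline, and 10 points per shape violation. It is zero exactly when
all 34 components are satisfied, and any monotone aggregation preserves
the verdict logic, which is the binding contract.

## Genetic algorithm

Full-scale runs use 260 individuals (10 per parameter), 5% elitism,
and stop on zero cost, 100 stall generations, or 1000 generations.
Parents are chosen by size-3 tournaments; offspring by uniform
crossover and per-gene Gaussian mutation (rate 0.15, SD 10% of the
parameter range, clipped to bounds). Every individual is evaluated by
realize → sample → superimpose → detect → histogram → score, with a
per-individual derived seed so serial and parallel evaluation would
give identical results. Restart runs (`run_with_reseeds()`) re-draw the
population within ±25% of the original range widths around the previous
best genome. The forward procedure raises the amplitude lower limit in
10 µV steps (one amplitude bin) while fits remain good enough,
returning the upper-bound genome; the backward procedure starts high
(200 µV) and descends until a fit first converges. Both procedures
accept an injectable runner so their walk logic is testable without GA
runs.

## Statistical acceptance

A "good enough" fit is finally accepted by comparing, separately for
amplitude and rise-time marginals, the SAD scores of the simulated
distribution against each non-reference real file with the
corresponding real-real SAD row of the worst (most discrepant) real
file, using one-sided Wilcoxon signed-rank paired tests: the underfit
test asks whether the simulated median SAD significantly exceeds the
worst real-real median. The analogous comparison against the best real
file flags "excellent" (over-)fits for guidance only. The two underfit
tests are Bonferroni-corrected (each at α = 0.025). P-values are exact
— a shifted convolution over doubled average ranks handles ties — for
n ≤ 25, with a tie- and continuity-corrected normal approximation
above; zero differences are dropped.

## The synthetic-data generator

Every experiment in the tests and the acceptance script is built from
the generator, which emulates the two-epoch protocol: an
Ornstein–Uhlenbeck noise floor (SD 0.012 mV, correlation time 5 ms,
baseline −70 mV) for both epochs, minis drawn from a log-normal
amplitude distribution (CV 0.35) and log-normal rise times (mean 2 ms,
log-SD 0.7, satisfying the quarter-SD skew constraint), superimposed at
a Poisson rate; and half-millisecond ±100 pA pulse responses embedding
the cell's true capacitance and membrane time constant. The noise SD
was fixed by the requirement that noise-alone fluctuations essentially
never exceed an 80 µV detection threshold — the scale at which such a
threshold is "unreasonably high" — under this detector's amplitude
convention. When a population is generated from a fixed per-event
charge, each cell's true mean amplitude is exactly `Q/C_total`.

What the generator does *not* emulate: line noise and other
nonstationarities, electrode drift, seal degradation, glitches (unless
enabled), correlated release, active dendritic conductances, and the
recording-length heterogeneity of real datasets. Passing tests
therefore demonstrate that the estimator chain is correct and
self-consistent under the stated noise model, not that it is robust to
every pathology of real recordings — the quality-control module exists
precisely to exclude such segments before fitting.

## Problem sizes and numerical choices

The validation experiments run at desk scale by design: 60 s epochs at
10 kHz, comparison files of 6 s (ten real files, so the acceptance
tests have n = 9 pairs and can actually reject), single-sweep pairings
of 3 s, GA populations of 60 with at most 80 generations, and a fixed
0.05 mV amplitude lower limit standing in for the forward threshold
procedure. Recovery tolerances at this scale are 15% on the fitted
mean amplitude and 25% on the rate. The population experiment uses 8
cells, 100–400 pF, 30 fC, 30 s epochs. Full-scale parameters (260
individuals, 1000 generations, 100 s files) remain the defaults of
`ga_config()`.

Other numerical choices: sample indices are 0-based with half-open
intervals; all times in ms, potentials in mV, currents in pA,
capacitances in pF, charges in fC (so fC/pF = mV and mV·pF = fC);
score comparisons carry a 1e-12 absolute tolerance so bit-level noise
never flips a verdict; the stabilization point of the pulse-decay
log-linear fit is where the curvature of ln(V), measured over 1 ms
steps, stays below 1%/ms² for 1 ms (coarse-step differencing keeps the
second derivative usable on noisy data); the bridge-balance jump is
back-extrapolated from a single-exponential fit over 0.2–2 ms after
the edge, which is robust to the pipette-capacitance artifact.

## Limitations

The fitted distribution is an upper bound on the mean mini amplitude,
not a unique solution: distributions with ever more sub-noise events
fit equally well, which is why the amplitude lower-limit procedures
exist. The cable geometry is a single uniform cable — adequate because
only the (amplitude, rise time) shape family it spans matters to the
fit, but not a morphological model. ABF files are not read directly;
recordings must be converted to the portable CSV/JSON container. The
GA's operator settings are re-specified rather than inherited from any
particular optimization toolbox, so fitted genomes are comparable only
within this implementation, though the verdict and acceptance logic are
implementation-independent.
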