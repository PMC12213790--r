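# minisfit

Quantal analysis of miniature excitatory postsynaptic potentials
(minis, mEPSPs) from somatic whole-cell voltage recordings, for
synaptic physiologists who record a *noise with minis* epoch and a
pharmacologically isolated *noise alone* epoch from the same neuron.

In large pyramidal cells most minis are attenuated below the noise
floor by the membrane capacitance, so amplitude histograms of detected
events are biased and direct subtraction of a noise-alone histogram
leaves negative bins (larger minis overshadow smaller ones and noise
fluctuations). `minisfit` instead infers the *source* distribution of
minis by simulation: events drawn from a candidate distribution are
superimposed on the real noise-alone trace, detected with exactly the
same settings as the real recording, and a genetic algorithm adjusts
the candidate until the detected amplitude and 10–90% rise-time
histograms are statistically indistinguishable from the real ones —
detection biases then cancel between the two sides.

## The model

* **Waveforms.** Simulated mEPSPs are the analytical response of a
  passive uniform cable (sealed ends, 100 lumped exponential modes,
  `τ_k = τ_m / (1 + (kπ/L)²)`) to a double-exponential synaptic
  current (`τ₁` = 0.15–3 ms, `τ₂` = 2 ms) injected at electrotonic
  distance `X`. In the isopotential limit the peak obeys the capacitor
  law `V = Q/C`.
* **Source distribution.** A mixture of four rotated bivariate normals
  in (amplitude × rise time); the three non-base components may carry
  negative counts that *sculpt* the shape, negative bins are zeroed,
  and an amplitude lower limit bounds the unresolvable small-event
  tail. With `τ₁` and `τ_m` this is the GA's 26-parameter genome.
* **Cost.** 15 discrepancy scores against a reference real histogram
  (6 SADs, 6 MADs over amplitude/tail/rise/joint views, 3 signed tail
  sums), cut off at the "15-score combined 50th centile" of real–real
  file pairings; 15 envelope-deviation scores against the band of all
  real histograms; 4 shape penalties (unimodality, rise-time mean ≤
  5 ms, mean−median ≥ 0.25 SD rise-time skew, no amplitude cliff) — 34
  fitness components.
* **Acceptance.** One-sided Wilcoxon signed-rank tests (exact, ties
  handled) compare the simulated–real SAD set with the worst real–real
  SAD set, Bonferroni-corrected across the amplitude and rise-time
  marginals: a fit is accepted when it cannot be picked out as the
  worst outlier.
* **Downstream.** Incidence rates (fitted / subtracted / thresholded),
  mean amplitude vs `1/C_total` regression whose through-origin slope
  is the mean injected charge per mini `Q = ΔV/Δ(1/C)` in fC, and a
  generic mean-normalized average source distribution.

A synthetic-data module generates complete two-epoch recordings with
known ground truth (colored OU noise, log-normal sources, pulse
responses embedding the true capacitance), so the whole chain is
testable without any experimental data.

## Worked example

```r
library(minisfit)

# one synthetic cell: 200 pF, true mean mini amplitude 0.35 mV, 25 minis/s
cell <- synthetic_cell_spec(c_total = 200, mean_amp = 0.35, true_rate = 25)
rec <- generate_recording_pair(cell, noise_model(),
                               durations = c(minis = 20000, noise = 20000),
                               seed = 1L)
print(rec$minis)
#> <voltage_trace> 200000 samples, dt = 0.1 ms (20.000 s), 7 sweep(s), epoch 'noise_with_minis'

ev <- detect_events(rec$minis)
head(ev, 3)
#>   peak_time_ms peak_vm baseline_vm amplitude_mV rise_10_90_ms decay_tc_ms
#> 1         18.0   -69.6       -70.0        0.366          2.26        80.8
#> 2         48.0   -69.4       -69.9        0.492          3.17        11.7
#> 3         79.2   -69.6       -69.8        0.273          1.62         3.5

# naive noise subtraction (biased: an upper bound on the mean, a lower
# bound on the rate)
dn <- detect_events(rec$noise)
hm <- event_histogram2d(ev$amplitude_mV, ev$rise_10_90_ms)
hn <- event_histogram2d(dn$amplitude_mV, dn$rise_10_90_ms)
sub <- subtract_histograms(hm, hn, 20000, 20000)
incidence_rate(sub, method = "subtracted")   # 24.1 minis/s
1000 * subtracted_mean_amplitude(sub)        # 342 uV

# charge per mini across a population: slope of mean amplitude vs 1/C
pop <- generate_population(n_cells = 6, c_range = c(100, 400),
                           true_charge = 30,
                           durations = c(minis = 5000, noise = 5000),
                           seed = 2L)
charge_regression(data.frame(c_total = pop$truth$c_total,
                             mean_amp = pop$truth$true_mean_amp))
#> charge regression over 6 cells:
#>   free fit: y = 30x + 2.12e-17;  origin fit: y = 30x
#>   Q estimate = 30 fC;  r = 1.000, R2 = 1.000
```

The full GA fit is driven the same way: `prepare_fitting()` builds the
real comparison files, centile cutoffs and envelope from the two
epochs; `run_ga()` (or `fit_forward()` / `fit_backward()`, which walk
the amplitude lower limit) fits the source distribution; and
`accept_fit()` runs the Wilcoxon acceptance tests. A thin command-line
wrapper with `simulate`, `detect`, `qc`, `fit`, `accept` and
`subtract` subcommands is installed at `inst/scripts/minis.R`.

See the vignette (`vignettes/minisfit-methods.Rmd`) for the model,
the cost function, all tunable parameters and the numerical choices.

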