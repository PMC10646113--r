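---
title: "Models and methods behind skeletime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind skeletime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the modelling and statistical choices the package
makes, in the order the pipeline uses them: the oscillator model and its
stimuli, the synthetic-data generators, the rhythmometry estimators, the
resetting quantifications, and the count-matrix stages. Throughout, the
"defaults" are the conditions under which the package's tests and
acceptance analyses run.

## The Poincaré oscillator ensemble

Skeletal tissue recordings are modelled as the mean of `n_cells`
independent Poincaré oscillators. The Poincaré (amplitude–phase) model is
the minimal limit-cycle formalism that exhibits the full catalogue of
behaviours observed in clock-reporter recordings: stable oscillation with
radial relaxation, weak (type 1) versus strong (type 0) resetting depending
on stimulus strength, damping of the population signal by
desynchronization rather than by loss of single-cell rhythmicity, and
amplitude resynchronization by a common stimulus. We deliberately do not
use a mechanistic transcription–translation model: no equation in the
underlying biology is known quantitatively for these tissues, and the
phenomenological model keeps every parameter interpretable and fittable.

Per cell, with radius $r$, phase $\varphi$ and limit radius $A_0$:

$$\dot r = \lambda r (A_0 - r), \qquad
  \dot\varphi = 2\pi/\tau_i + \sigma_\varphi\,\xi(t),$$

with the observable $y = \text{baseline} + \text{gain}\cdot r\cos\varphi +
\varepsilon$. Phase is reported in hours after the reporter peak, so the
observable peaks at phase 0 by construction.

Key parameters (defaults in parentheses):

* `tau_h` (24 h) — intrinsic period; `tau_sd_h` (0.5 h) — between-cell SD.
* `phase_noise` (0.1 rad·h^-1/2^) — phase diffusion intensity.
* `relax_rate` λ (0.5 h^-1^) — radial relaxation; fast enough that the
  radial transient after a kick is over well within the 12-h post-stimulus
  window that phase estimation excludes.
* `n_cells` (1000) — ensemble size. Real explants contain orders of
  magnitude more cells; 1000 is the desk-scale point at which the
  finite-sample noise of the ensemble acrophase (which scales roughly as
  $1/(R\sqrt{2N})$ with $R$ the phase-coherence order parameter) stops
  dominating the phase-shift quantifications.
* `dt_h` (0.05 h) — fixed-step Euler–Maruyama integration in polar
  coordinates. The system is stiffness-free, and a fixed step makes runs
  bit-reproducible for a given seed, which an adaptive stepper would not.

The damping defaults were chosen against a stated behavioural target — an
unstimulated, initially synchronized ensemble decays below half of its
first-cycle amplitude within roughly five circadian cycles, matching the
gradual loss of ensemble rhythmicity seen in undisturbed explant cultures.
The pair (`tau_sd_h` = 0.5 h, `phase_noise` = 0.1) meets that target; a
smaller pair such as (0.25, 0.05) analytically retains ~80 % of the
starting amplitude after five cycles and was therefore rejected. These
constants are configuration, not biological claims: the true per-cell
desynchronization rates of explants are unknown.

## Stimuli and their calibration

A stimulus of dose $d$ displaces the Cartesian oscillator state by
$\varepsilon(d) = \varepsilon_{\max}\, d/(d + K)$ along a fixed direction.
Saturation is the simplest transfer function consistent with a response
that grows with dose but cannot grow without bound; the data available to
anchor it are *outputs* (phase shifts at given doses), not the transfer
function itself, so $\varepsilon_{\max}$ and the kick direction are fitted:

* **Osmotic** (dose in mOsm above iso-osmotic): root finding on the
  deterministic pipeline so that a +400 mOsm instantaneous kick at the
  mid-descending phase yields a 9.5-h phase delay. $K$ = 300 mOsm (mid
  range of the doses studied, a design choice). Fitted:
  $\varepsilon_{\max}$ = 1.9827, direction 85°. The +200 mOsm kick is then
  0.79·$A_0$ < $A_0$, which is what makes the default stimulus type 1.
* **Loading** (dose in MPa): a grid over candidate directions crossed with
  root finding on the per-pulse magnitude so that five daily 45-min pulses
  at the trough phase accumulate an 8-h advance; the magnitude is then
  refined on the full noisy-ensemble protocol (mean over fixed seeds
  101–106) because heterogeneous ensembles accumulate systematically more
  advance than the single deterministic oscillator under the same pulses.
  Fitted: $\varepsilon_{\max}$ = 0.7390, $K$ = 0.25 MPa, direction 30°.

One geometric trade-off deserves emphasis. A fixed-direction kick cannot
simultaneously (a) leave the phase untouched when applied exactly at the
reporter peak (which would require the kick to point along the peak axis)
and (b) produce a >6-h delay at the mid-descending phase (which requires
the kick to point well below that axis, at circadian phase ~20 h). We
resolve it in favour of the quantitative endpoints (the 9.5-h maximal
delay, the 8-h in-vivo advance, type 1 at +200 mOsm): the calibrated
directions therefore do not reproduce the qualitative "no shift at the
peak" pattern for weak kicks on a single oscillator. The amplitude boost
of peak-phase stimulation is still reproduced at the ensemble level, where
it is a resynchronization phenomenon rather than a radial one.

Two conventions close the stimulus model: an event with a duration is
applied as a constant drive whose total impulse equals the instantaneous
kick of the same dose (this keeps single pulses and sustained 12:12
forcing commensurable), and a kick that lands exactly on the origin — where
phase is undefined — assigns phase 0, a measure-zero tie-break that makes
the map total and deterministic.

## Synthetic single cells and counts

`simulate_cell_population()` emulates fluorescence imaging of
*unsynchronized* primary cells, which oscillate at low amplitude. Cells
start desynchronized on a decaying low orbit (`limit_radius` 0.15,
`init_radius` 0.35, λ = 0.1), so an untreated cell's successive peaks
decline, while a treated (responder) cell's kick re-inflates its radius
and its next peak is higher. Responders are drawn per cell with the stated
probability (default 0.66) from a seeded binomial, and the draw is the
ground truth against which classification is scored.

`simulate_count_timeseries()` emulates the RNA-seq design: 13 timepoints,
0–48 h every 4 h. Rhythmic genes carry a cosine on the log2 scale
(default amplitude 1 log2 unit, uniform random acrophase); "responsive"
genes additionally gain a step of `true_log2fc` (default 2) from t ≥ 4 h,
emulating early response genes; counts are negative binomial (dispersion
0.1) with uniform library-size factors in [0.7, 1.3]. The generator does
not emulate gene–gene correlation, varying per-gene dispersions,
compositional effects, or annotation structure — so passing tests
demonstrate estimator correctness under the stated model, not performance
on real RNA-seq.

Replicates per timepoint are a free design parameter (the real design's
replicate count is not part of the generator's anchors). The transcriptome
scenario uses `n_reps = 4`: a power computation for the Welch test below
shows that with 3 replicates per group the smallest attainable p-value
(~3·10^-3^ at fold change 2 and dispersion 0.1) cannot clear a
Benjamini–Hochberg threshold at ~800 tests, while 4 replicates detect the
planted fold changes with high precision.

## Detrending and rhythmometry

Detrending subtracts a centred moving average (default window 24 h) and
trims the half-window at each edge rather than padding — padded edges
would fabricate data where phase estimates are most fragile. When the
sampling grid divides the window exactly, the average uses trapezoidal
weights spanning precisely one period; the periodic trapezoid rule is
exact for a pure cycle, so a 24-h cosine passes through detrending
untouched and detrending is idempotent. Subtraction (not division) is the
default because it preserves amplitude units, which the %-of-reference-peak
quantifications depend on; divisive normalisation is available as a mode.

The fixed-period cosinor is solved in the linear sine/cosine
parameterisation; rhythmicity is the zero-amplitude F test on
(2, n−3) degrees of freedom, and the permutation variant recomputes the
same F under time-label permutations with the add-one estimate
(b+1)/(B+1). The damped cosinor profiles the linear parameters out and
searches (period, damping) by a 1-h period grid in [18, 30] h crossed with
a damping grid, refined by Nelder–Mead; ties on equal residual sum of
squares break towards smaller damping, then the period closer to 24 h.
The acrophase convention everywhere is "hours after the reference time at
which the fitted curve peaks", in [0, period).

Phase shifts are reported in (−12, +12] h with advances positive. The
baseline-extrapolation estimator fits the pre-event window, predicts peak
times, and compares them with a cosinor fit of the post-event window that
excludes a 12-h transient (the immediate radial/phase transient after a
kick contaminates the fit; the exclusion length is configurable). For
multi-pulse protocols the baseline window ends at the *first* pulse. The
control-referenced estimator uses a parallel control's fitted peak as the
prediction and needs no baseline, which is why the treadmill analysis uses
it.

The phase transition curve unwraps new phase over sorted old phases by
shortest-path steps; the winding number is the net number of cycles after
closing the curve around one full cycle of old phase. Classification
requires at least 6 phases because 4-point curves cannot fix the winding
reliably; simulated classifications use 12.

## Count-matrix stages

The count filter reads "exceeding 50 counts in at least one timepoint"
strictly (> 50) and applies it per sample by default — for a
one-sample-per-timepoint design the two readings coincide, and a
replicate-mean mode is provided. Normalisation is log2(CPM + 1).
Differential response is a per-gene Welch t test on the normalised values
with BH adjustment and direction calls at the stated |log2FC| and q
cutoffs; it deliberately stands in for a negative-binomial GLM, trading
power for a fully in-repo, assumption-light test that the synthetic
designs have adequate replicates for. Rhythmicity tiers mirror the
two-threshold reporting of the source analyses: tier 1 at raw p < 0.05,
tier 2 at BH q < 0.05 (tier 2 ⊆ tier 1 by construction). Phase projection
z-scores genes across the reference timepoints, applies the same scaling
to the query, and assigns the timepoint with maximal Pearson correlation —
a directly testable stand-in for reading phase off a PCA plot.

## Problem sizes and determinism

The default analyses run at desk scale: ensembles of 1000 cells sampled
every 0.25 h over 5–9 simulated days, count matrices of 600–1000 genes
over 13 timepoints, permutation tests of 500–2000 permutations, and
20-seed replications for the calibration-style checks. Every stochastic
entry point takes an explicit seed, simulations restore the caller's RNG
state, and identical seeds give bit-identical outputs; there is no hidden
global state.

## Known limitations

* The oscillator is phenomenological; parameters such as λ and the kick
  direction have no direct molecular interpretation, and MPa→mOsm
  conversion is not modelled physically.
* The fixed-direction kick cannot reproduce every qualitative phase-response
  feature simultaneously (see the calibration trade-off above).
* Ensemble damping comes solely from desynchronization; single-cell
  amplitude death and cell–cell coupling are absent.
* The Welch differential test is less powerful than count-likelihood
  methods at few replicates; conclusions about real RNA-seq power should
  not be drawn from it.
* The whole-period mid-descending/trough phase categories are fixed at
  6/12 h after the reporter peak; tissues whose waveform is strongly
  non-sinusoidal would need category definitions of their own.
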