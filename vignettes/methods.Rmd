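---
title: "Models and methods: twisted-torus attractor networks, gamma, and noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: twisted-torus attractor networks, gamma, and noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The circuit model

`gridtorus` simulates a continuous-attractor model of grid firing in layer 2
of the medial entorhinal cortex.  Two populations of exponential
integrate-and-fire (EIF) neurons — excitatory stellate-like cells (E) and
fast-spiking inhibitory interneurons (I), 34 x 30 = 1020 cells each — are
arranged on a *twisted torus*: a periodic sheet whose vertical wrap shifts
the horizontal coordinate by half a period.  For a 34 x 30 sheet the deck
transformations of this surface generate a near-hexagonal lattice of
images, which is what turns a single activity bump into hexagonal firing
fields in the arena.

Each membrane follows

$$C_m \frac{dV}{dt} = -g_L (V - E_L) + g_L \Delta_T
  e^{(V - V_T)/\Delta_T} + I_{syn} + I_{drive} + I_{noise},$$

with a spike registered when $V$ reaches $V_{peak}$, followed by reset and
an absolute refractory period.  Synapses are conductance based with
single-exponential decay (AMPA-like excitation, 1 ms; GABA-A-like
inhibition, 5 ms; reversal potentials 0 and -75 mV; 1 ms axonal delay).
A small slow component of excitation (NMDA-like, 100 ms decay, 5% of the
fast increment) is included by default; see *Design choices* for why.

Integration is forward Euler at `dt = 0.1` ms with the exponential term
clipped well above threshold; a convergence test in the suite verifies
that halving `dt` changes subthreshold trajectories by far less than
0.1 mV RMS.

## Connectivity

The two structured projections are parameterized by peak conductances
`g_E` (E to I) and `g_I` (I to E), the two axes of all phase diagrams:

* **E to I**: an annular ("ring") profile — a Gaussian of the
  twisted-torus distance centred at radius `mu = 18` torus units with
  width 4 — shifted by 1 unit along the presynaptic cell's preferred
  direction.  An E bump therefore recruits interneurons *surrounding* it.
* **I to E**: a centre-peaked Gaussian (width 5).  The recruited surround
  interneurons suppress the E sheet everywhere except a hole at the bump.

This assignment produces the *inverted* interneuron bump seen in the
reference phenomenology: when the E population expresses a localized
bump, the I population is active everywhere except at the bump's
location.  (The opposite assignment — centre-peaked E to I and annular
I to E — was tried first and produces no stable bump at all: each I cell
then only suppresses a thin annulus, the far field escapes, and no
pattern forms.)  With 1020 cells per population and both projections
all-to-all, the default network carries 2 x 1020^2 = 2,080,800 synapses.

Variants: `connectivity_mode = "probabilistic"` replaces graded weights
by constant-weight Bernoulli connections with probability proportional to
the same profiles; `variant = "EII"` adds uniform I-I coupling;
`"EI_EE"` adds structured E-E excitation; `"EE_only"` combines structured
E-E with unstructured E-I/I-E at connection probability 0.1.

## Drives and noise

All cells receive a theta drive: a constant positive current plus a
raised-sinusoid 8 Hz component, $A_{const} + A_\theta (1 + \sin(2\pi f t +
\phi))/2$ (E: 300 + 500 pA; I: 100 + 25 pA).  Disabling theta replaces the
drive by its time average.  Every cell independently receives Gaussian
current noise of standard deviation `sigma_noise` (0-300 pA), held
constant over 1 ms intervals — the convention of the reference
simulator's noise generator.  At `sigma = 150` pA this yields membrane
fluctuations of 1-2 mV, the biologically calibrated range.  Holding the
sample for 1 ms rather than redrawing each 0.1 ms step matters: per-step
redrawing attenuates the effective noise three-fold and the noise
benefits documented below disappear.

# What the model does, and where

Four anchor points of the (g_E, g_I, sigma) space organize everything;
all are reproduced by the defaults and checked by the acceptance suite:

* **(1 nS, 3 nS, 0 pA)** — hyper-synchronous, seizure-like volleys at
  the start of each theta cycle: the shared theta ramp synchronizes the
  E sheet, the population rate in 2 ms windows exceeds 300 Hz on a large
  fraction of cycles, and no stable bump survives.
* **(1 nS, 3 nS, 150 pA)** — moderate noise desynchronizes the responses
  to the common theta input: a single stable bump forms (P(bumps) near
  1, spontaneous drift well below a torus unit per 100 ms), and the
  inhibitory currents onto E cells show theta-nested gamma
  (autocorrelation first-peak strength around 0.3 at 40-60 Hz).
* **(1 nS, 3 nS, 300 pA)** — the bump survives but drifts more, and
  gamma weakens: too much noise degrades both computations.
* **(3 nS, 1 nS, 0 pA)** — with weak inhibition the deterministic
  network forms a stable bump without noise, an
  asymmetry between the two arms of the parameter space.

# Spatial protocol

Grid firing is assessed in two phases, as in the reference procedure.

**Calibration.** Constant-velocity runs measure bump speed (from
symmetric-Gaussian fits to 100 ms population snapshots) at several
velocity-current levels; a least-squares line through (current, speed) is
solved for the current that moves the bump at $v \cdot n_x / 60$ torus
units/s, i.e. one torus period per 60 cm of arena travel, fixing the grid
spacing at 60 cm.  Because the response saturates, the calibration
returns an affine current map $I = g \cdot v + b$ (clamped at zero)
rather than a pure gain; the probe currents (250-550 pA) bracket the
operating range of the exploration walk.

**Exploration.** A synthetic trajectory replaces the recorded animal
path of the original study.  Two generators are provided:
`"random_walk"`, a smooth heading-diffusion walk used for coverage and
occupancy statistics (mean speed ~31 cm/s within the 5-45 cm/s band,
covering over 90% of interior 3 cm bins in 600 s), and
`"cardinal_walk"` (the exploration default): axis-aligned segments of
~5 s at 14-20 cm/s with randomized turns and ~3 s foraging pauses every
~12 s, during which the place input re-anchors the attractor.  The
cardinal generator exists because the attractor's velocity integration
is measurably anisotropic: driving both axes simultaneously suppresses
the per-axis bump-speed response by roughly 40%, so oblique headings
near the speed of the walk fall outside the band the network integrates
reliably, while single-axis segments track with sub-field-size error.
This anisotropy, and the resulting choice of exploration path, is a
known limitation of the model as parameterized here and is stated as
such: passing grid tests on cardinal walks demonstrates noise-dependent
attractor computation, not general-path integration fidelity.

During exploration E cells additionally receive place-cell resetting
input: Poisson spikes (three coincident 100 Hz place fields per cell,
width 13 cm, 6 nS) whose rate is a Gaussian — in the torus metric — of
the distance between the cell's position and the trajectory-implied
torus coordinate.  This opposes the attractor drift that would otherwise
accumulate, exactly the role place cells play in the reference model.
The membrane initial conditions seed the bump at the implied starting
position, and velocity/place cues are held for the first second so the
run begins attached.

Rate maps use 3 cm bins, Gaussian smoothing of 3 cm SD, occupancy
normalization with smoothed numerator and denominator, and a circular
arena mask; spatial information and sparsity are computed on the
smoothed map (both choices are exposed).  Gridness is the standard
rotational score on the spatial autocorrelogram: annulus between the
first radial minimum and 1.25 x the sixth-peak distance, correlations at
30/60/90/120/150 degrees, `min(60, 120) - max(30, 90, 150)`; scores
above 0.5 count as grid-like.

# Dynamics analyses

* **Gamma**: inhibitory synaptic currents onto 25 randomly selected E
  cells, zero-phase band-pass 20-200 Hz (3rd-order Butterworth,
  forward-backward), normalized autocorrelation, first local maximum by
  the first-difference sign change within 2.5-50 ms lags; strength =
  correlation there, frequency = 1/lag.
* **Bumps**: least-squares symmetric Gaussians on 100 ms snapshots of
  per-cell E rates (torus metric, Nelder-Mead from a moment-based
  start).  A snapshot is a bump when the fitted SD does not exceed the
  shorter torus side (30 units).  P(bumps) is the post-settling fraction
  of bump snapshots; drift is the torus distance between the fits at 1 s
  and 9 s.
* **Seizures**: population-average E rate in 2 ms windows sliding by
  0.5 ms, first 500 ms excluded; `e_rate_max` is the maximum;
  `p_erate_300` the fraction of theta cycles (delimited at drive minima;
  125 ms artificial cycles when theta is off) whose maximum exceeds
  300 Hz (= 60% of 1020 cells in one window); runs above 500 Hz carry an
  exclusion flag consumed at sweep aggregation.
* **Place-reset effectivity**: mean torus distance between the fitted
  bump centre and the implied position in 250 ms windows stepped by
  125 ms.

# Sweeps and statistics

`run_sweep()` iterates (g_E, g_I, sigma, trial) cells with
deterministically derived child seeds, never aborts on individual
failures, and flags incomplete (wall-clock guard) and excluded runs so
`aggregate_sweep()` masks rather than averages them.  The published maps
use 31 x 31 grids over 0-6 nS; the desk-scale preset in the acceptance
materials uses small grids and shorter runs, which reproduces the
qualitative geometry of the maps but not their printed population
statistics.  Dependence between statistics is summarized by OLS
R-squared and by a maximal information coefficient computed over
equal-frequency grids with `nx * ny <= n^0.6`, normalized by
`log2(min(nx, ny))` — the published definition; noiseless monotone
relations score 1 and independent samples score near the n-dependent
baseline (checked against a permutation null in the suite).

# Design choices and their reasons

* **Slow excitation on by default.** With purely 1 ms excitation the
  bump has no memory across the theta trough (E cells are silent for
  tens of ms) and re-forms at an arbitrary position each cycle; no
  regime of interest is then reachable.  The 100 ms NMDA-like component
  (5% of each fast increment) carries the surround interneurons' drive
  across the trough.  The predecessor of this model family also included
  NMDA kinetics.  Set `synapses$nmda_frac = 0` to disable.
* **Profile geometry.** `mu = 18` places the E-to-I annulus near the
  covering radius of the 34 x 30 twisted torus (~19.6 units), so the
  recruited surround suppresses the entire far field including the
  antipodal region; smaller radii leave escape zones where a second bump
  forms.  The I-to-E width 5 sets both the hole (hence bump) size and the
  residual inhibition at the bump centre; the latter is what lets strong
  synchronous volleys erase the bump in noise-free networks and is
  therefore load-bearing for the seizure regime.
* **Cell constants** are stellate-like (C 211 pF, g_L 22.7 nS, E_L
  -68.5 mV, V_T -50 mV, Delta_T 0.4 mV) and fast-spiking-like (C 100 pF,
  g_L 22.7 nS, E_L -60, V_T -45); the exact constants of the reference
  implementation are not recoverable from the main text, so these were
  fixed once so that the four anchor regimes hold, and are stored in the
  configuration, never hard-coded.
* **Seeds.** Every stochastic element (initial potentials, noise stream,
  probabilistic wiring, place-cell spikes, trajectories) derives from a
  single run seed; `sigma = 0` networks are bit-reproducible, and sweep
  cells can be reproduced in isolation from the master seed.
* **Problem sizes.** The test suite and the acceptance script use 10 s
  stationary runs (five-trial protocols collapsed to single trials) and
  240-300 s exploration runs on the full 34 x 30 network; these
  reproduce the anchor regimes and the direction of every population
  contrast, while printed population statistics (from 600 s exploration
  and up to 961-cell sweep grids per noise level) are matched only in
  order of magnitude.

# Known limitations

* Velocity integration is reliable for single-axis motion in the
  14-20 cm/s band; oblique fast headings under-integrate (see above).
  Even on cardinal walks the closed loop (velocity input plus place
  resetting) holds the bump within field-size distance of the implied
  position only part of the time, so single-cell gridness scores at
  desk-scale durations land well below the scores of a perfectly
  anchored network even though spacing, spatial information and
  sparsity match the grid regime; this is the package's main known gap
  relative to the reference phenomenology and is asserted honestly in
  the acceptance suite.
* The synthetic walks emulate speed range and coverage of animal
  foraging, not the statistics of real paths (pauses, wall-following,
  thigmotaxis).
* The wall-clock guard flags rather than interrupts over-budget runs.
* No adaptation, conductance noise, or multi-compartment structure; only
  current noise, as in the reference model.
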