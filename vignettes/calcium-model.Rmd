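---
title: "Modeling mechanically evoked calcium transients: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling mechanically evoked calcium transients: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caflux)
```

## The problem

When an epithelial monolayer is mechanically stimulated at the
cell–substrate interface — here by nanoscale shear of a photoresponsive
substrate under a scanned laser — the directly perturbed cells fire a fast
cytosolic Ca²⁺ surge (rising within a few seconds) followed by a slow decay
back to baseline over tens of seconds. The signal spreads to adjacent cells
through gap junctions, and the two populations differ in kinetics: directly
stimulated ("target") cells decay markedly more slowly than their
neighbors, even at matched amplitude. `caflux` implements the quantitative
machinery around that observation: a single-cell kinetic model in which
co-entering Na⁺ throttles the Na⁺/Ca²⁺ exchanger, the fluorescence-trace
feature pipeline, the model fit to amplitude-quantile averaged traces,
in-silico perturbation experiments, and a synthetic-data generator that
lets every step be tested without microscopy data.

## The model

Two dimensionless state variables, the relative cytosolic Ca²⁺
concentration $c$ and the relative Na⁺ concentration $n$ (both 1 at rest),
plus a slow inactivation gate $h$ on the release unit:

$$\frac{dc}{dt} = J_\theta(t) + J_{CRU} + J_{pump} + J_{leak} + J_{NCX},
\qquad
\frac{dn}{dt} = J_\theta^*(t) + J_{pump}^* + J_{leak}^*.$$

The stimulus influx $J_\theta(t)$ is a rectangular pulse (onset, duration,
intensity); its Na⁺ twin is $J_\theta^* = J_\theta$ in target cells, where
the mechanosensitive channels are non-selective cation channels, and
$J_\theta^* = 0$ in neighbor cells, which receive Ca²⁺ through gap
junctions without a Na⁺ load. The flux forms are a minimal excitable CICR
system of the two-variable (Atri-class) type, with one explicit knob for
the Na⁺–NCX interaction:

* $J_{leak} = k_{leak}$ — constant inward leak;
* $J_{pump} = -V_{pump}\,c^2/(K_{pump}^2+c^2)$ — lumped SERCA/PMCA
  extrusion;
* $J_{CRU} = V_{cru}\,h\,c^m/(K_{cru}^m+c^m)$ — Ca²⁺-induced Ca²⁺ release,
  with gate dynamics $dh/dt = (h_\infty(c)-h)/\tau_h$,
  $h_\infty(c) = K_h^2/(K_h^2+c^2)$, which terminates the regenerative
  release;
* $J_{NCX} = -V_{ncx}\,\dfrac{c}{K_{ncx}+c}\,n^{-q_{ncx}}$ — the exchanger;
  the factor $n^{-q}$ encodes that a raised cytosolic Na⁺ level erodes the
  transmembrane Na⁺ gradient the exchanger runs on. $q_{ncx}=0$ switches
  the coupling off;
* $J_{pump}^* = -k_{na}\,n$ and $J_{leak}^* = k_{na}$ — first-order Na⁺
  relaxation. Na⁺ dynamics are deliberately not fed back from NCX turnover:
  the absolute cytosolic Na⁺ pool is orders of magnitude larger than the
  Ca²⁺ it moves.

The biology fixes the flux inventory (leak, pump, CRU, NCX, stimulus)
and the Na⁺-inhibition mechanism, but not the algebra; the forms above are
this package's own concrete choice within that inventory, selected as the
smallest excitable CICR system with an explicit Na⁺ knob. The inactivation
gate is likewise a design choice: $\tau_h \to 0$ recovers a gateless,
purely algebraic CRU.

Both leak constants are solved at construction so that $c=n=1$,
$h=h_\infty(1)$ is an exact equilibrium; `resting_state()` re-verifies the
balance to $10^{-10}\,\mathrm{s^{-1}}$ and rejects hand-edited parameter
sets. Integration uses `deSolve::ode` (lsoda, rtol $10^{-8}$, atol
$10^{-10}$), with the pulse edges handled by integrating the three smooth
segments separately; a test cross-checks the adaptive solution against a
fixed-step fourth-order Runge–Kutta reference at $dt = 10^{-3}$ s.

## The trace pipeline

Fluorescence is taken proportional to $c$ (a linear indicator with no
saturation), because the analysis compares baseline-normalized intensities
directly with the model's relative concentration. The pipeline mirrors the
imaging protocol: 1.23 s frames, 10 pre-stimulus frames, 121 post-stimulus
frames.

* **Normalization**: each trace is divided by $I_{basal}$, the mean of the
  10 frames immediately preceding the stimulus.
* **Amplitude**: the maximum normalized intensity over post-stimulus
  frames (baseline-window maxima are ignored).
* **50% decay time**: the time from the frame of the maximum to the first
  crossing of the mid-level between maximum and baseline,
  $(A+1)/2$, located by linear interpolation between frames. The
  literature also uses the phrase "50% of the maximum"; both conventions
  exist (`decay_reference = "mid_basal"` is the default, `"half_max"` the
  alternative) because the operational definition in the experimental
  protocol is the mid-level one. Linear interpolation matters: frames are
  1.23 s apart while decays run 40–70 s, so nearest-frame quantization
  would add up to ±0.6 s of noise per trace.
* **Classification**: cells are convex polygons in continuous µm
  coordinates; a *target* overlaps the stimulation rectangle with positive
  area, a *neighbor* is within an adjacency distance (default 0.5 µm
  boundary distance) of a target, everything else is *other*. Overlap uses
  Sutherland–Hodgman clipping, adjacency a segment-distance computation;
  tests compare against an independent interval-arithmetic oracle on
  random rectangle layouts.
* **Group averaging**: per group, responder traces are ranked by amplitude
  (ties broken by cell id) and split into near-equal quantile bins
  (default quartiles); the bin average is the frame-wise mean. Groups with
  fewer traces than bins get a reduced bin count with a warning.

## Fitting

The fit minimises the pooled, unweighted sum of squared frame-wise
residuals across all (group, bin) averaged traces — averages of many cells
have near-homogeneous noise, so weighting would add assumptions without
information. Shared kinetic parameters are fitted once across all bins
simultaneously (on a log scale); each bin has its own stimulus onset,
duration and intensity. Bounds: onset within ±3 frames of the known
stimulation time; duration in [0.03, 10] s (the pattern inscription takes
tens of milliseconds, the observed surge 2–5 s); intensity positive.
The optimizer is bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) with
multi-start (default 8 seeded starts: the informed initial guess plus
uniform draws within bounds); the objective is smooth and low-dimensional,
so global search machinery is unnecessary. Same seed, data and bounds give
a bitwise-identical result.

**Identifiability.** For bins whose response barely engages the CICR
nonlinearity (weak neighbor bins), the pulse duration and intensity trade
off almost exactly at constant total influx charge
(intensity × duration): a short strong pulse and a long weak pulse of the
same charge produce indistinguishable traces at 1.23 s sampling and
realistic noise. The recovery tests therefore check the intensity itself
where it is identifiable (target bins, where the regenerative release pins
the pulse shape) and the influx charge everywhere. The shared exchanger
exponent $q_{ncx}$ is well identified by the target/neighbor decay
contrast.

## Calibration

The shipped default parameters (`default_parameters()`,
`inst/extdata/default_params.json`) were produced by
`scripts/calibrate.R` (seed 20231109): 24 Latin-hypercube multi-starts of
Nelder–Mead on a weighted relative-error objective, then four polish
rounds, against six summary targets measured through the same trace
pipeline as any data — amplitude 2.4 and 50% decay time 71 s with the Na⁺
pathway active; amplitude 2.0 and decay time 40 s with it disabled; a 70%
amplitude-increase loss under store depletion; and a relative
amplitude-increase of 0.53 at influx fraction 0.45 on the sweep curve.
The calibrated set reproduces all six within a few percent:

```{r calibration, eval = FALSE}
params <- default_parameters()
stim <- standard_stimulus()
traj <- simulate_model(params, stim, t_end = 162, dt_out = 1.23)
trace_features(normalize_trace(trajectory_to_trace(traj)))
#> amplitude 2.47, decay50 70.1 s
sodium_free(params, stim)
#> amplitude 1.97, decay50 40.3 s
store_depletion(params, stim)$reduction_pct
#> 69.8
```

One calibrated value deserves comment: the fitted Na⁺ relaxation rate
$k_{na} \approx 6\times10^{-4}\,\mathrm{s^{-1}}$ is slow, meaning the
cytosolic Na⁺ load persists well beyond the recording window. The decay
contrast constrains only that Na⁺ stays elevated *through* the ~70 s decay;
anything slower is observationally equivalent within the 161 s record, and
the calibration has no information to pin it further. Consequently $c$
re-approaches its resting value on the Na⁺ relaxation timescale (tens of
minutes) after a Na⁺-coupled pulse — still asymptotically stable, as the
return-to-rest test verifies over a long horizon.

## Perturbation experiments

* `influx_sweep()` scales the stimulus intensity by fractions of its
  calibrated value with every kinetic parameter (including CICR) held
  fixed — a graded in-silico channel knock-out. The resulting
  amplitude-increase curve is concave: at full influx the release unit is
  near saturation, so amplitude falls more slowly than influx.
  `ms_fraction_estimate()` inverts the curve (after scaling its full-influx
  point to the observed wild-type increase) by monotone interpolation at an
  observed knock-out increase. With the observed baseline increases
  (wild type 1.22; knock-out clones 0.71 and 0.59) the implied influx loss
  is 51% and 57% — the knocked-out channel carries at least half of the
  mechanosensitive influx.
* `store_depletion()` re-runs the simulation with $V_{cru}=0$ (emptied ER
  stores) and reports the lost fraction of the amplitude increase (~70%
  at the calibrated set: most of the transient is internal amplification).
* `sodium_free()` clamps $n = 1$ *and* sets $J_\theta^* = 0$: replacing
  extracellular Na⁺ with an ion the exchanger cannot transport both removes
  the stimulus Na⁺ load and preserves the exchanger's driving force, so
  both effects belong to the perturbation. Intensity-only scaling is used
  in the sweep (the pulse duration is a property of the mechanical event,
  not of channel count).

## The synthetic-data generator

`synth_config()` + `generate_traces()` emulate one imaging experiment:
a confluent monolayer tiled by jittered rectangular cells (sub-micron
gaps), a 1.4 × 80 µm stimulation rectangle across the middle row,
per-group responder probabilities (target 0.7, neighbor 0.5, other 0.1 —
free knobs; the observation behind them is only that part of the
stimulated cells respond), per-cell log-normal scaling of the stimulus
intensity (sdlog 0.25) as the source of amplitude heterogeneity, log-normal
baselines, and noise $I_{basal}\,c\,(1+\varepsilon_m) +
I_{basal}\,\varepsilon_a$ with $\sigma_m = 0.02$, $\sigma_a = 0.01$ —
a photon-noise-like model at desk simplicity. Output is byte-identical
under a fixed seed.

What it does **not** emulate: photobleaching, indicator saturation,
motion, segmentation error, spatially correlated noise, dome structures,
or any real gap-junction diffusion physics (neighbor cells simply receive
an uncoupled, reduced-intensity influx, default 60% of the target's).
Passing tests on synthetic data therefore demonstrate that the pipeline
and fit recover what the generator put in — internal consistency and
identifiability under the stated noise — not that the model is correct for
any particular real recording.

## Problem sizes and numerical choices

The packaged analyses and tests use one field of 100–200 cells, 131
frames, quantile bins of 2 per group for the fit, 21-point sweeps, and a
3-start fit with a 100-iteration cap — sizes chosen so the full workflow
reruns in minutes on a laptop while leaving every statistical check
well-powered. Degenerate inputs are handled explicitly: empty stimulation
regions classify everything as "other"; traces that never cross the decay
level carry an undefined-decay flag rather than a number; zero-variance
covariates make the correlation undefined rather than NaN; simulation
failures inside the fit objective return penalty residuals so the
optimizer survives pathological proposals.

## Known limitations

* Single-cell and zero-dimensional: no spatial Ca²⁺ diffusion, no explicit
  gap-junction flux, no membrane potential.
* The flux forms are a modeling choice, not a measured mechanism;
  parameter values are a calibration to summary statistics, not a fit to
  raw traces, and should be treated as one consistent point in a likely
  non-unique set.
* The neighbor-bin stimulus intensity is identifiable only as a charge
  (see *Fitting*).
* The fluorescence proxy is linear; strongly saturating indicators would
  bias amplitudes downward in real data in a way the pipeline does not
  correct.
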