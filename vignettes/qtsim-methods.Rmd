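---
title: "qtsim: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{qtsim: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Drug-induced prolongation of the QT interval is a central concern in
cardiac safety assessment.  The definitive clinical readout is the
Thorough QT (TQT) study, which asks whether a compound prolongs the
heart-rate-corrected QT interval by 5 ms or more.  Long before a TQT study
is possible, automated patch-clamp screens measure how strongly a compound
blocks the major ventricular ion channels.  `qtsim` implements the
in-silico bridge between the two: it converts multi-channel screening
potencies into conductance scalings of human ventricular action potential
(AP) models, paces those models to steady state, and asks whether the
predicted change in action potential duration (APD90 — duration at 90%
repolarisation, the cellular analogue of QT at 1 Hz pacing) reaches the
same 5 ms criterion at clinically relevant free plasma concentrations.

## Dose-response model

Screens report, per compound and channel, the proportion of peak current
remaining at each tested concentration.  These are summarised by a Hill
curve

$$ R([C]) = \frac{1}{1 + ([C]/IC_{50})^n}, $$

with the Hill coefficient fixed at $n = 1$: with typical screening data a
free coefficient adds variance without adding information, so only the
$IC_{50}$ is fitted.  Potencies are handled as pIC50s ($-\log_{10}$ of the
molar $IC_{50}$); concentrations are micromolar throughout, converted at
the boundary ($IC_{50}\,[\mu M] = 10^{6 - pIC_{50}}$).

Fitting is ordinary least squares on the fraction-remaining scale, with
raw fractions clipped to $[0,1]$.  The one-parameter objective is
minimised by a deterministic multi-start Brent search seeded from the
fixed grid $0, 1, \dots, 12$; the best SSE wins and ties break towards the
smaller pIC50, so a fit is a pure function of its data.  Two conventions
matter downstream:

* **Flooring.**  A fitted pIC50 at or below 0 (an $IC_{50}$ above 1 M) is
  stored as exactly 0.  A floored potency is not discarded: it is carried
  into simulation, where it produces at most 0.01% block at the top
  screening concentration of 100 µM — numerically present, biologically
  negligible.
* **Flat screens.**  A screen whose strongest observed response is less
  than 5% block (all fractions above 0.95) is reported floored outright
  rather than chasing a marginal optimum; such data carry no usable
  potency signal, and ordinary least squares would otherwise return an
  arbitrary weakly-identified value.

## Conductance block

The pharmacology enters the electrophysiology through the
conductance-block (pore-block) approximation: binding is assumed fast
relative to channel gating, to occur in any channel conformation, and to
leave gating kinetics untouched, so a compound simply scales each
channel's maximal conductance by the unblocked fraction:

$$ g_j = \left(1 + \frac{[C]}{IC_{50,j}}\right)^{-1} \bar g_j . $$

State-dependent or kinetic drug binding is deliberately out of scope.

Five screened channels map onto model currents: hERG → $I_{Kr}$,
KCNQ1/MinK → $I_{Ks}$, NaV1.5 → $I_{Na}$, CaV1.2 → $I_{CaL}$,
Kv4.3/KChIP2.2 → $I_{to}$.  $I_{K1}$ is also a scalable handle — it is
needed to reproduce the single-channel-block phenotypes — but no screen
ever sets it.  One mapping subtlety: Kv4.3 carries the *fast* transient
outward current.  The Grandi model distinguishes fast and slow $I_{to}$
components, so its block handle scales only the fast conductance; the ten
Tusscher and O'Hara models have a single $I_{to}$, which is scaled as a
whole.

## The three ventricular models

Three human ventricular AP models are compiled into the package as C
right-hand sides, transcribed from the published model definitions:

| registry name | model | variant | states |
|---|---|---|---|
| `tentusscher2006` | ten Tusscher & Panfilov (2006) | epicardial | 19 |
| `grandi2010` | Grandi, Pasqualini & Bers (2010) | epicardial | 39 |
| `ohara2011` | O'Hara, Virag, Varro & Rudy (2011) | endocardial | 41 |

The endocardial O'Hara variant is used because that model was primarily
parameterised against endocardial data.  The models are *not* parsed from
CellML at run time; they are fixed transcriptions, and their fidelity is
guarded by tests: quiescence at the published resting state, conductance
linearity of every block handle, gate-boundary invariance, agreement of
the adaptive solution with an independent fixed-step RK4 integration of
the same equations (1 µs steps; trace agreement within 1 mV, APD90 within
1 ms), and the qualitative single-channel-block signatures
(O'Hara fails to repolarise under complete hERG block; ten Tusscher alone
prolongs strongly under $I_{Ks}$ block; all three shorten under
$I_{CaL}$ block).  Potassium in the Grandi model is held constant, as in
its published code.

Each model keeps its own CellML-style square-pulse stimulus (ten
Tusscher: −52 A/F for 1 ms; Grandi: −9.5 A/F for 5 ms; O'Hara: −80 A/F
for 0.5 ms), configurable through the model object.

## Pacing and APD measurement

QTc is defined so as to equal QT at 1 Hz, so all simulations pace at 1 Hz.
Integration uses a stiff adaptive solver (`deSolve::lsoda`) with relative
tolerance $10^{-6}$, absolute tolerance $10^{-8}$, and a maximum step
smaller than the stimulus duration so the square pulse is never stepped
over.  Pseudo-steady state is declared when the relative 2-norm of the
change in the full state vector between successive pace onsets falls
below a tolerance (default $10^{-6}$, capped at 10 000 paces).  This
criterion is a design choice of this package; it is deliberately exposed
(`convergence_tol`, `max_paces`) rather than hard-wired.  When a period-2
(alternans-like) rhythm prevents convergence, the result honestly reports
`converged = FALSE` together with the final pace — masking such dynamics
by averaging would misrepresent the model.

APD90 is measured on a densely sampled final pace (0.1 ms sampling, far
below the 5 ms decision threshold): baseline is the pre-stimulus voltage
at pace onset, amplitude is peak minus baseline, and APD90 runs from the
point of maximum upstroke velocity to the first downward crossing of
(peak − 0.9 × amplitude), linearly interpolated between samples.  Timing
from the upstroke rather than the stimulus makes the measure robust to
stimulus artefact; both conventions exist in the literature and the
repolarisation percentage is a parameter.  Two failure modes are flagged
rather than numbered: amplitude below 10 mV (`no_depolarisation`) and a
missing downward crossing (`repolarisation_failure`, the cell stuck at
depolarised potentials).  Flags propagate — a difference of APDs with a
flagged operand is a flagged difference.

## Concentration sweeps

Sweeps cover 1 nM to 100 µM in 20 points equally spaced in $\log_{10}$,
read as 20 grid points inclusive of both endpoints.  Concentrations are
visited in ascending order and each solve is warm-started from the
previous concentration's steady state, emulating a sequential wash-on
protocol; a cold-start mode re-equilibrates from control at every
concentration, and a regression test holds the two within 1 ms of each
other where no failure flags arise (no spurious hysteresis).  Failed
points are flagged and serialised, never silently dropped, so
repolarisation failure remains visible downstream; they are excluded from
interpolation (a query between a numeric and a flagged point is reported
non-evaluable rather than invented).

## Uncertainty propagation

Screening potencies are noisy.  The package propagates assay variability
by resampling: each channel's pIC50 is perturbed independently as
$\mathcal N(\text{pIC50}, \sigma_{\text{channel}})$, draws below 0 are
re-floored at 0, the sweep is re-run per draw, and the pointwise empirical
2.5th/97.5th percentiles form a 95% credible band.  The per-channel
$\sigma$ is *data*, not code: it should come from control-assay
variability for the platform at hand, and defaults to 0.2 log units — a
typical screen-to-screen spread — when nothing better is supplied.  Draws
are generated once per band from a single seed, so bands are bit-identical
across runs and independent of execution order.  Draws showing
repolarisation failure at a concentration are excluded from the
percentiles there and reported as a failure fraction instead.  The
percentile estimator itself is the usual order-statistics rule with linear
interpolation, exposed as `percentile()` so it can be tested against an
independent oracle.

A simulation study in the test suite checks calibration directly: with
"true" potencies drawn from the same distribution the sampler assumes, the
95% band covers the true curve's ΔAPD90 in about 95% of replicates
(binomial tolerance at 200 replicates, reduced grid and pacing).

## TQT evaluation

Clinical exposure is summarised per compound by Cmax (ng/mL) at the
highest TQT dose, percent plasma protein binding, and molecular weight;
since 1 ng/mL is 1 µg/L, the free molar concentration is

$$ C_{free}\,[\mu M] = \frac{C_{max}}{MW}\Bigl(1 - \frac{PB}{100}\Bigr). $$

A prediction is scored against the observed mean QTc change at that dose.
Observed positive means ΔQTc ≥ 5 ms (inclusive).  Predicted positive
means the maximum interpolated ΔAPD90 over a symmetric fold-change window
$[C/f,\; C f]$ (intersected with the sweep grid) reaches 5 ms; $f = 1$ is
the point evaluation at the estimated concentration, and repolarisation
failure anywhere in the window counts as positive.  The window
acknowledges that estimated clinical exposures are uncertain to an order
of magnitude or more.  The same symmetric rule is applied to
observed-negative compounds, which means widening the window can create
false positives as well as recover false negatives; predictions are
therefore monotone in the window only in the positive direction, and the
summary table reports every (model, dataset, window) cell separately with
no ensembling across models.

Sensitivity, specificity and accuracy are computed from exact integer
counts and only rounded for display.  Sensitivity with no observed
positives is reported as undefined, never as zero.

## Data

The package bundles the screening panel it analyses: pIC50s for 34
marketed compounds across hERG (Quattro, Barracuda, and manual
patch-clamp sources), CaV1.2 (Quattro, Barracuda), NaV1.5 and KCNQ1
(Quattro, second Quattro), and Kv4.3 (Quattro).  The Barracuda screen
covers 26 of the 34 compounds; absent cells are absent, not zero — in
particular the Barracuda/second-Quattro dataset has no Kv4.3 screen, so
$I_{to}$ stays unblocked there.  Three dataset definitions mirror the
screening campaigns: `Q` (Quattro for all five channels), `BQ2`
(Barracuda for hERG and CaV1.2, second Quattro for NaV1.5 and KCNQ1) and
`MQ` (Quattro with the manual patch-clamp hERG value substituted).

Clinical TQT exposures are **not** bundled.  `generate_synthetic_tqt()`
produces schema-identical synthetic cohorts (molecular weight uniform on
200–700 g/mol, log-uniform Cmax, realistic protein binding, and a
configurable effect model with retained truth labels), which is what the
end-to-end tests and the acceptance script evaluate against.  Metrics
computed on synthetic cohorts exercise the machinery; they do not estimate
clinical performance.

## What the synthetic generators do and do not emulate

The concentration-effect generator produces independent Gaussian noise
around an exact Hill curve on a log-spaced grid — adequate for testing
estimator bias and spread, but real screens show heteroscedastic,
occasionally non-monotone artefacts (well failures, solubility limits)
that are not modelled.  The TQT generator draws exposure covariates
independently of the screening potencies, so synthetic
sensitivity/specificity values reflect the bookkeeping, not pharmacology.
Passing tests on these fixtures therefore demonstrates correctness of the
pipeline, not predictive performance on real compounds.

## Numerical choices and problem sizes

Defaults follow full rigour (steady-state tolerance $10^{-6}$, up to
10 000 paces, 20-point grids, 500-draw bands).  The test suite and the
acceptance script run the identical protocol at reduced sizes chosen as
the package's own test design: steady states to $2\times10^{-6}$ relative
change (a few hundred paces), 8-point grids for the 34-compound panel
sweep, 150-draw bands with 200-replicate coverage checks, and
fixed-step reference integrations at 1 µs for one pace.  The ten Tusscher
model is the workhorse of the cheap end-to-end tests because it is the
smallest of the three systems; the fidelity and phenotype tests cover all
three.

## Known limitations

* Single cells only: no tissue or pseudo-ECG stage, so predicted ΔAPD90
  is compared directly with clinical ΔQTc without rescaling.
* The conductance-block approximation ignores binding kinetics and
  state-dependence, which matter more for pro-arrhythmia than for plain
  APD prolongation.
* Screens cover five channels; trafficking effects, channel activation
  (as opposed to block), metabolites and nervous-system effects are
  invisible to the pipeline.
* The steady-state detection rule and the upstroke-referenced APD
  convention are this package's choices among reasonable alternatives;
  both are configurable so results can be aligned with other tools.
* Model transcriptions are verified by internal consistency, published
  resting/APD values and phenotype tests, not against an external CellML
  toolchain at run time.
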