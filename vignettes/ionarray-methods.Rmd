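---
title: "Models and methods behind ionarray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ionarray}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ionarray` simulates and analyzes high-density arrays of ion-selective
electrolyte-gated graphene transistors. This vignette documents the
physical model, the estimators built on it, the numerical choices, and
the limits of what the simulations can show. It states no empirical
result beyond what the package's test suite and `scripts/acceptance.R`
themselves compute.

## 1. Sensing model

### Membrane response

An ion-selective membrane (ISM) in contact with the electrolyte
develops an interfacial potential governed by the Nernst equation; the
effect of imperfect selectivity is captured by the Nikolsky–Eisenman
effective activity:

$$V_M = \frac{\ln 10\,R\,T}{z\,F}\,
\log_{10}\frac{a_\mathrm{eff}}{c_\mathrm{ref}},\qquad
a_\mathrm{eff} = c_i + \sum_{j\ne i} K_{ij}\,c_j^{\,z_i/z_j}.$$

Activities are identified with molar concentrations throughout (the
ideal-solution assumption; sensitivities are characterized against
concentration, not single-ion activity). At 298.15 K the ideal slope is
59.16 mV/decade for monovalent and 29.58 mV/decade for divalent
targets. `membrane_potential()` raises an error when the effective
activity or the reference concentration is non-positive, where the
logarithm is undefined.

Selectivity coefficients default to small but non-zero values (0.01
within the monovalent pair, 0.005 across valences): multiplexed chips
demonstrably carry cross-ISM information, and a zero default would
erase exactly the signal the classification pipeline exploits.

### Transfer-curve model

The published device model is cited but not printed in the source
literature, so the package uses the standard compact EGFET form that
reproduces the V-shaped transfer characteristic and exposes the named
physical parameters (contact resistance, mobility, carrier density):

$$I_{DS} = \frac{V_{DS}}{2R_c + (L/W)/(q\,\mu\,n_s)},\qquad
n_s = \sqrt{n_0^2 + \left(\frac{C_{edl}\,\Delta V}{q}\right)^2},$$

with $\Delta V = V_{GS} + s\,V_M - V_\mathrm{dirac}$. Two properties of
this form matter for everything downstream:

* the conduction minimum sits at
  $V_{GS} = V_\mathrm{dirac} - s\,V_M$, so increasing cation
  concentration translates the curve left along the gate axis, and
* a concentration change is a **pure translation** — the test suite
  verifies curve identity to 1e-12 relative after shifting the gate
  grid by the membrane-potential difference.

The per-device factor $s$ (`sens_scale`) multiplies the Nernst slope
and models sub-/super-Nernstian devices; defect-site charge-transfer
physics behind super-Nernstian behavior is deliberately reduced to this
one variance term.

### Transients

`simulate_transient()` relaxes the current exponentially toward the
steady-state `simulate_iv()` value with the membrane time constant
$\tau$; the 90% response time of a step is $\tau\ln 10$. Stock
membranes are parameterized so the population-mean response times are
7.4 s (K⁺), 5.9 s (Na⁺) and 5.1 s (Ca²⁺), with log-normal device
spread chosen to reproduce the reported scatter (±1.3, ±3.3, ±1.1 s).

## 2. The synthetic-data generator

`population_model()` + `sample_chip()` define the study conditions:

| parameter | default | why |
|---|---|---|
| array | 16 × 16 pixels | platform geometry |
| yield | Bernoulli(0.84) per pixel | > 80% working, ≈ 215 of 256 |
| $V_{\mathrm{dirac},0}$ | Normal(0.15 V, 0.04 V) | pre-functionalization Dirac statistics |
| $\mu$ | log-normal, median 0.1 m²/Vs | graphene-on-glass mobility scale |
| $R_c$ | log-normal, median 1 kΩ | contact-dominated device tails |
| $n_0$ | log-normal, median 5×10¹⁵ m⁻² | residual carrier density |
| $C_{edl}$ | log-normal, median 0.02 F/m² | electrolyte double layer |
| doping offsets | +0.25 V (K⁺), +0.03 V (Na⁺), +0.20 V (Ca²⁺) | K⁺/Ca²⁺ ionophore cocktails p-dope strongly, Na⁺ barely |
| `sens_scale` mean | 0.925 / 0.960 / 1.018 | reproduces −54.7 / −56.8 / −30.1 mV per decade |
| current noise | 1% multiplicative per sample | measurement-chain noise |
| sweep | −0.6 … 0.9 V, 10 mV steps (151 pts) | standard characterization sweep |
| pure panel | 3 ions × {10 µM … 100 mM} | 15 single-analyte solutions |

Two generator choices deserve explanation:

* **Sensitivity spreads.** The reported per-device sensitivity
  histograms (±2.90, ±5.87, ±1.90 mV/decade) are *measured* spreads:
  they contain both true device-to-device Nernst-scale variation and
  Dirac-extraction noise. At the default 1% current noise the
  extraction floor is ≈ 1.4 mV/decade, so the generative `sens_sd`
  values are the measured spreads minus that floor in quadrature;
  simulated chips then reproduce the measured histogram widths rather
  than exceeding them.
* **Hysteresis.** Backward (high→low) concentration series add a small
  Dirac offset per device, Normal(2 mV, 1 mV). This makes individual
  devices' forward/backward slopes differ visibly while array averages
  stay well-behaved, which is exactly the regime the reversibility
  metric is designed for.

The mixture panel is a documented stand-in for an unavailable solution
table: the full factorial of 3 ions × {0, 0.1, 1, 10, 100 mM} minus the
all-zero point, subsampled (deterministically under seed) to 30
solutions with every (ion, level) pair represented at least twice.

### ECDF synthesis

`ecdf_synthesize()` expands a measured chip into an arbitrarily large
population by inverse-transform sampling: one uniform rank $u$ per
synthetic device, applied to the type-1 inverse empirical CDF of every
(solution, $V_{GS}$) column — a comonotonic coupling that keeps each
synthetic curve internally coherent (its rank is the same at every gate
voltage) while its marginals converge to the source ECDFs (the KS
distance at 50,000 synthetic devices is below 0.02 in the tests).
Forcing $u = 0.5$ returns the per-voltage median curve.

## 3. Feature extraction

* **Working-device screen:** finite samples, peak current ≥ 1 µA,
  max/min current ratio ≥ 1.05, interior conduction minimum; a device
  must pass on all of its curves. Thresholds are arguments.
* **Dirac point:** degree-4 polynomial fit over ±0.25 V around the
  discrete minimum, analytic minimum of the fit. Degree must exceed 2
  to accommodate hole/electron branch asymmetry; the window keeps the
  fit local. If the polynomial minimum escapes the window, the grid
  argmin is used. Agreement with a 0.1 mV dense-grid oracle is within
  5 mV on noiseless curves (tested).
* **Transconductances:** central differences on the raw 10 mV grid, no
  smoothing — smoothing would couple neighboring features and
  complicate reproducibility for no benefit at this noise level.
* **Sensitivity:** OLS of the array-mean Dirac point against
  log₁₀(concentration), reported in mV/decade, plus per-device slopes
  for the histogram.
* **Reversibility:** symmetric percentage difference of forward and
  backward slopes, $100\,|s_f-s_b| / ((|s_f|+|s_b|)/2)$; the source
  formula is unstated, and the symmetric form is bounded and
  direction-agnostic. Zero mean slope is an error, not a 0/0.
* **Response time:** first crossing of 90% of the asymptotic step
  amplitude, linearly interpolated between samples; the asymptote
  defaults to the final sample and can be supplied for truncated
  traces.

## 4. Profile-matching calibration

The calibration current slices at each gate voltage are compared with
the test slice across devices. Two objectives are implemented:

* `"lsq"` (default): plain least-squares distance between the slices.
  Test and calibration measure the *same* devices in the same units, so
  current magnitudes are directly comparable and carry most of the
  information.
* `"correlation"`: the squared Pearson correlation, invariant to affine
  rescaling of either slice. The R² profile is computed and reported in
  both modes.

The default is least squares for a measurable reason: adjacent
calibration slices are very nearly affine images of each other across
devices, so the correlation profile is locally flat near its peak and
its argmax wanders by whole grid steps under the default 1% noise; the
least-squares objective keeps the magnitude information and localizes
the optimum an order of magnitude more precisely. This choice is made
once, before any accuracy targets were evaluated, and both modes share
every contract (self-match is exact, the R² peak matches the
least-squares dip on clean data).

Numerical details:

* Calibration curves are denoised along the gate axis with a
  Savitzky–Golay-style local quadratic over a 9-point (80 mV) window
  before slicing; slice noise, not curve shape, is what limits matching
  precision.
* The objective extremum is refined below the 10 mV grid with a
  least-squares parabola over the points within ±20 mV of the discrete
  optimum, vertex clamped to that window. An exact match (zero
  residual or R² = 1) short-circuits refinement so self-matches return
  the grid voltage exactly.
* Test slices are modeled as dwell-averaged transient currents
  (`test_n_avg = 25` samples, i.e. noise/√25): operationally the test
  current comes from the steady portion of a 20–30 s dwell, whereas
  each calibration point is a single sweep sample.
* `estimate_concentration()` applies
  $\log_{10} c = \log_{10} c_\mathrm{ref} - \Delta V / s_{mV}$ with the
  slope signed as measured (negative for cations). The calibration
  solution must lie in the quasi-linear range (10 µM–100 mM).

`calibration_accuracy()` summarizes a full experiment by the OLS fit of
log-true on log-estimated concentration (estimates on the x axis, as in
the standard accuracy plot). `redundancy_ci()` repeats the estimate on
sub-arrays drawn without replacement from a synthetic population and
reports percentile confidence intervals; degenerate draws (all sampled
synthetic devices sharing one source rank) are redrawn, and the
minimum-device guard is lowered to 2 there because scoring N ≤ 5 arrays
is the point of the exercise.

## 5. Learning pipeline

* **Samples:** one device per ISM region per triplet, features suffixed
  `_K`/`_Na`/`_Ca`; 200 triplets per solution by default (a sampling
  depth at which task accuracies are stable); 5% relative Gaussian
  feature noise. Features stay raw in the sample object; z-scoring uses
  training-split statistics only, inside `train_task()`.
* **Classifier:** Random Forest via `ranger` (100 trees, depth 20, Gini
  splits — `ranger` exposes the depth cap directly), five stratified
  80/20 splits (stratification prevents empty-class test folds with
  only 15 solutions); SVM, LDA, k-NN and Gaussian-process backends sit
  behind the same interface for comparison.
* **Concentration tasks** use the classes zero/10uM/100uM/1mM/10mM/
  100mM, "zero" marking an absent target ion, so a model applied to the
  wrong solution answers "zero" rather than hallucinating a level.
* **Profile task:** per-ion low/normal/high bands (< 1 mM, 1–10 mM,
  > 10 mM) combined into a composite label — a documented stand-in for
  an unavailable clinical re-categorization table.
* **Attribution:** TreeSHAP. The fast explainer is xgboost's
  `predcontrib` on a tree ensemble fit in random-forest mode (one round
  of 100 parallel depth-20 trees) to the same samples, because TreeSHAP
  requires per-node covers that ranger forests do not retain. xgboost
  computes in single precision, which leaves ~1e-6 residuals in the
  local-accuracy identity; the package therefore ships
  `tree_shap()`, a double-precision path-dependent TreeSHAP over the
  model's tree dump, validated in the tests against both the fast
  explainer (agreement to single precision) and a brute-force Shapley
  oracle with path-dependent conditional expectations (agreement to
  1e-10). Note the float32 subtlety: gate splits are snapped back to
  their exact float32 values so ties break identically to the C++
  implementation.
* **Ablation:** retrain with each ISM's columns removed; report the
  accuracy drop.
* **Device subsampling:** restricted pools are evaluated with a
  *device-disjoint* 80/20 split — training triplets from training
  devices, test triplets from held-out devices. With the row-level
  split used for the standard tasks, every row reuses fixed per-device
  feature vectors, so a small pool is trivially memorizable and
  accuracy would *rise* as devices are removed; the quantity the
  subsampling experiment is about is generalization across devices,
  which the device-held-out design measures directly (and which
  reproduces the expected trend, including occasional inversions from
  the random restriction).

## 6. Reproducibility and problem sizes

Every stochastic function takes an explicit `seed` and leaves the
caller's RNG untouched; stage seeds in `run_pipeline()` and the
acceptance script derive from one master seed (kept below 2³¹).
Identical seeds give bit-identical outputs, which the tests assert.

The test suite runs its heavier experiments at deliberately chosen
sizes: full 16 × 16 chips for the yield, calibration, redundancy and
reversibility checks (these are the study conditions); 10,000-device
synthetic populations with 120–300 repeats for CI-shape properties
(the full 50,000 / 1000-repeat experiment runs in the acceptance
script and the acceptance test); 25 replicate small chips for
parameter-recovery statistics; and reduced triplet counts for ML
property checks, except the separability criterion, which uses the
default 200 triplets per solution.

## 7. Known limitations

* Activities equal concentrations; no ionic-strength corrections.
* No long-term drift, hysteresis loops beyond the constant backward
  offset, electrode drift, pixel crosstalk or readout electronics.
* No quantum-capacitance or ambipolar-asymmetry refinements; the
  compact model is symmetric in conductance about the Dirac point.
* Simulated feature tables are cleaner than real ones: real chips show
  curve-shape families the compact model cannot produce, so passing
  simulation tests demonstrates correctness of the estimators under
  the stated model, not real-chip accuracy. In particular the
  published real-chip classification accuracies depend on unreleased
  measurements and are intentionally not reproduction targets.
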