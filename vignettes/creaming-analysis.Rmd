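---
title: "Methods: creaming-stability analytics for oil-in-water emulsions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: creaming-stability analytics for oil-in-water emulsions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(creamdex)
```

## The problem

Oil-in-water food emulsions destabilise by creaming: buoyant oil droplets
rise, flocculate and coalesce until a cream layer separates from a serum
phase.  For a dairy-like product built on argan oil, sodium caseinate
(emulsifier) and modified starch (continuous-phase stabiliser), the
formulation question is which combination of three composition factors
(oil 10--20 % w/w, starch 0--1.5 %, caseinate 0--2 %) and two process
factors (stirring velocity 10,000--20,000 rpm, stirring time 5--20 min)
yields an emulsion that survives storage and lacto-fermentation without
phase separation.

`creamdex` implements the complete analytical chain around that question:
droplet sizing from micrographs, screening-design modelling of the size
responses, yield-value extraction from flow curves, and a yield-stress
based *creaming index* that ranks formulations by their resistance to
creaming.

## Droplet sizing

Micrographs are segmented with a global Otsu threshold, connected-component
labelling and two shape filters: a minimum equivalent-circle diameter
(default 3 px) and a minimum circularity $4\pi A/P^2$ (default 0.6).
Objects touching the image border are discarded because their diameters are
censored.  Each surviving region is summarised by its equivalent-circle
diameter $2\sqrt{A/\pi}$, converted to micrometres by the full-image-width
calibration (`pxToUm()`): one pixel is `imageWidthUm / imageWidthPx`
micrometres.  Digitised perimeters systematically underestimate the true
perimeter, so ideal disks can score circularities slightly above 1; the
filter is therefore a lower bound only.

A droplet population is summarised by its arithmetic mean and its Sauter
(volume--surface) mean
$$d_{32} = \frac{\sum_i d_i^3}{\sum_i d_i^2},$$
which weights the distribution the way an oil--water interface does and is
never smaller than the arithmetic mean (power-mean inequality; the test
suite asserts this over randomised sets, together with scale equivariance).
Storage stability is read from the 5-hour variation rate
$100\,(S_{t5}-S_{t0})/S_{t0}$.

Laboratory practice counts a fixed number of droplets (50) per image;
`subsampleDroplets()` reproduces that convention with a seeded uniform
subsample, but the default is to use every detection, which is strictly
more informative.  The bundled study table reports "mean droplet size"
without stating whether it is arithmetic or Sauter; the package computes
both and treats the printed values as generic sizes when reproducing the
derived columns.

## The synthetic-data generator

Because no raw micrographs or rheograms are deposited anywhere, the
generator is a first-class module.  It emulates:

* **Micrographs** — disks with log-normal diameters (default
  `meanlog = log(10)`, `sdlog = 0.25`, i.e. a median droplet of 10 um,
  matching the ~11--16 um Sauter means of the stable emulsions) rendered
  dark on light at 0.25 um/px on a 1000 px frame, placed uniformly at
  random without overlap (100 retries per droplet, largest first), plus
  additive Gaussian intensity noise (default sd 0.05 on the [0,1] scale)
  clipped to the valid range.  The truth table carries the exactly
  rendered diameters, so detector accuracy is measurable, not assumed.
  Log-normality is a modelling convention for homogenised emulsions, not a
  measured fact about these particular ones.
* **Flow curves** — a Herschel--Bulkley stress response
  $\sigma(f)=\tau_0+K f^n$ on the laboratory sweep grid (0.05--500 Hz),
  with additive stress noise truncated at zero.  The study states only
  "plastic-type" behaviour; Herschel--Bulkley is the minimal standard model
  with a true static flow limit $\tau_0$, and $0<n\le 1$ keeps the curves
  shear-thinning.
* **Design responses** — $y = g^{-1}(X\beta+\varepsilon)$ for any
  coefficient map over coded factors, interactions and block contrasts,
  with $g$ one of the four canonical transforms.  Noise-free simulation
  followed by refitting recovers $\beta$ to numerical precision, which
  anchors the model-fitting tests.

What the generator does *not* emulate — optics (diffraction, depth of
field), partially fused droplet clusters, polydispersity-coupled rheology —
bounds what green tests mean: they certify the measurement and modelling
chain, not the microscope.

## The screening design and its models

The built-in 24-run plan (21 vertices + 3 centre points in 3 blocks of 8)
is shipped verbatim; generating optimal designs is out of scope.  Factors
are coded onto $[-1,+1]$ by $2(x-\mathrm{mid})/\mathrm{range}$, and blocks
enter as fixed sum-to-zero contrasts so that the reported constant is the
grand constant of the linearisation equation.

Responses are linearised with a Box-Cox power transform.  The scan
minimises the SSE of the model on the normalised scale
$y^{(\lambda)} = (y^\lambda-1)/(\lambda\dot g^{\lambda-1})$ (log limit
$\dot g\ln y$, $\dot g$ the geometric mean) over a default grid
$\lambda\in[-2,2]$ in steps of 0.01 — equivalent to profile maximum
likelihood, and cross-checked against an independent implementation in the
tests.  The scan uses the model that will actually be fitted, block columns
included.  A canonical family (log10, square root, inverse square root,
identity) is named when the best $\lambda$ falls within 0.25 of it.

Default term sets per response were chosen as the unique sets whose refit
reproduces every legible printed coefficient of the published linearisation
table to its printed rounding (the printed interaction rows are partly
garbled; in particular the variation-rate model's CD term appears
mislabelled as a duplicate DE row, and the T5 model's DE coefficient is
missing from print although the remaining columns only match when DE is in
the model).  Term sets are ordinary arguments, so other readings are one
keyword away.  When an interaction is requested its parent main effects are
added automatically (model hierarchy, as in the published treatment of
starch).

Fit quality is reported as the triple raw $R^2 = 1-\mathrm{SSE/SST}$,
adjusted $R^2$, and predicted $R^2 = 1-\mathrm{PRESS/SST}$ with PRESS from
the closed-form leave-one-out identity $e_i/(1-h_{ii})$ (asserted equal to
explicit refit-without-row-$i$ predictions).  Because the published values
do not state whether blocks are included in $R^2$, both conventions are
returned; the with-blocks triple matches the published one for the T0 size
model (0.965/0.928/0.857 against printed 0.96/0.93/0.85).

Effect screening ranks |t| values against two limits: the two-sided
$t$ critical value at $\alpha$ (default 0.05) and the Bonferroni-corrected
value at $\alpha/m$ with $m$ the number of screened effects.  Under a
pure-noise response the family-wise rate of crossing the Bonferroni limit
stays below $\alpha$ (asserted over seeded simulations).  One published
narrative claim is not reproducible from the printed data: the oil main
effect's printed variation-rate coefficient (−0.29) is too small relative
to its standard error to clear either limit, so the package's tests assert
the four dominant factors (starch, caseinate, stirring velocity, stirring
time) rather than all five.

A second irreproducibility is the transform choice for the T0 size.  The
scan's best $\lambda$ on that model is 0.27 with 95 % interval
$[-0.07, 0.59]$: the published log10 choice lies inside the interval but is
not the minimum-SSE pick (the square-root family is marginally closer), and
no defensible scan convention we examined — blocks in or out, mains-only or
full interaction model — reproduces all three published family choices at
once.  The package reports the scan honestly and lets the user impose a
family; the corresponding acceptance test records the discrepancy as a
failure rather than masking it.

Ordinal creaming classes (1--5) are modelled, as in the published
treatment, by OLS after an inverse-square-root transform.  That is
statistically crude for an ordinal response and is kept only for fidelity;
treat its inferences qualitatively.

## Yield value and the creaming index

For a plastic-type matrix the static flow limit $\tau_y$ is read directly
off the flow curve as the stress at the minimum sweep frequency
(`yieldValue()`, default).  That reading and a true static yield stress
differ in general, so a Herschel--Bulkley fit (`fitHerschelBulkley()`,
bounded Levenberg--Marquardt) is provided as a model-based cross-check;
for noise-free curves the difference between the reading and $\tau_0$ is
exactly $K f_{\min}^n$, which the tests assert.  A median-of-lowest-decade
plateau variant is available for noisy sweeps.  Frequencies are kept in Hz
as measured; no conversion to rad/s is applied.

The micro-stress of a suspended droplet is taken linear in its diameter,
$\sigma = k\,d$.  The law is empirical: the ten printed (diameter,
pressure) pairs of the study's creaming table are consistent with a single
constant to under 0.8 % relative residual, and $k$ is calibrated from them
by through-origin least squares, giving $k^\star \approx 32.5$ Pa per
metre of diameter.  Physically $k$ bundles the density contrast, $g$ and a
geometric prefactor, none of which are recoverable separately; it is an
ordinary argument everywhere it is used.

The creaming index
$$\mathrm{CI} = \frac{\tau_y}{\sigma(d)}$$
is the minimum number of droplets an aggregate must contain for its weight
to overcome the static flow limit; the higher, the more stable.  It is
computed for the Sauter mean (ADS) and the largest observed droplet (LDS —
the maximum, the study defining no percentile), so the pair brackets the
critical aggregate size; since LDS ≥ ADS the indices always satisfy
$\mathrm{CI_{ADS}} \ge \mathrm{CI_{LDS}}$, with the exact ratio LDS/ADS.
Indices are kept real-valued and rounded only for display.

The stability-selection rule keeps formulations with storage variation
strictly below 12 % and creaming class at least 3; on the bundled table it
returns exactly the five emulsions the study carried into fermentation,
with run 24 (every factor at its high level) ranked most stable.

## Numerical choices and degenerate inputs

* Box-Cox grid $[-2,2]$ step 0.01; the $\lambda=0$ limit is handled
  analytically and the objective is numerically continuous across it.
* OLS uses QR via `lm()`; rank-deficient term sets raise an aliasing error
  naming the collinear columns instead of silently dropping them.
* The Herschel--Bulkley fit starts from (min stress, range-based K,
  n = 0.5) with bounds $\tau_0, K \ge 0$, $0 < n \le 2$; yield-free data
  drive $\tau_0$ to the active zero bound.
* Featureless images segment to an empty detection set, not an error;
  empty droplet sets and empty flow curves are errors.
* CSV writers emit 17 significant digits so write→read round-trips are
  lossless; report JSON is written deterministically, and identical
  configuration plus seed gives byte-identical bundles.
* Test and acceptance problem sizes (10 micrographs of 50 droplets, 100
  noisy flow curves, 200--500 null-model simulations) were chosen as the
  smallest sizes at which the Monte-Carlo margins in the assertions are
  comfortable.

## Known limitations

Heavily fused droplet clusters are not split (no watershed), so overlap
defaults to off in the generator; detection on real, crowded cream-phase
images will undercount.  The micro-stress law is a one-constant empirical
calibration, not buoyancy physics, and fermentation-phase behaviour
(pH-driven casein aggregation) is outside the model entirely: the pipeline
predicts which formulations *enter* fermentation stable, not what the
ferment does to them.
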