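---
title: "Methods: gradient-nanotopography screening with nanomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gradient-nanotopography screening with nanomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The screening problem

A combinatorial nanoarray carries a continuous gradient of line-pattern
feature sizes -- from tens of micrometres down to the hundred-nanometre
scale -- on a single 1 cm substrate. Stem cells seeded on the array
experience a different topographical cue at every position, so one
culture reports an entire dose-response relationship between feature
size and a cell behavior (adhesion, proliferation, neuronal
differentiation, axonal growth, axonal alignment). `nanomap` implements
the computational side of this screen end to end:

1. **Optics** -- simulate the two-beam interference exposure that writes
   the gradient and calibrate substrate position against local feature
   size.
2. **Synthetic data** -- generate seeded cell observations and
   fluorescence-like images with known ground truth, so every later
   stage is testable without microscope data.
3. **Image quantification** -- segmentation, shape, tile intensity,
   orientation and neurite-length measurements that turn images into
   scattered (x, y, z) observations.
4. **Behavior mapping** -- Gaussian process regression (GPR) with
   Bayesian hyperparameter optimization, interpolating scattered
   observations into a dense behavior map with uncertainty.
5. **Scoring** -- five-level radar tables, per-behavior optimal feature
   sizes, and a cross-cell-type mechanosensitivity comparison.

This package is organised as an analysis workflow: the numbered scripts
under `analysis/` are thin narrative drivers, while every computation
lives in the package functions so the test suite and
`scripts/acceptance.R` exercise the same code paths. The orchestration
layer (`run_screen()`, `validate_config()`, YAML configs) plays the role
of a command-line front end; no shell wrapper is shipped because the
scripts and functions are the interface a computational user works with.

# Interference optics

## Model

Two coherent beams of wavelength $\lambda$ interfere on the resist. With
beam angles $\theta_1, \theta_2$ measured from the substrate normal
(signed by transverse propagation direction), the fringe period is the
grating equation

$$\Lambda = \frac{\lambda}{\sin\theta_1 + \sin\theta_2}.$$

Beam 1 arrives directly at a fixed grazing angle $\beta$ from the
substrate plane ($\theta_1 = 90^\circ - \beta$). Beam 2 is folded onto
the substrate by a cylindrical mirror whose cross-section is a circular
arc of radius $R = 2f$; its local angle $\theta_2(x)$ varies along the
substrate, which is what turns the single-period interference of a flat
Lloyd's mirror into a continuous period gradient. `trace_reflected_angle()`
solves the ray-arc reflection per position (dense sweep bracketing plus
root refinement); `local_period()` applies the grating equation;
`focal_length_mm = Inf` selects the analytic flat-mirror (Lloyd) mode
whose period $\lambda / (2\cos\beta)$ is constant.

## Mounting convention and its two constants

A circular-arc mirror and an incidence angle do not by themselves fix a
geometry; the arc's placement matters. The package adopts one mounting
convention, fixed once: the arc centre sits at 30 degrees elevation
above the substrate plane at distance $R$ from the point where the arc
meets the plane, and the usable substrate is the *gradient branch* of
the reflected fan -- the monotone stretch of landing positions over
which the mirror beam sweeps from co-propagation with the direct beam
(fringe period diverging) towards the specular Lloyd value (period
minimal). Exposure coordinates start at the illuminated edge of this
branch plus a 0.1 mm inset that keeps the divergent co-propagation
point just off-substrate. Both constants were chosen by a parameter
study of the implemented model -- the mounting elevation controls the
shape of the period-versus-position curve, the inset its dynamic range
-- so that the default $\beta = 67^\circ$, $f = 10$ mm array shows the
characteristic behavior of the fabricated gradients: a period span of
two orders of magnitude whose logarithm is nearly linear in position
(central-80% $R^2 \approx 0.96$), and a span that narrows monotonically
as $\beta$ goes $62^\circ \to 67^\circ \to 72^\circ$.

Simplifications worth naming: the tracing is 2-D (the incidence plane),
scalar, and treats the direct beam as unobstructed by the mirror body,
as in beam-splitter-style two-beam exposures; resist development
kinetics are reduced to a thresholded sinusoidal dose. The simulated
period range at the defaults (about 0.4-60 um) is wider at the top and
narrower at the bottom than the fabricated array's printed 0.1-20 um;
the synthetic-data generator therefore uses an idealized exponential
profile spanning exactly 20 um to 0.1 um (`exponential_profile()`) as
its default substrate, and the ray-traced profile is the subject of the
optics analyses.

## Duty cycle

Fringe visibility follows the mirror-beam amplitude estimated from the
fan's energy spread (arc length per unit landing length). The developed
line fraction of a sinusoidal dose $D(u) = \bar D + V\cos(2\pi u)$ above
a threshold $T$ has the closed form $d = \arccos((T - \bar D)/V)/\pi$,
clipped to $[0, 1]$ and flipped for positive-tone resist. The
development threshold is set so the widest-period position develops at
duty cycle 0.5. The dose model is deliberately minimal -- no published
dose values exist for this process -- and is exercised against a
root-finding quadrature oracle in the tests.

## Calibration

`fit_size_calibration()` regresses $\log \Lambda$ on position.
Because the log feature size is nearly linear in position, the fitted
line (its $R^2$ is reported) makes position a trackable proxy for local
feature size; `position_to_feature_size()` and its inverse are used by
every downstream stage. The zero-variance convention assigns
$R^2 = 0$ and slope 0 to constant profiles.

# Synthetic data generator

## What it emulates

* **Seeding densities**: 10,000 cells per cm^2 for adhesion, growth and
  proliferation screens; 40,000 per cm^2 for differentiation -- the
  screening densities. Cells are a homogeneous Poisson process over the
  non-void area.
* **Cell-free voids**: rectangular regions (default 30% of the area)
  containing no cells. These create the false-null failure mode --
  positions with no cells would otherwise read as zero behavior -- that
  motivates GP interpolation.
* **Peaked size responses**: every screened behavior is unimodal in
  feature size, so responses follow a log-Gaussian
  $z(s) = b + A\exp(-(\log s - \log s_0)^2 / 2\sigma^2)$ plus Gaussian
  measurement noise. Default peak sizes per behavior: adhesion 20 um
  (the largest lines; a monotone response modelled by a peak at the
  range edge), proliferation 1 um, differentiation 2 um, axonal growth
  5 um, axonal alignment 0.2 um (nanoscale lines). Defaults
  $A = 1$, $b = 0.2$, $\sigma = 0.6$ (log units), noise sd 0.15 give a
  signal-to-noise ratio at which hold-out $R^2$ around 0.8 is
  attainable -- heterogeneous but informative single-cell readouts.
* **Impaired mechanosensitivity**: a "patient" cell type is emulated by
  halving every behavior amplitude at equal noise
  (`default_response_models(amplitude_scale = 0.5)`).
* **Rendering**: cells become anisotropic Gaussian blobs whose
  half-maximum footprint matches the cell's area/eccentricity/
  orientation, on a 5% background with shot-like noise, at 0.65 um per
  pixel and 16-bit scale on disk; aligned-fiber textures
  (`render_fiber_image()`) exercise the orientation module the way
  electrospun-nanofiber micrographs do.

## What it does not emulate

Cell-cell interactions, migration between structures (the screening
geometry is chosen to avoid it), nucleus/cytoplasm substructure,
illumination vignetting and stitching seams, dead-cell debris, and any
mechanistic link between the five behaviors (each is generated
independently). Passing tests therefore demonstrate that the analysis
recovers known structure from data *of this idealized kind*; they bound
algorithmic error, not biological validity on real images.

All generators are seeded (`sub_seed()` fans one master seed into
per-stage streams) and bitwise reproducible.

# Image quantification

Images are matrices with the first index along x, values in $[0, 1]$.
Illumination background is removed by grayscale morphological opening
with a disc (rolling-ball equivalent). Objects are segmented by a
global Otsu threshold (configurable -- the original pipeline's exact
threshold is unpublished), 8-connected labelling, and an inclusive
8-80 pixel area window at 0.65 um per pixel, then measured: centroid,
area, perimeter, circularity $4\pi A/P^2$ (clipped to $[0,1]$; a single
pixel has perimeter 1 by the boundary-pixel-count convention),
second-moment ellipse axes, and mean intensity per channel. Cell
polarization is defined as $1 - \text{circularity}$ (the bounded
reading of "reverse of circularity"). Intensity-based readouts tile the
image into 48-576 rectangles (the factorization nearest the image
aspect, exact partition) with background-subtracted means -- the
pixelized differentiation readout. The CFSE/DAPI proliferation ratio is
computed per object and is invariant under common intensity scaling;
zero-DAPI objects are dropped with a log message.

Orientation analysis re-implements the structure-tensor approach of the
ImageJ directionality plugin: Gaussian-smoothed gradients, tensor
smoothing, per-pixel orientations weighted by coherence times energy,
2-degree axial bins on $[-90, 90)$. The alignment score is
$1 - $ circular variance on doubled angles (axial data); the dominant
angle is the weighted axial mean of the top mode. Neurite lengths
replace manual axon tracing with Zhang-Suen skeletonization and
path-length summation (orthogonal steps 1 px, diagonal $\sqrt 2$);
components whose skeletons contain junctions (entangled axons) and,
when a topography is supplied, components spanning feature sizes
differing by more than 2x are excluded, mirroring the stated manual
exclusion rules. A dead-cell-fraction style correction for round
debris is *not* applied; the known over-representation of alignment in
images with many round cell bodies carries over to this surrogate.

# Behavior mapping

Observations (per-cell metrics or per-tile intensities -- mixing the
two provenances is an error) are split 90/10 into training and held-out
test sets. The surface model is an exact GP with anisotropic squared
exponential kernel (Matern 5/2 available) plus white noise; the prior
mean is the training mean.

Hyperparameters (two length scales, signal variance, noise variance)
are optimized on log10 scale within data-driven bounds -- length scales
between the median nearest-neighbour spacing and the domain size,
variances between $10^{-6}$ and $10$ times the label variance -- by
minimizing the negative log marginal likelihood. The marginal
likelihood was chosen over CV loss as the Bayesian-optimization
objective because it needs no inner split and its gradients/shape are
smooth at small $n$; this is the one place the original description is
ambiguous ("objective function"), and either choice fits the same
interface. The optimizer is expected improvement (EI) over a GP
surrogate on the unit cube, seeded with a stratified initial design
plus one informed guess (15% length scales, label variance), followed
by a Nelder-Mead polish of the incumbent -- the polish removes the
occasional EI run that stalls in a noise-dominated corner. The
incumbent objective is non-increasing by construction and the whole
trace is seeded and reproducible.

Exact GP conditioning costs $O(n^3)$, so likelihood evaluations use a
seeded subsample of at most 400 training points and the final
conditioning at most 1000; predictions are chunked. At the default
scene sizes (about 7000 cells) this retains hold-out $R^2 \approx 0.8$
while keeping a full map under a few seconds.

`predict_grid()` evaluates posterior mean and predictive sd on exactly
250,000 points (500 x 500 on a square box; non-square boxes use the
nearest aspect-preserving factorization of exactly 250,000) spanning
the observation bounding box. Predictions over cell-free voids are the
false-null correction: the map reports what the cue at that position
would elicit, not the absent measurement. `marginalize_to_size_curve()`
maps grid columns to feature size through the calibration and averages
over y within log-spaced size bins (default 8), yielding the
size-response curve.

# Scoring

Curve values are assigned to 5 equal-width levels. Equal-width (not
quantile) binning is essential: quantile levels would erase exactly the
amplitude differences that distinguish an impaired-mechanosensitivity
cell type. For cross-type comparisons the level bins are computed on
the pooled per-behavior value range (`shared_value_ranges()`) so all
types are scored against the same standards; level assignment happens
after GP smoothing (smoothing first, discretizing second keeps the
levels a visualization of the fitted surface rather than of raw noise).
The per-behavior sensitivity index is the level range across size bins
(0-4), and the overall index its mean across behaviors -- the simplest
statistic that is location-invariant, non-decreasing in response
amplitude, and maps "only slight differences across cues" to a low
score. `optimal_feature_size()` takes the argmax bin, ties resolving to
the smallest size (documented, arbitrary), and is invariant under
monotone transforms of the values. Degenerate flat curves score all
level 1 with a warning.

# Numerical choices and degenerate inputs

* Cholesky factorizations escalate jitter ($0, 10^{-10}, \dots,
  10^{-4}$ times signal variance) and log when jitter was needed.
* Co-propagating interference ($\sin\theta_1 + \sin\theta_2 \to 0$) is
  clamped with a warning; periods can never fall below $\lambda/2$.
* Zero fringe visibility makes the duty cycle all-or-nothing, with a
  warning.
* All-identical labels yield a degenerate noise-only surface with a
  warning rather than an error.
* Blank images yield empty object collections; empty neurite tables are
  valid results.
* Grid factorization and tile factorization always partition exactly;
  tile requests outside 48-576 and hold-out fractions outside (0, 1)
  are errors, as is mixing per-cell and per-tile observations.

# Problem sizes used by the tests and acceptance script

The property suites run at sizes chosen to make the statistical checks
sharp yet quick: 20 seeded scenes at 10,000 cells per cm^2 with 30%
voids for peak recovery (grids of 22,500 points; the 250,000-point
default is exercised separately), and 20 replicate pairs at 2,000 cells
per cm^2 for the five-behavior mechanosensitivity contrast. These are
the package's own choices of demonstration scale; the statistical
margins (20/20 recovery, hold-out $R^2$ median about 0.83, index
contrast 4 vs 2) are wide at these sizes.

# Known limitations

* The optical model is a surrogate: its mounting constants reproduce
  the qualitative gradient behavior, not the fabricated array's exact
  period-position table, and absolute simulated periods differ from the
  printed range (see above).
* Segmentation is a functional stand-in for the original
  CellProfiler pipeline, validated only on synthetic renderings.
* The GP treats behaviors independently; no multi-output coupling.
* Level assignment remains intentionally simple ("arbitrary" five-level
  scoring); the sensitivity index is one defensible summary among
  several (a variance-based index would also serve).
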