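# nanomap

Screening how nanotopography steers stem cell behavior, on one
substrate. A gradient nanoarray written by two-beam laser interference
carries line patterns from ~20 um down to the 100 nm scale across 1 cm,
so a single culture of neural stem cells reports an entire
feature-size dose-response for each behavior: adhesion, proliferation,
neuronal differentiation, axonal growth and axonal alignment. `nanomap`
implements the computational pipeline for this screen -- for
bioengineers designing topographical neural interfaces and for anyone
who needs spatially resolved phenotype maps from scattered single-cell
readouts.

The pipeline, end to end:

* **Optics simulation** -- ray-traced two-beam interference against a
  curved (radius `2f`) mirror gives the local fringe period
  `Lambda(x) = lambda / (sin theta1 + sin theta2(x))`; a log-linear fit
  of period against position calibrates substrate position as a proxy
  for feature size.
* **Synthetic data** -- seeded scenes with known peaked size-responses
  `z(s) = b + A exp(-(log s - log s0)^2 / 2 sigma^2)`, cell-free void
  regions, and rendered fluorescence-like images.
* **Image quantification** -- Otsu + 8-connected segmentation with the
  8-80 px area window (0.65 um/px), shape and intensity measures,
  structure-tensor orientation histograms, skeleton-based neurite
  lengths, CFSE/DAPI proliferation ratios.
* **Behavior mapping** -- exact Gaussian process regression with an
  expected-improvement Bayesian search over kernel hyperparameters,
  90/10 hold-out validation, and a 250,000-point prediction grid that
  fills in cell-free regions (the false-null correction).
* **Scoring** -- size-response curves on 8 log-spaced bins, five-level
  radar tables under shared standards, per-behavior optimal feature
  sizes, and a cross-cell-type mechanosensitivity index.

## Worked example

One behavior map from scratch -- axonal growth, whose synthetic
ground-truth response peaks at 5 um lines:

```r
library(nanomap)

topo  <- exponential_profile()              # 20 um -> 0.1 um across 1 cm
cal   <- fit_size_calibration(topo)
scene <- make_scene(topo, response_model("axonal_growth", 5),
                    density_per_cm2 = 10000, void_fraction = 0.3,
                    seed = 2024, height_um = 10000)
obs   <- assemble_observations(scene$cells, "z",
                               behavior_name = "axonal_growth")
sp    <- split_holdout(obs, 0.10, seed = 1)
hyp   <- optimize_hyperparameters(sp$train, n_iterations = 15, seed = 2)
surf  <- fit_surface(sp$train, hyp)
holdout_error(surf, sp$test)
grid  <- predict_grid(surf)                 # 250,000-point behavior map
curve <- marginalize_to_size_curve(grid, cal, 8, size_range = c(0.1, 20))
optimal_feature_size(curve)
```

Running `analysis/03_behavior_mapping.R`, which is this example with
its outputs written to `results/mapping/`, prints:

```
Scene: 6994 cells, 14 cell-free void regions (30% of area)
Hold-out split: 6295 train / 699 test (90/10)
Hold-out: RMSE 0.149, R^2 0.824
Prediction grid: 250000 points (500 x 500)
Size-response curve argmax: bin 6 (2.74-5.32 um), true peak 5 um
```

meaning: from noisy scattered cells with 30% of the array empty, the
GP map predicts held-out cells with R^2 0.82 and the marginalized
size-response curve localizes the growth optimum in the size bin
containing the true 5 um peak.

The other drivers follow the same pattern: `01_optics_calibration.R`
(simulated period spans 211/142/93 for beta = 62/67/72 degrees, narrowing
with steeper beams; central-80% log-linearity R^2 = 0.960),
`02_image_quantification.R` (segmentation, tiles, orientation recovery
within 2 degrees, neurite lengths), and `04_screen_scoring.R` (three cell
types x five behaviors; the synthetic patient-derived type with halved
response amplitudes scores overall sensitivity index 2.0 against 4.0
for the healthy types -- the impaired-mechanosensitivity contrast).

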