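# guvquant

Quantification of lectin binding to giant unilamellar vesicles (GUVs) and
polarized epithelial cells from multi-channel fluorescence microscopy.

## The problem

Bacterial lectins such as LecA (*Pseudomonas aeruginosa*) and the Shiga toxin
B-subunit (StxB) both recognise the glycosphingolipid Gb3, yet bind
different membrane domains depending on the Gb3 acyl chain and the order of
the surrounding lipid phase. The standard in-vitro readout is an equatorial
confocal section of a GUV: the membrane appears as a circle, a fluorescent
ld-phase marker (e.g. a BODIPY-labelled phosphatidylcholine) stains the
liquid-disordered arcs brightly, and each lectin channel shows free protein
in solution plus protein accumulated at the rim.

`guvquant` turns such images into numbers:

* **Binding efficiency** of a lectin to a vesicle (or to one lipid phase of
  it), defined as the contrast between rim-bound and free protein

  $$\mathrm{BE} = \frac{I_\mathrm{rim} - I_\mathrm{solution}}{I_\mathrm{solution}}$$

  where `I_rim` is the rim signal and `I_solution` the median free-lectin
  intensity outside all vesicles. A lectin that cannot bind gives BE = 0 by
  construction.
* **ld/lo phase segmentation** of the rim from the marker channel's angular
  intensity profile (deterministic two-cluster split, bright = ld for an
  ld-partitioning marker), with per-phase binding efficiencies.
* **Rim segregation** of two lectins as the Pearson correlation of their
  angular rim profiles (−1 = complementary arcs, +1 = co-localised).
* **Apical/basolateral polarity**: per-cell AP and BL membrane intensities
  from z-stacks of polarized monolayers, population AP/BL ratios
  (ratio of means over isolated labeled cells) and paired two-tailed
  t-tests across experiments.
* **Condition statistics**: box-plot summaries (median, quartiles, min/max)
  and pairwise Mann–Whitney U tests with Holm correction.

Detection uses a circular Hough transform on the gradient of the marker
channel followed by a sub-pixel algebraic circle fit to the per-angle radial
rim peaks. Everything is exercised against a built-in forward simulator
(`simulate_guv_image()`, `simulate_cell_stack()`) that renders scenes with
known ground truth, PSF-limited Gaussian rims, Poisson shot noise and
Gaussian read noise.

## Worked example

Simulate a phase-separated vesicle carrying two lectins with opposite phase
preferences, then quantify it:

```r
library(guvquant)
arcs <- data.frame(start = c(0, pi), end = c(pi, 2*pi), phase = c("ld", "lo"))
guv <- guv_spec(center = c(64, 64), radius = 25, phase_arcs = arcs,
                lectin_contrast = list(lectin_1 = c(ld = 1, lo = 7),
                                       lectin_2 = c(ld = 5, lo = 0.5)))
scene <- scene_spec(image_shape = c(128L, 128L), guvs = list(guv),
                    solution_intensity = c(lectin_1 = 100, lectin_2 = 100),
                    noise = list(gaussian_sigma = 2, poisson_scale = 1),
                    seed = 1)
sim <- simulate_guv_image(scene)
res <- run_pipeline(sim$image,
                    pipeline_config(detection = list(radius_range = c(15, 35))))
#> guvquant: 1 GUV(s) detected, 0 excluded, 1 phase-separated
round(res$results[, c("x", "y", "radius", "be_ld_lectin_1", "be_lo_lectin_1",
                      "be_ld_lectin_2", "be_lo_lectin_2")], 3)
#>        x      y radius be_ld_lectin_1 be_lo_lectin_1 be_ld_lectin_2 be_lo_lectin_2
#> 1 64.007 64.069 24.913          1.003          6.943          4.997          0.537
round(res$segregation$correlation, 3)
#> [1] -0.996
```

The vesicle is found to within a tenth of a pixel, the per-phase binding
efficiencies recover the generative contrasts (1 and 7 for lectin 1, 5 and
0.5 for lectin 2) to a few percent under shot noise, and the strongly
negative profile correlation quantifies the segregation of the two lectins
along the rim. `write_results()` exports per-GUV and per-bin CSV tables
(stamped with the configuration hash) plus a QC overlay PNG.

A command-line interface covering simulation, quantification and reporting
is installed at `system.file("cli", "guvquant", package = "guvquant")`:

```sh
guvquant simulate guv --config scene.yaml --seed 1 --out scene/
guvquant quantify guv -i scene/scene.tif -c pipeline.yaml -o out/
guvquant report -i out/results.csv --condition condition -o report/
```

## Acceptance script

`scripts/acceptance.R` re-derives the package's acceptance target from
scratch: it simulates the canonical no-binding scene (a vesicle whose
lectin channel sits at the free-solution level throughout the rim band),
runs detection, solution estimation, rim profiling and the
binding-efficiency computation, and writes the resulting value as JSON.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
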