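---
title: "Methods: quantifying lectin binding to GUVs with guvquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying lectin binding to GUVs with guvquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guvquant)
```

## The measurement model

An equatorial confocal section shows a GUV as a circular rim. Three channels
matter: a membrane marker that partitions into the liquid-disordered (ld)
phase, and one or two lectin channels in which free protein fills the
exterior solution and bound protein accumulates on the rim.

The central statistic is the **binding efficiency**, the contrast between
bound and free lectin:

$$\mathrm{BE} = \frac{I_\mathrm{rim} - I_\mathrm{sol}}{I_\mathrm{sol}},$$

with `I_sol` the free-lectin intensity in solution. Two properties anchor
the definition: a lectin that cannot bind gives BE = 0, and the statistic is
invariant under any rescaling of the channel (gain, exposure, labelling
stoichiometry), because it is a ratio. Both properties are enforced by
tests. BE cannot fall below −1 for non-negative intensities.

`I_sol` is estimated per channel as the **median** intensity over all pixels
outside every detected vesicle disk dilated by the rim band plus a safety
margin. The median rather than the mean resists bright debris and
undetected vesicles; the lumen is *not* used because lectin is applied
outside intact vesicles and the lumen is lectin-free.

## Detection

Vesicles are found in the marker channel by a circular Hough transform:
pixels with strong intensity gradients vote for centres one radius away
along the gradient direction (both senses, since the inner and outer slope
of a rim both produce edges). Votes are normalised by circumference so the
score is comparable across radii; the default threshold (0.35 votes per
circumference pixel) was chosen so that a rim bright on only half the
circle — a phase-separated vesicle with a dim lo arc — is still detected
while blank noise fields produce nothing. Non-maximum suppression removes
any candidate whose centre lies within the smaller of the two radii of a
better-scoring candidate; ties prefer the larger radius (a rim's inner edge
should not shadow the rim itself).

The integer Hough solution is then refined by locating the radial peak of
the marker rim on 72 rays (parabolic sub-sample interpolation) and fitting
an algebraic circle (Kåsa fit) through the peak points, iterated twice.
On clean synthetic scenes this reaches centre and radius errors well below
0.1 px; the refined geometry is what makes the rim-peak statistic below
unbiased.

Vesicles touching the border, overlapping another vesicle's rim band,
smaller than the configured minimum, or containing saturated rim pixels are
flagged and excluded from quantification (contrast is undefined under
clipping) but reported with their flags.

## Rim profiles and the rim statistic

The rim profile samples each of `n_bins = 360` angular bins (1°) along a
radial ray across the band `radius ± band_halfwidth` (default 3 px,
comfortably wider than a confocal PSF). The per-bin value is the **maximum
along the ray**, which is robust to sub-pixel centre error for a thin rim.
Per-bin values drive phase segmentation, segregation correlation and the
profile diagrams.

For the scalar binding efficiency a per-bin maximum is statistically poor:
under shot noise the maximum of several noisy samples is biased upwards,
and interpolated resampling attenuates a curved peak. The default BE
statistic (`"pooled_peak"`) therefore pools the *raw pixels* of the rim band
over the selected bins, averages them in 0.25 px radial-distance bins, and
reads the apex of a parabola fitted over ±0.5 px around the detected rim
radius. Pooling hundreds of bins before taking the peak removes the
max-selection bias; using raw pixels avoids interpolation loss; centring
the fit window on the refined radius (rather than the noisy argmax) avoids
attenuation from window jitter. When the local curvature is not concave —
a flat, non-binding profile — the estimator falls back to the raw maximum
of the pooled curve, which keeps the no-binding case exactly zero. The
classical per-bin form (`"bin_mean_max"`) remains available and agrees with
the pooled form on noise-free data; the tests require the pooled estimator
to recover contrasts between 0.5 and 10 with under 2% bias at rim
signal-to-noise ≥ 10.

Degenerate inputs are errors, not warnings: empty bin subsets, non-positive
solution intensities, bands leaving the image, flagged detections.

## Phase segmentation

The marker's angular profile is split by a deterministic two-cluster 1-D
k-means (centres initialised at the 25th/75th percentiles, so there is no
random initialisation and no seed sensitivity). The brighter cluster is
labelled with the marker's preferred phase — `ld` for an ld-partitioning
marker; the polarity is a configuration flag because other markers enrich
in the ordered phase. Labels are smoothed by a circular majority filter
(window 5 bins). A vesicle is called **uniform** when the bright/dim mean
ratio is below 2 (an arbitrary but declared threshold: phase-separated
marker patterns in practice show several-fold contrast) or when either
class covers less than 5% of bins after smoothing.

Per-phase binding efficiencies exclude bins within one bin of a detected
phase boundary, where the PSF mixes the two phases. With 1° bins this
exclusion is geometrically thin; analyses of heavily blurred data should
raise `boundary_exclude` to cover the PSF's angular footprint
(≈ `psf_sigma / radius` radians).

Rim segregation of two lectins is the Pearson correlation of their per-bin
profiles; zero-variance profiles return a flagged missing value rather than
a number.

## Cell polarity

Apical and basolateral membrane voxel masks are an *input contract* (from
the simulator's ground truth or user-supplied label images); automated 3-D
segmentation of real monolayers is out of scope. Per experiment, the AP/BL
ratio is the **ratio of means** across isolated labeled cells — not the
mean of per-cell ratios — matching how such polarity ratios are
conventionally computed from population mean intensities. "Isolated" is
operationalised as no other labeled cell's mask within 2 µm of the cell's
lateral boundary; non-isolated cells never enter any summary. Conditions
are compared by a paired two-tailed t-test on per-experiment ratios;
zero-variance differences are degenerate (all-zero differences give t = 0,
p = 1; constant non-zero differences are flagged as undefined). Summaries
flag conditions measured with 50 cells or fewer.

## Condition statistics

Condition summaries report median, 25th/75th percentiles and min/max — the
box-plot convention used for per-GUV binding efficiencies. Quartiles use
linear interpolation between order statistics (R type 7); the dialect is
recorded in the output because quartile conventions differ between tools.
Pairwise comparisons default to the two-sided Mann–Whitney U test (exact
for small tie-free samples) with Holm adjustment across the family; the
underlying source did not name its test, so the choice is declared here and
Welch's t is available as an alternative. Undersized groups (< 3 values)
are flagged rather than silently dropped and do not consume adjustment
power.

## The simulator's stated world

The generator renders what the analysis assumes, with exported ground
truth:

* **Rim model.** The rim's radial profile is Gaussian with σ = `rim_width`
  (default 1.5 px ≈ 150 nm at 0.1 µm/px), mimicking the PSF-limited image
  of a thin bilayer. Because the rim width *is* the PSF in this model, the
  extra whole-field blur `psf_sigma` defaults to 0; turning it on blurs the
  scene further but then rim peaks no longer equal `(1 + contrast)·S`
  exactly, so the recovery suites run without it.
* **Lectin channel.** Exterior at the solution intensity `S`, lumen at the
  background offset (lectin cannot cross an intact bilayer), rim peak at
  `(1 + contrast)·S`. The lumen-to-solution transition is rendered as a
  Gaussian rolloff of the same width as the rim, reaching `S` exactly at
  the rim circle: a hard intensity step at the rim centreline would be
  optically impossible and would make the rim-peak ground truth ill-defined
  under pixel sampling.
* **Marker channel.** Pure rim signal, bright on ld arcs (default 200 a.u.)
  and dim on lo arcs (default 50 a.u.), zero in solution and lumen.
* **Noise.** Poisson shot noise on the photon-scaled signal followed by
  additive Gaussian read noise, then clamping at zero. With the default
  photon scale (1 photon per a.u.) and `S = 100`, the dimmest quantified
  structure sits at SNR ≥ 10, the regime the recovery criteria state. One
  integer seed drives the whole scene; rendering is bit-reproducible.
* **Geometry.** Scenes in which rim bands intersect are rejected — their
  ground truth would be ill-posed. Vesicles crossing the border are
  rendered but flagged. Angles are measured from the +x axis towards +y
  (y down, 0-based pixel coordinates, origin top-left) in every module.
* **Cell stacks.** Cells are rectangular prisms on a grid with a one-voxel
  gap (so per-cell membrane masks are disjoint); the apical membrane is the
  top face, the basolateral membrane the bottom face plus lateral walls.
  A tenth of the cells are receptor-positive by default, emulating 1:10
  mixing with wild-type cells; the default AP/BL intensity pairs (27/10 and
  70/10) produce polarity ratios of 2.7 and 7, the magnitudes reported for
  the two lectins on polarized epithelia. The labelling draw is the first
  random number consumed from the seed, so tests can re-derive it.

What the simulator does **not** emulate: membrane fluctuations and
undulations, tubular invaginations, photobleaching, uneven illumination,
spectral crosstalk, debris, non-circular or out-of-plane vesicles, and
realistic cell shapes. A green test therefore establishes that the
estimators are correct and unbiased *under the stated optical and noise
model*, not that they are robust to every artefact of real data; the QC
flags and the configurable thresholds are the handles for real images.

Lipid compositions (e.g. "DOPC/cholesterol/sphingomyelin/Gb3") are treated
as condition labels only; the package never computes on mol-% values.

## Numerical choices

* Ray sampling uses bilinear interpolation by default; Catmull–Rom cubic is
  available (`interp = "cubic"`) and recovers curved peaks more faithfully
  in per-bin profiles.
* The pooled radial histogram uses 0.25 px bins; the parabola is fitted
  over ±2 bins and its vertex is trusted only inside the fitted window,
  with near-zero curvature treated as flat (this guards the exactness of
  the zero anchor against machine-precision curvature).
* The two-cluster split runs Lloyd iterations to convergence from the
  percentile initialisation; a profile without spread (or one whose
  clusters collapse) is uniform by definition.
* Hough accumulator peaks must exceed their 8-neighbourhood after 3×3
  smoothing; the detection score is votes per circumference pixel.
* CSV outputs carry the SHA-1 hash of the full configuration, and runs with
  identical configuration and seed are byte-identical.

## Known limitations

* Rim statistics assume an approximately circular vesicle; strongly
  deformed or tubulated membranes violate the model and should be excluded
  upstream.
* The per-bin maximum statistic, while robust to centre error, is biased
  under noise; use the default pooled statistic for quantitative contrasts.
* Phase segmentation is two-class; three-phase coexistence or gradual
  composition gradients are outside the model.
* Real-data cell polarity requires externally supplied membrane masks.
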