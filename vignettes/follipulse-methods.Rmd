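---
title: "Quantifying apical pulses and early follicle elongation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying apical pulses and early follicle elongation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(follipulse)
```

## The biological question and the measurements

During the first phase of Drosophila egg-chamber elongation (stages 3–7),
the follicular epithelium elongates along the anterior–posterior (AP) axis
without rotation-driven basal remodelling. The behaviour at the heart of
this phase is the apical pulse: a transient contraction–relaxation of a
follicle cell's apical surface driven by medio-apical Myosin II, patterned
in space as a gradient emanating from the poles where the polar cells sit.
`follipulse` implements the quantitative toolbox needed to measure this
process from multi-channel time-lapse projections and fixed images:

* **Pulse intensity** of one cell: (maximum surface − minimum surface) /
  mean surface of its apical-area time series (dimensionless). A follicle's
  pulse activity is the mean of `100 ×` this over its analyzable cells, with
  a floor of 10 cells per follicle before a follicle enters the statistic.
* **Pulse isotropy**: the AP and mediolateral (ML) bounding-box extents at
  the frame of maximal area divided by the same extents at the frame of
  minimal area; their ratio (ML/AP) is 1 for an isotropic pulse.
* **Myosin–area cross-correlation**: per cell, both series are linearly
  detrended and z-scored, correlated at integer lags with each lag
  normalized by its overlapping-sample count, and averaged over cells; the
  lead–lag is the lag of the most negative correlation, positive when
  myosin accumulation precedes the surface minimum.
* **Elongation coefficient**: the OLS slope of follicle long axis on short
  axis across a previtellogenic cohort (stages < 8); 1 means no elongation.
  Cohorts are compared by separate-slopes ANCOVA
  (`long ~ short × genotype`) with Bonferroni-adjusted pairwise slope
  contrasts.
* **Extrapolated aspect ratio (eAR)**: a per-pole aspect ratio obtained by
  measuring the follicle width at 25% of its AP length from that pole's
  tip. For an ellipse this chord is √3/2 of the full width, so the pole's
  "predicted" width is `w25 · 2/√3` and eAR = length / predicted width.
  Note the geometry: a chord can never exceed the full width, so the
  extrapolation constant must be √3/2 ≈ 0.866 (a printed factor of 3/2 in
  parts of the literature is impossible and is not reproduced here).
  Anterior/posterior eAR tables are compared by a two-way repeated-measures
  ANOVA (pole within follicle, genotype between) followed by the two
  Bonferroni-adjusted per-genotype paired pole contrasts.
* **Spatial gradients**: any per-cell metric binned by Euclidean distance
  from the polar-cell landmark, with an optional least-squares fit of
  `metric(d) = baseline + A·exp(−d/λ)` to the bin means.
* **Planar polarity**: per-bond mean intensities binned by the bond's axial
  angle to the AP axis and normalized by the global mean bond intensity;
  rose histograms in 10° bins; a Rayleigh test on doubled angles for
  division-orientation bias; and the tissue cell-elongation tensor, with
  per-cell magnitude `½·ln(axis ratio)` (log-nematic convention) and the
  tissue average taken on the nematic components `(m·cos2θ, m·sin2θ)`.

Two-sample comparisons follow the field's routing convention: both groups
are tested for normality with the D'Agostino–Pearson omnibus test (K²,
implemented in the package because no installed R package provides it) and
compared with an unpaired Student t-test when both pass at α = 0.05,
otherwise with an unpaired Mann–Whitney test; groups below the normality
test's minimum n = 8 go straight to the rank test.

## Segmentation and tracking

Cells are segmented on membrane-channel maximum projections by the standard
junctional-marker recipe: Gaussian blur (`blur_sigma`, default 1.5 px),
inversion, and a watershed in which minima shallower than `h_minima_depth`
(default 0.08 intensity units) are suppressed — a marker-controlled
watershed with h-minima markers. Regions outside `[min_area, max_area]`
(defaults 5 and 2000 µm²) are removed and border-touching cells are cleared
by default, since cells clipped by the field of view cannot be measured
faithfully. Tracking is greedy maximal-overlap assignment on
intersection-over-union between consecutive frames (a track ends below
`min_iou` = 0.3); at 15 s sampling, displacements are far below a cell
diameter, so global assignment would add complexity without accuracy. Only
tracks spanning every frame enter pulse statistics, mirroring a fixed
40-frame analysis window. Bonds are the boundary pixel pairs between
adjacent labels; a bond's angle is the axial principal direction of its
interface-step midpoints (using the full two-pixel band would contaminate
the direction with the band thickness), and bond intensities are sampled on
the interface band with vertex-adjacent pixels excluded, because pixels at
tricellular vertices mix signal from other bonds.

## The synthetic-data generator

No imaging data are deposited with the study this package targets, so every
estimator is validated against a generator with known ground truth.
`tissueSpec()` defines a flat sheet of Voronoi cells (jittered-grid seeds)
whose areas pulse kinematically: each cell's territory is its static
polygon scaled about its seed by per-axis factors `1 − A·drive(t)`, where
the drive is a train of raised-cosine episodes of `pulse_period_s`
(default 180 s — pulses last about three minutes) separated by
exponentially distributed pauses (`pause_mean_s`, default 120 s) with
random phase, so cells pulse asynchronously and show no sharp period. The
fractional area amplitude follows
`A(d) = baseline + (A_pole − baseline)·exp(−d/λ)` from the pole landmark
(defaults: 0.4 at the pole — about 40% surface variation — decaying to 0.1
with λ = 30 µm). The total amplitude splits between axes as
`A_AP = A/(1+r)`, `A_ML = A·r/(1+r)` with `anisotropy_ratio` r (default 1,
isotropic). The myosin channel fills each cell with
`base + gain·A·drive(t + lag)`, i.e. the same drive advanced by
`myosin_lag_frames` (default 2 frames = 30 s, myosin leading contraction).
The membrane channel draws the static junction lines plus the widening
inter-outline band of contracted cells, optionally multiplies bonds in a
given angle band by `bond_enrichment` (per-bond factors are flooded into
the band by first-arrival propagation so enrichment does not bleed across
vertices), then applies a Gaussian PSF (`psf_sigma_px`, default 0.8 px =
0.2 µm at the default calibration) and shot plus read noise
(`photon_scale` = 200 photons per intensity unit, `gaussian_sd` = 0.05),
which puts the membrane ridge at a signal-to-noise ratio of roughly 10.
Defaults mirror the imaging regime of the study system: 40 frames at 15 s,
0.25 µm/px, 50 cells of ~50 µm² apical surface.

Ground truth records the per-frame label masks, the static tessellation,
per-cell seed positions, distances, imposed and realized amplitudes (the
realized amplitude is what the executed drive actually produced within the
finite window), rendered mean areas, a border-cell flag, and the global
parameters (lag, decay length, anisotropy, enrichment).

Design notes on the generator, and what it does not emulate:

* Pulses are **kinematic**: territories contract independently and the
  junctional band widens to absorb the difference. There is no force
  balance, no neighbour deformation, no tissue rotation and no curvature —
  the curved follicle surface is treated as the locally flat plane of a
  maximum projection. Passing recovery tests therefore demonstrates the
  estimators, not the mechanics of real tissue.
* A smooth cell-size gradient (`pole_size_drop`, for emulating the smaller
  apical surfaces near the poles) is imposed through the seed density —
  seeds are compressed radially towards the pole — because in a
  tessellation local weights alone cannot realize a smooth global size
  field: neighbours with nearly equal weights tile space at equal density.
* Cells whose territory touches the field edge respond to contraction in
  quantized jumps (their field-edge side is a degenerate straight boundary
  aligned with the lattice), so border cells carry attenuated amplitudes.
  Analyses exclude them, exactly as clipped field-of-view cells are
  excluded when measuring real movies.
* Pulse amplitude distributions and pause statistics are not reported for
  the real tissue; the raised-cosine shape and the exponential pause with
  120 s mean are this package's choices, exposed in the spec and echoed
  into every output's provenance block.

## Numerical choices

* **eAR measurement.** Lengths come from the cumulative pixel-count
  function `N(u)` along the AP axis, whose derivative is the local width.
  Tips are located by fitting `N^{2/3}` (linear near a smooth convex tip,
  since the width grows like √(u−tip)) with a quadratic correction and
  taking its root; the width at the 25% station is the derivative of a
  local quartic fit of `N(u)` over a window of 0.3·L around the station.
  This avoids both the half-pixel bias of bounding-box extents and the
  lattice aliasing of binned row counts at degenerate orientations (0°,
  45°, 90°). On discrete ellipses with minor semi-axis ≥ 10 px the eAR
  deviates from the true axis ratio by at most ~1.7% over a battery of
  sizes and orientations (tested to 2%).
* **Gradient fits** are weighted by the number of cells per bin and use
  each bin's mean cell distance as its abscissa — the geometric bin centre
  misplaces sparse near-pole bins and biases the decay length upward.
  Fixed-width bins start at 0; the outermost (partial) bin is kept only
  when it holds at least 3 cells.
* **Cross-correlation** detrends by default so that monotone growth of the
  apical surface does not masquerade as correlation; a raw mode is
  available (`detrend = FALSE`). Lags are normalized by `T − |τ|`
  overlapping samples, and zero-variance series are skipped with a warning.
* **Ties** in the pulse-extrema frames (`which.max`/`which.min`) resolve to
  the earliest frame; watershed ties follow the seeded order of the
  tessellation.
* **t-tests** default to the Student equal-variance form (within-condition
  variance is low in the data this mirrors); Welch is available via
  `var_equal = FALSE`. The ANCOVA pairwise slope contrasts use Bonferroni
  adjustment — the only correction named in the statistical conventions
  this package follows — with other `emmeans` adjustments available via the
  `adjust` argument.
* **Regression includes an intercept** by default (a through-origin mode is
  exposed), and stage filtering keeps records with unknown stage.

## Validation scales

The test-suite recovery checks run at deliberately modest sizes chosen to
make each estimator well conditioned: lag recovery uses the default
50-cell, 40-frame movie at each lag in {1, 2, 4}; isotropy uses the default
movie at anisotropy 1 and 2; decay-length recovery uses movies whose field
spans roughly 3λ with the pole at the field centre (λ = 15: one 144-cell
96-µm field; λ = 30: two pooled 256-cell 128-µm fields; λ = 60: three
pooled 784-cell 224-µm fields at 1 µm/px), 60 frames so nearly every cell
completes a full pulse, and border cells excluded; polarity recovery pools
three default movies and reads bonds off the static ground-truth
tessellation, isolating the bond measurement from segmentation (which has
its own criterion: ≥95% of interior cells at IoU ≥ 0.7 with identities
held across all 40 frames at default noise). The ANCOVA type-I rate is
estimated from 200 null cohort pairs.

## Known limitations

* Euclidean distances in the projection plane ignore surface curvature;
  geodesic corrections are out of scope, as is any 3D segmentation (cell
  heights are measured inputs to `cellVolume()`, not computed).
* The tracker has no occlusion or merge/split handling; it is adequate for
  slowly moving, well-segmented epithelia only.
* Bond-intensity recovery through the full watershed route is damped by a
  few percent relative to ground-truth bonds (angle noise near tricellular
  vertices); quantitative polarity factors are best read with the reported
  ~10% accuracy in mind.
* `follicle_pulse_amplitude` treats "% of apical surface variation" as
  100 × pulse intensity; the source conventions do not distinguish the two.
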