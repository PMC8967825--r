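---
title: "SphereMap: surface fitting, Mercator unwrapping and spot counting for spherical embryos"
author: "SphereMap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SphereMap methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SphereMap)
```

## The problem

Light-sheet microscopy of whole zebrafish embryos produces large 3D(+time)
fluorescence volumes in which the biology of interest — for instance the
lateral plate mesoderm progenitors that give rise to the mesothelium — lives
on or near the surface of an approximately spherical embryo. Two analysis
needs recur:

* **Visualization**: display the entire embryo surface in a single 2D image
  while preserving the local geometry of migrating cells, and
* **Quantification**: count reporter-positive cells per embryo, per region
  of interest, across developmental time and between conditions (e.g.
  wildtype versus a morpholino knockdown).

SphereMap implements both as a reproducible pipeline over explicit S4 value
classes (`VoxelVolume`, `SphereModel`, `ProjectionGrid`, `MapLayerStack`,
`SpotSet`), plus a synthetic-embryo simulator with exact ground truth that
the whole test suite and the acceptance script are built on.

Conventions: every physical quantity is in micrometres; triples are ordered
(z, y, x) = (planes, rows, cols); voxel *i* (1-based) is centred at
coordinate (*i* − 1) × spacing, i.e. the origin is the centre of the first
voxel. Voxel anisotropy (coarser z than x/y) is carried through every
interpolation and distance computation.

## Surface estimation

The embryo's bounding sphere is estimated in four steps, each exposed as a
function and composed by `estimateSurface()`:

1. **Binning** (`binVolume`, default 4 per axis). Block *means*, not sums,
   so that intensity thresholds remain comparable across binning factors;
   trailing partial blocks average over the voxels they actually contain,
   and the voxel spacing is multiplied by the factor.
2. **Adaptive binarization** (`adaptiveBinarize`). A voxel is foreground
   iff its intensity is at least `2(1 − s)` times the local mean over a box
   window, with sensitivity `s = 0.4` by default. The widely used adaptive
   thresholding routines do not document their exact formula, so this
   contract is fixed here explicitly: it is monotone in `s` (raising the
   sensitivity can only grow the foreground), ties count as foreground
   (judged at a 10⁻⁹ relative tolerance so exact rational ties are immune
   to floating-point summation order), and the local mean uses edge
   replication. The default window per axis is the smallest odd integer ≥
   axis length / 8 — local statistics at embryo scale.
3. **Surface point cloud** (`extractSurface`). The largest 26-connected
   foreground component is kept and the physical coordinates of its
   boundary voxels (foreground with a background 6-neighbour; the volume
   border counts as background) are returned. A voxel-based boundary was
   chosen over a triangulated isosurface mesh: the downstream fit needs
   only points, and meshing would introduce its own parameters. No outlier
   rejection is applied by default, since none is claimed by the original
   analysis workflow this reimplements.
4. **Algebraic sphere fit** (`fitSphere`). Solving
   `x² + y² + z² = 2ax + 2by + 2cz + d` by linear least squares gives
   centre `(a, b, c)` and radius `√(a² + b² + c² + d)`. The fit is exact on
   noiseless sphere samples, equivariant under translation, and degenerate
   inputs (fewer than 4 points, coplanar clouds, non-positive squared
   radius) raise errors naming the degeneracy.

**When does this work?** The adaptive threshold marks regions that stand
out against their local neighbourhood. For a *thin, dense, contiguous*
fluorescent cell sheet — the situation of a confluent reporter-positive
blastoderm — the binarized component is a thin shell whose inner and outer
boundary voxels lie symmetrically about the true radius, and the fit is
accurate to a fraction of a binned voxel (the acceptance run measures
≈ 0.2 % radius error on a 256³ anisotropic volume at peak SNR ≈ 10). Two
failure modes are worth knowing. With *sparse, isolated* cells the largest
connected component is a single blob and the "surface" degenerates to that
blob. With a *uniformly filled* bright ball the local-mean rule fires only
in a band just inside the edge (deep interior voxels never exceed 1.2× their
own neighbourhood), so the cloud carries a one-sided inner boundary that
biases the radius several percent inward. The surface-fit scenarios in the
tests therefore use a dense sheet (2500 cells at 5 µm separation on a
100 µm sphere), chosen from this threshold algebra, and the package leaves
segmentation parameters exposed for real data that deviate from it.

## Mercator unwrapping

`makeGrid()` builds the map geometry: columns uniform in longitude on
[0°, 360°), rows uniform in the **Mercator ordinate**
`y = R ln tan(π/4 + φ/2)` between ±y(φmax). Row placement uniform in *y*
(rather than in latitude) is precisely what makes the map conformal — the
property that justifies Mercator for migration analysis, since small
circles on the sphere stay round on the map and local angles are preserved
at the price of a sec²(φ) area inflation.

The Mercator ordinate diverges at the poles, so although the map nominally
spans −90° to +90°, a truncation latitude is unavoidable; the default is
±85°, configurable. For applications that genuinely need the poles, an
equirectangular mode (rows uniform in latitude, ±90° allowed) is provided —
it sacrifices conformality, and the package asserts nothing about it beyond
its row placement. The reference radius scaling *y* is the *fitted* sphere
radius for all layers, so that layers of a multi-layer stack stay
pixel-aligned.

Each map pixel takes the volume intensity at
`center + r(sin φ, cos φ sin λ, cos φ cos λ)` with `r = R + offset`,
interpolated trilinearly in physical coordinates (nearest-neighbour is
available for label volumes); points outside the voxel-centre bounding box
return a fill value rather than erroring. `projectMultilayer()` samples a
series of concentric shells — 2 µm apart by default — and
`maxProjectLayers()` collapses the stack into a maximum-intensity Mercator
projection.

Default grid size: one column per `pixelSize` of equatorial arc
(`nCols = round(2πR / pixelSize)`; the natural choice for `pixelSize` is
the smallest voxel spacing, i.e. Nyquist at the equator) and rows at the
same physical scale.

**Measured properties.** On an analytically rendered uniform shell the map
is flat to within ±1 % away from the truncation rows (the residual ripple
is trilinear interpolation droop, bounded by `h²·max|f″|/8 ≈ 0.8 %` for a
radial Gaussian shell of σ = 8 µm sampled at 2 µm voxels). Small
Gaussian-profiled geodesic discs at latitudes 0°/30°/60° project to blobs
of aspect ratio 1 within ~1 %, with linear size scaling as sec(latitude)
within ~2 %. The conformality probe is deliberately small (tangential
σ = 4 µm on a 100 µm sphere, measured on a 1 µm map grid): conformality is
a *local* property, and a probe of tangential size σ adds a moment bias of
order (σ tan φ / R)², which this size keeps below 1 % at 60° — larger
probes would report their own extent, not the projection's behaviour.

## Spot counting

`detectSpots()` reimplements, with fully exposed parameters, the kind of
automated cell picking normally done in commercial software whose
parameters are unpublished:

1. **Baseline subtraction** — Gaussian blur at `backgroundSigma`
   (default 15 µm, i.e. 5 spot sigmas; converted per axis to voxels,
   reflective boundaries), subtracted and clipped at zero. A broad baseline
   attenuates a σ = 3 µm blob by well under 10 % while removing constant
   background and slow shading exactly.
2. **Local maxima** — 26-neighbourhood maxima of the subtracted volume at
   or above `detectionThreshold` (default 25 intensity units, chosen
   between the noise floor at background 10 — Poisson sd ≈ 3 plus read
   noise 2 — and the ≈ 110 blob peak).
3. **Greedy physical suppression** — peaks ordered by descending intensity
   (ties by lexicographic (z, y, x) index) are accepted only if at least
   `minSeparation` (default 8 µm) from every accepted peak.
4. **Centroid refinement** — intensity-weighted mean over a
   ±2 `expectedSpotSigma` window; if refinement pulls two centroids closer
   than `minSeparation`, the lower-priority one is dropped so the
   separation invariant holds exactly on the output.

In the exact-recovery regime (no noise, pairwise separation ≥ 4 cell
sigmas) the detected count equals the true count and each centroid lands
within one voxel of its cell; at peak SNR 10 under the full camera model,
recall and precision stay above 0.95 across seeds. Counts in axis-aligned
µm boxes use an inclusive-lo/exclusive-hi rule, making counts over a
partition of space exactly additive. `quantifyTimecourse()` assembles one
row per embryo × timepoint × ROI (always including a `whole` ROI) — counts
are reported per embryo, never pooled.

## The synthetic embryo

`EmbryoSpec()`/`generateVolume()` simulate the *structure* that the
algorithms consume, with exact ground truth:

* cells uniformly distributed on a shell at `sphereRadius + shellOffset`,
  rejection-sampled to a minimum pairwise distance (an error names the
  achievable density when the shell cannot hold the request);
* each cell an analytically evaluated Gaussian blob, isotropic in µm,
  rendered through the anisotropic voxel grid (no convolution kernels, so
  no truncation ambiguity);
* optional yolk autofluorescence filling the sphere interior with a soft
  edge;
* a standard camera model applied last: Poisson shot noise on
  (signal + background) in photon units via a configurable gain, then
  additive Gaussian read noise, then clipping at zero.

Identical specs give bit-identical volumes (single seeded generator);
time-course volumes draw per-(timepoint, condition) seeds by hashing the
base seed with the labels, so any single volume can be regenerated
independently.

Defaults were fixed once as plausible study conditions: a 100 µm-radius
embryo in a 128³ volume at 2 µm isotropic spacing (256³ at (2, 1, 1) µm for
the anisotropic surface-estimation scenario), cell sigma 3 µm (a small
nucleus), amplitude 110 over background 10 with gain 1 and read noise
sd 2 — peak SNR ≈ 10 (`amplitudeForPeakSNR()` solves the quadratic exactly
when a scenario pins the SNR), 12 µm minimum separation (= 4σ, the exact
counting regime) and 200 cells for counting scenarios. The intensity
statistics of real fused light-sheet volumes are not published, so these
are calibration choices, not facts about any particular dataset.

**What the simulator does *not* emulate** — and hence what passing tests do
not show about real data: the embryo is a perfect sphere (no yolk
extension, no tail), blobs are Gaussian (no real optical PSF, no
depth-dependent aberration or attenuation), there is no stripe/shadow
artefact from the light sheet, no cell movement during acquisition, and no
registration error between views. Results on real volumes therefore depend
on upstream fusion quality and on segmentation parameters in ways the
synthetic suite cannot certify.

## Numerical choices and degenerate inputs

* Binning uses exact block means; uneven trailing blocks average what they
  contain.
* The binarization tie rule (ties → foreground) is applied at 10⁻⁹
  relative tolerance (see above).
* `fitSphere` refuses < 4 points, rank-deficient (coplanar) designs and
  non-positive squared radii with named errors rather than returning
  garbage.
* `mercatorY` errors at |φ| ≥ 90°; `makeGrid` explains the pole
  singularity and points at the equirectangular mode.
* Out-of-volume samples are a fill value by design (maps routinely reach
  outside the data near the poles); non-positive sampling radii are
  errors naming the offending layer offset.
* Spot ties are broken deterministically (intensity, then (z, y, x)
  index), so detection is reproducible to the bit.
* Volumes are stored as 32-bit fixed-point TIFF pages (the TIFF writer
  quantizes to a 32-bit integer grid) with a power-of-two intensity step
  recorded, as its integer exponent, in a JSON sidecar beside the image
  together with the voxel spacing; integer-valued intensities round-trip
  exactly and arbitrary ones are quantized at ~10⁻¹⁰ of range. Reading a
  TIFF without spacing metadata requires an explicit spacing — never a
  silent default.

## Problem sizes used in validation

The test suite and `scripts/acceptance.R` run entirely on simulated data
at sizes chosen to exercise every code path at full fidelity: 128³ volumes
for counting, projection and time-course scenarios (six volumes for the
3-timepoint × 2-condition course), one 256³ anisotropic volume for surface
estimation, 100 replicates × 500 points for the noisy sphere fit and 20
seeds for the SNR-10 detection benchmark. The acceptance run completes in
about two minutes on a single CPU.

## Known limitations

* Only spheres are fitted; ellipsoidal or free-form embryo shapes (late
  somitogenesis, yolk extension) are out of scope.
* The map's polar axis defaults to the volume's z axis; aligning it to the
  animal–vegetal axis requires rotating the input volume upstream, as no
  canonical orientation is defined by the data themselves.
* Spot detection assumes roughly isotropic, blob-like cells of known
  scale; touching cells closer than the suppression distance merge.
* No statistical testing is performed on count differences between
  conditions — the output is the per-embryo count table.
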