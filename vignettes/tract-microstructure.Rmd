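---
title: "Assigning multi-fixel microstructure to tracts: methods and design"
author: "unravelr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning multi-fixel microstructure to tracts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unravelr)
```

## The problem

Diffusion MRI tractometry asks: what are the microstructural properties of a
specific white-matter pathway? The classical answer — average a scalar map
such as DTI fractional anisotropy (FA) over the voxels a tract traverses — is
confounded wherever fibers cross: in a crossing voxel the single-tensor FA
describes neither population, and up to 90% of white-matter voxels contain
more than one fiber population. Multi-fixel models resolve this at the voxel
level: each voxel holds up to $K$ *fixels* (fiber populations), each with its
own orientation $\hat u_{vk}$, volume fraction $f_{vk}$, and metrics
$M_{vk}$ (FA, fiber volume fraction FVF, ...). What is then needed is a rule
connecting macroscopic tractography streamlines to the right fixel in each
voxel. This package implements that connection.

## The model

A tract $T$ is a set of streamlines; each streamline is a polyline whose
straight segments are subdivided at voxel boundaries into intra-voxel
subsegments $s$ with direction $\hat u_{vs}$ and length $l_{vs}$ (mm). The
key quantity is the relative contribution $\alpha_{vsk} \in [0,1]$ of fixel
$k$ to segment $s$ in voxel $v$, with $\sum_k \alpha_{vsk} = 1$. Three
definitions are provided:

* **vol** — relative volume: $\alpha_{vsk} = f_{vk} / \sum_{k'} f_{vk'}$,
  orientation-blind;
* **cfo** — closest fixel only: the fixel with the smallest axial angle to
  $\hat u_{vs}$ takes everything;
* **ang** — angular weighting: with $\theta_k$ the axial angle between
  segment and fixel and $\phi = \min(90, \sum_k \theta_k)$,
  $$\alpha_{vsk} = \frac{\phi - \theta_k}{\phi K - \sum_{k'} \theta_{k'}}
  \quad (K > 1), \qquad \alpha = 1 \quad (K = 1).$$

Contributions aggregate into fixel weight maps
$w_{vk} = \sum_s \alpha_{vsk}\, l_{vs}$, the total-segment-length map
$w_v = \sum_k w_{vk} = \sum_s l_{vs}$ (a tractography-only tract-presence
measure), tract microstructure maps
$M_v = \sum_k w_{vk} M_{vk} / \sum_k w_{vk}$, and the tract-wide mean
$\bar M = \sum_v \gamma_v M_v / \sum_v \gamma_v$ with either
$\gamma_v = w_v$ (**tsl**, length-weighted) or $\gamma_v = 1$ on
tract-occupied voxels (**roi**). Two algebraic identities — the map equals
the segment-aggregated form $\sum_s l_{vs} M_{vs} / \sum_s l_{vs}$, and the
tsl mean equals the global segment aggregate — are implemented as an
independent second code path (`segment_level_map`) and asserted to $10^{-9}$
in the test suite.

## Conventions and numerical choices

**Axial angles.** Fixel peaks and streamline directions are sign-ambiguous,
so all angles are computed as $\arccos|\hat u \cdot \hat v| \in [0°, 90°]$.
This is also the only reading under which the $\phi = \min(90, \cdot)$ cap
in the angular weight is meaningful. Angles are evaluated in world (RAS mm)
space: peak vectors are conventionally stored in world coordinates, and
anisotropic voxels would distort voxel-space angles.

**cfo ties.** Equal angular distances are resolved to the lowest fixel
index. Any fixed rule works; a deterministic one makes maps bit-reproducible.
The spurious-fixel experiment below deliberately hits this tie.

**ang degeneracies.** When all $\theta_k$ equal $\phi$ (including the
all-aligned case $\theta_k \equiv 0$) the formula is $0/0$; the continuity
limit $1/K$ is returned (threshold: denominator $< 10^{-12}$ in degrees).

**Absent fixels.** A fixel slot with fraction $\le 0$ or near-zero
orientation norm is absent — multi-fixel model outputs pad unused slots with
zeros. Voxels with no fixels (CSF) yield undefined (`NaN`) map values and are
excluded from tract means under both weightings, so CSF cannot dilute
white-matter summaries.

**Geometry.** Voxel centers sit at integer 0-based voxel coordinates; voxel
$(i,j,k)$ owns the half-open box $[i-0.5, i+0.5)$ per axis. Subsegments are
found by parametric ray marching against the half-integer boundary planes;
lengths are measured in world mm and sum exactly (to $10^{-9}$ relative) to
the parent segment length. All pieces of one straight segment keep the parent
segment's direction. Pieces falling outside the volume are excluded with a
message rather than an error, since real tractograms routinely brush mask
edges. A segment through a voxel corner is measure-zero ambiguous; either
assignment preserves the length sum, which is what we guarantee.

**roi membership.** A voxel belongs to the tract's ROI iff $w_v$ exceeds a
threshold (default 0 mm, i.e. any streamline presence). The optional
`min_length` lets users suppress edge voxels crossed by a sliver of a single
streamline, which otherwise enter the roi mean with full weight.

**Accumulation.** Weights accumulate voxel-major with a deterministic
reduction, so repeated runs are bit-identical.

## The synthetic phantom

`generate_phantom()` builds the package's validation scene at the fixel
level: a 32 × 32 × 1 slice of 2 mm isotropic voxels containing two horizontal
tracts (T1 top, FVF 0.70; T2 bottom, FVF 0.66) crossed by two vertical
tracts whose FVF increases linearly from top (0.40) to bottom (0.70), CSF
voxels with no fixels elsewhere, and 50 straight streamlines per tract
(1 mm steps) at seeded random offsets across each band. Crossing voxels hold
both tracts' fixels at 90°, fractions 0.5/0.5, each fixel carrying its own
tract's ground truth — so every map and mean has an exact expected value.

Choices the scene description leaves open, fixed here once: the vertical
tracts' FVF endpoints (0.40 → 0.70, a plausible low-to-high white-matter
range), FA ground truths (T1 0.78, T2 0.74, vertical 0.45 → 0.70; ordinary
deep-white-matter values, high for the coherent horizontal bundles), grid
size, band widths (4 voxels) and streamline count. All are `phantom_spec`
parameters; the defaults above are what the tests and the acceptance script
use.

The phantom is generated directly at the fixel level rather than by
simulating a diffusion signal and fitting a multi-fixel model: the framework
consumes fixels, so fixel-level ground truth exercises every implemented
equation at desk scale. The Monte-Carlo substrate parameters the geometry
emulates (intra-axonal diffusivity 2.0 μm²/ms, extracellular 1.0 μm²/ms,
gamma-distributed axon diameters of mean 1.0 μm) are recorded in the
manifest as provenance only. Consequently the phantom does **not** model
estimation noise on orientations or metrics (unless `jitter_sd > 0`),
partial-volume ramps at band edges, curvature, or dispersion — passing its
tests demonstrates correctness of the weighting and aggregation machinery,
not robustness to real-data model-fitting error.

`corrupt_fixels()` adds the one estimation-error mode that matters for
comparing strategies: within a region, a true single fixel is replaced by two
spurious fixels tilted ±15° about the true axis with metrics offset ±0.1
(both configurable). For a segment running along the true axis the two
spurious fixels tie in angle: closest-fixel-only resolves the tie to one
fixel and inherits its full +0.1 offset, while angular weighting splits
evenly and cancels the offsets — reproducing the known overestimation of
cfo-based streamline metrics under fixel-splitting errors, and motivating
angular weighting.

```{r phantom}
ph <- generate_phantom(phantom_spec(seed = 1))
ph
fit <- unravel(ph$field, ph$tracts$T1, strategy = "ang")
summary(fit)
```

With perfect fixels, `ang` and `cfo` with tsl weighting recover the
generating FVF exactly (streamlines run along the horizontal axis, so the
crossing vertical fixel sits at 90° and receives zero weight), while `vol`
is contaminated by the crossing tract:

```{r contamination}
fitv <- unravel(ph$field, ph$tracts$T1, metrics = "FVF", strategy = "vol")
c(ang = coef(fit)[["FVF"]], vol = coef(fitv)[["FVF"]])
```

## Problem sizes

The default phantom (4 × 50 streamlines of ~64 points on a 32 × 32 grid,
about 4,700 subsegments per tract) runs a full fit in a few seconds; the
property suites sample $10^4$ random voxel-segment configurations and a
handful of random fields of ~150 voxels. These sizes were chosen so the
entire validation cycle runs interactively on a laptop while still covering
1-, 2- and 3-fixel voxels, empty voxels, anisotropic and translated grids.

## I/O

Fixel fields are read from "peaks"-style NIfTI (4D, last dimension
$3K$: consecutive xyz triplets, world RAS, all-zero = absent) plus 4D
fraction and metric volumes sharing the grid and affine; this single-file
layout was preferred to directory-per-fixel encodings, and the loader is the
one place another dialect would be added. Tractograms are read and written in
MRtrix TCK (already world mm) and TrackVis TRK v2 (corner-origin voxel-mm,
mapped through the header's `vox_to_ras`); both are validated against each
other in the tests. Maps are written as 32-bit float NIfTI with `NaN` as the
undefined sentinel; means and profiles as CSV; each run emits a JSON manifest
with config, seed and package version.

## Known limitations

* Only the angular-weight family above is implemented; for $K > 2$ other
  contribution definitions may be preferable, and none is standard.
* Straight-segment geometry: no curved-arc subdivision or resampling; the
  step size is taken as given.
* `scan_rescan_stats` uses the symmetric (Bland-Altman) percentage-change
  denominator $((m_1 + m_2)/2)$; with the first-scan denominator values
  differ at the second decimal for typical FA test-retest changes.
* The phantom's realism limits are described above; group-level statistics
  beyond scan-rescan percentage changes are out of scope.
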