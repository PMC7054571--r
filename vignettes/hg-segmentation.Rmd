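---
title: "Surface-based segmentation of Heschl's gyrus: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-based segmentation of Heschl's gyrus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgseg)
```

## The problem

Heschl's gyrus (HG) — the first transverse temporal gyrus, containing
primary auditory cortex — lies on the "open" supratemporal plane,
contiguous with its neighbours, so grey/white intensity contrast alone
cannot delimit it. Atlas-driven parcellations place it approximately but
make systematic errors: the medial portion of the gyrus is assigned to the
posterior segment of the lateral sulcus, labels spill into the adjacent
transverse temporal sulcus, and duplicated gyri are split arbitrarily
between the HG and planum temporale labels. At the same time HG morphology
varies strongly across individuals and hemispheres: a single gyrus, a
common stem duplication (CSD — one gyrus partially split by a sulcus
intermedius), or a full posterior duplication (FPD — a fully separate
second gyrus). The anatomical convention adopted here includes CSDs in HG
and assigns FPDs to the planum temporale.

`hgseg` refines the atlas parcellation into a fine HG label using only
surface geometry: per-vertex mean curvature with the FreeSurfer sign
convention (negative = locally convex = gyral, positive = concave =
sulcal), and hop-layer morphology on the vertex adjacency graph.

## The algorithm and its assumptions

Two vertex-set streams are built from four atlas ROIs (transverse temporal
gyrus, transverse temporal sulcus, planum temporale, posterior segment of
the lateral sulcus):

* **auditory complex** = gyrus ∪ sulcus ∪ planum — the search region for
  gyral crowns;
* **expansion mask** = complex ∪ posterior lateral sulcus — the region
  within which gyri are regrown. Including the lateral-sulcus ROI is what
  lets the pipeline recover the medial end of HG when the atlas mislabels
  it.

Each stream is thresholded at curvature < 0 (keeping gyri) and opened on
the vertex graph. Crowns are the final-complex vertices with curvature
< −0.1 mm⁻¹; they are regrown into the final expansion mask by connected
components; components with fewer than 100 vertices are discarded; the
component with the most anterior area-weighted centroid is the label.

Assumptions worth making explicit:

* curvature sign is meaningful — the input must be the mean curvature of
  the grey–white boundary surface, not a smoothed/averaged variant with a
  different scale;
* the four ROI names exist in the annotation (names are configurable);
* anterior is the +Y surface RAS axis (configurable), and hemisphere
  surfaces are processed independently;
* within the merged auditory region, the most anterior surviving gyral
  component is HG. A CSD stays one component because the gyral
  (curvature < 0) vertices of its two ridges connect through the common
  stem; an FPD is separated from HG by a complete sulcus of positive
  curvature and therefore forms its own, rejected component.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `gyral_threshold` | 0 | mm⁻¹ | strict cutoff selecting convex (gyral) vertices |
| `crown_threshold` | −0.1 | mm⁻¹ | strict cutoff selecting gyral crowns |
| `opening_depth` | 3 | hop layers | erosion/dilation radius of the opening |
| `min_cluster_vertices` | 100 | vertices | smallest candidate gyrus kept |
| `anterior_axis` | 2 (+Y) | — | RAS axis used for "most anterior" |

Both thresholds are strict (`<`): a vertex at exactly −0.1 is not a crown.
The opening's structuring element is expressed in hop layers on the vertex
graph, not millimetres: depth 3 removes the three outermost layers of a
patch during erosion and therefore deletes any attached formation up to
six vertices wide, while the subsequent dilation — which can only reach
vertices within three hops of the eroded core — restores the rim of wide
blobs without reinstating the strips. Erosion and dilation with the same
ball form an adjunction, so the opening is anti-extensive, increasing and
idempotent; the test suite asserts all three on randomized sets.

## Numerical choices

* **Vertex areas** are barycentric (one third of each incident triangle),
  so they sum exactly to the mesh area.
* **Mean curvature** uses the cotangent mean-curvature-normal operator
  with barycentric areas, signed by the outward vertex normal so that
  convex vertices are negative. On a radius-10 mm icosphere this yields
  −0.100 mm⁻¹ within 0.1%.
* **Gaussian curvature** is the angle deficit (2π − Σ angles; π at
  boundary vertices) over the vertex area, which makes the discrete
  Gauss–Bonnet theorem exact on closed meshes up to roundoff.
* **"Volumetric centre"** of a candidate gyrus is implemented as the
  area-weighted centroid of its white-surface vertices. A literal
  volumetric centre would need voxelized grey matter that the pipeline
  never constructs; area weighting is the closest surface-native
  analogue and only the anterior *ordering* of candidates matters.
* **Grey-matter volume** of a label is the per-vertex prism
  Σ t·(a_white + a_pial)/2. This is internally consistent and matches
  analytic slabs and spherical shells within 1–2%; bit-parity with any
  particular neuroimaging tool's volume command is a non-goal.
* **Thickness mean** is unweighted over label vertices (the convention of
  the reference stats tools); area weighting would change values by < 1%
  on the synthetic patches.
* **Ties** in anterior coordinate (exactly equal centroids) resolve to
  the larger candidate, then to the smaller lowest vertex index — both
  deterministic.
* **Crowns outside the expansion mask** (possible because the two streams
  are opened independently) are intersected into the mask with a warning
  rather than an error: the regrowth is defined only inside the mask.
* The cluster-size check runs after regrowth, on candidate components,
  i.e. between growth and anterior selection.

## The synthetic test bed

Real surface reconstructions are not shipped, so the generator emulates
the geometry the pipeline cares about: a 120 × 90-vertex triangulated
patch over 60 × 45 mm (≈ 0.5 mm spacing, comparable to a FreeSurfer
mesh), with 1–2 oblique Gaussian ridges (amplitude 5 mm, σ 4 mm,
obliquity 15°, crest separation 12 mm) running mediolaterally. With these
values the crest curvature is ≈ −A/(2σ²) ≈ −0.16 mm⁻¹ — comfortably below
the crown threshold, as on real gyri — and the convex band of each ridge
is ≈ 8 mm wide. For CSDs the inter-ridge valley is filled medially by a
common-stem bridge over (1 − span) of the gyrus length (span defaults to
0.5); for FPDs the two ridges stay fully separated by a concave valley.
Smooth vertical jitter (SD 0.15 mm, correlation length 2 mm) perturbs the
height field; being spatially correlated it shifts curvature by
~0.04 mm⁻¹, an order of magnitude below crest curvature — per-vertex white
noise would instead produce curvature noise larger than the thresholds at
0.5 mm spacing, which real, smoothed reconstructions do not show. The
pial surface is the white surface offset along vertex normals by a smooth
thickness field (2.5 ± 0.25 mm).

The parcellation bands (gyral ROI half-width 5.5 mm, 4 mm sulcus band,
planum posterior of it, posterior-lateral-sulcus strip on the medial 6 mm)
are derived from the same geometry, and three atlas error modes can be
injected into the *parcellation only* (geometry is never altered):
excluding the medial 10 mm of the gyrus ROI, spilling the gyrus ROI into
the sulcus band, and moving a CSD's second ridge into the planum ROI.
Ground truth is computed on the noise-free geometry with the same
discrete curvature operator the pipeline uses, so truth and input share
one curvature definition; the analytic ridge-distance fields remain the
independent cross-check for band membership.

What passing on this test bed shows — and what it does not: the fixtures
exercise mask merging, curvature thresholds, opening behaviour, CSD/FPD
topology, anterior selection and error recovery at realistic mesh
resolution, but they are a smooth idealization. Real cortex adds
irregular gyral geometry, curvature fields smoothed by reconstruction
pipelines, topological quirks and third/fourth transverse gyri; accuracy
on real data must be established against manual labels, as the original
validation literature does with pooled automated-vs-manual correlations.

One measurement definition deserves note: when the medial-exclusion error
is injected, recovery is reported against the *recoverable* strip — the
mis-assigned vertices that the pipeline selects when no error is injected
(same seed). A few per cent of the strip's ground-truth vertices have
weakly negative noise-free curvature that jitter flips positive; no
labelling-robust pipeline can select those, so counting them would
measure the jitter, not the recovery.

## Statistical toolkit

Comparing an automated and an atlas method against the same manual
reference on one sample yields two *dependent* correlations sharing a
variable; an independent-samples Fisher test would be miscalibrated. The
package therefore implements the Meng–Rosenthal–Rubin z (the naive
independent variant is available behind a flag for comparison). Its null
calibration is verified by simulation (rejection rate 0.05 ± 0.01 at
α = 0.05 over 10,000 replicates of trivariate normal samples, n = 50 per
replicate — large enough for the asymptotic test, small enough to be the
hard case). Published pooled validation z-scores (4.30 left, 6.16 right,
n = 181) are reproduced from their printed, rounded inputs to within
~1.5% and ~3%; the residual is attributable to input rounding and to the
published analysis not stating which dependent-correlation variant was
used, so these serve as soft cross-checks rather than exact targets.
Partial correlations are computed as correlations of least-squares
residuals with n − 2 − k degrees of freedom, one-tailed in the positive
direction (the direction of the volume–behaviour hypotheses these
analyses test).

## Problem sizes and scope

The test suite and acceptance script use: 20 seeds × 3 morphotypes at the
default 120 × 90 grid for segmentation accuracy; ≥ 100 randomized sets on
grid and sphere meshes (≤ 2000 vertices) for oracle equivalence; a
subdivision-4 icosphere (2562 vertices) for geometry; 10,000 replicates
for null calibration; n = 2000 for partial-correlation recovery. These
sizes give sub-percent Monte-Carlo error on every reported quantity while
keeping a full run in minutes on one CPU.

Known limitations: no GIFTI/volume I/O (FreeSurfer binary and ASCII
formats only, "new"-format variants); no geodesic-millimetre morphology
(hop layers only — on strongly anisotropic meshes the two differ); no
shape typology of the segmented gyrus, no FPD-inclusive selection
variants, and no handling of third or further transverse gyri beyond
their exclusion by anterior selection.
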