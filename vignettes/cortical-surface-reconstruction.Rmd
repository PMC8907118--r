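---
title: "Cortical surface reconstruction from implicit level-set representations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortical surface reconstruction from implicit level-set representations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cortrec)
```

## The problem and the model

Reconstructing the cortical surface from a T1-weighted MR volume means
producing two nested, closed, genus-0 triangle meshes per hemisphere: the
*white* surface (white-matter/grey-matter boundary) and the *pial* surface
(outer grey-matter boundary). Classical pipelines deform explicit meshes and
spend most of their time repairing topological defects. `cortrec` instead
works with an **implicit representation**: the surface is the zero set of a
voxel-wise *level-set* field \(\phi\), a truncated signed Euclidean distance
that is negative inside the surface, zero on it, and positive outside.

The workflow has four steps:

1. **Normalize** intensities: affine rescale to 0–255, then z-score
   (`normalize_intensity()`).
2. **Segment** hemispheric white matter with a 3D U-Net (softmax head,
   cross-entropy loss), yielding one binary mask per hemisphere.
3. **Regress** the level set with the same U-Net architecture, adapted by
   replacing the softmax output layer with a plain convolution and training
   with mean squared error. Inputs are two channels: the normalized image
   and one hemisphere mask; each hemisphere is an independent task, so the
   two can run in parallel.
4. **Correct and extract**: volumetric topology correction of \(\phi\)
   followed by topology-preserving isosurface extraction gives a watertight,
   genus-0 mesh without any mesh-repair stage.

Morphometrics (cortical thickness, sulcal depth), mesh quality, surface
displacement, parcellation Dice overlap and test–retest instability are
computed by the `metrics` functions on the explicit meshes.

## Level-set encoding

`encode_levelset()` computes, at every voxel centre, the *exact* Euclidean
distance to the mesh (point-to-triangle queries through an AABB tree with
best-first traversal), signs it by ray-parity (rays cast along grid columns
in index space, where affine maps preserve incidence), and clamps to
±`truncation`.

* **Truncation default: 8 mm.** Wide enough to cover the cortical ribbon
  and its neighbourhood, narrow enough to keep regression targets bounded.
  Regression targets are scaled by `1/truncation` into \([-1, 1]\) for
  conditioning and unscaled before extraction.
* Degenerate ray–triangle incidences (a ray exactly through an edge) have
  measure zero for the meshes produced here; column-parallel triangles are
  skipped and their parity contribution is carried by adjacent triangles.
* A voxel centre lying exactly on the mesh gets distance 0 and is treated
  as inside ("negative inside" convention) by the extractor.

## Topology: one simplicial complex for correction *and* extraction

The usual digital-topology route pairs a (6,26) or (26,6) voxel
connectivity with a marching-cubes table. We instead fix the **Freudenthal
decomposition** (six tetrahedra per cube; 14-neighbour lattice adjacency)
and use it for both operations:

* `correct_topology()` fills interior cavities, then grows a region from
  the most-interior voxel (minimum \(\phi\)), admitting negative voxels in
  increasing-\(\phi\) order (priority queue; ties broken by voxel index)
  only when they are *simple points*: the full subcomplex of the 14-vertex
  link spanned by region neighbours — and the one spanned by the rest —
  must each be nonempty, connected, and of Euler characteristic 1. A
  rejected voxel is retried whenever a neighbour joins the region.
* `extract_surface()` runs marching tetrahedra on the same decomposition.
  Every tetrahedron is split by the linear interpolant; crossing vertices
  on shared edges are welded through global edge keys, so the mesh is
  watertight by construction, and each facet is oriented along the local
  field gradient (outward).

The point of sharing the complex: the sublevel set of the piecewise-linear
interpolant deformation-retracts onto the full subcomplex spanned by the
negative voxels, so the corrected region's topology and the extracted
mesh's topology *provably* coincide — after correction the mesh has
\(V - E + F = 2\), always. A cube-table extractor paired with a voxel-pair
simple-point test leaves diagonal configurations where the two disagree.
The cost is that isosurface vertices live on tetrahedral edges (cube edges
plus face/body diagonals) rather than cube edges only.

Re-signing after correction keeps all untouched voxels at their exact
distances and clamps flipped voxels to ±0.25 voxel, so the zero crossing
stays inside the flipped cell and sub-voxel accuracy is preserved away
from cuts. Note that cutting a handle (e.g. a solid torus) necessarily
flips voxels as deep as the tube radius; there is no bound on the depth of
flipped voxels in general.

## The U-Net

One architecture, two heads (`net_config()`):

* Encoder stage: a 3×3×3 convolution + leaky ReLU (slope 0.01), then
  2×2×2 max pooling; channels double per stage.
* Decoder stage: 2× nearest upsampling followed by a 1×1×1 convolution
  (the exact per-voxel linear map a stride-2 2×2×2 transposed convolution
  applies), concatenation with the same-resolution encoder features, then
  a 3×3×3 convolution + leaky ReLU.
* Head: 1×1×1 convolution; channel-wise softmax for segmentation, nothing
  for regression (outputs unbounded).

Training (`train_network()`) uses Adam with the linear schedule
\(\mathrm{lr}(e) = \mathrm{lr}_0 - e \cdot d\) (defaults
\(\mathrm{lr}_0 = 10^{-3}\), \(d = 10^{-6}\), epochs numbered from 0), a
batch size of 2, at most 1000 epochs, and early stopping when the relative
epoch-loss change stays below \(10^{-4}\) for 50 consecutive epochs — the
defaults mirror the full-scale training regime; the desk-scale runs below
use far fewer epochs. Augmentation (random flips along non-lateral axes)
exists but is off by default: resampling degrades exact regression
targets. For segmentation, `class_weights = "balanced"` weights voxels
inversely to class frequency — with white matter occupying under 2% of a
phantom volume, unweighted cross-entropy spends hundreds of epochs
predicting background. Convolution arithmetic runs in single precision
(im2col + BLAS GEMM); the GEMMs are memory-bound, so this halves traffic
at no observable cost to training.

`predict_sliding()` tiles volumes larger than the patch at half-patch
stride and blends with a Gaussian window (\(\sigma = \mathrm{patch}/8\)),
which conserves constants and feathers seams. Save/load round trips
(`save_model()`/`load_model()`) reproduce bit-identical predictions.

## The phantom generator

`generate_phantom()` provides ground truth the real pipeline never has:

* The white surface is a radially perturbed icosphere,
  \(r(\theta,\varphi) = R + \sum_{l=2}^{L}\sum_m c_{lm} Y_{lm}\), with
  Gaussian coefficients decaying as \(1/l\) and rescaled so the maximum
  excursion equals `fold_amplitude`. Spherical-harmonic folding is
  genus-0 by construction and band-limited, giving a tunable
  "gyrification" knob.
* The pial surface is the white surface displaced along vertex normals by
  exactly `cortical_thickness_true`, so thickness recovery has a known
  answer; a face-normal flip test catches self-folding offsets (the
  amplitude is reduced and the build retried up to 3 times).
* Level sets of both surfaces are encoded exactly; tissue labels follow
  from their signs (per-hemisphere GM/WM codes; two hemispheres are two
  disjoint blobs offset along world x with a ≥4-voxel gap).
* Intensities: tissue mean × smooth multiplicative bias field (sum of
  three random low-frequency cosines, amplitude ±5% by default) plus
  additive Gaussian noise. With `partial_volume = TRUE` (default),
  boundary voxels mix tissue means by volume fractions derived from the
  signed distances — the partial-volume effect is what encodes sub-voxel
  surface position in real T1w data, and without it sub-voxel regression
  targets are not identifiable from the image.
* One master seed drives named sub-streams (harmonics, noise, bias,
  per-session realisations), so `phantom_sessions()` can vary only the
  noise while sharing the exact geometry across repeated "scans".

What the phantom does **not** emulate: MRI acquisition physics (no
k-space, Rician noise, or motion), skull/CSF compartments, midline
anatomy, lesions, and real cortical geometry (two smooth nested blobs, not
a folded sheet with medial wall). Passing tests therefore demonstrate
correctness of the geometry/learning machinery under known truth, not
clinical performance.

## Study conditions (problem sizes)

Chosen once as the package's desk-scale defaults:

* Geometry checks: 48³ voxels at 1 mm, white radius 14 mm, folding 3 mm
  (≤ radius/4), thickness 2.5 mm.
* Regression learning: 32³ at 1 mm, radius 8 mm, folding 1.6 mm,
  thickness 2.4 mm, single hemisphere; 16 training phantoms, tiny net
  (3 stages, base 8 channels, patch 32³, head bias started at the clamp),
  35 epochs.
* Segmentation learning and the end-to-end pipeline: 48×32×32 at 2 mm (so
  the network's receptive field spans the volume — left/right assignment
  is positional information that must reach every voxel from the volume
  borders), two hemispheres of radius 9 mm; 4 stages, base 8 channels,
  class-weighted cross-entropy (weights 1/20/20 for
  background/left-WM/right-WM: strong enough to lift the <2% foreground,
  capped so the weighted posterior argmax does not over-segment
  boundaries). The pipeline's regression model is trained on the same
  two-hemisphere frames, one hemisphere task per sample (32 tasks,
  15 epochs), and topology correction during reconstruction is seeded at
  the most interior voxel of each hemisphere mask.

## Numerical choices and edge cases

* Exact zeros in \(\phi\) are treated as inside by the extractor
  (deterministic tie-break; no perturbation of stored values).
* `correct_topology` seeds at the global minimum; disconnected foreground
  components other than the seed's are removed (re-signed positive).
* Interior cavities are filled *before* growth (background 14-components
  not touching the grid border).
* `hemisphere_split` assigns left/right by world-x centroid under the RAS
  convention (+x right); with more than two components the largest two are
  kept and smaller ones merge to the nearest centroid, with a warning.
* Sulcal depth needs a "midsurface": we smooth the mesh by implicit
  (backward-Euler) Laplacian steps — clamped cotangent weights, lumped
  mass matrix, diffusion step of one squared mean edge length, 50 steps by
  default — and rescale about the centroid so the mean signed depth is
  exactly zero (the midsurface bisects gyri and sulci by construction).
  Because the smoothed copy keeps vertex correspondence, depth is the
  per-vertex offset projected on the midsurface vertex normal ("distance
  along the midsurface normal"); a closest-point distance would
  systematically undershoot on steep folds. Positive depth = inside the
  midsurface = sulcal. This is a convention, not an equivalence to any
  particular neuroimaging tool's sulc map. (Explicit surface smoothing via
  `smooth_surface()` is separate: Taubin \(\lambda/\mu\) passes with
  \(1/\lambda + 1/\mu = 0.1\), cotangent or uniform weights.)
* Thickness defaults to the symmetric point-to-surface average of the two
  directions; displacement defaults to one-directional
  (reconstructed → reference), each with a flag.

## Known limitations

* The homotopic growth guarantees genus 0 but not minimal cuts: the cut
  disk through a handle is wherever the two fronts meet in \(\phi\)-order.
* Marching tetrahedra produce more (and skinnier) triangles than cube
  tables; mean triangle quality of raw extractions is below what
  mesh-optimised pipelines report, and `smooth_surface()` is the provided
  remedy.
* The U-Nets here are deliberately tiny and trained on phantoms; they are
  a test of the learning path, not transferable models.
* Level sets are dense grids; no narrow-band storage.
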