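# cortrec

Cortical surface reconstruction from T1-weighted-like MR volumes via an
implicit **level-set** representation: a 3D U-Net segments hemispheric white
matter and regresses a truncated signed-distance field whose zero set is the
cortical surface; volumetric topology correction and topology-preserving
isosurface extraction then produce a watertight, genus-0 triangle mesh —
no mesh-repair stage. The package is aimed at researchers who want a fully
testable, self-contained desk-scale implementation of this reconstruction
family: every stage can be validated against synthetic brain phantoms with
exactly known ground-truth surfaces.

## The pieces

* **Level set**: \(\phi(x)\) = signed Euclidean distance (mm) to the
  surface, negative inside, clamped to ±truncation (default 8 mm).
  `encode_levelset()` computes it exactly from a mesh;
  `extract_surface()` inverts it by marching tetrahedra on the Freudenthal
  decomposition, after `correct_topology()` makes the negative region a
  topological ball by homotopic growth with simple-point tests. Correction
  and extraction share one simplicial complex, so the extracted mesh
  always has Euler characteristic \(V - E + F = 2\).
* **Learning**: `build_network()` / `train_network()` implement a
  configurable 3D U-Net (3×3×3 conv + leaky ReLU per stage, 2×2×2 max
  pooling, upsample + conv decoder with copy-and-concatenate skips) with a
  softmax/cross-entropy head for segmentation and a plain-conv/MSE head
  for level-set regression; Adam with learning rate
  \(10^{-3} - e\cdot10^{-6}\) at epoch \(e\), batch size 2, 50-epoch
  convergence window. `predict_sliding()` does overlapping-window
  inference with Gaussian blending.
* **Phantoms**: `generate_phantom()` builds folded nested surfaces
  (spherical-harmonic radial perturbation, pial = white + exact normal
  offset), their exact level sets, tissue labels and T1-like intensities
  (partial volume, bias field, noise); `phantom_sessions()` repeats the
  "scan" with fresh noise for test–retest studies.
* **Metrics**: triangle quality
  \(Q = 4\sqrt{3}A/(e_1^2+e_2^2+e_3^2)\) (1 = equilateral, 0 =
  degenerate), vertex-to-surface displacement, cortical thickness, sulcal
  depth, parcellation Dice, and across-session instability
  (per-vertex SD).
* **Pipeline**: `run_pipeline()` chains normalize → segment → regress →
  correct → extract per hemisphere (independent tasks, optionally
  parallel) and writes surfaces, level sets and a JSON manifest. A thin
  CLI lives at `exec/cortrec` (subcommands `phantom`, `train`, `predict`,
  `extract`, `reconstruct`, `evaluate`).

## Worked example

Round-trip a phantom through the implicit representation and measure how
far the reconstructed surface is from the known truth:

```r
library(cortrec)

ph   <- generate_phantom(phantom_params(), seed = 2)  # 48^3, 1 mm voxels
surf <- extract_surface(ph$white_levelset$lh)         # correct + extract
surf
#> <cortrec_mesh> 11672 vertices, 23340 faces, Euler characteristic 2

d <- surface_displacement(surf, ph$white_mesh$lh, symmetric = TRUE)
round(c(mean = d$symmetric_mean, max = max(d$a_to_b)), 4)
#>   mean    max
#> 0.0162 0.0807

q <- triangle_quality(surf)
round(q$q_mean, 3)
#> 0.654

th <- cortical_thickness(ph$white_mesh$lh, ph$pial_mesh$lh)
round(c(mean = mean(th), truth = ph$params$cortical_thickness_true), 3)
#>  mean truth
#> 2.496 2.500
```

The mesh is closed and genus 0 (Euler characteristic 2), the mean
reconstruction error is ~0.016 mm — about 1/60 of a voxel — and the
ground-truth cortical thickness is recovered to a few microns on the exact
meshes. Raw marching-tetrahedra triangles are skinnier than an optimised
mesh (mean Q ≈ 0.6); `smooth_surface()` trades a little fidelity for
quality if needed.

Training and applying the tiny networks end to end takes a few minutes
(see `tests/testthat/helper-fixtures.R` for the exact study conditions the
test suite uses):

```sh
exec/cortrec train --task seg      --out models/seg
exec/cortrec train --task levelset --out models/reg
exec/cortrec reconstruct --image t1.nii.gz \
  --seg-model models/seg --reg-model models/reg --out-dir run/
```

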