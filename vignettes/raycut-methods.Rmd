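---
title: "Seed-based radial graph-cut segmentation: model, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-based radial graph-cut segmentation: model, parameters and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raycut)
```

## The model

`raycut` segments a single blob-like 3D object — the motivating application
is the prostate central gland in T2-weighted MR — from one user-supplied
seed point assumed to lie inside the object. The construction is a
minimum-cost closed-set problem solved by an s-t minimum cut:

1. **Template.** A regular icosahedron subdivided `n` times (an icosphere)
   supplies `R = 10·4^n + 2` near-uniform unit directions. Two rays are
   *neighbours* when their template vertices share a triangle edge
   (`build_template()`, `neighbors_of()`).

2. **Ray grid.** From the seed, each ray is sampled at radii
   `step, 2·step, …, Z·step` (the seed itself is not a node — a shared node
   at radius 0 would be degenerate). Sample `(r, z)` reads the grey value of
   the voxel containing the sample point (`sample_rays()`).

3. **Costs.** The object's mean grey value `m` is estimated as the average
   over a cube of half-width `mean_radius_voxels` around the seed's voxel
   (`estimate_mean()`). The node cost is `c(r, z) = |I(r, z) − m|`: nodes
   whose intensity resembles the seed neighbourhood are cheap
   (`compute_costs()`). Samples outside the volume get a finite constant
   exceeding every attainable in-bounds cost, so the cut can never prefer
   leaving the volume yet no infinities enter the arithmetic.

4. **Graph.** Terminal weights telescope the costs along each ray:
   `w(r, 1) = c(r, 1)` and `w(r, z) = c(r, z) − c(r, z−1)`, so the summed
   weight of a closed set equals the summed cost of its outermost layer per
   ray — the candidate surface. Infinity-weighted arcs `(r, z) → (r, z−1)`
   make retained sets closed (an object containing a node contains everything
   between it and the seed); arcs `(r, z) → (r′, max(1, z − Δr))` between
   neighbouring rays bound the boundary-index difference across an edge by
   the stiffness parameter `Δr`; arcs `s → (r, 1)` keep the innermost layer
   inside, encoding the assumption that the seed is interior. Negative
   weights become source arcs of capacity `−w`, non-negative ones sink arcs
   of capacity `w` (`node_weights()`, `build_graph()`).

5. **Cut.** A max-flow/min-cut then yields the minimum-cost closed set; the
   per-ray boundary index `k[r]` is the outermost retained layer, and
   `sum(c[r, k[r]])` is provably minimal over all surfaces satisfying the
   stiffness constraint (`min_cut_surface()`). The surface is turned into a
   triangulated mesh (vertices at `k[r]·step` along each ray) and a binary
   mask by a radial inside test (`surface_to_mesh()`, `voxelize()`).

With `Δr = 0` all boundary indices coincide, so the result is exactly a
sphere placed at the common layer minimising the summed cost — a useful
sanity property that the tests exercise directly.

## Numerical and design choices

* **Intensity lookup.** Node intensities are read from the voxel containing
  the sample point (`method = "nearest"`, the default), which treats a
  hard-edged homogeneous object exactly: all interior nodes cost zero, and
  the maximal optimal surface lies on the outermost zero-cost layer.
  Trilinear interpolation (`method = "linear"`) is available; note that it
  blends boundary voxels into interior samples, which pulls the recovered
  surface roughly one voxel inward on hard-edged objects (on the 15 mm
  reference phantom below this costs about ten Dice points). It is the
  better choice only when sub-voxel smoothness of the cost field matters
  more than boundary placement.

* **Tie-breaking.** Among equally cheap closed sets the *maximal* one is
  returned: after max-flow, a node is retained unless the sink is still
  reachable from it through unsaturated residual arcs. On cost plateaus —
  homogeneous interiors — this places the boundary at the outermost optimal
  layer, i.e. at the object's extent rather than hugging the seed. The
  exhaustive reference implementation (`brute_force_surface()`) breaks ties
  towards the lexicographically largest index vector, which coincides with
  the maximal closed set because minimum-cost closed sets are preserved
  under union and intersection; the equality of both routes, including tie
  cases, is checked in the test suite.

* **Infinite capacities** are the finite constant `sum(|w|) + 1`, which no
  s-t cut of smaller total weight can saturate.

* **Geometry.** All sampling happens in world millimetres honouring spacing,
  origin and a full direction matrix (0-based indices, voxel centres at
  `origin + direction · (spacing ∘ index)`). Anisotropic grids are routine
  for MR and are covered by tests.

* **Voxelization** exploits the fact that the cut surface is star-shaped
  about the seed: a voxel centre at distance ρ in direction u is inside iff
  ρ ≤ s(u), where s(u) interpolates the three incident rays' cut radii with
  normalised cone (barycentric) coordinates over the template triangle
  containing u. This is exact for the represented surface, deterministic,
  and cheaper than general mesh voxelization. Candidate triangles are the
  ones incident to the direction's nearest template vertex; ties on edges
  resolve to the lowest triangle index.

## Defaults and what they mean

| parameter | default | meaning |
|---|---|---|
| `subdivision_level` | 3 (642 rays) | angular resolution ≈ 8°; finer levels refine the surface at 4× node cost per level |
| `Z` | 60 | samples per ray; with `step = min(spacing)` this is the maximal radial reach in voxels |
| `step` | `min(spacing)` mm | radial sampling distance; one in-plane voxel |
| `delta_r` | 2 | neighbouring rays may differ by ≤ 2 layers; 0 forces a sphere |
| `mean_radius_voxels` | 3 | 7³ cube for the mean grey value estimate |

The source publication states the graph construction and the role of the
stiffness parameter but not the template size, sample counts or
neighbourhood used in its prostate experiments; the defaults above are this
package's own choices, sized so that the default reach (≈ 60 in-plane
voxels) covers prostate-scale objects in clinical MR.

## The phantom generator

`make_phantom()` produces hard-edged spheres and ellipsoids (voxel centre
inside the analytic shape → foreground intensity) with optional i.i.d.
Gaussian noise from an explicit seed, plus the exact noise-free truth mask.
This emulates the geometry and contrast situation the algorithm targets —
a roughly isointense blob on a differing background — and deliberately not
MR realism: no Rician noise, no bias field, no texture, and (unless
`pv_shell = TRUE`, which adds a one-voxel linear transition) no
partial-volume blur. Passing phantom tests therefore demonstrates the
correctness of the optimisation and geometry, not clinical performance;
the published clinical figures (mean Dice ≈ 79% over ten prostate cases)
were obtained on external MR data with expert seeds that this package does
not redistribute — only the summary arithmetic over that published table is
reproduced here (`pcg_case_metrics()`).

Test problem sizes are chosen to keep the whole suite within a couple of
minutes: oracle comparisons run on the 12-ray icosahedron with `Z ≤ 5`
where exhaustive search is cheap, and end-to-end checks use 64³ volumes
with 642 rays.

## Known limitations

* **Noisy homogeneous interiors.** The optimum minimises the summed cost of
  the boundary nodes only. When noise breaks the interior cost plateau,
  every interior layer is approximately equally cheap, and layers close to
  the seed are slightly favoured because neighbouring rays there sample the
  same few voxels (correlated costs are easier to cherry-pick). The cut
  then remains *contained* in the object — leaking across a high-contrast
  boundary stays expensive, which is what the noisy acceptance check
  asserts — but may retract well inside it. Real MR interiors are not pure
  noise around a constant, and the published workflow relies on the
  operator repositioning the seed when a result is unsatisfying; for
  synthetic studies, keep noise moderate or pre-smooth.
* **Star-shaped objects only.** Every surface representable by the graph is
  star-shaped about the seed; concave organs or objects the seed does not
  "see" radially are out of scope, as are multi-object or coupled-surface
  extensions.
* **No intensity normalisation.** Costs are raw absolute deviations; bias
  fields or strong coil profiles distort them. Preprocessing is the user's
  responsibility.

## Reproducibility

The pipeline is deterministic: identical volume, seed and configuration
give bitwise-identical masks, meshes and reports. The only randomness in
the package is the phantom noise, which takes a mandatory explicit seed and
restores the caller's RNG state.
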