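---
title: "Inferring cell neighborhoods from nuclei centroids: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cell neighborhoods from nuclei centroids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellneighbors)
```

## The model

`cellneighbors` treats "being neighbors" as a property of space-filling
cells: two cells touch when no third cell comes between them and they are
close enough for their membranes to meet. With only nuclei centroids
available, the package approximates this in three steps.

**Candidate graph.** The Delaunay triangulation of the centroids is the
dual of the Voronoi tessellation: if the Voronoi regions of two points
touch, the points are joined by a Delaunay edge. For convex, roughly
space-filling cells the Voronoi region is a good proxy for cell territory,
so the Delaunay edge set is a *superset* of the true contact graph — it
contains the nearest-neighbor graph and is stable against small nuclear
displacements. The errors it does make are systematic: long edges along
the convex hull, and edges that "tunnel past" an intervening cell. In 3D
the Delaunay cells are tetrahedra; each is decomposed into its four
triangular faces, after which every downstream step is identical in 2D
and 3D.

**Edge features.** Each candidate edge $(i, j)$ carries the centroid
distance $r_{ij}$ (length units of the input; the method is scale
invariant so the units are arbitrary) and the maximum subtended angle
$\Theta_{ij}$ (degrees): over every triangle $(i, j, k)$ of the candidate
graph, the angle at the shared neighbor $k$ between the rays $k\to i$ and
$k\to j$, maximized over $k$. An isolated pair far from everything has a
small $\Theta_{ij}$; a pair whose segment nearly passes through a third
nucleus has $\Theta_{ij}$ near $180^\circ$. The two features target
exactly the two Delaunay failure modes: $r$ catches hull artifacts, and
$\Theta$ catches non-pairwise blocking that no distance cutoff can see.

The shared-neighbor set is restricted to triangles of the triangulation
(in 3D, to tetrahedron *faces* containing the edge) rather than all
nodes. In a triangulated graph these are the cells that genuinely sit
between the pair, and the cost stays linear in the number of edges. This
is a deliberate reading of "shared neighbors": co-membership in a
tetrahedron without a shared face does not contribute.

**Threshold selection.** The critical pair $(r^*, \Theta^*)$ maximizes the
communicability efficiency
$$E(r, \Theta) = F(r, \Theta) - L(r, \Theta),$$
where $F$ is the joint empirical CDF of the edge features (the fraction
of candidate pairs with $r_{ij} \le r$ and $\Theta_{ij} \le \Theta$) and
$$L(r, \Theta) = \frac{1}{2}\left(
  \frac{r - r_{\min}}{r_{\max} - r_{\min}} +
  \frac{\Theta - \Theta_{\min}}{\Theta_{\max} - \Theta_{\min}}\right)$$
is the expected value of $F$ if each feature were uniform over its
observed range — the fraction of edges a tissue with no preferred spatial
organization would retain. $E$ is the excess of actual over "random"
connectivity; it vanishes identically at the joint maxima and its
maximizer connects the most cells at the least cost. An edge is kept iff
$r_{ij} \le r^*$ **and** $\Theta_{ij} \le \Theta^*$ (both closed
inequalities). A one-dimensional variant, $E(r) = F(r) - L(r)$ over
distances only, reproduces classical pairwise thresholding and is kept as
an ablation baseline (`optimize_distance_only()`).

## Assumptions

- Cells are approximately convex and space filling; nuclei lie roughly at
  cell centers. Dendritic or highly stellate cells violate this and the
  Voronoi abstraction with them.
- The centroid coordinates are isotropic. Anisotropic voxel sizes must be
  applied before triangulation (the `spacing` argument of
  `extract_centroids()` / `--spacing` flag): the angle statistic is not
  invariant under anisotropic scaling.
- The tissue has *some* spatial regularity. If the features really were
  uniform on their ranges, $E$ would hover near zero and the selected
  thresholds would be arbitrary.

## Parameters that matter

The inference itself has **no free parameters** — $(r^*, \Theta^*)$ come
from the data. The remaining knobs:

| parameter | where | default | meaning |
|---|---|---|---|
| `theta_bounds` | `loss_mean()`, `optimize_thresholds()` | observed $[\Theta_{\min}, \Theta_{\max}]$ | normalization bounds of the angle term of $L$ |
| `joggle` | `build_candidate_graph()` | 0 | symbolic-perturbation fraction for exactly degenerate inputs |
| `min_size` | `extract_centroids()` | 5 px/vox | discard segmented components smaller than this |
| `jitter` | `generate_tissue()` | 0.1 | displacement radius / lattice spacing of synthetic tissues |

On `theta_bounds`: the limiting argument behind $E$ requires $L = 1$
exactly where $F = 1$, which holds when the angle term is normalized by
the *observed* extrema; that is therefore the default. Normalizing by the
full geometric range $[0^\circ, 180^\circ]$ is a defensible alternative
(pass `theta_bounds = c(0, 180)`) and changes results only when the
observed maximum falls well short of $180^\circ$. Similarly, $F$ is
computed over candidate (Delaunay) edges, not over all $\binom{n}{2}$
pairs: the filter only ever decides among candidate edges, so the ECDF
lives on them.

## Numerical choices

- **Optimization domain.** $F$ is piecewise constant with jumps only at
  observed feature values, and $L$ is strictly increasing between them,
  so the continuous maximum of $E$ is attained on the Cartesian grid of
  observed unique $r$ times observed unique $\Theta$; the optimizer
  searches exactly that grid. Ties are broken toward smaller $r$, then
  smaller $\Theta$ — the stricter graph — making the output
  deterministic.
- **Collapsed ranges.** If all $r$ (or all $\Theta$) coincide, the
  corresponding term of $L$ is defined as 0: no filtering is possible
  along a collapsed axis, so $E = F$ and every edge is kept.
- **Near-duplicate centroids** (closer than $10^{-9}$ of the bounding-box
  diagonal) are rejected with an error, not merged: duplicated nuclei
  indicate an upstream segmentation fault that silent merging would hide.
- **Degenerate configurations.** Collinear/coplanar inputs are rejected
  via an affine-rank check. Exactly cocircular/cospherical configurations
  (perfect square or cubic lattices) have no unique triangulation; the
  result of the underlying routine is accepted, and a documented `joggle`
  option applies a tiny deterministic perturbation when explicit
  tie-breaking is wanted. Test fixtures use jittered lattices, which are
  non-degenerate with probability one.
- **3D triangulation.** 2D triangulations come from the `deldir` package;
  the 3D path is an incremental Bowyer–Watson implementation native to
  this package. Coordinates are affinely rescaled to the unit box (a
  similarity, so the Delaunay complex is unchanged) and inserted inside a
  super-tetrahedron at $3 \times 10^3$ box units — far enough that its
  circumspheres behave as half-spaces at double precision, close enough
  to keep the circumcenter solves well conditioned. In-sphere tests use a
  relative tolerance of $10^{-12}$, and every insertion checks that the
  re-triangulated cavity is a closed ball; a failure (possible only for
  near-degenerate inputs) raises an error pointing at `joggle` rather
  than returning a silently wrong complex. The builder is validated
  against a brute-force empty-circumcircle/circumsphere oracle over all
  point triples/quadruples on random configurations.
- **Angles** are computed from squared side lengths via the law of
  cosines with the cosine clamped to $[-1, 1]$, in degrees throughout.
- **Zero-denominator metrics** (e.g. PPV of an empty prediction) are
  reported as `NaN` with a warning, never as 0: silent zeros would bias
  averages across runs.

## What the synthetic generator does and does not emulate

`generate_tissue()` produces centroids on a hexagonal (2D) or
square/cubic lattice perturbed by uniform-in-disc/ball jitter, or uniform
random points, clipped to a box. Its ground truth is *exact*: two cells
are neighbors iff their Voronoi regions clipped to the box share a facet
of positive measure (length/area tolerance $10^{-8}$/$10^{-7}$ of the box
diagonal, which cleanly excludes the zero-measure corner contacts of
perfect lattices, e.g. square-lattice diagonals). In 2D the clipped
tessellation comes from `deldir`; in 3D each candidate facet is computed
directly by clipping the pair's bisector plane by the box and by the
dominance half-spaces of the other points, nearest first with early
termination — a route deliberately independent of the package's own
triangulation code, which is what makes the "truth edges are a subset of
Delaunay edges" duality check in the test suite meaningful.

Low jitter emulates highly regular epithelia; high jitter and
uniform-random tissues emulate irregular ones. Clipping (rather than
periodic boundaries) keeps boundary cells in play, which is where the
candidate graph errs. The generator does **not** emulate curved
epithelial sheets, strongly anisotropic or elongated cells, nuclei
displaced from cell centers, or segmentation errors — so passing recovery
tests demonstrates correctness of the machinery on the Voronoi
abstraction, not performance on any particular real tissue.
`render_nuclei_image()` adds an optional image front-end — isotropic
Gaussian blobs (sd = radius/2, peak 1) plus Gaussian read noise — which
exercises Otsu thresholding, connected-component labelling
(8-/26-connectivity) and intensity-weighted centroiding end to end, again
without background gradients, PSF asymmetry or brightness variation.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` use: 100 random point sets of
up to 12 points for the brute-force Delaunay oracle (the oracle
enumerates all $\binom{n}{d+1}$ simplices, so it is kept small by
design); 50 random feature tables of 5–50 edges against dense-grid
($500 \times 500$) threshold maximization; 20 uniform-random tissues of
$n = 30$ under 5 random similarity transforms each; 20 seeds of $n = 100$
hexagonal (2D) and cubic (3D) tissues at jitter 0.1 for ground-truth
recovery; and 20 seeds of $n = 30$ irregular 2D tissues for the
joint-versus-distance-only ablation. The ablation uses small irregular
tissues because that is where non-pairwise blocking is most common and
the angle term has the most precision to add; regular tissues saturate
both filters. These sizes give stable means while keeping every check
cheap to re-run.

## Known limitations

- Non-convex and irregularly shaped cells (neurons, dendritic cells) are
  outside the Voronoi abstraction; their contact graphs are not well
  approximated by any filtered Delaunay triangulation of nuclei
  centroids.
- Weighted, regularized or alpha-shape triangulations and periodic
  boundary conditions are not implemented.
- The loss is fixed to the mean-normalized form (and its 1-D distance
  variant); it is the only property of $L$ the method relies on that it
  increases in both arguments, but alternative losses are not exposed.
- The image front-end is a convenience (global Otsu + component
  labelling); it is not a general nuclear segmentation tool and will
  undersegment touching nuclei.
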