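---
title: "Compressive instabilities in discrete fiber networks around contracting cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressive instabilities in discrete fiber networks around contracting cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibernet)
```

## The model

Fibrous extracellular matrix (collagen, fibrin) is remodelled dramatically by
contractile cells: narrow bands of severe densification and fiber alignment
radiate from cells and join neighbouring cells or clusters ("tethers").
`fibernet` implements a two-dimensional discrete model of this process.

The matrix occupies a disk of radius $R$ containing one or two circular
cavities of radius $r_c$ (the cells); all lengths are nondimensionalized by
$r_c$. The domain is triangulated, and **every triangle side is a fiber**:
a nonlinear spring whose state is its *effective stretch*
$\lambda = |\mathbf{x}_i - \mathbf{x}_j| / l_{ij}$, the deformed endpoint
distance over the relaxed length. A fiber with $\lambda < 1$ is interpreted
as buckled; its energy $W(\lambda)$ encodes the post-buckling response
through the force law $S(\lambda) = dW/d\lambda$ (nondimensionalized by a
reference fiber stiffness):

* **Family 1** — $S_{1k}(\lambda) = \lambda^k - 1$, $k \in \{1,3,5,7\}$:
  stiffening in tension, gradual loss of stiffness in compression down to
  the crushing limit, but $dS/d\lambda > 0$ everywhere. This is *stable
  (supercritical)* post-buckling, the traditional picture; $k = 1$ is a
  linear, non-buckling spring.
* **Family 2** — $S_{2k}(\lambda) = \lambda^k - \lambda^{k-2}$,
  $k \in \{5,7\}$: the stiffness changes sign at
  $\lambda^* = \sqrt{(k-2)/k}$ (0.775 for $k=5$, $\approx 0.845$ for
  $k=7$). Below $\lambda^*$ a compressed fiber has negative stiffness and
  is *unstable (subcritical)*: it collapses toward $\lambda = 0$. This
  models the unstable buckling observed in hierarchical beams and single
  collagen fibrils.

The total energy sums fiber energies and an **interpenetration penalty**
per triangle,

$$\hat E = \sum_{j=1}^{F} W(\lambda_j) + \sum_{k=1}^{K} A_k\,\Phi(J_k),
\qquad \Phi(J) = e^{-Q (J - b)},$$

where $J_k$ is the oriented deformed-to-reference area ratio of element
$k$ (piecewise-constant Jacobian determinant of the nodal interpolation),
$A_k$ its reference area, and $Q = 50$, $b = 1/4$ by default. $\Phi$ is
negligible for $J > b$ and enormous for $J < 0$, so it arrests element
inversion — physically, fibers of nonzero thickness resisting being
crushed through one another — while leaving ordinary states unaffected.
Negative $J$ would mean orientation reversal (interpenetration of matter);
a converged solution should contain none, and the package flags any.

Cell contraction is a Dirichlet condition: cavity-boundary nodes move
radially toward their cell center to radius $(1-\gamma) r_c$ and are held
fixed; the outer boundary is free. Equilibria are local minimizers of
$\hat E$ over the free nodal positions.

### Instability mechanisms

The energy is nonconvex even for linear fibers, because fibers rotate
freely (the single-fiber energy is a sombrero: a surface of revolution
with its minimum on the circle $|\mathbf{x}| = l_0$). Two discrete
mechanisms matter:

* **Element collapse (snap-through)**: a triangle compressed through
  $J = 0$ would invert into its mirror image; the unpenalized energy along
  this path is an even two-well curve vanishing at $J = \pm 1$. The
  penalty removes the inverted well; under load the element is bistable,
  with a reference-like and a penalty-stabilized, highly compressed state.
  This occurs in *every* law, including linear.
* **Fiber collapse**: only in Family 2, a fiber compressed below
  $\lambda^*$ collapses; geometry then forces the area of every adjacent
  element toward zero, so fiber collapse implies element collapse (not
  conversely). `elementary_instabilities`-style toys for both mechanisms
  are exported (`single_fiber_energy_surface()`, `triangle_energy_profile()`,
  `bistable_load_response()`) and double as oracles for the network code.

One analytical point the toy system makes precise: with $Q = 50$,
$b = 1/4$, the *unforced* penalized triangle profile is strictly
decreasing on $0 < J < 1$ — both the fiber term and the penalty push
toward $J = 1$ — so the compressed well exists only **under a compressive
load**, and only clearly so for compression-softening laws, whose force
hump (near $J \approx 0.75$) is well separated from the penalty wall
(near $J \approx 0.3$). `bistable_load_response()` exhibits this window;
for the linear law at these penalty parameters the loaded 1-DOF triangle
is monostable.

## Numerical method

Minimization uses Polak–Ribière+ nonlinear conjugate gradient with a
strong-Wolfe line search ($c_1 = 10^{-4}$, $c_2 = 0.1$; bracketing plus
safeguarded quadratic interpolation, with Armijo backtracking as a
fallback), periodic restarts (every $2\times$ the DOF count), and exact
elimination of fixed DOFs. The energy and its exact analytic gradient are
assembled in compiled code. Non-finite trial energies simply shrink the
step; the penalty exponent is clamped at 500 during line-search trials
(never active at convergence — asserted on every result).

Convergence is declared when the root-mean-square gradient over free DOFs
falls below `grad_tol` (default $10^{-6}\, F/N$, a scale-free tolerance in
the dimensionless force unit; forces are $O(1)$). The RMS norm was chosen
over the infinity norm because at these tolerances the latter spends
thousands of iterations polishing individual nodal residuals that change
no reported metric.

Because $\hat E$ is nonconvex, *which* minimum is found is part of the
protocol and is deliberately controlled:

* **Continuation**: contraction is applied in 5% increments, each level
  warm-started from the previous equilibrium. A non-converged level is
  re-approached through up to 3 bisected intermediate levels.
* **Symmetry breaking**: the first level starts from the reference
  configuration plus a seeded uniform perturbation of the free nodes
  (default $10^{-3}\times$ the mean fiber length), mimicking physical
  imperfection so the optimizer can leave saddle points. At desk scale the
  reached equilibria proved remarkably robust: amplitudes from $10^{-3}$
  to $10^{-1}$ and direct (non-continuation) solves from strongly
  perturbed states reach identical energies.

## Mesh generation

Meshes are built from boundary rings (arc spacing $\approx$ the target
edge; at least 8 nodes per cavity, with a deterministic $10^{-10} r_c$
radial perturbation that breaks exact cocircularity for the Delaunay
predicate) plus interior points on a seeded, jittered hexagonal lattice,
triangulated with an internal Bowyer–Watson Delaunay routine and filtered
against the cavities. Two Laplacian smoothing passes (boundary pinned,
re-triangulating between passes) relax the lattice into a well-shaped
quasi-uniform triangulation — bulk minimum triangle angles of 45–58° —
while keeping it unstructured; without smoothing, occasional jitter
slivers collapse prematurely and contaminate the densification extremes
with mesh artifacts. Interior coordination is $\approx 6$, as expected
for a triangulation (real ECM is 3–4; `reduce_connectivity()` prunes
edges uniformly at random — never cavity-boundary fibers, never
disconnecting the network — to reach a target coordination, and keeps the
area penalty of triangles that lose a side: the penalty models excluded
volume of matter, not any specific fiber; `retain_penalty = FALSE`
switches this off).

Defaults (single cell $R = 10\,r_c$, fiber length $0.25\,r_c$, about
5,900 nodes; two cells at separation $s$: $R = s/2 + 5$) were chosen so
the cell is a few fiber lengths across — the regime of single-cell
experiments — and the reported metrics are mesh-converged at desk scale
(halving the edge to 0.30 moves stretch extremes by $\lesssim 0.02$).
The decay study uses $R \in \{5, 10\}$ at edge $0.3\,r_c$ to keep two
domain sizes within a few minutes of compute.

## What the simulations show

```{r single-cell, eval = FALSE}
out <- run_single_cell("2-5", gamma = 0.5, R = 10, target_edge = 0.25,
                       seed = 1)
out$report$rho_max        # ~ 3.2: densified bands
out$report$lambda_min_interior  # ~ 0.26: collapsed fibers
out$onsets                # fiber-collapse onset ~ 0.35
```

Family-2 single-cell runs at 50% contraction develop localized densified
bands (densification ratio $\varrho = 1/J \approx 3$) reaching several
deformed cell radii into the matrix, with collapsed fibers inside;
Family-1 runs stay moderate ($\varrho \lesssim 2$) with no fiber
collapse. Sweeps show the two onsets distinctly: $\lambda_\min$ departs
from the boundary-imposed line $\lambda_\min = 1 - \gamma$ at the
fiber-collapse onset (Family 2 only), while $1/\varrho_{\max} = J_\min$
shows a sudden drop at element collapse (all laws; $\gamma \approx 55\%$
for the linear law at this resolution). Displacement decay powers
$u_r \propto A r^{-n}$ fitted over free nodes in $r \in [1.2, 0.9R]$
(log–log least squares, inward displacements above $10^{-8}$) come out
well below the 2D linear-elastic $n = 1$ for every law. Two-cell runs
form connected $\varrho \ge 2$ tethers between the cavities — early for
Family 2, only at extreme contraction (if at all) for the linear law.

### Post-processing conventions

* $\varrho = 1/J$ per element; extremes reported with and without
  elements/fibers on a cavity boundary. A fiber is "on the cell boundary"
  iff **both** endpoints are cavity-boundary nodes.
* Bands and tethers are connected components (edge adjacency of
  triangles) of elements with $\varrho \ge$ a threshold, default 2 —
  separating densified ($\varrho \approx 3$) from background; the
  verdicts are insensitive to thresholds in 1.8–2.5 at desk scale, and
  the threshold is a parameter everywhere. A *tether* is a single
  component containing elements incident to each cavity. Band reach is
  measured in deformed cell radii $(1-\gamma) r_c$.
* Fiber-collapse onset: first level with
  $\lambda_\min < (1-\gamma) - \delta$, $\delta = 0.1$ — large enough to
  clear mesh noise, far below the collapse drop ($\approx 0.3$).
  Element-collapse onset: first level where $J_\min$ drops by a factor
  $\ge 1.5$ between consecutive 5% levels.
* Orientation histograms bin acute fiber angles (to the radial or
  two-cell-axis direction) in 10° bins, split by tension vs compression.

## Known limitations

* The model is two-dimensional, elastic and quasi-static: no
  viscoelasticity, crosslink plasticity, fiber merger, or filopodial
  activity. Densification is fully reversible on unloading.
* The synthetic meshes are quasi-uniform and nearly homogeneous. Real ECM
  has coordination 3–4, heterogeneous fiber lengths and radii;
  `reduce_connectivity()` captures only the first of these. Passing tests
  therefore validate the model's mechanics, not quantitative agreement
  with any particular gel.
* Extreme-value summaries ($\lambda_\min$, $\varrho_{\max}$) are tail
  statistics carried by a handful of collapsed elements. They are
  internally consistent — an element at $J \approx 1/3$ ($\varrho
  \approx 3$) geometrically forces its compressed side to
  $\lambda \approx 0.25$–0.30 — but more sensitive to resolution and
  disorder than bulk quantiles (the 0.1% stretch quantile is
  $\approx 0.72$ for Family-1 $k=5$ and $\approx 0.32$ for Family-2
  $k=5$ at 50% contraction, both notably above the true minima).
* Tether formation at desk-scale resolution lags fiber-collapse onset by
  one to three 5% contraction steps: the densified chain between two
  cells completes only once bands from both cells join. Finer meshes
  narrow but do not close this gap in our experiments.
* The minimizer returns local minima by design; results are
  path-dependent through the continuation schedule and seeds, and
  reproducible bit-for-bit given identical configuration.
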