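---
title: "Fiber walks: tip-driven growth with lateral expansion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fiber walks: tip-driven growth with lateral expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberwalk)
```

## The model

Tip-driven growth — root tips, fungal hyphae, pollen tubes — elongates at a
moving apex while the tissue behind the tip thickens.  Models that treat the
two processes separately (grow a path first, inflate it afterwards) produce
boundaries with curvature singularities and, for thick enough inflation,
self-intersections.  The fiber walk couples them: it is a growing
self-avoiding random walk on the d-dimensional unit hypercubic lattice in
which **every elongation step also contracts the lattice laterally around the
new tip**, absorbing the sideways neighbours into the tip vertex.  The
contracted region is the space the fiber claims for its expansion; it feeds
back on the walk because the inherited, contracted edges change what the next
steps can reach.

Two processes are provided:

* `"growing_saw"` — the plain kinetic growth walk: at each step the walk
  chooses uniformly among the tip's edges whose far endpoint has not been
  visited (Lyklema's growing self-avoiding walk).  No contraction.
* `"fiber_walk"` — the same elongation rule, but each step is followed by a
  lateral contraction at the new tip.

Both stop in a *stopping configuration*: a tip whose incident edges all lead
to fiber vertices (they are then *self-avoiding edges* — lattice edges joining
two fiber vertices without belonging to the fiber).

## Contraction: lateral selection, merges, label algebra

Every lattice edge is bi-directed and carries a direction label in
$\{-1,0,1\}^d$ per direction; on the uncontracted lattice the label is the
unit difference vector of the endpoint positions, and the reverse label is
always the entrywise negation.  After a step with incoming growth label $g$,
the edges *incident from the side* are the outgoing, non-self-avoiding tip
edges whose label

1. has no entry opposite in sign to a nonzero entry of $g$, and
2. differs from $g$.

Their far endpoints are merged into the tip, in label-lexicographic order
(merges on the uncontracted neighbourhood commute; the fixed order makes runs
reproducible).  A merge discards the merge edge and re-attaches every other
edge of the absorbed vertex to the tip, recomputing

* the label, entrywise as $\mathrm{sign}(m_k + \ell_k)$, where $m$ is the
  merge-edge label and $\ell$ the inherited-edge label — the unique elementary
  rule that keeps every entry in $\{-1,0,1\}$ and reproduces the worked merge
  geometry;
* the Euclidean length from the (unchanged) endpoint positions; and
* the contraction count, incremented by one relative to the source edge.

When re-attachment would duplicate an existing tip edge, a single edge is
kept with the larger contraction count, self-avoiding if either was (the
lattice stays a simple graph).  Because every inherited edge has the
absorbing tip as one endpoint, any contracted edge incident to a *later* tip
leads to a fiber vertex and is therefore self-avoiding; selected lateral
edges are consequently always unit edges, which bounds the merges per step by
$2(d-1)$ and yields the 2D edge-length classes by direct case analysis:
fiber steps have lengths $\{1, \sqrt2, 2\}$ and self-avoiding edges
$\{1, \sqrt2, 2, \sqrt5, 3\}$.  `edge_length_histogram()` tallies both over
ensembles; the test suite asserts the bounds and that each class is attained.

```{r first-step}
w <- walk_state(2, "fiber_walk")
force_step(w, c(1, 0))     # deterministic step for illustration
merge_counts(w)            # the two side vertices merged into the tip
feasible_edges(w)[, c("x1", "x2", "length", "contraction_count")]
```

The seven follow-up candidates of lengths $1$, $\sqrt2$ and $2$ are the
contracted-lattice geometry the theory predicts.

## The lattice is infinite; the implementation is lazy

Vertices and their unit edges are materialized the first time the walk
touches them; before a vertex is absorbed, its full unit neighbourhood is
materialized so inheritance always sees the complete original neighbourhood.
Positions never move — a merged vertex's original integer position is
recorded on the absorbing vertex (`merged_from`), which is what the boundary
reconstruction uses.  Laziness is observationally transparent: a walk on a
pre-materialized window replays to the identical event log.

Every step writes an undo record (sizes of the vertex/edge stores, copies of
modified records, coordinate-map changes), so `undo_step()` restores the
previous state bit-exactly — the basis of both backtracking restarts and the
serialization tests.

## Boundary reconstruction in 2D

The expansion boundary separates the claimed region — fiber vertices plus all
merged-in positions — from the rest of the plane.  The construction works on
the unit faces of the embedding:

* faces with one or two adjacent claimed corners are crossed by the polyline
  through their centroid, the **dual point** of the face;
* a face with three claimed corners is cut by a chord in front of its
  unclaimed corner (its centroid lies inside the claimed region);
* a face with two *diagonally* claimed corners is a saddle and is resolved as
  connected — both corners belong to the same fiber, and the disconnected
  resolution would make the polyline touch itself at the centroid, violating
  simplicity.

Crossing points sit on the unit edges with exactly one claimed endpoint, at
the **intermediate-lattice offset** from the claimed end: for an edge of
length $L$ created by $c$ contractions the offset is $L / (2(c+1))$, i.e. the
half-edge distance on unit edges, and an absolute $0.5$ lattice units on the
axis-aligned contracted edges (lengths 2 and 3).  On a length-3 self-avoiding
edge the two intermediate vertices leave a central gap of width 2 — the room
a future fiber plus its expansion would need.  `build_intermediate_lattice()`
exposes the intermediate vertices themselves; for the polyline the offset is
applied to the first covered unit edge (clamped to it), which keeps every
crossing on the face skeleton and the traversal well-defined.  Each crossing
is shared by exactly two faces, so the arcs glue into disjoint simple loops
without any general polygon clipper; the outer loop is the boundary and
enclosed inner loops are reported as pockets.

Consequences, all property-tested: the polyline is closed and simple, the
fiber and all merged-in vertices lie strictly inside, and the enclosed area
is non-decreasing as the walk grows.  At right-angle turns of the fiber the
inner side is either covered by claimed area (the contraction absorbed it) or
receives a boundary vertex, so the boundary has no curvature singularity at
turns; `check_right_angle_avoidance()` reports this per turn.
`smooth_boundary()` applies corner-cutting (Chaikin) subdivision — the
quadratic B-spline refinement — purely cosmetically.

The boundary is defined in 2D only; 3D/4D walks simulate fine but have no
boundary surface here.

## Ensemble statistics and their estimation choices

**Stopping times.** `stopping_time_ensemble()` runs walks to their natural
stopping configuration (or a cap, recorded as censored; censored walks enter
the empirical CDF at the cap).  The median is the smallest length at which
half the walks have terminated.  Under the defaults (2D, max 300 steps) the
growing SAW's median is 59 with mean trapping length ≈ 71, in line with the
classical trapping analysis of the kinetic growth walk (Hemmer & Hemmer
1984); the fiber walk's median is 27 — expansion inhibits elongation, and the
two distributions separate decisively under a two-sample Kolmogorov–Smirnov
test at any practical ensemble size.

**MSD scaling.** The mean squared Euclidean displacement from the origin
position to the tip position per step is averaged over walks driven to a
fixed length (default 1,000 walks × 200 steps) with restarts, and the scaling
exponent $\nu$ is half the least-squares log–log slope in the scaling region,
so the ordinary diffusive walk is the $\nu = 1/2$ anchor
(`simulate_simple_walk()` recovers it within its bootstrap CI).  The scaling
region is the maximal suffix, from step 30 onwards, over which windowed local
slopes stay within 0.1 of the terminal slope.  Local slopes use 5-point
windows over **log-spaced** sample points: with linearly spaced windows the
window's extent in $\log s$ shrinks like $1/s$, and at $s \approx 200$ the
local slope of a Monte-Carlo curve is dominated by noise (in practice the
detected region then collapses to the last few steps).  Standard errors come
from bootstrap resampling of walks (default 1,000 replicates).

**Restarts.** Walks trapped before the target length are backtracked: the
last step (including its merges) is undone via the event log, the undone
choice is excluded at that depth, and the step is resampled — a depth-first
search with per-depth exclusion sets.  When a fiber walk seals itself into a
pocket smaller than its remaining step budget, proving the pocket unusable is
exponential, so ensembles cap backtracks per walk (default 20,000) and
resample a fresh walk when the cap is hit (counted and reported).  A
`"rejection"` policy (discard and restart) is available as a sensitivity
check.  Stopping-time ensembles and scaling ensembles are strictly separate
code paths, since restarts override natural stopping.

**Contraction scaling.** The log–log slope of the mean cumulative merge count
against the step count, on the same region rule; the slope is reported raw
(a constant-merges-per-step process has exponent 1).  We obtain ≈ 0.99 in 2D
and ≈ 0.99 in 3D/4D: merges per step decline slightly as the walk crowds its
own expansion, so the exponent cannot exceed 1 under this counting.

```{r msd, eval = FALSE}
m <- msd_curve(2, "fiber_walk", n_walks = 1000, max_steps = 200, seed = 1)
fit_exponent(m)
#> <fw_scaling_fit> slope 1.225 (nu = 0.613 +/- 0.011) on steps [30, 200]
```

## Problem sizes

Defaults reproduce the study conditions: stopping times use ensembles of
10,000–100,000 walks capped at 300 steps (the acceptance script uses 20,000);
scaling runs use 1,000 walks of length 200 in dimensions 2–4.  The test suite
scales some property sweeps down (e.g. 100 boundary checks at 40 steps,
exhaustive enumeration of all 780 six-step growing-SAW configurations for the
chi-square comparison) — sizes chosen so each check retains its statistical
power.

## What the simulations do and do not show

The generator *is* the model: there is no external data, so passing tests
demonstrate internal consistency (theorems, invariants, distributional
agreement with exhaustive enumeration) and reproducibility of the ensemble
statistics under the stated protocols.  They do not validate the fiber walk
against measured root geometry.  Known limitations:

* At 200 steps the 2D processes are still crossing over; the fitted 2D
  exponents (fiber ≈ 0.59–0.62, growing SAW ≈ 0.55–0.60 across seeds) sit
  above the asymptotic regime and depend mildly on the ensemble seed — the
  bootstrap SE (~0.01) understates seed-to-seed spread.
* The label-recalculation rule is the sign-of-sum reconstruction isolated
  behind `combine_label_entries()`; any alternative elementary rule can be
  swapped in there.
* One fiber per lattice; no branching, no interacting fibers, no biased step
  probabilities.
* Whether a fiber may traverse an inherited (contracted) edge is not
  restricted beyond non-self-avoidance; sensitivity to this reading is
  visible only in the tail of the stopping-time distribution.
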