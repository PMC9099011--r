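---
title: "Planning cortico-tumoral trajectories: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning cortico-tumoral trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CorticoPath)
```

CorticoPath plans transcortical access corridors to deep brain lesions
on a labeled voxel volume in two stages: an exhaustive screening of
straight entry-window-to-tumor corridors, followed by tabular
Q-learning on a 26-neighbor voxel graph that can bend the trajectory
around critical anatomy. This vignette explains the underlying models,
the parameters that matter, the numerical conventions, and what the
synthetic phantom does and does not establish about behavior on real
data.

## The planning space

A `VoxelVolume` is a rows x columns x slices scalar grid with
millimetre spacing; coordinates are 1-based `(row, col, slice)` triples
throughout the package, the natural R convention (serialized
trajectories record `"indexing": "1-based"` so downstream consumers are
not left guessing). A paired `LabelMap` assigns each voxel a structure
id from a `StructureCatalog`: arteries, veins, sinuses, tracts,
eloquent cortex and deep nuclei each carry a non-negative penalty, and
exactly one structure — the tumor — is the goal. Published anatomical
tables name the avoid-structures but put no numbers on them, so the
shipped default catalog expresses the usual clinical hierarchy
(arteries and dural sinuses 100, tracts and eloquent cortex 80, deep
nuclei 60, superficial veins 40, in penalty units per touched voxel)
and is fully overridable through a JSON catalog file.

Extracranial air never counts: scoring and the Stage-2 environment are
restricted to a head mask, either supplied explicitly or derived as the
largest 26-connected component above an Otsu threshold, closed with a
3x3x3 element.

## Stage 1: exhaustive linear screening

Each of the six volume faces is tiled with n x n windows at unit
stride. The offset convention runs u from 1 to U-n (one less than full
containment would allow) on each in-face axis; with it, the closed form
`2(X-n)(Y-n) + 2(X-n)(Z-n) + 2(Y-n)(Z-n)` reproduces the reference
case-study counts for all four studied cell dimensions exactly
(745,984 / 675,840 / 641,920 / 544,768 on 512 x 512 x 144), which is
why the package treats it as the implied convention.

Every window's face-center voxel is joined to the tumor voxel nearest
it, so corridors stop at the proximal tumor boundary rather than at a
single fixed seed point; ties break to the lexicographically smallest
voxel. The segment between the two voxel centers is voxelized by
parametric boundary-crossing traversal. When the segment passes exactly
through a corner or edge, all tied axes advance together: the
corner-touched side voxels have zero chord length inside the segment
and are not part of the voxelization. The test suite checks the
traversal against an exact brute-force oracle that intersects the
segment's parameter interval with every candidate voxel's axis slabs; a
fixed-step dense sampler is also kept for short segments. A sampling
oracle alone is not sufficient at scale: about one random 32-voxel
segment in twenty passes through a voxel with a chord shorter than a
1e-3-of-length step, which a sampler misses by construction.

The corridor is the union, over center-line voxels, of the n x n
axis-aligned window parallel to the entry face (`corridorShape =
"prism"`), or the in-face disc of radius n/2 (`"cylinder"`), clipped to
the volume and deduplicated. Its penalty is the sum over in-mask
corridor voxels of the touched structure's penalty — per voxel, not per
structure, so long traversals of a tract cost proportionally more than
a clean crossing. Tumor voxels and background contribute nothing.

Scoring all windows at full corridor resolution would be wasteful, so
the reduction runs in four score-then-keep passes. The published
procedure fixes four stages and the keep-sizes 80/40/20 from the second
stage on but not each stage's criterion; this implementation uses
sampling density as the funnel: stride 8 over the center line, stride
2, the full center line, then the full swept corridor, with a
configurable first keep-size defaulting to 400. Ties break by shorter
center line, then by (face, u, v); every pass and the final list use
the same ordering, making the output bit-reproducible. With all four
passes set to full-corridor scoring (`stageSampling = c(0, 0, 0, 0)`)
the funnel is provably equivalent to exhaustive global top-k selection,
and the suite verifies this on a 16^3 instance.

The `entryAreaCm2` parameter (default 1.5 cm^2, the usual keyhole
aperture) converts to a cell dimension via
`round(sqrt(area) / in-plane spacing)` for workflows that think in
apertures rather than voxels.

## Stage 2: Q-learning on the voxel-node graph

The agent state is a voxel; the 26 actions are the unit offsets to the
8 in-plane neighbors plus 9 in each adjacent slice, indexed
lexicographically over (dr, dc, ds) — an enumeration shared by the
table, the trainer, the walkers and the oracle. A stay-in-place action
is excluded: under a negative step cost it can never help.

How Stage-1 output becomes the environment depends on corridor width.
Narrow corridors (n below `modeThreshold`, default 40) are too thin to
search inside, so their entry points become start states and the whole
in-head voxel set becomes the node set; wide corridors become the node
set themselves. A mixed list gives the corridor-union node set with
every path's entry center as a start. Entry centers sit on the volume
faces — outside the head — so starts are snapped to the nearest
admissible node, effectively projecting the face window onto the scalp.

Rewards accrue on entering a node: +`goalReward` (default 100,
terminal) for tumor voxels, -penalty x `penaltyScale` for labeled
structures (terminal by default — an episode that touches a vessel is
over, matching the clinical reading that such a trajectory is simply
invalid; set `terminalOnHit = FALSE` to model graded harm instead), and
`stepCost = -1` for every other node, the unit charge that makes
shorter paths preferable. The update is the standard
temporal-difference rule
`Q(s,a) += alpha * (r + gamma * max Q(s',.) - Q(s,a))` with
`maxFuture = 0` at terminal destinations.

Defaults, chosen once and used everywhere:

* `alpha = 0.8`. Transitions on the voxel grid are deterministic, so
  each update is close to an exact Bellman backup and a high learning
  rate mainly accelerates propagation; there is no sampling noise to
  average away.
* `gamma = 0.99`. With goal +100 and step cost -1, the discounted value
  of reaching the tumor stays positive for entries up to roughly 60
  moves deep — realistic scalp-to-tumor distances — so trained values
  point toward the tumor rather than toward endless wandering. (The
  corridor micro-world keeps its own gamma = 0.9 for closed-form
  metadata, and any gamma may be passed explicitly.)
* `epsilon = 0.1`, with optional linear decay via `epsilonEnd`. For
  oracle-exact convergence of the greedy policy from *every* start we
  recommend — and the acceptance suite uses — annealing from 1 to 0.05:
  with a constant small epsilon the greedy policy can lock onto a
  one-move-longer route from a few starts and stay there for hundreds
  of thousands of episodes, because the better action's chain is never
  explored once values turn positive.
* `episodes = 500000`, the reference training budget; tests and
  examples scale this down (the suites use 10,000-100,000 episodes on
  worlds of 1,000-400,000 nodes, sizes chosen to keep the default test
  run fast while leaving convergence margins).
* `maxSteps` defaults to 4x the Chebyshev diagonal of the bounding box
  — generous relative to any optimal path, small enough that lost
  episodes end quickly.
* Start policy `"starts"` draws uniformly from the Stage-1 entry
  states (the pipeline behavior); `"uniform"` draws from all nodes for
  random-onset exploration of the whole head.

Greedy extraction walks the argmax action (ties to the lowest action
index) until a terminal node; revisiting a node aborts with a cycle
diagnosis and a node without admissible actions aborts as a dead end —
both mark an undertrained table rather than looping forever.
`rankStarts()` orders the start states by greedy discounted return with
failed extractions flagged and placed last. The pipeline accepts only
trajectories whose final voxel is positive-reward terminal: a greedy
walk that ends in a vein is reported as a failure, not as a plan.

`valueIterationOracle()` computes Bellman-optimal values under the
identical semantics by synchronous sweeps to a sup-norm change below
1e-10, and extracts greedy paths with the same tie-break. It exists as
the independent correctness reference: on corridor micro-worlds the
trained greedy return must match it to 1e-6.

## The phantom, and what the tests do and do not show

`generatePhantom()` builds an ellipsoidal head (semi-axes 0.42 x dims)
containing a spherical tumor slightly lateral of center (radius 0.08 x
min dim), vessel-like tubes (Catmull-Rom polylines through random
in-head waypoints, dilated to radius 2) alternating artery/vein labels,
and tract-like oblique sheets (thickness 3), with class-mean
intensities (air 0, tissue 400, tumor 700, vessel 800, tract 500) plus
Gaussian noise (sd 20) — enough contrast for Otsu head-masking to be
trivial. Every structure draws from its own child seed, so adding a
structure type never perturbs the others, and the whole phantom is a
pure function of its spec.

The phantom emulates the *geometry* of labeled anatomy, not MR physics:
no bias fields, no partial-volume effects, no realistic vessel trees or
fiber geometry, and structures are disjoint by construction. Passing
tests therefore demonstrate that the planner's combinatorics, scoring,
environment construction and learning behave exactly as specified on
head-like labeled volumes — they do not validate clinical utility,
label accuracy, or robustness to annotation noise on patient scans.

One geometric caveat surfaced by testing: tract sheets span the entire
head cross-section, so on very small phantoms a sheet can separate
every thin corridor from the tumor; with terminal structure contact the
goal is then genuinely unreachable and value iteration confirms that
"wander forever" (value -1/(1-gamma)) is optimal. This is correct
planner behavior on an over-dense phantom, and the reason small
pipeline fixtures use vessels-only phantoms.

`generateCorridorWorld()` is the analytic counterpart: a hazard-walled
straight corridor with a single far-face goal whose optimal return per
start is a closed-form geometric series over the Chebyshev-optimal move
count, recorded in metadata independently of any value-iteration run.
With width > 1 multiple optimal paths exist and the metadata flags the
tie; with hazard penalty 0 the walls become ordinary step-cost nodes.

## File formats and numerical conventions

DICOM support covers what this planner consumes: single-frame,
uncompressed little-endian (implicit or explicit VR) series, one axial
slice per file, 16-bit monochrome pixels, sorted by image position
projected on the slice normal with instance number as fallback;
duplicate positions are an error, not a guess. The writer emits
explicit-VR MR Image files with fresh instance identifiers (intensities
clipped to [0, 32767]), and the suite cross-checks both directions
against an independent DICOM implementation. NIfTI volumes are
first-class citizens for the same data. Polygon annotations follow the
labelme layout — points are (x, y) = (col, row) and are transposed on
read — and are filled under the even-odd rule testing pixel centers at
half-integer coordinates, boundary-touching centers excluded;
overlapping polygons resolve to the higher-penalty structure (ties to
the higher id), the conservative choice for safety scoring.

Determinism is treated as a feature throughout: enumeration order,
funnel tie-breaks, snapping tie-breaks, the action enumeration and the
single seeded RNG stream make identical configurations reproduce
byte-identical trajectory files.

## Known limitations

Stage-1 cross-sections are face-parallel, not oblique; there is no
multi-sequence fusion or registration, so annotations must live in the
planning volume's frame; a single tumor target is assumed; the Q-table
is dense over admissible nodes, which is comfortable up to a few
hundred thousand nodes but not designed for full-resolution
whole-volume environments at sub-millimetre spacing; and penalty
magnitudes, while overridable, have no calibrated clinical meaning —
only their ordering is anchored.
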