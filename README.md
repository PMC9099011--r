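# CorticoPath

Two-stage surgical trajectory planning on labeled 3D MR volumes.

Keyhole and transcortical approaches to deep brain tumors must thread a
corridor from a small scalp entry to the lesion while sparing arteries,
veins, dural sinuses, white-matter tracts, eloquent cortex and deep
nuclei. CorticoPath plans such corridors on a labeled T1 voxel volume
(DICOM series or NIfTI, with labelme-style polygon annotations) in two
stages, for neurosurgical planning research and for benchmarking
reinforcement-learning path planners on anatomical grids.

## Method

**Stage 1 — exhaustive linear screening.** Every face of the volume is
tiled with n x n entry windows at unit stride (u in [1, U-n],
v in [1, V-n] on each face), giving

```
N(n) = 2 (X-n)(Y-n) + 2 (X-n)(Z-n) + 2 (Y-n)(Z-n)
```

candidate windows. Each window's center is connected to the nearest
tumor-surface voxel by a 26-connected voxelized segment; the swept n x n
prism (or cylinder) around that line is scored by summing, per voxel,
the penalty of any labeled structure it touches (extracranial voxels and
tumor voxels score 0). A four-pass funnel — line sampled at every 8th
voxel, every 2nd voxel, every voxel, then the full corridor — keeps
400 / 80 / 40 / 20 candidates, sorted by ascending penalty.

**Stage 2 — tabular Q-learning.** The surviving paths define a
26-neighbor voxel-node environment: narrow paths (n below the mode
threshold, default 40) contribute their entry points as start states
over the whole head mask, wide paths contribute their corridors as the
node set. Entering the tumor yields +100 and ends the episode, entering
a penalized structure yields its negative penalty (terminal by default),
any other node costs -1. The table is trained with the standard update

```
Q(s,a) <- Q(s,a) + alpha * ( r + gamma * max_a' Q(s',a') - Q(s,a) )
```

under an epsilon-greedy policy, and the best nonlinear cortico-tumoral
path is read out greedily per start. A value-iteration oracle with the
same reward semantics verifies trained policies in the test suite.

A seeded synthetic head phantom (ellipsoidal head, spherical tumor,
tubular vessels, sheet-like tracts) makes every stage testable without
patient data.

## Worked example

```r
library(CorticoPath)

ph    <- generatePhantom(phantomSpec(dims = c(64, 64, 32), seed = 1))
goal  <- goalRegion(ph$labels, ph$catalog)
windows <- enumerateEntryWindows(dim(ph$labels), n = 4)
nrow(windows)
#> [1] 13920

cfg   <- plannerConfig(cellDims = 4, stageSizes = c(200, 80, 40, 20))
paths <- stagedReduction(windows, goal, ph$labels, ph$catalog,
                         ph$headMask, cfg)
paths[[1]]
#> LinearPath n=4 face=z_max (u=50, v=34): 16 center-line voxels,
#>   256 corridor voxels, penalty 920

env <- buildEnvironment(paths, ph$labels, ph$catalog, ph$headMask, cfg)
env
#> QEnvironment 64 x 64 x 32: 40608 nodes, 12483 terminal, 20 start state(s)

qc <- qConfig(episodes = 20000L, epsilon = 1, epsilonEnd = 0.05, seed = 1L)
tr <- train(env, qc)
rk <- rankStarts(tr$qtable, env, gamma = qc@gamma)
best <- extractBestPath(tr$qtable, env, unlist(rk[1, 1:3]), gamma = qc@gamma)
best
#> TrajectoryResult: 13 voxels from (49, 35, 27), return 79.0677, cause 'terminal'
```

The 13,920 candidates are the unit-stride 4x4 windows over the six
faces of the 64x64x32 phantom. The best linear corridor enters through
the top face and accumulates penalty 920 from the structures it grazes.
After training, the top-ranked entry reaches the tumor in 12 moves with
discounted return 79.07 (every traversed voxel is unlabeled tissue; the
terminal voxel is tumor). `runPipeline()` wraps these steps and writes
the per-dimension path lists, ranked starts, best trajectory JSON and a
NIfTI overlay into a run directory; `inst/cli/corticopath.R` exposes the
same as a command line.

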