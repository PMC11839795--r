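---
title: "Planning surgical corridors on voxel risk maps with tabular Q-learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning surgical corridors on voxel risk maps with tabular Q-learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpath)
```

## The problem

Choosing a surgical approach to a deep brain target — for example the
mediobasal temporal region, reached through corridors such as the
transsylvian or the supracerebellar-transtentorial approach — means
trading off which structures the corridor traverses. `qpath` formalizes
the comparison: each anatomical segment of a parcellated volume carries a
penalty score in $[0, 1]$ (0 risk-free, 1 penalized), every voxel inherits
the score of its segment, and a corridor is judged by the arithmetic sum
of the voxel penalties it touches. Hand-drawn straight pathways are scored
directly; in addition, a tabular Q-learning agent searches the voxel
adjacency graph for a *nonlinear* corridor of minimum total penalty from a
clinician-chosen surface entry voxel to the target region. Approaches are
then ranked by the Q-learning score — lowest is best.

## The risk field

`assign_risk()` maps a labeled volume plus a segment/score table to a
per-voxel penalty field. Two combination rules exist for multi-modality
layers (parcellation, vascular, tract fields) and `fuse_layers()` offers
both: the default `max` keeps the highest penalty at each voxel, which
preserves the $[0,1]$ range and the reading "1 marks a structure that must
be penalized"; `sum_clipped` adds layers and clips at 1. Per-voxel fusion
and per-path totalling are kept distinct on purpose: path totals are
always plain sums over member voxels, whatever the fusion rule.

Unscored segments are a hard error unless the caller passes an explicit
`default`; silently treating unscored anatomy as risk-free would bias
every comparison. Segment names are matched after trimming, whitespace
squeezing and case-folding, because hand-maintained score tables are
typographically irregular; duplicate names with conflicting scores are
rejected at load time with the offending name, and the shipped example
table (`inst/extdata/example_risk_table.csv`) keeps one value per name.

## Hand-drawn pathways as cylinders

`voxelize_cylinder()` rasterizes the straight segment between two mm
points as the set of voxels whose *centers* lie within `diameter_mm / 2`
of the closed segment (flat caps, inclusive boundary), with distances
computed in mm so anisotropic grids are handled. Center-distance
membership — rather than partial-volume overlap — matches how a segment
editor paints a tube and is exactly testable: the suite checks masks
against an independent all-voxel point-to-segment distance oracle, and the
reference case (4 mm diameter along a grid axis at 0.8 mm isotropic
spacing) keeps exactly 21 voxels per transverse slice, the 5×5
neighborhood minus its four corners. The 4 mm (0.4 cm) default is the
conventional drawn-pathway diameter. Each voxel counts once in a total
even where a corridor overlaps itself, because the scored object is a set
of coordinates. Curved hand-drawn corridors enter as binary NRRD masks
instead; nonlinear paths are the planner's job.

## The Q-learning planner

The Q-table is indexed by *(voxel, adjacent voxel)* pairs rather than
(state, action) pairs: under the configured connectivity (26-neighbor by
default, 6 selectable) each ordered adjacent pair holds a value, and every
other pair reads the sentinel $-1$, meaning "no transition". At
initialization admissible entries are drawn uniformly from $[0, 1)$ using
the configured seed.

Updates use the temporal-difference rule

$$Q(S,A) \leftarrow Q(S,A) + \alpha \left[ R + \gamma \min_{A'} Q(S',A') - Q(S,A) \right]$$

in its *penalty-minimizing* form: the per-step penalty is
$R = \text{step\_cost} + \text{risk}(S')$, the backup takes the minimum
finite successor value, greedy action selection takes the argmin, and the
target region is absorbing (`goal_terminal`, backup value 0). This is the
classic argmax formulation applied to negated rewards; it keeps all
Q-values non-negative and makes "lower score = better corridor" hold
throughout, consistent with ranking approaches by their *lowest* total
Q-value.

Design choices where the formulation is genuinely open:

* **Per-step penalty.** Node risk alone makes every zero-risk path
  equally good regardless of length (and the optimum non-unique). The
  default `step_cost = 0.01` per move breaks plateaus in favor of shorter
  corridors while staying small against segment scores of 0.1–1.0.
  Optionally `scale_diagonal` multiplies the step cost by the move's mm
  length, penalizing diagonal moves proportionally; by default the cost is
  purely risk-based.
* **Learning rate.** `alpha = 1` by default: on a voxel grid both the
  transition and the penalty are deterministic, so the full-overwrite
  update is exact asynchronous value iteration and converges to the exact
  optimal cost-to-go; fractional `alpha` merely slows convergence here
  (it matters only for stochastic environments).
* **Discount.** `gamma = 1` by default so that the learned values are
  undiscounted total penalties — the same objective the reports sum and
  the same objective the Dijkstra oracle minimizes. Termination is
  guaranteed by the absorbing target and the per-episode step cap
  (`4 * sum(dims)` by default).
* **Exploration.** $\varepsilon$-greedy with geometric decay (1.0 toward
  0.05, factor 0.995/episode). Because the table is initialized in
  $[0, 1)$ while converged values on low-risk plateaus are of order
  0.01–0.1, unvisited moves tend to look *expensive* rather than
  optimistic, and only persistent exploration can reveal a shortcut. For
  oracle-equivalence validation the suite therefore raises
  `epsilon_min` to 0.5 and widens the stability window — with a large
  `episodes_max` this reliably reaches the exact optimum on the grid sizes
  tested.
* **Early stopping.** Training stops once the greedy entry-to-target path
  is unchanged for `stable_episodes` consecutive episodes (or at
  `episodes_max`). The per-episode greedy cost is kept in the result
  (`greedy_costs`) for convergence inspection.
* **Q-score reading.** "Summing the Q-values of the nodes on the output
  path" is ambiguous when the table stores pair values: a node has no
  single Q-value. `q_score()` sums the traversed *transition* entries
  $q(\text{node}_i, \text{node}_{i+1})$; a single-voxel path scores 0.
* **Barriers.** Optionally `barrier_threshold` removes voxels at or above
  a risk level from the graph entirely. Off by default: the base model
  penalizes risky structures rather than forbidding them, and both
  readings stay available.
* **Determinism.** A single seeded generator drives initialization and
  exploration, so a fixed seed makes the entire pipeline — including the
  CLI — byte-reproducible, which is how the "no randomness in the
  outcome" property is operationalized and tested.
* **Tie-breaking.** Everywhere lexicographic in $(i, j, k)$: neighbor
  offsets are enumerated in lexicographic order, argmin takes the first
  minimum, and the oracle reconstructs the lexicographically smallest
  optimal path.

The planner reports, per run: the extracted `voxel_path`, `q_score`, the
`qr_score` (arithmetic sum of per-voxel risk over the path, by exactly the
same `path_total_risk()` that scores hand masks), and the `penalty_cost`
(the objective value, directly comparable with the oracle).

## The Dijkstra oracle

`dijkstra_oracle()` computes the exact minimum of
$\sum(\text{step\_cost} + \text{risk}(v))$ by shortest-path distances on
the same adjacency graph (edge $u \to v$ weighted
$\text{step\_cost} \cdot m + \text{risk}(v)$, a zero-weight edge from each
target voxel to a virtual sink), using igraph for the distance
computation and a deterministic lexicographic walk for path
reconstruction. It is the independent yardstick in the test suite — the
planner is validated against it, never implemented by it. Equality is
asserted on *cost*, not on the path, to tolerate ties.

## The synthetic phantom

`generate_phantom()` emulates the *product* of atlas-based parcellation,
not the process: background regions are 3D Voronoi cells of seeded points
(label-complete and cheap — the pipeline only needs named labels with
scores, not anatomy), tubes stand in for vessels/tracts as all voxels
within a fixed radius of a random polyline (score 1.0), and optional
corridors paint a dedicated low-risk channel (score ≤ 0.1) along a
boundary-entry-to-interior-target segment plus a distinct zero-score
target ball. Default spacing is 0.8 mm isotropic, mirroring a
high-resolution T1 grid; region scores are drawn from
$\{0.1, 0.3, 0.5, 0.7, 1.0\}$, the value set of a rated segment table.
Everything is a pure function of the spec and its seed.

What the phantom deliberately does **not** emulate: real cortical
geometry and topology, partial-volume effects, registration error between
modality layers, or the sheer scale of a clinical volume
(320 × 320 × 236 ≈ 24.2 M voxels). Tests passing on phantoms show the
*algorithms* are correct under the stated model; they say nothing about
segmentation quality or clinical validity of a particular score table.

`generate_toy_case()` provides three named regression fixtures
(`free_line`, `center_block`, `wall_with_gap`) whose optimal costs are
recomputed by the oracle at call time rather than stored, so configuration
changes propagate; the suite cross-checks them against an independent
exhaustive path enumeration.

## Numerical and degenerate-input choices

* Voxel indices are 0-based $(i,j,k)$; the center of voxel $(i,j,k)$ sits
  at $\text{origin} + (i,j,k) \cdot \text{spacing}$ (no origin convention
  is imposed by the cubic-coordinate model, so the origin defaults to 0).
* Oracle path reconstruction uses a relative tolerance of $10^{-9}$ when
  testing edge optimality; penalty sums at the problem sizes involved are
  exact well beyond that.
* Degenerate inputs fail loudly: a zero-length cylinder axis, a cylinder
  entirely outside the volume, entry inside the target for training (a
  single-voxel path is only legal in `extract_path`), unreachable targets
  under barriers, out-of-range scores, non-integer label maps, missing
  header spacing without an explicit override.
* `fuse_layers` requires identical shapes and spacings; fusion assumes
  pre-aligned layers and no resampling is attempted.
* NRRD I/O is a minimal NRRD0004 dialect (scalar 3D, `raw`/`ascii`/`gzip`
  encodings, `spacings` or diagonal `space directions`); `raw` round-trips
  doubles bit-exactly.

## Validation problem sizes

The shipped suite validates at desk scale, chosen to exercise every code
path while keeping a full run in about a minute: oracle equivalence on 50
random volumes of 8–15 voxels per axis with voxel risks drawn from
$\{0, 0.3, 0.7, 1.0\}$ (exact cost match demanded in ≥ 95% of cases and
no undercut ever); cylinder voxelization against the brute-force oracle
in a 64³ volume; CLI byte-determinism and approach ranking on 24-voxel
phantoms; cost monotonicity under 100 single-voxel risk increases on 10³
grids. The planner itself has no size limit beyond memory and patience:
the Q-table is dense over (node × move), so a clinical-scale volume is
better handled by planning inside a cropped region of interest.

## Known limitations

* Tabular Q-learning visits every relevant (voxel, neighbor) pair;
  training cost grows quickly with volume size. The Dijkstra oracle gives
  the same optimum in a fraction of the time — the Q-learning route is
  the point of the package, the oracle is the check.
* Published per-approach scores from clinical volumes are not
  reproducible without the original subject's MRI, the clinicians'
  drawn segmentations and the original hyperparameters; comparisons here
  are therefore validated as *properties* (optimality, determinism,
  ranking direction) on synthetic data.
* Hand pathways are straight segments or externally supplied masks;
  interactive drawing is out of scope.
* Risk is isotropic and per-voxel; no anisotropic or directional risk.
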