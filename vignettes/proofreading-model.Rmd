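---
title: "Models and algorithms behind proofreadr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and algorithms behind proofreadr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proofreadr)
```

Automated segmentation of electron-microscopy (EM) volumes produces *bodies* —
sets of voxels sharing one label, each meant to be (part of) one neuron — but
it makes two characteristic errors: **false merges**, where one body spans
several neurons, and **false splits**, where one neuron is scattered across
several bodies. Proofreading is the manual repair of these errors, and at
connectome scale it is a multi-person workflow that needs sparse data
structures, versioned storage, fast interactive splitting, workflow metadata,
and coordination between editors. proofreadr implements that computational
core as a headless library plus a small CLI, testable end to end on synthetic
data. This vignette explains the models, the tunable parameters, and the
design decisions where the design was genuinely open.

## Sparse bodies: run-length encoding

A body is stored as its foreground voxels only, run-length encoded along the
x axis. A run is `(z, y, x_start, length)`; the run table is kept canonical —
sorted lexicographically by `(z, y, x_start)`, runs disjoint and maximal — so
two encodings of the same voxel set are always identical, which the test
suite exploits for bit-exact round-trip checks. Coordinates are 0-based and
global; boxes are half-open `[min, max)`, which removes every ±1 ambiguity.
Dense arrays use `dim = c(nx, ny, nz)` with x fastest.

The choice of x as the run axis matches row-major slice storage; nothing else
in the package depends on it. The binary file format (magic `PRLE`, scale and
run count as little-endian uint32, runs as four int32) is this package's own;
compatibility with any external data service's wire format is a non-goal.

## Block store, versions, and multi-scale retrieval

Volumes live in cubic blocks of `edge` voxels (default 32, a power of two so
block boundaries nest across pyramid scales). Retrieval is whole-block: when
a body needs grayscale context, every block its mask touches is returned
verbatim, including out-of-body voxels — slightly more memory for much less
data slicing.

Versioning is copy-on-write: a version is a layer of blocks plus a parent
pointer, reads fall through the layer chain, committed layers are immutable,
and only the working tip mutates. Branching from any committed version gives
checkpoint/restart semantics. `body_diff()` decomposes one body across two
versions into added (drawn green), removed (red) and unchanged (gray) voxel
sets — the conventional display for tracking proofreading progress.

Pyramid level $s$ downsamples each axis by $2^s$. Binary masks are pooled
with OR (a coarse voxel is foreground iff any child is), which preserves thin
neurites in coarse previews at the cost of slight dilation; a label-valued
mode pooling would drop them. Because of this rule,
`get_body_sparse(store, b, s)` is *exactly*
`downsample_mask(get_body_sparse(store, b, 0), s)`, a property the suite
asserts. `progressive_fetch()` yields the mask coarsest-first and stops after
the first scale whose voxel count exceeds `size_threshold` (default
5×10^6 voxels); the coarsest served scale defaults to 5 — a factor of 32 per
axis, which reduces even very large bodies to a real-time payload.

## The split engine

### Flooding model

Splitting a false merge is a seeded watershed run directly on grayscale:
membranes are darker than cytoplasm in EM, so with priority
$p(v) = 255 - I(v)$ bright cytoplasm floods first and fronts meet at dark
membrane ridges. No edge-enhancement pass is applied — on this data the
accuracy gain does not repay its cost. Connectivity is fixed at 6 for both
flooding and component analysis, preventing leaks through voxel corners
across one-voxel membranes.

### Determinization

A watershed's label map is only defined up to tie-breaking, so the package
fixes a fully deterministic rule:

* seeds claim their voxels immediately, in seed-list order;
* a voxel is claimed at water level $\max(\text{parent's level}, p(v))$ —
  levels never decrease along a flooding path;
* within one level the flood advances in synchronous breadth-first waves;
* when two fronts propose the same voxel in the same wave, the proposal whose
  originating seed appears *earlier in the seed list* wins.

The outcome therefore depends only on per-voxel quantities — claim level,
wave index, seed rank — and never on queue arrival order. That last point is
what makes bounded splitting exact (below): a naive first-come-first-served
queue makes the result depend on the global processing order, which changes
when the computation is restricted to a box, flipping individual
membrane-crest voxels. Seed *rank* rather than label value breaks ties so
that permuting seed labels permutes the output regions identically.
An independent pure-R implementation of the same rule serves as the oracle in
the test suite; the shipped kernel (a bucketed flood in C++) must match it
voxel for voxel on hundreds of random instances.

### Components, boxes, previews

A body may consist of several disconnected components. Because a flood never
crosses components, one flood over the whole body mask handles them all:
regions sharing a seed label are automatically joined across components, and
a component containing no seed stays unlabelled — it lands in the *residual*
and remains with the origin body when the result is persisted.

With a user bounding box, the flood runs on `mask ∩ box` only; each
6-connected component of `mask \ box` is then attached to the in-box region
it touches across the box face. A component touching several regions goes to
the one with the largest contact-voxel count (ties: smallest label); one
touching none goes to the residual. The bounded result equals the unbounded
one whenever the box contains the whole *merging border* — the voxels where
regions meet — with a small safety margin (membrane thickness plus about one
voxel) so that the box also holds the bright corridors that wrap around the
border's terminations; the acceptance checks construct their random boxes
that way. `local_preview()` is the same computation without the attachment
step, for a fast look before committing.

For gigantic bodies (bounding box above `bbox_budget`, default $10^9$
voxels), the split first runs on a $2^k$-downsampled copy (mask OR-pooled,
grayscale mask-averaged) and full-resolution voxels inherit their parent
coarse voxel's region; boundary refinement is out of scope.

Painting a single stroke in a 3D view is emulated by `ray_seeds()`: a 3D DDA
walks the ray, and every body voxel between the first and last hit becomes a
seed; background gaps along the ray are skipped.

### Persisting a split

`apply_split()` keeps the original body ID on the *largest* region — most
annotations stay attached to the surviving body — and draws fresh,
allocator-sequential IDs for the rest. The allocator never reissues an ID
within a store's lifetime. Voxel counts are conserved exactly under both
merge and split, which the fuzz tests assert over a thousand random
operations.

## Annotations

Body records (a free-text name and one of seven statuses: "not examined",
"traced", "traced in ROI", "partially traced", "orphan", "hard to trace",
"finalized") are keyed by body ID and rewritten explicitly when IDs retire
in a merge; on a name conflict the target's record wins and the source name
is appended to the target's comment log. Point annotations — owner-private
bookmarks, shared to-do marks ("to-do"/"done", with a "to merge"/"to split"
action hint), and synaptic elements — are keyed by *position* and associated
with a body by resolving that position against the current label volume at
query time, so merges and splits never leave them stale. Synapses are
directed pre→post links between elements; moving an element rewrites its
link endpoints and deleting one deletes its links, so links cannot dangle.
The sequencer is a body table filterable by regular expression and sortable
by synapse count, voxel count, name or status.

## The librarian

Concurrent editing is coordinated by per-body exclusive locks: acquire is
re-entrant for the holder and *denial is a value*, not an error, so clients
can retry; release is holder-only. Every mutating operation calls a guard
first and must leave the store untouched when refused — the suite checks
state hashes around refused mutations. Merging requires locks on **all**
participant bodies. There is no lease expiry; locks live until released.

## Synthetic fixtures

The generator emulates the one property of EM data the split engine relies
on: bright cytoplasm compartments separated by dark membranes. Geometry is a
3D Voronoi partition of `n_cells` uniform random sites — the simplest
partition with curved borders. The membrane is the band where the distances
to the nearest and second-nearest sites differ by less than
`membrane_width`, a band of roughly that thickness centred on the bisector;
membrane voxels keep the label of the nearest site, so labels partition the
volume with no background. Intensities default to cytoplasm 200 and membrane
50 with additive Gaussian noise σ = 10 clipped to 0–255 — a 15σ separation,
comfortably above the 5σ the statistical contract requires. Volumes are
bit-identical per RNG seed.

What the fixtures do *not* emulate: organelles and other dark interior
structure, membrane gaps, anisotropic section thickness, staining gradients,
and realistic neurite geometry. Passing the recovery tests therefore shows
the machinery is correct on data satisfying the membrane-darkness
assumption, not that real EM volumes will split at the same accuracy —
organelles near boundaries are precisely the known failure mode of running
watershed on raw grayscale.

`make_false_merge()` unions ground-truth cells under one ID (warning if they
are nowhere 6-adjacent, since such a merge is implausible);
`make_false_split()` cuts a cell with an axis-aligned plane. Both return the
truth mapping for scoring. Centroid seeding (`centroid_seeds()`) — one seed
per cell at the foreground voxel nearest the cell centroid — recovers false
merges with at least 0.95 mean voxel agreement over the generator's
condition grid (2–6 cells, σ ≤ 10), which the acceptance suite measures on
20 fixtures of 40³ voxels.

## Numerical and scale choices

* Degenerate inputs: fewer than two surviving seed labels is an
  `insufficient seeds` error; empty volumes are legal everywhere (empty run
  tables, empty boxes); a box clipping decode is silent by contract.
* Ray seeding uses a 10^-9 entry nudge so rays starting exactly on a box
  face are inside it.
* Problem sizes in the tests were chosen to exercise every code path while
  keeping the default run a few minutes: oracle equivalence on 500 volumes
  up to 12³, bounded-split equality on 100+ random boxes over tubes and 24³
  fixtures, recovery on 20 fixtures of 40³, a 1000-operation fuzz on a 32³
  store, and a 4-user × 200-step lock interleaving.
* The store keeps whole blocks in memory; it is an in-process emulation for
  desk-scale volumes, not a service. Persistence is one directory with one
  file per version layer.

## Known limitations

* Watershed on raw grayscale inherits the organelle failure mode described
  above; boundary-map or affinity-based flooding is deliberately out of
  scope.
* OR-pooled coarse masks slightly overstate a body's extent; coarse-level
  splits of giant bodies are not refined at full resolution.
* The attachment rule for an outside component touching several regions
  (largest contact, then smallest label) is a determinization of a case the
  interactive workflow rarely produces; other choices would be defensible.
* Locks are advisory within one process; there is no crash recovery or
  authentication.
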