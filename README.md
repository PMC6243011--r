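# proofreadr

Connectome reconstruction from electron-microscopy (EM) volumes starts with
an automated segmentation whose voxels are grouped into *bodies* — candidate
neurons. The segmentation contains **false merges** (one body spanning
several neurons) and **false splits** (one neuron scattered across bodies),
and fixing them at scale is a collaborative, interactive workflow.
proofreadr implements the computational core of such a
segmentation-based proofreading system as a headless R library with a small
command-line interface, for people building or studying proofreading
pipelines: sparse body representation, versioned block storage, interactive
false-merge splitting, workflow annotations, and multi-user locking — all
testable end to end on synthetic data.

## What is inside

* **Sparse volumes** — a body is its foreground voxels only, run-length
  encoded along x as runs `(z, y, x_start, length)`; encode/decode are exact
  inverses and the canonical run table makes round trips bit-identical.
  Multi-scale pyramids downsample by 2 per level with OR pooling; block
  covers and surface-point extraction (foreground voxels with a background
  6-neighbour) support display and block-aligned retrieval.
* **Versioned body store** — voxel→body-ID maps held in cubic blocks
  (default 32³) with copy-on-write version layers: commit, branch, per-body
  retrieval at any scale, progressive coarse-to-fine fetch, whole-block
  grayscale context, merge, split persistence, and green/red/gray body diffs
  between versions.
* **Split engine** — seeded watershed on raw grayscale restricted to the
  body mask, with priority 255 − intensity so bright cytoplasm floods before
  dark membranes and fronts meet at the ridges:

  $$p(v) = 255 - I(v), \qquad \text{claim level}(v) = \max(\text{parent level}, p(v))$$

  flooding is deterministic (level-synchronous waves, seed-rank
  tie-breaking), components with no seed stay with the origin body, equal
  seed labels join across components, and computation can be bounded to a
  box with connected-component reattachment — exact whenever the box
  contains the whole merging border (plus a membrane-width margin).
  Ray-shot seeding emulates painting a stroke in 3D.
* **Annotations** — body names and the seven workflow statuses, owner-private
  bookmarks, shared to-do marks, synapse elements with directed pre→post
  links, region/body queries resolved against the current labels, and a
  sequencer table (regex filter, sortable by synapse count and more).
* **Librarian** — per-body exclusive locks with deny-on-conflict; every
  mutating operation is guarded and refused mutations change nothing.
* **Fixtures** — synthetic EM-like volumes (bright Voronoi cells, dark
  membrane bands, Gaussian noise) with ground truth, plus false-merge and
  false-split scenario builders used by every test.

## Worked example

Generate a synthetic volume, fake a false merge of two cells, and undo it
with centroid seeds:

```r
library(proofreadr)

fx <- generate_cells(fixture_spec(shape = c(32, 32, 32), n_cells = 3,
                                  rng_seed = 42))
fm <- make_false_merge(fx$labels, c(1, 2))   # cells 1+2 under one ID

st <- body_store()                            # edge-32 blocks, in memory
put_labels(st, fm$labels)
put_grayscale(st, fx$gray)

get_body_sparse(st, 1)
#> <rle volume: 13400 voxels in 1024 runs, scale 0, body 1>

seeds <- centroid_seeds(fx$labels, c(1, 2))   # one seed per true cell
res <- split_body(st, 1, seeds)
res
#> <split result: 2 region(s) [5771, 7629], residual 0 voxels, 0 seed(s) dropped>
```

The two regions are the two true cells (13400 = 5771 + 7629 voxels; nothing
left behind). Persist the split under a lock and inspect what changed:

```r
v0 <- commit_version(st)
acquire_lock(st, 1, "alice")
apply_split(st, 1, res, "alice")
#>    1    2
#>    4    1        # larger region keeps ID 1, the other becomes body 4

v1 <- commit_version(st)
tidy(body_diff(st, v0, v1, 1))
#> # A tibble: 3 × 3
#>   change    voxel_count color
#>   <chr>           <int> <chr>
#> 1 added               0 green
#> 2 removed          5771 red
#> 3 unchanged        7629 gray
```

Body 1 lost exactly the 5771 voxels that became body 4. Annotation records
follow the surviving IDs:

```r
set_body_name(st, 1, "KC-alpha"); set_body_status(st, 1, "traced")
set_body_name(st, 4, "KC-beta")
sequencer_query(st, sort_key = "voxel_count")
#> # A tibble: 2 × 5
#>    body name     status       voxel_count synapse_count
#>   <int> <chr>    <chr>              <int>         <int>
#> 1     1 KC-alpha traced              7629             0
#> 2     4 KC-beta  not examined        5771             0
```

The same flow is available from a shell via the launcher installed at
`inst/cli/proofreadr` (subcommands `fixtures`, `store`, `merge`, `split`,
`lock`, `annot`, `synapse`, `bodies`); exit codes are 0 on success, 1 on
validation errors, 2 on lock/consistency refusals.

## File formats

* Dense grayscale: multi-page 8-bit TIFF (page = z slice, rows = y,
  columns = x).
* Labels (CLI exchange): JSON `{"shape": [nx,ny,nz], "bodies": {"<id>":
  [[z,y,x_start,length], ...]}}`.
* Sparse volumes: binary `PRLE` files (little-endian; scale + run count as
  uint32, runs as four int32) or a JSON debug form; both formats are this
  package's own.
* Seeds: JSON array of `{"x":…, "y":…, "z":…, "label":…}`.
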