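# Versioned, block-based label store with a grayscale companion.
#
# The store emulates, in process, the subset of a block-oriented volume data
# service a proofreading client needs: voxel -> body-ID mapping held in cubic
# blocks, copy-on-write version layers forming a tree, per-body sparse
# retrieval at any pyramid scale, block-aligned grayscale fetch, and the two
# mutating edits (merge, split) guarded by the librarian's locks.
#
# A version layer is an environment mapping block key "bx,by,bz" to a dense
# integer array edge^3 (dim c(e, e, e), x fastest). Reads of a block walk the
# layer chain tip -> parent -> ... and take the first hit; absent blocks are
# background. Committed layers are immutable; only the working tip mutates.

#' Create an in-memory versioned body store
#'
#' @param block_edge Voxels per block side (power of two; default 32).
#' @param max_scale Coarsest pyramid level served, i.e. downsampling by
#'   `2^max_scale` per axis (default 5, a factor of 32 — the scale at which
#'   even very large bodies reduce to a real-time payload).
#' @return A `prf_store` (mutable environment).
#' @export
#' @examples
#' st <- body_store()
#' lab <- array(0L, c(4, 4, 4)); lab[1:2, , ] <- 7L
#' put_labels(st, lab)
#' rle_stats(get_body_sparse(st, 7))$voxel_count
body_store <- function(block_edge = 32L, max_scale = 5L) {
  spec <- block_spec(block_edge)
  st <- new.env(parent = emptyenv())
  st$spec <- spec
  st$max_scale <- as.integer(max_scale)
  st$versions <- new.env(parent = emptyenv())
  st$version_counter <- 1L
  st$tip <- "v1"
  st$versions[["v1"]] <- list(parent = NA_character_,
                              blocks = new.env(parent = emptyenv()),
                              committed = FALSE)
  st$gray <- new.env(parent = emptyenv())
  st$has_gray <- FALSE
  st$next_id <- 1L
  st$locks <- new.env(parent = emptyenv())
  st$ann <- new_annotation_tables()
  class(st) <- c("prf_store", "environment")
  st
}

#' @export
print.prf_store <- function(x, ...) {
  cat(sprintf("<body store: edge %d, %d version(s), tip %s, %d bodies>\n",
              x$spec$edge, length(ls(x$versions)), x$tip,
              length(list_bodies(x))))
  invisible(x)
}

block_key <- function(bx, by, bz) paste(bx, by, bz, sep = ",")

key_to_index <- function(key) as.integer(strsplit(key, ",", fixed = TRUE)[[1]])

version_chain <- function(store, version) {
  chain <- character()
  v <- version
  while (!is.na(v)) {
    if (is.null(store$versions[[v]])) stop_not_found(sprintf("unknown version '%s'", v))
    chain <- c(chain, v)
    v <- store$versions[[v]]$parent
  }
  chain
}

# effective block (dense integer array) at a version, or NULL if background
read_block <- function(store, key, version = store$tip) {
  for (v in version_chain(store, version)) {
    blk <- store$versions[[v]]$blocks[[key]]
    if (!is.null(blk)) return(blk)
  }
  NULL
}

# all block keys visible at a version (union over the chain)
visible_keys <- function(store, version = store$tip) {
  unique(unlist(lapply(version_chain(store, version),
                       function(v) ls(store$versions[[v]]$blocks)), use.names = FALSE))
}

assert_tip_writable <- function(store, version) {
  if (store$versions[[version]]$committed)
    stop_immutability(sprintf("version '%s' is committed and immutable", version))
}

# Write a dense patch into blocks of the tip layer (read-modify-write through
# the chain so partial-block writes keep surrounding voxels).
write_patch <- function(store, arr, offset, version = store$tip, is_gray = FALSE) {
  e <- store$spec$edge
  d <- dim(arr)
  lo <- offset
  hi <- offset + d                      # exclusive
  b_lo <- fdiv(lo, e)
  b_hi <- fdiv(hi - 1L, e)
  layer <- if (is_gray) store$gray else store$versions[[version]]$blocks
  for (bz in b_lo[3]:b_hi[3]) for (by in b_lo[2]:b_hi[2]) for (bx in b_lo[1]:b_hi[1]) {
    key <- block_key(bx, by, bz)
    blk <- if (is_gray) store$gray[[key]] else read_block(store, key, version)
    if (is.null(blk)) blk <- array(0L, c(e, e, e))
    g0 <- pmax(c(bx, by, bz) * e, lo)   # global inclusive
    g1 <- pmin((c(bx, by, bz) + 1L) * e, hi)  # global exclusive
    bi <- g0 - c(bx, by, bz) * e        # 0-based within block
    ai <- g0 - lo                       # 0-based within arr
    n <- g1 - g0
    blk[(bi[1] + 1):(bi[1] + n[1]), (bi[2] + 1):(bi[2] + n[2]),
        (bi[3] + 1):(bi[3] + n[3])] <-
      arr[(ai[1] + 1):(ai[1] + n[1]), (ai[2] + 1):(ai[2] + n[2]),
          (ai[3] + 1):(ai[3] + n[3])]
    layer[[key]] <- blk
  }
  invisible(NULL)
}

#' Ingest a dense label array at the working tip
#'
#' Voxels with value 0 are background and overwrite existing labels in the
#' written region. The ID allocator is advanced past every ingested ID so it
#' never reissues one.
#'
#' @param store A `prf_store`.
#' @param labels Dense 3D integer array of body IDs (`dim = c(nx, ny, nz)`).
#' @param offset Global coordinate of `labels[1, 1, 1]`; non-negative.
#' @param version Version to write (default the working tip). Writing a
#'   committed version raises an immutability error.
#' @export
put_labels <- function(store, labels, offset = c(0L, 0L, 0L),
                       version = store$tip) {
  stopifnot(inherits(store, "prf_store"))
  if (is.null(dim(labels)) || length(dim(labels)) != 3)
    stop_dimensionality("labels must be a 3D array")
  offset <- as_voxel_coord(offset, "offset")
  if (any(offset < 0L)) stop_validation("stored voxels must have non-negative coordinates")
  if (is.null(store$versions[[version]])) stop_not_found(sprintf("unknown version '%s'", version))
  assert_tip_writable(store, version)
  storage.mode(labels) <- "integer"
  write_patch(store, labels, offset, version)
  store$next_id <- max(store$next_id, max(labels, 0L) + 1L)
  invisible(store)
}

#' Load the grayscale companion volume
#'
#' @param store A `prf_store`.
#' @param gray Dense 3D array of 8-bit intensities (0-255).
#' @param offset Global coordinate of `gray[1, 1, 1]`.
#' @export
put_grayscale <- function(store, gray, offset = c(0L, 0L, 0L)) {
  stopifnot(inherits(store, "prf_store"))
  if (is.null(dim(gray)) || length(dim(gray)) != 3)
    stop_dimensionality("grayscale must be a 3D array")
  if (min(gray) < 0 || max(gray) > 255)
    stop_validation("grayscale intensities must be 8-bit (0-255)")
  storage.mode(gray) <- "integer"
  write_patch(store, gray, as_voxel_coord(offset, "offset"), is_gray = TRUE)
  store$has_gray <- TRUE
  invisible(store)
}

#' Body IDs present at a version
#'
#' @param store A `prf_store`.
#' @param version Version ID (default working tip).
#' @return Sorted integer vector of body IDs with at least one voxel.
#' @export
list_bodies <- function(store, version = store$tip) {
  ids <- integer()
  for (key in visible_keys(store, version)) {
    blk <- read_block(store, key, version)
    ids <- union(ids, blk[blk != 0L])
  }
  sort(ids)
}

#' Retrieve one body as an RLE sparse volume
#'
#' The scale-0 mask is assembled from the visible blocks; coarser scales are
#' its OR-pooled downsampling, so `get_body_sparse(store, b, s)` equals
#' `downsample_mask(get_body_sparse(store, b, 0), s)` exactly.
#'
#' @param store A `prf_store`.
#' @param body Positive body ID.
#' @param scale Pyramid level (0 = full resolution).
#' @param version Version to read (default working tip).
#' @return A `prf_rle` with `body_id = body`.
#' @export
get_body_sparse <- function(store, body, scale = 0L, version = store$tip) {
  stopifnot(inherits(store, "prf_store"))
  body <- as.integer(body)
  rle <- body_mask_scale0(store, body, version)
  if (rle_stats(rle)$voxel_count == 0L)
    stop_not_found(sprintf("body %d not found in version '%s'", body, version))
  if (scale > 0L) rle <- downsample_mask(rle, scale)
  rle
}

# scale-0 mask, empty volume when the body is absent (no error)
body_mask_scale0 <- function(store, body, version = store$tip) {
  e <- store$spec$edge
  parts <- list()
  for (key in visible_keys(store, version)) {
    blk <- read_block(store, key, version)
    if (!any(blk == body)) next
    bi <- key_to_index(key)
    parts[[length(parts) + 1L]] <- rle_encode(blk == body, offset = bi * e)$runs
  }
  if (length(parts) == 0) return(rle_volume(NULL, body_id = body))
  rle_volume(dplyr::bind_rows(parts), scale = 0L, body_id = body)
}

#' Fetch a body coarse-to-fine
#'
#' Emulates progressive loading for 3D display: the mask is fetched first at
#' the coarsest scale, then at each next finer scale, stopping after the
#' first scale whose voxel count exceeds `size_threshold` (or at scale 0).
#'
#' @param store A `prf_store`.
#' @param body Body ID.
#' @param size_threshold Voxel budget per refinement step (default 5e6).
#' @return List of `prf_rle` at strictly decreasing scale; always at least one
#'   element.
#' @export
progressive_fetch <- function(store, body, size_threshold = 5e6) {
  full <- get_body_sparse(store, body, 0L)   # not-found error if absent
  out <- list()
  for (s in seq(store$max_scale, 0L)) {
    m <- if (s > 0L) downsample_mask(full, s) else full
    out[[length(out) + 1L]] <- m
    if (rle_stats(m)$voxel_count > size_threshold) break
  }
  out
}

#' Fetch the block-aligned grayscale context of a body
#'
#' Whole blocks only: every block intersecting the body's foreground is
#' returned verbatim, including its out-of-body voxels — trading a little
#' memory for not slicing data.
#'
#' @param store A `prf_store`.
#' @param body Body ID.
#' @return A `prf_patch_set`: list with `edge` and `patches`, each patch a
#'   list of `index` (`c(bx, by, bz)`) and `data` (dense `edge^3` array).
#' @export
fetch_body_grayscale <- function(store, body) {
  stopifnot(inherits(store, "prf_store"))
  if (!store$has_gray) stop_config("no grayscale volume loaded")
  mask <- get_body_sparse(store, body, 0L)
  cover <- block_cover(mask, store$spec)
  e <- store$spec$edge
  patches <- purrr::pmap(cover, function(bz, by, bx) {
    blk <- store$gray[[block_key(bx, by, bz)]]
    if (is.null(blk)) blk <- array(0L, c(e, e, e))
    list(index = c(bx, by, bz), data = blk)
  })
  structure(list(edge = e, patches = patches), class = "prf_patch_set")
}

# dense grayscale + mask over the body's tight bounding box, assembled from
# whole-block patches; the working form for the split engine
body_dense_context <- function(store, body) {
  mask_rle <- get_body_sparse(store, body, 0L)
  box <- rle_stats(mask_rle)$bbox
  dec <- rle_decode(mask_rle, box)
  ps <- fetch_body_grayscale(store, body)
  e <- ps$edge
  gray <- array(0L, dim(dec$mask))
  for (p in ps$patches) {
    g0 <- p$index * e
    lo <- pmax(g0, box$min); hi <- pmin(g0 + e, box$max)
    if (any(hi <= lo)) next
    bi <- lo - g0; ai <- lo - box$min; n <- hi - lo
    gray[(ai[1] + 1):(ai[1] + n[1]), (ai[2] + 1):(ai[2] + n[2]),
         (ai[3] + 1):(ai[3] + n[3])] <-
      p$data[(bi[1] + 1):(bi[1] + n[1]), (bi[2] + 1):(bi[2] + n[2]),
             (bi[3] + 1):(bi[3] + n[3])]
  }
  list(mask = dec$mask, gray = gray, offset = box$min, rle = mask_rle)
}

fresh_body_id <- function(store) {
  id <- store$next_id
  store$next_id <- id + 1L
  id
}

# relabel voxels in the tip: map is a named integer vector old -> new
relabel_voxels <- function(store, map) {
  old_ids <- as.integer(names(map))
  for (key in visible_keys(store)) {
    blk <- read_block(store, key)
    hit <- blk %in% old_ids
    if (!any(hit)) next
    blk[hit] <- map[as.character(blk[hit])]
    store$versions[[store$tip]]$blocks[[key]] <- blk
  }
  invisible(NULL)
}

#' Merge bodies into the first-selected ID
#'
#' All voxels of every listed body are relabelled to the first ID in `ids`
#' (the anchor of an interactive merge); the other IDs are retired and the
#' annotation tables are re-pointed at the target. The caller must hold the
#' librarian lock on every participant.
#'
#' @param store A `prf_store`.
#' @param ids Two or more distinct existing body IDs; the first is the target.
#' @param user Lock holder performing the merge.
#' @return The target body ID, invisibly.
#' @export
merge_bodies <- function(store, ids, user) {
  stopifnot(inherits(store, "prf_store"))
  ids <- as.integer(ids)
  if (length(ids) < 2 || anyDuplicated(ids))
    stop_validation("merge needs at least two distinct body IDs")
  guard(store, ids, user)
  present <- list_bodies(store)
  missing <- setdiff(ids, present)
  if (length(missing) > 0)
    stop_not_found(sprintf("unknown body ID(s): %s", paste(missing, collapse = ", ")))
  assert_tip_writable(store, store$tip)
  target <- ids[1]
  retired <- ids[-1]
  relabel_voxels(store, setNames(rep(target, length(retired)), retired))
  sync_after_relabel(store, setNames(rep(target, length(retired)), as.character(retired)))
  invisible(target)
}

#' Persist a split partition into the store
#'
#' The largest region keeps the original body ID (so most annotations stay
#' attached to the surviving body); every other region receives a fresh,
#' allocator-sequential ID. Voxels of the body not covered by any region stay
#' with the original body. Requires the librarian lock on `body`.
#'
#' @param store A `prf_store`.
#' @param body Body being split.
#' @param partition A `prf_split_result` (regions in global coordinates).
#' @param user Lock holder.
#' @return Named integer vector mapping split label -> body ID.
#' @export
apply_split <- function(store, body, partition, user) {
  stopifnot(inherits(store, "prf_store"), inherits(partition, "prf_split_result"))
  body <- as.integer(body)
  guard(store, body, user)
  body_vox <- rle_voxels(body_mask_scale0(store, body))
  if (nrow(body_vox) == 0) stop_not_found(sprintf("unknown body ID: %d", body))
  assert_tip_writable(store, store$tip)
  regions <- partition$regions
  sizes <- vapply(regions, function(r) rle_stats(r)$voxel_count, integer(1))
  for (r in regions) {
    out <- dplyr::anti_join(rle_voxels(r), body_vox, by = c("x", "y", "z"))
    if (nrow(out) > 0)
      stop_consistency("split region contains voxels outside the body")
  }
  labels <- names(regions)
  keep <- labels[which.max(sizes)]      # first max wins on ties
  mapping <- setNames(rep(body, length(labels)), labels)
  for (lb in labels) {
    if (lb == keep || sizes[[lb]] == 0L) next
    nid <- fresh_body_id(store)
    mapping[[lb]] <- nid
    vox <- rle_voxels(regions[[lb]])
    paint_voxels(store, vox, nid)
  }
  sync_after_relabel(store, setNames(integer(0), character(0)))
  mapping
}

# set the label of individual voxels in the tip (read-modify-write per block)
paint_voxels <- function(store, xyz, id) {
  if (nrow(xyz) == 0) return(invisible(NULL))
  e <- store$spec$edge
  xyz <- dplyr::mutate(xyz, bx = fdiv(.data$x, e), by = fdiv(.data$y, e),
                       bz = fdiv(.data$z, e))
  for (grp in split(xyz, paste(xyz$bx, xyz$by, xyz$bz, sep = ","))) {
    key <- block_key(grp$bx[1], grp$by[1], grp$bz[1])
    blk <- read_block(store, key)
    if (is.null(blk)) blk <- array(0L, c(e, e, e))
    lin <- (grp$z - grp$bz[1] * e) * e * e + (grp$y - grp$by[1] * e) * e +
      (grp$x - grp$bx[1] * e) + 1L
    blk[lin] <- as.integer(id)
    store$versions[[store$tip]]$blocks[[key]] <- blk
  }
  invisible(NULL)
}

#' Commit the working tip / branch from a committed version
#'
#' `commit_version()` freezes the tip (it becomes immutable) and opens a new
#' empty child layer as the working tip; reads on the new tip fall through to
#' the committed ancestry. `branch_version()` opens a working tip on top of
#' any committed version, so proofreading can restart from a checkpoint.
#'
#' @param store A `prf_store`.
#' @return `commit_version()` returns the ID of the committed version;
#'   `branch_version()` returns the new tip's ID.
#' @export
commit_version <- function(store) {
  stopifnot(inherits(store, "prf_store"))
  committed <- store$tip
  store$versions[[committed]]$committed <- TRUE
  new_tip(store, parent = committed)
  committed
}

#' @rdname commit_version
#' @param parent A committed `VersionID` to branch from.
#' @export
branch_version <- function(store, parent) {
  stopifnot(inherits(store, "prf_store"))
  if (is.null(store$versions[[parent]]))
    stop_not_found(sprintf("unknown version '%s'", parent))
  if (!store$versions[[parent]]$committed)
    stop_validation("can only branch from a committed version")
  new_tip(store, parent = parent)
  store$tip
}

new_tip <- function(store, parent) {
  store$version_counter <- store$version_counter + 1L
  id <- paste0("v", store$version_counter)
  store$versions[[id]] <- list(parent = parent,
                               blocks = new.env(parent = emptyenv()),
                               committed = FALSE)
  store$tip <- id
  id
}

#' Three-way diff of one body between two versions
#'
#' Decomposes a body's scale-0 voxel set across versions A and B into voxels
#' added (in B only — drawn green), removed (in A only — red) and unchanged
#' (both — gray).
#'
#' @param store A `prf_store`.
#' @param version_a,version_b Version IDs.
#' @param body Body ID (must exist in at least one of the versions).
#' @return A `prf_body_diff` with `added`, `removed`, `unchanged` (`prf_rle`).
#' @export
body_diff <- function(store, version_a, version_b, body) {
  stopifnot(inherits(store, "prf_store"))
  a <- body_mask_scale0(store, body, version_a)
  b <- body_mask_scale0(store, body, version_b)
  if (rle_stats(a)$voxel_count == 0L && rle_stats(b)$voxel_count == 0L)
    stop_not_found(sprintf("body %d absent from both versions", body))
  structure(list(added = rle_setdiff(b, a),
                 removed = rle_setdiff(a, b),
                 unchanged = rle_intersect(a, b),
                 body = as.integer(body),
                 version_a = version_a, version_b = version_b),
            class = "prf_body_diff")
}

#' @export
print.prf_body_diff <- function(x, ...) {
  cat(sprintf("<body %d diff %s -> %s: +%d / -%d / =%d voxels>\n",
              x$body, x$version_a, x$version_b,
              rle_stats(x$added)$voxel_count,
              rle_stats(x$removed)$voxel_count,
              rle_stats(x$unchanged)$voxel_count))
  invisible(x)
}

#' Tidy a body diff into one row per change class
#'
#' @param x A `prf_body_diff`.
#' @param ... Unused.
#' @return Tibble with `change` (added/removed/unchanged), `voxel_count`, and
#'   the display `color` convention (green/red/gray).
#' @export
tidy.prf_body_diff <- function(x, ...) {
  tibble(change = c("added", "removed", "unchanged"),
         voxel_count = c(rle_stats(x$added)$voxel_count,
                         rle_stats(x$removed)$voxel_count,
                         rle_stats(x$unchanged)$voxel_count),
         color = c("green", "red", "gray"))
}

#' Plot a body diff as a z-projection
#'
#' @param object A `prf_body_diff`.
#' @param ... Unused.
#' @return A ggplot with added voxels green, removed red, unchanged gray.
#' @export
autoplot.prf_body_diff <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(rle_voxels(object$added), change = "added"),
    dplyr::mutate(rle_voxels(object$removed), change = "removed"),
    dplyr::mutate(rle_voxels(object$unchanged), change = "unchanged"))
  df <- dplyr::distinct(df, .data$x, .data$y, .data$change)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$change)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(added = "#2ca02c", removed = "#d62728",
                                          unchanged = "gray60")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("body %d: %s vs %s", object$body,
                                  object$version_a, object$version_b))
}

#' Resolve the body ID under each position
#'
#' @param store A `prf_store`.
#' @param xyz Data frame with columns `x`, `y`, `z`.
#' @param version Version to resolve against (default working tip).
#' @return Integer vector of body IDs (0 = background).
#' @export
label_at <- function(store, xyz, version = store$tip) {
  if (nrow(xyz) == 0) return(integer())
  e <- store$spec$edge
  out <- integer(nrow(xyz))
  bx <- fdiv(xyz$x, e); by <- fdiv(xyz$y, e); bz <- fdiv(xyz$z, e)
  keys <- paste(bx, by, bz, sep = ",")
  for (key in unique(keys)) {
    sel <- which(keys == key)
    blk <- read_block(store, key, version)
    if (is.null(blk)) next
    lin <- (xyz$z[sel] - bz[sel] * e) * e * e + (xyz$y[sel] - by[sel] * e) * e +
      (xyz$x[sel] - bx[sel] * e) + 1L
    out[sel] <- blk[lin]
  }
  out
}

# total labelled voxel count at a version (conservation checks, sequencer)
body_voxel_counts <- function(store, version = store$tip) {
  counts <- integer()
  for (key in visible_keys(store, version)) {
    blk <- read_block(store, key, version)
    t <- table(blk[blk != 0L])
    for (nm in names(t)) counts[nm] <- sum(counts[nm], t[[nm]], na.rm = TRUE)
  }
  ids <- as.integer(names(counts))
  tibble(body = ids[order(ids)], voxel_count = as.integer(counts[order(ids)]))
}
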