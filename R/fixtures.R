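# Synthetic EM-like volumes: bright cytoplasm compartments separated by dark
# membrane boundaries, with ground-truth labels, plus builders for the two
# proofreading error scenarios (false merge, false split).
#
# Geometry is a 3D Voronoi partition of random sites — the simplest partition
# with curved borders. The membrane is the band where the distances to the
# nearest and second-nearest sites differ by less than the membrane width,
# i.e. a band of roughly that thickness centred on the inter-cell bisector;
# membrane voxels keep the label of their nearest site (no background gap).

#' Specify a synthetic cell fixture
#'
#' @param shape Volume shape `c(nx, ny, nz)`.
#' @param n_cells Number of Voronoi cells (`>= 2`).
#' @param membrane_width Thickness of the dark inter-cell band (voxels).
#' @param cytoplasm_mean,membrane_mean 8-bit intensities; the membrane must be
#'   darker than the cytoplasm (defaults 200 and 50).
#' @param noise_sigma Additive Gaussian noise standard deviation (default 10);
#'   intensities are clipped to 0-255 after adding noise.
#' @param rng_seed Integer seed; volumes are bit-identical per seed.
#' @return A `prf_fixture_spec`.
#' @export
fixture_spec <- function(shape = c(48L, 48L, 48L), n_cells = 2L,
                         membrane_width = 2L, cytoplasm_mean = 200L,
                         membrane_mean = 50L, noise_sigma = 10,
                         rng_seed = 1L) {
  shape <- as_voxel_coord(shape, "shape")
  n_cells <- as.integer(n_cells)
  if (n_cells < 2L) stop_validation("n_cells must be >= 2")
  if (membrane_width < 1L) stop_validation("membrane_width must be >= 1")
  if (!(membrane_mean < cytoplasm_mean))
    stop_validation("membranes must be darker than cytoplasm")
  if (noise_sigma < 0) stop_validation("noise_sigma must be >= 0")
  if (prod(as.numeric(shape)) < 512 * n_cells)
    stop_validation("volume too small: allow at least 8^3 voxels per cell")
  structure(list(shape = shape, n_cells = n_cells,
                 membrane_width = as.integer(membrane_width),
                 cytoplasm_mean = as.integer(cytoplasm_mean),
                 membrane_mean = as.integer(membrane_mean),
                 noise_sigma = as.numeric(noise_sigma),
                 rng_seed = as.integer(rng_seed)),
            class = "prf_fixture_spec")
}

#' Generate a synthetic grayscale + ground-truth label volume
#'
#' @param spec A [fixture_spec()].
#' @return List with `gray` (integer 3D array, 0-255), `labels` (integer 3D
#'   array, values 1..n_cells, no background), and `sites` (n_cells x 3
#'   matrix of cell sites).
#' @export
#' @examples
#' fx <- generate_cells(fixture_spec(shape = c(24, 24, 24), n_cells = 2,
#'                                   noise_sigma = 0))
#' sort(unique(as.vector(fx$labels)))
generate_cells <- function(spec) {
  stopifnot(inherits(spec, "prf_fixture_spec"))
  d <- spec$shape
  withr::with_seed(spec$rng_seed, {
    sites <- cbind(runif(spec$n_cells, 0, d[1]),
                   runif(spec$n_cells, 0, d[2]),
                   runif(spec$n_cells, 0, d[3]))
    noise <- if (spec$noise_sigma > 0)
      rnorm(prod(as.numeric(d)), 0, spec$noise_sigma) else 0
  })
  # squared distance to each site, axis-separable accumulation
  xs <- seq_len(d[1]) - 0.5; ys <- seq_len(d[2]) - 0.5; zs <- seq_len(d[3]) - 0.5
  best <- array(Inf, d); second <- array(Inf, d); lab <- array(0L, d)
  for (i in seq_len(spec$n_cells)) {
    di <- outer(outer((xs - sites[i, 1])^2, (ys - sites[i, 2])^2, "+"),
                (zs - sites[i, 3])^2, "+")
    closer <- di < best
    second <- ifelse(closer, best, pmin(second, di))
    lab[closer] <- i
    best <- pmin(best, di)
  }
  membrane <- (sqrt(second) - sqrt(best)) < spec$membrane_width
  gray <- ifelse(membrane, spec$membrane_mean, spec$cytoplasm_mean) + noise
  gray <- array(as.integer(pmin(255, pmax(0, round(gray)))), d)
  list(gray = gray, labels = lab, sites = sites)
}

#' Build a false-merge scenario from a label volume
#'
#' Unions the listed ground-truth cells under the first listed ID — the input
#' a split has to undo. Warns (but proceeds) if the cells are not pairwise
#' 6-adjacent anywhere, since such a merge would be implausible in real data.
#'
#' @param labels Integer 3D label array.
#' @param ids Two or more label IDs to merge.
#' @return List with `labels` (modified array) and `truth` (named integer
#'   vector mapping each original ID to the merged ID).
#' @export
make_false_merge <- function(labels, ids) {
  ids <- as.integer(ids)
  if (length(ids) < 2) stop_validation("need at least two IDs to merge")
  present <- unique(as.vector(labels))
  if (!all(ids %in% present)) stop_not_found("some IDs are absent from the label volume")
  if (!all_pairwise_adjacent(labels, ids))
    warn("merged cells are not pairwise 6-adjacent; merging anyway")
  out <- labels
  out[out %in% ids[-1]] <- ids[1]
  list(labels = out, truth = setNames(rep(ids[1], length(ids)), ids))
}

# every pair of ids shares at least one 6-adjacent voxel pair somewhere
all_pairwise_adjacent <- function(labels, ids) {
  d <- dim(labels)
  pairs <- list()
  add_pairs <- function(a, b) {
    sel <- a %in% ids & b %in% ids & a != b
    if (any(sel)) unique(cbind(pmin(a[sel], b[sel]), pmax(a[sel], b[sel])))
    else NULL
  }
  seen <- rbind(
    add_pairs(labels[-d[1], , ], labels[-1, , ]),
    add_pairs(labels[, -d[2], ], labels[, -1, ]),
    add_pairs(labels[, , -d[3]], labels[, , -1]))
  need <- utils::combn(sort(ids), 2)
  if (is.null(seen)) return(FALSE)
  seen_keys <- unique(paste(seen[, 1], seen[, 2]))
  all(paste(need[1, ], need[2, ]) %in% seen_keys)
}

#' Build a false-split scenario by cutting a cell with a plane
#'
#' Voxels of `id` on the far side of the axis-aligned plane get a fresh ID
#' (`max(labels) + 1`); the near side keeps `id`.
#'
#' @param labels Integer 3D label array.
#' @param id Cell to cut.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param coord Plane position: voxels with axis coordinate `>= coord`
#'   (0-based) move to the new ID.
#' @return List with `labels`, `new_id`, and `truth` (named vector mapping
#'   both halves back to the original ID).
#' @export
make_false_split <- function(labels, id, axis = c("x", "y", "z"), coord) {
  axis <- match.arg(axis)
  id <- as.integer(id)
  d <- dim(labels)
  ax <- match(axis, c("x", "y", "z"))
  idx <- slice.index(labels, ax) - 1L   # 0-based coordinate along the axis
  far <- labels == id & idx >= coord
  near <- labels == id & idx < coord
  if (!any(far) || !any(near))
    stop_validation("degenerate cut: one side of the plane is empty")
  new_id <- max(labels) + 1L
  out <- labels
  out[far] <- new_id
  list(labels = out, new_id = new_id,
       truth = setNames(c(id, id), c(id, new_id)))
}

#' Centroid seeds for a set of ground-truth cells
#'
#' One seed per cell, at the cell's foreground voxel nearest its centroid,
#' labelled 1..k in the order given — the canonical seeding for recovering a
#' false merge of those cells.
#'
#' @param labels Integer 3D label array (ground truth).
#' @param ids Cell IDs to seed.
#' @param offset Global coordinate of `labels[1, 1, 1]`.
#' @return A `prf_seed_set`.
#' @export
centroid_seeds <- function(labels, ids, offset = c(0L, 0L, 0L)) {
  offset <- as_voxel_coord(offset, "offset")
  d <- dim(labels)
  out <- list()
  for (k in seq_along(ids)) {
    idx <- which(labels == ids[k]) - 1L
    if (length(idx) == 0) stop_not_found(sprintf("no voxels with label %d", ids[k]))
    x <- idx %% d[1]; y <- (idx %/% d[1]) %% d[2]; z <- idx %/% (d[1] * d[2])
    cx <- mean(x); cy <- mean(y); cz <- mean(z)
    i <- which.min((x - cx)^2 + (y - cy)^2 + (z - cz)^2)
    out[[k]] <- tibble(x = x[i] + offset[1], y = y[i] + offset[2],
                       z = z[i] + offset[3], label = k)
  }
  s <- dplyr::bind_rows(out)
  seed_set(s$x, s$y, s$z, s$label)
}

#' Scatter random synaptic elements over a label volume
#'
#' Places `n_links` pre/post pairs at uniform random foreground positions
#' (pre and post in different cells when possible) — a lightweight stand-in
#' for upstream automatic synapse prediction, useful for exercising the
#' annotation tables.
#'
#' @param store A `prf_store` whose tip holds the labels.
#' @param labels Integer 3D label array the positions are drawn from.
#' @param n_links Number of pre -> post pairs.
#' @param rng_seed Integer seed.
#' @export
scatter_synapses <- function(store, labels, n_links = 5L, rng_seed = 1L) {
  d <- dim(labels)
  fg <- which(labels != 0)
  withr::with_seed(rng_seed, {
    for (i in seq_len(n_links)) {
      repeat {
        pick <- sample(fg, 2L)
        p0 <- pick - 1L
        pos <- cbind(p0 %% d[1], (p0 %/% d[1]) %% d[2], p0 %/% (d[1] * d[2]))
        if (!any(duplicated(rbind(as.matrix(store$ann$synapses[, c("x", "y", "z")]),
                                  pos)))) break
      }
      edit_synapse(store, "add", position = pos[1, ], kind = "pre")
      edit_synapse(store, "add", position = pos[2, ], kind = "post")
      edit_synapse(store, "link", pre = pos[1, ], post = pos[2, ])
    }
  })
  invisible(store)
}
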