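# Shared builders for store-backed tests.

# store loaded with a Voronoi fixture in which cells `merge_ids` were falsely
# merged under the first ID; returns the store plus the ground truth
make_merged_store <- function(shape = c(32L, 32L, 32L), n_cells = 3L,
                              merge_ids = c(1L, 2L), rng_seed = 7L,
                              noise_sigma = 10, edge = 32L) {
  fx <- generate_cells(fixture_spec(shape = shape, n_cells = n_cells,
                                    noise_sigma = noise_sigma,
                                    rng_seed = rng_seed))
  fm <- make_false_merge(fx$labels, merge_ids)
  st <- body_store(edge)
  put_labels(st, fm$labels)
  put_grayscale(st, fx$gray)
  list(store = st, fx = fx, merged = fm, body = merge_ids[1])
}

with_lock <- function(store, bodies, user, expr) {
  for (b in bodies) acquire_lock(store, b, user)
  on.exit(for (b in bodies) try(release_lock(store, b, user), silent = TRUE))
  force(expr)
}

# tight box around the inter-region boundary of an unbounded split result
merging_border_box <- function(result, ctx) {
  lab <- array(0L, dim(ctx$mask))
  for (lb in names(result$regions)) {
    vox <- rle_voxels(result$regions[[lb]])
    lab[sweep(as.matrix(vox), 2, ctx$offset) + 1L] <- as.integer(lb)
  }
  d <- dim(lab)
  border <- array(FALSE, d)
  cmp <- function(a, b) a > 0 & b > 0 & a != b
  h <- cmp(lab[-d[1], , , drop = FALSE], lab[-1, , , drop = FALSE])
  border[-d[1], , ][h] <- TRUE; border[-1, , ][h] <- TRUE
  h <- cmp(lab[, -d[2], , drop = FALSE], lab[, -1, , drop = FALSE])
  border[, -d[2], ][h] <- TRUE; border[, -1, ][h] <- TRUE
  h <- cmp(lab[, , -d[3], drop = FALSE], lab[, , -1, drop = FALSE])
  border[, , -d[3]][h] <- TRUE; border[, , -1][h] <- TRUE
  vox <- which(border, arr.ind = TRUE)
  bbox(apply(vox, 2, min) - 1L + ctx$offset,
       apply(vox, 2, max) + ctx$offset)
}

# sample() treats a length-1 numeric as 1:n; this never does
pick <- function(x, n = 1) x[sample.int(length(x), n)]
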