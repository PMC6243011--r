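# Versioned block store: ingest, retrieval, grayscale fetch, merge/split,
# commit/branch, and body diffs.

test_that("label ingest and read-back are exact", {
  st <- body_store(32)
  put_labels(st, array(0L, c(32, 32, 32)))
  expect_equal(length(list_bodies(st)), 0L)

  withr::with_seed(31, lab <- array(sample(0:3, 16^3, replace = TRUE), c(16, 16, 16)))
  put_labels(st, lab)
  for (id in 1:3)
    expect_same_voxels(rle_voxels(get_body_sparse(st, id)), scan_voxels(lab == id))

  # ingest at offset (32,0,0): exactly the x-block column 1 is populated
  st2 <- body_store(32)
  put_labels(st2, array(5L, c(32, 8, 8)), offset = c(32, 0, 0))
  cov <- block_cover(get_body_sparse(st2, 5), st2$spec)
  expect_equal(as.data.frame(cov), data.frame(bz = 0L, by = 0L, bx = 1L))
})

test_that("sparse retrieval honours pyramid scales", {
  st <- body_store(32)
  lab <- array(0L, c(64, 64, 64))
  lab[] <- 9L
  put_labels(st, lab)

  one <- body_store(32)
  put_labels(one, array(c(7L, rep(0L, 7)), c(2, 2, 2)))
  r <- get_body_sparse(one, 7)
  expect_equal(as.data.frame(r$runs), data.frame(z = 0L, y = 0L, x_start = 0L,
                                                 length = 1L))

  s5 <- get_body_sparse(st, 9, scale = 5)
  g0 <- glance(get_body_sparse(st, 9, scale = 0))
  g5 <- glance(s5)
  expect_equal(g0$extent_x / g5$extent_x, 32)

  # scale-s fetch is exactly the OR-downsampling of the scale-0 fetch
  withr::with_seed(32, lab2 <- array(sample(0:2, 24^3, replace = TRUE), c(24, 24, 24)))
  st2 <- body_store(32)
  put_labels(st2, lab2)
  expect_identical(get_body_sparse(st2, 1, scale = 2)$runs,
                   downsample_mask(get_body_sparse(st2, 1, scale = 0), 2)$runs)

  expect_error(get_body_sparse(st, 12345), class = "prf_not_found_error")
})

test_that("progressive fetch refines until the size threshold", {
  st <- body_store(32)
  lab <- array(9L, c(64, 64, 64))
  put_labels(st, lab)

  # 64^3 solid body, threshold 100: scale 3 holds 8^3 = 512 > 100,
  # so the sequence is scales 5, 4, 3
  seq1 <- progressive_fetch(st, 9, size_threshold = 100)
  expect_equal(vapply(seq1, function(r) r$scale, integer(1)), c(5L, 4L, 3L))
  expect_true(rle_stats(seq1[[3]])$voxel_count > 100)
  expect_true(rle_stats(seq1[[2]])$voxel_count <= 100)

  # tiny body never exceeds a huge threshold: every scale down to 0
  st2 <- body_store(32)
  tiny <- array(0L, c(8, 8, 8)); tiny[1:2, 1:5, 1] <- 3L
  put_labels(st2, tiny)
  seq2 <- progressive_fetch(st2, 3, size_threshold = 1e6)
  expect_equal(vapply(seq2, function(r) r$scale, integer(1)), 5:0)

  # threshold 0 stops at the coarsest scale
  seq3 <- progressive_fetch(st, 9, size_threshold = 0)
  expect_equal(length(seq3), 1L)
  expect_equal(seq3[[1]]$scale, 5L)
})

test_that("grayscale fetch returns whole covering blocks verbatim", {
  st <- body_store(8)
  withr::with_seed(33, gray <- array(sample(0:255, 24^3, replace = TRUE), c(24, 24, 24)))
  lab <- array(0L, c(24, 24, 24))
  lab[2, 2, 2] <- 1L                      # 1-voxel body -> one 8^3 patch
  lab[7:10, 5, 5] <- 2L                   # straddles two x-blocks
  put_labels(st, lab)
  put_grayscale(st, gray)

  p1 <- fetch_body_grayscale(st, 1)
  expect_equal(length(p1$patches), 1L)
  expect_equal(dim(p1$patches[[1]]$data), c(8L, 8L, 8L))

  p2 <- fetch_body_grayscale(st, 2)
  expect_equal(length(p2$patches), 2L)

  # patches restricted to the body mask equal the masked dense grayscale
  ctx <- proofreadr:::body_dense_context(st, 2)
  vox <- scan_voxels(lab == 2)
  local_idx <- sweep(as.matrix(vox), 2, ctx$offset) + 1L
  expect_equal(ctx$gray[local_idx], gray[as.matrix(vox) + 1L])

  st_nog <- body_store(8)
  put_labels(st_nog, lab)
  expect_error(fetch_body_grayscale(st_nog, 1),
               class = "prf_configuration_error")
})

test_that("merge assigns the first ID to all voxels and conserves counts", {
  withr::with_seed(34, lab <- array(sample(1:4, 16^3, replace = TRUE), c(16, 16, 16)))
  st <- body_store(16)
  put_labels(st, lab)
  before <- proofreadr:::body_voxel_counts(st)
  n5 <- sum(lab %in% c(1, 3, 4))

  with_lock(st, c(1, 3, 4), "alice", {
    target <- merge_bodies(st, c(1, 3, 4), "alice")
    expect_equal(target, 1L)
  })
  expect_equal(sort(list_bodies(st)), c(1L, 2L))
  expect_equal(rle_stats(get_body_sparse(st, 1))$voxel_count, n5)
  expect_equal(sum(proofreadr:::body_voxel_counts(st)$voxel_count),
               sum(before$voxel_count))

  # union semantics
  expect_same_voxels(rle_voxels(get_body_sparse(st, 1)),
                     scan_voxels(lab == 1 | lab == 3 | lab == 4))

  with_lock(st, c(1, 2), "alice",
    expect_error(merge_bodies(st, c(1, 99), "alice"),
                 class = "prf_lock_error"))
  expect_error(merge_bodies(st, c(1, 2), "bob"), class = "prf_lock_error")
})

test_that("split keeps the original ID on the largest region", {
  m <- make_merged_store(shape = c(24, 24, 24), rng_seed = 35)
  st <- m$store
  res <- split_body(st, m$body, centroid_seeds(m$fx$labels, c(1, 2)))
  sizes <- vapply(res$regions, function(r) rle_stats(r)$voxel_count, integer(1))
  before_total <- sum(proofreadr:::body_voxel_counts(st)$voxel_count)

  mapping <- with_lock(st, m$body, "alice", apply_split(st, m$body, res, "alice"))
  largest <- names(sizes)[which.max(sizes)]
  expect_equal(unname(mapping[largest]), m$body)
  expect_equal(sum(mapping != m$body), length(sizes) - 1L)
  # conservation across the split
  expect_equal(sum(proofreadr:::body_voxel_counts(st)$voxel_count), before_total)
  # the new body has exactly the other region's voxels
  new_id <- unname(mapping[mapping != m$body])
  other <- names(mapping)[mapping != m$body]
  expect_same_voxels(rle_voxels(get_body_sparse(st, new_id)),
                     rle_voxels(res$regions[[other]]))
})

test_that("identity split allocates nothing; foreign voxels are refused", {
  m <- make_merged_store(shape = c(24, 24, 24), rng_seed = 36)
  st <- m$store
  whole <- get_body_sparse(st, m$body)
  identity_res <- proofreadr:::new_split_result(
    regions = list("1" = whole), residual = rle_volume(), dropped_seed_count = 0L)
  ids_before <- list_bodies(st)
  with_lock(st, m$body, "alice", {
    mp <- apply_split(st, m$body, identity_res, "alice")
    expect_equal(unname(mp), m$body)
  })
  expect_equal(list_bodies(st), ids_before)

  bad <- proofreadr:::new_split_result(
    regions = list("1" = whole,
                   "2" = voxels_to_rle(data.frame(x = 9999, y = 0, z = 0))),
    residual = rle_volume(), dropped_seed_count = 0L)
  with_lock(st, m$body, "alice",
    expect_error(apply_split(st, m$body, bad, "alice"),
                 class = "prf_consistency_error"))
  expect_error(apply_split(st, m$body, identity_res, "bob"),
               class = "prf_lock_error")
})

test_that("committed versions are immutable and reads fall through", {
  st <- body_store(16)
  lab <- array(0L, c(16, 16, 16)); lab[1:8, , ] <- 1L; lab[9:16, , ] <- 2L
  put_labels(st, lab)
  v1 <- commit_version(st)

  pre_mask <- rle_voxels(get_body_sparse(st, 1, version = v1))
  with_lock(st, c(1, 2), "alice", merge_bodies(st, c(1, 2), "alice"))

  # committed version still sees the pre-merge body
  expect_same_voxels(rle_voxels(get_body_sparse(st, 1, version = v1)), pre_mask)
  expect_equal(rle_stats(get_body_sparse(st, 1))$voxel_count, 16^3)
  expect_error(put_labels(st, lab, version = v1),
               class = "prf_immutability_error")

  # chain of commits: nearest-ancestor data wins
  v2 <- commit_version(st)
  patch <- array(7L, c(4, 4, 4))
  put_labels(st, patch, offset = c(0, 0, 0))
  v3 <- commit_version(st)
  expect_equal(rle_stats(get_body_sparse(st, 7, version = v3))$voxel_count, 64L)
  expect_error(get_body_sparse(st, 7, version = v2), class = "prf_not_found_error")
  expect_equal(rle_stats(get_body_sparse(st, 1, version = v2))$voxel_count, 16^3)

  # two branches from one parent diverge independently
  b1 <- branch_version(st, v1)
  put_labels(st, array(3L, c(2, 2, 2)), offset = c(0, 0, 0))
  three_b1 <- rle_stats(get_body_sparse(st, 3))$voxel_count
  b2 <- branch_version(st, v1)
  expect_error(get_body_sparse(st, 3, version = b2), class = "prf_not_found_error")
  expect_equal(rle_stats(get_body_sparse(st, 3, version = b1))$voxel_count,
               three_b1)
  expect_error(branch_version(st, "nope"), class = "prf_not_found_error")
})

test_that("body diffs partition into added/removed/unchanged", {
  st <- body_store(16)
  lab <- array(0L, c(16, 4, 4))
  lab[1:5, 1, 1] <- 1L                      # A = x in [0,5)
  put_labels(st, lab)
  va <- commit_version(st)
  lab2 <- array(0L, c(16, 4, 4))
  lab2[3:7, 1, 1] <- 1L                     # B = x in [2,7)
  put_labels(st, lab2)
  vb <- commit_version(st)

  d <- body_diff(st, va, vb, 1)
  expect_equal(sort(rle_voxels(d$removed)$x), c(0L, 1L))
  expect_equal(sort(rle_voxels(d$unchanged)$x), c(2L, 3L, 4L))
  expect_equal(sort(rle_voxels(d$added)$x), c(5L, 6L))
  expect_equal(tidy(d)$color, c("green", "red", "gray"))

  # identity diff
  d0 <- body_diff(st, vb, vb, 1)
  expect_equal(rle_stats(d0$added)$voxel_count, 0L)
  expect_equal(rle_stats(d0$removed)$voxel_count, 0L)
  expect_equal(rle_stats(d0$unchanged)$voxel_count, 5L)

  expect_error(body_diff(st, va, vb, 42), class = "prf_not_found_error")

  # random mask pair: three-way partition matches the per-voxel oracle
  withr::with_seed(37, {
    ma <- random_mask(c(10, 10, 10), 0.4)
    mb <- random_mask(c(10, 10, 10), 0.4)
  })
  st2 <- body_store(16)
  put_labels(st2, array(as.integer(ma), dim(ma)))
  va2 <- commit_version(st2)
  put_labels(st2, array(as.integer(mb), dim(mb)))
  vb2 <- commit_version(st2)
  d2 <- body_diff(st2, va2, vb2, 1)
  expect_same_voxels(rle_voxels(d2$added), scan_voxels(mb & !ma))
  expect_same_voxels(rle_voxels(d2$removed), scan_voxels(ma & !mb))
  expect_same_voxels(rle_voxels(d2$unchanged), scan_voxels(ma & mb))
  # pairwise disjoint
  all3 <- dplyr::bind_rows(rle_voxels(d2$added), rle_voxels(d2$removed),
                           rle_voxels(d2$unchanged))
  expect_equal(anyDuplicated(all3), 0L)
})

test_that("a store survives a save/load round trip", {
  m <- make_merged_store(shape = c(16, 16, 16), n_cells = 2,
                         merge_ids = c(1, 2), rng_seed = 38)
  st <- m$store
  commit_version(st)
  set_body_name(st, 1, "KC-alpha")
  set_body_status(st, 1, "hard to trace")
  edit_point_annotation(st, "todo", "add", position = c(1, 2, 3),
                        action = "to split")
  acquire_lock(st, 1, "alice")
  dir <- withr::local_tempdir()
  save_store(st, dir)
  st2 <- load_store(dir)
  expect_identical(get_body_sparse(st2, 1)$runs, get_body_sparse(st, 1)$runs)
  expect_equal(get_body_annotation(st2, 1)$status, "hard to trace")
  expect_equal(nrow(st2$ann$todos), 1L)
  expect_false(acquire_lock(st2, 1, "bob")$granted)
  expect_equal(st2$tip, st$tip)
  expect_equal(st2$next_id, st$next_id)
})
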