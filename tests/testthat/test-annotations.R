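# Workflow annotations: statuses, bookmarks, to-dos, synapses, queries,
# relabel sync, and the sequencer table.

two_body_store <- function() {
  st <- body_store(16)
  lab <- array(0L, c(16, 16, 4))
  lab[1:8, , ] <- 5L
  lab[9:16, , ] <- 9L
  put_labels(st, lab)
  st
}

test_that("exactly seven statuses are admissible", {
  expect_length(body_statuses(), 7L)
  st <- two_body_store()
  for (s in body_statuses()) {
    set_body_status(st, 5, s)
    expect_equal(get_body_annotation(st, 5)$status, s)
  }
  expect_error(set_body_status(st, 5, "done-ish"), class = "prf_validation_error")
  expect_error(set_body_status(st, 404, "traced"), class = "prf_not_found_error")
  # a fresh body reads as "not examined"
  expect_equal(get_body_annotation(st, 9)$status, "not examined")
})

test_that("bookmarks are owner-private; to-dos are shared and toggle", {
  st <- two_body_store()
  edit_point_annotation(st, "bookmark", "add", position = c(1, 1, 1),
                        type = "false merge", comment = "check", owner = "alice")
  region <- bbox(c(0, 0, 0), c(4, 4, 4))
  expect_equal(nrow(query_annotations(st, region = region, user = "alice")$bookmarks), 1L)
  expect_equal(nrow(query_annotations(st, region = region, user = "bob")$bookmarks), 0L)
  expect_equal(nrow(query_annotations(st, region = region, user = "bob",
                                      include_all = TRUE)$bookmarks), 1L)

  edit_point_annotation(st, "todo", "add", position = c(2, 2, 2),
                        action = "to merge")
  expect_equal(query_annotations(st, region = region, user = "bob")$todos$status,
               "to-do")
  edit_point_annotation(st, "todo", "set-status", position = c(2, 2, 2),
                        status = "done")
  expect_equal(query_annotations(st, region = region, user = "bob")$todos$status,
               "done")

  # move: gone at p, present at q
  edit_point_annotation(st, "todo", "move", position = c(2, 2, 2), to = c(9, 9, 3))
  expect_equal(nrow(query_annotations(st, region = region, user = "x")$todos), 0L)
  expect_equal(nrow(query_annotations(st, region = bbox(c(9, 9, 3), c(10, 10, 4)),
                                      user = "x")$todos), 1L)
  expect_error(edit_point_annotation(st, "todo", "delete", position = c(0, 0, 0)),
               class = "prf_not_found_error")
  expect_error(edit_point_annotation(st, "todo", "add", position = c(1, 1, 1),
                                     action = "to improve"),
               class = "prf_validation_error")
})

test_that("synapse edits keep links consistent", {
  st <- two_body_store()
  a <- c(1, 1, 1); b <- c(9, 1, 1)
  edit_synapse(st, "add", position = a, kind = "pre", confidence = 0.8)
  edit_synapse(st, "add", position = b, kind = "post")
  edit_synapse(st, "link", pre = a, post = b)
  expect_equal(nrow(st$ann$links), 1L)

  # wrong-kind links are refused
  edit_synapse(st, "add", position = c(2, 2, 2), kind = "pre")
  expect_error(edit_synapse(st, "link", pre = a, post = c(2, 2, 2)),
               class = "prf_validation_error")
  expect_error(edit_synapse(st, "add", position = a, kind = "pre"),
               class = "prf_validation_error")   # duplicate coordinate

  # moving an endpoint rewrites the link
  b2 <- c(9, 2, 1)
  edit_synapse(st, "move", position = b, to = b2)
  expect_equal(unlist(st$ann$links[1, c("post_x", "post_y", "post_z")],
                      use.names = FALSE), b2)

  # deleting an endpoint deletes incident links, the peer survives
  edit_synapse(st, "delete", position = a)
  expect_equal(nrow(st$ann$links), 0L)
  expect_equal(nrow(st$ann$synapses), 2L)
})

test_that("region and body queries return the right records", {
  st <- two_body_store()
  pts <- list(c(1, 1, 1), c(3, 3, 1), c(12, 1, 1))
  for (i in seq_along(pts))
    edit_synapse(st, "add", position = pts[[i]],
                 kind = if (i < 3) "pre" else "post")
  got <- query_annotations(st, region = bbox(c(0, 0, 0), c(8, 8, 4)), user = "u")
  expect_equal(nrow(got$synapses), 2L)
  expect_equal(nrow(query_annotations(st, region = bbox(c(30, 30, 0), c(40, 40, 4)),
                                      user = "u")$synapses), 0L)

  # body query follows merges: marks of an absorbed body re-associate
  expect_equal(nrow(query_annotations(st, body = 5, user = "u")$synapses), 2L)
  with_lock(st, c(5, 9), "alice", merge_bodies(st, c(5, 9), "alice"))
  expect_equal(nrow(query_annotations(st, body = 5, user = "u")$synapses), 3L)
  expect_error(query_annotations(st, region = bbox(c(0,0,0), c(1,1,1)), body = 5),
               class = "prf_validation_error")
})

test_that("relabel sync re-points body records and keeps the target's name", {
  st <- two_body_store()
  set_body_name(st, 5, "target-name")
  set_body_name(st, 9, "source-name")
  set_body_status(st, 9, "orphan")
  with_lock(st, c(5, 9), "alice", merge_bodies(st, c(5, 9), "alice"))
  ann <- get_body_annotation(st, 5)
  expect_equal(ann$name, "target-name")
  expect_match(ann$comment_log, "source-name")
  expect_equal(nrow(st$ann$body_ann), 1L)

  # mapping with no matching records counts zero updates
  expect_equal(sync_after_relabel(st, c("123" = 456L)), 0L)
  expect_equal(sync_after_relabel(st, setNames(integer(0), character(0))), 0L)
  expect_error(sync_after_relabel(st, c("5" = 9L, "9" = 5L)),
               class = "prf_validation_error")
})

test_that("todo marks inside a split region resolve to the new body", {
  m <- make_merged_store(shape = c(24, 24, 24), n_cells = 2,
                         merge_ids = c(1, 2), rng_seed = 51)
  st <- m$store
  res <- split_body(st, 1, centroid_seeds(m$fx$labels, c(1, 2)))
  # drop a todo on each region before applying
  marks <- lapply(res$regions, function(r) unlist(rle_voxels(r)[1, ]))
  for (p in marks) edit_point_annotation(st, "todo", "add", position = p)
  mapping <- with_lock(st, 1, "alice", apply_split(st, 1, res, "alice"))
  for (lb in names(mapping)) {
    got <- query_annotations(st, body = mapping[[lb]], user = "u")$todos
    expect_true(nrow(got) >= 1)
    expect_true(any(got$x == marks[[lb]]["x"] & got$y == marks[[lb]]["y"] &
                      got$z == marks[[lb]]["z"]))
  }
})

test_that("the sequencer filters by regex and sorts stably", {
  st <- body_store(16)
  lab <- array(0L, c(16, 16, 4))
  lab[1:4, , ] <- 1L; lab[5:8, , ] <- 2L; lab[9:16, , ] <- 3L
  put_labels(st, lab)
  set_body_name(st, 1, "KC-a"); set_body_name(st, 2, "KC-b")
  set_body_name(st, 3, "MBON-1")
  # synapses: 3 on body 2, 1 on body 1
  edit_synapse(st, "add", position = c(5, 1, 1), kind = "pre")
  edit_synapse(st, "add", position = c(6, 1, 1), kind = "post")
  edit_synapse(st, "add", position = c(7, 1, 1), kind = "pre")
  edit_synapse(st, "add", position = c(1, 1, 1), kind = "post")

  kc <- sequencer_query(st, filter_regex = "KC.*")
  expect_equal(sort(kc$body), c(1L, 2L))

  by_syn <- sequencer_query(st, sort_key = "synapse_count", descending = TRUE)
  expect_equal(by_syn$body[1], 2L)
  expect_equal(by_syn$synapse_count, c(3L, 1L, 0L))

  by_vox <- sequencer_query(st, sort_key = "voxel_count", descending = TRUE)
  expect_equal(by_vox$body[1], 3L)
  expect_equal(nrow(sequencer_query(st)), 3L)
  expect_error(sequencer_query(st, filter_regex = "(["),
               class = "prf_validation_error")
})

test_that("random edit sequences never leave dangling links", {
  st <- two_body_store()
  withr::with_seed(52, {
    alive <- list()
    for (i in 1:150) {
      op <- sample(c("add", "move", "delete", "link"), 1,
                   prob = c(0.4, 0.2, 0.2, 0.2))
      if (op == "add" || length(alive) == 0) {
        p <- c(sample(0:15, 1), sample(0:15, 1), sample(0:3, 1))
        if (length(proofreadr:::match_pos(st$ann$synapses, p)) == 0) {
          edit_synapse(st, "add", position = p,
                       kind = sample(c("pre", "post"), 1))
          alive[[length(alive) + 1]] <- p
        }
      } else if (op == "move") {
        j <- sample(length(alive), 1)
        q <- c(sample(0:15, 1), sample(0:15, 1), sample(0:3, 1))
        if (length(proofreadr:::match_pos(st$ann$synapses, q)) == 0) {
          edit_synapse(st, "move", position = alive[[j]], to = q)
          alive[[j]] <- q
        }
      } else if (op == "delete") {
        j <- sample(length(alive), 1)
        edit_synapse(st, "delete", position = alive[[j]])
        alive[[j]] <- NULL
      } else {
        syn <- st$ann$synapses
        pres <- syn[syn$kind == "pre", ]; posts <- syn[syn$kind == "post", ]
        if (nrow(pres) > 0 && nrow(posts) > 0) {
          edit_synapse(st, "link",
                       pre = unlist(pres[sample(nrow(pres), 1), c("x", "y", "z")]),
                       post = unlist(posts[sample(nrow(posts), 1), c("x", "y", "z")]))
        }
      }
      # invariant: every link endpoint is an existing element of the right kind
      lk <- st$ann$links
      if (nrow(lk) > 0) {
        for (r in seq_len(nrow(lk))) {
          ip <- proofreadr:::match_pos(st$ann$synapses,
                                       unlist(lk[r, c("pre_x", "pre_y", "pre_z")]))
          io <- proofreadr:::match_pos(st$ann$synapses,
                                       unlist(lk[r, c("post_x", "post_y", "post_z")]))
          expect_length(ip, 1L)
          expect_length(io, 1L)
        }
      }
    }
  })
})
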