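# Workflow annotations: body status/name records, owner-scoped bookmarks,
# shared to-do marks, synapse elements with directed pre->post links, and the
# sequencer body table.
#
# Point annotations are keyed by position and associated with a body by
# resolving that position against the current label volume at query time, so
# merges and splits never leave a mark pointing at a stale location.
# Body-keyed records (name/status) are rewritten explicitly when IDs retire.

#' The seven admissible body statuses
#'
#' @return Character vector of the pre-defined proofreading statuses.
#' @export
body_statuses <- function() {
  c("not examined", "traced", "traced in ROI", "partially traced",
    "orphan", "hard to trace", "finalized")
}

new_annotation_tables <- function() {
  a <- new.env(parent = emptyenv())
  a$body_ann <- tibble(body = integer(), name = character(),
                       status = character(), comment_log = character())
  a$bookmarks <- tibble(x = integer(), y = integer(), z = integer(),
                        type = character(), comment = character(),
                        owner = character())
  a$todos <- tibble(x = integer(), y = integer(), z = integer(),
                    status = character(), action = character())
  a$synapses <- tibble(x = integer(), y = integer(), z = integer(),
                       kind = character(), confidence = double(),
                       verified = logical())
  a$links <- tibble(pre_x = integer(), pre_y = integer(), pre_z = integer(),
                    post_x = integer(), post_y = integer(), post_z = integer())
  a
}

assert_body_exists <- function(store, body) {
  if (!(as.integer(body) %in% list_bodies(store)))
    stop_not_found(sprintf("unknown body ID: %d", as.integer(body)))
}

#' Annotate a body with a status or a name
#'
#' A body has at most one annotation record; the status must be one of the
#' seven values in [body_statuses()] (fresh bodies read as "not examined").
#'
#' @param store A `prf_store`.
#' @param body Body ID (must exist).
#' @param status One of [body_statuses()].
#' @param name Free text, ideally a biologically meaningful neuron name.
#' @export
set_body_status <- function(store, body, status) {
  stopifnot(inherits(store, "prf_store"))
  if (!(status %in% body_statuses()))
    stop_validation(sprintf("'%s' is not one of the %d admissible statuses",
                            status, length(body_statuses())))
  assert_body_exists(store, body)
  upsert_body_ann(store, as.integer(body), status = status)
}

#' @rdname set_body_status
#' @export
set_body_name <- function(store, body, name) {
  stopifnot(inherits(store, "prf_store"))
  assert_body_exists(store, body)
  upsert_body_ann(store, as.integer(body), name = as.character(name))
}

upsert_body_ann <- function(store, body, status = NULL, name = NULL) {
  a <- store$ann
  i <- which(a$body_ann$body == body)
  if (length(i) == 0) {
    a$body_ann <- dplyr::bind_rows(
      a$body_ann,
      tibble(body = body, name = NA_character_, status = "not examined",
             comment_log = ""))
    i <- nrow(a$body_ann)
  }
  if (!is.null(status)) a$body_ann$status[i] <- status
  if (!is.null(name)) a$body_ann$name[i] <- name
  invisible(store)
}

#' Read one body's annotation record
#'
#' @param store A `prf_store`.
#' @param body Body ID.
#' @return One-row tibble (`body`, `name`, `status`, `comment_log`); a body
#'   never annotated reads as status "not examined".
#' @export
get_body_annotation <- function(store, body) {
  a <- store$ann
  i <- which(a$body_ann$body == as.integer(body))
  if (length(i) == 0)
    return(tibble(body = as.integer(body), name = NA_character_,
                  status = "not examined", comment_log = ""))
  a$body_ann[i, ]
}

match_pos <- function(tbl, pos) {
  which(tbl$x == pos[1] & tbl$y == pos[2] & tbl$z == pos[3])
}

#' Add, move, delete or re-status a point annotation
#'
#' Bookmarks are private to their owner (`type` such as "false merge" plus a
#' free comment); to-do marks are shared reviewing marks with status "to-do"
#' or "done" and, while pending, an action hint "to merge"/"to split"/"none".
#'
#' @param store A `prf_store`.
#' @param kind `"bookmark"` or `"todo"`.
#' @param verb `"add"`, `"move"`, `"delete"`, or (todos) `"set-status"`.
#' @param position Coordinate `c(x, y, z)` of the annotation.
#' @param to Target coordinate for `"move"`.
#' @param type,comment,owner Bookmark fields.
#' @param status,action To-do fields (`status` in to-do/done).
#' @export
edit_point_annotation <- function(store, kind = c("bookmark", "todo"),
                                  verb = c("add", "move", "delete", "set-status"),
                                  position, to = NULL, type = "", comment = "",
                                  owner = "", status = "to-do", action = "none") {
  stopifnot(inherits(store, "prf_store"))
  kind <- match.arg(kind)
  verb <- match.arg(verb)
  pos <- as_voxel_coord(position, "position")
  a <- store$ann
  if (kind == "bookmark") {
    i <- match_pos(a$bookmarks, pos)
    switch(verb,
      add = {
        a$bookmarks <- dplyr::bind_rows(
          a$bookmarks, tibble(x = pos[1], y = pos[2], z = pos[3], type = type,
                              comment = comment, owner = owner))
      },
      move = {
        if (length(i) == 0) stop_not_found("no bookmark at source position")
        to <- as_voxel_coord(to, "target position")
        a$bookmarks$x[i] <- to[1]; a$bookmarks$y[i] <- to[2]; a$bookmarks$z[i] <- to[3]
      },
      delete = {
        if (length(i) == 0) stop_not_found("no bookmark at position")
        a$bookmarks <- a$bookmarks[-i, ]
      },
      `set-status` = stop_validation("bookmarks have no status"))
  } else {
    i <- match_pos(a$todos, pos)
    switch(verb,
      add = {
        if (!(status %in% c("to-do", "done"))) stop_validation("to-do status must be to-do or done")
        if (!(action %in% c("none", "to merge", "to split")))
          stop_validation("to-do action must be none, to merge or to split")
        a$todos <- dplyr::bind_rows(
          a$todos, tibble(x = pos[1], y = pos[2], z = pos[3],
                          status = status, action = action))
      },
      move = {
        if (length(i) == 0) stop_not_found("no to-do mark at source position")
        to <- as_voxel_coord(to, "target position")
        a$todos$x[i] <- to[1]; a$todos$y[i] <- to[2]; a$todos$z[i] <- to[3]
      },
      delete = {
        if (length(i) == 0) stop_not_found("no to-do mark at position")
        a$todos <- a$todos[-i, ]
      },
      `set-status` = {
        if (length(i) == 0) stop_not_found("no to-do mark at position")
        if (!(status %in% c("to-do", "done"))) stop_validation("to-do status must be to-do or done")
        a$todos$status[i] <- status
      })
  }
  invisible(store)
}

#' Edit synaptic elements and their directed links
#'
#' A synapse is a pre-synaptic and a post-synaptic element joined by a
#' directed pre -> post link. At most one element per exact coordinate.
#' Moving an element rewrites every incident link endpoint; deleting an
#' element deletes its incident links, so links never dangle.
#'
#' @param store A `prf_store`.
#' @param verb `"add"`, `"move"`, `"delete"`, `"link"`, or `"unlink"`.
#' @param position Element coordinate (`add`/`move`/`delete`).
#' @param to Target coordinate (`move`).
#' @param kind `"pre"` or `"post"` (`add`).
#' @param confidence,verified Element attributes (`add`).
#' @param pre,post Link endpoints (`link`/`unlink`): coordinates of an
#'   existing pre-kind and post-kind element.
#' @export
edit_synapse <- function(store, verb = c("add", "move", "delete", "link", "unlink"),
                         position = NULL, to = NULL, kind = c("pre", "post"),
                         confidence = 1, verified = FALSE,
                         pre = NULL, post = NULL) {
  stopifnot(inherits(store, "prf_store"))
  verb <- match.arg(verb)
  a <- store$ann
  if (verb %in% c("add", "move", "delete")) {
    pos <- as_voxel_coord(position, "position")
    i <- match_pos(a$synapses, pos)
    if (verb == "add") {
      kind <- match.arg(kind)
      if (length(i) > 0) stop_validation("an element already exists at this position")
      if (confidence < 0 || confidence > 1) stop_validation("confidence must be in [0, 1]")
      a$synapses <- dplyr::bind_rows(
        a$synapses, tibble(x = pos[1], y = pos[2], z = pos[3], kind = kind,
                           confidence = as.numeric(confidence),
                           verified = isTRUE(verified)))
    } else if (verb == "move") {
      if (length(i) == 0) stop_not_found("no synaptic element at source position")
      to <- as_voxel_coord(to, "target position")
      if (length(match_pos(a$synapses, to)) > 0)
        stop_validation("an element already exists at the target position")
      a$synapses$x[i] <- to[1]; a$synapses$y[i] <- to[2]; a$synapses$z[i] <- to[3]
      ip <- which(a$links$pre_x == pos[1] & a$links$pre_y == pos[2] & a$links$pre_z == pos[3])
      a$links$pre_x[ip] <- to[1]; a$links$pre_y[ip] <- to[2]; a$links$pre_z[ip] <- to[3]
      io <- which(a$links$post_x == pos[1] & a$links$post_y == pos[2] & a$links$post_z == pos[3])
      a$links$post_x[io] <- to[1]; a$links$post_y[io] <- to[2]; a$links$post_z[io] <- to[3]
    } else {
      if (length(i) == 0) stop_not_found("no synaptic element at position")
      a$synapses <- a$synapses[-i, ]
      drop <- (a$links$pre_x == pos[1] & a$links$pre_y == pos[2] & a$links$pre_z == pos[3]) |
        (a$links$post_x == pos[1] & a$links$post_y == pos[2] & a$links$post_z == pos[3])
      a$links <- a$links[!drop, ]
    }
  } else {
    pre <- as_voxel_coord(pre, "pre position")
    post <- as_voxel_coord(post, "post position")
    ip <- match_pos(a$synapses, pre)
    io <- match_pos(a$synapses, post)
    if (length(ip) == 0 || length(io) == 0)
      stop_not_found("link endpoints must be existing synaptic elements")
    if (a$synapses$kind[ip] != "pre" || a$synapses$kind[io] != "post")
      stop_validation("links are directed pre -> post: endpoints have wrong kinds")
    exists <- any(a$links$pre_x == pre[1] & a$links$pre_y == pre[2] &
                  a$links$pre_z == pre[3] & a$links$post_x == post[1] &
                  a$links$post_y == post[2] & a$links$post_z == post[3])
    if (verb == "link") {
      if (!exists)
        a$links <- dplyr::bind_rows(
          a$links, tibble(pre_x = pre[1], pre_y = pre[2], pre_z = pre[3],
                          post_x = post[1], post_y = post[2], post_z = post[3]))
    } else {
      if (!exists) stop_not_found("no such link")
      keep <- !(a$links$pre_x == pre[1] & a$links$pre_y == pre[2] &
                a$links$pre_z == pre[3] & a$links$post_x == post[1] &
                a$links$post_y == post[2] & a$links$post_z == post[3])
      a$links <- a$links[keep, ]
    }
  }
  invisible(store)
}

#' Query annotations by region or by body
#'
#' Coordinate queries return records whose position lies in `region`
#' (half-open box); body queries resolve each record's position against the
#' current label volume and return those on `body`. Bookmarks are filtered to
#' the requesting user's own unless `include_all` (admin tooling) is set.
#'
#' @param store A `prf_store`.
#' @param region Optional `prf_bbox`.
#' @param body Optional body ID (exactly one of `region`/`body`).
#' @param user Requesting user (bookmark visibility).
#' @param include_all Return all users' bookmarks.
#' @return Named list of tibbles: `bookmarks`, `todos`, `synapses`.
#' @export
query_annotations <- function(store, region = NULL, body = NULL, user = "",
                              include_all = FALSE) {
  stopifnot(inherits(store, "prf_store"))
  if (is.null(region) == is.null(body))
    stop_validation("supply exactly one of region or body")
  a <- store$ann
  pick <- function(tbl) {
    if (nrow(tbl) == 0) return(tbl)
    if (!is.null(region)) {
      tbl[bbox_contains(region, tbl), ]
    } else {
      tbl[label_at(store, tbl) == as.integer(body), ]
    }
  }
  bm <- pick(a$bookmarks)
  if (!include_all && nrow(bm) > 0) bm <- bm[bm$owner == user, ]
  list(bookmarks = bm, todos = pick(a$todos), synapses = pick(a$synapses))
}

#' Re-point body-keyed annotations after merge/split
#'
#' Invoked by the store's merge/split hooks with a retired-ID -> target-ID
#' mapping: every body annotation referencing a retired ID is folded into the
#' target's record. On a name conflict the target's record wins and the
#' source name is appended to the target's comment log. Position-keyed marks
#' need no rewrite — they resolve at query time.
#'
#' @param store A `prf_store`.
#' @param mapping Named integer vector, names = retired IDs, values = targets.
#' @return Number of records updated, invisibly.
#' @export
sync_after_relabel <- function(store, mapping) {
  stopifnot(inherits(store, "prf_store"))
  if (length(mapping) == 0) return(invisible(0L))
  retired <- as.integer(names(mapping))
  targets <- as.integer(mapping)
  if (any(targets %in% retired))
    stop_validation("relabel mapping must not contain cycles (target is retired)")
  a <- store$ann
  n <- 0L
  for (k in seq_along(retired)) {
    i <- which(a$body_ann$body == retired[k])
    if (length(i) == 0) next
    j <- which(a$body_ann$body == targets[k])
    if (length(j) == 0) {
      a$body_ann$body[i] <- targets[k]
    } else {
      src <- a$body_ann[i, ]
      if (!is.na(src$name) && nzchar(src$name))
        a$body_ann$comment_log[j] <- paste0(
          a$body_ann$comment_log[j],
          sprintf("[merged name from %d: %s]", retired[k], src$name))
      a$body_ann <- a$body_ann[-i, ]
    }
    n <- n + 1L
  }
  invisible(n)
}

#' Sequencer: a filterable, sortable table of annotated bodies
#'
#' @param store A `prf_store`.
#' @param filter_regex Optional regular expression applied to body names.
#' @param sort_key One of `"synapse_count"`, `"voxel_count"`, `"name"`,
#'   `"status"`.
#' @param descending Sort direction (stable sort).
#' @return Tibble with `body`, `name`, `status`, `voxel_count`,
#'   `synapse_count`.
#' @export
sequencer_query <- function(store, filter_regex = NULL,
                            sort_key = c("synapse_count", "voxel_count",
                                         "name", "status"),
                            descending = TRUE) {
  stopifnot(inherits(store, "prf_store"))
  sort_key <- match.arg(sort_key)
  a <- store$ann
  tbl <- a$body_ann[, c("body", "name", "status")]
  if (!is.null(filter_regex)) {
    ok <- tryCatch(suppressWarnings(grepl(filter_regex, tbl$name)),
                   error = function(e) stop_validation(
                     sprintf("invalid regular expression: %s", filter_regex)))
    tbl <- tbl[!is.na(tbl$name) & ok, ]
  }
  counts <- body_voxel_counts(store)
  tbl <- dplyr::left_join(tbl, counts, by = "body")
  tbl$voxel_count[is.na(tbl$voxel_count)] <- 0L
  syn <- store$ann$synapses
  syn_body <- if (nrow(syn) > 0) label_at(store, syn) else integer()
  tbl$synapse_count <- vapply(tbl$body, function(b) sum(syn_body == b), integer(1))
  ord <- order(tbl[[sort_key]], decreasing = descending, method = "radix")
  tbl[ord, ]
}
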