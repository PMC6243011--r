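# On-disk form of a store: one directory holding meta.json, the annotation
# tables and lock table as JSON, and one file per version layer (its blocks).
# The layout is this package's own; serving data over a network is out of
# scope.

#' Save / load a body store directory
#'
#' @param store A `prf_store`.
#' @param dir Directory path (created if missing).
#' @return `save_store()` returns `dir` invisibly; `load_store()` a
#'   `prf_store`.
#' @export
save_store <- function(store, dir) {
  stopifnot(inherits(store, "prf_store"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vids <- ls(store$versions)
  meta <- list(block_edge = store$spec$edge, max_scale = store$max_scale,
               tip = store$tip, next_id = store$next_id,
               version_counter = store$version_counter, has_gray = store$has_gray,
               versions = lapply(setNames(vids, vids), function(v) {
                 e <- store$versions[[v]]
                 list(parent = e$parent, committed = e$committed)
               }))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       null = "null", na = "null")
  for (v in vids)
    saveRDS(as.list(store$versions[[v]]$blocks),
            file.path(dir, paste0("layer-", v, ".rds")))
  saveRDS(as.list(store$gray), file.path(dir, "grayscale.rds"))
  ann <- store$ann
  jsonlite::write_json(
    list(body_ann = ann$body_ann, bookmarks = ann$bookmarks, todos = ann$todos,
         synapses = ann$synapses, links = ann$links,
         locks = lapply(as.list(store$locks), function(l)
           list(holder = l$holder, acquired_at = format(l$acquired_at)))),
    file.path(dir, "annotations.json"), dataframe = "columns", na = "null")
  invisible(dir)
}

#' @rdname save_store
#' @export
load_store <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  store <- body_store(meta$block_edge, meta$max_scale)
  store$tip <- meta$tip
  store$next_id <- as.integer(meta$next_id)
  store$version_counter <- as.integer(meta$version_counter)
  store$has_gray <- isTRUE(meta$has_gray)
  rm(list = ls(store$versions), envir = store$versions)
  for (v in names(meta$versions)) {
    blocks <- new.env(parent = emptyenv())
    lst <- readRDS(file.path(dir, paste0("layer-", v, ".rds")))
    for (k in names(lst)) blocks[[k]] <- lst[[k]]
    parent <- meta$versions[[v]]$parent
    store$versions[[v]] <- list(
      parent = if (is.null(parent) || is.na(parent)) NA_character_ else parent,
      blocks = blocks, committed = isTRUE(meta$versions[[v]]$committed))
  }
  glist <- readRDS(file.path(dir, "grayscale.rds"))
  for (k in names(glist)) store$gray[[k]] <- glist[[k]]
  ann_raw <- jsonlite::read_json(file.path(dir, "annotations.json"),
                                 simplifyVector = TRUE)
  restore_tbl <- function(raw, template) {
    if (is.null(raw) || length(raw) == 0 ||
        (is.data.frame(raw) && nrow(raw) == 0)) return(template)
    out <- as_tibble(raw)
    for (cn in names(template)) {
      t <- template[[cn]]
      out[[cn]] <- if (is.integer(t)) as.integer(out[[cn]])
        else if (is.logical(t)) as.logical(out[[cn]])
        else if (is.numeric(t)) as.numeric(out[[cn]])
        else as.character(out[[cn]])
    }
    out[, names(template)]
  }
  a <- store$ann
  a$body_ann <- restore_tbl(ann_raw$body_ann, a$body_ann)
  a$bookmarks <- restore_tbl(ann_raw$bookmarks, a$bookmarks)
  a$todos <- restore_tbl(ann_raw$todos, a$todos)
  a$synapses <- restore_tbl(ann_raw$synapses, a$synapses)
  a$links <- restore_tbl(ann_raw$links, a$links)
  for (k in names(ann_raw$locks))
    store$locks[[k]] <- list(holder = ann_raw$locks[[k]]$holder,
                             acquired_at = as.POSIXct(ann_raw$locks[[k]]$acquired_at))
  store
}
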