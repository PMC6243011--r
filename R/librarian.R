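# Lock-based multi-user coordination.
#
# Every body carries at most one exclusive edit lock at a time. A client must
# acquire the lock before any mutating operation; a second client asking for a
# held body is denied (a value, not an error) and performs no mutation. Locks
# live until released — there is no lease expiry.

#' Acquire an exclusive edit lock on a body
#'
#' Granting is re-entrant: a user who already holds the lock is granted again.
#' Denial is returned as a value so callers can retry or move on.
#'
#' @param store A `prf_store` (the lock table lives with the store).
#' @param body Body ID to lock.
#' @param user Requesting user name.
#' @return List with `granted` (logical) and `holder` (current holder).
#' @export
#' @examples
#' st <- body_store()
#' acquire_lock(st, 7, "alice")$granted
#' acquire_lock(st, 7, "bob")           # denied, holder "alice"
acquire_lock <- function(store, body, user) {
  stopifnot(inherits(store, "prf_store"))
  key <- as.character(as.integer(body))
  cur <- store$locks[[key]]
  if (is.null(cur) || identical(cur$holder, user)) {
    store$locks[[key]] <- list(holder = user, acquired_at = Sys.time())
    return(list(granted = TRUE, holder = user))
  }
  list(granted = FALSE, holder = cur$holder)
}

#' Release a lock
#'
#' Only the holder may release; releasing an unlocked body or someone else's
#' lock raises an ownership (lock) error and leaves the table unchanged.
#'
#' @inheritParams acquire_lock
#' @export
release_lock <- function(store, body, user) {
  stopifnot(inherits(store, "prf_store"))
  key <- as.character(as.integer(body))
  cur <- store$locks[[key]]
  if (is.null(cur) || !identical(cur$holder, user))
    stop_lock(sprintf("user '%s' does not hold the lock on body %s", user, key))
  rm(list = key, envir = store$locks)
  invisible(TRUE)
}

#' Guard a mutation behind the lock table
#'
#' Called by every mutating store operation before touching voxels: passes
#' silently iff `user` holds the lock on every listed body, otherwise raises
#' a lock error — the refused mutation must leave the store unchanged.
#'
#' @param store A `prf_store`.
#' @param bodies One or more body IDs the mutation touches.
#' @param user Acting user.
#' @export
guard <- function(store, bodies, user) {
  stopifnot(inherits(store, "prf_store"))
  for (b in as.integer(bodies)) {
    cur <- store$locks[[as.character(b)]]
    if (is.null(cur) || !identical(cur$holder, user))
      stop_lock(sprintf("body %d is not locked by user '%s'", b, user))
  }
  invisible(TRUE)
}

#' Snapshot of the lock table
#'
#' @param store A `prf_store`.
#' @return Tibble with columns `body`, `holder`, `acquired_at`.
#' @export
lock_status <- function(store) {
  stopifnot(inherits(store, "prf_store"))
  keys <- ls(store$locks)
  if (length(keys) == 0)
    return(tibble(body = integer(), holder = character(),
                  acquired_at = as.POSIXct(character())))
  dplyr::arrange(dplyr::bind_rows(lapply(keys, function(k) {
    e <- store$locks[[k]]
    tibble(body = as.integer(k), holder = e$holder, acquired_at = e$acquired_at)
  })), .data$body)
}
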