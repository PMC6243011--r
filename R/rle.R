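# Run-length-encoded sparse volumes.
#
# A body mask is stored as foreground voxels only, run-length encoded along x.
# The run table is a tibble with integer columns (z, y, x_start, length),
# sorted lexicographically by (z, y, x_start); runs with the same (z, y) are
# disjoint and maximal (never adjacent). Coordinates are global: there is no
# separate offset field.

#' Construct an RLE sparse volume from a run table
#'
#' Normalises the run table: sorts by `(z, y, x_start)` and fuses overlapping
#' or adjacent runs so the stored form is canonical. An empty run table is a
#' valid (empty) body.
#'
#' @param runs Tibble/data frame with integer columns `z`, `y`, `x_start`,
#'   `length` (`length >= 1`).
#' @param scale Non-negative pyramid level; level `s` is downsampled by `2^s`
#'   per axis relative to level 0.
#' @param body_id Optional positive body ID this mask belongs to.
#' @return A `prf_rle` object.
#' @export
rle_volume <- function(runs = NULL, scale = 0L, body_id = NA_integer_) {
  if (is.null(runs) || nrow(runs) == 0) {
    runs <- tibble(z = integer(), y = integer(), x_start = integer(),
                   length = integer())
  } else {
    runs <- as_tibble(runs)[, c("z", "y", "x_start", "length")]
    runs <- dplyr::mutate(runs, dplyr::across(dplyr::everything(), as.integer))
    if (any(runs$length < 1L)) stop_validation("run lengths must be >= 1")
    runs <- normalize_runs(runs)
  }
  scale <- as.integer(scale)
  if (is.na(scale) || scale < 0L) stop_validation("scale must be a non-negative integer")
  structure(list(runs = runs, scale = scale, body_id = as.integer(body_id)),
            class = "prf_rle")
}

# Sort and fuse: classic interval merge per (z, y) row, fully vectorised.
normalize_runs <- function(runs) {
  runs <- dplyr::arrange(runs, .data$z, .data$y, .data$x_start)
  if (nrow(runs) < 2) return(runs)
  end <- runs$x_start + runs$length
  new_row <- c(TRUE, runs$z[-1] != runs$z[-nrow(runs)] |
                     runs$y[-1] != runs$y[-nrow(runs)])
  # running max of end within each (z,y) row, lagged: a run starts a new
  # fused interval iff it is a new row or starts beyond everything seen so far
  grp_end <- end
  idx <- seq_len(nrow(runs))
  row_id <- cumsum(new_row)
  cmax <- stats::ave(end, row_id, FUN = cummax)
  lag_cmax <- c(0L, cmax[-length(cmax)])
  starts_interval <- new_row | runs$x_start > lag_cmax
  int_id <- cumsum(starts_interval)
  out <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(runs, .end = end, .int = int_id), .data$.int),
    z = .data$z[1], y = .data$y[1],
    x_start = min(.data$x_start), .max_end = max(.data$.end),
    .groups = "drop")
  tibble(z = out$z, y = out$y, x_start = out$x_start,
         length = out$.max_end - out$x_start)
}

#' @export
print.prf_rle <- function(x, ...) {
  s <- rle_stats(x)
  cat(sprintf("<rle volume: %d voxels in %d runs, scale %d%s>\n",
              s$voxel_count, nrow(x$runs), x$scale,
              if (is.na(x$body_id)) "" else sprintf(", body %d", x$body_id)))
  invisible(x)
}

#' Encode a dense binary mask as an RLE sparse volume
#'
#' @param mask 3D array (logical or numeric; non-zero is foreground) with
#'   `dim = c(nx, ny, nz)`, x fastest.
#' @param offset Global coordinate `c(x, y, z)` of `mask[1, 1, 1]`.
#' @inheritParams rle_volume
#' @return A `prf_rle` whose decoded voxel set is exactly the foreground of
#'   `mask`, with maximal sorted runs.
#' @export
#' @examples
#' m <- array(FALSE, c(6, 1, 1)); m[3:5, 1, 1] <- TRUE
#' rle_encode(m)$runs
rle_encode <- function(mask, offset = c(0L, 0L, 0L), scale = 0L,
                       body_id = NA_integer_) {
  d <- dim(mask)
  if (is.null(d) || length(d) != 3)
    stop_dimensionality("mask must be a 3D array")
  offset <- as_voxel_coord(offset, "offset")
  idx <- which(mask != 0)
  if (length(idx) == 0) return(rle_volume(NULL, scale, body_id))
  nx <- d[1]
  col <- (idx - 1L) %/% nx              # column = y + ny*z, constant within an x-run
  brk <- diff(idx) != 1L | diff(col) != 0L
  starts <- c(1L, which(brk) + 1L)
  ends <- c(which(brk), length(idx))
  i0 <- idx[starts] - 1L
  x <- i0 %% nx
  y <- (i0 %/% nx) %% d[2]
  z <- i0 %/% (nx * d[2])
  runs <- tibble(z = as.integer(z + offset[3]),
                 y = as.integer(y + offset[2]),
                 x_start = as.integer(x + offset[1]),
                 length = as.integer(ends - starts + 1L))
  rle_volume(runs, scale, body_id)
}

#' Decode an RLE sparse volume to a dense mask
#'
#' @param rle A `prf_rle`.
#' @param box Optional `prf_bbox` to decode into; defaults to the tight
#'   bounding box. Foreground outside `box` is clipped silently.
#' @return List with `mask` (logical 3D array, `dim = c(nx, ny, nz)`) and
#'   `offset` (global coordinate of `mask[1, 1, 1]`, the box min).
#' @export
rle_decode <- function(rle, box = NULL) {
  stopifnot(inherits(rle, "prf_rle"))
  if (is.null(box)) box <- rle_stats(rle)$bbox
  d <- bbox_dims(box)
  m <- array(FALSE, dim = pmax(d, 0L))
  r <- rle$runs
  if (nrow(r) > 0 && !bbox_is_empty(box)) {
    keep <- r$z >= box$min[3] & r$z < box$max[3] &
            r$y >= box$min[2] & r$y < box$max[2] &
            r$x_start + r$length > box$min[1] & r$x_start < box$max[1]
    r <- r[keep, ]
    if (nrow(r) > 0) {
      x0 <- pmax(r$x_start, box$min[1]) - box$min[1]
      x1 <- pmin(r$x_start + r$length, box$max[1]) - box$min[1]   # exclusive
      len <- x1 - x0
      base <- (r$z - box$min[3]) * d[1] * d[2] + (r$y - box$min[2]) * d[1] + x0
      lin <- sequence(len, from = base + 1L)
      m[lin] <- TRUE
    }
  }
  list(mask = m, offset = box$min)
}

#' Voxel count and tight bounding box of an RLE volume
#'
#' @param rle A `prf_rle`.
#' @return List with `voxel_count` and `bbox` (empty box for an empty volume).
#' @export
rle_stats <- function(rle) {
  stopifnot(inherits(rle, "prf_rle"))
  r <- rle$runs
  if (nrow(r) == 0) return(list(voxel_count = 0L, bbox = empty_bbox()))
  list(voxel_count = sum(r$length),
       bbox = bbox(c(min(r$x_start), min(r$y), min(r$z)),
                   c(max(r$x_start + r$length), max(r$y) + 1L, max(r$z) + 1L)))
}

#' Expand an RLE volume to a voxel table
#'
#' @param rle A `prf_rle`.
#' @return Tibble with integer columns `x`, `y`, `z`, one row per foreground
#'   voxel, in run order.
#' @export
rle_voxels <- function(rle) {
  r <- rle$runs
  if (nrow(r) == 0) return(tibble(x = integer(), y = integer(), z = integer()))
  tibble(x = as.integer(sequence(r$length, from = r$x_start)),
         y = rep(r$y, r$length),
         z = rep(r$z, r$length))
}

#' Build an RLE volume from a voxel table
#'
#' @param xyz Data frame with integer columns `x`, `y`, `z` (duplicates
#'   allowed; they collapse).
#' @inheritParams rle_volume
#' @return A `prf_rle`.
#' @export
voxels_to_rle <- function(xyz, scale = 0L, body_id = NA_integer_) {
  if (nrow(xyz) == 0) return(rle_volume(NULL, scale, body_id))
  xyz <- dplyr::arrange(dplyr::distinct(as_tibble(xyz)[, c("x", "y", "z")]),
                        .data$z, .data$y, .data$x)
  brk <- diff(xyz$x) != 1L | diff(xyz$y) != 0L | diff(xyz$z) != 0L
  starts <- c(1L, which(brk) + 1L)
  ends <- c(which(brk), nrow(xyz))
  rle_volume(tibble(z = xyz$z[starts], y = xyz$y[starts],
                    x_start = xyz$x[starts],
                    length = as.integer(ends - starts + 1L)),
             scale, body_id)
}

# Set algebra on same-scale volumes, used by body diffs and the split engine.
rle_setdiff <- function(a, b) {
  voxels_to_rle(dplyr::anti_join(rle_voxels(a), rle_voxels(b),
                                 by = c("x", "y", "z")), scale = a$scale)
}

rle_intersect <- function(a, b) {
  voxels_to_rle(dplyr::inner_join(rle_voxels(a), rle_voxels(b),
                                  by = c("x", "y", "z")), scale = a$scale)
}

rle_union <- function(a, b) {
  voxels_to_rle(dplyr::bind_rows(rle_voxels(a), rle_voxels(b)), scale = a$scale)
}

#' Tidy a sparse volume into its run table
#'
#' @param x A `prf_rle`.
#' @param ... Unused.
#' @return The run tibble with `scale` and `body_id` columns appended.
#' @export
tidy.prf_rle <- function(x, ...) {
  dplyr::mutate(x$runs, scale = x$scale, body_id = x$body_id)
}

#' One-row summary of a sparse volume
#'
#' @inheritParams tidy.prf_rle
#' @return Tibble with voxel count, run count, scale and bounding-box extents.
#' @export
glance.prf_rle <- function(x, ...) {
  s <- rle_stats(x)
  d <- bbox_dims(s$bbox)
  tibble(voxel_count = s$voxel_count, n_runs = nrow(x$runs), scale = x$scale,
         extent_x = d[1], extent_y = d[2], extent_z = d[3])
}

#' Plot a z-projection of a sparse volume
#'
#' @param object A `prf_rle`.
#' @param ... Unused.
#' @return A ggplot raster of the xy projection (voxel counts along z).
#' @export
autoplot.prf_rle <- function(object, ...) {
  v <- rle_voxels(object)
  df <- dplyr::count(v, .data$x, .data$y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$n)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(name = "voxels") +
    ggplot2::labs(x = "x", y = "y",
                  title = sprintf("body %s, scale %d",
                                  ifelse(is.na(object$body_id), "?", object$body_id),
                                  object$scale))
}
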