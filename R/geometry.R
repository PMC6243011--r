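# Coordinates and axis-aligned boxes.
#
# A coordinate is an integer vector c(x, y, z), 0-based.  Boxes are half-open:
# `min` is inclusive, `max` exclusive, so widths are simply max - min and a box
# is empty iff min == max on any axis.  Dense arrays use dim = c(nx, ny, nz)
# with x the fastest-varying axis, i.e. arr[x + 1, y + 1, z + 1] addresses
# global voxel offset + (x, y, z).

as_coord <- function(p, what = "coordinate") {
  p <- as.numeric(p)
  if (length(p) != 3 || any(!is.finite(p)))
    stop_validation(sprintf("%s must be three finite numbers", what))
  p
}

as_voxel_coord <- function(p, what = "coordinate") {
  p <- as_coord(p, what)
  if (any(p != floor(p)))
    stop_validation(sprintf("%s must be integer voxel indices", what))
  as.integer(p)
}

#' Construct a half-open bounding box
#'
#' Boxes are `[min, max)` on every axis: `min` is the first voxel inside the
#' box and `max` the first voxel beyond it. A box is empty when `min == max`
#' on any axis.
#'
#' @param min,max Integer coordinates `c(x, y, z)`; `min <= max` axis-wise.
#' @return A `prf_bbox` object.
#' @export
#' @examples
#' bbox(c(0, 0, 0), c(32, 32, 32))
bbox <- function(min, max) {
  min <- as_voxel_coord(min, "box min")
  max <- as_voxel_coord(max, "box max")
  if (any(max < min)) stop_validation("box max must be >= min on every axis")
  structure(list(min = min, max = max), class = "prf_bbox")
}

empty_bbox <- function() bbox(c(0L, 0L, 0L), c(0L, 0L, 0L))

bbox_is_empty <- function(b) any(b$max == b$min)

bbox_dims <- function(b) b$max - b$min

bbox_volume <- function(b) prod(as.numeric(bbox_dims(b)))

bbox_contains <- function(b, xyz) {
  # xyz: matrix/tibble with columns x,y,z
  xyz <- as.matrix(xyz[, c("x", "y", "z")])
  xyz[, 1] >= b$min[1] & xyz[, 1] < b$max[1] &
    xyz[, 2] >= b$min[2] & xyz[, 2] < b$max[2] &
    xyz[, 3] >= b$min[3] & xyz[, 3] < b$max[3]
}

bbox_intersect <- function(a, b) {
  lo <- pmax(a$min, b$min)
  hi <- pmin(a$max, b$max)
  if (any(hi < lo)) return(empty_bbox())
  bbox(lo, hi)
}

bbox_union <- function(a, b) {
  if (bbox_is_empty(a)) return(b)
  if (bbox_is_empty(b)) return(a)
  bbox(pmin(a$min, b$min), pmax(a$max, b$max))
}

bbox_dilate <- function(b, margin) {
  margin <- as.integer(margin)
  if (bbox_is_empty(b)) return(b)
  bbox(b$min - margin, b$max + margin)
}

#' @export
print.prf_bbox <- function(x, ...) {
  if (bbox_is_empty(x)) {
    cat("<bbox: empty>\n")
  } else {
    cat(sprintf("<bbox [%s) x [%s) x [%s)>\n",
                paste(c(x$min[1], x$max[1]), collapse = ", "),
                paste(c(x$min[2], x$max[2]), collapse = ", "),
                paste(c(x$min[3], x$max[3]), collapse = ", ")))
  }
  invisible(x)
}

#' Block geometry
#'
#' Storage and retrieval operate on fixed-size cubic blocks; the conventional
#' edge is 32 voxels (64 for some datasets). Edges must be powers of two so
#' block boundaries nest across pyramid scales.
#'
#' @param edge Voxels per block side; a power of two. Default 32.
#' @return A `prf_block_spec` object.
#' @export
block_spec <- function(edge = 32L) {
  edge <- as.integer(edge)
  if (length(edge) != 1 || is.na(edge) || edge < 1 || bitwAnd(edge, edge - 1L) != 0L)
    stop_validation("block edge must be a positive power of two")
  structure(list(edge = edge), class = "prf_block_spec")
}
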