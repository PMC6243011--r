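# Multi-scale pyramid and block arithmetic, computed on the run table
# directly — no dense intermediate.

#' Downsample a binary sparse volume by factor-2 levels
#'
#' Each level halves every axis. A coarse voxel is foreground iff *any* of its
#' `2^levels`-cubed children is foreground (OR pooling), which preserves thin
#' branches in coarse-scale previews; coordinates are floor-divided by
#' `2^levels`.
#'
#' @param rle A `prf_rle`.
#' @param levels Number of pyramid levels to descend (`>= 1`).
#' @return A `prf_rle` at `scale = rle$scale + levels`.
#' @export
#' @examples
#' v <- voxels_to_rle(data.frame(x = 5, y = 3, z = 1))
#' downsample_mask(v, 1)$runs   # single voxel at (2, 1, 0)
downsample_mask <- function(rle, levels) {
  stopifnot(inherits(rle, "prf_rle"))
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 1L) stop_validation("levels must be >= 1")
  f <- 2L^levels
  r <- rle$runs
  if (nrow(r) == 0) return(rle_volume(NULL, rle$scale + levels, rle$body_id))
  x0 <- fdiv(r$x_start, f)
  x1 <- fdiv(r$x_start + r$length - 1L, f)
  rle_volume(tibble(z = fdiv(r$z, f), y = fdiv(r$y, f),
                    x_start = x0, length = x1 - x0 + 1L),
             scale = rle$scale + levels, body_id = rle$body_id)
}

# floor division that is correct for negative coordinates too
fdiv <- function(a, b) as.integer(floor(a / b))

#' Blocks touched by a sparse volume
#'
#' Block index on each axis is `floor(coordinate / edge)`.
#'
#' @param rle A `prf_rle` (any scale; indices are in that scale's grid).
#' @param spec A [block_spec()].
#' @return Tibble with integer columns `bz`, `by`, `bx`, sorted and
#'   deduplicated: every listed block contains at least one foreground voxel
#'   and together they cover all of them.
#' @export
block_cover <- function(rle, spec = block_spec()) {
  stopifnot(inherits(rle, "prf_rle"), inherits(spec, "prf_block_spec"))
  e <- spec$edge
  r <- rle$runs
  if (nrow(r) == 0) return(tibble(bz = integer(), by = integer(), bx = integer()))
  b0 <- fdiv(r$x_start, e)
  b1 <- fdiv(r$x_start + r$length - 1L, e)
  n <- b1 - b0 + 1L
  out <- tibble(bz = rep(fdiv(r$z, e), n), by = rep(fdiv(r$y, e), n),
                bx = as.integer(sequence(n, from = b0)))
  dplyr::arrange(dplyr::distinct(out), .data$bz, .data$by, .data$bx)
}

#' Extract the surface voxels of a body
#'
#' A surface voxel is a foreground voxel with at least one background
#' 6-neighbour — the tight one-voxel shell used to render a body as a cloud
#' of spheres without meshing it.
#'
#' @param rle A `prf_rle`.
#' @param radius Display radius attached to the point set (voxels).
#' @return A `prf_surface`: list with `points` (tibble `x`, `y`, `z`) and
#'   `radius`.
#' @export
extract_surface_points <- function(rle, radius = 1) {
  stopifnot(inherits(rle, "prf_rle"))
  if (radius <= 0) stop_validation("radius must be positive")
  s <- rle_stats(rle)
  if (s$voxel_count == 0L)
    return(structure(list(points = tibble(x = integer(), y = integer(), z = integer()),
                          radius = radius), class = "prf_surface"))
  # decode with a 1-voxel pad so border voxels see background neighbours
  box <- bbox_dilate(s$bbox, 1L)
  m <- rle_decode(rle, box)$mask
  d <- dim(m)
  ix <- 2:(d[1] - 1); iy <- 2:(d[2] - 1); iz <- 2:(d[3] - 1)
  core <- m[ix, iy, iz, drop = FALSE]
  interior <- core &
    m[ix - 1, iy, iz, drop = FALSE] & m[ix + 1, iy, iz, drop = FALSE] &
    m[ix, iy - 1, iz, drop = FALSE] & m[ix, iy + 1, iz, drop = FALSE] &
    m[ix, iy, iz - 1, drop = FALSE] & m[ix, iy, iz + 1, drop = FALSE]
  surf <- core & !interior
  idx <- which(surf) - 1L
  nx <- d[1] - 2L; ny <- d[2] - 2L
  structure(list(points = tibble(x = as.integer(idx %% nx + s$bbox$min[1]),
                                 y = as.integer((idx %/% nx) %% ny + s$bbox$min[2]),
                                 z = as.integer(idx %/% (nx * ny) + s$bbox$min[3])),
                 radius = radius),
            class = "prf_surface")
}

#' @export
print.prf_surface <- function(x, ...) {
  cat(sprintf("<surface point set: %d points, radius %g>\n",
              nrow(x$points), x$radius))
  invisible(x)
}
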