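# False-merge correction: seeded-watershed splitting of one body, with
# optional bounded computation + connected-component reattachment, local
# preview, ray-shot 3D seeding, and a coarse pre-pass for giant bodies.

#' Split configuration
#'
#' @param bounding_box Optional `prf_bbox`: restrict the watershed to this box
#'   and re-attach outside pieces by connected-component analysis. Exact
#'   whenever the box contains the whole merging border.
#' @param preview_margin Margin (voxels) around the seed bounding box used by
#'   [local_preview()].
#' @param invert_intensity Flood bright voxels first (default `TRUE`; EM
#'   membranes are dark).
#' @param bbox_budget Bounding-box voxel budget above which the split runs on
#'   a `2^k`-downsampled copy first and full-resolution voxels inherit their
#'   parent coarse voxel's region (default `1e9`).
#' @return A `prf_split_config`. Flood and component connectivity is fixed at
#'   6 to prevent leaks through voxel corners.
#' @export
split_config <- function(bounding_box = NULL, preview_margin = 0L,
                         invert_intensity = TRUE, bbox_budget = 1e9) {
  if (!is.null(bounding_box)) stopifnot(inherits(bounding_box, "prf_bbox"))
  if (preview_margin < 0) stop_validation("preview_margin must be >= 0")
  if (bbox_budget < 1) stop_validation("bbox_budget must be positive")
  structure(list(connectivity = 6L, bounding_box = bounding_box,
                 preview_margin = as.integer(preview_margin),
                 invert_intensity = isTRUE(invert_intensity),
                 bbox_budget = bbox_budget),
            class = "prf_split_config")
}

new_split_result <- function(regions, residual, dropped_seed_count) {
  structure(list(regions = regions, residual = residual,
                 dropped_seed_count = as.integer(dropped_seed_count)),
            class = "prf_split_result")
}

#' @export
print.prf_split_result <- function(x, ...) {
  sizes <- vapply(x$regions, function(r) rle_stats(r)$voxel_count, integer(1))
  cat(sprintf("<split result: %d region(s) [%s], residual %d voxels, %d seed(s) dropped>\n",
              length(x$regions), paste(sizes, collapse = ", "),
              rle_stats(x$residual)$voxel_count, x$dropped_seed_count))
  invisible(x)
}

#' Tidy a split result into one row per region
#'
#' @param x A `prf_split_result`.
#' @param ... Unused.
#' @return Tibble with `label` and `voxel_count` (plus a residual row).
#' @export
tidy.prf_split_result <- function(x, ...) {
  dplyr::bind_rows(
    tibble(label = names(x$regions),
           voxel_count = vapply(x$regions, function(r) rle_stats(r)$voxel_count,
                                integer(1))),
    tibble(label = "residual",
           voxel_count = rle_stats(x$residual)$voxel_count))
}

#' One-row summary of a split result
#'
#' @inheritParams tidy.prf_split_result
#' @export
glance.prf_split_result <- function(x, ...) {
  tibble(n_regions = length(x$regions),
         region_voxels = sum(vapply(x$regions,
                                    function(r) rle_stats(r)$voxel_count,
                                    integer(1))),
         residual_voxels = rle_stats(x$residual)$voxel_count,
         dropped_seeds = x$dropped_seed_count)
}

#' Plot the mid-slice of a split result
#'
#' @param object A `prf_split_result`.
#' @param ... Unused.
#' @return A ggplot raster of the z mid-slice, one colour per region.
#' @export
autoplot.prf_split_result <- function(object, ...) {
  df <- dplyr::bind_rows(c(
    lapply(names(object$regions), function(lb)
      dplyr::mutate(rle_voxels(object$regions[[lb]]), region = lb)),
    list(dplyr::mutate(rle_voxels(object$residual), region = "residual"))))
  zmid <- stats::median(df$z)
  df <- df[df$z == zmid, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$region)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("split result, slice z = %d", zmid))
}

# --- shared plumbing ---------------------------------------------------------

# Localize seeds against (mask, offset): drop off-array / off-mask seeds,
# normalize labels to 1..k. Returns list(seeds (local coords), k, dropped).
prepare_seeds <- function(seeds, mask, offset) {
  seeds <- as_seed_set(seeds)
  d <- dim(mask)
  loc <- dplyr::mutate(as_tibble(seeds),
                       x = .data$x - offset[1], y = .data$y - offset[2],
                       z = .data$z - offset[3])
  inside <- loc$x >= 0 & loc$x < d[1] & loc$y >= 0 & loc$y < d[2] &
    loc$z >= 0 & loc$z < d[3]
  keep <- inside
  keep[inside] <- mask[cbind(loc$x[inside] + 1L, loc$y[inside] + 1L,
                             loc$z[inside] + 1L)] != 0
  dropped <- sum(!keep)
  if (dropped > 0) warn(sprintf("%d seed(s) outside the body were ignored", dropped))
  norm <- normalize_seed_labels(loc[keep, ])
  list(seeds = norm$seeds, k = norm$k, dropped = dropped,
       label_map = norm$label_map)
}

# named list "1".."k" of prf_rle regions from a dense label array
regions_from_labels <- function(lab, offset, k) {
  out <- list()
  for (lb in seq_len(k))
    out[[as.character(lb)]] <- rle_encode(lab == lb, offset = offset)
  out
}

# watershed on mask restricted to a (local-coordinate, half-open) box
flood_in_box <- function(gray, mask, seeds_local, box_local, invert = TRUE) {
  idx_mask <- array(FALSE, dim(mask))
  rng <- lapply(1:3, function(a) (box_local$min[a] + 1L):(box_local$max[a]))
  idx_mask[rng[[1]], rng[[2]], rng[[3]]] <- TRUE
  m_in <- mask & idx_mask
  seeds <- seed_set(seeds_local$x, seeds_local$y, seeds_local$z,
                    seeds_local$label)
  seeded_watershed(gray, m_in, seeds, offset = c(0L, 0L, 0L),
                   invert_intensity = invert)
}

# --- operations --------------------------------------------------------------

#' Bounded split with component reattachment
#'
#' Runs the watershed only on `mask` inside `box`; each 6-connected component
#' of the mask outside the box is then attached to the in-box region it
#' touches across the box face. A component touching several regions goes to
#' the one with the largest contact-voxel count (ties: smallest label); a
#' component touching none goes to the residual. The result equals the
#' unbounded split whenever `box` contains the entire merging border.
#'
#' @param gray,mask Dense congruent 3D arrays (intensities / body foreground).
#' @param seeds A `prf_seed_set` (global coordinates); all surviving seeds
#'   must lie inside `box`.
#' @param box A `prf_bbox` in global coordinates.
#' @param offset Global coordinate of `gray[1, 1, 1]`.
#' @param invert_intensity See [split_config()].
#' @param attach Attach outside components (set `FALSE` for previews).
#' @return A `prf_split_result` (regions in global coordinates).
#' @export
bounded_split <- function(gray, mask, seeds, box, offset = c(0L, 0L, 0L),
                          invert_intensity = TRUE, attach = TRUE) {
  if (!identical(dim(gray), dim(mask)))
    stop_dimensionality("grayscale and mask shapes differ")
  offset <- as_voxel_coord(offset, "offset")
  d <- dim(mask)
  prep <- prepare_seeds(seeds, mask, offset)
  if (prep$k < 2)
    stop_seeds("fewer than two distinct seed labels survive inside the mask")
  box_local <- bbox_intersect(bbox(box$min - offset, box$max - offset),
                              bbox(c(0L, 0L, 0L), d))
  if (bbox_is_empty(box_local)) stop_validation("box does not intersect the volume")
  s <- prep$seeds
  in_box <- s$x >= box_local$min[1] & s$x < box_local$max[1] &
    s$y >= box_local$min[2] & s$y < box_local$max[2] &
    s$z >= box_local$min[3] & s$z < box_local$max[3]
  if (!all(in_box))
    stop_validation("all surviving seeds must lie inside the bounding box")
  lab <- flood_in_box(gray, mask, s, box_local, invert_intensity)
  if (attach) {
    outside <- mask != 0
    rng <- lapply(1:3, function(a) (box_local$min[a] + 1L):(box_local$max[a]))
    outside[rng[[1]], rng[[2]], rng[[3]]] <- FALSE
    comp <- label_components(outside)
    n_comp <- max(comp)
    if (n_comp > 0) {
      assignment <- component_attachment(comp, n_comp, lab, d)
      for (ci in seq_len(n_comp))
        if (assignment[ci] > 0L) lab[comp == ci] <- assignment[ci]
    }
  }
  residual <- rle_encode(mask != 0 & lab == 0L, offset = offset)
  new_split_result(regions_from_labels(lab, offset, prep$k), residual,
                   prep$dropped)
}

# contact-based attachment: for each outside component, tally 6-adjacent
# region-labelled voxels; 0 = no contact (residual)
component_attachment <- function(comp, n_comp, lab, d) {
  cv <- which(comp > 0)
  i0 <- cv - 1L
  x <- i0 %% d[1]; y <- (i0 %/% d[1]) %% d[2]; z <- i0 %/% (d[1] * d[2])
  tally <- list()
  shifts <- rbind(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
                  c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))
  for (si in seq_len(nrow(shifts))) {
    nxp <- x + shifts[si, 1]; nyp <- y + shifts[si, 2]; nzp <- z + shifts[si, 3]
    ok <- nxp >= 0 & nxp < d[1] & nyp >= 0 & nyp < d[2] & nzp >= 0 & nzp < d[3]
    if (!any(ok)) next
    nlin <- nzp[ok] * d[1] * d[2] + nyp[ok] * d[1] + nxp[ok] + 1L
    nl <- lab[nlin]
    hit <- nl > 0L
    if (!any(hit)) next
    tally[[length(tally) + 1L]] <- tibble(comp = comp[cv[ok]][hit],
                                          region = nl[hit])
  }
  assignment <- integer(n_comp)
  if (length(tally) > 0) {
    t <- dplyr::count(dplyr::bind_rows(tally), .data$comp, .data$region)
    t <- dplyr::arrange(t, .data$comp, dplyr::desc(.data$n), .data$region)
    best <- t[!duplicated(t$comp), ]
    assignment[best$comp] <- best$region
  }
  assignment
}

#' Local preview of a split around the seeds
#'
#' Equivalent to [bounded_split()] with the box set to the tight bounding box
#' of the surviving seeds dilated by `margin`, except that pieces outside the
#' box are *not* attached — they all stay in the residual. Intended for a
#' fast look at the cut before committing to the full computation.
#'
#' @inheritParams bounded_split
#' @param margin Non-negative dilation of the seed bounding box (voxels).
#' @return A `prf_split_result` whose regions are confined to the preview box.
#' @export
local_preview <- function(gray, mask, seeds, margin = 0L,
                          offset = c(0L, 0L, 0L), invert_intensity = TRUE) {
  if (margin < 0) stop_validation("margin must be >= 0")
  offset <- as_voxel_coord(offset, "offset")
  prep <- prepare_seeds(seeds, mask, offset)
  if (prep$k < 2)
    stop_seeds("fewer than two distinct seed labels survive inside the mask")
  s <- prep$seeds
  sb <- bbox_dilate(bbox(c(min(s$x), min(s$y), min(s$z)),
                         c(max(s$x) + 1L, max(s$y) + 1L, max(s$z) + 1L)),
                    as.integer(margin))
  box_global <- bbox(sb$min + offset, sb$max + offset)
  bounded_split(gray, mask, seeds, box_global, offset = offset,
                invert_intensity = invert_intensity, attach = FALSE)
}

#' Split one stored body with painted seeds
#'
#' Fetches the body's scale-0 sparse mask and its block-aligned grayscale
#' context, then floods each 6-connected component of the body independently
#' with the seeds falling on it. Regions carrying the same seed label across
#' components are joined into one output region; components carrying no seed
#' go to the residual and stay with the origin body when the result is
#' persisted with [apply_split()]. With `config$bounding_box` set, the
#' computation is bounded and outside pieces are re-attached (see
#' [bounded_split()]); bodies whose bounding box exceeds `config$bbox_budget`
#' voxels are split on a downsampled copy first.
#'
#' @param store A `prf_store` with a grayscale companion.
#' @param body Body ID to split.
#' @param seeds A `prf_seed_set` in global coordinates.
#' @param config A [split_config()].
#' @return A `prf_split_result` in global coordinates, regions keyed by
#'   normalized seed label.
#' @export
split_body <- function(store, body, seeds, config = split_config()) {
  stopifnot(inherits(store, "prf_store"), inherits(config, "prf_split_config"))
  ctx <- body_dense_context(store, body)
  d <- dim(ctx$mask)
  if (prod(as.numeric(d)) > config$bbox_budget && is.null(config$bounding_box))
    return(split_body_downsampled(ctx, seeds, config))
  if (!is.null(config$bounding_box)) {
    bounded_split(ctx$gray, ctx$mask, seeds, config$bounding_box,
                  offset = ctx$offset,
                  invert_intensity = config$invert_intensity)
  } else {
    prep <- prepare_seeds(seeds, ctx$mask, ctx$offset)
    if (prep$k < 2)
      stop_seeds("fewer than two distinct seed labels survive inside the body")
    s <- prep$seeds
    lab <- seeded_watershed(ctx$gray, ctx$mask,
                            seed_set(s$x, s$y, s$z, s$label),
                            offset = c(0L, 0L, 0L),
                            invert_intensity = config$invert_intensity)
    residual <- rle_encode(ctx$mask != 0 & lab == 0L, offset = ctx$offset)
    new_split_result(regions_from_labels(lab, ctx$offset, prep$k), residual,
                     prep$dropped)
  }
}

# coarse pre-pass for giant bodies: flood a 2^k-downsampled copy, then let
# every full-resolution voxel inherit its parent coarse voxel's region
split_body_downsampled <- function(ctx, seeds, config) {
  d <- dim(ctx$mask)
  k <- 0L
  while (prod(as.numeric(ceiling(d / 2^k))) > config$bbox_budget) k <- k + 1L
  f <- 2L^k
  cm <- pool3(ctx$mask != 0, f, any)
  cnt <- pool3(array(as.integer(ctx$mask != 0), d), f, sum)
  gsum <- pool3(array(as.integer(ctx$gray) * as.integer(ctx$mask != 0), d), f, sum)
  cg <- array(0L, dim(cm))
  nz <- cnt > 0
  cg[nz] <- as.integer(round(gsum[nz] / cnt[nz]))
  seeds <- as_seed_set(seeds)
  cs <- dplyr::distinct(dplyr::mutate(
    as_tibble(seeds),
    x = fdiv(.data$x - ctx$offset[1], f), y = fdiv(.data$y - ctx$offset[2], f),
    z = fdiv(.data$z - ctx$offset[3], f)))
  prep <- prepare_seeds(seed_set(cs$x, cs$y, cs$z, cs$label), cm, c(0L, 0L, 0L))
  if (prep$k < 2)
    stop_seeds("fewer than two distinct seed labels survive inside the body")
  s <- prep$seeds
  lab_c <- seeded_watershed(cg, cm, seed_set(s$x, s$y, s$z, s$label),
                            invert_intensity = config$invert_intensity)
  # full-resolution voxels inherit the coarse assignment
  vox <- rle_voxels(ctx$rle)
  cx <- fdiv(vox$x - ctx$offset[1], f); cy <- fdiv(vox$y - ctx$offset[2], f)
  cz <- fdiv(vox$z - ctx$offset[3], f)
  vl <- lab_c[cbind(cx + 1L, cy + 1L, cz + 1L)]
  regions <- list()
  for (lb in seq_len(prep$k))
    regions[[as.character(lb)]] <- voxels_to_rle(vox[vl == lb, ])
  residual <- voxels_to_rle(vox[vl == 0L, ])
  new_split_result(regions, residual, prep$dropped)
}

# factor-f pooling of a 3D array (pads up to a multiple of f)
pool3 <- function(a, f, fun) {
  d <- dim(a)
  dc <- as.integer(ceiling(d / f))
  pad <- array(vector(typeof(a), 1), dc * f)
  pad[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- a
  dim(pad) <- c(f, dc[1], f, dc[2], f, dc[3])
  apply(pad, c(2, 4, 6), fun)
}

#' Generate seeds by shooting a ray through a body
#'
#' Emulates painting a single stroke in a 3D view: the ray is traversed voxel
#' by voxel (3D DDA); every body-foreground voxel between the first and the
#' last hit becomes a seed with the given label. Gaps where the ray crosses
#' background inside the body's extent are skipped.
#'
#' @param body_mask A `prf_rle` body mask.
#' @param origin Real 3-vector, ray origin in global coordinates (may lie
#'   outside the body).
#' @param direction Non-zero real 3-vector.
#' @param label Seed label for every generated seed.
#' @return A `prf_seed_set`; empty when the ray misses the body.
#' @export
ray_seeds <- function(body_mask, origin, direction, label = 1L) {
  stopifnot(inherits(body_mask, "prf_rle"))
  direction <- as.numeric(direction)
  if (length(direction) != 3 || all(direction == 0) || any(!is.finite(direction)))
    stop_validation("direction must be a non-zero 3-vector")
  origin <- as_coord(origin, "origin")
  s <- rle_stats(body_mask)
  if (s$voxel_count == 0L) return(seed_set())
  box <- s$bbox
  vox <- ray_voxels(origin, direction, box)
  if (nrow(vox) == 0) return(seed_set())
  dec <- rle_decode(body_mask, box)
  fg <- dec$mask[cbind(vox$x - box$min[1] + 1L, vox$y - box$min[2] + 1L,
                       vox$z - box$min[3] + 1L)]
  hits <- which(fg)
  if (length(hits) == 0) return(seed_set())
  span <- seq(min(hits), max(hits))
  keep <- span[fg[span]]
  seed_set(vox$x[keep], vox$y[keep], vox$z[keep], rep(label, length(keep)))
}

# Amanatides & Woo voxel traversal of a half-open box; returns the voxels the
# ray passes through, in order
ray_voxels <- function(origin, direction, box) {
  dirn <- direction / sqrt(sum(direction^2))
  t0 <- 0; t1 <- Inf
  for (a in 1:3) {
    if (dirn[a] == 0) {
      if (origin[a] < box$min[a] || origin[a] >= box$max[a])
        return(tibble(x = integer(), y = integer(), z = integer()))
    } else {
      ta <- (box$min[a] - origin[a]) / dirn[a]
      tb <- (box$max[a] - origin[a]) / dirn[a]
      t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
    }
  }
  if (t1 <= t0) return(tibble(x = integer(), y = integer(), z = integer()))
  eps <- 1e-9
  p <- origin + (t0 + eps) * dirn
  v <- floor(p)
  step <- sign(dirn)
  t_max <- rep(Inf, 3); t_delta <- rep(Inf, 3)
  for (a in 1:3) {
    if (dirn[a] != 0) {
      nxt <- if (step[a] > 0) v[a] + 1 else v[a]
      t_max[a] <- t0 + eps + (nxt - p[a]) / dirn[a]
      t_delta[a] <- abs(1 / dirn[a])
    }
  }
  xs <- integer(); ys <- integer(); zs <- integer()
  t <- t0
  while (all(v >= box$min - 1) && all(v <= box$max) && t <= t1 + eps) {
    if (all(v >= box$min) && all(v < box$max)) {
      xs <- c(xs, v[1]); ys <- c(ys, v[2]); zs <- c(zs, v[3])
    }
    a <- which.min(t_max)
    t <- t_max[a]
    v[a] <- v[a] + step[a]
    t_max[a] <- t_max[a] + t_delta[a]
  }
  tibble(x = as.integer(xs), y = as.integer(ys), z = as.integer(zs))
}
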