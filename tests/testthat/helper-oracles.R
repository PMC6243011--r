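# Independent reference implementations used as oracles. These deliberately
# avoid the package's own code paths: per-voxel scans, dense pooling, and a
# naive pure-R priority flood.

# per-voxel scan of a dense mask -> sorted voxel data frame (global coords)
scan_voxels <- function(mask, offset = c(0L, 0L, 0L)) {
  d <- dim(mask)
  idx <- which(mask != 0) - 1L
  df <- data.frame(x = idx %% d[1] + offset[1],
                   y = (idx %/% d[1]) %% d[2] + offset[2],
                   z = idx %/% (d[1] * d[2]) + offset[3])
  df[order(df$z, df$y, df$x), , drop = FALSE]
}

sorted_vox <- function(df) {
  df <- as.data.frame(df)[, c("x", "y", "z")]
  rownames(df) <- NULL
  df[order(df$z, df$y, df$x), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

expect_same_voxels <- function(a, b) {
  expect_equal(unname(as.matrix(sorted_vox(a))), unname(as.matrix(sorted_vox(b))))
}

random_mask <- function(d, p = 0.4) array(runif(prod(d)) < p, d)

# dense OR pooling by factor f (naive triple loop over coarse voxels)
or_pool_dense <- function(mask, f) {
  d <- dim(mask)
  dc <- ceiling(d / f)
  out <- array(FALSE, dc)
  for (cz in seq_len(dc[3])) for (cy in seq_len(dc[2])) for (cx in seq_len(dc[1])) {
    xs <- ((cx - 1) * f + 1):min(cx * f, d[1])
    ys <- ((cy - 1) * f + 1):min(cy * f, d[2])
    zs <- ((cz - 1) * f + 1):min(cz * f, d[3])
    out[cx, cy, cz] <- any(mask[xs, ys, zs])
  }
  out
}

# erosion-difference surface oracle: foreground voxels with any background
# 6-neighbour, computed per voxel
surface_oracle <- function(mask) {
  d <- dim(mask)
  vox <- which(mask != 0, arr.ind = TRUE)
  keep <- logical(nrow(vox))
  shifts <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                  c(0, 0, -1), c(0, 0, 1))
  for (i in seq_len(nrow(vox))) {
    for (s in seq_len(6)) {
      n <- vox[i, ] + shifts[s, ]
      if (any(n < 1) || any(n > d) || !mask[n[1], n[2], n[3]]) {
        keep[i] <- TRUE
        break
      }
    }
  }
  data.frame(x = vox[keep, 1] - 1L, y = vox[keep, 2] - 1L, z = vox[keep, 3] - 1L)
}

# Naive pure-R water-level flood, the independent reference for the
# watershed: priority = 255 - intensity; seeds claim their voxels up front in
# list order; a voxel is claimed at level max(parent level, own priority);
# within one level the flood advances in synchronous waves and simultaneous
# proposals for a voxel are resolved by seed rank (earlier seed wins).
naive_flood <- function(gray, mask, seeds) {
  d <- dim(gray)
  n <- prod(d)
  pri <- pmin(pmax(255L - as.integer(gray), 0L), 255L)
  msk <- as.logical(mask != 0)
  lab <- integer(n)
  rnk <- rep(-1L, n)
  buckets <- vector("list", 256)
  add <- function(lv, df) buckets[[lv + 1L]] <<- rbind(buckets[[lv + 1L]], df)
  for (i in seq_len(nrow(seeds))) {
    v <- seeds$z[i] * d[1] * d[2] + seeds$y[i] * d[1] + seeds$x[i] + 1L
    if (v < 1 || v > n || !msk[v] || lab[v] != 0L) next
    lab[v] <- seeds$label[i]
    rnk[v] <- i - 1L
    add(pri[v], data.frame(v = v, label = seeds$label[i], rank = i - 1L))
  }
  # 6-neighbour proposals for a set of expanding voxels, vectorised
  propose <- function(vs, labs, rnks) {
    i0 <- vs - 1L
    x <- i0 %% d[1]; y <- (i0 %/% d[1]) %% d[2]; z <- i0 %/% (d[1] * d[2])
    shifts <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                    c(0, 0, -1), c(0, 0, 1))
    out <- NULL
    for (s in seq_len(6)) {
      nx <- x + shifts[s, 1]; ny <- y + shifts[s, 2]; nz <- z + shifts[s, 3]
      ok <- nx >= 0 & nx < d[1] & ny >= 0 & ny < d[2] & nz >= 0 & nz < d[3]
      if (!any(ok)) next
      w <- nz[ok] * d[1] * d[2] + ny[ok] * d[1] + nx[ok] + 1L
      keep <- msk[w] & lab[w] == 0L
      if (any(keep))
        out <- rbind(out, data.frame(v = w[keep], label = labs[ok][keep],
                                     rank = rnks[ok][keep]))
    }
    out
  }
  for (level in 0:255) {
    cur <- buckets[[level + 1L]]
    while (!is.null(cur) && nrow(cur) > 0) {
      self <- lab[cur$v] != 0L & rnk[cur$v] == cur$rank & lab[cur$v] == cur$label
      open <- lab[cur$v] == 0L
      expand <- cur[self, , drop = FALSE]
      props <- cur[open, , drop = FALSE]
      if (nrow(props) > 0) {
        props <- props[order(props$rank), , drop = FALSE]
        props <- props[!duplicated(props$v), , drop = FALSE]
        lab[props$v] <- props$label
        rnk[props$v] <- props$rank
        expand <- rbind(expand, props)
      }
      nxt <- NULL
      if (nrow(expand) > 0) {
        pp <- propose(expand$v, expand$label, expand$rank)
        if (!is.null(pp)) {
          p <- pri[pp$v]
          same <- p <= level
          if (any(same)) nxt <- pp[same, , drop = FALSE]
          for (lv in unique(p[!same])) add(lv, pp[!same & p == lv, , drop = FALSE])
        }
      }
      cur <- nxt
    }
  }
  array(lab, d)
}

# one random watershed instance: grayscale, mask, and >= 2 surviving seeds
random_ws_instance <- function(max_edge = 12L) {
  d <- sample(3:max_edge, 3, replace = TRUE)
  gray <- array(sample(0:255, prod(d), replace = TRUE), d)
  mask <- random_mask(d, p = runif(1, 0.4, 0.9))
  fg <- which(mask) - 1L
  if (length(fg) < 4) return(NULL)
  k <- sample(2:4, 1)
  pick <- sample(fg, min(length(fg), k * 2))
  seeds <- data.frame(x = pick %% d[1], y = (pick %/% d[1]) %% d[2],
                      z = pick %/% (d[1] * d[2]),
                      label = rep_len(seq_len(k), length(pick)))
  if (length(unique(seeds$label)) < 2) return(NULL)
  list(gray = gray, mask = mask, seeds = seeds)
}

# voxel agreement of a two-or-more-way split against ground-truth labels;
# regions are matched to truth cells in seed order (region i <-> cell ids[i])
split_agreement <- function(result, truth_labels, ids) {
  num <- 0L; den <- 0L
  for (i in seq_along(ids)) {
    vox <- rle_voxels(result$regions[[as.character(i)]])
    if (nrow(vox) == 0) next
    num <- num + sum(truth_labels[as.matrix(vox) + 1L] == ids[i])
    den <- den + nrow(vox)
  }
  den <- den + rle_stats(result$residual)$voxel_count
  num / den
}

# deterministic hash of everything readable at every committed version + tip
store_state_hash <- function(store) {
  vids <- sort(ls(store$versions))
  payload <- lapply(vids, function(v) {
    keys <- sort(proofreadr:::visible_keys(store, v))
    lapply(keys, function(k) proofreadr:::read_block(store, k, v))
  })
  rlang::hash(list(payload, as.list(store$ann$body_ann),
                   store$ann$bookmarks, store$ann$todos,
                   store$ann$synapses, store$ann$links))
}
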