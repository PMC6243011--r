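# Seed sets for the split engine.

#' Construct a seed set
#'
#' Seeds are labelled points painted on the body to be split: voxels carrying
#' the same label end up in the same split region. Coordinates are global.
#'
#' @param x,y,z Integer coordinate vectors (recycled to a common length).
#' @param label Positive integer labels, parallel to the coordinates.
#' @return A `prf_seed_set` (tibble with columns `x`, `y`, `z`, `label`).
#' @export
seed_set <- function(x = integer(), y = integer(), z = integer(),
                     label = integer()) {
  s <- tibble(x = as.integer(x), y = as.integer(y), z = as.integer(z),
              label = as.integer(label))
  if (nrow(s) > 0 && (any(is.na(s$label)) || any(s$label < 1L)))
    stop_validation("seed labels must be positive integers")
  class(s) <- c("prf_seed_set", class(s))
  s
}

as_seed_set <- function(s) {
  if (inherits(s, "prf_seed_set")) return(s)
  seed_set(s$x, s$y, s$z, s$label)
}

# map labels to contiguous 1..k preserving order of first appearance of the
# sorted unique values; returns list(seeds, k, label_map) where label_map is
# named original -> normalized
normalize_seed_labels <- function(seeds) {
  u <- sort(unique(seeds$label))
  map <- setNames(seq_along(u), u)
  seeds$label <- as.integer(map[as.character(seeds$label)])
  list(seeds = seeds, k = length(u), label_map = map)
}

#' Read / write seed files
#'
#' Seed files are JSON arrays of `{"x":..,"y":..,"z":..,"label":..}` records.
#'
#' @param seeds A `prf_seed_set`.
#' @param path File path.
#' @export
write_seeds_json <- function(seeds, path) {
  seeds <- as_seed_set(seeds)
  jsonlite::write_json(as.data.frame(seeds[, c("x", "y", "z", "label")]),
                       path, dataframe = "rows")
  invisible(path)
}

#' @rdname write_seeds_json
#' @export
read_seeds_json <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(df) == 0) return(seed_set())
  seed_set(df$x, df$y, df$z, df$label)
}
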