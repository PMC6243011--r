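# On-disk forms of a sparse volume.
#
# Binary form (the CLI's native exchange format; little-endian):
#   magic "PRLE" (4 bytes), scale (uint32), run count (uint32),
#   then each run as four signed int32: z, y, x_start, length.
# This layout is this package's own; it is not wire-compatible with any
# external data service.
#
# JSON debug form: {"scale": s, "runs": [[z, y, x_start, length], ...]}.

RLE_MAGIC <- charToRaw("PRLE")

#' Write / read the binary RLE file format
#'
#' @param rle A `prf_rle`.
#' @param path File path.
#' @return `write_rle()` returns `path` invisibly; `read_rle()` returns a
#'   `prf_rle` with an identical run list (bit-exact round trip).
#' @export
write_rle <- function(rle, path) {
  stopifnot(inherits(rle, "prf_rle"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(RLE_MAGIC, con)
  writeBin(c(rle$scale, nrow(rle$runs)), con, size = 4L, endian = "little")
  if (nrow(rle$runs) > 0) {
    m <- rbind(rle$runs$z, rle$runs$y, rle$runs$x_start, rle$runs$length)
    writeBin(as.integer(m), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' @rdname write_rle
#' @export
read_rle <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (!identical(magic, RLE_MAGIC)) stop_validation("not an RLE volume file")
  hdr <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  n <- hdr[2]
  if (n == 0) return(rle_volume(NULL, scale = hdr[1]))
  v <- readBin(con, "integer", 4L * n, size = 4L, endian = "little")
  m <- matrix(v, nrow = 4L)
  rle_volume(tibble(z = m[1, ], y = m[2, ], x_start = m[3, ], length = m[4, ]),
             scale = hdr[1])
}

#' Write / read the JSON debug form of an RLE volume
#'
#' @inheritParams write_rle
#' @export
write_rle_json <- function(rle, path) {
  stopifnot(inherits(rle, "prf_rle"))
  runs <- unname(apply(as.matrix(rle$runs[, c("z", "y", "x_start", "length")]),
                       1, as.list))
  runs <- lapply(runs, function(r) as.integer(unlist(r)))
  jsonlite::write_json(list(scale = rle$scale, runs = runs), path,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_rle_json
#' @export
read_rle_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  runs <- obj$runs
  if (is.null(runs) || length(runs) == 0) return(rle_volume(NULL, scale = obj$scale))
  m <- matrix(as.integer(unlist(runs)), ncol = 4L, byrow = !is.matrix(runs))
  if (is.matrix(runs)) m <- matrix(as.integer(runs), ncol = 4L)
  rle_volume(tibble(z = m[, 1], y = m[, 2], x_start = m[, 3], length = m[, 4]),
             scale = obj$scale)
}
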