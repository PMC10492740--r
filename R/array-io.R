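## Chunk-grid arithmetic, chunk encoding, and whole-array / region I/O.
## Conventions fixed across the package: zero-based indices, half-open
## regions, row-major ("C") chunk layout. R arrays are column-major, so
## serialization transposes axis order; the bytes on disk are row-major.

#' Region: a zero-based half-open N-dimensional window
#'
#' @slot origin Per-axis non-negative integers (zero-based).
#' @slot extent Per-axis positive integers; the region covers
#'   `[origin, origin + extent)` on each axis.
#' @export
setClass("Region",
  representation(origin = "numeric", extent = "numeric"),
  validity = function(object) {
    if (length(object@origin) != length(object@extent))
      return("origin and extent must have equal rank")
    if (any(object@origin < 0) || any(object@origin != floor(object@origin)))
      return("origin entries must be non-negative integers")
    if (any(object@extent < 1) || any(object@extent != floor(object@extent)))
      return("extent entries must be positive integers")
    TRUE
  })

#' @rdname Region-class
#' @param origin,extent See slots.
#' @export
region <- function(origin, extent) {
  new("Region", origin = as.numeric(origin), extent = as.numeric(extent))
}

setMethod("show", "Region", function(object) {
  cat("Region origin (", paste(object@origin, collapse = ", "),
      ") extent (", paste(object@extent, collapse = ", "), ")\n", sep = "")
})

#' Chunk-grid shape
#'
#' Number of chunks along each axis: the per-axis ceiling of
#' `shape / chunk_shape`.
#'
#' @param shape Per-axis array extents (positive integers).
#' @param chunkShape Per-axis chunk extents, same rank.
#' @return Integer-valued numeric vector of grid extents.
#' @export
#' @examples
#' gridShape(c(2048, 2048), c(1024, 1024))  # 2 x 2 chunks
gridShape <- function(shape, chunkShape) {
  shape <- as.numeric(shape); chunkShape <- as.numeric(chunkShape)
  if (length(shape) != length(chunkShape))
    stop("shape and chunk_shape must have equal rank", call. = FALSE)
  if (any(shape < 1) || any(chunkShape < 1) ||
      any(shape != floor(shape)) || any(chunkShape != floor(chunkShape)))
    stop("extents must be positive integers", call. = FALSE)
  ceiling(shape / chunkShape)
}

#' Store key of one chunk object
#'
#' Joins the array path with the chunk's zero-based grid indices using the
#' array's dimension separator.
#'
#' @param arrayPath Path of the array node in the store.
#' @param gridIndex Zero-based chunk indices, one per axis.
#' @param separator `"/"` or `"."`.
#' @param grid Optional grid shape; when given, `gridIndex` is bounds-checked.
#' @return The store key string.
#' @export
#' @examples
#' chunkKey("0", c(0, 0, 0, 0, 0), ".")  # "0/0.0.0.0.0"
chunkKey <- function(arrayPath, gridIndex, separator = "/", grid = NULL) {
  if (!separator %in% c("/", "."))
    stop("separator must be '/' or '.'", call. = FALSE)
  gridIndex <- as.numeric(gridIndex)
  if (any(gridIndex < 0) || any(gridIndex != floor(gridIndex)))
    stop("grid indices must be non-negative integers", call. = FALSE)
  if (!is.null(grid)) {
    if (length(grid) != length(gridIndex) || any(gridIndex >= grid))
      stop("grid index (", paste(gridIndex, collapse = ","),
           ") outside grid (", paste(grid, collapse = ","), ")",
           call. = FALSE)
  }
  joinKey(arrayPath, paste(format(gridIndex, scientific = FALSE,
                                  trim = TRUE), collapse = separator))
}

## dense block <-> row-major element vector
flattenC <- function(block) {
  d <- dim(block)
  if (is.null(d) || length(d) == 1L) return(as.vector(block))
  as.vector(aperm(block, rev(seq_along(d))))
}

unflattenC <- function(values, shape) {
  if (length(shape) == 1L) return(array(values, dim = shape))
  aperm(array(values, dim = rev(shape)), rev(seq_along(shape)))
}

#' Encode / decode one chunk
#'
#' `encodeChunk` serializes a dense block of exactly the schema's chunk
#' shape to row-major little-endian bytes and applies the codec;
#' `decodeChunk` is its exact inverse.
#'
#' @param block Dense array whose `dim` equals the schema's chunk shape.
#' @param schema An [ArraySchema-class].
#' @return `encodeChunk`: a raw vector; `decodeChunk`: the dense block.
#' @export
encodeChunk <- function(block, schema) {
  d <- dim(block)
  if (is.null(d)) d <- length(block)
  if (!identical(as.numeric(d), as.numeric(schema@chunkShape)))
    stop("block shape (", paste(d, collapse = ","),
         ") does not match chunk shape (",
         paste(schema@chunkShape, collapse = ","), ")", call. = FALSE)
  codecCompress(encodeValues(flattenC(block), schema@dtype), schema@codec)
}

#' @rdname encodeChunk
#' @param bytes Raw vector produced by `encodeChunk`.
#' @export
decodeChunk <- function(bytes, schema) {
  n <- prod(schema@chunkShape)
  values <- decodeValues(codecDecompress(bytes, schema@codec),
                         schema@dtype, n)
  unflattenC(values, schema@chunkShape)
}

## zero-based multi-index iteration over a grid (row-major order)
gridIndices <- function(grid) {
  if (prod(grid) == 0) return(list())
  ix <- do.call(expand.grid, lapply(rev(grid), function(n) 0:(n - 1)))
  lapply(seq_len(nrow(ix)), function(i) rev(as.numeric(ix[i, ])))
}

## extract data[origin:origin+extent) (zero-based), keeping dims
subBlock <- function(data, origin, extent) {
  idx <- lapply(seq_along(origin),
                function(a) seq.int(origin[a] + 1, origin[a] + extent[a]))
  do.call(`[`, c(list(data), idx, list(drop = FALSE)))
}

## assign block into target at zero-based origin
assignBlock <- function(target, origin, block) {
  d <- dim(block)
  idx <- lapply(seq_along(origin),
                function(a) seq.int(origin[a] + 1, origin[a] + d[a]))
  do.call(`[<-`, c(list(target), idx, list(value = block)))
}

#' Write a dense array as a chunked store node
#'
#' Writes the `.zarray` metadata document plus one encoded chunk object per
#' grid cell. Edge chunks are padded to the full chunk shape with the fill
#' value; readers crop them back.
#'
#' @param store A [KVStore-class].
#' @param path Array path within the store.
#' @param data Dense array; `dim(data)` must equal the schema shape
#'   (a plain vector is treated as rank 1).
#' @param schema An [ArraySchema-class].
#' @return The schema, invisibly.
#' @export
writeArray <- function(store, path, data, schema) {
  d <- dim(data)
  if (is.null(d)) d <- length(data)
  if (length(d) != length(schema@shape))
    stop("data rank ", length(d), " does not match schema rank ",
         length(schema@shape), call. = FALSE)
  if (!identical(as.numeric(d), as.numeric(schema@shape)))
    stop("data shape (", paste(d, collapse = ","),
         ") does not match schema shape (",
         paste(schema@shape, collapse = ","), ")", call. = FALSE)
  dim(data) <- d
  writeSchema(store, path, schema)
  grid <- gridShape(schema@shape, schema@chunkShape)
  ch <- schema@chunkShape
  for (cell in gridIndices(grid)) {
    origin <- cell * ch
    extent <- pmin(ch, schema@shape - origin)
    block <- subBlock(data, origin, extent)
    if (!identical(as.numeric(dim(block)), as.numeric(ch))) {
      full <- array(schema@fillValue, dim = ch)
      full <- assignBlock(full, rep(0, length(ch)), block)
      block <- full
    }
    kvPut(store, chunkKey(path, cell, schema@dimensionSeparator, grid),
          encodeChunk(block, schema))
  }
  invisible(schema)
}

#' Read a rectangular region of a stored array
#'
#' Returns exactly the requested voxels, decoding only the chunks that
#' intersect the region (the lazy-access contract). Grid cells with no
#' stored object are read as the fill value.
#'
#' @param store A [KVStore-class].
#' @param path Array path within the store.
#' @param reg A [Region-class]; must lie within the array bounds.
#' @return Dense array of the region's extent.
#' @export
readRegion <- function(store, path, reg) {
  schema <- readSchema(store, path)
  o <- reg@origin; e <- reg@extent
  if (length(o) != length(schema@shape))
    stop("region rank does not match array rank", call. = FALSE)
  if (any(o + e > schema@shape))
    stop("region [", paste(o, collapse = ","), ")+(",
         paste(e, collapse = ","), ") exceeds array shape (",
         paste(schema@shape, collapse = ","), ")", call. = FALSE)
  ch <- schema@chunkShape
  grid <- gridShape(schema@shape, schema@chunkShape)
  out <- array(schema@fillValue, dim = e)
  lo <- floor(o / ch)
  hi <- floor((o + e - 1) / ch)
  for (cell in gridIndices(hi - lo + 1)) {
    cell <- cell + lo
    key <- chunkKey(path, cell, schema@dimensionSeparator, grid)
    if (!kvExists(store, key)) next  # implicit fill
    block <- decodeChunk(kvGet(store, key), schema)
    cOrigin <- cell * ch
    a0 <- pmax(o, cOrigin)
    a1 <- pmin(o + e, cOrigin + ch)
    piece <- subBlock(block, a0 - cOrigin, a1 - a0)
    out <- assignBlock(out, a0 - o, piece)
  }
  out
}

#' @rdname readRegion
#' @return `readArray` reads the full extent.
#' @export
readArray <- function(store, path) {
  schema <- readSchema(store, path)
  readRegion(store, path, region(rep(0, length(schema@shape)),
                                 schema@shape))
}
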