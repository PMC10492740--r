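## ArraySchema: the shape/chunk/dtype/codec/fill description of one stored
## array (one pyramid level), serialized as the ".zarray" metadata document.

#' ArraySchema: description of one chunked array
#'
#' Captures everything needed to read or write one stored array: per-axis
#' extents, the chunk grid, the element dtype, the per-chunk codec, the
#' fill value assumed for absent chunks, the (fixed, row-major) layout
#' order and the separator used in chunk keys.
#'
#' @slot shape Positive integer extents per axis.
#' @slot chunkShape Positive integer chunk extents, same rank as `shape`.
#' @slot dtype Dtype code from the fixed registry (see [dtypeCodes()]).
#' @slot codec A [CodecSpec-class] or `NULL` (uncompressed).
#' @slot fillValue Scalar representable in `dtype`; the value read for any
#'   voxel whose chunk object is absent.
#' @slot order Layout order, always `"C"` (row-major).
#' @slot dimensionSeparator `"/"` (nested directories, the write default)
#'   or `"."` (flat chunk names, accepted on read).
#' @export
setClass("ArraySchema",
  representation(shape = "numeric", chunkShape = "numeric",
                 dtype = "character", codec = "CodecSpecOrNULL",
                 fillValue = "numeric", order = "character",
                 dimensionSeparator = "character"),
  validity = function(object) {
    s <- object@shape; ch <- object@chunkShape
    if (length(s) < 1L) return("shape must have at least one axis")
    if (length(ch) != length(s))
      return("chunk_shape rank must equal shape rank")
    if (any(!is.finite(s)) || any(s < 1) || any(s != floor(s)))
      return("shape entries must be positive integers")
    if (any(!is.finite(ch)) || any(ch < 1) || any(ch != floor(ch)))
      return("chunk_shape entries must be positive integers")
    if (!object@dtype %in% dtypeCodes())
      return(paste0("unknown dtype code '", object@dtype, "'"))
    if (!dtypeRepresentable(object@fillValue, object@dtype))
      return("fill_value is not representable in the dtype")
    if (!identical(object@order, "C"))
      return("layout order must be 'C' (row-major)")
    if (!object@dimensionSeparator %in% c("/", "."))
      return("dimension_separator must be '/' or '.'")
    TRUE
  })

#' @rdname ArraySchema-class
#' @param shape,chunkShape,dtype,codec,fillValue,dimensionSeparator See slots.
#' @return An `ArraySchema`.
#' @export
#' @examples
#' arraySchema(c(1, 1, 1, 256, 256), c(1, 1, 1, 128, 128), "u2")
arraySchema <- function(shape, chunkShape = shape, dtype = "u2",
                        codec = codecSpec("zlib", level = 5L),
                        fillValue = 0, dimensionSeparator = "/") {
  new("ArraySchema", shape = as.numeric(shape),
      chunkShape = as.numeric(chunkShape), dtype = dtype, codec = codec,
      fillValue = as.numeric(fillValue), order = "C",
      dimensionSeparator = dimensionSeparator)
}

#' @rdname ArraySchema-class
#' @param object,x An `ArraySchema`.
#' @export
setMethod("show", "ArraySchema", function(object) {
  codec <- if (is.null(object@codec)) "raw" else object@codec@id
  cat("ArraySchema <", object@dtype, "> shape (",
      paste(object@shape, collapse = ", "), ") chunks (",
      paste(object@chunkShape, collapse = ", "), ") codec ", codec,
      " fill ", object@fillValue, "\n", sep = "")
})

#' @rdname ArraySchema-class
#' @export
setGeneric("schemaShape", function(x) standardGeneric("schemaShape"))
#' @rdname ArraySchema-class
#' @export
setMethod("schemaShape", "ArraySchema", function(x) x@shape)

#' @rdname ArraySchema-class
#' @export
setGeneric("schemaChunks", function(x) standardGeneric("schemaChunks"))
#' @rdname ArraySchema-class
#' @export
setMethod("schemaChunks", "ArraySchema", function(x) x@chunkShape)

#' @rdname ArraySchema-class
#' @export
setGeneric("schemaDtype", function(x) standardGeneric("schemaDtype"))
#' @rdname ArraySchema-class
#' @export
setMethod("schemaDtype", "ArraySchema", function(x) x@dtype)

## ---- .zarray document ----

zarrayDoc <- function(schema) {
  list(
    zarr_format = 2L,
    shape = I(as.integer(schema@shape)),
    chunks = I(as.integer(schema@chunkShape)),
    dtype = dtypeToZarr(schema@dtype),
    compressor = codecToDoc(schema@codec),
    fill_value = schema@fillValue,
    order = "C",
    filters = NULL,
    dimension_separator = schema@dimensionSeparator
  )
}

parseZarray <- function(doc) {
  need <- c("shape", "chunks", "dtype")
  miss <- setdiff(need, names(doc))
  if (length(miss))
    stop("invalid array metadata: missing field(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!is.null(doc$zarr_format) && !identical(as.integer(doc$zarr_format[[1]]), 2L))
    stop("unsupported zarr_format: ", doc$zarr_format, call. = FALSE)
  if (!is.null(doc$order) && !identical(doc$order[[1]], "C"))
    stop("unsupported layout order '", doc$order, "'", call. = FALSE)
  sep <- if (is.null(doc$dimension_separator)) "." else
    doc$dimension_separator[[1]]
  fill <- if (is.null(doc$fill_value)) 0 else as.numeric(doc$fill_value[[1]])
  arraySchema(shape = unlist(doc$shape), chunkShape = unlist(doc$chunks),
              dtype = dtypeFromZarr(doc$dtype[[1]]),
              codec = codecFromDoc(doc$compressor),
              fillValue = fill, dimensionSeparator = sep)
}

writeSchema <- function(store, path, schema) {
  jsonPut(store, joinKey(path, ".zarray"), zarrayDoc(schema))
  invisible(store)
}

readSchema <- function(store, path) {
  key <- joinKey(path, ".zarray")
  if (!kvExists(store, key))
    stop("no array at path '", path, "'", call. = FALSE)
  parseZarray(jsonGet(store, key))
}
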