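## Per-chunk compression codecs and the pluggable registry.

#' CodecSpec: a per-chunk compression codec
#'
#' Identifies the codec applied to every stored chunk of an array, plus its
#' parameters (e.g. the compression level). The ids `"raw"` (no compression,
#' serialized as a `null` compressor) and `"zlib"`/`"gzip"` are implemented
#' natively; other ids seen in the wild (`"blosc"`, `"zstd"`, ...) are
#' accepted by the metadata parser and resolved through the codec registry
#' at read time.
#'
#' @slot id Codec identifier (non-empty string).
#' @slot params Named list of codec parameters.
#' @export
setClass("CodecSpec",
  representation(id = "character", params = "list"),
  validity = function(object) {
    if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
      return("codec id must be a non-empty string")
    if (length(object@params) && is.null(names(object@params)))
      return("codec params must be a named list")
    TRUE
  })

setClassUnion("CodecSpecOrNULL", c("CodecSpec", "NULL"))

#' @rdname CodecSpec-class
#' @param id Codec id string.
#' @param ... Codec parameters, e.g. `level = 5`.
#' @return A `CodecSpec` object, or `NULL` when `id` is `"raw"`/`NULL`.
#' @export
#' @examples
#' codecSpec("zlib", level = 5)
codecSpec <- function(id, ...) {
  if (is.null(id) || identical(id, "raw")) return(NULL)
  new("CodecSpec", id = id, params = list(...))
}

setMethod("show", "CodecSpec", function(object) {
  p <- if (length(object@params))
    paste0("(", paste(names(object@params), unlist(object@params),
                      sep = "=", collapse = ", "), ")") else ""
  cat("CodecSpec:", object@id, p, "\n")
})

## registry: id -> list(compress = f(raw, params), decompress = f(raw, params))
.codecRegistry <- new.env(parent = emptyenv())

#' Register a chunk codec implementation
#'
#' Extends the codec registry so arrays compressed with additional
#' algorithms can be read and written. Without a registered implementation,
#' reading such an array fails with a clear error and validation reports a
#' warning rather than an error.
#'
#' @param id Codec id string.
#' @param compress Function `(raw, params) -> raw`.
#' @param decompress Function `(raw, params) -> raw`.
#' @return Invisibly, the id.
#' @export
registerCodec <- function(id, compress, decompress) {
  stopifnot(is.character(id), nzchar(id),
            is.function(compress), is.function(decompress))
  assign(id, list(compress = compress, decompress = decompress),
         envir = .codecRegistry)
  invisible(id)
}

#' @rdname registerCodec
#' @export
registeredCodecs <- function() sort(ls(.codecRegistry))

## ids the metadata parser accepts without a registered implementation
.KNOWN_CODEC_IDS <- c("zlib", "gzip", "blosc", "zstd", "lz4", "bz2")

codecImpl <- function(id) {
  impl <- get0(id, envir = .codecRegistry)
  if (is.null(impl))
    stop("unknown codec '", id, "': no registered implementation",
         call. = FALSE)
  impl
}

.zlibCompress <- function(bytes, params) {
  memCompress(bytes, type = "gzip")
}
.zlibDecompress <- function(bytes, params) {
  out <- tryCatch(memDecompress(bytes, type = "gzip"),
                  error = function(e) NULL)
  if (is.null(out))
    stop("corrupted chunk payload: zlib decompression failed", call. = FALSE)
  out
}

.initCodecs <- function() {
  registerCodec("zlib", .zlibCompress, .zlibDecompress)
  registerCodec("gzip", .zlibCompress, .zlibDecompress)
}

.onLoad <- function(libname, pkgname) .initCodecs()

codecCompress <- function(bytes, codec) {
  if (is.null(codec)) return(bytes)
  codecImpl(codec@id)$compress(bytes, codec@params)
}

codecDecompress <- function(bytes, codec) {
  if (is.null(codec)) return(bytes)
  codecImpl(codec@id)$decompress(bytes, codec@params)
}

## CodecSpec <-> zarr v2 "compressor" JSON fragment
codecToDoc <- function(codec) {
  if (is.null(codec)) return(NULL)
  c(list(id = codec@id), codec@params)
}

codecFromDoc <- function(doc) {
  if (is.null(doc) || (is.atomic(doc) && length(doc) == 1L && is.na(doc)))
    return(NULL)
  if (is.null(doc$id))
    stop("compressor block lacks an 'id' field", call. = FALSE)
  params <- doc[setdiff(names(doc), "id")]
  do.call(codecSpec, c(list(id = doc$id), params))
}
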