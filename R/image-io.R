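## Writing and reading complete multiscale images (a Zarr group holding
## one array per resolution level plus the "multiscales" attributes).

## default chunking: one (t,c,z) hyperplane tile of at most 1024 x 1024
defaultChunkShape <- function(shape) {
  n <- length(shape)
  ch <- rep(1, n)
  ch[n - 1] <- min(shape[n - 1], 1024)
  ch[n] <- min(shape[n], 1024)
  ch
}

#' Named chunk-shape presets
#'
#' `"auto"` tiles the trailing y/x plane at up to 1024 x 1024 with all
#' other axes chunked at 1; `"volumetric"` is the (1, 1, 128, 128, 128)
#' preset recommended for z-stack archives.
#'
#' @param preset `"auto"` or `"volumetric"`.
#' @param shape Image shape the preset is resolved against.
#' @return Per-axis chunk extents.
#' @export
chunkPreset <- function(preset = c("auto", "volumetric"), shape) {
  preset <- match.arg(preset)
  n <- length(shape)
  if (preset == "auto") return(defaultChunkShape(shape))
  if (n < 3) stop("volumetric preset needs at least 3 axes", call. = FALSE)
  ch <- rep(1, n)
  ch[(n - 2):n] <- pmin(shape[(n - 2):n], 128)
  ch
}

#' Write a dense image as a multiscale OME-Zarr group
#'
#' Builds the pyramid with [buildPyramid()], writes one chunked array per
#' level (named "0", "1", ...) and the `multiscales` attribute block.
#'
#' @param store A [KVStore-class].
#' @param path Group path for the image.
#' @param data Dense array (2-5 dimensions).
#' @param axes Axis list; defaults to [defaultAxes()] of the data rank.
#' @param dtype Dtype code for storage.
#' @param kind `"intensity"` (mean pyramid) or `"label"` (mode pyramid).
#' @param chunkShape Per-axis chunk extents, or `"auto"`.
#' @param codec A [CodecSpec-class] or `NULL`.
#' @param omero Optional channel-rendering list (see [channelRendering()]).
#' @param extraAttrs Named list merged into the group attributes.
#' @inheritParams buildPyramid
#' @return The image path, invisibly.
#' @export
writeMultiscaleImage <- function(store, path, data, axes = NULL,
                                 dtype = "u2", kind = "intensity",
                                 chunkShape = "auto",
                                 codec = codecSpec("zlib", level = 5L),
                                 minExtent = 256, maxLevels = NULL,
                                 spatialFactor = 2, includeZ = FALSE,
                                 baseScale = NULL, name = NA_character_,
                                 fillValue = 0, omero = NULL,
                                 extraAttrs = list()) {
  d <- dim(data); if (is.null(d)) { d <- length(data); dim(data) <- d }
  if (is.null(axes)) axes <- defaultAxes(length(d))
  pyr <- buildPyramid(data, axes, kind = kind, dtype = dtype,
                      minExtent = minExtent, maxLevels = maxLevels,
                      spatialFactor = spatialFactor, includeZ = includeZ,
                      baseScale = baseScale, name = name)
  writeGroup(store, path)
  for (i in seq_along(pyr$levels)) {
    lv <- pyr$levels[[i]]
    shape <- dim(lv)
    ch <- if (identical(chunkShape, "auto")) defaultChunkShape(shape)
          else pmin(as.numeric(chunkShape), shape)
    schema <- arraySchema(shape, ch, dtype, codec = codec,
                          fillValue = fillValue)
    writeArray(store, joinKey(path, as.character(i - 1)), lv, schema)
  }
  attrs <- c(list(multiscales = list(multiscalesToDoc(pyr$meta))),
             if (!is.null(omero)) list(omero = omero), extraAttrs)
  putAttrs(store, path, attrs)
  invisible(path)
}

#' Read the multiscale metadata of an image group
#'
#' Parses the first `multiscales` entry of the group's attributes.
#'
#' @param store A [KVStore-class].
#' @param path Image group path.
#' @param entry Which multiscales entry (1-based) when several images share
#'   the group.
#' @return A [MultiscaleMeta-class].
#' @export
readImageMeta <- function(store, path, entry = 1L) {
  attrs <- getAttrs(store, path)
  ms <- attrs$multiscales
  if (is.null(ms) || length(ms) < entry)
    stop("no multiscales metadata at '", path, "'", call. = FALSE)
  parseMultiscales(ms[[entry]])
}

#' Read one resolution level of an image
#'
#' @inheritParams readImageMeta
#' @param level Zero-based level index.
#' @return Dense array of that level.
#' @export
readImageLevel <- function(store, path, level = 0L, entry = 1L) {
  meta <- readImageMeta(store, path, entry)
  if (level < 0 || level >= length(meta@datasets))
    stop("level ", level, " absent: image has ",
         length(meta@datasets), " level(s)", call. = FALSE)
  readArray(store, joinKey(path, meta@datasets[[level + 1]]@path))
}
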