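## bioformats2raw-style conversion: an ordered supplier of 2D planes
## (TIFF pages via the tiff package, or in-memory arrays) streamed into a
## validated 5-D multiscale image.

#' PlaneSource: ordered supplier of 2D planes
#'
#' The converter's input contract: declared sizes over (t, c, z, y, x), an
#' element dtype, and a function returning the 2D plane at any zero-based
#' (t, c, z) index. Decouples conversion from the input format.
#'
#' @slot sizes Named numeric vector with entries `t`, `c`, `z`, `y`, `x`.
#' @slot dtype Dtype code of the planes.
#' @slot getPlane Function `(t, c, z) -> matrix` of dim (y, x), zero-based.
#' @slot pixelSizes Optional named physical sizes (`z`, `y`, `x`) in
#'   micrometers; `numeric(0)` when unknown.
#' @slot channelNames Optional channel names (`character(0)` when unknown).
#' @export
setClass("PlaneSource",
  representation(sizes = "numeric", dtype = "character",
                 getPlane = "function", pixelSizes = "numeric",
                 channelNames = "character"),
  validity = function(object) {
    need <- c("t", "c", "z", "y", "x")
    if (!all(need %in% names(object@sizes)))
      return("sizes must be named t, c, z, y, x")
    if (any(object@sizes < 1) || any(object@sizes != floor(object@sizes)))
      return("sizes must be positive integers")
    if (!object@dtype %in% dtypeCodes())
      return("unknown dtype code")
    if (length(object@channelNames) &&
        length(object@channelNames) != object@sizes[["c"]])
      return("one channel name per channel required")
    TRUE
  })

#' @rdname PlaneSource-class
#' @param sizes,dtype,getPlane,pixelSizes,channelNames See slots.
#' @export
planeSource <- function(sizes, dtype, getPlane, pixelSizes = numeric(0),
                        channelNames = character(0)) {
  new("PlaneSource", sizes = sizes, dtype = dtype, getPlane = getPlane,
      pixelSizes = pixelSizes, channelNames = channelNames)
}

setMethod("show", "PlaneSource", function(object) {
  cat("PlaneSource <", object@dtype, "> t=", object@sizes[["t"]],
      " c=", object@sizes[["c"]], " z=", object@sizes[["z"]],
      " y=", object@sizes[["y"]], " x=", object@sizes[["x"]], "\n",
      sep = "")
})

#' @rdname PlaneSource-class
#' @param data Dense array of 2-5 dimensions, interpreted as the trailing
#'   part of (t, c, z, y, x).
#' @return `arrayPlaneSource` wraps an in-memory array as a plane source.
#' @export
arrayPlaneSource <- function(data, dtype = "u2", pixelSizes = numeric(0),
                             channelNames = character(0)) {
  d <- dim(data); if (is.null(d)) stop("data must be an array")
  if (length(d) < 2 || length(d) > 5)
    stop("data must have 2-5 dimensions", call. = FALSE)
  full <- c(rep(1, 5 - length(d)), d)
  dim(data) <- full
  planeSource(
    sizes = c(t = full[1], c = full[2], z = full[3], y = full[4],
              x = full[5]),
    dtype = dtype,
    getPlane = function(t, c, z)
      matrix(data[t + 1, c + 1, z + 1, , ], nrow = full[4]),
    pixelSizes = pixelSizes, channelNames = channelNames)
}

#' TIFF-stack plane source
#'
#' Wraps the grayscale pages of one TIFF file as a [PlaneSource-class].
#' `dimensionOrder` names the (t, c, z) dimensions the page sequence
#' iterates over, fastest-varying first (e.g. `"CZ"`: channel varies
#' fastest). Sizes for all but one named dimension are given in `sizes`;
#' the remaining one is inferred from the page count, which must divide
#' evenly.
#'
#' @param path TIFF file path.
#' @param dimensionOrder String over the letters T, C, Z, fastest first.
#' @param sizes Named integer vector fixing all but one of the named
#'   dimensions, e.g. `c(C = 2)` with order `"CZ"`.
#' @param dtype Dtype code of the pixel data (default `"u2"`;
#'   8-bit files fit `"u1"`).
#' @return A [PlaneSource-class].
#' @export
tiffPlaneSource <- function(path, dimensionOrder = "T", sizes = c(),
                            dtype = "u2") {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nPages <- length(pages)
  dims <- lapply(pages, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop("TIFF pages have differing shapes", call. = FALSE)
  if (length(dims[[1]]) != 2)
    stop("only grayscale (single-sample) TIFF pages are supported",
         call. = FALSE)
  letters_ <- strsplit(toupper(dimensionOrder), "")[[1]]
  if (!length(letters_) || !all(letters_ %in% c("T", "C", "Z")) ||
      anyDuplicated(letters_))
    stop("dimensionOrder must be a permutation over T, C, Z", call. = FALSE)
  counts <- rep(NA_real_, length(letters_))
  names(counts) <- letters_
  given <- toupper(names(sizes))
  for (i in seq_along(sizes)) counts[given[i]] <- as.numeric(sizes[[i]])
  nUnknown <- sum(is.na(counts))
  if (nUnknown > 1)
    stop("sizes must fix all but one dimension of '", dimensionOrder, "'",
         call. = FALSE)
  fixedProd <- prod(counts, na.rm = TRUE)
  if (nUnknown == 1) {
    if (nPages %% fixedProd != 0)
      stop("page count ", nPages, " not divisible by the declared sizes",
           call. = FALSE)
    counts[is.na(counts)] <- nPages / fixedProd
  } else if (fixedProd != nPages) {
    stop("declared sizes imply ", fixedProd, " pages, file has ", nPages,
         call. = FALSE)
  }
  full <- c(T = 1, C = 1, Z = 1)
  full[names(counts)] <- counts
  strides <- c(T = 0, C = 0, Z = 0)
  s <- 1
  for (l in letters_) { strides[l] <- s; s <- s * counts[[l]] }
  planeSource(
    sizes = c(t = full[["T"]], c = full[["C"]], z = full[["Z"]],
              y = dims[[1]][1], x = dims[[1]][2]),
    dtype = dtype,
    getPlane = function(t, c, z) {
      page <- t * strides[["T"]] + c * strides[["C"]] + z * strides[["Z"]]
      pages[[page + 1]]
    })
}

#' ConvertOptions: tunables of the converter
#'
#' @param chunkShape Per-axis chunk extents over (t, c, z, y, x), or
#'   `"auto"` (plane tiles up to 1024 x 1024), or `"volumetric"`
#'   ((1, 1, 128, 128, 128), the preset recommended for z-stack archives).
#' @param resolutionLevels Integer level count, or `"auto"` to halve y/x
#'   down to `minExtent`.
#' @param codec A [CodecSpec-class] or `NULL`.
#' @param minExtent Auto-level stop threshold (largest downsampled extent).
#' @param dimensionSeparator `"/"` or `"."` for chunk keys.
#' @return A named list of validated options.
#' @export
convertOptions <- function(chunkShape = "auto", resolutionLevels = "auto",
                           codec = codecSpec("zlib", level = 5L),
                           minExtent = 256, dimensionSeparator = "/") {
  if (!identical(chunkShape, "auto") &&
      !identical(chunkShape, "volumetric")) {
    chunkShape <- as.numeric(chunkShape)
    if (length(chunkShape) != 5 || any(chunkShape < 1) ||
        any(chunkShape != floor(chunkShape)))
      stop("chunkShape must be 5 positive extents, 'auto' or 'volumetric'",
           call. = FALSE)
  }
  if (!identical(resolutionLevels, "auto")) {
    resolutionLevels <- as.numeric(resolutionLevels)
    if (length(resolutionLevels) != 1 || resolutionLevels < 1 ||
        resolutionLevels != floor(resolutionLevels))
      stop("resolutionLevels must be a positive integer or 'auto'",
           call. = FALSE)
  }
  list(chunkShape = chunkShape, resolutionLevels = resolutionLevels,
       codec = codec, minExtent = minExtent,
       dimensionSeparator = dimensionSeparator)
}

## write level 0 chunk-by-chunk without materializing the 5-D array:
## gather the planes under each (t,c,z) chunk slab, tile y/x, encode, put
streamLevel0 <- function(source, store, path, schema) {
  sz <- source@sizes
  grid <- gridShape(schema@shape, schema@chunkShape)
  ch <- schema@chunkShape
  for (cell in gridIndices(grid)) {
    origin <- cell * ch
    block <- array(schema@fillValue, dim = ch)
    for (dt in seq_len(min(ch[1], sz[["t"]] - origin[1])) - 1)
      for (dc in seq_len(min(ch[2], sz[["c"]] - origin[2])) - 1)
        for (dz in seq_len(min(ch[3], sz[["z"]] - origin[3])) - 1) {
          plane <- source@getPlane(origin[1] + dt, origin[2] + dc,
                                   origin[3] + dz)
          if (!identical(as.numeric(dim(plane)),
                         as.numeric(c(sz[["y"]], sz[["x"]]))))
            stop("plane (", origin[1] + dt, ",", origin[2] + dc, ",",
                 origin[3] + dz, ") has shape (",
                 paste(dim(plane), collapse = ","),
                 "), declared (", sz[["y"]], ",", sz[["x"]], ")",
                 call. = FALSE)
          ys <- origin[4] + seq_len(min(ch[4], sz[["y"]] - origin[4]))
          xs <- origin[5] + seq_len(min(ch[5], sz[["x"]] - origin[5]))
          block[dt + 1, dc + 1, dz + 1, seq_along(ys), seq_along(xs)] <-
            plane[ys, xs, drop = FALSE]
        }
    kvPut(store, chunkKey(path, cell, schema@dimensionSeparator, grid),
          encodeChunk(block, schema))
  }
}

#' Convert a plane source into a multiscale OME-Zarr image
#'
#' Writes a 5-D (t, c, z, y, x) image whose level-0 pixels equal the
#' source planes exactly, then builds the pyramid per the options. Level 0
#' is streamed chunk-by-chunk so the full image is never held in memory.
#' Axis units (micrometer) are recorded when the source declares physical
#' pixel sizes, and channel names land in the rendering block.
#'
#' @param source A [PlaneSource-class].
#' @param store A [KVStore-class].
#' @param path Image group path to create.
#' @param options See [convertOptions()].
#' @return The image path, invisibly.
#' @export
convertStack <- function(source, store, path, options = convertOptions()) {
  validObject(source)
  sz <- source@sizes
  shape <- as.numeric(sz[c("t", "c", "z", "y", "x")])
  ch <- if (identical(options$chunkShape, "auto"))
    defaultChunkShape(shape)
  else if (identical(options$chunkShape, "volumetric"))
    chunkPreset("volumetric", shape)
  else pmin(options$chunkShape, shape)
  axes <- defaultAxes(5)
  baseScale <- rep(1, 5)
  if (length(source@pixelSizes)) {
    ps <- source@pixelSizes
    for (i in seq_along(axes)) {
      nm <- axes[[i]]@name
      if (nm %in% names(ps)) {
        baseScale[i] <- ps[[nm]]
        axes[[i]]@unit <- "micrometer"
      }
    }
  }
  writeGroup(store, path)
  schema0 <- arraySchema(shape, ch, source@dtype, codec = options$codec,
                         dimensionSeparator = options$dimensionSeparator)
  writeSchema(store, joinKey(path, "0"), schema0)
  streamLevel0(source, store, path = joinKey(path, "0"), schema0)

  maxLevels <- if (identical(options$resolutionLevels, "auto")) NULL
               else options$resolutionLevels
  plan <- planLevels(shape, axes, minExtent = options$minExtent,
                     maxLevels = maxLevels)
  nAxes <- 5L
  factors <- rep(1, nAxes)
  factors[plan@downsampledAxes] <- plan@spatialFactor
  prev <- NULL
  for (i in seq_along(plan@levelShapes)[-1]) {
    if (is.null(prev)) prev <- readArray(store, joinKey(path, "0"))
    cur <- downsampleMean(prev, factors, source@dtype)
    lvShape <- as.numeric(dim(cur))
    schema <- arraySchema(lvShape, pmin(ch, lvShape), source@dtype,
                          codec = options$codec,
                          dimensionSeparator = options$dimensionSeparator)
    writeArray(store, joinKey(path, as.character(i - 1)), cur, schema)
    prev <- cur
  }
  datasets <- lapply(seq_along(plan@levelShapes), function(i)
    datasetEntry(as.character(i - 1),
                 levelScale(baseScale, i - 1, plan@spatialFactor,
                            plan@downsampledAxes)))
  meta <- multiscaleMeta(axes, datasets,
                         downsamplingMethod =
                           "local mean (edge-truncated windows)")
  omero <- NULL
  if (length(source@channelNames)) {
    nC <- sz[["c"]]
    r <- dtypeRange(source@dtype)
    hi <- if (is.finite(r[2])) r[2] else 1
    omero <- channelRendering(colors = rep("FFFFFF", nC),
                              windows = rep(list(c(0, 0, hi, hi)), nC),
                              labels = source@channelNames)
  }
  attrs <- c(list(multiscales = list(multiscalesToDoc(meta))),
             if (!is.null(omero)) list(omero = omero))
  putAttrs(store, path, attrs)
  invisible(path)
}
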