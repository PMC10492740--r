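## The NGFF 0.4 image metadata model: axes, per-level datasets with
## scale/translation transforms, optional channel-rendering block, and
## serialization to/from the "multiscales" attribute document.

NGFF_VERSION <- "0.4"
AXIS_TYPES <- c("time", "channel", "space")

#' Axis: one named image dimension
#'
#' @slot name Axis name, unique within an axis list (e.g. "t","c","z","y","x").
#' @slot type One of `"time"`, `"channel"`, `"space"`.
#' @slot unit Optional physical unit (e.g. `"micrometer"`, `"second"`);
#'   `NA` when absent.
#' @export
setClass("Axis",
  representation(name = "character", type = "character", unit = "character"),
  validity = function(object) {
    if (length(object@name) != 1L || is.na(object@name) ||
        !nzchar(object@name))
      return("axis name must be a non-empty string")
    if (length(object@type) != 1L || !object@type %in% AXIS_TYPES)
      return(paste0("axis type must be one of ",
                    paste(AXIS_TYPES, collapse = ", ")))
    TRUE
  })

#' @rdname Axis-class
#' @param name,type,unit See slots.
#' @export
axis_ <- function(name, type, unit = NA_character_) {
  new("Axis", name = name, type = type, unit = as.character(unit))
}

setMethod("show", "Axis", function(object) {
  u <- if (is.na(object@unit)) "" else paste0(" [", object@unit, "]")
  cat("Axis ", object@name, ":", object@type, u, "\n", sep = "")
})

#' Default axis list for a given rank
#'
#' The trailing `ndim` entries of the canonical 5-D order
#' t (time), c (channel), z, y, x (space). Version 0.4 images carry between
#' 2 and 5 dimensions; higher ranks are rejected.
#'
#' @param ndim Number of dimensions, 2..5.
#' @return List of [Axis-class] objects.
#' @export
#' @examples
#' vapply(defaultAxes(5), function(a) a@name, "")
defaultAxes <- function(ndim) {
  if (!is.numeric(ndim) || length(ndim) != 1L || ndim != floor(ndim))
    stop("ndim must be a single integer", call. = FALSE)
  if (ndim > 5)
    stop("more than 5 dimensions unsupported in version 0.4", call. = FALSE)
  if (ndim < 2)
    stop("images have at least 2 dimensions", call. = FALSE)
  full <- list(axis_("t", "time"), axis_("c", "channel"),
               axis_("z", "space"), axis_("y", "space"),
               axis_("x", "space"))
  full[(5 - ndim + 1):5]
}

#' DatasetEntry: one resolution level of a multiscale image
#'
#' @slot path Array name of the level ("0" is full resolution).
#' @slot scale Per-axis positive scale factors (index -> physical).
#' @slot translation Optional per-axis offsets; `numeric(0)` when absent.
#' @export
setClass("DatasetEntry",
  representation(path = "character", scale = "numeric",
                 translation = "numeric"),
  validity = function(object) {
    if (length(object@path) != 1L || !nzchar(object@path))
      return("dataset path must be a non-empty string")
    if (any(object@scale <= 0) || any(!is.finite(object@scale)))
      return("scale entries must be positive finite numbers")
    if (length(object@translation) &&
        length(object@translation) != length(object@scale))
      return("translation length must equal scale length")
    TRUE
  })

#' @rdname DatasetEntry-class
#' @param path,scale,translation See slots.
#' @export
datasetEntry <- function(path, scale, translation = numeric(0)) {
  new("DatasetEntry", path = path, scale = as.numeric(scale),
      translation = as.numeric(translation))
}

#' MultiscaleMeta: the multiscale image description
#'
#' Ordered axes plus an ordered list of resolution levels, highest
#' resolution first, each carrying a scale (and optional translation)
#' transform. Axis order is constrained to time, then channel, then 2-3
#' space axes, and the total rank to 2-5.
#'
#' @slot version Metadata version, `"0.4"`.
#' @slot name Optional image name (`NA` when absent).
#' @slot axes List of [Axis-class], ordered.
#' @slot datasets List of [DatasetEntry-class], level 0 first.
#' @slot downsamplingMethod Free-text provenance of the reducer used to
#'   build lower levels (`NA` when unknown).
#' @export
setClass("MultiscaleMeta",
  representation(version = "character", name = "character", axes = "list",
                 datasets = "list", downsamplingMethod = "character"),
  validity = function(object) {
    if (!identical(object@version, NGFF_VERSION))
      return(paste0("unsupported multiscales version '", object@version, "'"))
    n <- length(object@axes)
    if (n < 2 || n > 5)
      return("axis count must be between 2 and 5")
    if (!all(vapply(object@axes, is, TRUE, "Axis")))
      return("axes must be Axis objects")
    types <- vapply(object@axes, function(a) a@type, "")
    names <- vapply(object@axes, function(a) a@name, "")
    if (anyDuplicated(names)) return("axis names must be unique")
    if (sum(types == "time") > 1) return("at most one time axis")
    if (sum(types == "channel") > 1) return("at most one channel axis")
    nspace <- sum(types == "space")
    if (nspace < 2 || nspace > 3) return("2 or 3 space axes required")
    ## order: time, then channel, then space (each block optional)
    rank <- c(time = 1, channel = 2, space = 3)[types]
    if (is.unsorted(rank))
      return("axis order must be time, then channel, then space")
    if (length(object@datasets) < 1)
      return("at least one dataset (resolution level) required")
    if (!all(vapply(object@datasets, is, TRUE, "DatasetEntry")))
      return("datasets must be DatasetEntry objects")
    badLen <- vapply(object@datasets,
                     function(d) length(d@scale) != n, TRUE)
    if (any(badLen))
      return("every dataset scale must have one entry per axis")
    TRUE
  })

#' @rdname MultiscaleMeta-class
#' @param axes,datasets,name,downsamplingMethod See slots.
#' @export
multiscaleMeta <- function(axes, datasets, name = NA_character_,
                           downsamplingMethod = NA_character_) {
  new("MultiscaleMeta", version = NGFF_VERSION,
      name = as.character(name), axes = axes, datasets = datasets,
      downsamplingMethod = as.character(downsamplingMethod))
}

setMethod("show", "MultiscaleMeta", function(object) {
  ax <- paste(vapply(object@axes, function(a) a@name, ""), collapse = ",")
  cat("MultiscaleMeta v", object@version, " axes (", ax, ") ",
      length(object@datasets), " level(s)\n", sep = "")
})

#' @rdname MultiscaleMeta-class
#' @param x A `MultiscaleMeta`.
#' @export
setGeneric("msAxes", function(x) standardGeneric("msAxes"))
#' @rdname MultiscaleMeta-class
#' @export
setMethod("msAxes", "MultiscaleMeta", function(x) x@axes)

#' @rdname MultiscaleMeta-class
#' @export
setGeneric("msDatasets", function(x) standardGeneric("msDatasets"))
#' @rdname MultiscaleMeta-class
#' @export
setMethod("msDatasets", "MultiscaleMeta", function(x) x@datasets)

axisNames <- function(axes) vapply(axes, function(a) a@name, "")
axisTypes <- function(axes) vapply(axes, function(a) a@type, "")

#' Per-axis scale at a pyramid level
#'
#' Multiplies the base (level 0) scale by `spatialFactor^level` on the
#' downsampled axes, leaving other axes unchanged.
#'
#' @param baseScale Per-axis scale at level 0.
#' @param level Level index (0 = full resolution).
#' @param spatialFactor Integer downsampling factor per level (>= 2).
#' @param downsampledAxes Logical vector (or integer positions) marking the
#'   axes that are downsampled.
#' @return Per-axis scale at the requested level.
#' @export
#' @examples
#' levelScale(c(1, 1, 1, 0.5, 0.5), 1, 2, c(4, 5))
levelScale <- function(baseScale, level, spatialFactor = 2,
                       downsampledAxes) {
  if (level < 0 || level != floor(level))
    stop("level must be a non-negative integer", call. = FALSE)
  if (spatialFactor < 2)
    stop("spatial factor must be at least 2", call. = FALSE)
  mask <- rep(FALSE, length(baseScale))
  mask[downsampledAxes] <- TRUE
  out <- as.numeric(baseScale)
  out[mask] <- out[mask] * spatialFactor^level
  out
}

## ---- serialization ----

axisToDoc <- function(a) {
  doc <- list(name = a@name, type = a@type)
  if (!is.na(a@unit)) doc$unit <- a@unit
  doc
}

datasetToDoc <- function(d) {
  ct <- list(list(type = "scale", scale = I(d@scale)))
  if (length(d@translation))
    ct <- c(ct, list(list(type = "translation",
                          translation = I(d@translation))))
  list(path = d@path, coordinateTransformations = ct)
}

#' Serialize / parse the "multiscales" attribute document
#'
#' `multiscalesToDoc` renders a [MultiscaleMeta-class] as the list that,
#' JSON-encoded, forms one entry of the image group's `multiscales`
#' attribute; `parseMultiscales` is the inverse and fails with a
#' descriptive message on missing axes, missing datasets or an unknown
#' version.
#'
#' @param meta A [MultiscaleMeta-class].
#' @return `multiscalesToDoc`: a list ready for JSON encoding.
#' @export
multiscalesToDoc <- function(meta) {
  validObject(meta)
  doc <- list(version = meta@version,
              axes = lapply(meta@axes, axisToDoc),
              datasets = lapply(meta@datasets, datasetToDoc))
  if (!is.na(meta@name)) doc$name <- meta@name
  if (!is.na(meta@downsamplingMethod))
    doc$metadata <- list(method = meta@downsamplingMethod)
  doc
}

parseAxis <- function(doc) {
  if (is.null(doc$name) || is.null(doc$type))
    stop("axis entry lacks name or type", call. = FALSE)
  axis_(doc$name[[1]], doc$type[[1]],
        if (is.null(doc$unit)) NA_character_ else doc$unit[[1]])
}

parseDataset <- function(doc) {
  if (is.null(doc$path))
    stop("dataset entry lacks a path", call. = FALSE)
  cts <- doc$coordinateTransformations
  if (is.null(cts) || !length(cts))
    stop("dataset '", doc$path, "' lacks coordinateTransformations",
         call. = FALSE)
  types <- vapply(cts, function(ct) ct$type[[1]], "")
  if (types[1] != "scale" || sum(types == "scale") != 1)
    stop("dataset '", doc$path,
         "' must carry exactly one scale transform, first", call. = FALSE)
  extra <- setdiff(types, c("scale", "translation"))
  if (length(extra))
    stop("unsupported transform type '", extra[1], "'", call. = FALSE)
  if (sum(types == "translation") > 1)
    stop("dataset '", doc$path, "' has more than one translation",
         call. = FALSE)
  tr <- numeric(0)
  if ("translation" %in% types)
    tr <- unlist(cts[[which(types == "translation")]]$translation)
  datasetEntry(doc$path[[1]], unlist(cts[[1]]$scale), tr)
}

#' @rdname multiscalesToDoc
#' @param doc A list parsed from one `multiscales` JSON entry.
#' @return `parseMultiscales`: a [MultiscaleMeta-class].
#' @export
parseMultiscales <- function(doc) {
  if (is.null(doc$version))
    stop("multiscales entry lacks a version", call. = FALSE)
  if (!identical(doc$version[[1]], NGFF_VERSION))
    stop("unsupported multiscales version '", doc$version[[1]], "'",
         call. = FALSE)
  if (is.null(doc$axes))
    stop("multiscales entry lacks axes", call. = FALSE)
  if (is.null(doc$datasets) || !length(doc$datasets))
    stop("multiscales entry lacks datasets", call. = FALSE)
  multiscaleMeta(
    axes = lapply(doc$axes, parseAxis),
    datasets = lapply(doc$datasets, parseDataset),
    name = if (is.null(doc$name)) NA_character_ else doc$name[[1]],
    downsamplingMethod = if (is.null(doc$metadata$method)) NA_character_
                         else doc$metadata$method[[1]])
}

## ---- optional channel rendering ("omero" block) ----

#' Channel rendering block
#'
#' Optional display metadata per channel: an RGB color, an intensity
#' window, a label and an active flag. Written under the `omero` attribute
#' and parsed leniently on read.
#'
#' @param colors Character vector of 6-hex-digit RGB strings.
#' @param windows List (one per channel) of numeric `c(min, start, end, max)`.
#' @param labels Optional channel names.
#' @param active Logical vector.
#' @return A list in the attribute-document layout.
#' @export
channelRendering <- function(colors, windows, labels = NULL, active = NULL) {
  n <- length(colors)
  if (is.null(labels)) labels <- paste0("channel ", seq_len(n) - 1)
  if (is.null(active)) active <- rep(TRUE, n)
  stopifnot(length(windows) == n, length(labels) == n, length(active) == n)
  chans <- lapply(seq_len(n), function(i) {
    w <- as.numeric(windows[[i]])
    stopifnot(length(w) == 4)
    if (!(w[1] <= w[2] && w[2] <= w[3] && w[3] <= w[4]))
      stop("window must satisfy min <= start <= end <= max", call. = FALSE)
    if (!grepl("^[0-9A-Fa-f]{6}$", colors[i]))
      stop("channel color must be 6 hex digits", call. = FALSE)
    list(color = colors[i],
         window = list(min = w[1], start = w[2], end = w[3], max = w[4]),
         label = labels[i], active = active[i])
  })
  list(channels = chans)
}
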