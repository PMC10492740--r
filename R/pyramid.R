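## Multiscale pyramid construction: level planning, mean downsampling for
## intensity images, mode downsampling for label images.

#' PyramidPlan: the level layout of a multiscale pyramid
#'
#' @slot levelShapes List of shape vectors, level 0 (the input shape) first;
#'   downsampled axes shrink by ceiling division at each level.
#' @slot spatialFactor Integer downsampling factor (default 2).
#' @slot downsampledAxes Integer positions of the axes that shrink.
#' @slot minExtent Stop once the largest downsampled extent is at or below
#'   this threshold.
#' @slot maxLevels Optional cap on the number of levels (`NA` = none).
#' @export
setClass("PyramidPlan",
  representation(levelShapes = "list", spatialFactor = "numeric",
                 downsampledAxes = "numeric", minExtent = "numeric",
                 maxLevels = "numeric"),
  validity = function(object) {
    if (!length(object@levelShapes)) return("at least one level required")
    shapes <- object@levelShapes
    for (i in seq_along(shapes)[-1]) {
      if (any(shapes[[i]] > shapes[[i - 1]]))
        return("level shapes must be non-increasing per axis")
      expect <- shapes[[i - 1]]
      expect[object@downsampledAxes] <-
        ceiling(expect[object@downsampledAxes] / object@spatialFactor)
      if (!identical(as.numeric(shapes[[i]]), as.numeric(expect)))
        return("each level must be the ceiling-division of the previous")
    }
    TRUE
  })

#' @rdname PyramidPlan-class
#' @param x A `PyramidPlan`.
#' @export
setGeneric("levelShapes", function(x) standardGeneric("levelShapes"))
#' @rdname PyramidPlan-class
#' @export
setMethod("levelShapes", "PyramidPlan", function(x) x@levelShapes)

setMethod("show", "PyramidPlan", function(object) {
  cat("PyramidPlan:", length(object@levelShapes), "level(s), factor",
      object@spatialFactor, "on axes",
      paste(object@downsampledAxes, collapse = ","), "\n")
  for (i in seq_along(object@levelShapes))
    cat("  level ", i - 1, ": (",
        paste(object@levelShapes[[i]], collapse = ", "), ")\n", sep = "")
})

## which axis positions get downsampled: the y/x space axes by default,
## plus z when includeZ (bioformats2raw-style planar halving)
downsampleAxisPositions <- function(axes, includeZ = FALSE) {
  types <- axisTypes(axes)
  space <- which(types == "space")
  if (length(space) < 2)
    stop("need at least 2 space axes", call. = FALSE)
  yx <- utils::tail(space, 2)
  if (includeZ && length(space) == 3) space else yx
}

#' Plan the resolution levels of a pyramid
#'
#' Repeated ceiling-halving (factor `spatialFactor`) of the downsampled
#' space axes, stopping once the largest downsampled extent is at or below
#' `minExtent` or `maxLevels` is reached. Always yields at least one level;
#' an image already below the threshold gets a single level.
#'
#' @param shape Per-axis extents of the full-resolution image.
#' @param axes Axis list of the same rank (see [defaultAxes()]).
#' @param minExtent Stop threshold, default 256 (one typical display tile).
#' @param maxLevels Optional cap on the level count.
#' @param spatialFactor Per-level factor, default 2.
#' @param includeZ Also downsample z (for isotropic volumes); default FALSE.
#' @return A [PyramidPlan-class].
#' @export
#' @examples
#' levelShapes(planLevels(c(1, 1, 1, 2048, 2048), defaultAxes(5)))
planLevels <- function(shape, axes, minExtent = 256, maxLevels = NULL,
                       spatialFactor = 2, includeZ = FALSE) {
  shape <- as.numeric(shape)
  if (length(shape) != length(axes))
    stop("shape rank ", length(shape), " does not match axis count ",
         length(axes), call. = FALSE)
  if (minExtent < 1)
    stop("minExtent must be at least 1", call. = FALSE)
  ds <- downsampleAxisPositions(axes, includeZ)
  shapes <- list(shape)
  cur <- shape
  repeat {
    if (!is.null(maxLevels) && length(shapes) >= maxLevels) break
    if (max(cur[ds]) <= minExtent) break
    nxt <- cur
    nxt[ds] <- ceiling(nxt[ds] / spatialFactor)
    shapes <- c(shapes, list(nxt))
    cur <- nxt
  }
  new("PyramidPlan", levelShapes = shapes, spatialFactor = spatialFactor,
      downsampledAxes = ds, minExtent = minExtent,
      maxLevels = if (is.null(maxLevels)) NA_real_ else maxLevels)
}

## pad an array with NA up to ceiling multiples of the factors
padToMultiple <- function(block, factors) {
  d <- dim(block)
  padded <- ceiling(d / factors) * factors
  if (identical(padded, d)) return(block)
  out <- array(NA_real_, dim = padded)
  assignBlock(out, rep(0, length(d)), block)
}

## stack every window offset as one column: rows = output cells
windowColumns <- function(block, factors) {
  d <- dim(block)
  outDim <- ceiling(d / factors)
  padded <- padToMultiple(block, factors)
  offsets <- gridIndices(factors)
  cols <- vapply(offsets, function(off) {
    idx <- lapply(seq_along(d),
                  function(a) seq.int(1 + off[a], dim(padded)[a],
                                      by = factors[a]))
    as.vector(do.call(`[`, c(list(padded), idx, list(drop = FALSE))))
  }, numeric(prod(outDim)))
  if (!is.matrix(cols)) cols <- matrix(cols, nrow = prod(outDim))
  list(cols = cols, outDim = outDim)
}

#' Downsample by local mean (intensity images)
#'
#' Output extent is the per-axis ceiling of `extent / factor`. Each output
#' voxel is the arithmetic mean of its (possibly edge-truncated) window,
#' computed in double precision and cast back to the input dtype with
#' round-half-to-even.
#'
#' @param block Dense array.
#' @param factors Per-axis integer window sizes (>= 1).
#' @param dtype Dtype code governing the cast; `"f8"` keeps full precision.
#' @return Dense array of the reduced extent.
#' @export
#' @examples
#' downsampleMean(matrix(c(1, 5, 3, 7), 2), c(2, 2), "u2")  # mean 4
downsampleMean <- function(block, factors, dtype = "f8") {
  d <- dim(block); if (is.null(d)) { d <- length(block); dim(block) <- d }
  factors <- as.numeric(factors)
  if (length(factors) != length(d))
    stop("one factor per axis required", call. = FALSE)
  if (any(factors < 1) || any(factors != floor(factors)))
    stop("factors must be positive integers", call. = FALSE)
  w <- windowColumns(block, factors)
  sums <- rowSums(w$cols, na.rm = TRUE)
  counts <- rowSums(!is.na(w$cols))
  array(castToDtype(sums / counts, dtype), dim = w$outDim)
}

#' Downsample by local mode (label images)
#'
#' Each output voxel is the most frequent value in its window; ties are
#' broken by the smallest value, so downsampled masks stay reproducible.
#' Requires integer-valued input.
#'
#' @inheritParams downsampleMean
#' @return Dense integer-valued array of the reduced extent.
#' @export
#' @examples
#' downsampleMode(matrix(c(1, 2, 2, 1), 2), c(2, 2))  # tie -> 1
downsampleMode <- function(block, factors) {
  d <- dim(block); if (is.null(d)) { d <- length(block); dim(block) <- d }
  if (any(block != floor(block), na.rm = TRUE))
    stop("label images require integer dtype", call. = FALSE)
  factors <- as.numeric(factors)
  if (length(factors) != length(d))
    stop("one factor per axis required", call. = FALSE)
  if (any(factors < 1) || any(factors != floor(factors)))
    stop("factors must be positive integers", call. = FALSE)
  w <- windowColumns(block, factors)
  modes <- apply(w$cols, 1, function(v) {
    v <- v[!is.na(v)]
    vals <- sort(unique(v))
    vals[which.max(tabulate(match(v, vals)))]  # first max = smallest value
  })
  array(modes, dim = w$outDim)
}

#' Build a multiscale pyramid in memory
#'
#' Level 0 is the input unmodified; each further level is derived from the
#' previous by local mean (`kind = "intensity"`) or local mode
#' (`kind = "label"`) over the planned factors. Returns the level blocks
#' together with the matching [MultiscaleMeta-class] whose per-level scales
#' follow [levelScale()].
#'
#' @param data Dense array.
#' @param axes Axis list matching the data rank.
#' @param kind `"intensity"` or `"label"`.
#' @param dtype Dtype code of the data (controls the mean cast).
#' @param baseScale Physical scale of level 0 (default all 1).
#' @param name Optional image name recorded in the metadata.
#' @inheritParams planLevels
#' @return List with elements `levels` (list of arrays) and `meta`.
#' @export
buildPyramid <- function(data, axes, kind = c("intensity", "label"),
                         dtype = "f8", minExtent = 256, maxLevels = NULL,
                         spatialFactor = 2, includeZ = FALSE,
                         baseScale = NULL, name = NA_character_) {
  kind <- match.arg(kind)
  d <- dim(data); if (is.null(d)) { d <- length(data); dim(data) <- d }
  if (length(d) != length(axes))
    stop("data rank does not match axis count", call. = FALSE)
  if (kind == "label" && !dtypeIsInteger(dtype))
    stop("label images require integer dtype", call. = FALSE)
  plan <- planLevels(d, axes, minExtent = minExtent, maxLevels = maxLevels,
                     spatialFactor = spatialFactor, includeZ = includeZ)
  nAxes <- length(axes)
  factors <- rep(1, nAxes)
  factors[plan@downsampledAxes] <- spatialFactor
  levels <- vector("list", length(plan@levelShapes))
  levels[[1]] <- data
  for (i in seq_along(levels)[-1]) {
    levels[[i]] <- if (kind == "label")
      downsampleMode(levels[[i - 1]], factors)
    else downsampleMean(levels[[i - 1]], factors, dtype)
  }
  if (is.null(baseScale)) baseScale <- rep(1, nAxes)
  datasets <- lapply(seq_along(levels), function(i)
    datasetEntry(as.character(i - 1),
                 levelScale(baseScale, i - 1, spatialFactor,
                            plan@downsampledAxes)))
  meta <- multiscaleMeta(axes, datasets, name = name,
                         downsamplingMethod =
                           if (kind == "label") "local mode (ties to smallest label)"
                           else "local mean (edge-truncated windows)")
  list(levels = levels, meta = meta, plan = plan)
}
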