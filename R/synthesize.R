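## Deterministic synthetic fixtures: multichannel 5-D images with known
## ground truth, labeled blob masks, whole HCS plates, and the single-rule
## mutations the validator tests rely on. All randomness comes from an
## explicitly specified Lehmer stream so fixtures are byte-identical
## across runs and platforms.

## Lehmer / Park-Miller multiplicative congruential generator:
## state <- (state * 48271) mod (2^31 - 1). Products stay below 2^47, so
## double arithmetic is exact everywhere.
lcgStream <- function(seed) {
  m <- 2147483647
  state <- as.numeric(seed) %% m
  if (state <= 0) state <- state + m - 1
  env <- new.env(parent = emptyenv())
  env$state <- state
  env
}

lcgNext <- function(rng) {
  rng$state <- (rng$state * 48271) %% 2147483647
  rng$state
}

## uniform integer in [lo, hi]
lcgInt <- function(rng, lo, hi) {
  lo + lcgNext(rng) %% (hi - lo + 1)
}

lcgUnif <- function(rng) lcgNext(rng) / 2147483647

#' Generate a deterministic synthetic image
#'
#' Produces a 2-5 dimensional image with known ground truth. Content
#' kinds: `"gradient"` (a smooth x+y ramp over the dtype range),
#' `"noise"` (uniform values from the package's Lehmer stream) and
#' `"blobs"` (bright disks on a dark background, one label per blob). For
#' blobs the result carries a paired label mask (channel axis collapsed)
#' and a ground-truth table of each blob's center, radius, channel and
#' label id; blobs are placed in disjoint x-strips so every requested blob
#' survives in the mask.
#'
#' @param shape 2-5 per-axis extents, trailing part of (t, c, z, y, x).
#' @param dtype Dtype code for the intensity image.
#' @param content `"gradient"`, `"blobs"` or `"noise"`.
#' @param blobCount Number of blobs (blobs content).
#' @param seed Integer seed; identical specs give identical bytes.
#' @return List with `data` (dense array), and for blobs `labels` (integer
#'   mask) and `truth` (data frame: label, channel, cy, cx, radius).
#' @export
#' @examples
#' img <- makeImage(c(1, 2, 1, 64, 64), content = "blobs", blobCount = 3)
#' img$truth
makeImage <- function(shape, dtype = "u2", content = c("gradient", "blobs",
                                                       "noise"),
                      blobCount = 5L, seed = 42L) {
  content <- match.arg(content)
  shape <- as.numeric(shape)
  if (length(shape) < 2 || length(shape) > 5)
    stop("shape must have between 2 and 5 dimensions", call. = FALSE)
  rng <- lcgStream(seed)
  n <- length(shape)
  ny <- shape[n - 1]; nx <- shape[n]
  r <- dtypeRange(dtype)
  hi <- if (is.finite(r[2])) r[2] else 1
  axes <- defaultAxes(n)
  nC <- if ("c" %in% axisNames(axes)) shape[axisNames(axes) == "c"] else 1

  if (content == "gradient") {
    ramp <- outer(seq_len(ny) - 1, seq_len(nx) - 1, `+`)
    ramp <- castToDtype(ramp / max(ramp[length(ramp)], 1) * hi, dtype)
    data <- array(0, dim = shape)
    data <- sweepPlane(data, ramp)
    return(list(data = data, truth = NULL, labels = NULL))
  }

  if (content == "noise") {
    total <- prod(shape)
    vals <- numeric(total)
    for (i in seq_len(total))
      vals[i] <- if (dtypeIsInteger(dtype)) lcgInt(rng, r[1], min(r[2], r[1] + 2^16))
                 else lcgUnif(rng)
    return(list(data = array(vals, dim = shape), truth = NULL,
                labels = NULL))
  }

  ## blobs: one disjoint x-strip per blob, random center/radius per strip
  if (blobCount < 0) stop("blobCount must be non-negative", call. = FALSE)
  data <- array(0, dim = shape)
  maskShape <- if ("c" %in% axisNames(axes))
    shape[axisNames(axes) != "c"] else shape
  if (length(maskShape) < 2) maskShape <- c(ny, nx)
  mask <- array(0, dim = maskShape)
  truth <- NULL
  if (blobCount > 0) {
    strip <- floor(nx / blobCount)
    if (strip < 3)
      stop("x extent too small for ", blobCount, " disjoint blobs",
           call. = FALSE)
    for (b in seq_len(blobCount)) {
      x0 <- (b - 1) * strip
      maxR <- max(1, floor((strip - 1) / 2) - 1)
      radius <- lcgInt(rng, 1, min(maxR, max(1, floor(ny / 4))))
      cx <- x0 + lcgInt(rng, radius, strip - 1 - radius)
      cy <- lcgInt(rng, radius, ny - 1 - radius)
      channel <- lcgInt(rng, 0, nC - 1)
      disk <- outer(seq_len(ny) - 1 - cy, seq_len(nx) - 1 - cx,
                    function(dy, dx) dy^2 + dx^2 <= radius^2)
      intensity <- castToDtype(hi * (0.5 + 0.5 * lcgUnif(rng)), dtype)
      data <- paintDisk(data, disk, channel, intensity, axes)
      mask <- paintMask(mask, disk, b)
      truth <- rbind(truth,
                     data.frame(label = b, channel = channel, cy = cy,
                                cx = cx, radius = radius))
    }
  }
  list(data = data, truth = truth, labels = mask)
}

## broadcast a (y, x) plane over all leading axes
sweepPlane <- function(data, plane) {
  d <- dim(data); n <- length(d)
  lead <- prod(d[-c(n - 1, n)])
  flat <- array(rep(as.vector(plane), each = max(lead, 1)), dim = c(lead, d[n - 1], d[n]))
  array(flat, dim = d)
}

## set disk pixels on one channel (all t/z), leaving others untouched
paintDisk <- function(data, disk, channel, value, axes) {
  d <- dim(data); n <- length(d)
  names_ <- axisNames(axes)
  idx <- lapply(seq_len(n), function(a) seq_len(d[a]))
  if ("c" %in% names_) idx[[which(names_ == "c")]] <- channel + 1
  sub <- do.call(`[`, c(list(data), idx, list(drop = FALSE)))
  subDim <- dim(sub)
  lead <- prod(subDim[-c(n - 1, n)])
  flat <- array(sub, dim = c(lead, subDim[n - 1], subDim[n]))
  for (l in seq_len(lead)) {
    pl <- flat[l, , ]
    pl[disk] <- value
    flat[l, , ] <- pl
  }
  sub <- array(flat, dim = subDim)
  do.call(`[<-`, c(list(data), idx, list(value = sub)))
}

paintMask <- function(mask, disk, label) {
  d <- dim(mask); n <- length(d)
  lead <- prod(d[-c(n - 1, n)])
  flat <- array(mask, dim = c(lead, d[n - 1], d[n]))
  for (l in seq_len(lead)) {
    pl <- flat[l, , ]
    pl[disk] <- label
    flat[l, , ] <- pl
  }
  array(flat, dim = d)
}

#' Write a synthetic image fixture to a store
#'
#' Convenience wrapper: generates with [makeImage()] and writes a full
#' multiscale image (plus, for blobs, its label mask under
#' `labels/blobs`).
#'
#' @inheritParams makeImage
#' @param store A [KVStore-class].
#' @param path Image group path.
#' @param withLabels Also write the blob label mask (blobs content only).
#' @param ... Passed to [writeMultiscaleImage()].
#' @return The image path, invisibly.
#' @export
makeImageFixture <- function(store, path, shape = c(1, 1, 1, 64, 64),
                             dtype = "u2", content = "gradient",
                             blobCount = 5L, seed = 42L,
                             withLabels = FALSE, ...) {
  img <- makeImage(shape, dtype, content, blobCount, seed)
  writeMultiscaleImage(store, path, img$data, dtype = dtype, ...)
  if (withLabels && !is.null(img$labels)) {
    colors <- if (!is.null(img$truth))
      data.frame(labelValue = img$truth$label,
                 r = (img$truth$label * 53) %% 256,
                 g = (img$truth$label * 101) %% 256,
                 b = (img$truth$label * 197) %% 256, a = 255)
    else NULL
    writeLabels(store, path, "blobs", img$labels,
                meta = labelMeta(colors = colors), dtype = "i4", ...)
  }
  invisible(path)
}

#' Write a full synthetic HCS plate fixture
#'
#' Generates a complete plate: every well holds `fields` multiscale field
#' images with deterministic per-well content (seed derived from the base
#' seed and the well position).
#'
#' @param store A [KVStore-class].
#' @param path Plate group path.
#' @param rows,cols Grid dimensions (rows named "A", "B", ...; columns
#'   "1", "2", ...).
#' @param fields Fields per well.
#' @param shape Per-field image shape.
#' @param dtype Dtype code.
#' @param seed Base seed.
#' @param missingWells Character vector of well paths to leave unwritten
#'   (sparse plates).
#' @param ... Passed to [writeMultiscaleImage()] via [writePlate()].
#' @return The plate path, invisibly.
#' @export
makePlateFixture <- function(store, path, rows = 2L, cols = 3L,
                             fields = 1L, shape = c(1, 1, 1, 32, 32),
                             dtype = "u2", seed = 42L,
                             missingWells = character(0), ...) {
  if (rows < 1 || cols < 1)
    stop("plate grid dimensions must be positive", call. = FALSE)
  rowNames <- LETTERS[seq_len(rows)]
  colNames <- as.character(seq_len(cols))
  plate <- plateMeta(rowNames, colNames, fieldCount = fields)
  wellPaths <- setdiff(plate@wells$path, missingWells)
  fieldImgs <- lapply(seq_along(wellPaths), function(i) {
    lapply(seq_len(fields), function(f) {
      s <- (seed + 9973 * i + 131 * f) %% 2147483647
      makeImage(shape, dtype, "noise", seed = s)$data
    })
  })
  names(fieldImgs) <- wellPaths
  writePlate(store, path, plate, fieldImgs, dtype = dtype, ...)
  invisible(path)
}

## ---- single-rule mutations (for validator tests) ----

.MUTATIONS <- c("axes6", "axesOrder", "dropMultiscales", "missingDataset",
                "datasetRank", "levelOrder", "transformLength",
                "scaleOrder", "unknownCodec", "deleteChunk", "labelDtype",
                "labelUnlisted", "wellPath", "missingWell", "dropPlate")

#' Mutate a valid fixture to violate exactly one rule
#'
#' Each mutation flips a single validation rule on an otherwise valid
#' tree, so the validator's finding codes can be exercised one at a time.
#'
#' @param store A [KVStore-class].
#' @param path Image (or plate, for the well mutations) group path.
#' @param mutation Mutation name; see [mutationNames()] for the list.
#' @return The expected finding code, invisibly.
#' @export
applyMutation <- function(store, path, mutation) {
  mutation <- match.arg(mutation, .MUTATIONS)
  editAttrs <- function(edit) {
    attrs <- getAttrs(store, path)
    putAttrs(store, path, edit(attrs))
  }
  editMs <- function(edit) editAttrs(function(attrs) {
    attrs$multiscales[[1]] <- edit(attrs$multiscales[[1]])
    attrs
  })
  code <- switch(mutation,
    axes6 = {
      editMs(function(ms) {
        ms$axes <- c(list(list(name = "q", type = "time")), ms$axes)
        ms
      })
      "E_AXES_COUNT"
    },
    axesOrder = {
      editMs(function(ms) { ms$axes <- rev(ms$axes); ms })
      "E_AXES_ORDER"
    },
    dropMultiscales = {
      editAttrs(function(attrs) { attrs$multiscales <- NULL; attrs })
      "E_MISSING_MULTISCALES"
    },
    missingDataset = {
      kvDelete(store, joinKey(path, "0", ".zarray"))
      "E_MISSING_DATASET"
    },
    datasetRank = {
      doc <- jsonGet(store, joinKey(path, "0", ".zarray"))
      doc$shape <- c(doc$shape, list(1L))
      doc$chunks <- c(doc$chunks, list(1L))
      jsonPut(store, joinKey(path, "0", ".zarray"), doc)
      "E_DATASET_RANK"
    },
    levelOrder = {
      ## swap the first and last dataset paths only, keeping the scale
      ## transforms in place so only the shape ordering rule flips
      editMs(function(ms) {
        last <- length(ms$datasets)
        if (last < 2) stop("levelOrder mutation needs >= 2 levels")
        p1 <- ms$datasets[[1]]$path
        ms$datasets[[1]]$path <- ms$datasets[[last]]$path
        ms$datasets[[last]]$path <- p1
        ms
      })
      "E_LEVEL_ORDER"
    },
    transformLength = {
      editMs(function(ms) {
        ct <- ms$datasets[[1]]$coordinateTransformations
        ct[[1]]$scale <- ct[[1]]$scale[-1]
        ms$datasets[[1]]$coordinateTransformations <- ct
        ms
      })
      "E_TRANSFORM_LENGTH"
    },
    scaleOrder = {
      editMs(function(ms) {
        last <- length(ms$datasets)
        if (last < 2) stop("scaleOrder mutation needs >= 2 levels")
        ct <- ms$datasets[[last]]$coordinateTransformations
        ct[[1]]$scale <- lapply(ct[[1]]$scale, function(s) 0.25 * as.numeric(s))
        ms$datasets[[last]]$coordinateTransformations <- ct
        ms
      })
      "E_SCALE_ORDER"
    },
    unknownCodec = {
      doc <- jsonGet(store, joinKey(path, "0", ".zarray"))
      doc$compressor <- list(id = "lz99")
      jsonPut(store, joinKey(path, "0", ".zarray"), doc)
      "W_UNKNOWN_CODEC"
    },
    deleteChunk = {
      doc <- jsonGet(store, joinKey(path, "0", ".zarray"))
      sep <- if (is.null(doc$dimension_separator)) "." else
        doc$dimension_separator[[1]]
      key <- chunkKey(joinKey(path, "0"),
                      rep(0, length(doc$shape)), sep)
      kvDelete(store, key)
      "I_IMPLICIT_FILL_CHUNK"
    },
    labelDtype = {
      nm <- listLabels(store, path)[1]
      if (is.na(nm)) stop("labelDtype mutation needs a label subtree")
      key <- joinKey(path, "labels", nm, "0", ".zarray")
      doc <- jsonGet(store, key)
      doc$dtype <- "<f4"
      jsonPut(store, key, doc)
      "E_LABEL_DTYPE"
    },
    labelUnlisted = {
      nm <- listLabels(store, path)[1]
      if (is.na(nm)) stop("labelUnlisted mutation needs a label subtree")
      lg <- joinKey(path, "labels")
      putAttrs(store, lg, list(labels = I(character(0))))
      "W_LABEL_UNLISTED"
    },
    wellPath = {
      attrs <- getAttrs(store, path)
      attrs$plate$wells[[1]]$path <- "Z/99"
      putAttrs(store, path, attrs)
      "E_WELL_PATH"
    },
    missingWell = {
      attrs <- getAttrs(store, path)
      wp <- attrs$plate$wells[[1]]$path[[1]]
      for (k in kvList(store, joinKey(path, wp))) kvDelete(store, k)
      "E_MISSING_WELL"
    },
    dropPlate = {
      editAttrs(function(attrs) { attrs$plate <- NULL; attrs })
      "E_MISSING_PLATE"
    })
  invisible(code)
}

#' @rdname applyMutation
#' @export
mutationNames <- function() .MUTATIONS
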