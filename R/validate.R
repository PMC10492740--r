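## Rule-based validation of OME-Zarr trees and a human-readable summary.
## Every rule has a stable finding code with a registered severity; a tree
## is ok iff no finding of severity "error" was produced.

.FINDING_CODES <- c(
  E_MISSING_MULTISCALES = "error",   # group lacks parseable multiscales
  E_AXES_COUNT          = "error",   # axis count outside 2..5
  E_AXES_ORDER          = "error",   # axis types/order/duplication illegal
  E_MISSING_DATASET     = "error",   # listed level has no stored array
  E_DATASET_RANK        = "error",   # array rank != axis count
  E_LEVEL_ORDER         = "error",   # shapes not non-increasing with level
  E_TRANSFORM_LENGTH    = "error",   # scale transform wrong/missing length
  E_SCALE_ORDER         = "error",   # per-axis scale decreases with level
  E_LABEL_DTYPE         = "error",   # label image stored with float dtype
  E_MISSING_PLATE       = "error",   # plate group lacks plate attributes
  E_WELL_PATH           = "error",   # well path malformed or undeclared
  E_MISSING_WELL        = "error",   # listed well group absent from store
  W_UNKNOWN_CODEC       = "warning", # codec id with no registered impl
  W_LABEL_UNLISTED      = "warning", # label subtree missing from listing
  I_IMPLICIT_FILL_CHUNK = "info"     # grid cells with no stored object
)

#' The registry of validation finding codes
#'
#' @return Named character vector mapping each stable finding code to its
#'   registered severity (`error`, `warning` or `info`).
#' @export
findingCodes <- function() .FINDING_CODES

#' ValidationReport: ordered findings from rule evaluation
#'
#' @slot findings Data frame with columns `severity`, `code`, `path`,
#'   `message`, ordered by path then code.
#' @slot ok `TRUE` iff no finding has severity `error`.
#' @export
setClass("ValidationReport",
  representation(findings = "data.frame", ok = "logical"),
  validity = function(object) {
    f <- object@findings
    need <- c("severity", "code", "path", "message")
    if (!all(need %in% names(f)))
      return("findings need severity, code, path, message columns")
    if (nrow(f)) {
      bad <- !f$code %in% names(.FINDING_CODES)
      if (any(bad))
        return(paste0("unregistered finding code '", f$code[bad][1], "'"))
      if (!identical(f$severity, unname(.FINDING_CODES[f$code])))
        return("finding severity inconsistent with the code registry")
    }
    if (!identical(object@ok, !any(f$severity == "error")))
      return("ok flag inconsistent with findings")
    TRUE
  })

newFinding <- function(code, path, message) {
  data.frame(severity = unname(.FINDING_CODES[code]), code = code,
             path = path, message = message, stringsAsFactors = FALSE)
}

emptyFindings <- function() {
  data.frame(severity = character(0), code = character(0),
             path = character(0), message = character(0),
             stringsAsFactors = FALSE)
}

makeReport <- function(findings) {
  findings <- findings[order(findings$path, findings$code), , drop = FALSE]
  rownames(findings) <- NULL
  new("ValidationReport", findings = findings,
      ok = !any(findings$severity == "error"))
}

#' @rdname ValidationReport-class
#' @param x A `ValidationReport`.
#' @export
setGeneric("reportOk", function(x) standardGeneric("reportOk"))
#' @rdname ValidationReport-class
#' @export
setMethod("reportOk", "ValidationReport", function(x) x@ok)

#' @rdname ValidationReport-class
#' @export
setGeneric("reportFindings", function(x) standardGeneric("reportFindings"))
#' @rdname ValidationReport-class
#' @export
setMethod("reportFindings", "ValidationReport", function(x) x@findings)

setMethod("show", "ValidationReport", function(object) {
  f <- object@findings
  cat("ValidationReport:", if (object@ok) "OK" else "INVALID",
      "(", sum(f$severity == "error"), "error(s),",
      sum(f$severity == "warning"), "warning(s),",
      sum(f$severity == "info"), "info )\n")
  for (i in seq_len(nrow(f)))
    cat(sprintf("  [%s] %s @ %s: %s\n", toupper(f$severity[i]), f$code[i],
                f$path[i], f$message[i]))
})

## count grid cells without a stored chunk object
missingChunkCount <- function(store, path, schema) {
  grid <- gridShape(schema@shape, schema@chunkShape)
  n <- 0L
  for (cell in gridIndices(grid))
    if (!kvExists(store, chunkKey(path, cell, schema@dimensionSeparator)))
      n <- n + 1L
  n
}

## validate one multiscales entry (already decoded JSON) against the rules
validateMultiscalesEntry <- function(store, path, ms, entryPath, isLabel) {
  f <- emptyFindings()
  axes <- ms$axes
  if (is.null(axes) || !length(axes)) {
    f <- rbind(f, newFinding("E_MISSING_MULTISCALES", entryPath,
                             "multiscales entry lacks an axes list"))
    return(f)
  }
  nAxes <- length(axes)
  axesCountOk <- nAxes >= 2 && nAxes <= 5
  if (!axesCountOk) {
    f <- rbind(f, newFinding("E_AXES_COUNT", entryPath,
      paste0("axis count ", nAxes,
             " outside the supported range 2-5 (version 0.4 images are ",
             "at most 5-dimensional: t, c, z, y, x)")))
  } else {
    types <- vapply(axes, function(a)
      if (is.null(a$type)) "" else a$type[[1]], "")
    names_ <- vapply(axes, function(a)
      if (is.null(a$name)) "" else a$name[[1]], "")
    rank <- c(time = 1, channel = 2, space = 3)[types]
    nspace <- sum(types == "space", na.rm = TRUE)
    if (any(!types %in% AXIS_TYPES) || anyDuplicated(names_) ||
        sum(types == "time") > 1 || sum(types == "channel") > 1 ||
        nspace < 2 || nspace > 3 || is.unsorted(rank)) {
      f <- rbind(f, newFinding("E_AXES_ORDER", entryPath,
        "axes must be unique, typed time/channel/space and ordered time, channel, then 2-3 space axes"))
    }
  }
  datasets <- ms$datasets
  if (is.null(datasets) || !length(datasets)) {
    f <- rbind(f, newFinding("E_MISSING_MULTISCALES", entryPath,
                             "multiscales entry lacks datasets"))
    return(f)
  }
  prevShape <- NULL
  prevScale <- NULL
  for (di in seq_along(datasets)) {
    ds <- datasets[[di]]
    dsPath <- if (is.null(ds$path)) "?" else ds$path[[1]]
    nodePath <- joinKey(path, dsPath)
    schema <- NULL
    if (!isArray(store, nodePath)) {
      f <- rbind(f, newFinding("E_MISSING_DATASET", nodePath,
        paste0("dataset '", dsPath, "' listed but no array is stored there")))
    } else {
      schema <- tryCatch(readSchema(store, nodePath), error = function(e) e)
      if (inherits(schema, "error")) {
        f <- rbind(f, newFinding("E_MISSING_DATASET", nodePath,
          paste0("array metadata unreadable: ",
                 conditionMessage(schema))))
        schema <- NULL
      }
    }
    if (!is.null(schema)) {
      if (axesCountOk && length(schema@shape) != nAxes)
        f <- rbind(f, newFinding("E_DATASET_RANK", nodePath,
          paste0("array rank ", length(schema@shape),
                 " does not match the ", nAxes, " declared axes")))
      if (!is.null(prevShape) &&
          length(prevShape) == length(schema@shape) &&
          any(schema@shape > prevShape))
        f <- rbind(f, newFinding("E_LEVEL_ORDER", nodePath,
          "level shapes must be non-increasing (highest resolution first)"))
      prevShape <- schema@shape
      if (!is.null(schema@codec) &&
          !schema@codec@id %in% registeredCodecs())
        f <- rbind(f, newFinding("W_UNKNOWN_CODEC", nodePath,
          paste0("codec '", schema@codec@id,
                 "' has no registered implementation; chunks cannot be ",
                 "decoded here")))
      if (isLabel && !dtypeIsInteger(schema@dtype))
        f <- rbind(f, newFinding("E_LABEL_DTYPE", nodePath,
          paste0("label images require integer dtype, found '",
                 schema@dtype, "'")))
      nMissing <- missingChunkCount(store, nodePath, schema)
      if (nMissing > 0)
        f <- rbind(f, newFinding("I_IMPLICIT_FILL_CHUNK", nodePath,
          paste0(nMissing, " grid cell(s) have no stored object and read ",
                 "as the fill value")))
    }
    ## transform checks from the JSON itself (independent of the array)
    cts <- ds$coordinateTransformations
    scales <- NULL
    if (!is.null(cts)) {
      ctTypes <- vapply(cts, function(ct)
        if (is.null(ct$type)) "" else ct$type[[1]], "")
      if ("scale" %in% ctTypes)
        scales <- unlist(cts[[which(ctTypes == "scale")[1]]]$scale)
    }
    if (is.null(scales) || (axesCountOk && length(scales) != nAxes)) {
      f <- rbind(f, newFinding("E_TRANSFORM_LENGTH", nodePath,
        paste0("dataset must carry one scale transform with ", nAxes,
               " entries")))
    } else {
      if (!is.null(prevScale) && length(prevScale) == length(scales) &&
          any(scales < prevScale))
        f <- rbind(f, newFinding("E_SCALE_ORDER", nodePath,
          "per-axis scale must be non-decreasing with level"))
      prevScale <- scales
    }
  }
  f
}

## lenient label-subtree walk
validateLabelsSubtree <- function(store, path) {
  f <- emptyFindings()
  labelsGroup <- joinKey(path, "labels")
  listed <- getAttrs(store, labelsGroup)$labels
  listed <- if (is.null(listed)) character(0) else unlist(listed)
  for (nm in listed) {
    rep_ <- validateNode(store, joinKey(labelsGroup, nm), isLabel = TRUE)
    f <- rbind(f, rep_)
  }
  ## subgroups that exist but are not listed
  present <- unique(dirname(grep(paste0("^", labelsGroup, "/[^/]+/\\.zgroup$"),
                                 kvList(store, labelsGroup), value = TRUE)))
  present <- basename(present)
  for (nm in setdiff(present, listed))
    f <- rbind(f, newFinding("W_LABEL_UNLISTED", joinKey(labelsGroup, nm),
      paste0("label image '", nm, "' exists but is not in the labels listing")))
  f
}

validateNode <- function(store, path, isLabel = FALSE) {
  f <- emptyFindings()
  attrs <- tryCatch(getAttrs(store, path), error = function(e) e)
  if (inherits(attrs, "error") || is.null(attrs$multiscales) ||
      !length(attrs$multiscales)) {
    return(rbind(f, newFinding("E_MISSING_MULTISCALES", path,
      "group has no parseable multiscales attribute")))
  }
  for (mi in seq_along(attrs$multiscales)) {
    entryPath <- if (length(attrs$multiscales) > 1)
      paste0(path, "#", mi - 1) else path
    f <- rbind(f, validateMultiscalesEntry(store, path,
                                           attrs$multiscales[[mi]],
                                           entryPath, isLabel))
  }
  f
}

#' Validate a multiscale image tree
#'
#' Evaluates the full rule set against the image group at `path`:
#' multiscales present and parseable, 2-5 axes with legal types and
#' time/channel/space order, every listed level stored with matching rank,
#' shapes non-increasing and scales non-decreasing with level, exactly one
#' scale transform of the right length per level, label subtrees integer-
#' typed and listed. Unknown codecs are warnings; grid cells without a
#' stored chunk are informational (implicit fill).
#'
#' @param store A [KVStore-class].
#' @param path Image group path; an error is raised (not a finding) when
#'   nothing exists there.
#' @return A [ValidationReport-class].
#' @export
validateImage <- function(store, path) {
  if (!length(kvList(store, path)))
    stop("path not found: '", path, "'", call. = FALSE)
  f <- validateNode(store, path)
  f <- rbind(f, validateLabelsSubtree(store, path))
  makeReport(f)
}

#' Validate an HCS plate tree
#'
#' Checks the plate attribute block, every declared well path against the
#' row/column name lists, the presence of every listed well group, and
#' validates each field as an image, aggregating all findings with
#' per-node paths.
#'
#' @inheritParams validateImage
#' @return A [ValidationReport-class].
#' @export
validatePlate <- function(store, path) {
  if (!length(kvList(store, path)))
    stop("path not found: '", path, "'", call. = FALSE)
  f <- emptyFindings()
  attrs <- tryCatch(getAttrs(store, path), error = function(e) e)
  if (inherits(attrs, "error") || is.null(attrs$plate))
    return(makeReport(newFinding("E_MISSING_PLATE", path,
      "group has no parseable plate attribute")))
  doc <- attrs$plate
  plate <- tryCatch(parsePlateDoc(doc), error = function(e) e)
  if (inherits(plate, "error"))
    return(makeReport(newFinding("E_MISSING_PLATE", path,
      paste0("plate attributes invalid: ", conditionMessage(plate)))))
  rows <- plate$rowNames; cols <- plate$columnNames
  for (i in seq_len(nrow(plate$wells))) {
    wp <- plate$wells$path[i]
    wellNode <- joinKey(path, wp)
    parts <- strsplit(wp, "/", fixed = TRUE)[[1]]
    okPath <- length(parts) == 2 && parts[1] %in% rows &&
      parts[2] %in% cols &&
      identical(rows[plate$wells$rowIndex[i] + 1], parts[1]) &&
      identical(cols[plate$wells$columnIndex[i] + 1], parts[2])
    if (!isTRUE(okPath)) {
      f <- rbind(f, newFinding("E_WELL_PATH", wellNode,
        paste0("well path '", wp,
               "' is not '{row_name}/{column_name}' over the declared names")))
      next
    }
    if (!isGroup(store, wellNode)) {
      f <- rbind(f, newFinding("E_MISSING_WELL", wellNode,
        paste0("well '", wp, "' is listed but has no stored group")))
      next
    }
    wellAttrs <- getAttrs(store, wellNode)
    images <- wellAttrs$well$images
    if (is.null(images)) next
    for (im in images) {
      imgPath <- joinKey(wellNode, im$path[[1]])
      f <- rbind(f, validateNode(store, imgPath))
    }
  }
  makeReport(f)
}

#' TreeSummary: size and layout overview of a stored tree
#'
#' @slot path Tree path the summary concerns.
#' @slot levels Data frame, one row per resolution level: `path`, `dtype`,
#'   `shape`, `chunks` (comma-joined extents), `nchunks` (grid cells),
#'   `storedChunks`, `storedBytes`, `rawBytes`.
#' @slot totalVoxels Product of the level-0 extents.
#' @slot plateGrid `c(rows, columns)` for plates, `NA` otherwise.
#' @export
setClass("TreeSummary",
  representation(path = "character", levels = "data.frame",
                 totalVoxels = "numeric", plateGrid = "numeric"))

setMethod("show", "TreeSummary", function(object) {
  cat("TreeSummary of '", object@path, "'\n", sep = "")
  if (!any(is.na(object@plateGrid)))
    cat("  plate grid:", object@plateGrid[1], "rows x",
        object@plateGrid[2], "columns\n")
  cat("  total voxels (level 0):",
      format(object@totalVoxels, big.mark = ",", scientific = FALSE), "\n")
  lv <- object@levels
  for (i in seq_len(nrow(lv)))
    cat(sprintf("  level %s: <%s> shape (%s) chunks (%s) %d/%d chunk(s) stored, %s bytes (raw %s)\n",
                lv$path[i], lv$dtype[i], lv$shape[i], lv$chunks[i],
                lv$storedChunks[i], lv$nchunks[i],
                format(lv$storedBytes[i], big.mark = ","),
                format(lv$rawBytes[i], big.mark = ",")))
})

storedByteSize <- function(store, path, schema) {
  total <- 0
  stored <- 0L
  grid <- gridShape(schema@shape, schema@chunkShape)
  for (cell in gridIndices(grid)) {
    key <- chunkKey(path, cell, schema@dimensionSeparator)
    if (kvExists(store, key)) {
      total <- total + length(kvGet(store, key))
      stored <- stored + 1L
    }
  }
  list(bytes = total, stored = stored, nchunks = prod(grid))
}

#' Summarize a stored image or plate
#'
#' Reports per-level geometry (shape, chunk shape, chunk counts), stored
#' and raw byte totals, the dtype, the total voxel count of level 0 and,
#' for plates, the grid dimensions. For a plate the levels of the first
#' present field are reported.
#'
#' @inheritParams validateImage
#' @return A [TreeSummary-class].
#' @export
summarizeTree <- function(store, path) {
  if (!length(kvList(store, path)))
    stop("path not found: '", path, "'", call. = FALSE)
  attrs <- getAttrs(store, path)
  plateGrid <- c(NA_real_, NA_real_)
  imgPath <- path
  if (!is.null(attrs$plate)) {
    plate <- parsePlateDoc(attrs$plate)
    plateGrid <- c(length(plate$rowNames), length(plate$columnNames))
    imgPath <- NULL
    for (wp in plate$wells$path) {
      cand <- joinKey(path, wp, "0")
      if (isGroup(store, cand)) { imgPath <- cand; break }
    }
    if (is.null(imgPath))
      stop("plate has no stored field images to summarize", call. = FALSE)
  }
  meta <- readImageMeta(store, imgPath)
  rows <- lapply(meta@datasets, function(ds) {
    nodePath <- joinKey(imgPath, ds@path)
    schema <- readSchema(store, nodePath)
    sz <- storedByteSize(store, nodePath, schema)
    data.frame(path = ds@path, dtype = schema@dtype,
               shape = paste(schema@shape, collapse = ", "),
               chunks = paste(schema@chunkShape, collapse = ", "),
               nchunks = sz$nchunks, storedChunks = sz$stored,
               storedBytes = sz$bytes,
               rawBytes = rawByteSize(schema@shape, schema@dtype),
               stringsAsFactors = FALSE)
  })
  levels <- do.call(rbind, rows)
  level0 <- readSchema(store, joinKey(imgPath, meta@datasets[[1]]@path))
  new("TreeSummary", path = path, levels = levels,
      totalVoxels = prod(level0@shape), plateGrid = plateGrid)
}

#' Render a validation report as a JSON document
#'
#' @param report A [ValidationReport-class].
#' @return A JSON string with fields `ok` and `findings`.
#' @export
reportToJson <- function(report) {
  as.character(jsonlite::toJSON(
    list(ok = report@ok,
         findings = lapply(seq_len(nrow(report@findings)), function(i)
           as.list(report@findings[i, ]))),
    auto_unbox = TRUE, pretty = 2))
}
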