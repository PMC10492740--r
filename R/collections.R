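## Grouped-image containers: the HCS plate -> well -> field hierarchy,
## plate montages, and label images stored beside their source image.

#' PlateMeta: layout of a high-content-screening plate
#'
#' @slot rowNames Ordered row names (conventionally letters "A", "B", ...).
#' @slot columnNames Ordered column names (conventionally "1", "2", ...).
#' @slot wells Data frame with columns `path` ("{row}/{column}"),
#'   `rowIndex`, `columnIndex` (zero-based into the name lists).
#' @slot fieldCount Maximum number of fields per well (>= 1).
#' @slot acquisitions Optional data frame with columns `id`, `name`
#'   (zero rows when absent).
#' @export
setClass("PlateMeta",
  representation(rowNames = "character", columnNames = "character",
                 wells = "data.frame", fieldCount = "numeric",
                 acquisitions = "data.frame"),
  validity = function(object) {
    ok <- function(x) all(grepl("^[A-Za-z0-9]+$", x))
    if (!length(object@rowNames) || !ok(object@rowNames))
      return("row names must be non-empty alphanumeric strings")
    if (!length(object@columnNames) || !ok(object@columnNames))
      return("column names must be non-empty alphanumeric strings")
    if (anyDuplicated(object@rowNames) || anyDuplicated(object@columnNames))
      return("row/column names must be unique")
    w <- object@wells
    if (!all(c("path", "rowIndex", "columnIndex") %in% names(w)))
      return("wells must have path, rowIndex, columnIndex")
    if (anyDuplicated(w$path)) return("duplicate well path")
    if (nrow(w)) {
      if (any(w$rowIndex < 0) || any(w$rowIndex >= length(object@rowNames)) ||
          any(w$columnIndex < 0) ||
          any(w$columnIndex >= length(object@columnNames)))
        return("well indices must point into the row/column name lists")
      expect <- paste(object@rowNames[w$rowIndex + 1],
                      object@columnNames[w$columnIndex + 1], sep = "/")
      if (!identical(as.character(w$path), expect))
        return("well paths must be '{row_name}/{column_name}'")
    }
    if (object@fieldCount < 1 ||
        object@fieldCount != floor(object@fieldCount))
      return("field count must be a positive integer")
    TRUE
  })

#' @rdname PlateMeta-class
#' @param rowNames,columnNames,fieldCount,acquisitions See slots.
#' @param wells Optional wells data frame; by default every row x column
#'   position is filled.
#' @export
#' @examples
#' plateMeta(c("A", "B"), c("1", "2", "3"))
plateMeta <- function(rowNames, columnNames, fieldCount = 1L,
                      wells = NULL, acquisitions = NULL) {
  if (is.null(wells)) {
    grid <- expand.grid(columnIndex = seq_along(columnNames) - 1,
                        rowIndex = seq_along(rowNames) - 1)
    wells <- data.frame(
      path = paste(rowNames[grid$rowIndex + 1],
                   columnNames[grid$columnIndex + 1], sep = "/"),
      rowIndex = grid$rowIndex, columnIndex = grid$columnIndex,
      stringsAsFactors = FALSE)
    wells <- wells[order(wells$rowIndex, wells$columnIndex), ]
    rownames(wells) <- NULL
  }
  if (is.null(acquisitions))
    acquisitions <- data.frame(id = integer(0), name = character(0))
  new("PlateMeta", rowNames = as.character(rowNames),
      columnNames = as.character(columnNames), wells = wells,
      fieldCount = as.numeric(fieldCount), acquisitions = acquisitions)
}

setMethod("show", "PlateMeta", function(object) {
  cat("PlateMeta ", length(object@rowNames), " x ",
      length(object@columnNames), " (", nrow(object@wells), " wells, ",
      object@fieldCount, " field(s))\n", sep = "")
})

#' @rdname PlateMeta-class
#' @param x A `PlateMeta`.
#' @export
setGeneric("plateWells", function(x) standardGeneric("plateWells"))
#' @rdname PlateMeta-class
#' @export
setMethod("plateWells", "PlateMeta", function(x) x@wells)

#' Store path of a well
#'
#' @param rowName,columnName Non-empty alphanumeric names.
#' @return `"{row}/{column}"`.
#' @export
#' @examples
#' wellPath("A", "1")
wellPath <- function(rowName, columnName) {
  for (nm in c(rowName, columnName))
    if (!is.character(nm) || length(nm) != 1L ||
        !grepl("^[A-Za-z0-9]+$", nm))
      stop("well row/column names must be non-empty alphanumeric strings",
           call. = FALSE)
  paste(rowName, columnName, sep = "/")
}

#' LabelMeta: display and provenance metadata of a label image
#'
#' @slot colors Data frame with columns `labelValue` and `r`, `g`, `b`, `a`
#'   in 0..255 (zero rows when absent).
#' @slot source Path of the segmented source image (`NA` when unknown).
#' @slot properties Optional per-label records (list of named lists, each
#'   carrying `labelValue`).
#' @export
setClass("LabelMeta",
  representation(colors = "data.frame", source = "character",
                 properties = "list"),
  validity = function(object) {
    co <- object@colors
    if (nrow(co)) {
      if (!all(c("labelValue", "r", "g", "b", "a") %in% names(co)))
        return("colors need labelValue, r, g, b, a columns")
      if (anyDuplicated(co$labelValue))
        return("label values in colors must be unique")
      rgba <- as.matrix(co[, c("r", "g", "b", "a")])
      if (any(rgba < 0) || any(rgba > 255))
        return("RGBA components must lie in [0, 255]")
    }
    TRUE
  })

#' @rdname LabelMeta-class
#' @param colors,source,properties See slots.
#' @export
labelMeta <- function(colors = NULL, source = NA_character_,
                      properties = list()) {
  if (is.null(colors))
    colors <- data.frame(labelValue = numeric(0), r = numeric(0),
                         g = numeric(0), b = numeric(0), a = numeric(0))
  new("LabelMeta", colors = colors, source = as.character(source),
      properties = properties)
}

## ---- plate I/O ----

plateToDoc <- function(plate) {
  doc <- list(
    version = NGFF_VERSION,
    rows = lapply(plate@rowNames, function(r) list(name = r)),
    columns = lapply(plate@columnNames, function(c) list(name = c)),
    wells = lapply(seq_len(nrow(plate@wells)), function(i)
      list(path = plate@wells$path[i],
           rowIndex = as.integer(plate@wells$rowIndex[i]),
           columnIndex = as.integer(plate@wells$columnIndex[i]))),
    field_count = as.integer(plate@fieldCount))
  if (nrow(plate@acquisitions))
    doc$acquisitions <- lapply(seq_len(nrow(plate@acquisitions)),
      function(i) list(id = as.integer(plate@acquisitions$id[i]),
                       name = plate@acquisitions$name[i]))
  doc
}

## lenient parse: returns a plain list so the validator can report
## malformed layouts as findings instead of failing to construct them
parsePlateDoc <- function(doc) {
  if (is.null(doc$rows) || is.null(doc$columns) || is.null(doc$wells))
    stop("plate attributes lack rows, columns or wells", call. = FALSE)
  wells <- do.call(rbind, lapply(doc$wells, function(w)
    data.frame(path = w$path[[1]],
               rowIndex = if (is.null(w$rowIndex)) NA_real_
                          else as.numeric(w$rowIndex[[1]]),
               columnIndex = if (is.null(w$columnIndex)) NA_real_
                             else as.numeric(w$columnIndex[[1]]),
               stringsAsFactors = FALSE)))
  acq <- if (is.null(doc$acquisitions))
    data.frame(id = integer(0), name = character(0))
  else do.call(rbind, lapply(doc$acquisitions, function(a)
    data.frame(id = as.integer(a$id[[1]]),
               name = if (is.null(a$name)) NA_character_ else a$name[[1]],
               stringsAsFactors = FALSE)))
  list(rowNames = vapply(doc$rows, function(r) r$name[[1]], ""),
       columnNames = vapply(doc$columns, function(c) c$name[[1]], ""),
       wells = wells,
       fieldCount = if (is.null(doc$field_count)) 1
                    else as.numeric(doc$field_count[[1]]),
       acquisitions = acq)
}

#' Read the plate layout of a stored plate
#'
#' @param store A [KVStore-class].
#' @param path Plate group path.
#' @return A [PlateMeta-class] (construction fails on malformed layouts;
#'   use [validatePlate()] for diagnosis).
#' @export
readPlateMeta <- function(store, path) {
  attrs <- getAttrs(store, path)
  if (is.null(attrs$plate))
    stop("no plate attributes at '", path, "'", call. = FALSE)
  p <- parsePlateDoc(attrs$plate)
  new("PlateMeta", rowNames = p$rowNames, columnNames = p$columnNames,
      wells = p$wells, fieldCount = p$fieldCount,
      acquisitions = p$acquisitions)
}

#' Write a full HCS plate
#'
#' Creates the three-level hierarchy: the plate group carries `plate`
#' attributes, each well group carries `well` attributes listing its
#' fields, and every field is written as a complete multiscale image.
#'
#' @param store A [KVStore-class].
#' @param path Plate group path.
#' @param plate A [PlateMeta-class].
#' @param fields Named list mapping well paths (e.g. `"A/1"`) to lists of
#'   dense field images. Every named well must be declared in `plate`;
#'   wells without entries are simply absent (sparse plates are valid).
#' @param ... Passed to [writeMultiscaleImage()] (dtype, chunking, codec,
#'   pyramid options).
#' @return The plate path, invisibly.
#' @export
writePlate <- function(store, path, plate, fields, ...) {
  validObject(plate)
  declared <- plate@wells$path
  if (anyDuplicated(names(fields)))
    stop("well '", names(fields)[duplicated(names(fields))][1],
         "' written twice", call. = FALSE)
  undeclared <- setdiff(names(fields), declared)
  if (length(undeclared))
    stop("well '", undeclared[1], "' not declared in the plate layout",
         call. = FALSE)
  over <- vapply(fields, length, 0L) > plate@fieldCount
  if (any(over))
    stop("well '", names(fields)[over][1], "' exceeds the field count",
         call. = FALSE)
  writeGroup(store, path)
  putAttrs(store, path, list(plate = plateToDoc(plate)))
  for (wp in names(fields)) {
    imgs <- fields[[wp]]
    rowDir <- joinKey(path, dirname(wp))
    writeGroup(store, rowDir)
    wellDir <- joinKey(path, wp)
    writeGroup(store, wellDir)
    putAttrs(store, wellDir, list(well = list(
      version = NGFF_VERSION,
      images = lapply(seq_along(imgs) - 1L,
                      function(i) list(path = as.character(i))))))
    for (i in seq_along(imgs))
      writeMultiscaleImage(store, joinKey(wellDir, as.character(i - 1)),
                           imgs[[i]], ...)
  }
  invisible(path)
}

#' Plate montage: one low-resolution mosaic of the whole plate
#'
#' Arranges one field of every well on the plate grid, row-major, taking
#' the requested pyramid level and the first time point, channel and z
#' section of each field. Missing wells are filled with the fill value, so
#' the mosaic extent is always (rows x cell height, columns x cell width).
#'
#' @param store A [KVStore-class].
#' @param platePath Plate group path.
#' @param level Pyramid level to sample (must exist in every present well).
#' @param field Zero-based field index.
#' @param fillValue Value for absent wells.
#' @return 2-D matrix of the mosaic.
#' @export
montage <- function(store, platePath, level = NULL, field = 0L,
                    fillValue = 0) {
  attrs <- getAttrs(store, platePath)
  if (is.null(attrs$plate))
    stop("no plate attributes at '", platePath, "'", call. = FALSE)
  plate <- parsePlateDoc(attrs$plate)
  if (field < 0 || field >= plate$fieldCount)
    stop("field index ", field, " out of range (field count ",
         plate$fieldCount, ")", call. = FALSE)
  nr <- length(plate$rowNames); nc <- length(plate$columnNames)
  cellDim <- NULL
  cells <- vector("list", nrow(plate$wells))
  for (i in seq_len(nrow(plate$wells))) {
    wp <- joinKey(platePath, plate$wells$path[i])
    imgPath <- joinKey(wp, as.character(field))
    if (!isGroup(store, imgPath)) next
    meta <- readImageMeta(store, imgPath)
    nLevels <- length(meta@datasets)
    lev <- if (is.null(level)) nLevels - 1L else level
    if (lev < 0 || lev >= nLevels)
      stop("level ", lev, " absent from well '", plate$wells$path[i],
           "' (", nLevels, " level(s))", call. = FALSE)
    block <- readImageLevel(store, imgPath, lev)
    d <- dim(block)
    ## first hyperplane of every leading (t/c/z) axis, trailing y/x kept
    idx <- c(as.list(rep(1, length(d) - 2)),
             list(seq_len(d[length(d) - 1]), seq_len(d[length(d)])))
    plane <- do.call(`[`, c(list(block), idx, list(drop = FALSE)))
    plane <- matrix(plane, nrow = d[length(d) - 1])
    if (is.null(cellDim)) cellDim <- dim(plane)
    if (!identical(dim(plane), cellDim))
      stop("well '", plate$wells$path[i],
           "' has a different cell size at this level", call. = FALSE)
    cells[[i]] <- plane
  }
  if (is.null(cellDim))
    stop("plate has no present wells to montage", call. = FALSE)
  out <- matrix(fillValue, nrow = nr * cellDim[1], ncol = nc * cellDim[2])
  for (i in seq_len(nrow(plate$wells))) {
    if (is.null(cells[[i]])) next
    r0 <- plate$wells$rowIndex[i] * cellDim[1]
    c0 <- plate$wells$columnIndex[i] * cellDim[2]
    out[r0 + seq_len(cellDim[1]), c0 + seq_len(cellDim[2])] <- cells[[i]]
  }
  out
}

## ---- label images ----

labelToDoc <- function(meta) {
  doc <- list(version = NGFF_VERSION)
  if (nrow(meta@colors))
    doc$colors <- lapply(seq_len(nrow(meta@colors)), function(i)
      list(`label-value` = meta@colors$labelValue[i],
           rgba = I(as.integer(meta@colors[i, c("r", "g", "b", "a")]))))
  if (!is.na(meta@source)) doc$source <- list(image = meta@source)
  if (length(meta@properties)) doc$properties <- meta@properties
  doc
}

parseLabelDoc <- function(doc) {
  colors <- if (is.null(doc$colors))
    NULL
  else do.call(rbind, lapply(doc$colors, function(co) {
    rgba <- unlist(co$rgba)
    data.frame(labelValue = as.numeric(co$`label-value`[[1]]),
               r = rgba[1], g = rgba[2], b = rgba[3], a = rgba[4])
  }))
  labelMeta(colors = colors,
            source = if (is.null(doc$source$image)) NA_character_
                     else doc$source$image[[1]],
            properties = if (is.null(doc$properties)) list()
                         else doc$properties)
}

#' Write a label image beside its source image
#'
#' Stores the segmentation under `"{image}/labels/{name}"` as a multiscale
#' image downsampled by local mode, records the name in the `labels` group
#' listing and attaches the `image-label` attribute block.
#'
#' @param store A [KVStore-class].
#' @param imagePath Path of the segmented source image group.
#' @param name Label image name (e.g. `"nuclei"`); must not already exist.
#' @param labels Dense integer-valued array.
#' @param meta A [LabelMeta-class].
#' @param dtype Integer dtype code for storage (default `"i4"`).
#' @param ... Passed to [writeMultiscaleImage()].
#' @return The label image path, invisibly.
#' @export
writeLabels <- function(store, imagePath, name, labels,
                        meta = labelMeta(), dtype = "i4", ...) {
  if (!dtypeIsInteger(dtype) || any(labels != floor(labels)))
    stop("label images require integer dtype", call. = FALSE)
  validObject(meta)
  labelsGroup <- joinKey(imagePath, "labels")
  listing <- getAttrs(store, labelsGroup)$labels
  listing <- if (is.null(listing)) character(0) else unlist(listing)
  if (name %in% listing)
    stop("label image '", name, "' already exists", call. = FALSE)
  labelPath <- joinKey(labelsGroup, name)
  writeGroup(store, labelsGroup)
  putAttrs(store, labelsGroup, list(labels = I(c(listing, name))))
  if (is.na(meta@source)) meta@source <- "../../"
  writeMultiscaleImage(store, labelPath, labels, dtype = dtype,
                       kind = "label",
                       extraAttrs = list(`image-label` = labelToDoc(meta)),
                       ...)
  invisible(labelPath)
}

#' List the label images stored beside an image
#'
#' @inheritParams writeLabels
#' @return Character vector of label names (empty when none).
#' @export
listLabels <- function(store, imagePath) {
  listing <- getAttrs(store, joinKey(imagePath, "labels"))$labels
  if (is.null(listing)) character(0) else unlist(listing)
}

#' Read back the image-label metadata of a stored label image
#'
#' @inheritParams writeLabels
#' @return A [LabelMeta-class].
#' @export
readLabelMeta <- function(store, imagePath, name) {
  attrs <- getAttrs(store, joinKey(imagePath, "labels", name))
  if (is.null(attrs$`image-label`))
    stop("no image-label attributes for '", name, "'", call. = FALSE)
  parseLabelDoc(attrs$`image-label`)
}
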