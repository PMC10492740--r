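## Key-value store abstraction. Keys are "/"-joined path segments; values
## are raw byte vectors. Two backends: a directory tree on a filesystem and
## an in-memory environment (which also records every get() for tests that
## assert the lazy-read contract).

#' KVStore: the key-value store contract
#'
#' A minimal byte-oriented store underneath every OME-Zarr tree: `kvPut`
#' then `kvGet` round-trips bytes exactly, and `kvList(prefix)` returns
#' every key previously put under that prefix. Chunk objects and JSON
#' metadata documents are both plain values, so any conforming backend
#' (local directory, object store, zip, ...) can hold a complete container.
#'
#' @seealso [directoryStore()], [memoryStore()]
#' @export
setClass("KVStore", representation("VIRTUAL"))

#' @rdname KVStore-class
#' @param store A `KVStore`.
#' @param key Store key ("/"-joined segments).
#' @export
setGeneric("kvGet", function(store, key) standardGeneric("kvGet"))

#' @rdname KVStore-class
#' @param bytes Raw vector to store.
#' @export
setGeneric("kvPut", function(store, key, bytes) standardGeneric("kvPut"))

#' @rdname KVStore-class
#' @param prefix Key prefix ("" lists everything).
#' @export
setGeneric("kvList", function(store, prefix = "") standardGeneric("kvList"))

#' @rdname KVStore-class
#' @export
setGeneric("kvDelete", function(store, key) standardGeneric("kvDelete"))

#' @rdname KVStore-class
#' @export
setGeneric("kvExists", function(store, key) standardGeneric("kvExists"))

normalizeKey <- function(key) {
  key <- gsub("/+", "/", key)
  key <- sub("^/", "", sub("/$", "", key))
  key
}

joinKey <- function(...) {
  parts <- c(...)
  normalizeKey(paste(parts[nzchar(parts)], collapse = "/"))
}

## ---- directory-backed store ----

#' @rdname KVStore-class
#' @export
setClass("DirectoryStore", contains = "KVStore",
  representation(root = "character"))

#' Filesystem-backed store
#'
#' Maps keys to files under a root directory; the standard on-disk layout
#' for OME-Zarr (group directories with `.zgroup`, array directories with
#' `.zarray`, chunk files named by their grid indices).
#'
#' @param root Directory path; created if absent.
#' @return A `DirectoryStore`.
#' @export
directoryStore <- function(root) {
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  new("DirectoryStore", root = normalizePath(root))
}

setMethod("kvGet", "DirectoryStore", function(store, key) {
  f <- file.path(store@root, normalizeKey(key))
  if (!file.exists(f))
    stop("key not found: '", key, "'", call. = FALSE)
  readBin(f, "raw", n = file.size(f))
})

setMethod("kvPut", "DirectoryStore", function(store, key, bytes) {
  f <- file.path(store@root, normalizeKey(key))
  dir.create(dirname(f), showWarnings = FALSE, recursive = TRUE)
  writeBin(bytes, f)
  invisible(store)
})

setMethod("kvList", "DirectoryStore", function(store, prefix = "") {
  keys <- list.files(store@root, recursive = TRUE, all.files = TRUE,
                     no.. = TRUE)
  prefix <- normalizeKey(prefix)
  if (nzchar(prefix))
    keys <- keys[startsWith(keys, paste0(prefix, "/")) | keys == prefix]
  sort(keys)
})

setMethod("kvDelete", "DirectoryStore", function(store, key) {
  f <- file.path(store@root, normalizeKey(key))
  if (file.exists(f)) file.remove(f)
  invisible(store)
})

setMethod("kvExists", "DirectoryStore", function(store, key) {
  file.exists(file.path(store@root, normalizeKey(key)))
})

setMethod("show", "DirectoryStore", function(object) {
  cat("DirectoryStore at", object@root, "|", length(kvList(object)),
      "objects\n")
})

## ---- in-memory store (instrumented) ----

#' @rdname KVStore-class
#' @export
setClass("MemoryStore", contains = "KVStore",
  representation(env = "environment", trace = "environment"))

#' In-memory store with access tracing
#'
#' Holds all objects in an environment. Every `kvGet` key is appended to an
#' access trace, so tests can assert that a region read touched only the
#' chunks intersecting the region.
#'
#' @return A `MemoryStore`.
#' @export
memoryStore <- function() {
  tr <- new.env(parent = emptyenv())
  tr$gets <- character()
  new("MemoryStore", env = new.env(parent = emptyenv()), trace = tr)
}

setMethod("kvGet", "MemoryStore", function(store, key) {
  key <- normalizeKey(key)
  store@trace$gets <- c(store@trace$gets, key)
  val <- get0(key, envir = store@env)
  if (is.null(val))
    stop("key not found: '", key, "'", call. = FALSE)
  val
})

setMethod("kvPut", "MemoryStore", function(store, key, bytes) {
  assign(normalizeKey(key), bytes, envir = store@env)
  invisible(store)
})

setMethod("kvList", "MemoryStore", function(store, prefix = "") {
  keys <- ls(store@env)
  prefix <- normalizeKey(prefix)
  if (nzchar(prefix))
    keys <- keys[startsWith(keys, paste0(prefix, "/")) | keys == prefix]
  sort(keys)
})

setMethod("kvDelete", "MemoryStore", function(store, key) {
  key <- normalizeKey(key)
  if (exists(key, envir = store@env)) rm(list = key, envir = store@env)
  invisible(store)
})

setMethod("kvExists", "MemoryStore", function(store, key) {
  exists(normalizeKey(key), envir = store@env)
})

setMethod("show", "MemoryStore", function(object) {
  cat("MemoryStore |", length(kvList(object)), "objects\n")
})

#' @rdname memoryStore
#' @param store A `MemoryStore`.
#' @return `storeTrace` returns the keys fetched since the last reset.
#' @export
storeTrace <- function(store) store@trace$gets

#' @rdname memoryStore
#' @export
clearTrace <- function(store) {
  store@trace$gets <- character()
  invisible(store)
}

## ---- JSON document helpers ----

jsonPut <- function(store, key, doc) {
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null",
                          digits = NA, pretty = 2)
  kvPut(store, key, charToRaw(as.character(txt)))
}

jsonGet <- function(store, key) {
  jsonlite::fromJSON(rawToChar(kvGet(store, key)), simplifyVector = FALSE)
}

## group / attribute plumbing (Zarr v2 dialect)
writeGroup <- function(store, path) {
  jsonPut(store, joinKey(path, ".zgroup"), list(zarr_format = 2L))
  invisible(store)
}

putAttrs <- function(store, path, attrs) {
  jsonPut(store, joinKey(path, ".zattrs"), attrs)
  invisible(store)
}

getAttrs <- function(store, path) {
  key <- joinKey(path, ".zattrs")
  if (!kvExists(store, key)) return(list())
  jsonGet(store, key)
}

isGroup <- function(store, path) kvExists(store, joinKey(path, ".zgroup"))
isArray <- function(store, path) kvExists(store, joinKey(path, ".zarray"))
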