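## Fixed little-endian dtype registry for the Zarr v2 dialect.
## Codes: u1,u2,u4 (unsigned), i1,i2,i4 (signed), f4,f8 (IEEE floats).

.DTYPES <- list(
  u1 = list(size = 1L, kind = "u", zarr = "|u1"),
  u2 = list(size = 2L, kind = "u", zarr = "<u2"),
  u4 = list(size = 4L, kind = "u", zarr = "<u4"),
  i1 = list(size = 1L, kind = "i", zarr = "|i1"),
  i2 = list(size = 2L, kind = "i", zarr = "<i2"),
  i4 = list(size = 4L, kind = "i", zarr = "<i4"),
  f4 = list(size = 4L, kind = "f", zarr = "<f4"),
  f8 = list(size = 8L, kind = "f", zarr = "<f8")
)

#' Supported dtype codes
#'
#' The fixed registry of element types the store understands: little-endian
#' unsigned/signed integers of 1, 2 and 4 bytes and IEEE floats of 4 and 8
#' bytes.
#'
#' @return Character vector of dtype codes.
#' @export
#' @examples
#' dtypeCodes()
dtypeCodes <- function() names(.DTYPES)

dtypeInfo <- function(code) {
  info <- .DTYPES[[code]]
  if (is.null(info))
    stop("unknown dtype code '", code, "'; supported: ",
         paste(dtypeCodes(), collapse = ", "), call. = FALSE)
  info
}

#' @rdname dtypeCodes
#' @param code Dtype code, e.g. `"u2"`.
#' @return `dtypeSize` returns the bytes per element.
#' @export
dtypeSize <- function(code) dtypeInfo(code)$size

dtypeIsInteger <- function(code) dtypeInfo(code)$kind %in% c("u", "i")

## zarr dtype string <-> registry code
dtypeToZarr <- function(code) dtypeInfo(code)$zarr
dtypeFromZarr <- function(str) {
  if (!is.character(str) || length(str) != 1L)
    stop("dtype entry must be a single string", call. = FALSE)
  if (grepl("^>", str))
    stop("big-endian dtype '", str, "' is not supported", call. = FALSE)
  code <- sub("^[<|=]", "", str)
  dtypeInfo(code)  # errors on unknown code
  code
}

## [min, max] representable for integer kinds; +-Inf for floats
dtypeRange <- function(code) {
  info <- dtypeInfo(code)
  bits <- info$size * 8
  switch(info$kind,
    u = c(0, 2^bits - 1),
    i = c(-(2^(bits - 1)), 2^(bits - 1) - 1),
    f = c(-Inf, Inf))
}

## TRUE if value can be stored losslessly in dtype
dtypeRepresentable <- function(value, code) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value)) return(FALSE)
  if (!dtypeIsInteger(code)) return(TRUE)
  r <- dtypeRange(code)
  value == floor(value) && value >= r[1] && value <= r[2]
}

## Cast floating-point intermediates back to a dtype: round half to even
## (base round() follows IEC 60559) for integer kinds, identity for floats.
castToDtype <- function(values, code) {
  if (dtypeIsInteger(code)) {
    r <- dtypeRange(code)
    pmin(pmax(round(values), r[1]), r[2])
  } else values
}

#' Raw (uncompressed) byte size of an array
#'
#' Product of the per-axis extents times the bytes per element of the dtype.
#' Useful for the back-of-envelope arithmetic behind chunking decisions, e.g.
#' a 24576 x 10656 x 2048 lightsheet tile of 2-byte voxels is about 1 TB.
#'
#' @param shape Integer vector of per-axis extents (all positive).
#' @param dtype Dtype code (see [dtypeCodes()]).
#' @return Number of bytes as a double (may exceed the integer range).
#' @export
#' @examples
#' rawByteSize(c(24576, 10656, 2048), "u2")  # ~1 TB
rawByteSize <- function(shape, dtype) {
  shape <- as.numeric(shape)
  if (length(shape) == 0 || any(!is.finite(shape)) || any(shape < 1) ||
      any(shape != floor(shape)))
    stop("shape must be positive integer extents", call. = FALSE)
  prod(shape) * dtypeSize(dtype)
}

## values (numeric vector) -> raw, little-endian, two's complement
encodeValues <- function(values, code) {
  info <- dtypeInfo(code)
  if (info$kind == "f")
    return(writeBin(as.double(values), raw(), size = info$size,
                    endian = "little"))
  v <- as.numeric(values)
  if (info$size == 4L) {
    ## write 32-bit values as two 16-bit halves: R's integer NA shares the
    ## 0x80000000 bit pattern, so 4-byte writeBin cannot carry INT_MIN /
    ## the upper unsigned range
    if (info$kind == "i") v <- ifelse(v < 0, v + 2^32, v)
    lo <- v %% 65536
    hi <- v %/% 65536
    half <- as.integer(rbind(lo, hi))
    half <- ifelse(half >= 32768L, half - 65536L, half)
    return(writeBin(half, raw(), size = 2L, endian = "little"))
  }
  if (info$kind == "u") {
    ## writeBin takes signed integers; map the upper half of the unsigned
    ## range onto two's-complement negatives (same byte pattern)
    bits <- info$size * 8
    v <- ifelse(v >= 2^(bits - 1), v - 2^bits, v)
  }
  writeBin(as.integer(v), raw(), size = info$size, endian = "little")
}

## raw -> numeric vector of n elements
decodeValues <- function(bytes, code, n) {
  info <- dtypeInfo(code)
  expected <- n * info$size
  if (length(bytes) != expected)
    stop("corrupted chunk payload: expected ", expected, " bytes, got ",
         length(bytes), call. = FALSE)
  if (info$kind == "f")
    return(readBin(bytes, "double", n = n, size = info$size,
                   endian = "little"))
  if (info$size == 4L) {
    half <- readBin(bytes, "integer", n = 2L * n, size = 2L,
                    signed = FALSE, endian = "little")
    v <- half[seq(1, 2 * n, by = 2)] + 65536 * half[seq(2, 2 * n, by = 2)]
    if (info$kind == "i") v <- ifelse(v >= 2^31, v - 2^32, v)
    return(v)
  }
  as.numeric(readBin(bytes, "integer", n = n, size = info$size,
                     signed = info$kind == "i", endian = "little"))
}
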