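## Independent brute-force oracles and small fixture builders used across
## the suite. The oracles deliberately share no code with the package
## internals they check.

## grid shape by enumerating chunk origins
naiveGridShape <- function(shape, chunkShape) {
  vapply(seq_along(shape), function(a) {
    length(seq.int(0, shape[a] - 1, by = chunkShape[a]))
  }, 0)
}

## nested-loop window reducers over arbitrary rank
naiveWindows <- function(block, factors, reduce) {
  d <- dim(block)
  outDim <- ceiling(d / factors)
  out <- array(NA_real_, dim = outDim)
  cells <- expand.grid(lapply(outDim, seq_len))
  for (i in seq_len(nrow(cells))) {
    cell <- as.numeric(cells[i, ])
    idx <- lapply(seq_along(d), function(a) {
      lo <- (cell[a] - 1) * factors[a] + 1
      seq.int(lo, min(lo + factors[a] - 1, d[a]))
    })
    vals <- as.vector(do.call(`[`, c(list(block), idx, list(drop = FALSE))))
    out[matrix(cell, 1)] <- reduce(vals)
  }
  out
}

naiveMean <- function(block, factors, dtype = "f8") {
  out <- naiveWindows(block, factors, mean)
  if (dtype %in% c("u1", "u2", "u4", "i1", "i2", "i4")) out <- round(out)
  out
}

naiveMode <- function(block, factors) {
  naiveWindows(block, factors, function(v) {
    u <- sort(unique(v))
    counts <- vapply(u, function(x) sum(v == x), 0)
    u[which.max(counts)]  # first max: ties resolve to the smallest value
  })
}

## random dense block of a given dtype (test-local randomness, seeded by
## the caller through set.seed)
randomBlock <- function(shape, dtype) {
  n <- prod(shape)
  vals <- switch(substr(dtype, 1, 1),
    u = sample.int(2^min(8 * as.integer(substr(dtype, 2, 2)), 16),
                   n, replace = TRUE) - 1,
    i = sample.int(127, n, replace = TRUE) - 64,
    ## dyadic rationals are exactly representable in 4-byte floats, so the
    ## round trip can be asserted bit-identically for f4 as well as f8
    f = round(stats::rnorm(n) * 64) / 64)
  array(as.numeric(vals), dim = shape)
}

## write a small multi-page grayscale TIFF; pages are matrices in [0, 1]
## scaled to 16-bit on write
writeTestTiff <- function(pages, path = tempfile(fileext = ".tif")) {
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  path
}

## full byte dump of a memory store, for tree-identity comparisons
storeBytes <- function(store) {
  keys <- kvList(store)
  stats::setNames(lapply(keys, function(k) kvGet(store, k)), keys)
}
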