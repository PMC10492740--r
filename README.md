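# ozarr

Chunked, cloud-optimized bioimaging containers in R: read, write, validate
and convert OME-Zarr trees (NGFF 0.4 on the Zarr v2 on-disk dialect).

## The problem

Modern microscopy produces images that do not fit the formats they were
born in: a single lightsheet tile of 24,576 × 10,656 × 2,048 two-byte
voxels is about 1 TB raw, and a high-content screen is thousands of such
images arranged in plates. OME-Zarr answers this with one abstraction:
every image is a hierarchy of **chunks** — atomic N-dimensional sub-blocks,
individually compressed and addressable by stable paths — plus
**multiscale pyramids** (progressively downsampled copies for
resolution-appropriate loading), all described by plain JSON metadata
documents that sit beside the data. The same layout holds a single 2-D
plane, a 5-D (t, c, z, y, x) time series, a segmentation stored beside the
image it annotates, or a complete plate → well → field screen.

`ozarr` implements that container end-to-end for R users who need to
produce, inspect or verify such trees without a Python stack:

- a key-value chunk store (filesystem or in-memory) with chunk-grid
  arithmetic, zlib per-chunk compression, padded edge chunks,
  implicit-fill reads and lazy region access — a region read touches only
  the chunks it intersects;
- the NGFF 0.4 metadata model (axes typed time/channel/space, per-level
  scale/translation transforms, optional channel rendering), capped at 5
  dimensions as that specification requires;
- pyramid construction: local **mean** for intensity data (computed in
  double, cast back by round-half-to-even), local **mode** with
  smallest-value tie-break for label images, ceiling-halving level plans
  with a configurable stop extent;
- HCS plates with plate/well attribute blocks and a low-resolution plate
  **montage**; label images listed and stored beside their source;
- a rule-based **validator** with stable finding codes
  (`E_AXES_COUNT`, `E_LEVEL_ORDER`, `W_UNKNOWN_CODEC`, ...) and a tree
  summary (per-level geometry, chunk counts, byte totals);
- a **converter** from ordered 2-D plane sources (TIFF stacks via the
  `tiff` package, or any in-memory supplier) that streams level 0
  chunk-by-chunk;
- a deterministic **fixture generator** (explicit Lehmer PRNG, so output
  is byte-identical across platforms) producing gradient/noise/blob
  images with ground truth, label masks and whole plates.

## Worked example

```r
library(ozarr)

store <- memoryStore()                      # or directoryStore("img.zarr")
img <- makeImage(c(1, 2, 1, 64, 64), content = "blobs", blobCount = 5)
writeMultiscaleImage(store, "img", img$data, dtype = "u2", minExtent = 16)
writeLabels(store, "img", "nuclei", img$labels)

validateImage(store, "img")
#> ValidationReport: OK ( 0 error(s), 0 warning(s), 0 info )

summarizeTree(store, "img")
#> TreeSummary of 'img'
#>   total voxels (level 0): 8,192
#>   level 0: <u2> shape (1, 2, 1, 64, 64) chunks (1, 1, 1, 64, 64) 2/2 chunk(s) stored, 172 bytes (raw 16,384)
#>   level 1: <u2> shape (1, 2, 1, 32, 32) chunks (1, 1, 1, 32, 32) 2/2 chunk(s) stored, 156 bytes (raw 4,096)
#>   level 2: <u2> shape (1, 2, 1, 16, 16) chunks (1, 1, 1, 16, 16) 2/2 chunk(s) stored, 98 bytes (raw 1,024)
```

Three pyramid levels were built (64 → 32 → 16 on y/x, stopping at the
16-pixel floor requested by `minExtent = 16`), each level is one
zlib-compressed chunk per channel, and the stored bytes show the
compression working (172 bytes for a 16 KB plane). The label mask lives
under `img/labels/nuclei` with its own mode-downsampled pyramid.

A single region read decodes only the chunks it intersects:

```r
readRegion(store, "img/0", region(c(0, 0, 0, 10, 10), c(1, 1, 1, 4, 4)))
```

The chunk-size arithmetic the format is designed around is exposed
directly — one lightsheet tile of the geometry above:

```r
rawByteSize(c(24576, 10656, 2048), "u2")
#> [1] 1.072668e+12          # ~1 TB raw
gridShape(c(24576, 10656, 2048), c(128, 128, 128))
#> [1] 192  84  16           # chunk grid at 128^3
```

A command-line wrapper ships in `inst/cli/ozarr.R`
(`Rscript ozarr.R validate <path> --json`, plus `create`, `convert`,
`info`, `montage` and `synth` subcommands; exit code 0 = valid,
1 = validation failure, 2 = usage, 3 = I/O).

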