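Package: ozarr
Title: Chunked Multiscale Bioimaging Containers (OME-Zarr, NGFF 0.4)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Read, write, validate and convert cloud-optimized OME-Zarr
    bioimaging containers (NGFF version 0.4 on the Zarr v2 on-disk dialect):
    a chunked N-dimensional array store with per-chunk compression and
    hierarchical JSON metadata, multiscale pyramid generation by local mean
    (intensity) or local mode (labels), high-content-screening plate layout
    with plate montages, label images stored beside their source, a
    rule-based validator with stable finding codes, a TIFF-stack converter,
    and a deterministic synthetic fixture generator so everything is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    jsonlite,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'ozarr-package.R'
    'dtypes.R'
    'codecs.R'
    'store.R'
    'schema.R'
    'array-io.R'
    'ngff.R'
    'pyramid.R'
    'image-io.R'
    'collections.R'
    'validate.R'
    'convert.R'
    'synthesize.R'
    'cli.R'
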