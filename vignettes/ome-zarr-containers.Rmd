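---
title: "Chunked multiscale bioimaging containers with ozarr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chunked multiscale bioimaging containers with ozarr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ozarr)
```

## The container model

An OME-Zarr tree is a directory (or any key-value store) of two kinds of
node: *groups*, which carry a `.zgroup` marker and JSON attributes in
`.zattrs`, and *arrays*, which carry a `.zarray` schema document plus one
object per cell of a chunk grid. Everything the package does — images,
pyramids, plates, labels — is composed from these two primitives, so any
backend satisfying the small `KVStore` contract (`kvPut` then `kvGet`
round-trips bytes; `kvList` enumerates a prefix) can hold a complete
container. Two backends ship: a filesystem directory and an in-memory
store whose `kvGet` calls are traced, which is how the test suite proves
the lazy-read contract rather than assuming it.

The on-disk dialect is Zarr v2 with NGFF 0.4 metadata. Zero-based
indices, half-open regions and row-major ("C") chunk layout are fixed
conventions throughout; R's column-major arrays are transposed during
serialization so the stored bytes are row-major and interoperable (the
suite cross-reads trees with the Python zarr implementation in both
directions).

### Chunks, fill values and edge padding

The chunk grid along each axis is `ceiling(shape / chunk_shape)`. Edge
chunks are stored **padded** to the full chunk shape with the schema's
fill value and cropped on read; this keeps every chunk object the same
decoded byte length, which is the standard v2 behaviour and makes chunk
arithmetic trivial. A grid cell with no stored object is not an error: it
reads as the fill value ("implicit fill"), and the validator reports it
at *info* severity, because sparse arrays are legitimate (a montage of a
half-empty plate relies on exactly this).

Region reads decode only the chunks intersecting the region. The choice
of chunk shape is a genuine trade-off the caller owns; the default tiles
the trailing y/x plane at up to 1024 × 1024 with all other axes at 1
(planar viewing), and a `volumetric` preset of (1, 1, 128, 128, 128) is
provided for isotropic volume access.

### Dtypes and codecs

The dtype registry is deliberately closed: little-endian `u1 u2 u4 i1 i2
i4 f4 f8`, the types that cover microscopy cameras, label ids and derived
statistics. Unknown codes are rejected at parse time rather than guessed.
R-specific care: 32-bit values are serialized as two 16-bit halves
because R's integer `NA` shares the `0x80000000` bit pattern with
`INT_MIN`/`2^31`, which a naive `writeBin` cannot carry.

Codecs are a pluggable registry. `"raw"` (a `null` compressor) and
`"zlib"`/`"gzip"` are built in, both backed by R's `memCompress`, which
emits an RFC 1950 zlib stream — the same framing the numcodecs `zlib`
codec uses, which is what the interoperability test relies on. Ids seen
in the wild (`blosc`, `zstd`, ...) are accepted by the metadata parser;
without a registered implementation, decoding fails with a clear error
and validation emits a *warning*, not an error, since the tree itself is
well-formed.

## The metadata model and its ceiling

NGFF 0.4 images carry 2–5 named axes, at most one `time` and one
`channel` axis and 2–3 `space` axes, ordered time → channel → space. The
version 0.4 text lists the canonical order (t, c, z, y, x) without
stating the constraint as a rule; this package enforces it, because every
consumer it targets assumes it. The 5-axis ceiling is likewise enforced
on both construction (`defaultAxes(6)` refuses) and validation
(`E_AXES_COUNT`), and deliberately not relaxed: later specification
versions allow N-D arrays, but silently accepting them under a 0.4
version tag would mislabel the data.

Each resolution level carries exactly one `scale` transform (optionally
followed by one `translation`); other transform types are rejected at
parse time rather than ignored, so a tree using features this package
cannot honour is caught loudly. Per-level scale must be non-decreasing
with level on every axis; the 0.4 text is ambiguous on strictness, so
decreases are flagged as errors (`E_SCALE_ORDER`) while equality is
allowed (non-downsampled axes keep their scale).

## Pyramids

Level plans halve (ceiling division) the y and x space axes per level,
stopping when the largest downsampled extent is ≤ `minExtent` (default
256, one typical display tile) or an explicit level cap is hit; z can be
included for isotropic volumes. The published description of
reference converters does not fix the downsampling operator, so the
operator used here is recorded in the metadata as free-text provenance
(`downsampling_method`) rather than assumed canonical.

Two reducers are implemented:

- **Intensity — local mean.** Windows are edge-truncated rectangles; the
  mean is accumulated in 8-byte float as sum/count and cast back to the
  storage dtype with round-half-to-even (base `round`, IEC 60559). Mean
  reduction over complete windows conserves the global mean exactly in
  float, which the suite asserts on even extents.
- **Labels — local mode.** Most-frequent value per window, ties broken
  by the smallest value. The tie-break makes label pyramids
  deterministic and guarantees no level introduces a value absent from
  level 0 (asserted as a property).

Both are checked against naive nested-loop oracles on random blocks of
extents up to 9 per axis.

## Plates, montages, labels

A plate is a three-level hierarchy: the plate group's `plate` attributes
declare ordered row and column names, the well list (paths
`"{row}/{column}"` with zero-based indices into the name lists) and the
field count; each well group lists its fields; each field is a full
multiscale image. Fixtures default to letter rows and numeral columns —
conventional plate nomenclature — but any alphanumerics are accepted.
Sparse plates (declared wells never written) are valid.

The montage arranges one field per well on the plate grid, row-major,
taking the first time point, channel and z section at a chosen level;
missing wells become fill-value cells, so the mosaic extent is always
(rows × cell height, columns × cell width). This is validated by
construction over randomized sparse grids up to 8 × 12 — published plate
overview figures imply per-well cell sizes that are not stated, so there
is no external mosaic size to compare against.

Label images live at `labels/{name}` beside their source image, with the
name recorded in the `labels` listing, a mode-downsampled pyramid, and an
`image-label` block holding optional per-label RGBA colors, provenance
(`source`) and property records. Integer dtype is enforced at write time
and at validation (`E_LABEL_DTYPE`).

## The validator

Validation is a rule set producing ordered findings (by path, then
code), each with a stable code from a published registry
(`findingCodes()`). The severity policy is a design decision:
specification violations are *errors*; interoperability risks that leave
the tree well-formed (unregistered codec, unlisted label subtree) are
*warnings*; implicit-fill chunks are *info*. A report is `ok` iff it
contains no error.

Two properties anchor the rule set. *Soundness*: everything this
package's writers emit validates with zero errors — asserted for images,
labels, plates and converted TIFFs. *Completeness by mutation*: for
every registered error code the fixture generator provides a mutation
that flips exactly that rule on an otherwise valid tree, and the suite
asserts the mutated tree yields that code and no other error. Validation
schemas and rules are bundled in code; nothing is fetched, so validation
runs fully offline.

## Conversion

`convertStack` consumes any `PlaneSource` — declared (t, c, z, y, x)
sizes, a dtype, and `get_plane(t, c, z)` — and writes a 5-D multiscale
image whose level-0 pixels equal the source planes exactly (asserted
plane-by-plane). Level 0 is streamed: planes are gathered per chunk
slab, encoded and written, so the full image is never materialized
during ingest. Higher levels are built by reading the previous level
whole and reducing it; that working set is bounded by the level-1 size,
a deliberate simplification at this package's target scales. Conversion
is single-threaded and writes no timestamps, so identical source and
options give byte-identical trees.

The TIFF adapter reads grayscale pages via the `tiff` package;
`dimensionOrder` names the (T, C, Z) dimensions the page sequence
iterates over, fastest first, with all but one size given and the last
inferred from the page count (which must divide evenly). Physical pixel
sizes, when declared, become micrometer axis units and level-0 scales;
channel names land in the optional rendering block.

## The fixture generator

Fixtures are the package's substitute for downloads, so they are
first-class, deterministic code. All randomness comes from an explicit
Lehmer multiplicative congruential stream (`state ← state · 48271 mod
2³¹−1`; products stay below 2⁴⁷, so double arithmetic is exact on every
platform) — never from R's ambient RNG — giving byte-identical trees for
identical seeds, asserted at the store-bytes level.

Three content kinds: `gradient` (smooth ramp over the dtype range),
`noise` (uniform draws), and `blobs` — bright disks with a paired label
mask and a ground-truth table (center, radius, channel, label id). Blobs
are placed in disjoint x-strips so no blob can occlude another: every
requested label is guaranteed present in the mask, which keeps the
ground truth exact rather than probabilistic. Plate fixtures derive
per-well seeds from the base seed and well index.

What the fixtures deliberately do not emulate: optics (no point-spread
function, no noise model), acquisition metadata, vendor formats, or
images larger than memory. Passing tests therefore demonstrate container
correctness — layout, metadata, arithmetic, round trips — not robustness
to the photometric quirks of real microscopes.

Default problem sizes are the package's own testing choices: fixture
extents ≤ 256, plates ≤ 8 × 12, pyramid stops at 4–16 pixels for small
fixtures. The 1 TB-scale numbers quoted in the documentation are
arithmetic over shapes (`rawByteSize`, `gridShape`), which is exact at
any scale and needs no large allocation.

## Numerical and degenerate-input choices

- Mean cast: round-half-to-even, then clamped to the dtype range.
- Mode ties: smallest value wins (reproducibility over fidelity).
- Region of zero extent: rejected at construction (`extent ≥ 1`).
- Arrays of rank 1 are legal at the store layer (the container is
  general), while *images* require rank ≥ 2.
- Fill values must be exactly representable in the dtype; `300` in `u1`
  is a construction error, not a silent wrap.
- Both dimension-separator dialects (`"/"` nested, `"."` flat) are read;
  writes default to `"/"` and record the choice in `.zarray`, since both
  occur in the wild and the figures of published datasets do not say
  which they use.

## Limitations

Zarr v3, sharding, consolidated metadata, remote object-store drivers,
blosc/zstd codecs (recognized, not decoded), multi-writer concurrency,
coordinate transforms beyond scale/translation, and proprietary
microscopy formats are all out of scope. The CLI is a thin `Rscript`
wrapper (`inst/cli/ozarr.R`) over exported functions; it adds no
behaviour of its own, and the suite asserts its outputs are identical to
direct library calls.
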