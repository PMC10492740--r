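gradientPlanes <- function(t, c, z, y, x) {
  ## page value encodes its (t, c, z) index so misrouting is detectable
  idx <- 0
  planes <- list()
  for (ti in seq_len(t)) for (ci in seq_len(c)) for (zi in seq_len(z)) {
    planes[[length(planes) + 1]] <-
      matrix((idx * 1000 + seq_len(y * x)) %% 65536, y, x, byrow = TRUE)
    idx <- idx + 1
  }
  planes
}

memorySource <- function(t, c, z, y, x) {
  planes <- gradientPlanes(t, c, z, y, x)
  planeSource(
    sizes = c(t = t, c = c, z = z, y = y, x = x), dtype = "u2",
    getPlane = function(ti, ci, zi)
      planes[[(ti * c + ci) * z + zi + 1]])
}

test_that("conversion produces a 5-D image with exact level-0 pixels", {
  src <- memorySource(1, 1, 2, 12, 10)
  store <- memoryStore()
  convertStack(src, store, "img", convertOptions(minExtent = 4))
  lv0 <- readImageLevel(store, "img", 0)
  expect_equal(dim(lv0), c(1, 1, 2, 12, 10))
  for (z in 0:1)
    expect_equal(matrix(lv0[1, 1, z + 1, , ], 12), src@getPlane(0, 0, z),
                 label = paste("plane z =", z))
})

test_that("converted trees validate cleanly and read back lazily", {
  src <- memorySource(2, 2, 1, 16, 16)
  store <- memoryStore()
  convertStack(src, store, "img",
               convertOptions(chunkShape = c(1, 1, 1, 8, 8),
                              minExtent = 4))
  expect_true(reportOk(validateImage(store, "img")))
  for (t in 0:1) for (c in 0:1) {
    got <- readRegion(store, "img/0",
                      region(c(t, c, 0, 0, 0), c(1, 1, 1, 16, 16)))
    expect_equal(matrix(got[1, 1, 1, , ], 16), src@getPlane(t, c, 0))
  }
})

test_that("oversized chunk requests collapse to one chunk per plane", {
  src <- memorySource(1, 1, 1, 6, 7)
  store <- memoryStore()
  convertStack(src, store, "img",
               convertOptions(chunkShape = c(1, 1, 1, 512, 512),
                              resolutionLevels = 1))
  schema <- readSchema(store, "img/0")
  expect_equal(gridShape(schemaShape(schema), schemaChunks(schema)),
               c(1, 1, 1, 1, 1))
})

test_that("conversion is deterministic, byte for byte", {
  run <- function() {
    store <- memoryStore()
    convertStack(memorySource(1, 2, 2, 10, 8), store, "img",
                 convertOptions(minExtent = 4))
    storeBytes(store)
  }
  expect_identical(run(), run())
})

test_that("physical pixel sizes become axis units and scales", {
  src <- planeSource(sizes = c(t = 1, c = 1, z = 1, y = 4, x = 4),
                     dtype = "u1",
                     getPlane = function(t, c, z) matrix(0, 4, 4),
                     pixelSizes = c(z = 2, y = 0.5, x = 0.5),
                     channelNames = "DAPI")
  store <- memoryStore()
  convertStack(src, store, "img", convertOptions(resolutionLevels = 1))
  meta <- readImageMeta(store, "img")
  units <- vapply(msAxes(meta), function(a) a@unit, "")
  expect_identical(units[3:5], rep("micrometer", 3))
  expect_equal(msDatasets(meta)[[1]]@scale, c(1, 1, 2, 0.5, 0.5))
  expect_identical(getAttrs(store, "img")$omero$channels[[1]]$label[[1]],
                   "DAPI")
})

test_that("inconsistent plane shapes abort conversion", {
  src <- planeSource(sizes = c(t = 1, c = 1, z = 2, y = 4, x = 4),
                     dtype = "u1",
                     getPlane = function(t, c, z)
                       matrix(0, 4, if (z > 0) 5 else 4))
  expect_error(convertStack(src, memoryStore(), "img"), "declared")
})

test_that("TIFF pages map to (t, c, z) per the declared fastest-first order", {
  pages <- lapply(0:5, function(i) matrix(i / 10, 6, 8))
  path <- writeTestTiff(pages)
  src <- tiffPlaneSource(path, dimensionOrder = "CZ", sizes = c(C = 2),
                         dtype = "u2")
  expect_equal(unname(src@sizes[c("c", "z")]), c(2, 3))
  ## page index = c + z * C; (c=1, z=2) -> page index 5 (the last page)
  raw <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  expect_equal(src@getPlane(0, 1, 2), raw[[6]])
  expect_equal(src@getPlane(1 - 1, 1 - 1, 1 - 1), raw[[1]])
  expect_equal(dim(src@getPlane(0, 0, 0)), c(6, 8))
})

test_that("single-page TIFFs become (1, 1, 1, y, x) sources", {
  path <- writeTestTiff(list(matrix(0.25, 5, 9)))
  src <- tiffPlaneSource(path)
  expect_equal(unname(src@sizes), c(1, 1, 1, 5, 9))
  store <- memoryStore()
  convertStack(src, store, "img", convertOptions(resolutionLevels = 1))
  expect_true(reportOk(validateImage(store, "img")))
})

test_that("TIFF page-count and shape mismatches are rejected", {
  path <- writeTestTiff(lapply(1:5, function(i) matrix(0, 4, 4)))
  expect_error(tiffPlaneSource(path, dimensionOrder = "CZ",
                               sizes = c(C = 2)), "not divisible")
  mixed <- writeTestTiff(list(matrix(0, 4, 4), matrix(0, 3, 4)))
  expect_error(tiffPlaneSource(mixed, dimensionOrder = "Z"),
               "differing shapes")
  expect_error(tiffPlaneSource(path, dimensionOrder = "QZ"),
               "permutation")
})
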