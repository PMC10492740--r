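test_that("default axes are the trailing part of (t, c, z, y, x)", {
  ax5 <- defaultAxes(5)
  expect_identical(vapply(ax5, function(a) a@name, ""),
                   c("t", "c", "z", "y", "x"))
  expect_identical(vapply(ax5, function(a) a@type, ""),
                   c("time", "channel", "space", "space", "space"))
  ax2 <- defaultAxes(2)
  expect_identical(vapply(ax2, function(a) a@name, ""), c("y", "x"))
  expect_error(defaultAxes(6), "more than 5 dimensions")
  expect_error(defaultAxes(1), "at least 2")
})

test_that("axis lists enforce the time, channel, space order", {
  expect_error(multiscaleMeta(rev(defaultAxes(4)),
                              list(datasetEntry("0", rep(1, 4)))),
               "order")
  expect_error(multiscaleMeta(defaultAxes(5)[c(1, 1, 3, 4, 5)],
                              list(datasetEntry("0", rep(1, 5)))),
               "unique|one time")
  expect_error(multiscaleMeta(defaultAxes(3),
                              list(datasetEntry("0", c(1, 1)))),
               "one entry per axis")
})

randomMeta <- function() {
  ndim <- sample(2:5, 1)
  axes <- defaultAxes(ndim)
  nLevels <- sample(1:3, 1)
  base <- round(runif(ndim, 0.1, 4), 3)
  ds <- lapply(seq_len(nLevels) - 1, function(lv) {
    tr <- if (runif(1) < 0.5) round(runif(ndim, -5, 5), 2) else numeric(0)
    datasetEntry(as.character(lv),
                 levelScale(base, lv, 2, (ndim - 1):ndim), tr)
  })
  multiscaleMeta(axes, ds,
                 name = if (runif(1) < 0.5) "img" else NA_character_,
                 downsamplingMethod =
                   if (runif(1) < 0.5) "local mean" else NA_character_)
}

test_that("multiscales serialization round-trips through JSON", {
  set.seed(33)
  for (i in 1:20) {
    meta <- randomMeta()
    json <- jsonlite::toJSON(multiscalesToDoc(meta), auto_unbox = TRUE,
                             digits = NA)
    back <- parseMultiscales(jsonlite::fromJSON(json,
                                                simplifyVector = FALSE))
    expect_equal(back, meta)
  }
})

test_that("serialized dataset order is preserved, level 0 first", {
  meta <- multiscaleMeta(defaultAxes(2),
                         list(datasetEntry("0", c(1, 1)),
                              datasetEntry("1", c(2, 2))))
  doc <- multiscalesToDoc(meta)
  expect_identical(vapply(doc$datasets, `[[`, "", "path"), c("0", "1"))
})

test_that("parsing fails descriptively on malformed documents", {
  meta <- multiscaleMeta(defaultAxes(2), list(datasetEntry("0", c(1, 1))))
  doc <- multiscalesToDoc(meta)
  expect_error(parseMultiscales(doc[setdiff(names(doc), "axes")]), "axes")
  expect_error(parseMultiscales(doc[setdiff(names(doc), "datasets")]),
               "datasets")
  bad <- doc; bad$version <- "0.9"
  expect_error(parseMultiscales(bad), "version")
  bad <- doc
  bad$datasets[[1]]$coordinateTransformations <- list(
    list(type = "rotation", rotation = list(1)))
  expect_error(parseMultiscales(bad), "scale transform|unsupported")
})

test_that("level scale doubles per level on the downsampled axes", {
  expect_equal(levelScale(c(1, 1, 1, 0.5, 0.5), 1, 2, c(4, 5)),
               c(1, 1, 1, 1, 1))
  expect_equal(levelScale(c(1, 1, 1, 1, 1), 0, 2, c(4, 5)),
               c(1, 1, 1, 1, 1))
  expect_equal(levelScale(c(1, 1, 1, 1, 1), 3, 2, c(4, 5)),
               c(1, 1, 1, 8, 8))
  expect_error(levelScale(c(1, 1), -1, 2, 2), "non-negative")
  expect_error(levelScale(c(1, 1), 1, 1, 2), "at least 2")
})

test_that("physical extent is conserved within one voxel across levels", {
  img <- makeImage(c(1, 1, 1, 48, 40), content = "gradient")
  pyr <- buildPyramid(img$data, defaultAxes(5), dtype = "u2",
                      minExtent = 8, baseScale = c(1, 1, 1, 0.5, 0.5))
  ext0 <- dim(pyr$levels[[1]]) * pyr$meta@datasets[[1]]@scale
  for (i in seq_along(pyr$levels)[-1]) {
    sc <- pyr$meta@datasets[[i]]@scale
    ext <- dim(pyr$levels[[i]]) * sc
    expect_true(all(abs(ext - ext0) <= sc),
                label = paste("level", i - 1))
  }
})

test_that("channel rendering enforces window ordering and hex colors", {
  cr <- channelRendering(c("FF0000", "00FF00"),
                         list(c(0, 10, 200, 255), c(0, 0, 255, 255)))
  expect_length(cr$channels, 2)
  expect_error(channelRendering("FF0000", list(c(0, 300, 200, 255))),
               "window")
  expect_error(channelRendering("red", list(c(0, 1, 2, 3))), "hex")
})
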