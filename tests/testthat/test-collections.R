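test_that("well paths are row/column joins of alphanumeric names", {
  expect_identical(wellPath("A", "1"), "A/1")
  expect_identical(wellPath("H", "12"), "H/12")
  expect_error(wellPath("", "1"), "alphanumeric")
  expect_error(wellPath("A", "1-2"), "alphanumeric")
})

makeWellImages <- function(plate, shape = c(1, 1, 1, 16, 16), seed = 1) {
  paths <- plateWells(plate)$path
  imgs <- lapply(seq_along(paths), function(i)
    list(makeImage(shape, content = "noise", seed = seed + i)$data))
  stats::setNames(imgs, paths)
}

test_that("plates write the full three-level hierarchy", {
  store <- memoryStore()
  plate <- plateMeta(c("A", "B"), c("1", "2", "3"))
  writePlate(store, "p", plate, makeWellImages(plate), dtype = "u2",
             minExtent = 8)
  attrs <- getAttrs(store, "p")
  expect_length(attrs$plate$wells, 6)
  wellGroups <- grep("^p/[A-B]/[0-9]+/\\.zgroup$", kvList(store, "p"),
                     value = TRUE)
  expect_length(wellGroups, 6)
  ## every written well path parses back through wellPath
  for (w in attrs$plate$wells) {
    parts <- strsplit(w$path[[1]], "/")[[1]]
    expect_identical(wellPath(parts[1], parts[2]), w$path[[1]])
  }
})

test_that("duplicate and undeclared wells are rejected", {
  store <- memoryStore()
  plate <- plateMeta("A", c("1", "2"))
  img <- list(makeImage(c(1, 1, 1, 8, 8), content = "gradient")$data)
  dup <- list(img, img)[c(1, 2)]
  names(dup) <- c("A/1", "A/1")
  expect_error(writePlate(store, "p", plate, dup, minExtent = 8),
               "written twice")
  expect_error(writePlate(store, "p", plate,
                          stats::setNames(list(img), "B/1"), minExtent = 8),
               "not declared")
  expect_error(writePlate(store, "p", plate,
                          stats::setNames(list(c(img, img)), "A/1"),
                          minExtent = 8),
               "field count")
  expect_error(plateMeta(c("A", "A"), "1"), "unique")
})

test_that("montage extents equal rows x height by columns x width", {
  set.seed(17)
  for (i in 1:4) {
    nr <- sample(2:8, 1); nc <- sample(2:12, 1)
    plate <- plateMeta(LETTERS[seq_len(nr)], as.character(seq_len(nc)))
    paths <- plateWells(plate)$path
    missing <- sample(paths, max(1, length(paths) %/% 4))
    store <- memoryStore()
    makePlateFixture(store, "p", rows = nr, cols = nc,
                     shape = c(1, 1, 1, 16, 16), minExtent = 8, seed = i,
                     missingWells = missing)
    m <- montage(store, "p", level = 1)
    expect_equal(dim(m), c(nr * 8, nc * 8),
                 label = paste("grid", nr, "x", nc))
  }
})

test_that("absent wells montage as fill value", {
  store <- memoryStore()
  makePlateFixture(store, "p", rows = 2, cols = 3,
                   shape = c(1, 1, 1, 16, 16), minExtent = 8,
                   missingWells = "B/2")
  m <- montage(store, "p", level = 0, fillValue = -1)
  expect_equal(dim(m), c(32, 48))
  cell <- m[17:32, 17:32]
  expect_true(all(cell == -1))
  expect_false(all(m[1:16, 1:16] == -1))
})

test_that("montage rejects absent levels and fields", {
  store <- memoryStore()
  makePlateFixture(store, "p", rows = 1, cols = 2,
                   shape = c(1, 1, 1, 16, 16), minExtent = 8)
  expect_error(montage(store, "p", level = 9), "level 9 absent")
  expect_error(montage(store, "p", field = 3), "field index")
})

test_that("label images are listed, typed and color-stable", {
  store <- memoryStore()
  img <- makeImage(c(1, 1, 1, 32, 32), content = "blobs", blobCount = 3,
                   seed = 12)
  writeMultiscaleImage(store, "img", img$data, dtype = "u2", minExtent = 8)
  colors <- data.frame(labelValue = 1:3, r = c(10, 20, 30),
                       g = c(1, 2, 3), b = c(100, 150, 200), a = 255)
  writeLabels(store, "img", "nuclei", img$labels,
              labelMeta(colors, properties = list(
                list(labelValue = 1, area = 12))),
              minExtent = 8)
  expect_identical(listLabels(store, "img"), "nuclei")
  attrs <- getAttrs(store, "img/labels/nuclei")
  expect_false(is.null(attrs$`image-label`))
  back <- readLabelMeta(store, "img", "nuclei")
  expect_equal(back@colors$labelValue, colors$labelValue)
  expect_equal(back@colors$r, colors$r)
  expect_equal(back@properties[[1]]$area, 12)

  expect_error(writeLabels(store, "img", "nuclei", img$labels),
               "already exists")
  expect_error(writeLabels(store, "img", "soft", img$labels + 0.5),
               "integer dtype")
  expect_error(labelMeta(data.frame(labelValue = c(1, 1), r = 0, g = 0,
                                    b = 0, a = 0)), "unique")
  expect_error(labelMeta(data.frame(labelValue = 1, r = 999, g = 0,
                                    b = 0, a = 0)), "255")
})

test_that("stored label pyramids keep the level-0 value set", {
  store <- memoryStore()
  img <- makeImage(c(1, 1, 1, 64, 64), content = "blobs", blobCount = 5,
                   seed = 3)
  writeMultiscaleImage(store, "img", img$data, dtype = "u2", minExtent = 8)
  writeLabels(store, "img", "blobs", img$labels, minExtent = 8)
  meta <- readImageMeta(store, "img/labels/blobs")
  base <- unique(as.vector(readImageLevel(store, "img/labels/blobs", 0)))
  for (lv in seq_along(meta@datasets)[-1] - 1) {
    vals <- unique(as.vector(readImageLevel(store, "img/labels/blobs", lv)))
    expect_true(all(vals %in% base))
  }
})
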