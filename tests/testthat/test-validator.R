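makeValidImage <- function(store, path = "img", withLabels = TRUE) {
  makeImageFixture(store, path, shape = c(1, 1, 1, 32, 32),
                   content = "blobs", blobCount = 3, seed = 21,
                   withLabels = withLabels, minExtent = 8)
}

test_that("natively written images validate with zero findings", {
  store <- memoryStore()
  makeValidImage(store)
  report <- validateImage(store, "img")
  expect_true(reportOk(report))
  expect_equal(nrow(reportFindings(report)), 0)
})

test_that("natively written plates validate with zero findings", {
  store <- memoryStore()
  makePlateFixture(store, "p", rows = 2, cols = 3,
                   shape = c(1, 1, 1, 16, 16), minExtent = 8)
  report <- validatePlate(store, "p")
  expect_true(reportOk(report))
  expect_equal(nrow(reportFindings(report)), 0)
})

test_that("every registered error code has a single-rule mutation", {
  codes <- findingCodes()
  triggered <- character(0)
  for (mut in mutationNames()) {
    store <- memoryStore()
    plateMut <- mut %in% c("wellPath", "missingWell", "dropPlate")
    if (plateMut) {
      makePlateFixture(store, "t", rows = 2, cols = 2,
                       shape = c(1, 1, 1, 16, 16), minExtent = 8)
    } else {
      makeValidImage(store, "t")
    }
    expected <- applyMutation(store, "t", mut)
    report <- if (plateMut) validatePlate(store, "t")
              else validateImage(store, "t")
    f <- reportFindings(report)
    expect_true(expected %in% f$code, label = paste("mutation", mut))
    sev <- codes[[expected]]
    if (sev == "error") {
      expect_identical(unique(f$code[f$severity == "error"]), expected,
                       label = paste("mutation", mut, "extra errors"))
      expect_false(reportOk(report))
    } else {
      expect_true(reportOk(report),
                  label = paste("mutation", mut, "must stay ok"))
    }
    triggered <- c(triggered, expected)
  }
  ## completeness: every registered error code is covered by some mutation
  errorCodes <- names(codes)[codes == "error"]
  expect_setequal(intersect(triggered, errorCodes), errorCodes)
})

test_that("findings are ordered by path then code", {
  store <- memoryStore()
  makeValidImage(store, "t")
  applyMutation(store, "t", "transformLength")
  applyMutation(store, "t", "unknownCodec")
  report <- validateImage(store, "t")
  f <- reportFindings(report)
  expect_identical(order(f$path, f$code), seq_len(nrow(f)))
  report2 <- validateImage(store, "t")
  expect_identical(reportFindings(report2), f)
})

test_that("validator accepts ranks 2 through 5 and rejects rank 6", {
  accepted <- integer(0)
  for (rank in 2:5) {
    store <- memoryStore()
    shape <- c(1, 1, 1, 16, 16)[(5 - rank + 1):5]
    makeImageFixture(store, "r", shape = shape, minExtent = 8)
    if (reportOk(validateImage(store, "r"))) accepted <- c(accepted, rank)
  }
  expect_identical(accepted, 2:5)
  store <- memoryStore()
  makeImageFixture(store, "r", shape = c(1, 1, 1, 16, 16), minExtent = 8)
  applyMutation(store, "r", "axes6")
  report <- validateImage(store, "r")
  expect_false(reportOk(report))
  expect_true("E_AXES_COUNT" %in% reportFindings(report)$code)
})

test_that("summaries report per-level geometry and voxel counts", {
  store <- memoryStore()
  makeImageFixture(store, "img", shape = c(1, 1, 1, 64, 48),
                   minExtent = 16)
  s <- summarizeTree(store, "img")
  expect_equal(nrow(s@levels), 3)
  expect_identical(s@levels$shape,
                   c("1, 1, 1, 64, 48", "1, 1, 1, 32, 24",
                     "1, 1, 1, 16, 12"))
  expect_equal(s@totalVoxels, 64 * 48)
  expect_true(all(s@levels$storedChunks == s@levels$nchunks))
  expect_error(summarizeTree(store, "nothing/here"), "not found")
})

test_that("plate summaries carry the grid dimensions", {
  store <- memoryStore()
  makePlateFixture(store, "p", rows = 2, cols = 3,
                   shape = c(1, 1, 1, 16, 16), minExtent = 8)
  s <- summarizeTree(store, "p")
  expect_equal(s@plateGrid, c(2, 3))
  expect_equal(s@totalVoxels, 256)
})

test_that("validation of a missing path raises, not reports", {
  store <- memoryStore()
  expect_error(validateImage(store, "absent"), "not found")
  expect_error(validatePlate(store, "absent"), "not found")
})

test_that("reports render to machine-readable JSON", {
  store <- memoryStore()
  makeValidImage(store, "t", withLabels = FALSE)
  applyMutation(store, "t", "axes6")
  txt <- reportToJson(validateImage(store, "t"))
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  expect_false(doc$ok)
  expect_identical(doc$findings[[1]]$code, "E_AXES_COUNT")
})
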