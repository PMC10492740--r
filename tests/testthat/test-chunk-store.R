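test_that("grid shape is per-axis ceiling division", {
  expect_equal(gridShape(10, 3), 4)
  expect_equal(gridShape(c(2048, 2048), c(1024, 1024)), c(2, 2))
  ## lightsheet tile geometry: 192 x 84 x 16 chunks of 128^3
  expect_equal(gridShape(c(24576, 10656, 2048), c(128, 128, 128)),
               naiveGridShape(c(24576, 10656, 2048), c(128, 128, 128)))
  expect_equal(gridShape(c(24576, 10656, 2048), c(128, 128, 128)),
               c(192, 84, 16))
  expect_error(gridShape(c(4, 4), 2), "rank")
  expect_error(gridShape(c(4, 0), c(2, 2)), "positive")
})

test_that("grid shape matches chunk-origin enumeration on small extents", {
  set.seed(11)
  for (rank in 1:3) {
    for (i in 1:25) {
      shape <- sample.int(10, rank, replace = TRUE)
      chunk <- pmin(sample.int(10, rank, replace = TRUE), shape)
      expect_equal(gridShape(shape, chunk), naiveGridShape(shape, chunk))
    }
  }
})

test_that("chunk keys join path and indices with the separator", {
  expect_identical(chunkKey("0", c(0, 0, 0, 0, 0), "."), "0/0.0.0.0.0")
  expect_identical(chunkKey("labels/nuclei/0", c(1, 2), "."),
                   "labels/nuclei/0/1.2")
  expect_identical(chunkKey("0", 3, "/"), "0/3")
  expect_error(chunkKey("0", c(1, 1), ",", grid = c(2, 2)), "separator")
  expect_error(chunkKey("0", c(2, 0), "/", grid = c(2, 2)), "outside")
})

test_that("raw byte size is extent product times element width", {
  expect_equal(rawByteSize(c(24576, 10656, 2048), "u2"), 1072668082176)
  expect_equal(rawByteSize(c(1, 1, 128, 128, 128), "u2"), 4194304)
  expect_equal(rawByteSize(1, "u1"), 1)
  expect_error(rawByteSize(c(4, 4), "u16"), "unknown dtype")
})

test_that("uncompressed chunks serialize row-major", {
  schema <- arraySchema(c(2, 2), c(2, 2), "u1", codec = NULL)
  block <- matrix(c(0, 2, 1, 3), 2)  # [[0,1],[2,3]] row-wise
  bytes <- encodeChunk(block, schema)
  expect_identical(as.integer(bytes), 0:3)
  expect_identical(decodeChunk(bytes, schema), block)
})

test_that("zlib chunks round-trip bit-exactly for float blocks", {
  set.seed(7)
  schema <- arraySchema(c(4, 5), c(4, 5), "f4",
                        codec = codecSpec("zlib", level = 5L))
  block <- array(round(rnorm(20) * 64) / 64, dim = c(4, 5))
  expect_identical(decodeChunk(encodeChunk(block, schema), schema), block)
})

test_that("unknown codec ids are rejected at the registry", {
  schema <- arraySchema(c(2, 2), c(2, 2), "u1", codec = codecSpec("lz99"))
  expect_error(encodeChunk(matrix(0, 2, 2), schema), "unknown codec")
})

test_that("corrupted payloads fail decoding with a clear message", {
  schema <- arraySchema(c(2, 2), c(2, 2), "u2",
                        codec = codecSpec("zlib", level = 5L))
  expect_error(decodeChunk(as.raw(c(1, 2, 3)), schema), "corrupted")
  rawSchema <- arraySchema(c(2, 2), c(2, 2), "u2", codec = NULL)
  expect_error(decodeChunk(as.raw(c(1, 2, 3)), rawSchema), "corrupted")
})

test_that("edge chunks are stored padded to the full chunk byte length", {
  store <- memoryStore()
  schema <- arraySchema(5, 2, "u1", codec = NULL, fillValue = 9)
  writeArray(store, "a", c(1, 2, 3, 4, 5), schema)
  chunkKeys <- setdiff(kvList(store, "a"), "a/.zarray")
  expect_length(chunkKeys, 3)
  last <- kvGet(store, "a/2")
  expect_identical(as.integer(last), c(5L, 9L))  # padded with fill
  expect_equal(as.vector(readArray(store, "a")), c(1, 2, 3, 4, 5))
})

test_that("write then full read is bit-identical for every dtype", {
  set.seed(101)
  for (dtype in dtypeCodes()) {
    for (i in 1:3) {
      rank <- sample(1:5, 1)
      shape <- sample.int(6, rank, replace = TRUE)
      chunk <- pmin(sample.int(4, rank, replace = TRUE), shape)
      data <- randomBlock(shape, dtype)
      codec <- if (i %% 2) codecSpec("zlib", level = 1L) else NULL
      store <- memoryStore()
      schema <- arraySchema(shape, chunk, dtype, codec = codec)
      writeArray(store, "x", data, schema)
      expect_identical(readArray(store, "x"), data,
                       label = paste("dtype", dtype, "case", i))
    }
  }
})

test_that("the full unsigned 32-bit range survives a round trip", {
  store <- memoryStore()
  vals <- c(0, 1, 2^31 - 1, 2^31, 2^32 - 1)
  schema <- arraySchema(5, 5, "u4", codec = NULL)
  writeArray(store, "u", vals, schema)
  expect_equal(as.vector(readArray(store, "u")), vals)
})

test_that("region reads return exactly the requested voxels", {
  store <- memoryStore()
  schema <- arraySchema(4, 2, "u2", codec = NULL)
  writeArray(store, "v", c(10, 20, 30, 40), schema)
  expect_equal(as.vector(readRegion(store, "v", region(1, 2))), c(20, 30))
  expect_equal(as.vector(readRegion(store, "v", region(0, 4))),
               c(10, 20, 30, 40))
  expect_error(readRegion(store, "v", region(3, 5)), "exceeds")
  expect_error(readRegion(store, "missing", region(0, 1)), "no array")
})

test_that("single-chunk regions fetch only the intersecting chunk", {
  store <- memoryStore()
  shape <- c(8, 8); chunk <- c(4, 4)
  schema <- arraySchema(shape, chunk, "u2", codec = NULL)
  writeArray(store, "lz", array(seq_len(64), dim = shape), schema)
  clearTrace(store)
  readRegion(store, "lz", region(c(5, 5), c(2, 2)))
  chunkGets <- grep("\\.z", storeTrace(store), value = TRUE, invert = TRUE)
  expect_identical(chunkGets, "lz/1/1")

  clearTrace(store)
  readRegion(store, "lz", region(c(3, 3), c(2, 2)))  # straddles 4 chunks
  chunkGets <- grep("\\.z", storeTrace(store), value = TRUE, invert = TRUE)
  expect_setequal(chunkGets, c("lz/0/0", "lz/0/1", "lz/1/0", "lz/1/1"))
})

test_that("deleted chunk objects read back as fill value", {
  store <- memoryStore()
  schema <- arraySchema(c(4, 4), c(2, 2), "i2", codec = NULL,
                        fillValue = -7)
  writeArray(store, "f", array(1, dim = c(4, 4)), schema)
  kvDelete(store, "f/0/1")
  out <- readArray(store, "f")
  expect_true(all(out[1:2, 3:4] == -7))
  expect_true(all(out[3:4, ] == 1))
})

test_that("schema and data must agree on rank and shape", {
  store <- memoryStore()
  schema <- arraySchema(c(2, 2, 2), c(2, 2, 2), "u1", codec = NULL)
  expect_error(writeArray(store, "x", matrix(0, 2, 2), schema), "rank")
  schema2 <- arraySchema(c(3, 3), c(2, 2), "u1", codec = NULL)
  expect_error(writeArray(store, "x", matrix(0, 2, 2), schema2), "shape")
  expect_error(arraySchema(c(4, 4), 2, "u1"), "rank")
  expect_error(arraySchema(c(4, 4), c(2, 2), "u9"), "dtype")
  expect_error(arraySchema(4, 2, "u1", fillValue = 300), "fill")
})

test_that("both dimension-separator dialects are read back", {
  for (sep in c("/", ".")) {
    store <- memoryStore()
    schema <- arraySchema(c(3, 3), c(2, 2), "u1", codec = NULL,
                          dimensionSeparator = sep)
    data <- array(as.numeric(seq_len(9)), dim = c(3, 3))
    writeArray(store, "s", data, schema)
    expect_identical(readArray(store, "s"), data)
  }
  ## a .zarray without the separator field defaults to "."
  store <- memoryStore()
  schema <- arraySchema(c(2, 2), c(2, 2), "u1", codec = NULL,
                        dimensionSeparator = ".")
  writeArray(store, "d", matrix(1:4 - 1, 2), schema)
  doc <- jsonlite::fromJSON(rawToChar(kvGet(store, "d/.zarray")),
                            simplifyVector = FALSE)
  doc$dimension_separator <- NULL
  kvPut(store, "d/.zarray",
        charToRaw(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null")))
  expect_identical(readArray(store, "d"), matrix(1:4 - 1, 2))
})

test_that("directory stores round-trip bytes and list by prefix", {
  root <- withr::local_tempdir()
  store <- directoryStore(root)
  kvPut(store, "a/b/c", as.raw(1:4))
  kvPut(store, "a/d", as.raw(9))
  expect_identical(kvGet(store, "a/b/c"), as.raw(1:4))
  expect_identical(kvList(store, "a"), c("a/b/c", "a/d"))
  kvDelete(store, "a/d")
  expect_false(kvExists(store, "a/d"))
  expect_error(kvGet(store, "a/d"), "not found")
})
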