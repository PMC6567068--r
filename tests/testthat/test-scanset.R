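test_that("ScanSet construction validates shapes and labels", {
  ds <- toyDataset(4L)
  expect_s4_class(ds, "ScanSet")
  expect_identical(nScans(ds), 12L)
  expect_identical(nrow(currents(ds)), 64L)
  expect_identical(classNames(ds), c("a", "b", "c"))
  expect_identical(scheme(ds), "custom")
  g <- toyGrid()
  expect_error(ScanSet(matrix(0, 63, 2), c("a", "b"), g), "match grid")
  expect_error(ScanSet(matrix(0, 64, 2), c("a", "z"), g,
                       classNames = c("a", "b")), "outside")
  expect_error(ScanSet(matrix(NA_real_, 64, 1), "a", g), "non-finite")
})

test_that("single scans extract as Voltammogram objects", {
  ds <- toyDataset(4L)
  v <- getScan(ds, 5)
  expect_s4_class(v, "Voltammogram")
  expect_identical(v@label, as.character(scanLabels(ds)[5]))
  expect_identical(v@currents, as.numeric(currents(ds)[, 5]))
  expect_true(is.finite(v@concentrationProxy))
})

test_that("scan CSV write/read round-trips field by field", {
  ds <- toyDataset(3L, seed = 7L)
  path <- tempfile(fileext = ".csv")
  writeScans(ds, path)
  back <- readScans(path, grid = potentialGrid(ds), scheme = scheme(ds),
                    classNames = classNames(ds))
  expect_equal(currents(back), currents(ds), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(as.character(scanLabels(back)),
                   as.character(scanLabels(ds)))
  expect_identical(colData(back)$sample_id, colData(ds)$sample_id)
  expect_equal(colData(back)$concentration_proxy,
               colData(ds)$concentration_proxy, tolerance = 1e-12)
  expect_identical(classNames(back), classNames(ds))
})

test_that("malformed scan CSVs are rejected and empty files tolerated", {
  ds <- toyDataset(2L)
  path <- tempfile(fileext = ".csv")
  writeScans(ds, path)
  # drop one current column -> row length mismatch
  df <- read.csv(path, check.names = FALSE)
  write.csv(df[, -ncol(df)], path, row.names = FALSE)
  expect_error(readScans(path, grid = potentialGrid(ds)), "does not match")
  empty <- tempfile(fileext = ".csv")
  file.create(empty)
  e <- readScans(empty, grid = toyGrid(), scheme = "custom",
                 classNames = c("a", "b"))
  expect_identical(nScans(e), 0L)
  expect_identical(scheme(e), "custom")
  expect_identical(classNames(e), c("a", "b"))
})

test_that("dataset truncation drops points, keeps labels, and composes", {
  ds <- generateDataset(seawaterLibrarySpec(scale = 0.05), seed = 3)
  tr <- truncateScans(ds, 502L, 100L)
  expect_identical(nrow(currents(tr)), 400L)
  expect_identical(as.character(scanLabels(tr)),
                   as.character(scanLabels(ds)))
  expect_equal(currents(tr), currents(ds)[503:902, ],
               ignore_attr = TRUE)
  # identity truncation
  id <- truncateScans(ds, 0L, 0L)
  expect_equal(currents(id), currents(ds), ignore_attr = TRUE)
  # composition
  ta <- truncateScans(truncateScans(ds, 10L, 0L), 0L, 20L)
  tb <- truncateScans(ds, 10L, 20L)
  expect_equal(currents(ta), currents(tb), ignore_attr = TRUE)
  expect_error(truncateScans(ds, 1000L, 1L), "fewer than 2")
})
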