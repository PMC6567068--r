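test_that("CAM combination is linear and normalizes min-max", {
  # degenerate: all-zero feature maps -> all-zero CAM
  z <- camFromFeatures(matrix(0, 20, 3), c(1, 1, 1))
  expect_identical(z$activations, rep(0, 20))
  # a single nonzero feature map with unit weight reproduces that map
  A <- matrix(0, 20, 3)
  A[, 2] <- sin(seq_len(20))
  one <- camFromFeatures(A, c(0, 1, 0))
  expect_equal(one$raw, A[, 2])
  expect_equal(one$activations,
               (A[, 2] - min(A[, 2])) / diff(range(A[, 2])))
  expect_equal(max(one$activations), 1)
  # linearity of the raw maps
  set.seed(9)
  A1 <- matrix(rnorm(60), 20, 3)
  A2 <- matrix(rnorm(60), 20, 3)
  w <- rnorm(3)
  expect_equal(camFromFeatures(A1 + A2, w)$raw,
               camFromFeatures(A1, w)$raw + camFromFeatures(A2, w)$raw,
               tolerance = 1e-9)
})

test_that("linear resampling preserves the argmax location", {
  A <- matrix(0, 25, 2)
  A[14, 1] <- 3
  A[13, 1] <- 2
  A[15, 1] <- 2
  up <- camFromFeatures(A, c(1, 0), outLength = 50L)
  expect_identical(length(up$activations), 50L)
  # index 14 of 25 maps to cell 27..28 of 50
  expect_lte(abs(which.max(up$activations) - 14 * 2), 2)
})

test_that("computeCAM follows the model's convolutional branch", {
  ds <- toyDataset(6L, noise = 0.02)
  fit <- trainDeep("fcn", ds, ds, deepTrainConfig(epochs = 25L, seed = 4))
  v <- getScan(ds, 1)
  cam <- computeCAM(fit, v)
  expect_s4_class(cam, "CAMResult")
  expect_identical(length(cam@activations), 64L)
  expect_true(all(cam@activations >= 0 & cam@activations <= 1))
  expect_equal(max(cam@activations), 1)
  expect_identical(cam@targetClass, v@label)
  # explicit target class and bare numeric trace
  cam2 <- computeCAM(fit, v@currents, targetClass = "b")
  expect_identical(cam2@targetClass, "b")
  expect_error(computeCAM(fit, v, targetClass = "nope"), "unknown")
  # the per-point export table lines up with the grid
  tab <- camTable(cam, v)
  expect_identical(names(tab), c("index", "potential", "current",
                                 "activation"))
  expect_identical(tab$index, 0:63)
  expect_equal(tab$potential, v@grid@potentials)
})

test_that("pure LSTM models cannot provide a CAM", {
  ds <- toyDataset(4L)
  fit <- trainDeep("lstm", ds, ds, deepTrainConfig(epochs = 3L, seed = 1))
  expect_error(computeCAM(fit, getScan(ds, 1)), "unsupported")
})

test_that("truncation with zero drops reproduces the baseline protocol", {
  ds <- toyDataset(8L, noise = 0.02)
  cfg <- deepTrainConfig(epochs = 20L, seed = 6)
  res <- camGuidedTruncation(ds, 0L, 0L, kind = "fcn",
                             plan = SplitPlan(0.7, 1L, seed = 2L),
                             config = cfg)
  expect_identical(res$report$length, c(64L, 64L))
  expect_identical(dim(res$confusionFull), dim(res$confusionTruncated))
  # identical data and seeds -> identical reports
  expect_equal(res$report$accuracy[1], res$report$accuracy[2])
})
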