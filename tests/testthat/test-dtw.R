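test_that("banded DTW reproduces hand-checked values", {
  expect_identical(dtwDistance(c(0, 1, 2), c(0, 1, 2)), 0)
  expect_identical(dtwDistance(c(0, 1, 2), c(0, 2, 2)), 1)
  # window 0 collapses to the pointwise L1 / squared distance
  a <- c(0.5, -1, 2, 0)
  b <- c(1, 0, -2, 3)
  expect_equal(dtwDistance(a, b, window = 0L), sum(abs(a - b)))
  expect_equal(dtwDistance(a, b, window = 0L, cost = "squared"),
               sum((a - b)^2))
  expect_error(dtwDistance(numeric(), 1), "empty")
  expect_error(dtwDistance(1:3, 1:3, window = -1), "window")
})

test_that("banded DP equals brute-force path enumeration on short traces", {
  set.seed(101)
  alphabet <- c(0, 1, 2)
  # exhaustive over all pairs of length-3 traces
  g3 <- as.matrix(expand.grid(alphabet, alphabet, alphabet))
  for (i in seq_len(nrow(g3))) {
    j <- sample(nrow(g3), 1)
    for (w in c(0L, 1L, 3L))
      expect_equal(dtwDistance(g3[i, ], g3[j, ], window = w),
                   bruteDtw(g3[i, ], g3[j, ], window = w))
  }
  # random pairs up to length 6, both costs, several windows
  for (rep in 1:150) {
    n <- sample(2:6, 1)
    a <- sample(alphabet, n, replace = TRUE)
    b <- sample(alphabet, n, replace = TRUE)
    w <- sample(0:6, 1)
    sq <- rep %% 2 == 0
    expect_equal(
      dtwDistance(a, b, window = w, cost = if (sq) "squared"
                                           else "absolute"),
      bruteDtw(a, b, window = w, squared = sq),
      label = sprintf("n=%d w=%d sq=%d", n, w, sq))
  }
})

test_that("DTW is symmetric, nonnegative and monotone in the window", {
  set.seed(7)
  for (i in 1:25) {
    a <- rnorm(12)
    b <- rnorm(12)
    d5 <- dtwDistance(a, b, window = 5L)
    expect_gte(d5, 0)
    expect_equal(d5, dtwDistance(b, a, window = 5L))
    ds <- vapply(c(0L, 2L, 5L, 12L), function(w)
      dtwDistance(a, b, window = w), 1.0)
    expect_true(all(diff(ds) <= 1e-12))
  }
})

test_that("1-NN DTW classifies by nearest neighbour with earliest-index ties", {
  ds <- toyDataset(6L, noise = 1e-4)
  fit <- fitDTW(ds, window = 10L)
  # a training scan is its own nearest neighbour
  expect_identical(knn1DtwPredict(fit, getScan(ds, 4)),
                   as.character(scanLabels(ds)[4]))
  # tie: two identical train scans with different labels -> earliest wins
  g <- toyGrid(8L)
  X <- matrix(c(rep(1, 8), rep(1, 8), rep(5, 8)), nrow = 8)
  tie <- ScanSet(X, c("first", "second", "far"), g)
  expect_identical(knn1DtwPredict(fitDTW(tie), rep(1, 8)), "first")
  # near noise-free classes are perfectly recovered
  sp <- stratifiedSplit(ds, SplitPlan(0.7, 1L, seed = 2L), 0L)
  pred <- predictLabel(fitDTW(sp$train), sp$test)
  expect_identical(pred, as.character(scanLabels(sp$test)))
})

test_that("DTW probability scores rank the predicted class first", {
  ds <- toyDataset(5L, noise = 1e-3)
  fit <- fitDTW(ds)
  P <- predictProb(fit, ds)
  expect_equal(rowSums(P), rep(1, nScans(ds)), tolerance = 1e-9)
  expect_identical(colnames(P)[max.col(P, "first")],
                   predictLabel(fit, ds))
})
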