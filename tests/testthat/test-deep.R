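test_that("architectures expose the published structure", {
  set.seed(1)
  m <- buildDeepModel("fcn", 3, 64L)
  info <- modelInfo(m)
  expect_identical(info$fcn_dim, 128L)
  expect_identical(info$lstm_dim, 0L)
  set.seed(1)
  ml <- buildDeepModel("lstm", 3, 64L, cells = 8L)
  il <- modelInfo(ml)
  expect_identical(il$fcn_dim, 0L)
  expect_identical(il$lstm_dim, 8L)
  # dimension shuffle: the recurrent block consumes one step of L features
  expect_identical(il$lstm_steps, 1L)
  expect_identical(il$length, 64L)
  mh <- buildDeepModel("alstm_fcn", 3, 64L, cells = 16L)
  ih <- modelInfo(mh)
  expect_identical(ih$fcn_dim, 128L)
  expect_identical(ih$lstm_dim, 16L)
  expect_error(buildDeepModel("mlp", 3, 64L), "arg")
  expect_error(buildDeepModel("fcn", 3, 5L), "kernel")
  expect_error(buildDeepModel("fcn", 1, 64L), "nClasses")
  expect_error(buildDeepModel("lstm", 3, 64L, cells = 7L), "cells")
})

test_that("convolution kernels start from the He distribution", {
  set.seed(42)
  m <- buildDeepModel("fcn", 4, 128L)
  st <- cswv:::nn_state_get(m@ptr)
  fanIn <- c(W1 = 8 * 1, W2 = 5 * 128, W3 = 3 * 256)
  for (nm in names(fanIn)) {
    v <- var(as.numeric(st[[nm]]))
    expect_lt(abs(v - 2 / fanIn[[nm]]) / (2 / fanIn[[nm]]), 0.2,
              label = paste("He variance of", nm))
  }
})

test_that("softmax probabilities normalize for every architecture", {
  ds <- toyDataset(4L)
  X <- t(currents(ds))
  for (k in c("lstm", "fcn", "lstm_fcn", "alstm_fcn")) {
    set.seed(3)
    m <- buildDeepModel(k, 3, 64L)
    P <- cswv:::nn_predict(m@ptr, X)
    expect_equal(rowSums(P), rep(1, nrow(X)), tolerance = 1e-5,
                 label = paste("softmax rows for", k))
  }
})

test_that("attention weights are a probability profile per scan", {
  ds <- toyDataset(4L)
  set.seed(3)
  m <- buildDeepModel("alstm_fcn", 3, 64L)
  A <- cswv:::nn_attention(m@ptr, t(currents(ds)))
  expect_true(all(A >= 0))
  expect_equal(rowSums(A), rep(1, nScans(ds)), tolerance = 1e-5)
  set.seed(3)
  plain <- buildDeepModel("lstm_fcn", 3, 64L)
  expect_error(cswv:::nn_attention(plain@ptr, t(currents(ds))),
               "attention")
})

test_that("the plateau schedule decays by 2^(1/3) and clips at the floor", {
  cfg <- deepTrainConfig()
  expect_equal(lrScheduleStep(0.001, 100, cfg), 0.001 * 2^(-1 / 3),
               tolerance = 1e-12)
  expect_equal(lrScheduleStep(0.001, 100, cfg), 7.937e-4,
               tolerance = 1e-4)
  expect_identical(lrScheduleStep(0.001, 50, cfg), 0.001)
  expect_identical(lrScheduleStep(0.001, 0, cfg), 0.001)
  # ten consecutive 100-epoch plateaus starting from 0.001 reach the floor
  lr <- 0.001
  for (p in 1:10) lr <- lrScheduleStep(lr, 100, cfg)
  expect_identical(lr, 1e-4)
  expect_lt(0.001 * 2^(-10 / 3), 1e-4)
})

test_that("analytic gradients match finite differences on small nets", {
  relErr <- function(a, b) abs(a - b) / max(abs(a), abs(b), 1e-4)
  for (kind in c("fcn", "alstm_fcn")) {
    set.seed(11)
    ptr <- cswv:::nn_new(kind, 12L, 3L, 8L, 0)  # dropout 0 for determinism
    N <- 5L
    X <- matrix(rnorm(N * 12), N, 12)
    y <- sample(0:2, N, TRUE)
    w <- runif(N, 0.5, 1.5)
    g <- cswv:::nn_gradients(ptr, X, y, w)
    st <- cswv:::nn_state_get(ptr)
    h <- 1e-2
    for (pn in intersect(c("W2", "W3", "Wd", "bd", "Wl", "wa"),
                         names(st))) {
      i <- length(st[[pn]]) %/% 2L + 1L
      stp <- st; stp[[pn]][i] <- stp[[pn]][i] + h
      stm <- st; stm[[pn]][i] <- stm[[pn]][i] - h
      num <- (cswv:::nn_loss(cswv:::nn_from_state(stp), X, y, w) -
                cswv:::nn_loss(cswv:::nn_from_state(stm), X, y, w)) /
        (2 * h)
      ana <- g[[paste0("d", pn)]][i]
      # single-precision forward: accept close relative OR absolute match
      expect_true(relErr(num, ana) < 0.05 || abs(num - ana) < 2e-3,
                  label = sprintf("%s gradient of %s (num %.4g ana %.4g)",
                                  kind, pn, num, ana))
    }
  }
})

test_that("class weighting scales the loss linearly", {
  set.seed(5)
  ptr <- cswv:::nn_new("fcn", 16L, 2L, 8L, 0)
  X <- matrix(rnorm(4 * 16), 4, 16)
  y <- c(0L, 1L, 0L, 1L)
  l1 <- cswv:::nn_loss(ptr, X, y, rep(1, 4))
  l2 <- cswv:::nn_loss(ptr, X, y, rep(2, 4))
  expect_equal(l2, 2 * l1, tolerance = 1e-5)
})

test_that("training separates a small library and logs its history", {
  ds <- toyDataset(8L, noise = 0.02)
  cfg <- deepTrainConfig(epochs = 60L, batchSize = 8L,
                         earlyStopPatience = Inf, seed = 2)
  fit <- trainDeep("fcn", ds, ds, cfg)
  h <- fit@history
  expect_lte(nrow(h), cfg$epochs)
  expect_identical(h$epoch, seq_len(nrow(h)))
  # the schedule only decays
  expect_true(all(diff(h$lr) <= 1e-12))
  expect_identical(h$valAccuracy[nrow(h)], 1)
  P <- predictProb(fit, ds)
  expect_identical(colnames(P)[max.col(P, "first")],
                   as.character(scanLabels(ds)))
})

test_that("training under a fixed seed is reproducible", {
  ds <- toyDataset(5L)
  cfg <- deepTrainConfig(epochs = 8L, batchSize = 8L, seed = 7)
  f1 <- trainDeep("lstm_fcn", ds, ds, cfg)
  f2 <- trainDeep("lstm_fcn", ds, ds, cfg)
  expect_identical(predictProb(f1, ds), predictProb(f2, ds))
  expect_identical(f1@history, f2@history)
})

test_that("early stopping halts after a validation plateau", {
  ds <- toyDataset(8L, noise = 0.02)
  cfg <- deepTrainConfig(epochs = 300L, batchSize = 8L,
                         earlyStopPatience = 5L, seed = 2)
  fit <- trainDeep("fcn", ds, ds, cfg)
  expect_lt(nrow(fit@history), 300L)
})

test_that("saved classifiers restore to identical predictions", {
  ds <- toyDataset(5L)
  fit <- trainDeep("alstm_fcn", ds, ds,
                   deepTrainConfig(epochs = 5L, seed = 3))
  path <- tempfile(fileext = ".rds")
  saveClassifier(fit, path)
  back <- readClassifier(path)
  expect_identical(predictProb(back, ds), predictProb(fit, ds))
  expect_identical(back@classLevels, fit@classLevels)
  # classical classifiers round-trip through the same bundle format
  lda <- fitLDA(ds)
  saveClassifier(lda, path)
  expect_equal(predictProb(readClassifier(path), ds),
               predictProb(lda, ds), tolerance = 1e-12)
})

test_that("refinement sweeps tabulate settings by repeat", {
  ds <- toyDataset(8L, noise = 0.05)
  plan <- SplitPlan(0.7, 2L, seed = 1L)
  cfg <- deepTrainConfig(epochs = 10L, batchSize = 8L, seed = 1)
  res <- sweepDeep("lstm", ds, cells = c(8L, 4L), plan = plan,
                   config = cfg)
  expect_identical(nrow(res), 4L)
  expect_setequal(unique(res$value), c(8, 4))
  expect_true(attr(res, "best") %in% c(8, 4))
  expect_identical(nrow(attr(res, "summary")), 2L)
  expect_error(sweepDeep("lstm", ds, plan = plan, config = cfg),
               "exactly one")
})
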