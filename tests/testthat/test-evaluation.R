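probsFor <- function(pred, lev, conf = 0.9) {
  P <- matrix((1 - conf) / (length(lev) - 1), length(pred), length(lev),
              dimnames = list(NULL, lev))
  for (i in seq_along(pred)) P[i, pred[i]] <- conf
  P
}

test_that("macro-F1 matches hand-computed confusion-matrix examples", {
  lev <- c("a", "b")
  # perfect
  expect_equal(macroF1(c("a", "a", "b"), probsFor(c("a", "a", "b"), lev)),
               1)
  # confusion [[2,0],[1,1]]: F1 = 0.8 and 2/3 -> macro 0.7333
  y <- c("a", "a", "b", "b")
  p <- c("a", "a", "a", "b")
  expect_equal(macroF1(y, probsFor(p, lev)), (0.8 + 2 / 3) / 2,
               tolerance = 1e-9)
  expect_equal(macroF1(y, probsFor(p, lev)),
               bruteMacroF1(matrix(c(2, 0, 1, 1), 2, byrow = TRUE)),
               tolerance = 1e-9)
  # all-one-class predictor on balanced two-class data -> 1/3
  expect_equal(macroF1(c("a", "b", "a", "b"),
                       probsFor(rep("a", 4), lev)), 1 / 3,
               tolerance = 1e-9)
  expect_error(macroF1(c("a", "z"), probsFor(c("a", "a"), lev)),
               "outside")
})

test_that("macro-F1 is invariant to class and scan permutations", {
  set.seed(21)
  lev <- c("a", "b", "c", "d")
  for (i in 1:15) {
    y <- sample(lev, 30, replace = TRUE)
    P <- matrix(runif(30 * 4), 30, 4, dimnames = list(NULL, lev))
    P <- P / rowSums(P)
    base <- macroF1(y, P)
    sh <- sample(30)
    expect_equal(macroF1(y[sh], P[sh, ]), base, tolerance = 1e-12)
    pc <- sample(4)
    expect_equal(macroF1(y, P[, pc]), base, tolerance = 1e-12)
  }
})

test_that("ROC-AUC reproduces the pairwise-comparison probability", {
  lev <- c("neg", "pos")
  mk <- function(scores) cbind(neg = 1 - scores, pos = scores)
  y <- c("pos", "neg", "pos", "neg")
  expect_equal(rocAuc(y, mk(c(0.9, 0.8, 0.4, 0.2)), "per_class")[["pos"]],
               0.75)
  # perfectly separating and anti-correlated scores
  expect_equal(rocAuc(c("pos", "neg"), mk(c(0.9, 0.1)),
                      "per_class")[["pos"]], 1)
  expect_equal(rocAuc(c("pos", "neg"), mk(c(0.1, 0.9)),
                      "per_class")[["pos"]], 0)
  # oracle equivalence on random binary instances of <= 12 scans incl ties
  set.seed(77)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    y <- c("pos", "neg", sample(lev, n - 2, replace = TRUE))
    s <- sample(seq(0, 1, 0.125), n, replace = TRUE)
    expect_equal(rocAuc(y, mk(s), "per_class")[["pos"]],
                 bruteAuc(s, y == "pos"),
                 label = sprintf("instance %d", i))
  }
})

test_that("ROC-AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  for (i in 1:10) {
    y <- sample(c("pos", "neg"), 40, replace = TRUE)
    y[1:2] <- c("pos", "neg")
    s <- round(runif(40), 2)
    ours <- rocAuc(y, cbind(neg = 1 - s, pos = s), "per_class")[["pos"]]
    ref <- as.numeric(pROC::auc(pROC::roc(y == "pos", s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("micro pooling and macro averaging treat classes as documented", {
  lev <- c("a", "b", "c")
  y <- c("a", "a", "b", "b")      # class c has no positives
  P <- probsFor(c("a", "a", "b", "a"), lev)
  expect_warning(m <- rocAuc(y, P, "macro"), "excluded")
  pc <- rocAuc(y, P, "per_class")
  expect_true(is.na(pc[["c"]]))
  expect_equal(m, mean(pc, na.rm = TRUE))
  micro <- rocAuc(y, P, "micro")
  expect_equal(micro, bruteAuc(as.vector(P),
                               as.vector(outer(y, lev, `==`))))
})

test_that("repeated evaluation aggregates per-repeat scores reproducibly", {
  ds <- toyDataset(10L, noise = 0.1)
  plan <- SplitPlan(0.7, 4L, seed = 5L)
  a <- repeatedEval("lda", ds, plan)
  b <- repeatedEval("lda", ds, plan)
  expect_identical(a@perRepeat, b@perRepeat)
  expect_identical(nrow(a@perRepeat), 4L)
  agg <- aggregateEval(a)
  expect_equal(agg$median[agg$metric == "macroF1"],
               median(a@perRepeat$macroF1))
  expect_equal(agg$IQR[agg$metric == "aucMicro"],
               unname(diff(quantile(a@perRepeat$aucMicro, c(0.25, 0.75)))))
  # confusion row sums equal pooled per-class test counts
  expect_equal(sum(a@confusion), 4 * nScans(ds) * 0.3)
  # constant sequence -> IQR 0
  aa <- a
  aa@perRepeat$macroF1 <- rep(0.5, 4)
  agg2 <- aggregateEval(aa)
  expect_identical(agg2$IQR[agg2$metric == "macroF1"], 0)
})

test_that("paired model comparison follows the signed-rank convention", {
  expect_message(p <- compareModels(rep(0.7, 10), rep(0.7, 10)), "tied")
  expect_identical(p, 1)
  expect_lt(compareModels(rep(0.9, 10), rep(0.5, 10)), 0.05)
  expect_error(compareModels(1:3 / 10, 1:4 / 10), "length")
})

test_that("holdout reports tally correctness per scan", {
  ds <- toyDataset(8L, noise = 0.05)
  fit <- fitLDA(ds)
  rep_ <- holdoutPredict(fit, ds)
  expect_identical(nrow(rep_@probs), nScans(ds))
  expect_equal(rowSums(rep_@probs), rep(1, nScans(ds)), tolerance = 1e-9)
  expect_gte(rep_@nCorrect, nScans(ds) - 1L)
  g <- toyGrid()
  other <- ScanSet(matrix(rnorm(64 * 2), 64, 2), c("z", "z"), g)
  expect_error(holdoutPredict(fit, other), "outside")
})
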