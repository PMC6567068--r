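test_that("the seawater library carries the published class structure", {
  spec <- seawaterLibrarySpec()
  cnt <- cswv:::.specClassCounts(spec)
  expect_identical(
    cnt[c("DQ", "MeP", "PQ", "Cd", "Cu", "Hg", "Pb", "HMM", "BPA", "NP",
          "SW")],
    c(DQ = 14L, MeP = 50L, PQ = 8L, Cd = 36L, Cu = 23L, Hg = 22L,
      Pb = 38L, HMM = 68L, BPA = 4L, NP = 34L, SW = 80L))
  expect_identical(sum(cnt), 377L)
  nm <- vapply(spec@classes, function(cl) cl@name, "")
  # Hg: one anodic stripping peak at 0.06 V
  hg <- spec@classes[[which(nm == "Hg")]]
  expect_length(hg@peaks, 1L)
  expect_equal(hg@peaks[[1]]@ep, 0.06)
  expect_identical(hg@peaks[[1]]@branch, "anodic")
  # blank seawater: background only
  sw <- spec@classes[[which(nm == "SW")]]
  expect_length(sw@peaks, 0L)
  expect_true(sw@includeOxygenBackground)
  # heavy-metal mixture: exactly the Cd, Hg and Pb stripping peaks
  hmm <- spec@classes[[which(nm == "HMM")]]
  expect_setequal(vapply(hmm@peaks, function(p) p@ep, 1.0),
                  c(-0.78, 0.06, -0.58))
  expect_true(all(vapply(hmm@peaks, function(p) p@branch, "") == "anodic"))
})

test_that("collapsing to the 4-class grouping preserves counts", {
  spec4 <- collapseTo4SW(seawaterLibrarySpec())
  cnt <- cswv:::.specClassCounts(spec4)
  expect_identical(cnt, c(HM = 187L, Ind = 38L, HandP = 72L, SW = 80L))
  expect_identical(sum(cnt),
                   sum(cswv:::.specClassCounts(seawaterLibrarySpec())))
  expect_identical(spec4@scheme, "4-SW")
  expect_error(collapseTo4SW(toyLibrary()), "unknown class")
})

test_that("generated datasets are standardized and deterministic", {
  spec <- seawaterLibrarySpec(scale = 0.1)
  ds1 <- generateDataset(spec, seed = 11)
  ds2 <- generateDataset(spec, seed = 11)
  ds3 <- generateDataset(spec, seed = 12)
  expect_identical(currents(ds1), currents(ds2))
  expect_false(identical(currents(ds1), currents(ds3)))
  expect_lt(abs(mean(currents(ds1))), 0.05)
  expect_lt(abs(sd(as.vector(currents(ds1))) - 1), 0.05)
})

test_that("class peaks land at their programmed grid indices", {
  ds <- generateDataset(seawaterLibrarySpec(scale = 0.3), seed = 2)
  g <- potentialGrid(ds)
  anodic <- which(g@branch == "anodic")
  cathodic <- which(g@branch == "cathodic")
  singles <- list(Hg = 0.06, Cu = -0.20, Pb = -0.58, Cd = -0.78)
  for (cl in names(singles)) {
    m <- classMeanTrace(ds, cl)
    got <- anodic[which.max(m[anodic])] - 1L
    expect_equal(got, as.numeric(indexOf(g, singles[[cl]], "anodic")),
                 tolerance = 2.5, label = paste("argmax for", cl))
  }
  # MeP: cathodic reduction peak rides the oxygen shoulder
  mep <- classMeanTrace(ds, "MeP")
  sw <- classMeanTrace(ds, "SW")
  diffTrace <- mep - sw
  got <- cathodic[which.min(diffTrace[cathodic])] - 1L
  expect_equal(got, as.numeric(indexOf(g, -0.71, "cathodic")),
               tolerance = 2.5)
  # blank seawater: cathodic minimum at the oxygen-reduction background
  swMin <- cathodic[which.min(sw[cathodic])] - 1L
  expect_true(swMin >= 450 && swMin <= 500)
})

test_that("peak magnitude grows with the concentration proxy", {
  base <- list(scheme = "custom", grid = toyGrid(), noise_sigma = 1e-9,
               classes = list(list(name = "a", n = 4L,
                                   peaks = list(list(ep = 0.4,
                                                     branch = "anodic",
                                                     width = 0.12)))))
  peakHeight <- function(conc) {
    spec <- genericLibrarySpec(base)
    spec@classes[[1]]@concentrationRange <- c(conc, conc + 1e-9)
    ds <- generateDataset(spec, seed = 5)
    g <- potentialGrid(ds)
    an <- which(g@branch == "anodic")
    m <- classMeanTrace(ds, "a")
    max(m[an]) - median(m[an])
  }
  h <- vapply(c(100, 400, 1600), peakHeight, 1.0)
  expect_true(all(diff(h) > 0))
})

test_that("classes stay separable as noise vanishes", {
  spec <- seawaterLibrarySpec(scale = 0.05, noiseSigma = 1e-6)
  ds <- generateDataset(spec, seed = 4)
  lev <- classNames(ds)
  means <- vapply(lev, function(cl) classMeanTrace(ds, cl),
                  numeric(nrow(currents(ds))))
  d <- as.matrix(dist(t(means)))
  diag(d) <- Inf
  expect_gt(min(d), 0.1)
})

test_that("generic and explosive-like layouts follow their structure", {
  e3 <- explosivesLibrarySpec("3-EXP")
  expect_identical(cswv:::.specClassCounts(e3),
                   c(A = 36L, B = 24L, C = 6L))
  e11 <- explosivesLibrarySpec("11-EXP")
  cnt <- cswv:::.specClassCounts(e11)
  expect_length(cnt, 11L)
  expect_true(all(cnt == 6L))
  expect_identical(sum(cnt), 66L)
  expect_error(genericLibrarySpec(list(scheme = "x", classes = list())),
               "no classes")
  expect_error(genericLibrarySpec(list(
    scheme = "x", grid = toyGrid(),
    classes = list(list(name = "a", n = 2L,
                        peaks = list(list(ep = 5, branch = "anodic")))))),
    "outside")
})
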