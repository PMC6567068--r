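#' @rdname LibrarySpec
#' @export
PeakSpec <- function(ep, branch, widthSigma = 0.03, amplitudeScale = 1,
                     sign = if (branch == "anodic") 1 else -1,
                     reverseFraction = 0) {
  new("PeakSpec", ep = ep, branch = match.arg(branch,
      c("cathodic", "anodic")), widthSigma = widthSigma,
      amplitudeScale = amplitudeScale, sign = sign,
      reverseFraction = reverseFraction)
}

#' @rdname LibrarySpec
#' @export
ClassSpec <- function(name, peaks = list(), includeOxygenBackground = TRUE,
                      nSamples, concentrationRange = c(50, 2000)) {
  new("ClassSpec", name = name, peaks = peaks,
      includeOxygenBackground = includeOxygenBackground,
      nSamples = as.integer(nSamples),
      concentrationRange = concentrationRange)
}

#' Synthetic scan-library specifications
#'
#' `LibrarySpec` assembles class signatures ([PeakSpec()], [ClassSpec()])
#' with the shared grid and the noise/baseline model used by
#' [generateDataset()]. `seawaterLibrarySpec()` returns the 11-class
#' chemicals-in-seawater library: diquat (DQ), methyl parathion (MeP),
#' paraquat (PQ), Cd, Cu, Hg, Pb, a Cd+Hg+Pb heavy-metal mixture (HMM),
#' bisphenol-A (BPA), nonylphenol (NP) and blank seawater (SW), with the
#' anodic stripping peaks at 0.06 V (Hg), -0.20 V (Cu), -0.58 V (Pb) and
#' -0.78 V (Cd), the printed herbicide/phenol peak table, an oxygen-reduction
#' background near -0.9 V on the cathodic branch, and the published per-class
#' scan counts (DQ 14, MeP 50, PQ 8, Cd 36, Cu 23, Hg 22, Pb 38, HMM 68,
#' BPA 4, NP 34, SW 80; 377 scans in total).
#'
#' @param scheme label-scheme name.
#' @param classes list of [ClassSpec()] objects.
#' @param grid shared [PotentialGrid-class].
#' @param noiseSigma additive white-noise standard deviation
#'   (post-standardization units).
#' @param baselineSlopeSd standard deviation of the random linear drift slope
#'   (units per point).
#' @param baselineInterceptSd standard deviation of the random offset.
#' @param oxygen oxygen-reduction background model: Gaussian `center` (V),
#'   `sigma` (V), `amplitude`, relative amplitude `jitter`, and the fraction
#'   `reverseFraction` carried onto the anodic branch.
#' @param background shared potential-dependent (non-faradaic) background:
#'   `charging` is the double-layer charging current magnitude, whose sign
#'   follows the sweep direction (positive on the anodic branch);
#'   `curvature` scales a capacitive term quadratic in potential; `window`
#'   and `tau` shape the exponential solvent-window rise at the potential
#'   limits; `jitter` is the relative per-scan amplitude jitter of all
#'   three terms.
#' @param amplitudeRef peak current of a full-concentration unit-scale peak.
#' @param scale optional down-scaling factor for the per-class counts
#'   (counts are rounded with a floor of 4 scans per class); the default 1
#'   reproduces the published library size.
#' @return a [LibrarySpec-class].
#' @export
LibrarySpec <- function(scheme, classes, grid = seawaterGrid(),
                        noiseSigma = 0.05, baselineSlopeSd = 1e-4,
                        baselineInterceptSd = 0.05,
                        oxygen = list(center = -0.9, sigma = 0.08,
                                      amplitude = 1, jitter = 0.2,
                                      reverseFraction = 0.3),
                        background = list(charging = 0.15,
                                          curvature = 0.25, window = 0.3,
                                          tau = 0.05, jitter = 0.1),
                        amplitudeRef = 10) {
  nm <- vapply(classes, function(cl) cl@name, "")
  if (anyDuplicated(nm)) stop("class names must be unique")
  new("LibrarySpec", scheme = scheme, classes = classes, grid = grid,
      noiseSigma = noiseSigma, baselineSlopeSd = baselineSlopeSd,
      baselineInterceptSd = baselineInterceptSd, oxygen = oxygen,
      background = background, amplitudeRef = amplitudeRef)
}

.metalPeaks <- list(
  Cd = -0.78, Hg = 0.06, Pb = -0.58)

.seawaterCounts <- c(DQ = 14L, MeP = 50L, PQ = 8L, Cd = 36L, Cu = 23L,
                     Hg = 22L, Pb = 38L, HMM = 68L, BPA = 4L, NP = 34L,
                     SW = 80L)

#' @rdname LibrarySpec
#' @export
seawaterLibrarySpec <- function(scale = 1, noiseSigma = 0.05,
                                grid = seawaterGrid()) {
  n <- .seawaterCounts
  if (scale != 1)
    n <- setNames(pmax(4L, as.integer(round(n * scale))), names(n))
  # two-electron metal strippings are narrower than the 30 mV default
  # (SWV half-widths ~45-50 mV for n = 2)
  strip <- function(ep) list(PeakSpec(ep, "anodic", widthSigma = 0.02))
  metals <- lapply(.metalPeaks, strip)
  herb <- function(epc, epa) list(
    PeakSpec(epc, "cathodic"),
    PeakSpec(epa, "anodic", widthSigma = 0.05, amplitudeScale = 0.4))
  phenol <- function(epc, epa1, epa2) list(
    PeakSpec(epc, "cathodic"),
    PeakSpec(epa1, "anodic"),
    PeakSpec(epa2, "anodic"))
  classes <- list(
    ClassSpec("DQ", herb(-0.52, -0.56), nSamples = n["DQ"]),
    ClassSpec("MeP", list(PeakSpec(-0.71, "cathodic",
                                   reverseFraction = 0.3)),
              nSamples = n["MeP"]),
    ClassSpec("PQ", herb(-0.51, -0.55), nSamples = n["PQ"]),
    ClassSpec("Cd", metals$Cd, nSamples = n["Cd"]),
    ClassSpec("Cu", strip(-0.20), nSamples = n["Cu"]),
    ClassSpec("Hg", metals$Hg, nSamples = n["Hg"]),
    ClassSpec("Pb", metals$Pb, nSamples = n["Pb"]),
    ClassSpec("HMM", c(metals$Cd, metals$Hg, metals$Pb),
              nSamples = n["HMM"]),
    ClassSpec("BPA", phenol(0.036, 0.044, 0.41), nSamples = n["BPA"]),
    ClassSpec("NP", phenol(0.016, 0.041, 0.48), nSamples = n["NP"]),
    ClassSpec("SW", list(), nSamples = n["SW"]))
  LibrarySpec("11-SW", classes, grid = grid, noiseSigma = noiseSigma)
}

.groups4SW <- list(
  HM = c("Cd", "Cu", "Hg", "Pb", "HMM"),
  Ind = c("BPA", "NP"),
  HandP = c("DQ", "PQ", "MeP"),
  SW = "SW")

#' Collapse the 11-class seawater library to the 4-class grouping
#'
#' Relabels the heavy metals (Cd, Cu, Hg, Pb and the mixture) as HM, the
#' industrial phenols (BPA, NP) as Ind, the herbicides/pesticide (DQ, PQ,
#' MeP) as HandP and keeps SW, preserving every class signature and count
#' (187/38/72/80 at full scale).
#'
#' @param spec the 11-class seawater [LibrarySpec-class].
#' @return the 4-class [LibrarySpec-class].
#' @export
collapseTo4SW <- function(spec) {
  stopifnot(is(spec, "LibrarySpec"))
  nm <- vapply(spec@classes, function(cl) cl@name, "")
  bad <- setdiff(nm, unlist(.groups4SW))
  if (length(bad)) stop("unknown class name: ", paste(bad, collapse = ", "))
  classes <- list()
  for (gname in names(.groups4SW)) {
    members <- spec@classes[nm %in% .groups4SW[[gname]]]
    if (!length(members)) next
    classes <- c(classes, lapply(members, function(cl) {
      cl@name <- gname
      cl
    }))
  }
  out <- spec
  out@scheme <- "4-SW"
  out@classes <- classes
  validObject(out)
  out
}

.specClassNames <- function(spec) {
  unique(vapply(spec@classes, function(cl) cl@name, ""))
}

.specClassCounts <- function(spec) {
  nm <- vapply(spec@classes, function(cl) cl@name, "")
  n <- vapply(spec@classes, function(cl) cl@nSamples, 1L)
  vapply(split(n, factor(nm, levels = unique(nm))), sum, 1L)
}

#' Build a library specification from a plain configuration list
#'
#' Supports arbitrary grids and class layouts, e.g. the 3-class explosive
#' structure (36/24/6 scans) or an 11-class layout with six scans per class.
#' Each class entry is a list with `name`, `n`, an optional concentration
#' range `conc`, and a list of `peaks` (each `ep`, `branch`, optional
#' `width`, `scale`, `sign`, `reverse`).
#'
#' @param config list with elements `scheme`, `classes` and optionally
#'   `grid` (a [PotentialGrid-class]), `noise_sigma`, `oxygen_background`
#'   (logical, default `FALSE` for non-seawater matrices).
#' @return a [LibrarySpec-class].
#' @export
genericLibrarySpec <- function(config) {
  if (is.null(config$classes) || !length(config$classes))
    stop("config lists no classes")
  grid <- if (is.null(config$grid)) seawaterGrid() else config$grid
  oxy <- isTRUE(config$oxygen_background)
  classes <- lapply(config$classes, function(cl) {
    peaks <- lapply(cl$peaks, function(p) {
      PeakSpec(p$ep, p$branch,
               widthSigma = if (is.null(p$width)) 0.03 else p$width,
               amplitudeScale = if (is.null(p$scale)) 1 else p$scale,
               sign = if (is.null(p$sign)) {
                 if (p$branch == "anodic") 1 else -1
               } else p$sign,
               reverseFraction = if (is.null(p$reverse)) 0 else p$reverse)
    })
    ClassSpec(cl$name, peaks, includeOxygenBackground = oxy,
              nSamples = cl$n,
              concentrationRange = if (is.null(cl$conc)) c(50, 2000)
                                   else cl$conc)
  })
  spec <- LibrarySpec(
    if (is.null(config$scheme)) "custom" else config$scheme,
    classes, grid = grid,
    noiseSigma = if (is.null(config$noise_sigma)) 0.05
                 else config$noise_sigma)
  for (cl in spec@classes) .checkPeaksOnGrid(cl, grid)
  spec
}

.checkPeaksOnGrid <- function(cl, grid) {
  for (p in cl@peaks) {
    rng <- range(grid@potentials[grid@branch == p@branch])
    if (p@ep < rng[1] || p@ep > rng[2])
      stop("peak at ", p@ep, " V outside the ", p@branch,
           " range of the grid (class ", cl@name, ")")
  }
  invisible(TRUE)
}

#' Generic explosive-like library layouts
#'
#' A synthetic stand-in emulating the *structure* of the explosive libraries
#' (3 classes with 36/24/6 scans, or 11 classes with 6 scans each) with
#' nitro-reduction-like cathodic peaks on the default grid; the real
#' explosive potential window is not reconstructed.
#'
#' @param scheme `"3-EXP"` or `"11-EXP"`.
#' @return a [LibrarySpec-class].
#' @export
explosivesLibrarySpec <- function(scheme = c("3-EXP", "11-EXP")) {
  scheme <- match.arg(scheme)
  peak <- function(ep, reverse = 0.3)
    list(ep = ep, branch = "cathodic", reverse = reverse)
  if (scheme == "3-EXP") {
    classes <- list(
      list(name = "A", n = 36, peaks = list(peak(-0.45), peak(-0.62),
                                            peak(-0.80))),
      list(name = "B", n = 24, peaks = list(peak(-0.55), peak(-0.75))),
      list(name = "C", n = 6, peaks = list()))
  } else {
    eps <- seq(-0.25, -0.85, length.out = 10)
    classes <- c(lapply(seq_along(eps), function(i)
      list(name = sprintf("E%02d", i), n = 6,
           peaks = list(peak(eps[i]),
                        peak(eps[i] - 0.12)))),
      list(list(name = "buffer", n = 6, peaks = list())))
  }
  genericLibrarySpec(list(scheme = scheme, classes = classes,
                          oxygen_background = FALSE))
}

setMethod("show", "LibrarySpec", function(object) {
  cnt <- .specClassCounts(object)
  cat("LibrarySpec:", object@scheme, "-", length(cnt), "classes,",
      sum(cnt), "scans\n")
  cat(" ", paste0(names(cnt), " (", cnt, ")", collapse = ", "), "\n")
})
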