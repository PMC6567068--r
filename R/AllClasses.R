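#' @import methods
#' @importFrom stats approx median prcomp predict quantile rnorm runif sd
#'   setNames var wilcox.test
#' @importFrom utils read.csv write.csv str
NULL

#' PotentialGrid: index/potential convention of a concatenated CSWV trace
#'
#' Maps sample index to applied potential for a cathodic-then-anodic
#' concatenated cyclic square-wave voltammetry (CSWV) trace. Sample indices
#' follow the field convention and are 0-based, so that the printed anchor
#' indices of the seawater library (e.g. index 770 at 0.072 V) apply
#' directly.
#'
#' @slot potentials numeric vector of applied potentials (V vs. Ag/AgCl),
#'   one per sample point, cathodic branch first.
#' @slot branch character vector, `"cathodic"` or `"anodic"` per point.
#' @slot step potential increment magnitude in V between neighbouring points.
#' @export
setClass("PotentialGrid",
  representation(potentials = "numeric", branch = "character",
                 step = "numeric"))

setValidity("PotentialGrid", function(object) {
  p <- object@potentials
  b <- object@branch
  if (length(p) != length(b)) return("potentials and branch differ in length")
  if (!all(b %in% c("cathodic", "anodic"))) return("unknown branch label")
  if (is.unsorted(match(b, c("cathodic", "anodic"))))
    return("cathodic points must precede anodic points")
  ca <- p[b == "cathodic"]
  an <- p[b == "anodic"]
  if (length(ca) > 1 && any(diff(ca) >= 0))
    return("cathodic potentials must be strictly decreasing")
  if (length(an) > 1 && any(diff(an) <= 0))
    return("anodic potentials must be strictly increasing")
  TRUE
})

#' ScanSet: a labeled library of CSWV scans
#'
#' A [SummarizedExperiment::SummarizedExperiment]-derived container holding
#' one concatenated cathodic+anodic current trace per scan (assay
#' `"currents"`, points in rows, scans in columns), per-scan metadata
#' (`label`, `concentration_proxy`, `sample_id` in `colData`) and the shared
#' [PotentialGrid-class] plus label scheme in `metadata()`.
#'
#' @export
setClass("ScanSet", contains = "SummarizedExperiment")

#' Voltammogram: one labeled scan
#'
#' @slot currents standardized current values, one per grid point.
#' @slot label class name.
#' @slot concentrationProxy ppb-scale concentration proxy (`NA` if absent).
#' @slot sampleId scan identifier.
#' @slot grid the [PotentialGrid-class] the currents are sampled on.
#' @export
setClass("Voltammogram",
  representation(currents = "numeric", label = "character",
                 concentrationProxy = "numeric", sampleId = "character",
                 grid = "PotentialGrid"))

setValidity("Voltammogram", function(object) {
  if (length(object@currents) != length(object@grid@potentials))
    return("currents length does not match grid")
  if (!all(is.finite(object@currents))) return("non-finite current values")
  TRUE
})

#' PeakSpec: one faradaic peak of a class signature
#'
#' @slot ep peak potential in V vs. Ag/AgCl.
#' @slot branch `"cathodic"` or `"anodic"`.
#' @slot widthSigma Gaussian standard deviation in V.
#' @slot amplitudeScale relative height (dimensionless).
#' @slot sign +1 for anodic (oxidation) current, -1 for cathodic (reduction).
#' @slot reverseFraction fraction of the peak mirrored at the same potential
#'   on the opposite branch; nonzero for irreversible reductions whose net
#'   square-wave current also responds on the reverse half-sweep, zero for
#'   one-shot anodic stripping peaks.
#' @export
setClass("PeakSpec",
  representation(ep = "numeric", branch = "character",
                 widthSigma = "numeric", amplitudeScale = "numeric",
                 sign = "numeric", reverseFraction = "numeric"))

setValidity("PeakSpec", function(object) {
  if (object@widthSigma <= 0) return("widthSigma must be positive")
  if (!object@branch %in% c("cathodic", "anodic")) return("unknown branch")
  if (!object@sign %in% c(-1, 1)) return("sign must be -1 or +1")
  if (object@reverseFraction < 0 || object@reverseFraction > 1)
    return("reverseFraction must be in [0, 1]")
  TRUE
})

#' ClassSpec: signature and sampling plan of one library class
#' @export
setClass("ClassSpec",
  representation(name = "character", peaks = "list",
                 includeOxygenBackground = "logical", nSamples = "integer",
                 concentrationRange = "numeric"))

setValidity("ClassSpec", function(object) {
  if (object@nSamples < 1L) return("nSamples must be >= 1")
  if (!all(vapply(object@peaks, is, TRUE, "PeakSpec")))
    return("peaks must be PeakSpec objects")
  if (length(object@concentrationRange) != 2 ||
      any(object@concentrationRange <= 0))
    return("concentrationRange must be two positive values")
  TRUE
})

#' LibrarySpec: a full synthetic scan-library definition
#' @export
setClass("LibrarySpec",
  representation(scheme = "character", classes = "list",
                 grid = "PotentialGrid", noiseSigma = "numeric",
                 baselineSlopeSd = "numeric", baselineInterceptSd = "numeric",
                 oxygen = "list", background = "list",
                 amplitudeRef = "numeric"))

# A label may be carried by several ClassSpec entries (signature
# subpopulations of one class, as in the collapsed 4-class seawater
# grouping); user-facing constructors enforce unique user-declared names.
setValidity("LibrarySpec", function(object) {
  nm <- vapply(object@classes, function(cl) cl@name, "")
  if (any(!nzchar(nm))) return("class names must be non-empty")
  if (!all(vapply(object@classes, is, TRUE, "ClassSpec")))
    return("classes must be ClassSpec objects")
  TRUE
})

#' SplitPlan: repeated stratified shuffle-split plan
#'
#' @slot trainFraction per-class train fraction (0.7 for the seawater and
#'   3-class explosive schemes, 0.5 for the 11-class explosive scheme).
#' @slot nRepeats number of repeated splits (25 for headline comparisons,
#'   5 for refinement sweeps).
#' @slot seed master seed; each repeat derives its own substream.
#' @export
setClass("SplitPlan",
  representation(trainFraction = "numeric", nRepeats = "integer",
                 seed = "integer"))

setValidity("SplitPlan", function(object) {
  if (object@trainFraction <= 0 || object@trainFraction >= 1)
    return("trainFraction must be in (0, 1)")
  if (object@nRepeats < 1L) return("nRepeats must be >= 1")
  TRUE
})

#' Virtual parent of all fitted scan classifiers
#' @export
setClass("CSWVClassifier",
  representation("VIRTUAL", classLevels = "character"))

#' 1-nearest-neighbour DTW classifier (stores its training library)
#' @export
setClass("DTWClassifier", contains = "CSWVClassifier",
  representation(train = "matrix", labels = "character",
                 window = "integer", cost = "character"))

#' PCA projection followed by an RBF support-vector machine
#' @export
setClass("PCASVMClassifier", contains = "CSWVClassifier",
  representation(center = "numeric", rotation = "matrix", fit = "ANY",
                 nComponents = "integer"))

#' Linear discriminant classifier with a capped discriminant embedding
#' @export
setClass("LDAClassifier", contains = "CSWVClassifier",
  representation(center = "numeric", rotation = "matrix", fit = "ANY",
                 nComponents = "integer"))

#' Untrained neural scan classifier (architecture + initialized weights)
#' @export
setClass("DeepModel",
  representation(ptr = "externalptr", kind = "character",
                 inputLength = "integer", nClasses = "integer",
                 cells = "integer", dropout = "numeric"))

#' Trained neural scan classifier
#'
#' Wraps the native network state plus the class order, input grid length and
#' the per-epoch training history (loss, validation accuracy, learning rate).
#' @export
setClass("DeepClassifier", contains = "CSWVClassifier",
  representation(ptr = "externalptr", kind = "character",
                 inputLength = "integer", cells = "integer",
                 history = "data.frame", config = "list"))

#' Per-repeat evaluation table with median/IQR aggregation
#' @export
setClass("EvalSummary",
  representation(kind = "character", scheme = "character",
                 perRepeat = "data.frame", perClassAUC = "data.frame",
                 confusion = "table", failures = "integer"))

#' Holdout prediction report
#' @export
setClass("HoldoutReport",
  representation(probs = "matrix", predicted = "character",
                 truth = "character", nCorrect = "integer",
                 maxSecondChoice = "numeric"))

#' Class activation map for one scan
#'
#' @slot activations activation per grid point, min-max normalized to [0, 1]
#'   (all zero when the raw map is constant).
#' @export
setClass("CAMResult",
  representation(activations = "numeric", targetClass = "character",
                 sampleId = "character", raw = "numeric"))

setValidity("CAMResult", function(object) {
  a <- object@activations
  if (any(a < -1e-8 | a > 1 + 1e-8)) return("activations must lie in [0, 1]")
  TRUE
})
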