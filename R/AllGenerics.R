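#' @rdname potentialAt
#' @export
setGeneric("potentialAt", function(grid, index) standardGeneric("potentialAt"))

#' @rdname indexOf
#' @export
setGeneric("indexOf",
  function(grid, potential, branch) standardGeneric("indexOf"))

#' @rdname ScanSet-accessors
#' @export
setGeneric("currents", function(x) standardGeneric("currents"))

#' @rdname ScanSet-accessors
#' @export
setGeneric("scanLabels", function(x) standardGeneric("scanLabels"))

#' @rdname ScanSet-accessors
#' @export
setGeneric("scheme", function(x) standardGeneric("scheme"))

#' @rdname ScanSet-accessors
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' @rdname ScanSet-accessors
#' @export
setGeneric("potentialGrid", function(x) standardGeneric("potentialGrid"))

#' @rdname truncateScans
#' @export
setGeneric("truncateScans",
  function(x, dropHead = 0L, dropTail = 0L) standardGeneric("truncateScans"))

#' Class-probability prediction
#'
#' All fitted classifiers expose a scans x classes probability matrix whose
#' rows sum to one; `predictLabel` is the corresponding argmax rule except
#' for the 1-NN DTW classifier, where it is the nearest-neighbour rule with
#' earliest-index tie breaking.
#'
#' @param object a fitted classifier.
#' @param newdata a [ScanSet-class] (or currents matrix, scans in rows).
#' @return `predictProb`: numeric matrix (scans x classes); `predictLabel`:
#'   character vector of class names.
#' @export
setGeneric("predictProb",
  function(object, newdata, ...) standardGeneric("predictProb"))

#' @rdname predictProb
#' @export
setGeneric("predictLabel",
  function(object, newdata, ...) standardGeneric("predictLabel"))

#' @rdname computeCAM
#' @export
setGeneric("computeCAM",
  function(object, scan, targetClass = NULL, ...)
    standardGeneric("computeCAM"))
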