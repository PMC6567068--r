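#' Build a ScanSet from a currents matrix and labels
#'
#' @param currents numeric matrix of standardized currents, grid points in
#'   rows and scans in columns.
#' @param labels class label per scan.
#' @param grid shared [PotentialGrid-class].
#' @param scheme label-scheme name (`"4-SW"`, `"11-SW"`, `"3-EXP"`,
#'   `"11-EXP"` or `"custom"`).
#' @param classNames ordered class list; defaults to the labels' order of
#'   first appearance.
#' @param concentrationProxy optional ppb-scale concentration proxy per scan.
#' @param sampleIds optional scan identifiers.
#' @return a [ScanSet-class].
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
#' @export
ScanSet <- function(currents, labels, grid, scheme = "custom",
                    classNames = NULL, concentrationProxy = NULL,
                    sampleIds = NULL) {
  currents <- as.matrix(currents)
  if (nrow(currents) != length(grid@potentials))
    stop("currents rows (", nrow(currents), ") do not match grid points (",
         length(grid@potentials), ")")
  n <- ncol(currents)
  if (length(labels) != n) stop("one label per scan required")
  if (is.null(classNames)) classNames <- unique(as.character(labels))
  if (!all(labels %in% classNames)) stop("label outside the class scheme")
  if (is.null(concentrationProxy)) concentrationProxy <- rep(NA_real_, n)
  if (is.null(sampleIds)) sampleIds <- sprintf("scan_%04d", seq_len(n))
  if (!all(is.finite(currents))) stop("non-finite current values")
  colnames(currents) <- sampleIds
  rownames(currents) <- sprintf("i_%04d", seq_len(nrow(currents)) - 1L)
  se <- SummarizedExperiment(
    assays = list(currents = currents),
    rowData = DataFrame(index = seq_len(nrow(currents)) - 1L,
                        branch = grid@branch, potential = grid@potentials),
    colData = DataFrame(label = factor(as.character(labels),
                                       levels = classNames),
                        concentration_proxy = as.numeric(concentrationProxy),
                        sample_id = sampleIds))
  out <- new("ScanSet", se)
  metadata(out)$grid <- grid
  metadata(out)$scheme <- scheme
  out
}

#' Accessors for ScanSet objects
#'
#' `currents()` returns the points x scans matrix, `scanLabels()` the label
#' factor, `classNames()` the ordered class list, `scheme()` the label-scheme
#' name, `potentialGrid()` the shared grid and `nScans()` the scan count.
#'
#' @param x a [ScanSet-class].
#' @name ScanSet-accessors
NULL

#' @rdname ScanSet-accessors
#' @export
setMethod("currents", "ScanSet",
          function(x) SummarizedExperiment::assay(x, "currents"))

#' @rdname ScanSet-accessors
#' @export
setMethod("scanLabels", "ScanSet", function(x) colData(x)$label)

#' @rdname ScanSet-accessors
#' @export
setMethod("scheme", "ScanSet", function(x) metadata(x)$scheme)

#' @rdname ScanSet-accessors
#' @export
setMethod("classNames", "ScanSet",
          function(x) levels(colData(x)$label))

#' @rdname ScanSet-accessors
#' @export
setMethod("potentialGrid", "ScanSet", function(x) metadata(x)$grid)

#' @rdname ScanSet-accessors
#' @export
nScans <- function(x) ncol(x)

#' Extract one scan as a Voltammogram
#'
#' @param x a [ScanSet-class].
#' @param i scan number (ordinary R 1-based column position).
#' @export
getScan <- function(x, i) {
  stopifnot(i >= 1, i <= ncol(x))
  cd <- colData(x)
  new("Voltammogram", currents = as.numeric(currents(x)[, i]),
      label = as.character(cd$label[i]),
      concentrationProxy = cd$concentration_proxy[i],
      sampleId = cd$sample_id[i], grid = potentialGrid(x))
}

setMethod("show", "ScanSet", function(object) {
  tab <- table(scanLabels(object))
  cat("ScanSet:", ncol(object), "scans x", nrow(object), "points, scheme",
      scheme(object), "\n")
  cat("  classes:", paste0(names(tab), " (", as.integer(tab), ")",
                           collapse = ", "), "\n")
})

#' Truncate every trace of a dataset (and its grid) by index
#'
#' Keeps indices `[dropHead, nPoints - dropTail)` of every scan, slicing the
#' grid consistently and leaving labels untouched. Dropping the first 502 and
#' last 100 points of a default 1002-point seawater trace keeps exactly the
#' anodic indices 502..901 and yields 400-point traces, the CAM-guided
#' reduced dataset.
#'
#' @param x a [ScanSet-class] or [PotentialGrid-class].
#' @param dropHead,dropTail number of points removed from the head/tail.
#' @export
setMethod("truncateScans", "ScanSet", function(x, dropHead = 0L,
                                               dropTail = 0L) {
  g <- truncateScans(potentialGrid(x), dropHead, dropTail)
  n <- nrow(x)
  keep <- seq.int(as.integer(dropHead) + 1L, n - as.integer(dropTail))
  cd <- colData(x)
  ScanSet(currents(x)[keep, , drop = FALSE], as.character(cd$label), g,
          scheme = scheme(x), classNames = classNames(x),
          concentrationProxy = cd$concentration_proxy,
          sampleIds = cd$sample_id)
})

#' Subset a ScanSet by scan position
#'
#' @param x a [ScanSet-class].
#' @param scans integer or logical index of scans to keep.
#' @export
subsetScans <- function(x, scans) {
  cd <- colData(x)
  ScanSet(currents(x)[, scans, drop = FALSE],
          as.character(cd$label)[scans], potentialGrid(x),
          scheme = scheme(x), classNames = classNames(x),
          concentrationProxy = cd$concentration_proxy[scans],
          sampleIds = cd$sample_id[scans])
}

#' Read and write scan-library CSV files
#'
#' One row per scan with header columns `sample_id`, `label`,
#' `concentration_proxy` followed by the per-point currents `i_0000`,
#' `i_0001`, ... `write` followed by `read` is the identity up to floating
#' point round-trip; class order is preserved through `classNames`.
#'
#' @param path CSV file path.
#' @param grid the [PotentialGrid-class] the currents are sampled on.
#' @param scheme,classNames label scheme of the stored library.
#' @return `readScans`: a [ScanSet-class].
#' @export
readScans <- function(path, grid = seawaterGrid(), scheme = "custom",
                      classNames = NULL) {
  emptySet <- function() {
    ScanSet(matrix(numeric(), nrow = length(grid@potentials), ncol = 0),
            character(), grid, scheme = scheme,
            classNames = if (is.null(classNames)) character()
                         else classNames)
  }
  if (file.size(path) == 0) return(emptySet())
  df <- read.csv(path, check.names = FALSE, colClasses = NA)
  fixed <- c("sample_id", "label", "concentration_proxy")
  if (nrow(df) == 0) {
    return(ScanSet(matrix(numeric(), nrow = length(grid@potentials),
                          ncol = 0),
                   character(), grid, scheme = scheme,
                   classNames = if (is.null(classNames)) character()
                                else classNames))
  }
  if (!all(fixed %in% names(df))) stop("malformed scan CSV header")
  cur <- as.matrix(df[, setdiff(names(df), fixed), drop = FALSE])
  if (ncol(cur) != length(grid@potentials))
    stop("row current count (", ncol(cur), ") does not match grid (",
         length(grid@potentials), ")")
  if (!is.numeric(cur)) stop("non-numeric current value")
  ScanSet(t(cur), df$label, grid, scheme = scheme, classNames = classNames,
          concentrationProxy = df$concentration_proxy,
          sampleIds = df$sample_id)
}

#' @rdname readScans
#' @param x a [ScanSet-class] to write.
#' @export
writeScans <- function(x, path) {
  cd <- colData(x)
  cur <- t(currents(x))
  colnames(cur) <- sprintf("i_%04d", seq_len(ncol(cur)) - 1L)
  df <- data.frame(sample_id = cd$sample_id,
                   label = as.character(cd$label),
                   concentration_proxy = cd$concentration_proxy,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(cur))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
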