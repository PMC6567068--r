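.asTraceMatrix <- function(x) {
  if (is(x, "ScanSet")) return(t(currents(x)))
  if (is(x, "Voltammogram")) return(matrix(x@currents, nrow = 1))
  if (is.numeric(x) && is.null(dim(x))) return(matrix(x, nrow = 1))
  as.matrix(x)
}

#' Dynamic time warping distance with a Sakoe-Chiba band
#'
#' Dynamic-programming recurrence
#' `D(i,j) = cost(a_i, b_j) + min(D(i-1,j), D(i,j-1), D(i-1,j-1))`
#' restricted to the band `|i - j| <= window`. With `window = 0` the band
#' collapses to the diagonal and the distance degenerates to the pointwise
#' L1 (or squared-L2) distance. Symmetric, nonnegative and zero iff the
#' traces are identical (absolute cost).
#'
#' @param a,b numeric traces (equal length in the classification pipeline,
#'   but unequal lengths are handled: the band is widened to the length
#'   difference when needed).
#' @param window band half-width in samples (default 10, the value used for
#'   the scan libraries).
#' @param cost local cost, `"absolute"` or `"squared"`.
#' @examples
#' dtwDistance(c(0, 1, 2), c(0, 2, 2))   # 1
#' @export
dtwDistance <- function(a, b, window = 10L, cost = c("absolute",
                                                     "squared")) {
  cost <- match.arg(cost)
  if (!length(a) || !length(b)) stop("empty trace")
  if (window < 0L) stop("window must be >= 0")
  dtw_cost(as.numeric(a), as.numeric(b), as.integer(window),
           cost == "squared")
}

#' Fit (store) a 1-nearest-neighbour DTW classifier
#'
#' @param train training [ScanSet-class].
#' @param window Sakoe-Chiba band half-width in samples.
#' @param cost local cost of [dtwDistance()].
#' @return a [DTWClassifier-class].
#' @export
fitDTW <- function(train, window = 10L, cost = "absolute") {
  stopifnot(nScans(train) >= 1L)
  new("DTWClassifier", train = .asTraceMatrix(train),
      labels = as.character(scanLabels(train)),
      classLevels = classNames(train), window = as.integer(window),
      cost = cost)
}

#' Nearest-neighbour label under DTW distance
#'
#' Returns the label of the training scan minimizing the banded DTW
#' distance; ties are broken in favour of the earliest training index.
#'
#' @param object a [DTWClassifier-class] (or a training [ScanSet-class]).
#' @param query a [Voltammogram-class], numeric trace, or [ScanSet-class].
#' @param ... `window`/`cost` when `object` is a ScanSet.
#' @export
knn1DtwPredict <- function(object, query, ...) {
  if (is(object, "ScanSet")) object <- fitDTW(object, ...)
  predictLabel(object, query)
}

setMethod("predictLabel", "DTWClassifier", function(object, newdata, ...) {
  Q <- .asTraceMatrix(newdata)
  D <- dtw_cross(Q, object@train, object@window,
                 object@cost == "squared")
  object@labels[apply(D, 1, which.min)]
})

setMethod("predictProb", "DTWClassifier", function(object, newdata, ...) {
  Q <- .asTraceMatrix(newdata)
  D <- dtw_cross(Q, object@train, object@window,
                 object@cost == "squared")
  lev <- object@classLevels
  # per-class nearest distance, softmax-scored for ranking purposes
  P <- matrix(0, nrow(Q), length(lev), dimnames = list(NULL, lev))
  for (i in seq_len(nrow(Q))) {
    d <- vapply(lev, function(cl) {
      sel <- object@labels == cl
      if (any(sel)) min(D[i, sel]) else Inf
    }, 1.0)
    s <- median(d[is.finite(d)])
    if (!is.finite(s) || s <= 0) s <- 1
    e <- exp(-(d - min(d)) / s)
    P[i, ] <- e / sum(e)
  }
  P
})

#' Fit a PCA-SVM scan classifier
#'
#' Projects the traces onto the leading principal components and trains an
#' RBF support-vector machine with pairwise-coupled class probabilities on
#' the scores.
#'
#' @param train training [ScanSet-class] with at least 2 classes.
#' @param nComponents number of principal components (default 3).
#' @return a [PCASVMClassifier-class].
#' @export
fitPCASVM <- function(train, nComponents = 3L) {
  X <- .asTraceMatrix(train)
  lab <- droplevels(scanLabels(train))
  if (nlevels(lab) < 2L) stop("at least 2 classes required")
  if (nrow(X) <= nComponents) stop("fewer scans than components")
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = nComponents)
  fit <- e1071::svm(pc$x, lab, kernel = "radial", probability = TRUE)
  new("PCASVMClassifier", center = pc$center, rotation = pc$rotation,
      fit = fit, nComponents = as.integer(nComponents),
      classLevels = classNames(train))
}

setMethod("predictProb", "PCASVMClassifier", function(object, newdata, ...) {
  X <- .asTraceMatrix(newdata)
  Z <- sweep(X, 2, object@center) %*% object@rotation
  pr <- attr(predict(object@fit, Z, probability = TRUE), "probabilities")
  .alignProbs(pr, object@classLevels)
})

#' Fit a linear discriminant scan classifier
#'
#' The traces are first mapped onto their exact principal-component span
#' (rank-limited so the within-class scatter is invertible), then a linear
#' discriminant model is fit. Classification uses the full discriminant
#' rule; `nComponents` caps the discriminant embedding returned by
#' [ldaEmbedding()] only.
#'
#' @inheritParams fitPCASVM
#' @return an [LDAClassifier-class].
#' @export
fitLDA <- function(train, nComponents = 3L) {
  X <- .asTraceMatrix(train)
  lab <- droplevels(scanLabels(train))
  if (nlevels(lab) < 2L) stop("at least 2 classes required")
  if (nrow(X) <= nComponents) stop("fewer scans than components")
  q <- min(nrow(X) - nlevels(lab), ncol(X), 128L)
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = q)
  keep <- pc$sdev[seq_len(ncol(pc$x))] > 1e-8 * pc$sdev[1]
  fit <- MASS::lda(pc$x[, keep, drop = FALSE], grouping = lab)
  new("LDAClassifier", center = pc$center,
      rotation = pc$rotation[, keep, drop = FALSE], fit = fit,
      nComponents = as.integer(nComponents),
      classLevels = classNames(train))
}

setMethod("predictProb", "LDAClassifier", function(object, newdata, ...) {
  X <- .asTraceMatrix(newdata)
  Z <- sweep(X, 2, object@center) %*% object@rotation
  pr <- predict(object@fit, Z)$posterior
  .alignProbs(pr, object@classLevels)
})

#' Discriminant embedding of scans
#'
#' @param object an [LDAClassifier-class].
#' @param newdata scans to embed.
#' @param k number of discriminant axes (defaults to the fitted component
#'   cap).
#' @export
ldaEmbedding <- function(object, newdata, k = object@nComponents) {
  X <- .asTraceMatrix(newdata)
  Z <- sweep(X, 2, object@center) %*% object@rotation
  emb <- predict(object@fit, Z)$x
  emb[, seq_len(min(k, ncol(emb))), drop = FALSE]
}

# expand a fitted model's probability table to the full class scheme,
# zero-filling classes unseen in training
.alignProbs <- function(pr, classLevels) {
  P <- matrix(0, nrow(pr), length(classLevels),
              dimnames = list(NULL, classLevels))
  P[, colnames(pr)] <- pr[, , drop = FALSE]
  P
}

setMethod("predictLabel", "CSWVClassifier", function(object, newdata, ...) {
  P <- predictProb(object, newdata, ...)
  colnames(P)[apply(P, 1, which.max)]
})
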