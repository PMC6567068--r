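#' Combine final-convolution feature maps into a class activation map
#'
#' Raw map: `CAM(t) = sum_k w_k A_k(t)` over the 128 final-block feature
#' maps, linearly resampled to `outLength` points and min-max normalized to
#' [0, 1]; a constant raw map normalizes to all zeros by convention.
#'
#' @param featureMaps length x 128 matrix of final-convolution activations.
#' @param weights output-layer weight vector attached to the GAP features
#'   of the target class.
#' @param outLength length of the returned map (the input trace length).
#' @return list with `activations` (normalized) and `raw`.
#' @export
camFromFeatures <- function(featureMaps, weights, outLength =
                              nrow(featureMaps)) {
  raw <- as.numeric(featureMaps %*% weights)
  if (length(raw) != outLength)
    raw <- approx(seq_along(raw), raw, n = outLength)$y
  rng <- range(raw)
  act <- if (diff(rng) <= 0) rep(0, outLength) else
    (raw - rng[1]) / diff(rng)
  list(activations = act, raw = raw)
}

#' Class activation map of a scan under a convolutional model
#'
#' Extracts the final 1-D convolution block's feature maps for the scan
#' (eval mode), weights them by the softmax layer's weights for
#' `targetClass` and normalizes, localizing the regions that drive the
#' classification decision. For the hybrid models only the output weights
#' attached to the convolutional branch's GAP features enter the map; the
#' recurrent branch is ignored. Pure LSTM models carry no convolutional
#' branch and are rejected.
#'
#' @param object a trained [DeepClassifier-class] containing an FCN branch.
#' @param scan a [Voltammogram-class] or numeric trace.
#' @param targetClass class whose activation is mapped; defaults to the
#'   scan's label when a labeled scan is given.
#' @return a [CAMResult-class].
#' @export
setMethod("computeCAM", "DeepClassifier",
          function(object, scan, targetClass = NULL, ...) {
  info <- modelInfo(object)
  if (info$fcn_dim == 0)
    stop("unsupported model: no convolutional branch (pure LSTM)")
  if (is(scan, "Voltammogram")) {
    if (is.null(targetClass)) targetClass <- scan@label
    sid <- scan@sampleId
    x <- scan@currents
  } else {
    x <- as.numeric(scan)
    sid <- "scan"
  }
  if (is.null(targetClass)) stop("targetClass required for a bare trace")
  if (!targetClass %in% object@classLevels)
    stop("unknown target class: ", targetClass)
  if (length(x) != object@inputLength)
    stop("trace length does not match the trained model")
  A <- nn_conv_features(object@ptr, x)
  di <- nn_dense_info(object@ptr)
  w <- di$W[seq_len(di$fcn_dim), match(targetClass, object@classLevels)]
  cam <- camFromFeatures(A, w, length(x))
  new("CAMResult", activations = cam$activations, raw = cam$raw,
      targetClass = targetClass, sampleId = sid)
})

setMethod("show", "CAMResult", function(object) {
  cat("CAMResult for class", object@targetClass, "(", object@sampleId, "):",
      length(object@activations), "points, argmax at index",
      which.max(object@activations) - 1L, "\n")
})

#' Export a CAM as a per-point table
#'
#' @param cam a [CAMResult-class].
#' @param scan the [Voltammogram-class] the map was computed on.
#' @param path optional CSV path; when `NULL` the data.frame is returned.
#' @return data.frame with 0-based index, potential, current and
#'   activation.
#' @export
camTable <- function(cam, scan, path = NULL) {
  df <- data.frame(index = seq_along(cam@activations) - 1L,
                   potential = scan@grid@potentials,
                   current = scan@currents,
                   activation = cam@activations)
  if (!is.null(path)) {
    write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  df
}

#' Plot a CAM as a heatmap over the trace
#'
#' @param cam a [CAMResult-class].
#' @param scan the scan it belongs to.
#' @param ... passed to [plot()].
#' @importFrom graphics points legend
#' @importFrom grDevices colorRampPalette
#' @export
plotCAM <- function(cam, scan, ...) {
  pal <- colorRampPalette(c("grey70", "orange", "red"))(100)
  cols <- pal[pmax(1L, ceiling(cam@activations * 100))]
  plot(seq_along(scan@currents) - 1L, scan@currents, type = "l",
       col = "grey85", xlab = "index", ylab = "standardized current", ...)
  points(seq_along(scan@currents) - 1L, scan@currents, col = cols,
         pch = 16, cex = 0.4)
  legend("topleft", bty = "n",
         legend = paste0("CAM: ", cam@targetClass))
  invisible(cam)
}

#' CAM-guided truncation experiment
#'
#' Truncates the dataset (dropping `dropHead` leading and `dropTail`
#' trailing points, as suggested by the concentration of class activation
#' in the retained window), retrains the designated model on the truncated
#' data under the same split, and reports paired confusion matrices and
#' accuracies for the full-length and truncated fits.
#'
#' @param ds a [ScanSet-class].
#' @param dropHead,dropTail points removed from head/tail (502 and 100
#'   reduce the 1002-point seawater traces to the 400-point anodic window).
#' @param kind neural model kind to retrain.
#' @param plan a [SplitPlan-class]; `repeatIndex` selects the split reused
#'   for both fits.
#' @param config a [deepTrainConfig()].
#' @param fullFit optional already-trained classifier for the full-length
#'   data under the same split, reused instead of retraining.
#' @return list with `truncated` (the reduced [ScanSet-class]) and a
#'   `report` data.frame plus `confusionFull` / `confusionTruncated`.
#' @export
camGuidedTruncation <- function(ds, dropHead, dropTail,
                                kind = "alstm_fcn",
                                plan = splitPlanFor(scheme(ds),
                                                    nRepeats = 1L),
                                repeatIndex = 0L,
                                config = deepTrainConfig(),
                                fullFit = NULL) {
  spFull <- stratifiedSplit(ds, plan, repeatIndex)
  if (is.null(fullFit))
    fullFit <- trainDeep(kind, spFull$train, spFull$test, config)
  pFull <- predictProb(fullFit, spFull$test)
  tds <- truncateScans(ds, dropHead, dropTail)
  spTr <- stratifiedSplit(tds, plan, repeatIndex)
  trFit <- trainDeep(kind, spTr$train, spTr$test, config)
  pTr <- predictProb(trFit, spTr$test)
  accF <- mean(colnames(pFull)[max.col(pFull, "first")] ==
                 as.character(scanLabels(spFull$test)))
  accT <- mean(colnames(pTr)[max.col(pTr, "first")] ==
                 as.character(scanLabels(spTr$test)))
  list(truncated = tds,
       report = data.frame(data = c("full", "truncated"),
                           length = c(nrow(ds), nrow(tds)),
                           accuracy = c(accF, accT)),
       confusionFull = confusionTable(scanLabels(spFull$test), pFull),
       confusionTruncated = confusionTable(scanLabels(spTr$test), pTr),
       fullFit = fullFit, truncatedFit = trFit)
}
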