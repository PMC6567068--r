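#' Macro-averaged F1 score
#'
#' Multiclass labels are taken as the argmax of the probability table;
#' per-class precision, recall and F1 are computed one-vs-rest and averaged
#' without class weights. A class predicted never and present never is
#' dropped; a class with support (or predictions) but zero F1 contributes 0.
#' The classification `threshold` is retained for the optional per-class
#' binary report ([binaryReport()]), where a scan counts as positive for a
#' class when its probability exceeds the threshold.
#'
#' @param yTrue true labels (factor or character).
#' @param probTable scans x classes probability matrix with class column
#'   names; rows must sum to 1.
#' @param threshold per-class binary threshold (default 0.5), unused by the
#'   multiclass macro score itself.
#' @examples
#' p <- matrix(c(.9, .1, .8, .2, .3, .7, .6, .4), 4, 2, byrow = TRUE,
#'             dimnames = list(NULL, c("a", "b")))
#' macroF1(c("a", "a", "b", "b"), p)
#' @export
macroF1 <- function(yTrue, probTable, threshold = 0.5) {
  lev <- colnames(probTable)
  yTrue <- as.character(yTrue)
  if (!all(yTrue %in% lev)) stop("label outside the class set")
  pred <- lev[max.col(probTable, ties.method = "first")]
  active <- lev[lev %in% yTrue | lev %in% pred]
  f1 <- vapply(active, function(cl) {
    tp <- sum(pred == cl & yTrue == cl)
    fp <- sum(pred == cl & yTrue != cl)
    fn <- sum(pred != cl & yTrue == cl)
    if (tp == 0) return(0)
    p <- tp / (tp + fp)
    r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, 1.0)
  mean(f1)
}

#' Per-class binary classification report at a fixed threshold
#' @inheritParams macroF1
#' @return data.frame with per-class precision, recall and F1 of the
#'   thresholded one-vs-rest decisions.
#' @export
binaryReport <- function(yTrue, probTable, threshold = 0.5) {
  lev <- colnames(probTable)
  yTrue <- as.character(yTrue)
  out <- lapply(lev, function(cl) {
    pos <- probTable[, cl] >= threshold
    tp <- sum(pos & yTrue == cl)
    fp <- sum(pos & yTrue != cl)
    fn <- sum(!pos & yTrue == cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    data.frame(class = cl, precision = p, recall = r,
               f1 = if (p + r > 0) 2 * p * r / (p + r) else 0)
  })
  do.call(rbind, out)
}

# Mann-Whitney form of the trapezoidal AUC with midpoint tie handling
.aucRank <- function(scores, positive) {
  nPos <- sum(positive)
  nNeg <- sum(!positive)
  if (nPos == 0 || nNeg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' One-vs-rest ROC-AUC (micro, macro or per class)
#'
#' Binarizes the labels one-vs-rest. The micro average pools all
#' (scan, class) pairs into a single ROC; the macro average is the
#' unweighted mean of the per-class AUCs; tied scores follow the standard
#' rank/midpoint convention (equivalent to trapezoidal integration of the
#' ROC curve). A class without positive (or without negative) instances in
#' the test set has no defined AUC: it is reported as `NA` and excluded
#' from the macro average with a warning.
#'
#' @inheritParams macroF1
#' @param average `"micro"`, `"macro"` or `"per_class"`.
#' @export
rocAuc <- function(yTrue, probTable, average = c("micro", "macro",
                                                 "per_class")) {
  average <- match.arg(average)
  lev <- colnames(probTable)
  yTrue <- as.character(yTrue)
  if (!all(yTrue %in% lev)) stop("label outside the class set")
  if (average == "micro") {
    ind <- as.vector(outer(yTrue, lev, `==`))
    return(.aucRank(as.vector(probTable), ind))
  }
  perClass <- vapply(lev, function(cl)
    .aucRank(probTable[, cl], yTrue == cl), 1.0)
  if (average == "per_class") return(perClass)
  if (anyNA(perClass))
    warning("class(es) without positives in test set excluded from the ",
            "macro average: ",
            paste(lev[is.na(perClass)], collapse = ", "))
  mean(perClass, na.rm = TRUE)
}

#' Confusion matrix at argmax
#' @inheritParams macroF1
#' @export
confusionTable <- function(yTrue, probTable) {
  lev <- colnames(probTable)
  pred <- lev[max.col(probTable, ties.method = "first")]
  table(truth = factor(as.character(yTrue), levels = lev),
        predicted = factor(pred, levels = lev))
}

.fitClassifier <- function(kind, train, val, config, nComponents = 3L,
                           window = 10L) {
  switch(kind,
         pca_svm = fitPCASVM(train, nComponents),
         lda = fitLDA(train, nComponents),
         dtw = fitDTW(train, window = window),
         lstm = , fcn = , lstm_fcn = , alstm_fcn =
           trainDeep(kind, train, val, config),
         stop("unknown model kind: ", kind))
}

#' Repeated stratified train/test evaluation of one model kind
#'
#' For each of the plan's repeats the dataset is split, the model fitted on
#' the training part (the neural models monitor the test split for plateau
#' detection) and scored on the test part: macro-F1, micro- and
#' macro-average ROC-AUC, accuracy and per-class AUCs. Failures of single
#' repeats are recorded and skipped. Per-repeat scores are retained for
#' paired model comparison; medians and IQRs summarize.
#'
#' @param kind `"pca_svm"`, `"lda"`, `"dtw"`, `"lstm"`, `"fcn"`,
#'   `"lstm_fcn"` or `"alstm_fcn"`.
#' @param ds a [ScanSet-class].
#' @param plan a [SplitPlan-class].
#' @param config [deepTrainConfig()] used by the neural kinds; repeat `r`
#'   trains with derived seed `config$seed + r`.
#' @param nComponents projection dimensionality of the PCA-SVM/LDA kinds.
#' @param window DTW band half-width.
#' @return an [EvalSummary-class].
#' @export
repeatedEval <- function(kind, ds, plan = splitPlanFor(scheme(ds)),
                         config = deepTrainConfig(), nComponents = 3L,
                         window = 10L) {
  rows <- list()
  pcRows <- list()
  lev <- classNames(ds)
  conf <- table(truth = factor(character(), lev),
                predicted = factor(character(), lev))
  failures <- integer()
  for (r in seq_len(plan@nRepeats) - 1L) {
    res <- tryCatch({
      sp <- stratifiedSplit(ds, plan, r)
      cfg <- config
      cfg$seed <- config$seed + r
      set.seed(cfg$seed)
      fit <- .fitClassifier(kind, sp$train, sp$test, cfg, nComponents,
                            window)
      P <- predictProb(fit, sp$test)
      yT <- scanLabels(sp$test)
      pc <- suppressWarnings(rocAuc(yT, P, "per_class"))
      list(row = data.frame(
             repeat_ = r,
             macroF1 = macroF1(yT, P),
             aucMicro = rocAuc(yT, P, "micro"),
             aucMacro = suppressWarnings(rocAuc(yT, P, "macro")),
             accuracy = mean(colnames(P)[max.col(P, "first")] ==
                               as.character(yT))),
           pc = data.frame(repeat_ = r, class = names(pc),
                           auc = as.numeric(pc)),
           conf = confusionTable(yT, P))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, r)
      warning("repeat ", r, " failed: ", conditionMessage(res))
      next
    }
    rows[[length(rows) + 1L]] <- res$row
    pcRows[[length(pcRows) + 1L]] <- res$pc
    conf <- conf + res$conf
  }
  new("EvalSummary", kind = kind, scheme = scheme(ds),
      perRepeat = do.call(rbind, rows), perClassAUC = do.call(rbind, pcRows),
      confusion = conf, failures = failures)
}

#' Median/IQR aggregation of an evaluation
#'
#' @param es an [EvalSummary-class].
#' @return data.frame with the median and interquartile range of each
#'   metric over the completed repeats.
#' @export
aggregateEval <- function(es) {
  stopifnot(is(es, "EvalSummary"))
  metrics <- c("macroF1", "aucMicro", "aucMacro", "accuracy")
  do.call(rbind, lapply(metrics, function(mname) {
    x <- es@perRepeat[[mname]]
    data.frame(metric = mname, median = median(x),
               IQR = unname(quantile(x, 0.75) - quantile(x, 0.25)))
  }))
}

#' @rdname repeatedEval
#' @param x an [EvalSummary-class].
#' @export
perRepeat <- function(x) x@perRepeat

setMethod("show", "EvalSummary", function(object) {
  cat("EvalSummary:", object@kind, "on", object@scheme, "-",
      nrow(object@perRepeat), "completed repeats",
      if (length(object@failures))
        paste0("(", length(object@failures), " failed)") else "", "\n")
  print(aggregateEval(object), row.names = FALSE)
})

#' Paired comparison of two models over repeated splits
#'
#' Two-sided Wilcoxon signed-rank test on paired per-repeat scores. When
#' every pair is tied the p-value is 1 by convention (message emitted).
#'
#' @param a,b paired numeric score vectors of equal length, or two
#'   [EvalSummary-class] objects evaluated under the same plan.
#' @param metric score column used when summaries are given.
#' @return the p-value.
#' @export
compareModels <- function(a, b, metric = "macroF1") {
  if (is(a, "EvalSummary")) a <- a@perRepeat[[metric]]
  if (is(b, "EvalSummary")) b <- b@perRepeat[[metric]]
  if (length(a) != length(b)) stop("paired score vectors differ in length")
  if (!length(a)) stop("empty score vectors")
  if (all(a == b)) {
    message("all paired scores tied; p = 1 by convention")
    return(1)
  }
  suppressWarnings(wilcox.test(a, b, paired = TRUE,
                               alternative = "two.sided")$p.value)
}

#' Predict a holdout set and tally correctness
#'
#' @param model a fitted classifier.
#' @param holdout a [ScanSet-class] whose scheme matches the model.
#' @return a [HoldoutReport-class] with the full probability vector per
#'   scan, predicted and true classes, the number of correct assignments
#'   and the largest second-choice probability over all scans.
#' @export
holdoutPredict <- function(model, holdout) {
  if (!all(as.character(scanLabels(holdout)) %in% model@classLevels))
    stop("holdout labels outside the model's class scheme")
  P <- predictProb(model, holdout)
  pred <- colnames(P)[max.col(P, ties.method = "first")]
  truth <- as.character(scanLabels(holdout))
  second <- apply(P, 1, function(p) sort(p, decreasing = TRUE)[2])
  new("HoldoutReport", probs = P, predicted = pred, truth = truth,
      nCorrect = sum(pred == truth), maxSecondChoice = max(second))
}

setMethod("show", "HoldoutReport", function(object) {
  cat("HoldoutReport:", object@nCorrect, "/", length(object@truth),
      "correct; largest second-choice probability",
      signif(object@maxSecondChoice, 3), "\n")
})
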