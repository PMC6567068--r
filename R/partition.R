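#' Construct a repeated stratified shuffle-split plan
#'
#' @param trainFraction per-class train fraction; the published protocol
#'   uses 0.7 for 4-SW, 11-SW and 3-EXP and 0.5 for 11-EXP.
#' @param nRepeats number of repeated splits (default 25).
#' @param seed master seed; repeat `r` uses a derived substream so any
#'   single repeat is reproducible in isolation.
#' @export
SplitPlan <- function(trainFraction = 0.7, nRepeats = 25L, seed = 0L) {
  new("SplitPlan", trainFraction = trainFraction,
      nRepeats = as.integer(nRepeats), seed = as.integer(seed))
}

#' Default split plan for a label scheme
#' @param scheme one of `"4-SW"`, `"11-SW"`, `"3-EXP"`, `"11-EXP"`.
#' @rdname SplitPlan
#' @export
splitPlanFor <- function(scheme, nRepeats = 25L, seed = 0L) {
  frac <- if (identical(scheme, "11-EXP")) 0.5 else 0.7
  SplitPlan(frac, nRepeats, seed)
}

#' Stratified shuffled train/test split
#'
#' Shuffles each class independently and assigns `round(f * n_c)` scans
#' (clamped so both sides keep at least one scan) to the training set, so
#' the per-class train fraction deviates from the target by at most one
#' scan. Deterministic in `(plan@seed, repeatIndex)`.
#'
#' @param ds a [ScanSet-class]; every class must hold at least 2 scans.
#' @param plan a [SplitPlan-class].
#' @param repeatIndex 0-based repeat number within the plan.
#' @return list with `train` and `test` [ScanSet-class] objects.
#' @examples
#' ds <- generateDataset(seawaterLibrarySpec(scale = 0.1), seed = 1)
#' sp <- stratifiedSplit(ds, SplitPlan(0.7, seed = 42), repeatIndex = 0)
#' table(scanLabels(sp$train))
#' @export
stratifiedSplit <- function(ds, plan, repeatIndex = 0L) {
  stopifnot(is(ds, "ScanSet"), is(plan, "SplitPlan"),
            repeatIndex >= 0L, repeatIndex < plan@nRepeats)
  lab <- scanLabels(ds)
  tab <- table(lab)
  if (any(tab < 2L))
    stop("every class needs at least 2 scans; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  set.seed((plan@seed %% 100000L) * 10007L + as.integer(repeatIndex) * 257L)
  trainIdx <- integer()
  for (cls in names(tab)) {
    idx <- which(lab == cls)
    idx <- sample(idx)
    nTr <- round(plan@trainFraction * length(idx))
    nTr <- max(1L, min(length(idx) - 1L, nTr))
    trainIdx <- c(trainIdx, idx[seq_len(nTr)])
  }
  trainIdx <- sort(trainIdx)
  testIdx <- setdiff(seq_len(ncol(ds)), trainIdx)
  list(train = subsetScans(ds, trainIdx), test = subsetScans(ds, testIdx))
}

#' Inverse-frequency class weights
#'
#' Rare-event style reweighting: class `c` receives
#' `w_c = N / (K * n_c)` with `N` total training scans, `K` the number of
#' classes present and `n_c` the class size, so every class carries equal
#' effective mass and the total weight is conserved
#' (`sum_c n_c * w_c = N`).
#'
#' @param train training [ScanSet-class] (or a label factor).
#' @return named numeric vector of per-class weights.
#' @export
computeClassWeights <- function(train) {
  lab <- if (is(train, "ScanSet")) scanLabels(train) else as.factor(train)
  lab <- droplevels(lab)
  if (!length(lab)) stop("empty training set")
  tab <- table(lab)
  if (any(tab == 0L)) stop("empty class in training set")
  w <- length(lab) / (length(tab) * as.numeric(tab))
  setNames(w, names(tab))
}
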