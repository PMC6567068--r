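# Independent oracles used by the operation tests: brute-force warping-path
# enumeration for DTW and exhaustive pairwise comparison for ROC-AUC.

bruteDtw <- function(a, b, window = Inf, squared = FALSE) {
  a <- unname(as.numeric(a))
  b <- unname(as.numeric(b))
  n <- length(a)
  m <- length(b)
  best <- Inf
  cost <- function(i, j) {
    d <- a[i] - b[j]
    if (squared) d^2 else abs(d)
  }
  rec <- function(i, j, acc) {
    if (abs(i - j) > window) return(invisible())
    acc <- acc + cost(i, j)
    if (acc >= best) return(invisible())
    if (i == n && j == m) {
      best <<- acc
      return(invisible())
    }
    if (i < n && j < m) rec(i + 1, j + 1, acc)
    if (i < n) rec(i + 1, j, acc)
    if (j < m) rec(i, j + 1, acc)
    invisible()
  }
  rec(1, 1, 0)
  best
}

bruteAuc <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  if (!length(sp) || !length(sn)) return(NA_real_)
  tot <- 0
  for (p in sp) tot <- tot + sum(p > sn) + 0.5 * sum(p == sn)
  tot / (length(sp) * length(sn))
}

bruteMacroF1 <- function(conf) {
  # conf: square matrix, rows = truth, cols = predicted
  f1 <- vapply(seq_len(nrow(conf)), function(k) {
    tp <- conf[k, k]
    fp <- sum(conf[-k, k])
    fn <- sum(conf[k, -k])
    if (tp == 0) return(0)
    p <- tp / (tp + fp)
    r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, 1.0)
  mean(f1)
}
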