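#' Generate a labeled synthetic scan library
#'
#' Each scan is built as linear baseline drift + the oxygen-reduction
#' background (a broad cathodic Gaussian near -0.9 V, jittered in amplitude)
#' + the class peaks as Gaussians in potential space, with the peak height
#' drawn per scan from a log-uniform concentration proxy over the class
#' concentration range and mapped linearly to current, + additive white
#' noise. The finished dataset is standardized to overall mean 0 / sd 1,
#' matching the near-z-scored regime the classifiers assume. Irreversible
#' reductions (nonzero `reverseFraction`) also leave an attenuated response
#' at the same potential on the opposite branch; anodic stripping peaks do
#' not, since the deposit is consumed when stripped.
#'
#' Per-scan random substreams are derived from the master seed and the scan
#' counter, so a dataset is reproducible and independent of generation
#' order.
#'
#' @param spec a [LibrarySpec-class].
#' @param seed master seed (integer).
#' @return a [ScanSet-class] with one column per scan.
#' @examples
#' ds <- generateDataset(seawaterLibrarySpec(scale = 0.1), seed = 1)
#' table(scanLabels(ds))
#' @export
generateDataset <- function(spec, seed = 0L) {
  stopifnot(is(spec, "LibrarySpec"))
  grid <- spec@grid
  for (cl in spec@classes) .checkPeaksOnGrid(cl, grid)
  nTot <- sum(vapply(spec@classes, function(cl) cl@nSamples, 1L))
  L <- length(grid@potentials)
  cur <- matrix(0, nrow = L, ncol = nTot)
  labels <- character(nTot)
  conc <- numeric(nTot)
  m <- 0L
  for (cl in spec@classes) {
    for (j in seq_len(cl@nSamples)) {
      m <- m + 1L
      set.seed(.scanSeed(seed, m))
      sc <- .simulateScan(cl, spec)
      cur[, m] <- sc$trace
      conc[m] <- sc$conc
      labels[m] <- cl@name
    }
  }
  # dataset-level standardization
  mu <- mean(cur)
  sdv <- sd(as.vector(cur))
  if (sdv > 0) cur <- (cur - mu) / sdv
  ScanSet(cur, labels, grid, scheme = spec@scheme,
          classNames = .specClassNames(spec), concentrationProxy = conc,
          sampleIds = sprintf("%s_%s_%03d", spec@scheme, labels,
                              seq_len(nTot)))
}

.scanSeed <- function(master, counter) {
  (as.integer(master) %% 100000L) * 20011L + counter * 7919L
}

.gaussianPeak <- function(grid, ep, sigma, height, branch) {
  sel <- grid@branch == branch
  out <- numeric(length(grid@potentials))
  out[sel] <- height * exp(-(grid@potentials[sel] - ep)^2 / (2 * sigma^2))
  out
}

.otherBranch <- function(branch) {
  if (branch == "cathodic") "anodic" else "cathodic"
}

# Fixed broad surface-redox humps of the screen-printed carbon electrode,
# one profile per branch (slight hysteresis between sweeps).  Shared by all
# classes, so they carry no class information, but they give every potential
# region a recognizable local shape.  Columns: E center (V), sigma (V), amp.
.electrodeHumps <- list(
  cathodic = rbind(c(0.75, 0.12, -0.35), c(0.45, 0.10, 0.30),
                   c(0.10, 0.15, -0.40), c(-0.30, 0.12, 0.35),
                   c(-0.62, 0.08, -0.25)),
  anodic = rbind(c(-0.65, 0.09, 0.25), c(-0.40, 0.12, -0.35),
                 c(-0.10, 0.10, 0.30), c(0.20, 0.12, -0.40),
                 c(0.60, 0.10, 0.35), c(0.85, 0.15, -0.25)))

# shared non-faradaic background: charging current following the sweep
# direction, capacitive curvature, the solvent-window rise at the potential
# limits and the electrode's broad surface humps; jittered in amplitude per
# scan
.nonFaradaicBackground <- function(grid, bg) {
  E <- grid@potentials
  jit <- function() 1 + runif(1, -bg$jitter, bg$jitter)
  chg <- bg$charging * jit() *
    ifelse(grid@branch == "anodic", 1, -1)
  curv <- bg$curvature * jit() * (E^2 - mean(E^2))
  rng <- range(E)
  win <- bg$window * jit() *
    (exp((E - rng[2]) / bg$tau) - exp((rng[1] - E) / bg$tau))
  humps <- numeric(length(E))
  hj <- jit()
  for (br in c("cathodic", "anodic")) {
    sel <- grid@branch == br
    if (!any(sel)) next
    for (r in seq_len(nrow(.electrodeHumps[[br]]))) {
      h <- .electrodeHumps[[br]][r, ]
      humps[sel] <- humps[sel] +
        hj * h[3] * exp(-(E[sel] - h[1])^2 / (2 * h[2]^2))
    }
  }
  chg + curv + win + humps
}

.simulateScan <- function(cl, spec) {
  grid <- spec@grid
  L <- length(grid@potentials)
  idx <- seq_len(L) - 1L
  trace <- runif(1, -1, 1) * spec@baselineSlopeSd * (idx - L / 2) +
    rnorm(1, 0, spec@baselineInterceptSd) +
    .nonFaradaicBackground(grid, spec@background)
  if (cl@includeOxygenBackground) {
    ox <- spec@oxygen
    amp <- -ox$amplitude * (1 + runif(1, -ox$jitter, ox$jitter))
    trace <- trace + .gaussianPeak(grid, ox$center, ox$sigma, amp,
                                   "cathodic")
    if (ox$reverseFraction > 0)
      trace <- trace + .gaussianPeak(grid, ox$center, ox$sigma,
                                     amp * ox$reverseFraction, "anodic")
  }
  cr <- cl@concentrationRange
  conc <- exp(runif(1, log(cr[1]), log(cr[2])))
  rel <- conc / max(cr)                      # linear concentration response
  for (p in cl@peaks) {
    h <- p@sign * p@amplitudeScale * spec@amplitudeRef * rel
    trace <- trace + .gaussianPeak(grid, p@ep, p@widthSigma, h, p@branch)
    if (p@reverseFraction > 0)
      trace <- trace + .gaussianPeak(grid, p@ep, p@widthSigma,
                                     h * p@reverseFraction,
                                     .otherBranch(p@branch))
  }
  trace <- trace + rnorm(L, 0, spec@noiseSigma)
  list(trace = trace, conc = conc)
}
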