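# Small in-code fixtures: a short-grid three-class library keeps the unit
# tests fast; the full-length seawater library is exercised where the
# published conventions demand it.

toyGrid <- function(n = 64L)
  PotentialGrid(nPoints = n, step = 0.05, cathodicStart = 0.8,
                anodicStart = -0.75, boundaryIndex = n %/% 2L)

toyLibrary <- function(nPerClass = 8L, noise = 0.05,
                       conc = c(800, 1200)) {
  # narrow concentration band: three cleanly separated classes
  genericLibrarySpec(list(
    scheme = "custom", grid = toyGrid(), noise_sigma = noise,
    classes = list(
      list(name = "a", n = nPerClass, conc = conc,
           peaks = list(list(ep = -0.3, branch = "anodic", width = 0.12))),
      list(name = "b", n = nPerClass, conc = conc,
           peaks = list(list(ep = 0.4, branch = "anodic", width = 0.12))),
      list(name = "c", n = nPerClass, conc = conc,
           peaks = list(list(ep = -0.2, branch = "cathodic",
                             width = 0.12))))))
}

toyDataset <- function(nPerClass = 8L, seed = 1L, noise = 0.05)
  generateDataset(toyLibrary(nPerClass, noise), seed = seed)

classMeanTrace <- function(ds, cl)
  rowMeans(currents(ds)[, scanLabels(ds) == cl, drop = FALSE])
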