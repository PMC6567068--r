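# Desk-scaled reference configuration shared by the heavier end-to-end
# tests: proportionally scaled seawater library on the 16 mV grid, desk
# training preset. Index-anchored checks use the default 4 mV grid.

deskSeawaterDataset <- function(scheme = c("11-SW", "4-SW"), seed = 101L,
                                scale = 0.25) {
  scheme <- match.arg(scheme)
  spec <- seawaterLibrarySpec(scale = scale, grid = seawaterGrid(0.016))
  if (scheme == "4-SW") spec <- collapseTo4SW(spec)
  generateDataset(spec, seed = seed)
}

# lazily computed shared heavy fixtures (one training run reused across
# test blocks where the protocol allows it)
.deskCache <- new.env(parent = emptyenv())

deskEval <- function(scheme, kind = "alstm_fcn", seed = 101L) {
  key <- paste(scheme, kind, seed, sep = "|")
  if (!is.null(.deskCache[[key]])) return(.deskCache[[key]])
  ds <- deskSeawaterDataset(scheme, seed = seed)
  plan <- splitPlanFor(scheme, nRepeats = 5L, seed = seed)
  es <- repeatedEval(kind, ds, plan,
                     config = deepTrainConfig(preset = "desk", seed = seed))
  .deskCache[[key]] <- list(ds = ds, plan = plan, es = es)
  .deskCache[[key]]
}
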