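# noise-free modular dataset in which every target has a large set of
# *identical* co-expression partners (loadings 1, offsets 0, no noise):
# the exact-recovery limit of all neighborhood predictors. Every module
# must exceed K (default 20) so that no top-K list reaches outside a
# module; nGenes is a multiple of moduleSize to avoid a shrunken
# remainder module.
exact_recovery_fixture <- function(seed = 1, nGenes = 125, nTargets = 4,
                                   moduleSize = 25) {
  simulateExpression(simConfig(
    nGenes = nGenes, nTargets = nTargets,
    moduleSizeRange = c(moduleSize, moduleSize),
    noiseSd = 0, loadingSd = 0, offsetSd = 0,
    backgroundFraction = 0, seed = seed))
}
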