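# Shared desk-scale recovery experiment (African Y model, lambda = 10,
# true L = 2 Mb). Built once and reused: the reference pools depend only
# on the model, so the coverage check and the qualitative
# large-L-recovery check draw on the same set.
.recoveryCache <- new.env(parent = emptyenv())

recoveryGrid <- c(5e4, 5e5, 1e6, 2e6, 3e6, 4e6, 6e6)

recoveryFixture <- function() {
    if (is.null(.recoveryCache$rec)) {
        cfg <- deskRescale(
            forwardConfig(yForwardDemography(africanDemography(), R = 1),
                          Lsel = 2e6, neutralBp = 5e5,
                          muSite = 3.42e-8, dfe = GammaDFE(),
                          sampleN = 8, burnInFactor = 10),
            lambda = 10)
        .recoveryCache$rec <- recoveryExperiment(
            trueL = 2e6, cfg = cfg, nDatasets = 200, grid = recoveryGrid,
            kPerGrid = 150, obsNeutralBp = 7.5e6, seed = 424242)
    }
    .recoveryCache$rec
}
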