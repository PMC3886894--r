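# Independent brute-force oracles used across test files.

# pi by explicit enumeration of all sample pairs (no count shortcuts)
bruteForcePi <- function(alleles, callableBp) {
    n <- nrow(alleles)
    total <- 0
    for (i in seq_len(n - 1L)) {
        for (j in seq(i + 1L, n)) {
            total <- total + sum(alleles[i, ] != alleles[j, ])
        }
    }
    total / (n * (n - 1) / 2) / callableBp
}

# exact Poisson-mixture log-likelihood by direct summation (no log-space)
directMixtureLoglik <- function(Sstar, Sobs, ratio) {
    log(mean(dpois(Sobs, ratio * Sstar)))
}

# random polymorphic haplotype matrix
randomHaplotypeMatrix <- function(n, S, callableBp,
                                  cls = chromosomeClass("Y")) {
    alleles <- matrix(0L, n, S)
    for (j in seq_len(S)) {
        c0 <- sample.int(n - 1L, 1L)
        alleles[sample.int(n, c0), j] <- 1L
    }
    makeHaplotypeMatrix(alleles, sort(sample.int(callableBp, S)) - 1L,
                        sprintf("s%d", seq_len(n)), callableBp, cls)
}

# small forward configuration for quick engine tests
quickForwardConfig <- function(N = 300, Lsel = 0, neutralBp = 1e5,
                               muSite = 1e-7, sampleN = 8,
                               burnInFactor = 8, dfe = GammaDFE()) {
    forwardConfig(PiecewiseDemography(0, N), Lsel = Lsel,
                  neutralBp = neutralBp, muSite = muSite,
                  dfe = dfe, sampleN = sampleN,
                  burnInFactor = burnInFactor)
}
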