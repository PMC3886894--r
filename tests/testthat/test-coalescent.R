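test_that("expected pairwise time matches closed forms", {
    expect_equal(expectedPairwiseTime(PiecewiseDemography(0, 10000)),
                 20000)
    # survival-integral evaluation for the expansion model:
    # 40000(1-e^-0.1) + e^-0.1 * 20000
    expect_equal(expectedPairwiseTime(africanDemography()),
                 40000 * (1 - exp(-0.1)) + exp(-0.1) * 20000)
    expect_equal(expectedPairwiseTime(africanDemography()), 21903.25,
                 tolerance = 1e-6)
    # three-epoch European Y model
    eurY <- demographyForChromosome(europeanDemography(), "Y", 1)
    s1 <- exp(-1100 / 5000)
    s2 <- s1 * exp(-400 / 500)
    expect_equal(expectedPairwiseTime(eurY),
                 5000 * (1 - exp(-1100 / 5000)) +
                     s1 * 500 * (1 - exp(-400 / 500)) + s2 * 5000)
    expect_equal(expectedPairwiseTime(eurY), 3011.343, tolerance = 1e-6)
})

test_that("sampled genealogies agree with the analytic pairwise time", {
    demos <- list(
        const = PiecewiseDemography(0, 1000),
        africanA = africanDemography(),
        africanY = demographyForChromosome(africanDemography(), "Y", 1),
        europeanA = europeanDemography(),
        europeanY = demographyForChromosome(europeanDemography(), "Y", 1))
    set.seed(11)
    for (nm in names(demos)) {
        dem <- demos[[nm]]
        t2 <- replicate(3000, sampleGenealogy(2, dem)$T2mean)
        se <- sd(t2) / sqrt(length(t2))
        expect_lt(abs(mean(t2) - expectedPairwiseTime(dem)), 3 * se,
                  label = paste("T2 deviation for", nm))
    }
})

test_that("total branch length matches the Watterson expectation", {
    set.seed(12)
    tt <- replicate(4000, sampleGenealogy(8, PiecewiseDemography(0, 1000))$Ttotal)
    expected <- 4 * 1000 * sum(1 / (1:7))
    se <- sd(tt) / sqrt(length(tt))
    expect_lt(abs(mean(tt) - expected), 3 * se)
})

test_that("a near-zero epoch forces coalescence at its boundary", {
    dem <- PiecewiseDemography(c(0, 500), c(1e9, 1e-3))
    set.seed(13)
    t2 <- replicate(50, sampleGenealogy(2, dem)$T2mean)
    expect_true(all(t2 >= 500 & t2 < 500.1))
})

test_that("mutation overlay is Poisson on the genealogy", {
    set.seed(14)
    g <- sampleGenealogy(8, PiecewiseDemography(0, 1000))
    expect_identical(dropMutations(g, 0, 100)$S, 0L)

    S <- replicate(3000, dropMutations(g, 0.002, 1000)$S)
    expect_lt(abs(mean(S) - 0.002 * g$Ttotal),
              3 * sd(S) / sqrt(length(S)))
})

test_that("for two samples pi times locus length equals S exactly", {
    set.seed(15)
    for (i in 1:25) {
        g <- sampleGenealogy(2, PiecewiseDemography(0, 500))
        m <- dropMutations(g, 0.01, 777)
        expect_equal(m$pi * 777, m$S)
    }
})

test_that("mean diversity matches theta and scales with size", {
    set.seed(16)
    # n = 2, constant N: E[pi*] = 4 N mu / d
    sim <- simulateDiversity(2, PiecewiseDemography(0, 2000),
                             muSite = 1e-6, locusBp = 5e4, nReps = 3000,
                             divergence = 0.01)
    expect_lt(abs(sim$mean - 4 * 2000 * 1e-6 / 0.01), 3 * sim$se)

    # doubling all epoch sizes doubles the mean
    sim2 <- simulateDiversity(2, PiecewiseDemography(0, 4000),
                              muSite = 1e-6, locusBp = 5e4, nReps = 3000,
                              divergence = 0.01)
    se <- sqrt((2 * sim$se)^2 + sim2$se^2)
    expect_lt(abs(sim2$mean - 2 * sim$mean), 3 * se)

    expect_error(simulateDiversity(2, PiecewiseDemography(0, 100), 1e-6,
                                   100, 10, divergence = 0),
                 "divergence")
})

test_that("simulated class means match the demography-specific analytic
           expectation", {
    # the corrected E[T2] integration reproduces the expected normalized
    # diversity per class under the study demographies: pi* = 2 mu E[T2]/d
    set.seed(17)
    for (lab in c("A", "Y")) {
        cls <- chromosomeClass(lab)
        dem <- demographyForChromosome(africanDemography(), lab, 1)
        n <- if (lab == "A") 16 else 8
        sim <- simulateDiversity(n, dem, muSite(cls), 2e5, 2500,
                                 divergence(cls))
        analytic <- 2 * muSite(cls) * expectedPairwiseTime(dem) /
            divergence(cls)
        expect_lt(abs(sim$mean - analytic), 3 * sim$se,
                  label = paste("class", lab))
    }
})

test_that("ratio ordering responds to the sex ratio", {
    set.seed(18)
    tab <- neutralRatioTable(0.5, PiecewiseDemography(0, 5000),
                             locusBp = c(A = 2e5, X = 2e5, Y = 2e5,
                                         MT = 2e5),
                             nReps = 1500)
    # at R = 0.5 (equilibrium): MT/A = 0.375 > 0.25 > Y/A = 0.1875
    expect_gt(tab$MTA, 0.25)
    expect_lt(tab$YA, 0.25)
})

test_that("the two-sided simulation P-value folds the tail fraction", {
    expect_equal(twoSidedSimPvalue(1:100, 50.5)$P2, 1)
    expect_equal(twoSidedSimPvalue(c(1, 2, 3), 10)$P2, 0)
    expect_equal(twoSidedSimPvalue(c(1, 2, 3), 0)$P1, 1)
    # P1 = 0.9875 folds to the 0.025 rejection threshold
    sims <- c(rep(1, 125), rep(3, 9875))
    expect_equal(twoSidedSimPvalue(sims, 2)$P1, 0.9875)
    expect_equal(twoSidedSimPvalue(sims, 2)$P2, 0.025)
    expect_error(twoSidedSimPvalue(numeric(0), 1), "non-empty")
})

test_that("coalescent haplotypes reproduce the replicate statistics", {
    set.seed(19)
    h <- coalescentHaplotypes(8, PiecewiseDemography(0, 2000), 1e-6, 1e4)
    expect_equal(ncol(h$alleles), h$S)
    expect_true(all(diff(h$positions) > 0))
    cs <- colSums(h$alleles)
    expect_true(all(cs > 0 & cs < 8))
})
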