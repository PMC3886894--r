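# compact configuration used by the IO and consistency tests
smallConfig <- function(R = 1, nLociA = 6L, bpA = 20000L,
                        pops = c("Africa", "Europe")) {
    allPops <- list(Africa = list(dem = africanDemography(), R = R),
                    Europe = list(dem = europeanDemography(), R = R))
    studyConfig(populations = allPops[pops],
                loci = list(A = list(n = nLociA, bp = bpA),
                            X = list(n = nLociA, bp = bpA),
                            Y = list(n = 1L, bp = 100000L),
                            MT = list(n = 1L, bp = 16569L)))
}

test_that("the toy fixture carries its documented hand values", {
    b <- toyFixture()
    hmY <- b@haplotypes$toy.Y
    expect_equal(pairwisePi(hmY), 11 / 6 / 1000)
    expect_equal(segregatingSites(hmY), 3L)
    expect_equal(sfsCounts(foldedSFS(hmY)), c(1L, 2L))

    hmA <- b@haplotypes$toy.A
    expect_equal(pairwisePi(hmA), 8 / 6 / 500)
    expect_equal(segregatingSites(hmA), 2L)

    # the genes mask [100, 200) removes the variant at 150
    masked <- applyMasks(hmY, b@masks)
    expect_equal(callableBp(masked), 900)
    expect_equal(segregatingSites(masked), 2L)

    # regeneration is bit-identical
    expect_identical(toyFixture(), toyFixture())
})

test_that("generation is deterministic in (config, seed)", {
    cfg <- smallConfig(pops = "Africa", nLociA = 2L)
    b1 <- generateNeutralStudy(cfg, seed = 7)
    b2 <- generateNeutralStudy(cfg, seed = 7)
    expect_identical(b1@haplotypes, b2@haplotypes)
    expect_identical(b1@manifest, b2@manifest)
    b3 <- generateNeutralStudy(cfg, seed = 8)
    expect_false(identical(b1@haplotypes, b3@haplotypes))
})

test_that("bundles survive a write/read round trip", {
    cfg <- smallConfig(pops = "Africa", nLociA = 2L)
    b <- generateNeutralStudy(cfg, seed = 5)
    dir <- file.path(tempdir(), "bundle-rt")
    writeBundle(b, dir)
    b2 <- readBundle(dir)

    expect_setequal(names(b2@haplotypes), names(b@haplotypes))
    for (key in names(b@haplotypes)) {
        h1 <- b@haplotypes[[key]]
        h2 <- b2@haplotypes[[key]]
        expect_identical(hapAlleles(h2), unname(hapAlleles(h1)),
                         label = key)
        expect_identical(hapPositions(h2), hapPositions(h1))
        expect_identical(hapSamples(h2), hapSamples(h1))
        expect_equal(callableBp(h2), callableBp(h1))
        expect_equal(classLabel(chromClass(h2)),
                     classLabel(chromClass(h1)))
    }
    for (mk in names(b@masks)) {
        expect_equal(start(b2@masks[[mk]]), start(b@masks[[mk]]))
        expect_equal(end(b2@masks[[mk]]), end(b@masks[[mk]]))
    }
    expect_equal(b2@manifest$seed, b@manifest$seed)
    expect_equal(b2@divergence$divergence, b@divergence$divergence)

    expect_error(readBundle(file.path(tempdir(), "no-such-dir")),
                 "manifest")
})

test_that("the hand-written VCF fixture parses to known statistics", {
    f <- system.file("extdata", "toy3_synthetic.vcf", package = "Ypopgen")
    expect_message(
        hm <- readHaplotypesVcf(f, chromosomeClass("Y"), 2000),
        "multiallelic")
    # 3 haploid samples; the multiallelic record and the sample-monomorphic
    # record are excluded, leaving columns (0,1,1), (1,0,0), (0,0,1):
    # pair differences 2 + 3 + 1 = 6 over 3 pairs and 2000 bp
    expect_equal(hapSamples(hm), c("m1", "m2", "m3"))
    expect_equal(segregatingSites(hm), 3L)
    expect_equal(pairwisePi(hm), 6 / 3 / 2000)
    expect_equal(pairwisePi(hm), bruteForcePi(hapAlleles(hm), 2000))
})

test_that("written VCFs are standard enough for external parsers", {
    b <- toyFixture()
    dir <- file.path(tempdir(), "bundle-vcf")
    writeBundle(b, dir)
    v <- vcfR::read.vcfR(file.path(dir, "toy.A.vcf"), verbose = FALSE)
    expect_equal(nrow(v@fix), 2L)
    gt <- vcfR::extract.gt(v)
    expect_equal(dim(gt), c(2L, 2L))       # 2 sites x 2 diploid samples
    expect_true(all(grepl("^[01]\\|[01]$", gt)))
})

test_that("neutral generation matches the estimation path at R = 1", {
    # enough independent loci that the X/A ratio concentrates: with ~35%
    # per-locus coalescent CV, 60 loci per class keep 3 sigma of the
    # equilibrium-free analytic ratio well inside the admissible interval
    cfg <- smallConfig(pops = "Africa", nLociA = 60L)
    b <- generateNeutralStudy(cfg, seed = 11)
    est <- sexRatioFromBundle(b, farFromGenesBp = 1e5)
    # analytic non-equilibrium expectation under the African model at R=1
    demX <- demographyForChromosome(africanDemography(), "X", 1)
    demA <- demographyForChromosome(africanDemography(), "A", 1)
    Qexp <- expectedPairwiseTime(demX) / expectedPairwiseTime(demA)
    expect_lt(abs(est$Q - Qexp), 0.2 * Qexp)
    expect_true(est$R > 0.3 && est$R < 3)
})

test_that("a female-skewed study is detected as such", {
    cfg <- smallConfig(R = 0.335, pops = "Africa", nLociA = 60L)
    set.seed(12)
    Rhat <- vapply(1:5, function(i) {
        b <- generateNeutralStudy(cfg, seed = 100 + i)
        sexRatioFromBundle(b, farFromGenesBp = 1e5)$R
    }, numeric(1))
    expect_lt(median(Rhat), 0.75)
    expect_gt(median(Rhat), 0.05)
})

test_that("Y selection bundles record truth and depress Y diversity", {
    cfg <- smallConfig(pops = "Africa", nLociA = 2L)
    dfe <- GammaDFE()
    piStar <- function(b) {
        hm <- b@haplotypes$Africa.Y
        normalizeByDivergence(pairwisePi(hm), 0.02051)
    }
    set.seed(13)
    sel <- vapply(1:6, function(i)
        piStar(generateYWithSelection(cfg, Lsel = 2e6, dfe = dfe,
                                      lambda = 10, seed = 200 + i)),
        numeric(1))
    neu <- vapply(1:6, function(i)
        piStar(generateYWithSelection(cfg, Lsel = 0, dfe = dfe,
                                      lambda = 10, seed = 300 + i)),
        numeric(1))
    se <- sqrt(var(sel) / 6 + var(neu) / 6)
    expect_lt(mean(sel), mean(neu) - 3 * se)

    b <- generateYWithSelection(cfg, Lsel = 2e6, dfe = dfe, lambda = 10,
                                seed = 42)
    expect_equal(b@manifest$trueL, 2e6)
    expect_equal(b@manifest$lambda, 10)
    expect_equal(b@manifest$generator, "y_selection")
})
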