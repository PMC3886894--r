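test_that("the DFE rescaling follows the chromosome-count rule", {
    expect_equal(rescaleDFE(8200, 51272, 5000), 1599.314,
                 tolerance = 1e-6)
    expect_equal(round(rescaleDFE(8200, 51272, 5000), -2), 1600)
    expect_equal(rescaleDFE(8200, 51272, 51272), 16400)
    expect_equal(rescaleDFE(1000, 1000, 500), 1000)
    expect_error(rescaleDFE(-1, 1, 1), "positive")
})

test_that("fitness effects are gamma draws scaled to per-copy deficits", {
    expect_identical(drawEffects(GammaDFE(), 0), numeric(0))

    set.seed(21)
    k <- 1e5
    g <- drawEffects(GammaDFE(), k) * 5000  # back to population scale
    # mean Ns = shape * scale = 294.4 (clamping at s = 1 trims a little,
    # so compare on the unclamped fraction via the theoretical se)
    se <- sqrt(0.184) * 1600 / sqrt(k)
    trimmed <- 0.184 * 1600 -
        integrate(function(x) (x - 5000) * dgamma(x, 0.184, scale = 1600),
                  5000, Inf)$value
    expect_lt(abs(mean(g) - trimmed), 3 * se)

    s <- drawEffects(GammaDFE(scale = 1e7), 1e5)
    expect_true(all(s >= 0 & s < 1))
})

test_that("offspring sampling is fitness-weighted multinomial", {
    set.seed(22)
    # equal fitness: counts are symmetric multinomial
    counts <- wf_offspring_counts(rep(1, 10), 10000L)
    expect_equal(sum(counts), 10000)
    expect_lt(abs(mean(counts) - 1000), 1e-9)
    reps <- t(replicate(300, wf_offspring_counts(rep(1, 10), 1000L)))
    expect_equal(colMeans(reps), rep(100, 10), tolerance = 0.1)
    # per-slot variance close to binomial 1000 * 0.1 * 0.9 = 90
    expect_lt(abs(mean(apply(reps, 2, var)) - 90), 25)

    # a nearly lethal parent (w = 1e-6) takes a vanishing share
    w <- c(1e-6, rep(1, 9))
    counts <- wf_offspring_counts(w, 100000L)
    expect_lte(counts[1], 3)
})

test_that("the reference step mutates and resamples correctly", {
    cfg <- quickForwardConfig(Lsel = 0, muSite = 0)
    st <- list(s = rep(list(numeric(0)), 10))
    set.seed(23)
    nxt <- wfStep(st, 12, cfg)
    expect_length(nxt$s, 12)
    expect_true(all(vapply(nxt$s, length, 1L) == 0))  # no mutation influx

    cfgMut <- quickForwardConfig(Lsel = 1e6, muSite = 1e-6)
    nxt2 <- wfStep(st, 500, cfgMut)
    influx <- sum(vapply(nxt2$s, length, 1L))
    expect_gt(influx, 0)  # Poisson(1) per offspring, 500 offspring
    expect_lt(abs(influx - 500), 4 * sqrt(500))
    expect_error(wfStep(st, 1, cfg), ">= 2")
})

test_that("batches are deterministic under a seed", {
    cfg <- quickForwardConfig(N = 100, Lsel = 1e5, muSite = 1e-6,
                              burnInFactor = 3)
    a <- batchReplicates(cfg, 5, seed = 99)
    b <- batchReplicates(cfg, 5, seed = 99)
    expect_identical(a, b)
    c <- batchReplicates(cfg, 5, seed = 100)
    expect_false(identical(a, c))
})

test_that("the neutral limit reproduces the coalescent distribution", {
    # haploid population of 500 chromosomes == diploid-equivalent N = 250
    cfg <- quickForwardConfig(N = 500, Lsel = 0, neutralBp = 1e5,
                              muSite = 1e-7, burnInFactor = 10)
    set.seed(24)
    fwd <- batchReplicates(cfg, 250)
    coal <- simulateCoalescent(8, PiecewiseDemography(0, 250), 1e-7, 1e5,
                               5000)
    seMean <- sqrt(var(fwd$Sneutral) / nrow(fwd) +
                   var(coal$S) / nrow(coal))
    expect_lt(abs(mean(fwd$Sneutral) - mean(coal$S)), 3 * seMean)

    # variance of S: compare with the standard error of a sample variance
    # estimated from the empirical fourth moment
    vf <- var(fwd$Sneutral); vc <- var(coal$S)
    m4 <- mean((fwd$Sneutral - mean(fwd$Sneutral))^4)
    seVar <- sqrt((m4 - vf^2) / nrow(fwd))
    expect_lt(abs(vf - vc), 4 * seVar)
})

test_that("background selection depresses linked neutral diversity", {
    dfe <- GammaDFE(shape = 0.184, scale = 1600, nHapRef = 500)
    base <- quickForwardConfig(N = 500, neutralBp = 5e5, muSite = 3.42e-7,
                               burnInFactor = 10, dfe = dfe)
    set.seed(25)
    means <- ses <- numeric(3)
    for (i in seq_along(c(0, 5e5, 2e6))) {
        cfg <- base
        cfg@Lsel <- c(0, 5e5, 2e6)[i]
        reps <- batchReplicates(cfg, 40, trackSelected = FALSE)
        means[i] <- mean(reps$piNeutral)
        ses[i] <- sd(reps$piNeutral) / sqrt(nrow(reps))
    }
    # monotone non-increasing within Monte-Carlo error, and the extreme
    # contrast is decisive
    expect_lt(means[2], means[1] + 3 * sqrt(ses[1]^2 + ses[2]^2))
    expect_lt(means[3], means[2] + 3 * sqrt(ses[2]^2 + ses[3]^2))
    expect_lt(means[3] + 3 * sqrt(ses[1]^2 + ses[3]^2), means[1])
})

test_that("selected-site bookkeeping is conserved", {
    dfe <- GammaDFE(shape = 0.184, scale = 1600, nHapRef = 300)
    cfg <- quickForwardConfig(N = 300, Lsel = 5e5, muSite = 3.42e-7,
                              burnInFactor = 10, dfe = dfe)
    set.seed(26)
    r <- runReplicate(cfg, returnCounts = TRUE)
    expect_equal(r$nSegSelected, length(r$segCounts))
    expect_true(all(r$segCounts >= 1 & r$segCounts <= r$finalN - 1))
    expect_true(all(r$segS >= 0 & r$segS < 1))
    expect_gte(r$nFixedDeleterious, 0)
})

test_that("fast and tracked paths agree in distribution", {
    dfe <- GammaDFE(shape = 0.184, scale = 1600, nHapRef = 300)
    cfg <- quickForwardConfig(N = 300, Lsel = 1e6, muSite = 3.42e-7,
                              burnInFactor = 8, dfe = dfe)
    set.seed(27)
    fast <- batchReplicates(cfg, 60, trackSelected = FALSE)
    tracked <- batchReplicates(cfg, 60, trackSelected = TRUE)
    expect_true(all(is.na(fast$nSegSelected)))
    se <- sqrt(var(fast$Ttotal) / 60 + var(tracked$Ttotal) / 60)
    expect_lt(abs(mean(fast$Ttotal) - mean(tracked$Ttotal)), 3 * se)
})

test_that("two sampled chromosomes give pi * bp == S", {
    cfg <- quickForwardConfig(N = 200, Lsel = 2e5, muSite = 1e-6,
                              sampleN = 2, burnInFactor = 5)
    set.seed(28)
    reps <- batchReplicates(cfg, 20)
    expect_equal(reps$piNeutral * cfg@neutralBp, reps$Sneutral)
})

test_that("desk rescaling preserves the scaled parameters", {
    cfg <- forwardConfig(yForwardDemography(africanDemography(), 1),
                         Lsel = 2e6)
    expect_identical(deskRescale(cfg, 1)@demHap@size, cfg@demHap@size)

    cfg10 <- deskRescale(cfg, 10)
    expect_equal(cfg10@demHap@size, c(1000, 500))
    expect_equal(cfg10@demHap@start, c(0, 400))
    expect_equal(cfg10@muSite, 3.42e-7)
    expect_equal(cfg10@dfe@nHapRef, 500)
    expect_equal(cfg10@dfe@scale, cfg@dfe@scale)  # gamma scale untouched
    # theta invariant: N * mu unchanged
    expect_equal(cfg10@demHap@size[2] * cfg10@muSite,
                 cfg@demHap@size[2] * cfg@muSite)
    expect_equal(cfg10@rescaleLambda, 10)

    expect_error(deskRescale(cfg, 5000), "sampleN")
})

test_that("the coding-sites test scans mean selection strengths", {
    demAuto <- PiecewiseDemography(0, 2000)
    set.seed(30)
    tab <- codingSitesTest(demAuto, meanSGrid = c(0.001, 0.05), R = 1,
                           observedPiStar = 1e-4, nReps = 25,
                           lambda = 5, neutralBp = 1e5)
    expect_equal(nrow(tab), 2L)          # one row per grid point
    expect_equal(tab$meanS, c(0.001, 0.05))
    expect_true(all(tab$P2 >= 0 & tab$P2 <= 1))
    # an observation far below every replicate is rejected outright
    expect_equal(tab$P2[tab$meanPiStar > 1e-3][1], 0)

    # an observation at the simulated median cannot be rejected
    cfg <- quickForwardConfig(N = 150, Lsel = 0, burnInFactor = 5)
    reps <- batchReplicates(cfg, 40)
    med <- median(reps$piNeutral)
    expect_gt(twoSidedSimPvalue(reps$piNeutral, med)$P2, 0.8)
})

test_that("neutral statistics are invariant under desk rescaling", {
    base <- forwardConfig(PiecewiseDemography(0, 1000), Lsel = 0,
                          neutralBp = 1e5, muSite = 1e-7,
                          burnInFactor = 10)
    set.seed(29)
    r1 <- batchReplicates(deskRescale(base, 2), 150)
    r2 <- batchReplicates(deskRescale(base, 10), 150)
    # S depends on N*mu and n only; means agree across lambda
    se <- sqrt(var(r1$Sneutral) / 150 + var(r2$Sneutral) / 150)
    expect_lt(abs(mean(r1$Sneutral) - mean(r2$Sneutral)), 3 * se)
})
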