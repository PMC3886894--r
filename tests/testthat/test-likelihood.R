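test_that("per-region mutation rates match the printed constants", {
    expect_equal(round(regionMu(7758906, 3.42e-8), 3), 0.265)
    expect_equal(round(regionMu(7974045, 3.42e-8), 3), 0.273)
    expect_equal(regionMu(5e5, 3.42e-8), 0.0171)
    expect_identical(regionMu(0, 1e-8), 0)
    expect_error(regionMu(-1, 1e-8), ">= 0")
})

test_that("the mixture likelihood reduces to closed forms", {
    # degenerate pool: every replicate has the same count
    pool <- ReferencePool(1e6, rep(10L, 50), muSim = 0.5)
    Sobs <- 40L  # lambda = (2/0.5 = 4)... mu/muSim = 4, lambda = 40
    expect_equal(loglikForL(pool, Sobs, mu = 2),
                 dpois(40, 40, log = TRUE))

    # S_obs = 0 against an invariant pool has probability one
    p0 <- ReferencePool(1e5, rep(0L, 10), muSim = 1)
    expect_equal(loglikForL(p0, 0, mu = 1), 0)
    # ... and probability zero for any positive count
    expect_identical(loglikForL(p0, 5, mu = 1), -Inf)

    # two-replicate pool, hand evaluation
    p2 <- ReferencePool(1e6, c(10L, 20L), muSim = 1)
    expect_equal(loglikForL(p2, 10, mu = 1),
                 log(0.5 * (dpois(10, 10) + dpois(10, 20))))
})

test_that("the log-sum-exp evaluation equals direct summation", {
    set.seed(31)
    for (i in 1:10) {
        Sstar <- sample(c(5L, 10L, 17L), 40, replace = TRUE)
        pool <- ReferencePool(1e6, Sstar, muSim = 0.1)
        Sobs <- rpois(1, 60)
        expect_equal(loglikForL(pool, Sobs, mu = 0.5),
                     directMixtureLoglik(Sstar, Sobs, 0.5 / 0.1))
    }
})

test_that("the likelihood is invariant to pool permutation", {
    set.seed(32)
    Sstar <- rpois(200, 30)
    p1 <- ReferencePool(1e6, Sstar, muSim = 0.0171)
    p2 <- ReferencePool(1e6, sample(Sstar), muSim = 0.0171)
    expect_equal(loglikForL(p1, 400, mu = 0.265),
                 loglikForL(p2, 400, mu = 0.265))
})

test_that("the curve fit reproduces the hand-interpolated interval", {
    res <- fitCurve(1:4, c(-3, -1, -1.5, -4))
    expect_equal(mleL(res), 2)
    # cutoff -2.92: left crossing -3 + 2 (L - 1) = -2.92 at L = 1.04;
    # right crossing -1.5 - 2.5 (L - 3) = -2.92 at L = 3.568
    expect_equal(confInt(res), c(1.04, 3.568))
    expect_false(any(boundaryFlags(res)))

    up <- fitCurve(1:4, c(-9, -5, -2, -1))
    expect_equal(mleL(up), 4)
    expect_equal(confInt(up)[2], 4)
    expect_true(boundaryFlags(up)[2])
    expect_false(boundaryFlags(up)[1])

    flat <- fitCurve(1:5, rep(-2, 5))
    expect_equal(confInt(flat), c(1, 5))
    expect_true(all(boundaryFlags(flat)))
})

test_that("fitL locates a peaked Poisson curve", {
    # degenerate single-replicate pools: logL(L) = dpois(Sobs; r * S*(L))
    pools <- list(ReferencePool(5e4, 100L, muSim = 1),
                  ReferencePool(5e5, 60L, muSim = 1),
                  ReferencePool(2e6, 30L, muSim = 1),
                  ReferencePool(6e6, 10L, muSim = 1))
    fit <- fitL(pools, Sobs = 62L, mu = 1)
    expect_equal(mleL(fit), 5e5)
    expect_true(confInt(fit)[1] > 5e4 && confInt(fit)[2] < 2e6)
    ll <- likGrid(fit)$logLik
    expect_equal(ll[2], dpois(62, 60, log = TRUE))
    expect_error(fitL(pools[1], 10, 1), "grid")
})

test_that("the profile fit reduces to the plain fit", {
    pools <- list(ReferencePool(1e5, c(10L, 12L), muSim = 1),
                  ReferencePool(1e6, c(20L, 22L), muSim = 1),
                  ReferencePool(3e6, c(40L, 44L), muSim = 1))
    plain <- fitL(pools, 21, 1)
    prof <- profileFitL(pools, scales = rep(1600, 3), Sobs = 21, mu = 1)
    expect_equal(mleL(prof), mleL(plain))
    expect_equal(confInt(prof), confInt(plain))

    # a uniformly dominating scale defines the whole profile
    pools2 <- c(pools, list(ReferencePool(1e5, 1000L, 1),
                            ReferencePool(1e6, 1000L, 1),
                            ReferencePool(3e6, 1000L, 1)))
    scales2 <- c(rep(1600, 3), rep(400, 3))
    prof2 <- profileFitL(pools2, scales2, Sobs = 21, mu = 1)
    expect_equal(likGrid(prof2)$logLik, likGrid(plain)$logLik)
    expect_true(all(likGrid(prof2)$scale == 1600))
})

test_that("confidence intervals converge as the pools grow", {
    # a small pool under-samples the tails of the genealogy-length
    # distribution and yields a spuriously narrow (overconfident)
    # interval; as k grows, the average width converges from below to its
    # asymptotic value. Toy regime: gamma genealogy lengths, S* ~
    # Poisson(mu_sim T), S_obs ~ Poisson(mu T) at true L = 2 Mb.
    set.seed(33)
    drawSstar <- function(k, L)
        rpois(k, 0.0171 * rgamma(k, 4, scale = 1500 * (2e6 / L)^0.5))
    widths <- sapply(c(20, 400, 2000), function(k) {
        mean(replicate(40, {
            pools <- lapply(c(5e5, 1e6, 2e6, 4e6), function(L)
                ReferencePool(L, drawSstar(k, L), muSim = 0.0171))
            Sobs <- rpois(1, 0.265 * rgamma(1, 4, scale = 1500))
            diff(confInt(fitL(pools, Sobs, mu = 0.265)))
        }))
    })
    expect_lte(widths[1], widths[2] * 1.05)       # downward-biased early
    expect_lt(abs(widths[3] - widths[2]) / widths[3], 0.15)  # converged
})

test_that("a modal observation recovers its own grid point", {
    set.seed(34)
    pools <- lapply(c(5e5, 1e6, 2e6, 4e6), function(L) {
        meanS <- 60 * (2e6 / L)^0.5
        ReferencePool(L, rpois(300, meanS), muSim = 0.0171)
    })
    # draw S_obs at the L = 2e6 pool's modal intensity
    Sobs <- round((0.265 / 0.0171) * 60)
    fit <- fitL(pools, Sobs, mu = 0.265)
    expect_equal(mleL(fit), 2e6)
})
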