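#' Exact expected pairwise coalescence time under piecewise demography
#'
#' Closed-form \eqn{E[T_2]} for two lineages under a piecewise-constant
#' demography, by piecewise-exponential integration of the survival
#' function: within epoch \eqn{j} of length \eqn{\Delta_j} and
#' diploid-equivalent size \eqn{N_j} the pair coalesces at rate
#' \eqn{1/(2N_j)}, so
#' \deqn{E[T_2] = \sum_j S_j \, 2N_j\left(1 - e^{-\Delta_j/(2N_j)}\right),
#'   \qquad S_j = \prod_{i<j} e^{-\Delta_i/(2N_i)},}
#' with the final (infinite) epoch contributing \eqn{S_{last} 2N_{last}}.
#' Serves as the analytic oracle for the genealogy sampler.
#'
#' @param dem a [PiecewiseDemography]
#' @return Expected pairwise coalescence time in generations.
#' @examples
#' expectedPairwiseTime(PiecewiseDemography(0, 10000))  # 2N = 20000
#' expectedPairwiseTime(africanDemography())            # 21903.25
#' @export
expectedPairwiseTime <- function(dem) {
    stopifnot(is(dem, "PiecewiseDemography"))
    starts <- dem@start
    sizes <- dem@size
    J <- length(starts)
    surv <- 1
    ET <- 0
    for (j in seq_len(J)) {
        if (j < J) {
            delta <- starts[j + 1L] - starts[j]
            p <- exp(-delta / (2 * sizes[j]))
            ET <- ET + surv * 2 * sizes[j] * (1 - p)
            surv <- surv * p
        } else {
            ET <- ET + surv * 2 * sizes[j]
        }
    }
    ET
}

#' Sample a Kingman genealogy under piecewise-constant demography
#'
#' Simulates the n-coalescent with pairwise rate \eqn{1/(2N(t))}; waiting
#' times are drawn by time-rescaling across epochs (an exponential clock is
#' run within each epoch and carried across boundaries). Returns the exact
#' realized tree as a branch table.
#'
#' Clusters are numbered 1..n for the leaves and n+1..2n-1 for internal
#' nodes in merge order; the root (2n-1) carries no branch.
#'
#' @param n sample size (chromosomes, >= 2)
#' @param dem a [PiecewiseDemography] of diploid-equivalent sizes
#' @return list with \code{n}; \code{Ttotal} (sum of branch lengths,
#'   generations); \code{T2mean} (mean pairwise coalescence time);
#'   \code{tmrca}; \code{merges} ((n-1) x 4 matrix: time, a, b, new);
#'   \code{branchLen} and \code{branchSize} (length and subtended leaf
#'   count per cluster id, root excluded).
#' @examples
#' set.seed(1)
#' g <- sampleGenealogy(8, PiecewiseDemography(0, 1000))
#' g$Ttotal
#' @export
sampleGenealogy <- function(n, dem) {
    stopifnot(is(dem, "PiecewiseDemography"))
    n <- as.integer(n)
    if (n < 2L) stop("n must be >= 2")
    starts <- dem@start
    sizes <- dem@size
    J <- length(starts)

    nNode <- 2L * n - 1L
    birth <- numeric(nNode)
    death <- rep(NA_real_, nNode)
    size <- c(rep(1L, n), integer(n - 1L))
    active <- seq_len(n)
    merges <- matrix(0, nrow = n - 1L, ncol = 4L,
                     dimnames = list(NULL, c("time", "a", "b", "new")))

    t <- 0
    epoch <- 1L
    nextNew <- n + 1L
    mi <- 0L
    k <- n
    pairSum <- 0
    while (k > 1L) {
        rate <- k * (k - 1L) / 2 / (2 * sizes[epoch])
        w <- rexp(1L, rate)
        bound <- if (epoch < J) starts[epoch + 1L] else Inf
        if (t + w >= bound) {
            t <- bound
            epoch <- epoch + 1L
            next
        }
        t <- t + w
        ij <- sample.int(k, 2L)
        a <- active[ij[1L]]
        b <- active[ij[2L]]
        death[a] <- t
        death[b] <- t
        birth[nextNew] <- t
        size[nextNew] <- size[a] + size[b]
        pairSum <- pairSum + t * as.numeric(size[a]) * as.numeric(size[b])
        mi <- mi + 1L
        merges[mi, ] <- c(t, a, b, nextNew)
        active <- c(active[-ij], nextNew)
        nextNew <- nextNew + 1L
        k <- k - 1L
    }
    branchLen <- (death - birth)[-nNode]
    list(n = n, Ttotal = sum(branchLen),
         T2mean = pairSum / (n * (n - 1L) / 2),
         tmrca = t, merges = merges,
         branchLen = branchLen, branchSize = size[-nNode])
}

#' Overlay neutral mutations on a genealogy
#'
#' Conditional on the genealogy, the number of segregating sites is Poisson
#' with mean \eqn{\mu_{region} T_{total}} (infinite-sites model); each
#' mutation falls on a branch with probability proportional to its length,
#' and is carried by the leaves that branch subtends. Per-site diversity is
#' the mean pairwise difference count divided by \code{locusBp}.
#'
#' @param g a genealogy from [sampleGenealogy()]
#' @param muRegion per-region per-generation neutral mutation rate
#' @param locusBp callable length of the region (bp)
#' @return list with \code{S}; \code{pi} (per site); \code{piRegion} (mean
#'   pairwise differences, count units); \code{mutBranch} (branch/cluster
#'   id of each mutation).
#' @examples
#' set.seed(1)
#' g <- sampleGenealogy(2, PiecewiseDemography(0, 1000))
#' dropMutations(g, muRegion = 0.01, locusBp = 1000)
#' @export
dropMutations <- function(g, muRegion, locusBp) {
    if (muRegion < 0) stop("muRegion must be >= 0")
    n <- g$n
    S <- if (muRegion == 0) 0L else rpois(1L, muRegion * g$Ttotal)
    if (S == 0L)
        return(list(S = 0L, pi = 0, piRegion = 0, mutBranch = integer(0)))
    mutBranch <- sample.int(length(g$branchLen), S, replace = TRUE,
                            prob = g$branchLen)
    cnt <- g$branchSize[mutBranch]
    piRegion <- sum(2 * cnt * (n - cnt)) / (n * (n - 1L))
    list(S = S, pi = piRegion / locusBp, piRegion = piRegion,
         mutBranch = mutBranch)
}

#' Simulate neutral diversity replicates
#'
#' Draws \code{nReps} independent genealogies and mutation overlays and
#' returns per-replicate segregating sites and per-site diversity.
#'
#' @param n sample size (chromosomes)
#' @param dem a [PiecewiseDemography] (diploid-equivalent sizes)
#' @param muSite per-site per-generation mutation rate
#' @param locusBp locus length in bp
#' @param nReps number of replicates
#' @return data.frame with columns \code{S} and \code{pi} (per site).
#' @examples
#' set.seed(1)
#' reps <- simulateCoalescent(8, PiecewiseDemography(0, 1000),
#'                            muSite = 1e-6, locusBp = 1e4, nReps = 100)
#' colMeans(reps)
#' @export
simulateCoalescent <- function(n, dem, muSite, locusBp, nReps) {
    if (nReps < 1L) stop("nReps must be >= 1")
    muRegion <- muSite * locusBp
    S <- integer(nReps)
    pi <- numeric(nReps)
    for (i in seq_len(nReps)) {
        g <- sampleGenealogy(n, dem)
        m <- dropMutations(g, muRegion, locusBp)
        S[i] <- m$S
        pi[i] <- m$pi
    }
    data.frame(S = S, pi = pi)
}

#' Mean divergence-normalized diversity with Monte-Carlo error
#'
#' Runs [simulateCoalescent()] and reports the mean of
#' \eqn{\pi^* = \pi / d} over replicates with its Monte-Carlo standard
#' error. Normalizing by per-site divergence \eqn{d} removes
#' mutation-rate differences between chromosome classes.
#'
#' @inheritParams simulateCoalescent
#' @param divergence per-site divergence to the outgroup (> 0)
#' @return list with \code{mean}, \code{se} and the replicate data.frame.
#' @export
simulateDiversity <- function(n, dem, muSite, locusBp, nReps, divergence) {
    if (!is.finite(divergence) || divergence <= 0)
        stop("divergence must be > 0")
    reps <- simulateCoalescent(n, dem, muSite, locusBp, nReps)
    piStar <- reps$pi / divergence
    list(mean = mean(piStar), se = sd(piStar) / sqrt(nReps),
         replicates = data.frame(reps, piStar = piStar))
}

#' Simulated diversity ratios across a grid of sex ratios
#'
#' For each value of R, simulates each chromosome class under its
#' class-specific demography (via [demographyForChromosome()], holding the
#' autosomal size fixed) and forms the ratios of mean normalized diversity
#' X/A, Y/A and mtDNA/A. Standard errors of the ratios are propagated from
#' the per-class Monte-Carlo errors (delta method, independent classes).
#' At R = 1 under a constant-size demography the ratios bracket the
#' equilibrium 0.75 / 0.25 / 0.25 references; under non-equilibrium
#' demographies the expected ratios deviate from those lines (classes with
#' smaller N sit deeper in the size changes), with exact expectation
#' \eqn{2\mu_c E[T_2^{(c)}]/d_c} ratios via [expectedPairwiseTime()].
#'
#' Samples default to 8 males per population: 16 autosomal chromosomes and
#' 8 chromosomes each for X, Y and mtDNA. Autosomal and X loci are split
#' into independent 50 kb sub-loci (free recombination between, none
#' within); the Y and mtDNA are single non-recombining loci.
#'
#' @param Rgrid numeric vector of Nm/Nf values
#' @param dem autosomal [PiecewiseDemography]
#' @param nMales number of sampled males per population
#' @param locusBp named lengths (bp) for classes A, X, Y, MT
#' @param nReps replicates per class per R
#' @param classes list of the four [ChromosomeClass] objects
#' @return data.frame with one row per R: simulated ratios and their
#'   standard errors.
#' @examples
#' set.seed(1)
#' neutralRatioTable(1, africanDemography(), nReps = 200)
#' @export
neutralRatioTable <- function(Rgrid, dem, nMales = 8,
                              locusBp = c(A = 1e6, X = 1e6, Y = 5e5,
                                          MT = 16569),
                              nReps = 10000,
                              classes = list(chromosomeClass("A"),
                                             chromosomeClass("X"),
                                             chromosomeClass("Y"),
                                             chromosomeClass("MT"))) {
    labels <- vapply(classes, classLabel, character(1))
    names(classes) <- labels
    nChrom <- c(A = 2L * nMales, X = nMales, Y = nMales, MT = nMales)
    out <- vector("list", length(Rgrid))
    for (r in seq_along(Rgrid)) {
        R <- Rgrid[r]
        m <- list()
        for (lab in c("A", "X", "Y", "MT")) {
            cls <- classes[[lab]]
            demC <- demographyForChromosome(dem, cls, R)
            sim <- simulateDiversity(nChrom[[lab]], demC, muSite(cls),
                                     locusBp[[lab]], nReps,
                                     divergence(cls))
            m[[lab]] <- sim
        }
        rat <- function(x, a) {
            v <- m[[x]]$mean / m[[a]]$mean
            se <- abs(v) * sqrt((m[[x]]$se / m[[x]]$mean)^2 +
                                (m[[a]]$se / m[[a]]$mean)^2)
            c(v, se)
        }
        xa <- rat("X", "A"); ya <- rat("Y", "A"); mta <- rat("MT", "A")
        out[[r]] <- data.frame(R = R,
                               XA = xa[1], seXA = xa[2],
                               YA = ya[1], seYA = ya[2],
                               MTA = mta[1], seMTA = mta[2])
    }
    do.call(rbind, out)
}

#' Two-sided simulation P-value
#'
#' From the one-sided tail proportion \eqn{P_1}, the fraction of simulated
#' values exceeding the observation, the two-sided P-value is
#' \eqn{P_2 = 1 - 2|P_1 - 0.5|}: 1 for a perfectly central observation, 0
#' for one outside the simulated distribution.
#'
#' @param simValues numeric vector of simulated statistics (non-empty)
#' @param observed the observed statistic
#' @return list with \code{P1} and \code{P2}.
#' @examples
#' twoSidedSimPvalue(1:100, 50.5)   # P2 = 1
#' @export
twoSidedSimPvalue <- function(simValues, observed) {
    if (length(simValues) < 1L) stop("simValues must be non-empty")
    P1 <- mean(simValues > observed)
    list(P1 = P1, P2 = 1 - 2 * abs(P1 - 0.5))
}

#' Haplotypes from one neutral coalescent locus
#'
#' Samples a genealogy, overlays mutations, assigns integer positions drawn
#' without replacement in \code{[0, locusBp)}, and returns the 0/1
#' haplotype matrix (samples x sites, columns in position order).
#'
#' @inheritParams simulateCoalescent
#' @return list with \code{alleles} (n x S matrix), \code{positions}
#'   (0-based, sorted) and \code{S}.
#' @export
coalescentHaplotypes <- function(n, dem, muSite, locusBp) {
    g <- sampleGenealogy(n, dem)
    m <- dropMutations(g, muSite * locusBp, locusBp)
    h <- .haplotypesFromGenealogy(g, m$mutBranch, locusBp)
    c(h, list(S = m$S))
}

# place mutations (branch ids) at integer positions drawn without
# replacement in [0, locusBp) and expand to a 0/1 haplotype matrix
.haplotypesFromGenealogy <- function(g, mutBranch, locusBp) {
    n <- g$n
    S <- length(mutBranch)
    if (S > locusBp)
        stop("more mutations than sites; increase locusBp")
    if (S == 0L)
        return(list(alleles = matrix(0L, n, 0), positions = integer(0)))
    members <- c(as.list(seq_len(n)), vector("list", n - 1L))
    for (i in seq_len(nrow(g$merges))) {
        a <- g$merges[i, "a"]; b <- g$merges[i, "b"]
        members[[g$merges[i, "new"]]] <- c(members[[a]], members[[b]])
    }
    pos <- sort(sample.int(locusBp, S)) - 1L
    alleles <- matrix(0L, n, S)
    for (j in seq_len(S))
        alleles[members[[mutBranch[j]]], j] <- 1L
    list(alleles = alleles, positions = as.integer(pos))
}
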