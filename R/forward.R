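#' Configuration for forward simulation of a non-recombining chromosome
#'
#' @param demHap [PiecewiseDemography] whose sizes are HAPLOID chromosome
#'   counts (for the Y, the number of breeding males per epoch); see
#'   [yForwardDemography()]
#' @param Lsel number of selected sites (bp); new mutations at these sites
#'   draw fitness effects from \code{dfe}
#' @param neutralBp length of the linked neutral region (bp)
#' @param muSite per-site per-generation mutation rate (applies to both
#'   selected and neutral sites)
#' @param dfe a [GammaDFE]
#' @param sampleN chromosomes sampled at present
#' @param burnInFactor burn-in length in units of the ancestral haploid
#'   size (default 10, i.e. 10 N generations at the ancestral size before
#'   the demographic epochs play out)
#' @return A [ForwardConfig].
#' @examples
#' forwardConfig(yForwardDemography(africanDemography(), R = 1), Lsel = 0)
#' @export
forwardConfig <- function(demHap, Lsel, neutralBp = 5e5, muSite = 3.42e-8,
                          dfe = GammaDFE(), sampleN = 8L,
                          burnInFactor = 10) {
    new("ForwardConfig", demHap = demHap, Lsel = Lsel,
        neutralBp = neutralBp, muSite = muSite, dfe = dfe,
        sampleN = as.integer(sampleN), burnInFactor = burnInFactor,
        rescaleLambda = 1)
}

#' Haploid Y demography for the forward simulator
#'
#' Converts an autosomal demography into the haploid Y chromosome count per
#' epoch under sex ratio R: each epoch's \eqn{N_{auto}} gives
#' \eqn{N_m = N_{auto}(1+R)/4} males, and the Y population is those
#' \eqn{N_m} chromosomes (twice the diploid-equivalent \eqn{N_{chrY} =
#' N_m/2}). With the ancestral \eqn{N_{auto} = 10{,}000} and R = 1 this is
#' the 5,000-chromosome Y population.
#'
#' @param demAuto autosomal [PiecewiseDemography]
#' @param R ratio Nm/Nf
#' @return A [PiecewiseDemography] of haploid counts.
#' @examples
#' yForwardDemography(africanDemography(), R = 1)   # 10000 now, 5000 anc
#' @export
yForwardDemography <- function(demAuto, R = 1) {
    demY <- demographyForChromosome(demAuto, "Y", R)
    PiecewiseDemography(demY@start, 2 * demY@size)
}

#' Rescale an autosomal DFE scale parameter to a haploid chromosome
#'
#' An autosomal population-scaled gamma DFE calibrated on
#' \code{chromsOrig} chromosomes is converted for a haploid simulation of
#' \code{chromsSim} chromosomes by dividing the scale by the chromosome
#' ratio and doubling (the autosomal model describes heterozygous fitness,
#' while every mutation on a haploid chromosome is fully exposed):
#' \deqn{scale_{sim} = \frac{scale_{orig}}{chroms_{orig}/chroms_{sim}}
#'   \times 2.}
#'
#' @param scaleOrig autosomal gamma scale (default 8200)
#' @param chromsOrig chromosomes behind the original calibration
#'   (default 51272)
#' @param chromsSim haploid chromosomes in the simulation
#' @return The rescaled gamma scale parameter.
#' @examples
#' rescaleDFE(8200, 51272, 5000)   # 1599.3, reported as 1600
#' @export
rescaleDFE <- function(scaleOrig = 8200, chromsOrig = 51272, chromsSim) {
    if (any(c(scaleOrig, chromsOrig, chromsSim) <= 0))
        stop("all arguments must be positive")
    scaleOrig / (chromsOrig / chromsSim) * 2
}

#' Draw per-copy fitness deficits from a gamma DFE
#'
#' Draws population-scaled effects \eqn{\gamma \sim \Gamma(shape, scale)}
#' and converts them to per-copy deficits \eqn{s = \gamma/nHapRef}, clamped
#' to \code{[0, 0.999999]} (a clamped draw is effectively lethal). The
#' haploid fitness multiplier of a mutation is \eqn{1 - s}.
#'
#' @param dfe a [GammaDFE]
#' @param k number of draws (>= 0)
#' @return Numeric vector of k deficits in [0, 0.999999].
#' @examples
#' set.seed(1)
#' mean(drawEffects(GammaDFE(), 1e4)) * 5000   # ~ 0.184 * 1600
#' @export
drawEffects <- function(dfe, k) {
    stopifnot(is(dfe, "GammaDFE"), k >= 0)
    if (k == 0) return(numeric(0))
    pmin(rgamma(k, shape = dfe@shape, scale = dfe@scale) / dfe@nHapRef,
         0.999999)
}

#' One forward Wright-Fisher generation (reference implementation)
#'
#' A single generation step on an explicit population state, used to test
#' the resampling and mutation semantics at small scale. Offspring choose
#' parents with probability proportional to fitness
#' \eqn{w = \prod_j (1 - s_j)} and each gains Poisson(muSite * Lsel) new
#' selected mutations.
#'
#' @param state list with \code{s}: a list of per-individual numeric
#'   vectors of fitness deficits
#' @param Nnext offspring population size (>= 2)
#' @param cfg a [ForwardConfig] (supplies Lsel, muSite, dfe)
#' @return The next state, same shape, plus \code{parent} (index chosen by
#'   each offspring).
#' @export
wfStep <- function(state, Nnext, cfg) {
    if (Nnext < 2) stop("population size must be >= 2")
    w <- vapply(state$s, function(s) prod(1 - s), numeric(1))
    counts <- wf_offspring_counts(w, as.integer(Nnext))
    parent <- rep.int(seq_along(w), counts)
    parent <- parent[sample.int(length(parent))]
    sNew <- lapply(parent, function(p) {
        k <- rpois(1L, cfg@muSite * cfg@Lsel)
        c(state$s[[p]], drawEffects(cfg@dfe, k))
    })
    list(s = sNew, parent = parent)
}

#' Run one forward replicate with background selection
#'
#' Simulates the haploid population forward through burn-in
#' (\code{burnInFactor} times the ancestral size, starting from a clonal
#' founder population) and the demographic epochs, with new selected
#' mutations drawn from the gamma DFE and fitness-weighted multinomial
#' resampling. At present, \code{sampleN} chromosomes are drawn without
#' replacement, their genealogy is traced through the recorded pedigree,
#' and neutral variation for the linked \code{neutralBp} region is overlaid
#' on it (Poisson given total branch length, infinite sites) -- exactly the
#' conditional distribution neutral mutations would have if carried
#' forward, since the chromosome does not recombine.
#'
#' @param cfg a [ForwardConfig]
#' @param returnGenealogy also return the traced genealogy (branch table
#'   compatible with [dropMutations()])
#' @param returnCounts also return carrier counts and effects of the
#'   segregating selected mutations (bookkeeping diagnostics)
#' @param trackSelected keep per-individual selected-mutation bookkeeping
#'   (needed for \code{nSegSelected}/\code{nFixedDeleterious}). With
#'   \code{FALSE} only fitness is propagated, which leaves the population
#'   dynamics and all sampled statistics unchanged (fitness is the only
#'   channel through which selected mutations act) but runs considerably
#'   faster; the bookkeeping fields are then \code{NA}.
#' @return list with \code{Sneutral}, \code{piNeutral} (per neutral site),
#'   \code{nSegSelected}, \code{nFixedDeleterious} (fixations after
#'   burn-in), \code{Ttotal} (generations), and optional extras.
#' @examples
#' set.seed(1)
#' cfg <- forwardConfig(PiecewiseDemography(0, 200), Lsel = 0,
#'                      neutralBp = 1e5, muSite = 1e-7, burnInFactor = 5)
#' runReplicate(cfg)[c("Sneutral", "piNeutral")]
#' @export
runReplicate <- function(cfg, returnGenealogy = FALSE,
                         returnCounts = FALSE, trackSelected = TRUE) {
    stopifnot(is(cfg, "ForwardConfig"))
    validObject(cfg)
    dem <- cfg@demHap
    burnInGens <- cfg@burnInFactor * round(dem@size[length(dem@size)])
    eng <- wf_run_replicate(dem@start, dem@size, burnInGens,
                            cfg@muSite * cfg@Lsel, cfg@dfe@shape,
                            cfg@dfe@scale, cfg@dfe@nHapRef,
                            cfg@sampleN, returnCounts, trackSelected)
    g <- list(n = eng$n, Ttotal = eng$Ttotal, merges = eng$merges,
              branchLen = eng$branchLen, branchSize = eng$branchSize)
    m <- dropMutations(g, cfg@muSite * cfg@neutralBp, cfg@neutralBp)
    out <- list(Sneutral = m$S, piNeutral = m$pi,
                nSegSelected = eng$nSegSelected,
                nFixedDeleterious = eng$nFixedDeleterious,
                Ttotal = eng$Ttotal)
    if (returnGenealogy) {
        out$genealogy <- g
        out$mutBranch <- m$mutBranch
    }
    if (returnCounts) {
        out$segCounts <- eng$segCounts
        out$segS <- eng$segS
        out$finalN <- eng$finalNint
    }
    out
}

#' Batches of independent forward replicates
#'
#' @param cfg a [ForwardConfig]
#' @param k number of replicates (>= 1)
#' @param seed optional integer; if given, \code{set.seed(seed)} first so
#'   the batch is reproducible
#' @param trackSelected see [runReplicate()]
#' @return data.frame with one row per replicate: \code{Sneutral},
#'   \code{piNeutral}, \code{nSegSelected}, \code{nFixedDeleterious},
#'   \code{Ttotal}.
#' @export
batchReplicates <- function(cfg, k, seed = NULL, trackSelected = TRUE) {
    if (k < 1L) stop("k must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    rows <- vector("list", k)
    for (i in seq_len(k)) {
        r <- runReplicate(cfg, trackSelected = trackSelected)
        rows[[i]] <- data.frame(Sneutral = r$Sneutral,
                                piNeutral = r$piNeutral,
                                nSegSelected = r$nSegSelected,
                                nFixedDeleterious = r$nFixedDeleterious,
                                Ttotal = r$Ttotal)
    }
    do.call(rbind, rows)
}

#' Desk-scale rescaling of a forward configuration
#'
#' Standard population rescaling by a factor \eqn{\lambda}: population
#' sizes are divided by \eqn{\lambda} (minimum 2), the per-site mutation
#' rate multiplied by \eqn{\lambda}, and epoch times divided by
#' \eqn{\lambda}; burn-in length scales automatically since it is expressed
#' in units of the ancestral size. Population-scaled selection
#' (\eqn{\gamma}) is left unchanged by shrinking \code{nHapRef} with the
#' population, so the products \eqn{N\mu} and \eqn{Ns} are invariant.
#' Rescaling truncates the strong tail of the DFE earlier (the per-copy
#' clamp \eqn{s < 1} corresponds to a smaller \eqn{\gamma}); such mutations
#' are eliminated essentially immediately at either scale.
#'
#' @param cfg a [ForwardConfig]
#' @param lambda rescaling factor (>= 1)
#' @return A rescaled [ForwardConfig]; \code{rescaleLambda} accumulates.
#' @examples
#' cfg <- forwardConfig(yForwardDemography(africanDemography(), 1),
#'                      Lsel = 2e6)
#' deskRescale(cfg, 10)
#' @export
deskRescale <- function(cfg, lambda) {
    stopifnot(is(cfg, "ForwardConfig"))
    if (lambda < 1) stop("lambda must be >= 1")
    sizes <- pmax(cfg@demHap@size / lambda, 2)
    if (round(sizes[1L]) < cfg@sampleN)
        stop("rescaled present population smaller than sampleN")
    dem <- PiecewiseDemography(cfg@demHap@start / lambda, sizes)
    dfe <- new("GammaDFE", shape = cfg@dfe@shape, scale = cfg@dfe@scale,
               nHapRef = cfg@dfe@nHapRef / lambda)
    new("ForwardConfig", demHap = dem, Lsel = cfg@Lsel,
        neutralBp = cfg@neutralBp, muSite = cfg@muSite * lambda,
        dfe = dfe, sampleN = cfg@sampleN,
        burnInFactor = cfg@burnInFactor,
        rescaleLambda = cfg@rescaleLambda * lambda)
}

#' Can purifying selection on coding sites alone explain observed Y
#' diversity?
#'
#' For each candidate mean selection coefficient, simulates background
#' selection from \code{Lsel} coding-region selected sites (gamma DFE with
#' fixed shape 0.184, scale set so the mean per-copy effect equals the
#' candidate) linked to a neutral region, computes normalized diversity
#' \eqn{\pi^* = \pi/d} per replicate, and reports the two-sided simulation
#' P-value of the observed \eqn{\pi^*_{obs}} under each model.
#'
#' @param demAuto autosomal [PiecewiseDemography]
#' @param meanSGrid mean per-copy selection coefficients to evaluate
#'   (study range 0.0001 to 0.09)
#' @param R sex ratio Nm/Nf
#' @param observedPiStar observed normalized Y diversity
#' @param Lsel number of selected (nonsynonymous) sites; default 60041
#' @param neutralBp linked neutral region; default 500 kb
#' @param nReps replicates per grid point
#' @param lambda desk-rescaling factor passed to [deskRescale()]
#' @param divergence per-site divergence used to normalize (Y: 0.02051)
#' @param shape gamma shape (fixed at 0.184)
#' @return data.frame with one row per mean s: \code{meanS},
#'   \code{meanPiStar}, \code{P1}, \code{P2}.
#' @export
codingSitesTest <- function(demAuto, meanSGrid, R, observedPiStar,
                            Lsel = 60041, neutralBp = 5e5, nReps = 1000,
                            lambda = 1, divergence = 0.02051,
                            shape = 0.184) {
    demHap <- yForwardDemography(demAuto, R)
    nHapRef <- round(demHap@size[length(demHap@size)])
    rows <- vector("list", length(meanSGrid))
    for (i in seq_along(meanSGrid)) {
        meanS <- meanSGrid[i]
        dfe <- GammaDFE(shape = shape, scale = meanS * nHapRef / shape,
                        nHapRef = nHapRef)
        cfg <- forwardConfig(demHap, Lsel = Lsel, neutralBp = neutralBp,
                             dfe = dfe)
        if (lambda > 1) cfg <- deskRescale(cfg, lambda)
        reps <- batchReplicates(cfg, nReps)
        piStar <- reps$piNeutral / divergence
        pv <- twoSidedSimPvalue(piStar, observedPiStar)
        rows[[i]] <- data.frame(meanS = meanS, meanPiStar = mean(piStar),
                                P1 = pv$P1, P2 = pv$P2)
    }
    do.call(rbind, rows)
}
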