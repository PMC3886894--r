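#' @useDynLib Ypopgen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rexp rpois rgamma runif rbinom dpois sd var median
#'   quantile setNames
#' @importFrom utils head tail read.table write.table
NULL

#' Effective numbers of breeding males and females
#'
#' Container for the male (\eqn{N_m}) and female (\eqn{N_f}) effective
#' population sizes. Their ratio \eqn{R = N_m/N_f} is the central parameter
#' of sex-biased demography: it controls the relative effective sizes of the
#' autosomes, X, Y and mtDNA.
#'
#' @slot Nm effective number of breeding males (individuals, > 0)
#' @slot Nf effective number of breeding females (individuals, > 0)
#' @export
setClass("SexRatio", representation(Nm = "numeric", Nf = "numeric"))

setValidity("SexRatio", function(object) {
    if (length(object@Nm) != 1L || length(object@Nf) != 1L)
        return("Nm and Nf must be single numbers")
    if (!is.finite(object@Nm) || !is.finite(object@Nf))
        return("Nm and Nf must be finite")
    if (object@Nm <= 0 || object@Nf <= 0)
        return("Nm and Nf must be > 0")
    TRUE
})

#' @rdname SexRatio-class
#' @param Nm,Nf effective numbers of breeding males and females
#' @return A \code{SexRatio} object.
#' @examples
#' sr <- SexRatio(5000, 5000)
#' nmnfRatio(sr)
#' @export
SexRatio <- function(Nm, Nf) new("SexRatio", Nm = Nm, Nf = Nf)

#' Diploid-equivalent effective sizes per chromosome class
#'
#' Effective sizes \eqn{N} on the scale where two lineages coalesce at rate
#' \eqn{1/(2N)} per generation, for autosomes, X, Y and mtDNA. Under equal
#' male and female numbers these stand in the classical 1 : 3/4 : 1/4 : 1/4
#' proportions.
#'
#' @slot Nauto,NchrX,NchrY,Nmt diploid-equivalent effective sizes
#' @export
setClass("EffectiveSizes", representation(
    Nauto = "numeric", NchrX = "numeric", NchrY = "numeric", Nmt = "numeric"))

setValidity("EffectiveSizes", function(object) {
    v <- c(object@Nauto, object@NchrX, object@NchrY, object@Nmt)
    if (length(v) != 4L || any(!is.finite(v)) || any(v <= 0))
        return("all effective sizes must be finite and > 0")
    ratio <- object@NchrX / object@Nauto
    if (ratio <= 9 / 16 || ratio >= 9 / 8)
        return("NchrX/Nauto must lie in (9/16, 9/8)")
    TRUE
})

#' Piecewise-constant demographic history
#'
#' Epochs of constant diploid-equivalent population size, present epoch
#' first. \code{start} gives the time (generations before present) at which
#' each epoch begins looking backwards; the first entry is 0 and times are
#' strictly increasing. The last epoch extends indefinitely into the past.
#'
#' @slot start numeric, epoch start times in generations before present
#' @slot size numeric, diploid-equivalent sizes (individuals)
#' @export
setClass("PiecewiseDemography",
         representation(start = "numeric", size = "numeric"))

setValidity("PiecewiseDemography", function(object) {
    if (length(object@start) != length(object@size))
        return("start and size must have equal length")
    if (length(object@start) < 1L)
        return("at least one epoch is required")
    if (object@start[1L] != 0)
        return("first epoch must start at time 0")
    if (any(diff(object@start) <= 0))
        return("epoch start times must be strictly increasing")
    if (any(!is.finite(object@size)) || any(object@size <= 0))
        return("all epoch sizes must be finite and > 0")
    TRUE
})

#' @rdname PiecewiseDemography-class
#' @param start,size epoch start times (generations ago, present first) and
#'   diploid-equivalent sizes
#' @return A \code{PiecewiseDemography}.
#' @examples
#' ## an expansion from 10,000 to 20,000 individuals 4,000 generations ago
#' PiecewiseDemography(c(0, 4000), c(20000, 10000))
#' @export
PiecewiseDemography <- function(start, size)
    new("PiecewiseDemography", start = as.numeric(start),
        size = as.numeric(size))

#' Chromosome class: mutation rate, inheritance and divergence
#'
#' Describes one of the four chromosome classes (autosome, X, Y, mtDNA):
#' its per-site per-generation mutation rate, copy numbers carried by each
#' sex, and per-site divergence to the outgroup used for normalization.
#'
#' @slot label one of "A", "X", "Y", "MT"
#' @slot muSite mutations per site per generation
#' @slot copiesPerMale,copiesPerFemale integer chromosome copy counts
#' @slot divergence substitutions per site versus the outgroup
#' @export
setClass("ChromosomeClass", representation(
    label = "character", muSite = "numeric",
    copiesPerMale = "integer", copiesPerFemale = "integer",
    divergence = "numeric"))

.CLASS_COPIES <- list(A = c(2L, 2L), X = c(1L, 2L), Y = c(1L, 0L),
                      MT = c(1L, 1L))

setValidity("ChromosomeClass", function(object) {
    if (!object@label %in% names(.CLASS_COPIES))
        return("label must be one of A, X, Y, MT")
    if (object@muSite <= 0) return("muSite must be > 0")
    if (object@divergence <= 0) return("divergence must be > 0")
    exp_cp <- .CLASS_COPIES[[object@label]]
    if (object@copiesPerMale != exp_cp[1L] ||
        object@copiesPerFemale != exp_cp[2L])
        return(sprintf("copy counts for class %s must be %d/%d",
                       object@label, exp_cp[1L], exp_cp[2L]))
    TRUE
})

#' Gamma distribution of fitness effects
#'
#' Population-scaled gamma DFE for new deleterious mutations. A draw
#' \eqn{\gamma \sim \Gamma(shape, scale)} is converted to a per-copy fitness
#' deficit \eqn{s = \gamma / nHapRef} (clamped below 1), where
#' \code{nHapRef} is the haploid population size the scale parameter is
#' calibrated to. Haploid fitness is multiplicative across mutations,
#' \eqn{w = \prod_j (1 - s_j)}.
#'
#' @slot shape gamma shape (dimensionless; default 0.184)
#' @slot scale gamma scale in population-scaled units (default 1600)
#' @slot nHapRef haploid size the scale is calibrated to (default 5000)
#' @export
setClass("GammaDFE", representation(
    shape = "numeric", scale = "numeric", nHapRef = "numeric"))

setValidity("GammaDFE", function(object) {
    if (object@shape <= 0) return("shape must be > 0")
    if (object@scale <= 0) return("scale must be > 0")
    if (object@nHapRef <= 0) return("nHapRef must be > 0")
    TRUE
})

#' @rdname GammaDFE-class
#' @param shape,scale gamma parameters of the population-scaled DFE
#' @param nHapRef haploid population size the scale is calibrated to
#' @return A \code{GammaDFE}.
#' @examples
#' GammaDFE()              # Y-chromosome default, mean Ns = 0.184 * 1600
#' @export
GammaDFE <- function(shape = 0.184, scale = 1600, nHapRef = 5000)
    new("GammaDFE", shape = shape, scale = scale, nHapRef = nHapRef)

#' Configuration for the forward Wright-Fisher simulator
#'
#' @slot demHap demography in haploid chromosome counts (present first);
#'   for the Y this is \eqn{N_m} per epoch
#' @slot Lsel number of selected sites (bp)
#' @slot neutralBp linked neutral sites (bp)
#' @slot muSite per-site per-generation mutation rate
#' @slot dfe a [GammaDFE]
#' @slot sampleN chromosomes sampled at present
#' @slot burnInFactor burn-in length in units of the ancestral haploid size
#' @slot rescaleLambda cumulative desk-rescaling factor applied so far
#' @export
setClass("ForwardConfig", representation(
    demHap = "PiecewiseDemography", Lsel = "numeric", neutralBp = "numeric",
    muSite = "numeric", dfe = "GammaDFE", sampleN = "integer",
    burnInFactor = "numeric", rescaleLambda = "numeric"))

setValidity("ForwardConfig", function(object) {
    if (object@Lsel < 0) return("Lsel must be >= 0")
    if (object@neutralBp < 1) return("neutralBp must be >= 1")
    if (object@muSite < 0) return("muSite must be >= 0")
    if (object@sampleN < 2L) return("sampleN must be >= 2")
    if (object@sampleN > object@demHap@size[1L])
        return("sampleN exceeds the present population size")
    if (object@burnInFactor < 0) return("burnInFactor must be >= 0")
    TRUE
})

#' Sample of haplotypes at variant sites
#'
#' Binary samples x sites matrix of haploid calls over variant positions,
#' together with the number of callable sites (monomorphic positions with
#' complete data included), the unit over which per-site diversity is
#' measured. Every retained column is polymorphic within the sample.
#'
#' @slot samples character, sample identifiers (rows of \code{alleles})
#' @slot positions integer, 0-based variant coordinates, strictly increasing
#' @slot alleles integer matrix of 0/1 alleles, samples x sites
#' @slot callable \code{GRanges} of callable intervals (1-based closed,
#'   converted from the 0-based half-open convention on input)
#' @slot callableBp number of sites passing all filters (total width of
#'   \code{callable})
#' @slot cls the [ChromosomeClass] the haplotypes belong to
#' @importClassesFrom GenomicRanges GRanges
#' @export
setClass("HaplotypeMatrix", representation(
    samples = "character", positions = "integer", alleles = "matrix",
    callable = "GRanges", callableBp = "numeric",
    cls = "ChromosomeClass"))

setValidity("HaplotypeMatrix", function(object) {
    a <- object@alleles
    if (nrow(a) != length(object@samples))
        return("alleles must have one row per sample")
    if (ncol(a) != length(object@positions))
        return("alleles must have one column per position")
    if (length(object@positions) &&
        any(diff(object@positions) <= 0))
        return("positions must be strictly increasing")
    if (length(a) && !all(a %in% c(0L, 1L)))
        return("alleles must be 0/1")
    if (ncol(a)) {
        cs <- colSums(a)
        if (any(cs == 0L) || any(cs == nrow(a)))
            return("every variant column must be polymorphic in the sample")
    }
    if (object@callableBp < ncol(a))
        return("callableBp must be >= the number of variant sites")
    TRUE
})

#' Folded site frequency spectrum
#'
#' Counts of segregating sites by minor-allele count \eqn{1..\lfloor n/2
#' \rfloor}. Used when ancestral states are unknown.
#'
#' @slot counts integer vector of length \code{floor(nChrom/2)}
#' @slot nChrom number of sampled chromosomes
#' @export
setClass("FoldedSFS",
         representation(counts = "integer", nChrom = "integer"))

setValidity("FoldedSFS", function(object) {
    if (length(object@counts) != object@nChrom %/% 2L)
        return("counts must have length floor(nChrom/2)")
    if (any(object@counts < 0L)) return("counts must be >= 0")
    TRUE
})

#' Reference pool of simulated segregating-site counts
#'
#' Segregating-site counts from forward-simulation replicates at one value
#' of \eqn{L} (and one DFE), feeding the approximate likelihood: each count
#' \eqn{S^*_i} stands in for the total genealogy length of its replicate via
#' \eqn{T^* \approx S^*/\mu_{sim}}.
#'
#' @slot L number of selected sites the pool was simulated at (bp)
#' @slot Sstar integer vector of simulated segregating-site counts
#' @slot muSim per-region per-generation neutral mutation rate of the
#'   simulated neutral region
#' @export
setClass("ReferencePool",
         representation(L = "numeric", Sstar = "integer", muSim = "numeric"))

setValidity("ReferencePool", function(object) {
    if (length(object@Sstar) < 1L) return("pool must contain >= 1 replicate")
    if (any(object@Sstar < 0L)) return("Sstar must be >= 0")
    if (object@muSim <= 0) return("muSim must be > 0")
    TRUE
})

#' @rdname ReferencePool-class
#' @param L selected sites (bp); @param Sstar simulated segregating-site
#'   counts; @param muSim per-region neutral mutation rate of the simulation
#' @return A \code{ReferencePool}.
#' @export
ReferencePool <- function(L, Sstar, muSim = 0.0171)
    new("ReferencePool", L = as.numeric(L), Sstar = as.integer(Sstar),
        muSim = muSim)

#' Result of a grid likelihood fit for L
#'
#' @slot grid data.frame with columns \code{L} and \code{logLik}
#' @slot mleL maximum-likelihood estimate of L (bp)
#' @slot ci lower and upper 95\% confidence bounds (1.92 log-likelihood
#'   units, linear interpolation between grid points)
#' @slot boundary logical(2); \code{TRUE} where the interval was censored at
#'   a grid edge
#' @export
setClass("LikelihoodResult", representation(
    grid = "data.frame", mleL = "numeric", ci = "numeric",
    boundary = "logical"))

setValidity("LikelihoodResult", function(object) {
    if (!all(c("L", "logLik") %in% names(object@grid)))
        return("grid must have columns L and logLik")
    if (length(object@ci) != 2L) return("ci must have length 2")
    if (object@ci[1L] > object@mleL || object@ci[2L] < object@mleL)
        return("ci must contain mleL")
    TRUE
})

#' Bundle of synthetic study data
#'
#' Everything a study-shaped dataset consists of: one [HaplotypeMatrix] per
#' (population, class), mask intervals, a divergence table, and a manifest
#' recording seeds and the true generating parameters so that downstream
#' estimates can be scored against truth.
#'
#' @slot haplotypes named list of [HaplotypeMatrix], names "pop.class"
#' @slot masks named list of \code{GRanges} mask sets
#' @slot divergence data.frame with columns class, divergence, muSite
#' @slot manifest list of seeds and true parameters
#' @export
setClass("StudyBundle", representation(
    haplotypes = "list", masks = "list", divergence = "data.frame",
    manifest = "list"))
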