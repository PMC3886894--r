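#' @importFrom GenomicRanges GRanges reduce setdiff width start end
#'   seqnames "start<-" "end<-"
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols "mcols<-"
NULL

#' Construct a haplotype matrix
#'
#' Monomorphic columns (no variation within the sample) are dropped, since
#' only polymorphic positions are variants; they remain counted through the
#' callable intervals.
#'
#' @param alleles 0/1 matrix, samples x sites
#' @param positions 0-based site coordinates (strictly increasing)
#' @param samples sample identifiers
#' @param callable \code{GRanges} of callable intervals, or a single
#'   number interpreted as the interval \code{[0, callable)} on the
#'   class's synthetic chromosome
#' @param cls a [ChromosomeClass]
#' @return A [HaplotypeMatrix].
#' @examples
#' hm <- makeHaplotypeMatrix(rbind(c(0L, 1L), c(1L, 0L)), c(4L, 9L),
#'                           c("s1", "s2"), 1000, chromosomeClass("Y"))
#' pairwisePi(hm)
#' @export
makeHaplotypeMatrix <- function(alleles, positions, samples, callable,
                                cls) {
    alleles <- as.matrix(alleles)
    storage.mode(alleles) <- "integer"
    dimnames(alleles) <- NULL
    positions <- as.integer(positions)
    if (is.numeric(callable) && !is(callable, "GRanges"))
        callable <- GRanges(paste0("synth_", cls@label),
                            IRanges(1L, as.integer(callable)))
    callable <- reduce(callable)
    if (ncol(alleles)) {
        cs <- colSums(alleles)
        keep <- cs > 0L & cs < nrow(alleles)
        alleles <- alleles[, keep, drop = FALSE]
        positions <- positions[keep]
    }
    new("HaplotypeMatrix", samples = samples, positions = positions,
        alleles = alleles, callable = callable,
        callableBp = sum(width(callable)), cls = cls)
}

#' @rdname makeHaplotypeMatrix
#' @param hm a [HaplotypeMatrix]
#' @return `callableRanges` returns the \code{GRanges} of callable
#'   intervals.
#' @export
callableRanges <- function(hm) hm@callable

#' Mask intervals
#'
#' Builds a mask set as a \code{GRanges} from 0-based half-open intervals
#' (BED convention); the label ("genes", "repeats", ...) is stored per
#' range in \code{mcols}.
#'
#' @param chrom chromosome names
#' @param start0,end0 0-based half-open interval bounds
#' @param label mask label
#' @return A \code{GRanges}.
#' @examples
#' maskSet("synth_Y", 100, 200, "genes")
#' @export
maskSet <- function(chrom, start0, end0, label = "mask") {
    if (any(end0 <= start0)) stop("intervals must satisfy start < end")
    gr <- GRanges(chrom, IRanges(start0 + 1L, end0))
    mcols(gr)$label <- label
    gr
}

#' Nucleotide diversity per site
#'
#' \eqn{\pi}: the average number of nucleotide differences per site
#' between all pairs of sequences. For a biallelic column carried by
#' \eqn{c} of \eqn{n} samples, \eqn{c(n-c)} of the \eqn{n(n-1)/2} pairs
#' differ, so
#' \deqn{\pi = \frac{\sum_{sites} c(n-c)}{\binom{n}{2} \cdot
#'   \mathrm{callable\ bp}}.}
#'
#' @param hm a [HaplotypeMatrix] with >= 2 samples
#' @return Per-site diversity.
#' @export
pairwisePi <- function(hm) {
    n <- nrow(hm@alleles)
    if (n < 2L) stop("need >= 2 samples")
    if (hm@callableBp < 1) stop("callableBp must be >= 1")
    if (ncol(hm@alleles) == 0L) return(0)
    cnt <- colSums(hm@alleles)
    sum(cnt * (n - cnt)) / (n * (n - 1) / 2) / hm@callableBp
}

#' Number of segregating sites
#'
#' @param hm a [HaplotypeMatrix]
#' @return Count of polymorphic columns.
#' @export
segregatingSites <- function(hm) ncol(hm@alleles)

#' Folded site frequency spectrum
#'
#' Histogram of minor-allele counts over \eqn{1..\lfloor n/2 \rfloor};
#' columns at exactly n/2 fold onto the n/2 bin. The counts always sum to
#' the number of segregating sites.
#'
#' @param hm a [HaplotypeMatrix]
#' @return A [FoldedSFS].
#' @export
foldedSFS <- function(hm) {
    n <- nrow(hm@alleles)
    half <- n %/% 2L
    cnt <- colSums(hm@alleles)
    minor <- pmin(cnt, n - cnt)
    new("FoldedSFS", counts = tabulate(minor, nbins = half),
        nChrom = as.integer(n))
}

#' Apply interval masks to a haplotype matrix
#'
#' Removes variant sites and callable positions falling in any mask
#' interval, recomputing the callable length from the interval arithmetic
#' (union of masks subtracted from the callable set). With
#' \code{farFromGenesBp} set, mask ranges labelled \code{"genes"} are
#' first expanded by that flank on both sides, so only sequence at least
#' that far from any gene survives -- the "far from genes" filter.
#' Applying the same masks twice is a no-op.
#'
#' @param hm a [HaplotypeMatrix]
#' @param masks a \code{GRanges} or list of \code{GRanges} (see
#'   [maskSet()])
#' @param farFromGenesBp optional non-negative flank (bp) applied to
#'   gene-labelled masks
#' @return The filtered [HaplotypeMatrix].
#' @export
applyMasks <- function(hm, masks, farFromGenesBp = NULL) {
    if (is(masks, "GRanges")) masks <- list(masks)
    if (length(masks) == 0L) return(hm)
    if (!is.null(farFromGenesBp) && farFromGenesBp < 0)
        stop("farFromGenesBp must be >= 0")
    expanded <- lapply(masks, function(gr) {
        if (!is.null(farFromGenesBp) && length(gr) &&
            !is.null(mcols(gr)$label) &&
            any(mcols(gr)$label == "genes")) {
            sel <- mcols(gr)$label == "genes"
            start(gr)[sel] <- pmax(1L, start(gr)[sel] - farFromGenesBp)
            end(gr)[sel] <- end(gr)[sel] + farFromGenesBp
        }
        gr
    })
    # masks may span several synthetic chromosomes; combining them emits
    # harmless disjoint-seqlevel warnings
    all <- suppressWarnings(
        reduce(do.call(c, unname(lapply(expanded, function(g) {
            mcols(g) <- NULL
            g
        })))))
    callable <- callableRanges(hm)
    chrom <- as.character(seqnames(callable))[1L]
    allC <- all[as.character(seqnames(all)) == chrom]
    newCallable <- suppressWarnings(
        GenomicRanges::setdiff(callable, allC, ignore.strand = TRUE))
    if (sum(width(newCallable)) < 1)
        stop("masks remove all callable sequence")
    if (length(hm@positions)) {
        pos1 <- hm@positions + 1L
        inMask <- rep(FALSE, length(pos1))
        if (length(allC)) {
            ov <- IRanges::overlapsAny(IRanges(pos1, pos1),
                                       IRanges(start(allC), end(allC)))
            inMask <- ov
        }
        hm@alleles <- hm@alleles[, !inMask, drop = FALSE]
        hm@positions <- hm@positions[!inMask]
    }
    hm@callable <- reduce(newCallable)
    hm@callableBp <- sum(width(hm@callable))
    hm
}

#' Normalize diversity by divergence
#'
#' \eqn{\pi^* = \pi/d}: dividing per-site diversity by per-site divergence
#' to the outgroup corrects for mutation-rate differences between
#' chromosome classes.
#'
#' @param pi per-site diversity
#' @param d per-site divergence (> 0)
#' @return Normalized diversity.
#' @examples
#' normalizeByDivergence(6.38e-4, 0.02051)
#' @export
normalizeByDivergence <- function(pi, d) {
    if (!is.finite(d) || d <= 0) stop("divergence must be > 0")
    pi / d
}

#' Mutation rate implied by divergence
#'
#' Under a molecular clock, per-site divergence accumulated over
#' \eqn{2 \times} the split time gives the per-generation rate
#' \deqn{\mu = \frac{d}{2 \cdot splitYears/genYears}.}
#'
#' @param d per-site divergence
#' @param splitYears species split time in years (default 6 Myr)
#' @param genYears years per generation (default 20)
#' @return Per-site per-generation mutation rate.
#' @examples
#' muFromDivergence(0.02051)   # 3.42e-8, the Y rate
#' @export
muFromDivergence <- function(d, splitYears = 6e6, genYears = 20) {
    if (d < 0 || splitYears <= 0 || genYears <= 0)
        stop("invalid arguments")
    d / (2 * splitYears / genYears)
}

#' Estimate Nm/Nf from X and autosomal diversity
#'
#' The estimation path used with putatively neutral (far-from-genes)
#' diversity: form \eqn{Q = \pi^*_X / \pi^*_A} and invert the
#' X/autosome effective-size ratio ([invertXARatio()]).
#'
#' @param piXStar,piAStar normalized X and autosomal diversity (far from
#'   genes)
#' @return list with \code{Q} and \code{R}; if Q falls outside the
#'   admissible interval (9/16, 9/8), \code{R} is \code{NA} with a
#'   warning.
#' @examples
#' estimateNmNf(0.0723, 0.0804)   # Q = 0.8993, R = 0.3352
#' estimateNmNf(0.0459, 0.0615)   # Q = 0.7463, R = 1.0299
#' @export
estimateNmNf <- function(piXStar, piAStar) {
    if (piXStar <= 0 || piAStar <= 0)
        stop("diversities must be > 0")
    Q <- piXStar / piAStar
    R <- tryCatch(invertXARatio(Q), error = function(e) {
        warning(conditionMessage(e))
        NA_real_
    })
    list(Q = Q, R = R)
}

#' Per-class diversity summary
#'
#' @param hm a [HaplotypeMatrix]
#' @return One-row data.frame: class, S, callableBp, pi, piStar.
#' @export
diversitySummary <- function(hm) {
    pi <- pairwisePi(hm)
    data.frame(class = hm@cls@label, S = segregatingSites(hm),
               callableBp = hm@callableBp, pi = pi,
               piStar = normalizeByDivergence(pi, hm@cls@divergence))
}
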