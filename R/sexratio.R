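#' Effective sizes of the four chromosome classes
#'
#' Maps male and female effective numbers \eqn{(N_m, N_f)} to the
#' diploid-equivalent effective size of each chromosome class:
#' \deqn{N_{auto} = \frac{4 N_m N_f}{N_m + N_f}, \quad
#'       N_{chrX} = \frac{9 N_m N_f}{2(2 N_m + N_f)}, \quad
#'       N_{chrY} = \frac{N_m}{2}, \quad
#'       N_{mt} = \frac{N_f}{2}.}
#' These are the classical results for autosomal, X-linked, Y-linked and
#' maternally inherited loci under random (Poisson) offspring variation.
#' With \eqn{N_m = N_f} they reduce to the familiar 1 : 3/4 : 1/4 : 1/4
#' proportions.
#'
#' @param sr a [SexRatio]
#' @return An [EffectiveSizes] object.
#' @examples
#' effectiveSizes(SexRatio(5000, 5000))   # 10000, 7500, 2500, 2500
#' @seealso [sizesFromAutosomal()] for the inverse given R,
#'   [expectedRatioCurves()] for the implied diversity ratios.
#' @export
effectiveSizes <- function(sr) {
    stopifnot(is(sr, "SexRatio"))
    validObject(sr)
    Nm <- sr@Nm
    Nf <- sr@Nf
    new("EffectiveSizes",
        Nauto = 4 * Nm * Nf / (Nm + Nf),
        NchrX = 9 * Nm * Nf / (2 * (2 * Nm + Nf)),
        NchrY = Nm / 2,
        Nmt   = Nf / 2)
}

#' Male and female effective sizes from the autosomal size and R
#'
#' Inverts the autosomal effective-size formula: given the autosomal
#' diploid-equivalent size \eqn{N_{auto}} and the ratio \eqn{R = N_m/N_f},
#' returns \eqn{N_m = N_{auto}(1+R)/4} and \eqn{N_f = N_m/R}. The autosomal
#' size is held fixed because demographic parameters are estimated from
#' autosomal markers; skewing R then redistributes that size between the
#' sexes.
#'
#' @param Nauto autosomal diploid-equivalent effective size (> 0)
#' @param R ratio Nm/Nf (> 0)
#' @return A [SexRatio]; \code{effectiveSizes()} of the result recovers
#'   \code{Nauto} exactly.
#' @examples
#' sizesFromAutosomal(10000, 1)       # Nm = Nf = 5000
#' sizesFromAutosomal(10000, 0.38)    # Nm = 3450
#' @export
sizesFromAutosomal <- function(Nauto, R) {
    if (!is.finite(Nauto) || Nauto <= 0)
        stop("Nauto must be a positive number")
    if (!is.finite(R) || R <= 0)
        stop("R must be a positive number")
    Nm <- Nauto * (1 + R) / 4
    SexRatio(Nm = Nm, Nf = Nm / R)
}

#' Expected diversity ratios as a function of R
#'
#' Expected ratios of normalized diversity relative to the autosomes, at
#' mutation-rate-corrected equilibrium, as closed forms in
#' \eqn{R = N_m/N_f}:
#' \deqn{X/A = \frac{9(R+1)}{16R+8}, \quad Y/A = \frac{R+1}{8}, \quad
#'       mt/A = \frac{R+1}{8R}.}
#' At \eqn{R = 1} these equal 0.75, 0.25 and 0.25. X/A and mt/A decrease in
#' R while Y/A increases, which is why the three ratios jointly constrain R.
#'
#' @param R numeric vector of Nm/Nf ratios (> 0)
#' @return data.frame with columns \code{R}, \code{XA}, \code{YA},
#'   \code{MTA}.
#' @examples
#' expectedRatioCurves(1)
#' expectedRatioCurves(c(0.25, 0.5, 1, 2))
#' @export
expectedRatioCurves <- function(R) {
    if (any(!is.finite(R)) || any(R <= 0))
        stop("R must be positive and finite")
    data.frame(R = R,
               XA = 9 * (R + 1) / (16 * R + 8),
               YA = (R + 1) / 8,
               MTA = (R + 1) / (8 * R))
}

#' Estimate Nm/Nf from the observed X/autosome diversity ratio
#'
#' Solves \eqn{Q = 9(R+1)/(16R+8)} for R in closed form:
#' \deqn{R = \frac{9 - 8Q}{16Q - 9}.}
#' A finite positive solution exists only for \eqn{Q \in (9/16, 9/8)}; the
#' lower limit corresponds to \eqn{R \to \infty} and the upper to
#' \eqn{R \to 0}.
#'
#' @param Q observed ratio of normalized X to autosomal diversity
#' @return The ratio R = Nm/Nf.
#' @examples
#' invertXARatio(0.75)                 # 1: equal sex ratio
#' round(invertXARatio(0.0723 / 0.0804), 4)
#' @export
invertXARatio <- function(Q) {
    if (!is.finite(Q) || Q <= 9 / 16 || Q >= 9 / 8)
        stop("Q = ", format(Q), " admits no finite positive Nm/Nf; ",
             "the admissible interval is (9/16, 9/8) = (0.5625, 1.125)")
    (9 - 8 * Q) / (16 * Q - 9)
}

#' Translate an autosomal demography to another chromosome class
#'
#' Rescales every epoch of an autosomal piecewise demography to the
#' diploid-equivalent size of the given chromosome class under the sex
#' ratio R: each epoch's \eqn{N_{auto}} is split into \eqn{(N_m, N_f)} via
#' [sizesFromAutosomal()] and the class's size taken from
#' [effectiveSizes()]. Epoch times are unchanged. For class "A" and any R
#' this is the identity.
#'
#' @param dem autosomal [PiecewiseDemography]
#' @param cls a [ChromosomeClass] (or a class label "A", "X", "Y", "MT")
#' @param R ratio Nm/Nf
#' @return A [PiecewiseDemography] for the class.
#' @examples
#' demographyForChromosome(africanDemography(), "Y", R = 1)
#' @export
demographyForChromosome <- function(dem, cls, R) {
    stopifnot(is(dem, "PiecewiseDemography"))
    label <- if (is(cls, "ChromosomeClass")) cls@label else
        match.arg(cls, c("A", "X", "Y", "MT"))
    sizes <- vapply(dem@size, function(Na) {
        es <- effectiveSizes(sizesFromAutosomal(Na, R))
        switch(label, A = es@Nauto, X = es@NchrX, Y = es@NchrY, MT = es@Nmt)
    }, numeric(1))
    PiecewiseDemography(dem@start, sizes)
}

#' Built-in chromosome classes
#'
#' The four chromosome classes with their per-site per-generation mutation
#' rates (estimated from human-chimpanzee alignments assuming a 6 Myr split
#' and 20-year generations; the mtDNA rate from the literature) and the
#' divergence constants used for normalization. The Y divergence is the
#' measured per-site human-chimp value 0.02051; for the other classes the
#' default divergence is \code{muSite * 2 * (6e6 / 20)}, the value exactly
#' implied by the same split-time calibration, so that normalization and
#' mutation-rate correction are mutually consistent.
#'
#' @param label one of "A", "X", "Y", "MT"
#' @param muSite,divergence optional overrides of the defaults
#' @return A [ChromosomeClass].
#' @examples
#' chromosomeClass("Y")
#' @export
chromosomeClass <- function(label = c("A", "X", "Y", "MT"),
                            muSite = NULL, divergence = NULL) {
    label <- match.arg(label)
    mu_default <- c(A = 2.11e-8, X = 1.65e-8, Y = 3.42e-8, MT = 1.7e-8)
    mu <- if (is.null(muSite)) mu_default[[label]] else muSite
    d <- if (is.null(divergence)) {
        if (label == "Y") 0.02051 else mu * 2 * (6e6 / 20)
    } else divergence
    cp <- .CLASS_COPIES[[label]]
    new("ChromosomeClass", label = label, muSite = mu,
        copiesPerMale = cp[1L], copiesPerFemale = cp[2L], divergence = d)
}

#' Study demographic models
#'
#' The two piecewise-constant autosomal demographies used throughout:
#' an African expansion from 10,000 to 20,000 individuals 4,000 generations
#' ago, and a European bottleneck from 10,000 down to 1,000 individuals
#' 1,500 generations ago followed by a recovery to 10,000 at 1,100
#' generations ago.
#'
#' @return A [PiecewiseDemography] (autosomal scale; use
#'   [demographyForChromosome()] for other classes).
#' @examples
#' africanDemography()
#' europeanDemography()
#' @export
africanDemography <- function()
    PiecewiseDemography(c(0, 4000), c(20000, 10000))

#' @rdname africanDemography
#' @export
europeanDemography <- function()
    PiecewiseDemography(c(0, 1100, 1500), c(10000, 1000, 10000))
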