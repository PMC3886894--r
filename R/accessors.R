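#' @rdname SexRatio-class
#' @export
setMethod("Nm", "SexRatio", function(x) x@Nm)
#' @rdname SexRatio-class
#' @export
setMethod("Nf", "SexRatio", function(x) x@Nf)
#' @rdname SexRatio-class
#' @export
setMethod("nmnfRatio", "SexRatio", function(x) x@Nm / x@Nf)

#' @rdname EffectiveSizes-class
#' @export
setMethod("Nauto", "EffectiveSizes", function(x) x@Nauto)
#' @rdname EffectiveSizes-class
#' @export
setMethod("NchrX", "EffectiveSizes", function(x) x@NchrX)
#' @rdname EffectiveSizes-class
#' @export
setMethod("NchrY", "EffectiveSizes", function(x) x@NchrY)
#' @rdname EffectiveSizes-class
#' @export
setMethod("Nmt", "EffectiveSizes", function(x) x@Nmt)

#' @rdname PiecewiseDemography-class
#' @export
setMethod("epochStarts", "PiecewiseDemography", function(x) x@start)
#' @rdname PiecewiseDemography-class
#' @export
setMethod("epochSizes", "PiecewiseDemography", function(x) x@size)
#' @rdname PiecewiseDemography-class
#' @export
setMethod("nEpochs", "PiecewiseDemography", function(x) length(x@start))

#' @rdname ChromosomeClass-class
#' @export
setMethod("classLabel", "ChromosomeClass", function(x) x@label)
#' @rdname ChromosomeClass-class
#' @export
setMethod("muSite", "ChromosomeClass", function(x) x@muSite)
#' @rdname ChromosomeClass-class
#' @export
setMethod("divergence", "ChromosomeClass", function(x) x@divergence)

#' @rdname HaplotypeMatrix-class
#' @export
setMethod("hapSamples", "HaplotypeMatrix", function(x) x@samples)
#' @rdname HaplotypeMatrix-class
#' @export
setMethod("hapPositions", "HaplotypeMatrix", function(x) x@positions)
#' @rdname HaplotypeMatrix-class
#' @export
setMethod("hapAlleles", "HaplotypeMatrix", function(x) x@alleles)
#' @rdname HaplotypeMatrix-class
#' @export
setMethod("callableBp", "HaplotypeMatrix", function(x) x@callableBp)
#' @rdname HaplotypeMatrix-class
#' @export
setMethod("chromClass", "HaplotypeMatrix", function(x) x@cls)

#' @rdname FoldedSFS-class
#' @export
setMethod("sfsCounts", "FoldedSFS", function(x) x@counts)
#' @rdname FoldedSFS-class
#' @export
setMethod("nChrom", "FoldedSFS", function(x) x@nChrom)

#' @rdname LikelihoodResult-class
#' @export
setMethod("mleL", "LikelihoodResult", function(x) x@mleL)
#' @rdname LikelihoodResult-class
#' @export
setMethod("confInt", "LikelihoodResult", function(x) x@ci)
#' @rdname LikelihoodResult-class
#' @export
setMethod("boundaryFlags", "LikelihoodResult", function(x) x@boundary)
#' @rdname LikelihoodResult-class
#' @export
setMethod("likGrid", "LikelihoodResult", function(x) x@grid)

setMethod("show", "SexRatio", function(object) {
    cat(sprintf("SexRatio: Nm = %.6g, Nf = %.6g (R = Nm/Nf = %.4f)\n",
                object@Nm, object@Nf, object@Nm / object@Nf))
})

setMethod("show", "EffectiveSizes", function(object) {
    cat(sprintf(paste0("EffectiveSizes (diploid-equivalent):\n",
                       "  N_auto = %.6g  N_chrX = %.6g",
                       "  N_chrY = %.6g  N_mt = %.6g\n"),
                object@Nauto, object@NchrX, object@NchrY, object@Nmt))
})

setMethod("show", "PiecewiseDemography", function(object) {
    cat("PiecewiseDemography with", length(object@start),
        "epoch(s) (present first):\n")
    for (i in seq_along(object@start)) {
        upper <- if (i < length(object@start))
            sprintf("%g", object@start[i + 1L]) else "Inf"
        cat(sprintf("  [%g, %s) generations ago: N = %g\n",
                    object@start[i], upper, object@size[i]))
    }
})

setMethod("show", "ChromosomeClass", function(object) {
    cat(sprintf(paste0("ChromosomeClass %s: mu = %.3g /site/gen, ",
                       "copies m/f = %d/%d, divergence = %.4g\n"),
                object@label, object@muSite, object@copiesPerMale,
                object@copiesPerFemale, object@divergence))
})

setMethod("show", "GammaDFE", function(object) {
    cat(sprintf(paste0("GammaDFE: shape = %.3g, scale = %.5g ",
                       "(mean Ns = %.4g), calibrated to %g haploids\n"),
                object@shape, object@scale, object@shape * object@scale,
                object@nHapRef))
})

setMethod("show", "ForwardConfig", function(object) {
    cat(sprintf(paste0("ForwardConfig: L_sel = %g bp, neutral = %g bp, ",
                       "mu = %.3g, n = %d, burn-in = %g x N_anc",
                       " (rescale lambda = %g)\n"),
                object@Lsel, object@neutralBp, object@muSite,
                object@sampleN, object@burnInFactor, object@rescaleLambda))
    cat("  haploid demography:\n")
    show(object@demHap)
})

setMethod("show", "HaplotypeMatrix", function(object) {
    cat(sprintf(paste0("HaplotypeMatrix (class %s): %d samples x %d ",
                       "variant sites, callable = %g bp\n"),
                object@cls@label, length(object@samples),
                ncol(object@alleles), object@callableBp))
})

setMethod("show", "FoldedSFS", function(object) {
    cat(sprintf("FoldedSFS over %d chromosomes (S = %d):\n",
                object@nChrom, sum(object@counts)))
    print(setNames(object@counts, seq_along(object@counts)))
})

setMethod("show", "ReferencePool", function(object) {
    cat(sprintf(paste0("ReferencePool at L = %g bp: k = %d replicates, ",
                       "mean S* = %.2f, mu_sim = %.4g\n"),
                object@L, length(object@Sstar), mean(object@Sstar),
                object@muSim))
})

setMethod("show", "LikelihoodResult", function(object) {
    cat(sprintf("LikelihoodResult: MLE L = %g bp, 95%% CI [%g, %g]%s\n",
                object@mleL, object@ci[1L], object@ci[2L],
                if (any(object@boundary)) " (censored at grid edge)" else ""))
    cat(sprintf("  grid of %d points spanning [%g, %g] bp\n",
                nrow(object@grid), min(object@grid$L), max(object@grid$L)))
})

setMethod("show", "StudyBundle", function(object) {
    cat("StudyBundle:\n  haplotypes:",
        paste(names(object@haplotypes), collapse = ", "), "\n")
    cat("  masks:", paste(names(object@masks), collapse = ", "), "\n")
    if (!is.null(object@manifest$seed))
        cat("  seed:", object@manifest$seed, "\n")
})
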