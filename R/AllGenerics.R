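#' @rdname SexRatio-class
#' @param object,x an object
#' @export
setGeneric("Nm", function(x) standardGeneric("Nm"))
#' @rdname SexRatio-class
#' @export
setGeneric("Nf", function(x) standardGeneric("Nf"))
#' @rdname SexRatio-class
#' @export
setGeneric("nmnfRatio", function(x) standardGeneric("nmnfRatio"))

#' @rdname EffectiveSizes-class
#' @param x an object
#' @export
setGeneric("Nauto", function(x) standardGeneric("Nauto"))
#' @rdname EffectiveSizes-class
#' @export
setGeneric("NchrX", function(x) standardGeneric("NchrX"))
#' @rdname EffectiveSizes-class
#' @export
setGeneric("NchrY", function(x) standardGeneric("NchrY"))
#' @rdname EffectiveSizes-class
#' @export
setGeneric("Nmt", function(x) standardGeneric("Nmt"))

#' @rdname PiecewiseDemography-class
#' @param x an object
#' @export
setGeneric("epochStarts", function(x) standardGeneric("epochStarts"))
#' @rdname PiecewiseDemography-class
#' @export
setGeneric("epochSizes", function(x) standardGeneric("epochSizes"))
#' @rdname PiecewiseDemography-class
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname ChromosomeClass-class
#' @param x an object
#' @export
setGeneric("classLabel", function(x) standardGeneric("classLabel"))
#' @rdname ChromosomeClass-class
#' @export
setGeneric("muSite", function(x) standardGeneric("muSite"))
#' @rdname ChromosomeClass-class
#' @export
setGeneric("divergence", function(x) standardGeneric("divergence"))

#' @rdname HaplotypeMatrix-class
#' @param x an object
#' @export
setGeneric("hapSamples", function(x) standardGeneric("hapSamples"))
#' @rdname HaplotypeMatrix-class
#' @export
setGeneric("hapPositions", function(x) standardGeneric("hapPositions"))
#' @rdname HaplotypeMatrix-class
#' @export
setGeneric("hapAlleles", function(x) standardGeneric("hapAlleles"))
#' @rdname HaplotypeMatrix-class
#' @export
setGeneric("callableBp", function(x) standardGeneric("callableBp"))
#' @rdname HaplotypeMatrix-class
#' @export
setGeneric("chromClass", function(x) standardGeneric("chromClass"))

#' @rdname FoldedSFS-class
#' @param x an object
#' @export
setGeneric("sfsCounts", function(x) standardGeneric("sfsCounts"))
#' @rdname FoldedSFS-class
#' @export
setGeneric("nChrom", function(x) standardGeneric("nChrom"))

#' @rdname LikelihoodResult-class
#' @param x an object
#' @export
setGeneric("mleL", function(x) standardGeneric("mleL"))
#' @rdname LikelihoodResult-class
#' @export
setGeneric("confInt", function(x) standardGeneric("confInt"))
#' @rdname LikelihoodResult-class
#' @export
setGeneric("boundaryFlags", function(x) standardGeneric("boundaryFlags"))
#' @rdname LikelihoodResult-class
#' @export
setGeneric("likGrid", function(x) standardGeneric("likGrid"))
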