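#' Configuration of a synthetic study
#'
#' Describes the cohort and genome structure the generator emulates: two
#' populations of 8 males each, with population-specific piecewise
#' demographies (an African expansion and a European bottleneck), a chosen
#' sex ratio R per population, and four chromosome classes. Autosomal and
#' X sequence is split into independent 50 kb loci (free recombination
#' between loci, none within -- many loci mimic genome-wide data); the Y
#' and mtDNA are single non-recombining loci. Mask geometry places gene
#' and repeat intervals at fixed densities on each synthetic chromosome.
#'
#' @param populations named list; each element a list with \code{dem} (a
#'   [PiecewiseDemography], autosomal) and \code{R} (Nm/Nf)
#' @param nMales sampled males per population
#' @param loci named list per class with \code{n} (number of independent
#'   loci) and \code{bp} (locus length)
#' @param classes named list of the four [ChromosomeClass] objects
#' @param maskGeometry list with \code{genesPerMb}, \code{geneBp},
#'   \code{repeatsPerMb}, \code{repeatBp}
#' @return A configuration list consumed by [generateNeutralStudy()] and
#'   [generateYWithSelection()].
#' @export
studyConfig <- function(populations = list(
                            Africa = list(dem = africanDemography(), R = 1),
                            Europe = list(dem = europeanDemography(),
                                          R = 1)),
                        nMales = 8L,
                        loci = list(A = list(n = 200L, bp = 50000L),
                                    X = list(n = 150L, bp = 50000L),
                                    Y = list(n = 1L, bp = 500000L),
                                    MT = list(n = 1L, bp = 16569L)),
                        classes = list(A = chromosomeClass("A"),
                                       X = chromosomeClass("X"),
                                       Y = chromosomeClass("Y"),
                                       MT = chromosomeClass("MT")),
                        maskGeometry = list(genesPerMb = 1, geneBp = 10000,
                                            repeatsPerMb = 100,
                                            repeatBp = 300)) {
    stopifnot(nMales >= 2L)
    list(populations = populations, nMales = as.integer(nMales),
         loci = loci, classes = classes, maskGeometry = maskGeometry)
}

.classChrom <- function(label) paste0("synth_", label)

.classSampleN <- function(label, nMales)
    if (label == "A") 2L * nMales else nMales

.sampleNames <- function(pop, label, nMales) {
    males <- sprintf("%s_m%d", pop, seq_len(nMales))
    if (label == "A") as.vector(rbind(paste0(males, "_h1"),
                                      paste0(males, "_h2")))
    else males
}

# concatenate independent coalescent loci into one synthetic chromosome
.simulateClassHaplotypes <- function(n, dem, cls, nLoci, locusBp) {
    mats <- vector("list", nLoci)
    poss <- vector("list", nLoci)
    for (l in seq_len(nLoci)) {
        h <- coalescentHaplotypes(n, dem, cls@muSite, locusBp)
        mats[[l]] <- h$alleles
        poss[[l]] <- h$positions + (l - 1L) * locusBp
    }
    list(alleles = do.call(cbind, mats),
         positions = as.integer(unlist(poss)),
         totalBp = nLoci * locusBp)
}

.generateMasks <- function(cfg, seed) {
    set.seed(seed)
    masks <- list()
    for (label in names(cfg$loci)) {
        chrom <- .classChrom(label)
        total <- cfg$loci[[label]]$n * cfg$loci[[label]]$bp
        for (kind in c("genes", "repeats")) {
            dens <- if (kind == "genes") cfg$maskGeometry$genesPerMb
                    else cfg$maskGeometry$repeatsPerMb
            w <- if (kind == "genes") cfg$maskGeometry$geneBp
                 else cfg$maskGeometry$repeatBp
            k <- rpois(1L, dens * total / 1e6)
            if (k > 0L && total > w) {
                s0 <- sort(sample.int(total - w, k)) - 1L
                masks[[paste(chrom, kind, sep = ".")]] <-
                    maskSet(chrom, s0, s0 + w, kind)
            }
        }
    }
    masks
}

#' Generate a neutral synthetic study
#'
#' Draws haplotypes for every (population, class) pair from the neutral
#' coalescent under the class-correct effective sizes implied by each
#' population's demography and sex ratio R, places masks, and records the
#' generating truth in the manifest.
#'
#' @param cfg a [studyConfig()]
#' @param seed integer seed; the bundle is a deterministic function of
#'   (cfg, seed)
#' @return A [StudyBundle].
#' @examples
#' cfg <- studyConfig(loci = list(A = list(n = 4L, bp = 20000L),
#'                                X = list(n = 4L, bp = 20000L),
#'                                Y = list(n = 1L, bp = 50000L),
#'                                MT = list(n = 1L, bp = 16569L)))
#' b <- generateNeutralStudy(cfg, seed = 1)
#' @export
generateNeutralStudy <- function(cfg, seed = 1L) {
    masks <- .generateMasks(cfg, seed)
    haps <- list()
    for (pop in names(cfg$populations)) {
        p <- cfg$populations[[pop]]
        for (label in names(cfg$loci)) {
            cls <- cfg$classes[[label]]
            demC <- demographyForChromosome(p$dem, cls, p$R)
            n <- .classSampleN(label, cfg$nMales)
            sim <- .simulateClassHaplotypes(n, demC, cls,
                                            cfg$loci[[label]]$n,
                                            cfg$loci[[label]]$bp)
            haps[[paste(pop, label, sep = ".")]] <- makeHaplotypeMatrix(
                sim$alleles, sim$positions,
                .sampleNames(pop, label, cfg$nMales),
                GRanges(.classChrom(label), IRanges(1L, sim$totalBp)),
                cls)
        }
    }
    manifest <- list(
        seed = as.integer(seed), generator = "neutral",
        nMales = cfg$nMales,
        populations = lapply(cfg$populations, function(p)
            list(R = p$R, epochStart = as.numeric(p$dem@start),
                 epochSize = as.numeric(p$dem@size))),
        loci = cfg$loci,
        classes = lapply(cfg$classes, function(cl)
            list(label = cl@label, muSite = cl@muSite,
                 divergence = cl@divergence)))
    new("StudyBundle", haplotypes = haps, masks = masks,
        divergence = data.frame(
            class = names(cfg$classes),
            divergence = vapply(cfg$classes, divergence, numeric(1)),
            muSite = vapply(cfg$classes, muSite, numeric(1)),
            row.names = NULL),
        manifest = manifest)
}

#' Generate a study whose Y chromosome evolved under purifying selection
#'
#' As [generateNeutralStudy()], but the Y haplotypes of each population
#' come from the forward simulator with \code{Lsel} selected sites (gamma
#' DFE) linked to the neutral Y locus; all other classes are neutral. The
#' manifest stores the true L for downstream recovery scoring.
#'
#' @param cfg a [studyConfig()]
#' @param Lsel true number of selected sites (bp)
#' @param dfe a [GammaDFE]
#' @param lambda desk-rescaling factor for the forward runs (1 = the
#'   study-scale population)
#' @param burnInFactor burn-in in units of ancestral size
#' @param seed integer seed
#' @return A [StudyBundle] with \code{manifest$trueL} set.
#' @export
generateYWithSelection <- function(cfg, Lsel, dfe = GammaDFE(),
                                   lambda = 1, burnInFactor = 10,
                                   seed = 1L) {
    bundle <- generateNeutralStudy(cfg, seed)
    yBp <- cfg$loci$Y$n * cfg$loci$Y$bp
    for (pop in names(cfg$populations)) {
        p <- cfg$populations[[pop]]
        fcfg <- forwardConfig(yForwardDemography(p$dem, p$R), Lsel = Lsel,
                              neutralBp = yBp,
                              muSite = cfg$classes$Y@muSite, dfe = dfe,
                              sampleN = cfg$nMales,
                              burnInFactor = burnInFactor)
        if (lambda > 1) fcfg <- deskRescale(fcfg, lambda)
        rep <- runReplicate(fcfg, returnGenealogy = TRUE)
        hap <- .haplotypesFromGenealogy(rep$genealogy, rep$mutBranch, yBp)
        bundle@haplotypes[[paste(pop, "Y", sep = ".")]] <-
            makeHaplotypeMatrix(hap$alleles, hap$positions,
                                .sampleNames(pop, "Y", cfg$nMales),
                                GRanges(.classChrom("Y"),
                                        IRanges(1L, yBp)),
                                cfg$classes$Y)
    }
    bundle@manifest$generator <- "y_selection"
    bundle@manifest$trueL <- Lsel
    bundle@manifest$dfe <- list(shape = dfe@shape, scale = dfe@scale,
                                nHapRef = dfe@nHapRef)
    bundle@manifest$lambda <- lambda
    bundle
}

#' Deterministic toy bundle with hand-computable statistics
#'
#' A tiny fixed dataset (no random number generation) whose summary
#' statistics are documented from first principles:
#'
#' Y class, 4 haplotypes over callable 1000 bp with variant columns
#' (0,0,1,1), (0,0,1,1), (0,0,0,1): the 6 sample pairs differ at
#' 0+2+3+2+3+1 = 11 sites, so pi = 11/(6*1000) = 0.0018333; S = 3; folded
#' SFS = (1 site at minor count 1, 2 sites at minor count 2).
#'
#' A class, 4 haplotypes over callable 500 bp with columns (0,1,1,0) and
#' (0,0,1,1): pair differences sum to 4+4 = 8, pi = 8/(6*500) = 0.0026667;
#' S = 2.
#'
#' A "genes" mask covers the Y interval \[100, 200), containing the
#' variant at position 150: masking drops it (S = 2, callable 900 bp).
#'
#' @return A [StudyBundle] with one population "toy" and classes Y and A.
#' @export
toyFixture <- function() {
    clsY <- chromosomeClass("Y")
    clsA <- chromosomeClass("A")
    yAll <- rbind(c(0L, 0L, 0L), c(0L, 0L, 0L), c(1L, 1L, 0L),
                  c(1L, 1L, 1L))
    hmY <- makeHaplotypeMatrix(yAll, c(50L, 150L, 400L),
                               paste0("toy_m", 1:4), 1000, clsY)
    aAll <- rbind(c(0L, 0L), c(1L, 0L), c(1L, 1L), c(0L, 1L))
    hmA <- makeHaplotypeMatrix(aAll, c(10L, 250L),
                               c("toy_m1_h1", "toy_m1_h2",
                                 "toy_m2_h1", "toy_m2_h2"), 500, clsA)
    new("StudyBundle",
        haplotypes = list(toy.Y = hmY, toy.A = hmA),
        masks = list(synth_Y.genes = maskSet("synth_Y", 100, 200,
                                             "genes")),
        divergence = data.frame(class = c("Y", "A"),
                                divergence = c(clsY@divergence,
                                               clsA@divergence),
                                muSite = c(clsY@muSite, clsA@muSite)),
        manifest = list(seed = 0L, generator = "toy", nMales = 4L,
                        loci = list(Y = list(n = 1L, bp = 1000L),
                                    A = list(n = 1L, bp = 500L))))
}

# ---- writers and readers ------------------------------------------------

.writeVcf <- function(hm, file) {
    chrom <- as.character(seqnames(hm@callable))[1L]
    total <- max(end(hm@callable))
    hdr <- c("##fileformat=VCFv4.2",
             "##source=Ypopgen-synthetic",
             sprintf("##contig=<ID=%s,length=%d>", chrom, total),
             paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                    "Description=\"Genotype\">"))
    diploid <- hm@cls@label == "A"
    if (diploid) {
        ids <- unique(sub("_h[12]$", "", hm@samples))
        gtOf <- function(col) {
            h <- hm@alleles[, col]
            paste(h[seq(1L, length(h), 2L)], h[seq(2L, length(h), 2L)],
                  sep = "|")
        }
    } else {
        ids <- hm@samples
        gtOf <- function(col) as.character(hm@alleles[, col])
    }
    hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                          "FILTER", "INFO", "FORMAT", ids),
                        collapse = "\t"))
    lines <- hdr
    if (ncol(hm@alleles)) {
        body <- vapply(seq_len(ncol(hm@alleles)), function(j) {
            paste(c(chrom, hm@positions[j] + 1L, ".", "A", "T", ".",
                    "PASS", ".", "GT", gtOf(j)), collapse = "\t")
        }, character(1))
        lines <- c(lines, body)
    }
    writeLines(lines, file)
}

.readVcf <- function(file, samples, cls, callable) {
    v <- vcfR::read.vcfR(file, verbose = FALSE)
    if (nrow(v@fix) == 0L) {
        n <- length(samples)
        return(makeHaplotypeMatrix(matrix(0L, n, 0), integer(0), samples,
                                   callable, cls))
    }
    multi <- grepl(",", v@fix[, "ALT"])
    if (any(multi)) {
        message(sum(multi), " multiallelic site(s) excluded")
        v@fix <- v@fix[!multi, , drop = FALSE]
        v@gt <- v@gt[!multi, , drop = FALSE]
    }
    gt <- vcfR::extract.gt(v)
    pos1 <- as.integer(v@fix[, "POS"])
    haps <- list()
    for (s in colnames(gt)) {
        fields <- strsplit(gt[, s], "[|/]")
        k <- length(fields[[1L]])
        for (h in seq_len(k)) {
            nm <- if (k > 1L) sprintf("%s_h%d", s, h) else s
            haps[[nm]] <- as.integer(vapply(fields, `[`, character(1), h))
        }
    }
    alleles <- do.call(rbind, haps)
    if (any(is.na(alleles)))
        stop("missing genotypes in ", file,
             ": sites must be called in all individuals")
    alleles <- alleles[samples, , drop = FALSE]
    makeHaplotypeMatrix(alleles, pos1 - 1L, samples, callable, cls)
}

#' Write or read a study bundle
#'
#' `writeBundle` serializes a [StudyBundle] to a directory: one VCF per
#' (population, class) (diploid phased genotypes for autosomes, haploid
#' otherwise), one BED per mask set, a divergence TSV and a YAML manifest
#' (which also records sample names and callable intervals so that
#' `readBundle` inverts the write exactly).
#'
#' @param b a [StudyBundle]
#' @param dir directory to write to (created if needed)
#' @return `writeBundle` returns \code{dir} invisibly; `readBundle`
#'   returns the reconstructed [StudyBundle].
#' @export
writeBundle <- function(b, dir) {
    stopifnot(is(b, "StudyBundle"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    io <- list()
    for (key in names(b@haplotypes)) {
        hm <- b@haplotypes[[key]]
        f <- paste0(key, ".vcf")
        .writeVcf(hm, file.path(dir, f))
        io[[key]] <- list(
            file = f, class = hm@cls@label, samples = hm@samples,
            muSite = hm@cls@muSite, divergence = hm@cls@divergence,
            callableStart0 = as.integer(start(hm@callable) - 1L),
            callableEnd0 = as.integer(end(hm@callable)))
    }
    for (mk in names(b@masks)) {
        gr <- b@masks[[mk]]
        bed <- data.frame(chrom = as.character(seqnames(gr)),
                          start = start(gr) - 1L, end = end(gr),
                          name = mcols(gr)$label)
        write.table(bed, file.path(dir, paste0(mk, ".bed")),
                    sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
    }
    write.table(b@divergence, file.path(dir, "divergence.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- b@manifest
    manifest$io <- io
    manifest$maskFiles <- as.list(setNames(paste0(names(b@masks), ".bed"),
                                           names(b@masks)))
    yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
    invisible(dir)
}

#' @rdname writeBundle
#' @export
readBundle <- function(dir) {
    mf <- file.path(dir, "manifest.yaml")
    if (!file.exists(mf)) stop("missing manifest: ", mf)
    manifest <- yaml::read_yaml(mf)
    io <- manifest$io
    haps <- list()
    for (key in names(io)) {
        info <- io[[key]]
        cls <- chromosomeClass(info$class, muSite = info$muSite,
                               divergence = info$divergence)
        callable <- GRanges(.classChrom(info$class),
                            IRanges(unlist(info$callableStart0) + 1L,
                                    unlist(info$callableEnd0)))
        haps[[key]] <- .readVcf(file.path(dir, info$file),
                                unlist(info$samples), cls, callable)
    }
    masks <- list()
    for (mk in names(manifest$maskFiles)) {
        bed <- read.table(file.path(dir, manifest$maskFiles[[mk]]),
                          sep = "\t",
                          col.names = c("chrom", "start", "end", "name"))
        masks[[mk]] <- maskSet(bed$chrom, bed$start, bed$end,
                               bed$name[1L])
    }
    div <- read.table(file.path(dir, "divergence.tsv"), sep = "\t",
                      header = TRUE)
    manifest$io <- NULL
    manifest$maskFiles <- NULL
    new("StudyBundle", haplotypes = haps, masks = masks,
        divergence = div, manifest = manifest)
}

#' Read haplotypes from a VCF file
#'
#' Parses a VCF (via \pkg{vcfR}) with haploid or phased diploid GT fields
#' into a [HaplotypeMatrix]. Multiallelic sites are excluded (with a
#' message); any missing genotype is an error, since sites must be called
#' in all individuals.
#'
#' @param file path to a VCF
#' @param cls a [ChromosomeClass]
#' @param callable callable intervals (\code{GRanges}) or a single total
#'   length
#' @param samples optional haplotype-row names enforcing order; defaults
#'   to the file's sample columns (suffixed _h1/_h2 when diploid)
#' @return A [HaplotypeMatrix].
#' @export
readHaplotypesVcf <- function(file, cls, callable, samples = NULL) {
    if (is.numeric(callable))
        callable <- GRanges(.classChrom(cls@label),
                            IRanges(1L, as.integer(callable)))
    if (is.null(samples)) {
        v <- vcfR::read.vcfR(file, verbose = FALSE)
        gt <- vcfR::extract.gt(v)
        diploid <- grepl("[|/]", gt[1L, 1L])
        samples <- if (diploid)
            as.vector(rbind(paste0(colnames(gt), "_h1"),
                            paste0(colnames(gt), "_h2")))
        else colnames(gt)
    }
    .readVcf(file, samples, cls, callable)
}

#' Sex-ratio estimate from a study bundle
#'
#' Runs the estimation path on bundle data: applies all masks (with the
#' far-from-genes flank) to the X and autosomal haplotypes of each
#' population, computes normalized diversity, and inverts the X/A ratio.
#'
#' @param b a [StudyBundle]
#' @param farFromGenesBp flank around gene masks (default 100 kb)
#' @return data.frame with one row per population: piXStar, piAStar, Q, R.
#' @export
sexRatioFromBundle <- function(b, farFromGenesBp = 1e5) {
    pops <- unique(sub("\\.[^.]+$", "", names(b@haplotypes)))
    rows <- lapply(pops, function(pop) {
        star <- vapply(c("X", "A"), function(label) {
            hm <- b@haplotypes[[paste(pop, label, sep = ".")]]
            if (length(b@masks))
                hm <- applyMasks(hm, b@masks, farFromGenesBp)
            normalizeByDivergence(pairwisePi(hm), hm@cls@divergence)
        }, numeric(1))
        est <- estimateNmNf(star[["X"]], star[["A"]])
        data.frame(population = pop, piXStar = star[["X"]],
                   piAStar = star[["A"]], Q = est$Q, R = est$R)
    })
    do.call(rbind, rows)
}
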