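#' Per-region neutral mutation rate
#'
#' @param bp base pairs with data (>= 0)
#' @param muSite per-site per-generation mutation rate
#' @return The per-region per-generation rate \code{bp * muSite}.
#' @examples
#' regionMu(7758906, 3.42e-8)   # 0.265
#' regionMu(5e5, 3.42e-8)       # 0.0171, the simulated-region rate
#' @export
regionMu <- function(bp, muSite) {
    if (bp < 0) stop("bp must be >= 0")
    bp * muSite
}

.logSumExp <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
}

#' Approximate log-likelihood of L from one reference pool
#'
#' The likelihood of the observed segregating-site count is approximated by
#' a Poisson mixture over simulated replicates: under infinite sites,
#' \eqn{S_{obs} \mid T} is Poisson with mean \eqn{\mu T}, and each
#' simulated count \eqn{S^*_i} stands in for its replicate's total
#' genealogy length via \eqn{T^*_i \approx S^*_i/\mu_{sim}}. Hence
#' \deqn{\hat{L}(L) = \frac{1}{k} \sum_{i=1}^{k}
#'   \Pr\!\left(S_{obs} ;\, \mathrm{Poisson}\!\left(
#'   \frac{\mu}{\mu_{sim}} S^*_i\right)\right),}
#' evaluated in log space with log-sum-exp. A replicate with
#' \eqn{S^*_i = 0} contributes probability 1 if \eqn{S_{obs} = 0} and 0
#' otherwise. If every term has probability zero the function returns
#' \code{-Inf} (so that grid scans continue past impossible values).
#'
#' @param pool a [ReferencePool]
#' @param Sobs observed segregating-site count in the neutral region
#' @param mu per-region per-generation neutral mutation rate of the
#'   observed data (see [regionMu()])
#' @return The approximate log-likelihood (may be \code{-Inf}).
#' @examples
#' p <- ReferencePool(1e6, Sstar = c(10L, 20L), muSim = 1)
#' loglikForL(p, Sobs = 10, mu = 1)
#' log(0.5 * (dpois(10, 10) + dpois(10, 20)))
#' @export
loglikForL <- function(pool, Sobs, mu) {
    stopifnot(is(pool, "ReferencePool"))
    if (Sobs < 0) stop("Sobs must be >= 0")
    lambda <- (mu / pool@muSim) * pool@Sstar
    .logSumExp(dpois(Sobs, lambda, log = TRUE)) - log(length(lambda))
}

#' Build reference pools over a grid of L
#'
#' Runs the forward simulator at each grid value of L (all other
#' configuration fixed) and collects the segregating-site counts of the
#' simulated neutral region. The pools depend only on the model, not the
#' data, so one set serves any number of observed datasets.
#'
#' @param grid numeric vector of L values (bp), sorted ascending
#' @param cfg a [ForwardConfig]; its \code{Lsel} is overridden per grid
#'   point and its \code{neutralBp}/\code{muSite} define \eqn{\mu_{sim}}
#' @param k replicates per grid point
#' @return Named list of [ReferencePool], one per grid value.
#' @export
buildReferencePools <- function(grid, cfg, k) {
    if (is.unsorted(grid, strictly = TRUE)) stop("grid must be sorted")
    muSim <- cfg@muSite * cfg@neutralBp
    pools <- vector("list", length(grid))
    for (i in seq_along(grid)) {
        cfgL <- cfg
        cfgL@Lsel <- grid[i]
        reps <- batchReplicates(cfgL, k, trackSelected = FALSE)
        pools[[i]] <- ReferencePool(grid[i], reps$Sneutral, muSim)
    }
    names(pools) <- format(grid, scientific = FALSE, trim = TRUE)
    pools
}

# interpolated crossing of `cutoff` between grid points (x1,y1) and
# (x2,y2); non-finite log-likelihoods are clamped far below the cutoff
.crossing <- function(x1, y1, x2, y2, cutoff) {
    clamp <- cutoff - 700
    if (!is.finite(y1)) y1 <- clamp
    if (!is.finite(y2)) y2 <- clamp
    x1 + (cutoff - y1) / (y2 - y1) * (x2 - x1)
}

.fitFromCurve <- function(L, logLik) {
    if (all(!is.finite(logLik)))
        stop("log-likelihood is -Inf over the entire grid")
    imax <- which.max(logLik)
    cutoff <- logLik[imax] - 1.92
    n <- length(L)

    lower <- L[1L]; lowerBound <- TRUE
    if (imax > 1L) for (i in seq(imax - 1L, 1L)) {
        if (!is.finite(logLik[i]) || logLik[i] < cutoff) {
            lower <- .crossing(L[i], logLik[i], L[i + 1L], logLik[i + 1L],
                               cutoff)
            lowerBound <- FALSE
            break
        }
    }
    upper <- L[n]; upperBound <- TRUE
    if (imax < n) for (i in seq(imax + 1L, n)) {
        if (!is.finite(logLik[i]) || logLik[i] < cutoff) {
            upper <- .crossing(L[i - 1L], logLik[i - 1L], L[i], logLik[i],
                               cutoff)
            upperBound <- FALSE
            break
        }
    }
    new("LikelihoodResult",
        grid = data.frame(L = L, logLik = logLik),
        mleL = L[imax], ci = c(lower, upper),
        boundary = c(lowerBound, upperBound))
}

#' MLE and interpolated confidence interval from a log-likelihood curve
#'
#' The curve machinery behind [fitL()], exposed for direct use: grid
#' argmax plus the 1.92-unit cutoff located by linear interpolation
#' between grid points, with censoring flags at the grid edges.
#'
#' @param L grid values (ascending)
#' @param logLik log-likelihood at each grid value
#' @return A [LikelihoodResult].
#' @examples
#' fitCurve(1:4, c(-3, -1, -1.5, -4))   # MLE 2, CI (1.04, 3.568)
#' @export
fitCurve <- function(L, logLik) {
    if (length(L) != length(logLik) || length(L) < 2L)
        stop("L and logLik must be parallel, length >= 2")
    if (is.unsorted(L, strictly = TRUE)) stop("L must be sorted")
    .fitFromCurve(L, logLik)
}

#' Grid maximum-likelihood fit for the number of selected sites
#'
#' Evaluates [loglikForL()] on every pool, takes the grid argmax as the
#' MLE, and forms an asymptotic 95\% confidence interval from all points
#' within 1.92 log-likelihood units of the maximum, locating the cutoff
#' between grid points by linear interpolation. When the curve never drops
#' below the cutoff before a grid edge, the edge is reported and the
#' corresponding boundary flag set (a censored bound).
#'
#' @param pools list of [ReferencePool] with strictly increasing \code{L}
#' @param Sobs observed segregating-site count
#' @param mu per-region neutral mutation rate of the observed data
#' @return A [LikelihoodResult].
#' @examples
#' pools <- list(ReferencePool(1e5, 5L, 0.0171),
#'               ReferencePool(1e6, 15L, 0.0171))
#' fitL(pools, Sobs = 80, mu = 0.265)
#' @export
fitL <- function(pools, Sobs, mu) {
    if (length(pools) < 2L) stop("need at least 2 grid points")
    L <- vapply(pools, function(p) p@L, numeric(1))
    if (is.unsorted(L, strictly = TRUE)) stop("pool grid must be sorted")
    ll <- vapply(pools, loglikForL, numeric(1), Sobs = Sobs, mu = mu)
    .fitFromCurve(L, unname(ll))
}

#' Profile likelihood over L with a nuisance DFE scale
#'
#' Joint fit over a two-dimensional grid of L and DFE scale parameters:
#' for each L the profile log-likelihood is the maximum over scales, and
#' the MLE/CI machinery of [fitL()] is applied to the profile curve. With
#' a single scale this reduces exactly to [fitL()].
#'
#' @param pools flat list of [ReferencePool] covering the (L, scale) grid
#' @param scales numeric vector parallel to \code{pools} giving each
#'   pool's DFE scale
#' @param Sobs,mu as in [fitL()]
#' @return A [LikelihoodResult] for the profile curve; its grid carries
#'   the maximizing scale per L in column \code{scale}.
#' @export
profileFitL <- function(pools, scales, Sobs, mu) {
    if (length(pools) != length(scales))
        stop("pools and scales must be parallel")
    L <- vapply(pools, function(p) p@L, numeric(1))
    ll <- vapply(pools, loglikForL, numeric(1), Sobs = Sobs, mu = mu)
    uL <- sort(unique(L))
    if (length(uL) < 2L) stop("need at least 2 distinct L values")
    prof <- numeric(length(uL))
    bestScale <- numeric(length(uL))
    for (i in seq_along(uL)) {
        sel <- which(L == uL[i])
        j <- sel[which.max(ll[sel])]
        prof[i] <- ll[j]
        bestScale[i] <- scales[j]
    }
    res <- .fitFromCurve(uL, prof)
    res@grid$scale <- bestScale
    res
}

#' Parameter-recovery experiment for the approximate likelihood
#'
#' Simulates \code{nDatasets} datasets at a known true L (each dataset's
#' observed statistic is the segregating-site count of an
#' \code{obsNeutralBp} neutral region linked to the selected sites), builds
#' one shared set of reference pools over the grid, fits every dataset,
#' and reports the mean and median MLE and the fraction of 95\% confidence
#' intervals containing the truth.
#'
#' @param trueL true number of selected sites (bp); must be on the grid
#' @param cfg a [ForwardConfig] template (its \code{neutralBp} is the
#'   simulated pool region defining \eqn{\mu_{sim}})
#' @param nDatasets number of simulated observed datasets
#' @param grid L grid (bp, ascending)
#' @param kPerGrid reference replicates per grid point
#' @param obsNeutralBp neutral region size of the simulated observed data
#' @param seed optional integer seed
#' @return list with \code{meanMLE}, \code{medianMLE}, \code{coverage}
#'   (fraction of CIs containing trueL), \code{mles}, \code{cis}
#'   (nDatasets x 2), \code{Sobs}, and the shared \code{pools}.
#' @export
recoveryExperiment <- function(trueL, cfg, nDatasets, grid,
                               kPerGrid = 200, obsNeutralBp = 7.5e6,
                               seed = NULL) {
    if (!trueL %in% grid) stop("grid must contain trueL")
    if (!is.null(seed)) set.seed(seed)
    pools <- buildReferencePools(grid, cfg, kPerGrid)
    cfgData <- cfg
    cfgData@Lsel <- trueL
    cfgData@neutralBp <- obsNeutralBp
    dataReps <- batchReplicates(cfgData, nDatasets,
                                trackSelected = FALSE)
    mu <- cfg@muSite * obsNeutralBp
    mles <- numeric(nDatasets)
    cis <- matrix(NA_real_, nDatasets, 2L)
    for (d in seq_len(nDatasets)) {
        fit <- fitL(pools, dataReps$Sneutral[d], mu)
        mles[d] <- fit@mleL
        cis[d, ] <- fit@ci
    }
    list(meanMLE = mean(mles), medianMLE = median(mles),
         coverage = mean(cis[, 1L] <= trueL & trueL <= cis[, 2L]),
         mles = mles, cis = cis, Sobs = dataReps$Sneutral, pools = pools)
}
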