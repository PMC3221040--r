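# Benjamini-Hochberg control over topological features, and the four
# decision procedures: peak-FWE, peak-FDR, cluster-FDR, voxel-FDR.

.checkP <- function(pvals) {
    if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1))
        stop("p-values must lie in [0, 1]")
}

#' Benjamini-Hochberg step-up selection
#'
#' Applies the BH step-up rule to a set of p-values: with order statistics
#' \eqn{p_{(1)} \le \dots \le p_{(m)}}, finds \eqn{k = \max\{j : p_{(j)}
#' \le j\alpha/m\}} and rejects the k smallest. Independence of the peak
#' p-values is assumed (Poisson clumping); the Benjamini-Yekutieli
#' variant, valid under arbitrary dependence, is available via
#' \code{method = "BY"}.
#'
#' @param pvals p-values in [0, 1]; may be empty.
#' @param alpha FDR level in (0, 1).
#' @param method \code{"BH"} (default) or \code{"BY"}.
#' @return list with \code{k} (number of rejections) and
#'   \code{threshold} (the adaptive p-value cutoff \eqn{p_{(k)}}, 0 when
#'   nothing is rejected).
#' @examples
#' bhSelect(c(0.01, 0.02, 0.5), alpha = 0.05)  # k = 2, threshold 0.02
#' @export
bhSelect <- function(pvals, alpha, method = c("BH", "BY")) {
    method <- match.arg(method)
    if (length(alpha) != 1L || alpha <= 0 || alpha >= 1)
        stop("alpha must lie strictly between 0 and 1")
    .checkP(pvals)
    m <- length(pvals)
    if (m == 0L) return(list(k = 0L, threshold = 0))
    ps <- sort(pvals)
    crit <- seq_len(m) * alpha / m
    if (method == "BY") crit <- crit / sum(1 / seq_len(m))
    ok <- which(ps <= crit)
    if (length(ok) == 0L) return(list(k = 0L, threshold = 0))
    k <- max(ok)
    list(k = k, threshold = ps[k])
}

#' FDR-adjusted p-values (q-values)
#'
#' The BH step-up adjusted p-value of each feature: the smallest FDR level
#' at which it would be rejected, \eqn{q_{(i)} = \min_{j \ge i} m
#' p_{(j)}/j} clipped at 1. \code{bhSelect(p, alpha)} rejects exactly the
#' features with \eqn{q \le \alpha}.
#'
#' @inheritParams bhSelect
#' @return q-values in input order, \code{q >= p} elementwise.
#' @examples
#' qValues(c(0.01, 0.02, 0.5))  # 0.03 0.03 0.50
#' @export
qValues <- function(pvals, method = c("BH", "BY")) {
    method <- match.arg(method)
    .checkP(pvals)
    p.adjust(pvals, method = method)
}

.marginalP <- function(z, field) {
    if (field@family == "gaussian") pnorm(z, lower.tail = FALSE)
    else pt(z, df = field@dof, lower.tail = FALSE)
}

#' Run one of the four thresholding procedures on an SPM
#'
#' Applies a decision procedure at level \code{alpha} to a statistical
#' map:
#' \describe{
#'   \item{\code{peak_fwe}}{harvest peaks above \code{u}; keep those whose
#'     FWE-corrected peak p-value (expected number of higher peaks in the
#'     search space) is at most \code{alpha}.}
#'   \item{\code{peak_fdr}}{BH over the conditional peak p-values
#'     \eqn{\rho_D(z)/\rho_D(u)} of all harvested peaks.}
#'   \item{\code{cluster_fdr}}{BH over the conditional extent p-values of
#'     all clusters above \code{u}; discovered peaks are every peak inside
#'     a significant cluster.}
#'   \item{\code{voxel_fdr}}{BH over the marginal upper-tail p-value of
#'     every in-mask voxel; the surviving voxel set is summarised, for
#'     comparison with the topological procedures, by the local maxima it
#'     contains (no height threshold \code{u} is involved).}
#' }
#'
#' @param map numeric array, the SPM; \code{NA} = out of mask.
#' @param procedure one of \code{"peak_fwe"}, \code{"peak_fdr"},
#'   \code{"cluster_fdr"}, \code{"voxel_fdr"}.
#' @param alpha error level (default 0.05).
#' @param u feature-defining threshold; required except for
#'   \code{voxel_fdr}.
#' @param space a \code{\link{SearchSpace}} matching \code{map}.
#' @param field a \code{\link{FieldSpec}}.
#' @param connectivity cluster connectivity (default 18).
#' @param peakConnectivity connectivity for maxima (default 26).
#' @param method \code{"BH"} or \code{"BY"} for the FDR procedures.
#' @return a \code{\link{ProcedureResult}}.
#' @examples
#' sp <- SearchSpace(c(32, 32, 16), fwhm = 4)
#' sim <- simulateSpm(nActivations = 4, shape = c(32, 32, 16), seed = 1)
#' runProcedure(sim$map, "peak_fdr", u = 2.5, space = sp, field = sim$field)
#' @export
runProcedure <- function(map, procedure = c("peak_fwe", "peak_fdr",
                             "cluster_fdr", "voxel_fdr"),
                         alpha = 0.05, u = NULL, space, field,
                         connectivity = 18L, peakConnectivity = 26L,
                         method = c("BH", "BY")) {
    procedure <- match.arg(procedure)
    method <- match.arg(method)
    stopifnot(is(space, "SearchSpace"), is(field, "FieldSpec"))
    map <- .as3d(map)
    if (!identical(dim(map)[seq_along(space@shape)], space@shape))
        stop("map shape does not match the search space")
    if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)")
    if (procedure != "voxel_fdr" && is.null(u))
        stop(procedure, " requires a feature-defining threshold u")

    emptyPeaks <- data.frame(i = integer(), j = integer(), k = integer(),
        height = numeric(), p_unc = numeric(), p_fwe = numeric(),
        q = numeric(), cluster = integer())
    emptyClusters <- data.frame(cluster = integer(), nVoxels = integer(),
        maxHeight = numeric(), extent_resels = numeric(),
        p_unc = numeric(), q = numeric())
    res <- function(pk, cl = emptyClusters, thr = 0, nHarv = 0L, u. = u)
        new("ProcedureResult", procedure = procedure, alpha = alpha,
            u = if (is.null(u.)) NA_real_ else as.numeric(u.),
            peaks = pk, clusters = cl, adaptiveThreshold = as.numeric(thr),
            nHarvested = as.integer(nHarv))

    if (procedure == "voxel_fdr") {
        inMask <- !is.na(map)
        pv <- .marginalP(map[inMask], field)
        sel <- bhSelect(pv, alpha, method)
        if (sel$k == 0L) return(res(emptyPeaks, nHarv = sum(inMask)))
        # survivors are exactly {z >= z*}; their local maxima summarise
        # the discovery set topologically
        zstar <- min(map[inMask][pv <= sel$threshold])
        pk <- findLocalMaxima(map, u = zstar * (1 - 1e-12) - 1e-12,
                              connectivity = peakConnectivity)
        pk$p_unc <- .marginalP(pk$height, field)
        pk$p_fwe <- peakPFwe(pk$height, space, field)
        pk$q <- qValues(pv, method)[match(pk$p_unc, pv)]
        pk$cluster <- NA_integer_
        return(res(pk, thr = sel$threshold, nHarv = sum(inMask)))
    }

    es <- labelClusters(map, u, connectivity, peakConnectivity)
    pk <- peaks(es)
    if (nrow(pk) == 0L) return(res(emptyPeaks))
    fwhmVox <- space@fwhm / space@voxelSize
    clAll <- clusters(es)
    clAll$extent_resels <- clAll$nVoxels / prod(fwhmVox)

    if (procedure %in% c("peak_fwe", "peak_fdr")) {
        if (procedure == "peak_fdr" && nrow(pk) < 20L)
            warning("only ", nrow(pk), " peaks harvested; FDR control over",
                    " so few features is of limited meaning")
        pk$p_unc <- suppressWarnings(
            peakPUncorrected(pk$height, u, field))
        pk$p_fwe <- peakPFwe(pk$height, space, field)
        if (procedure == "peak_fwe") {
            pk$q <- NA_real_
            keep <- pk$p_fwe <= alpha
            thr <- fweThreshold(alpha, space, field)
        } else {
            pk$q <- qValues(pk$p_unc, method)
            sel <- bhSelect(pk$p_unc, alpha, method)
            keep <- pk$q <= alpha
            thr <- sel$threshold
        }
        return(res(pk[keep, , drop = FALSE], cl = clAll, thr = thr,
                   nHarv = nrow(pk)))
    }

    # cluster_fdr
    cl <- clAll
    if (nrow(cl) == 0L) return(res(emptyPeaks))
    cl$p_unc <- suppressWarnings(
        clusterExtentP(cl$extent_resels, u, space, field))
    cl$q <- qValues(cl$p_unc, method)
    sel <- bhSelect(cl$p_unc, alpha, method)
    sig <- cl[cl$q <= alpha, , drop = FALSE]
    pk <- pk[pk$cluster %in% sig$cluster, , drop = FALSE]
    if (nrow(pk)) {
        pk$p_unc <- suppressWarnings(peakPUncorrected(pk$height, u, field))
        pk$p_fwe <- peakPFwe(pk$height, space, field)
        pk$q <- sig$q[match(pk$cluster, sig$cluster)]
    } else pk <- emptyPeaks
    res(pk, cl = sig, thr = sel$threshold, nHarv = nrow(cl))
}
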