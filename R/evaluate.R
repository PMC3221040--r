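# Performance metrics for thresholding procedures: minimum distances from
# discovered to true peaks, spatial-accuracy CDFs and their contrasts, and
# sensitivity ratios relative to peak-FWE.

#' Minimum distance from each discovery to the nearest true peak
#'
#' For each discovered peak \eqn{X_i}, the minimum over true activation
#' locations \eqn{\mu_j} of the Euclidean distance
#' \eqn{D_i = \min_j \|X_i - \mu_j\|}. This is the spatial-accuracy
#' currency of the evaluation harness: small distances mean discoveries
#' sit on true activations.
#'
#' @param discoveries a \code{\link{ProcedureResult}}, or a data frame
#'   with columns \code{i, j, k}.
#' @param truth a \code{\link{SimulationTruth}} with at least one
#'   activation.
#' @param voxelSize mm per voxel, per axis (default 1: distances in
#'   voxels).
#' @return numeric vector, one distance per discovery (length 0 when
#'   there are none).
#' @examples
#' tr <- sampleSignal(2, c(32, 32, 16), seed = 1)$truth
#' mu1 <- truePeaks(tr)[1, ]
#' minDistances(data.frame(i = mu1[1], j = mu1[2], k = mu1[3]), tr)  # 0
#' @export
minDistances <- function(discoveries, truth, voxelSize = 1) {
    if (is(discoveries, "ProcedureResult")) discoveries <- peaks(discoveries)
    stopifnot(is(truth, "SimulationTruth"))
    if (nrow(truth@mu) == 0L)
        stop("truth has no activations: minimum distance is undefined")
    if (nrow(discoveries) == 0L) return(numeric(0))
    voxelSize <- rep_len(voxelSize, 3L)
    X <- as.matrix(discoveries[, c("i", "j", "k")])
    M <- truth@mu
    vapply(seq_len(nrow(X)), function(r) {
        d2 <- (sweep(M, 2L, X[r, ]) %*% diag(voxelSize, 3L))^2
        sqrt(min(rowSums(d2)))
    }, numeric(1))
}

#' Empirical spatial-accuracy CDF
#'
#' The empirical cumulative distribution \eqn{\Phi_{proc}(d)} of the
#' minimum-distance statistics pooled over replicates, evaluated on a
#' common distance grid.
#'
#' @param distances numeric vector of minimum distances.
#' @param grid distance grid (default 0 to 16 voxels in steps of 0.25).
#' @param procedure optional label stored alongside the curve.
#' @return data frame with columns \code{procedure}, \code{d},
#'   \code{phi}; \code{phi} is non-decreasing in \code{d}.
#' @export
accuracyCurve <- function(distances, grid = seq(0, 16, by = 0.25),
                          procedure = NA_character_) {
    phi <- if (length(distances)) ecdf(distances)(grid)
           else rep(NA_real_, length(grid))
    data.frame(procedure = procedure, d = grid, phi = phi)
}

#' Accuracy contrast between a procedure and peak-FWE
#'
#' The pointwise difference \eqn{\Phi_{FWE}(d) - \Phi_{proc}(d)} between
#' the spatial-accuracy CDF of the peak-FWE reference and that of another
#' procedure, on their shared distance grid. Positive values mean the
#' procedure's discoveries lie further from true peaks than FWE's do. The
#' paired CDF values are retained for ROC-style plots of
#' \eqn{\Phi_{FWE}} against \eqn{\Phi_{proc}}.
#'
#' @param curveFwe,curveProc accuracy curves from
#'   \code{\link{accuracyCurve}} on identical grids.
#' @return data frame with columns \code{d}, \code{contrast},
#'   \code{phiFwe}, \code{phiProc}.
#' @export
accuracyContrast <- function(curveFwe, curveProc) {
    if (!isTRUE(all.equal(curveFwe$d, curveProc$d)))
        stop("accuracy curves must share a common distance grid")
    data.frame(d = curveFwe$d, contrast = curveFwe$phi - curveProc$phi,
               phiFwe = curveFwe$phi, phiProc = curveProc$phi)
}

#' Sensitivity ratio relative to peak-FWE
#'
#' The ratio of total discoveries made by a procedure to total peak-FWE
#' discoveries on the same simulated maps, pooled over replicates. Values
#' above 1 mean the procedure is more sensitive than FWE control.
#'
#' @param resultsProc,resultsFwe lists of \code{\link{ProcedureResult}}s
#'   (or numeric vectors of per-replicate discovery counts) from
#'   identical simulated maps, in the same replicate order.
#' @return list with \code{r} (the ratio; \code{NaN} for 0/0, \code{Inf}
#'   for x/0, both with a warning), \code{nProc} and \code{nFwe} (pooled
#'   counts).
#' @export
sensitivityRatio <- function(resultsProc, resultsFwe) {
    count <- function(x) {
        if (is.numeric(x)) return(x)
        vapply(x, function(r) nrow(peaks(r)), numeric(1))
    }
    np <- count(resultsProc); nf <- count(resultsFwe)
    if (length(np) != length(nf))
        stop("batches must contain the same number of replicates")
    np <- sum(np); nf <- sum(nf)
    r <- np / nf
    if (nf == 0)
        warning(if (np == 0) "0/0 discoveries: ratio undefined"
                else "no FWE discoveries: ratio infinite")
    list(r = r, nProc = np, nFwe = nf)
}

#' Run a full simulation-and-evaluation experiment
#'
#' For each replicate and each number of activations, simulates an SPM
#' and applies the four procedures (peak-FWE, peak-FDR, cluster-FDR,
#' voxel-FDR) at every feature-defining threshold in \code{u}, recording
#' each discovery's distance to the nearest true peak and the discovery
#' counts. Deterministic given \code{seed}.
#'
#' @param replicates number of simulated SPMs per condition.
#' @param nActivations numbers of true activations to simulate (vector).
#' @param u feature-defining thresholds (vector).
#' @param shape,nVolumes,noiseFwhm simulation geometry; see
#'   \code{\link{simulateSpm}}.
#' @param alpha error level for every procedure.
#' @param procedures subset of the four procedures to run.
#' @param seed master RNG seed.
#' @param verbose print progress.
#' @return list of tidy data frames: \code{distances} (procedure, u, n,
#'   replicate, D) and \code{counts} (procedure, u, n, replicate,
#'   nDiscoveries).
#' @examples
#' ex <- runExperiment(replicates = 1, nActivations = 8, u = 2.5,
#'                     shape = c(32, 32, 16), seed = 1)
#' head(ex$counts)
#' @export
runExperiment <- function(replicates, nActivations = c(2, 4, 8, 16, 32, 64),
                          u = c(2.5, 3.5, 4.5, 5.5),
                          shape = c(64L, 64L, 32L), nVolumes = 16L,
                          noiseFwhm = 4, alpha = 0.05,
                          procedures = c("peak_fwe", "peak_fdr",
                                         "cluster_fdr", "voxel_fdr"),
                          seed = 1L, verbose = FALSE) {
    set.seed(seed)
    dist <- list(); cnt <- list(); idx <- 0L
    for (n in nActivations) for (rep. in seq_len(replicates)) {
        sim <- simulateSpm(n, shape = shape, nVolumes = nVolumes,
                           noiseFwhm = noiseFwhm)
        vox <- if ("voxel_fdr" %in% procedures)
            suppressWarnings(runProcedure(sim$map, "voxel_fdr",
                alpha = alpha, space = sim$space, field = sim$field))
        for (uu in u) for (proc in procedures) {
            resu <- if (proc == "voxel_fdr") vox else
                suppressWarnings(runProcedure(sim$map, proc, alpha = alpha,
                    u = uu, space = sim$space, field = sim$field))
            D <- minDistances(resu, sim$truth)
            idx <- idx + 1L
            cnt[[idx]] <- data.frame(procedure = proc, u = uu, n = n,
                replicate = rep., nDiscoveries = length(D))
            if (length(D))
                dist[[idx]] <- data.frame(procedure = proc, u = uu, n = n,
                    replicate = rep., D = D)
        }
        if (verbose && rep. %% 20L == 0L)
            message("n = ", n, ": replicate ", rep., "/", replicates)
    }
    list(distances = do.call(rbind, dist), counts = do.call(rbind, cnt))
}

#' Summarise an experiment into accuracy curves and sensitivity ratios
#'
#' Pools the minimum distances of an experiment per (procedure, u, n)
#' cell into empirical CDFs, and the discovery counts into sensitivity
#' ratios relative to peak-FWE at the same cell.
#'
#' @param experiment result of \code{\link{runExperiment}}.
#' @param grid distance grid for the CDFs.
#' @return list with \code{curves} (procedure, u, n, d, phi) and
#'   \code{ratios} (procedure, u, n, r, nProc, nFwe).
#' @export
summariseExperiment <- function(experiment, grid = seq(0, 16, by = 0.25)) {
    ds <- experiment$distances
    cs <- experiment$counts
    cells <- unique(ds[, c("procedure", "u", "n")])
    curves <- do.call(rbind, lapply(seq_len(nrow(cells)), function(r) {
        sel <- ds$procedure == cells$procedure[r] & ds$u == cells$u[r] &
               ds$n == cells$n[r]
        cbind(cells[r, , drop = FALSE],
              accuracyCurve(ds$D[sel], grid)[, c("d", "phi")],
              row.names = NULL)
    }))
    cc <- unique(cs[, c("procedure", "u", "n")])
    ratios <- do.call(rbind, lapply(seq_len(nrow(cc)), function(r) {
        sel <- cs$procedure == cc$procedure[r] & cs$u == cc$u[r] &
               cs$n == cc$n[r]
        ref <- cs$procedure == "peak_fwe" & cs$u == cc$u[r] &
               cs$n == cc$n[r]
        nP <- sum(cs$nDiscoveries[sel]); nF <- sum(cs$nDiscoveries[ref])
        cbind(cc[r, , drop = FALSE],
              data.frame(r = nP / nF, nProc = nP, nFwe = nF),
              row.names = NULL)
    }))
    list(curves = curves, ratios = ratios)
}
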