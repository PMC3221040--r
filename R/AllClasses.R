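#' @import methods
#' @importFrom stats pnorm pt qnorm qt p.adjust rnorm rchisq rgamma runif
#'   sd uniroot setNames fft var ecdf
#' @importFrom utils write.table read.delim head
#' @useDynLib PeakFDR, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Statistical field specification
#'
#' Describes the marginal family of a random field: a unit-variance Gaussian
#' field or a Student t field with \code{dof} degrees of freedom, in
#' \code{dim} dimensions. Euler characteristic densities, peak p-values and
#' expected feature counts are all parameterised by this object.
#'
#' @slot family \code{"gaussian"} or \code{"t"}.
#' @slot dof degrees of freedom (\code{NA} for Gaussian fields).
#' @slot dim field dimension, 1, 2 or 3.
#' @export
setClass("FieldSpec",
    representation(family = "character", dof = "numeric", dim = "integer"))

setValidity("FieldSpec", function(object) {
    msg <- NULL
    if (length(object@family) != 1L ||
        !object@family %in% c("gaussian", "t"))
        msg <- c(msg, "family must be \"gaussian\" or \"t\"")
    if (object@family == "t" &&
        (length(object@dof) != 1L || is.na(object@dof) || object@dof < 1))
        msg <- c(msg, "t fields require dof >= 1")
    if (length(object@dim) != 1L || !object@dim %in% 1:3)
        msg <- c(msg, "dim must be 1, 2 or 3")
    if (is.null(msg)) TRUE else msg
})

#' @param family \code{"gaussian"} or \code{"t"}.
#' @param dof degrees of freedom of a t field; ignored for Gaussian.
#' @param dim field dimension (default 3).
#' @return \code{FieldSpec} returns a \code{FieldSpec} object.
#' @examples
#' FieldSpec("t", dof = 15)
#' FieldSpec("gaussian")
#' @rdname FieldSpec-class
#' @export
FieldSpec <- function(family = c("gaussian", "t"), dof = NA_real_, dim = 3L) {
    family <- match.arg(family)
    if (family == "gaussian") dof <- NA_real_
    new("FieldSpec", family = family, dof = as.numeric(dof),
        dim = as.integer(dim))
}

setMethod("show", "FieldSpec", function(object) {
    cat(sprintf("FieldSpec: %s field%s, D = %d\n", object@family,
        if (object@family == "t") sprintf(" (dof = %g)", object@dof) else "",
        object@dim))
})

#' Search space geometry
#'
#' The lattice over which an SPM is searched: its shape in voxels, voxel
#' size in mm, the smoothness of the component fields (FWHM per axis, mm),
#' and the derived resel counts \eqn{R_0, \dots, R_D}. For a box-shaped
#' region \eqn{R_0 = 1} (its Euler characteristic), \eqn{R_D} is the volume
#' divided by the product of the per-axis FWHMs, and intermediate counts are
#' the elementary symmetric sums of the side lengths in FWHM units.
#'
#' @slot shape integer vector of voxels per axis.
#' @slot voxelSize mm per voxel, per axis.
#' @slot fwhm smoothness FWHM in mm, per axis.
#' @slot resels numeric vector \eqn{R_0 \ldots R_D}.
#' @export
setClass("SearchSpace",
    representation(shape = "integer", voxelSize = "numeric",
                   fwhm = "numeric", resels = "numeric"))

setValidity("SearchSpace", function(object) {
    msg <- NULL
    D <- length(object@shape)
    if (!D %in% 1:3) msg <- c(msg, "shape must have 1-3 axes")
    if (any(object@shape < 1)) msg <- c(msg, "shape must be positive")
    if (length(object@voxelSize) != D || any(object@voxelSize <= 0))
        msg <- c(msg, "voxelSize must be positive, one per axis")
    if (length(object@fwhm) != D || any(!is.finite(object@fwhm)) ||
        any(object@fwhm <= 0))
        msg <- c(msg, "fwhm must be positive and finite, one per axis")
    if (length(object@resels) != D + 1L || any(object@resels < 0))
        msg <- c(msg, "resels must be non-negative, length dim + 1")
    if (is.null(msg)) TRUE else msg
})

#' @param shape voxels per axis.
#' @param fwhm smoothness FWHM per axis. Scalars are recycled. Units are mm
#'   (equivalently voxels when \code{voxelSize = 1}).
#' @param voxelSize mm per voxel, per axis (default 1: voxel units).
#' @return \code{SearchSpace} returns a \code{SearchSpace} object.
#' @examples
#' SearchSpace(c(64, 64, 32), fwhm = 4)
#' @rdname SearchSpace-class
#' @export
SearchSpace <- function(shape, fwhm, voxelSize = 1) {
    shape <- as.integer(shape)
    D <- length(shape)
    voxelSize <- rep_len(as.numeric(voxelSize), D)
    fwhm <- rep_len(as.numeric(fwhm), D)
    # side lengths in FWHM units
    r <- shape * voxelSize / fwhm
    resels <- switch(D,
        c(1, r),
        c(1, r[1] + r[2], r[1] * r[2]),
        c(1, r[1] + r[2] + r[3],
          r[1] * r[2] + r[1] * r[3] + r[2] * r[3],
          r[1] * r[2] * r[3]))
    new("SearchSpace", shape = shape, voxelSize = voxelSize, fwhm = fwhm,
        resels = resels)
}

setMethod("show", "SearchSpace", function(object) {
    cat(sprintf("SearchSpace: %s voxels, voxel size %s mm, FWHM %s mm\n",
        paste(object@shape, collapse = "x"),
        paste(signif(object@voxelSize, 4), collapse = "x"),
        paste(signif(object@fwhm, 4), collapse = "x")))
    cat("  resels R_0..R_D:", paste(signif(object@resels, 6),
        collapse = ", "), "\n")
})

#' Excursion set of a statistical map
#'
#' The suprathreshold set \eqn{\{Z > u\}} of an SPM, decomposed into
#' connected clusters, together with the local maxima (peaks) above
#' \code{u}. Peaks and clusters are stored as data frames; \code{labels}
#' holds the integer cluster label of every voxel (0 = subthreshold).
#'
#' @slot threshold the feature-defining threshold u.
#' @slot connectivity lattice connectivity used for clusters (6, 18 or 26).
#' @slot peaks data frame: i, j, k, height, cluster.
#' @slot clusters data frame: cluster, nVoxels, maxHeight.
#' @slot labels integer array of cluster labels, same shape as the map.
#' @export
setClass("ExcursionSet",
    representation(threshold = "numeric", connectivity = "integer",
                   peaks = "data.frame", clusters = "data.frame",
                   labels = "array"))

setValidity("ExcursionSet", function(object) {
    msg <- NULL
    p <- object@peaks
    if (nrow(p) && any(p$height <= object@threshold))
        msg <- c(msg, "all peaks must exceed the threshold")
    if (nrow(object@clusters) && any(object@clusters$nVoxels < 1))
        msg <- c(msg, "clusters must contain at least one voxel")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "ExcursionSet", function(object) {
    cat(sprintf(
        "ExcursionSet: u = %g, %d cluster(s), %d peak(s) (connectivity %d)\n",
        object@threshold, nrow(object@clusters), nrow(object@peaks),
        object@connectivity))
})

#' Ground truth of one simulated SPM
#'
#' Records the activations planted by the signal simulator: voxel locations
#' \code{mu} (1-based lattice indices, one row per activation), kernel
#' widths (FWHM, voxels) and peak heights (noise-SD units).
#'
#' @slot mu integer matrix of true peak locations, one row per activation.
#' @slot widths FWHM of each activation's kernel, voxels.
#' @slot heights peak amplitude of each activation.
#' @slot shape lattice shape the truth refers to.
#' @slot seed RNG seed used (NA if none was supplied).
#' @export
setClass("SimulationTruth",
    representation(mu = "matrix", widths = "numeric", heights = "numeric",
                   shape = "integer", seed = "numeric"))

setValidity("SimulationTruth", function(object) {
    msg <- NULL
    n <- nrow(object@mu)
    if (length(object@widths) != n || length(object@heights) != n)
        msg <- c(msg, "widths and heights must have one entry per activation")
    if (n && (any(object@mu < 1) ||
              any(sweep(object@mu, 2, object@shape, ">"))))
        msg <- c(msg, "all locations must lie inside the lattice")
    if (n && any(object@heights <= 0))
        msg <- c(msg, "heights must be positive")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "SimulationTruth", function(object) {
    cat(sprintf(
        "SimulationTruth: %d activation(s) on a %s lattice\n",
        nrow(object@mu), paste(object@shape, collapse = "x")))
    if (nrow(object@mu))
        cat(sprintf("  heights %s; widths (FWHM, voxels) %s\n",
            paste(signif(object@heights, 3), collapse = ", "),
            paste(signif(object@widths, 3), collapse = ", ")))
})

#' Result of one thresholding procedure
#'
#' Discoveries made on one SPM by one of the four decision procedures
#' (\code{peak_fwe}, \code{peak_fdr}, \code{cluster_fdr}, \code{voxel_fdr})
#' at level \code{alpha}. \code{peaks} holds the discovered peaks (for
#' cluster FDR, every peak inside a significant cluster; for voxel FDR, the
#' local maxima among surviving voxels) with their uncorrected, FWE and
#' q-values. \code{adaptiveThreshold} is the data-dependent cutoff actually
#' applied: an uncorrected p-value for the BH procedures, a statistic value
#' for peak FWE.
#'
#' @slot procedure one of the four procedure names.
#' @slot alpha nominal error level.
#' @slot u feature-defining threshold (NA for \code{voxel_fdr}).
#' @slot peaks data frame of discovered peaks.
#' @slot clusters data frame of the clusters involved: all harvested
#'   clusters (with extents) for the peak procedures, the significant
#'   ones for cluster FDR, empty for voxel FDR.
#' @slot adaptiveThreshold the applied cutoff.
#' @slot nHarvested number of candidate features tested.
#' @export
setClass("ProcedureResult",
    representation(procedure = "character", alpha = "numeric",
                   u = "numeric", peaks = "data.frame",
                   clusters = "data.frame", adaptiveThreshold = "numeric",
                   nHarvested = "integer"))

setValidity("ProcedureResult", function(object) {
    msg <- NULL
    if (!object@procedure %in%
        c("peak_fwe", "peak_fdr", "cluster_fdr", "voxel_fdr"))
        msg <- c(msg, "unknown procedure")
    if (object@alpha <= 0 || object@alpha >= 1)
        msg <- c(msg, "alpha must lie in (0,1)")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "ProcedureResult", function(object) {
    cat(sprintf(
        "ProcedureResult: %s at alpha = %g%s\n", object@procedure,
        object@alpha,
        if (is.na(object@u)) "" else sprintf(", u = %g", object@u)))
    cat(sprintf("  %d discovered peak(s) out of %d harvested feature(s)\n",
        nrow(object@peaks), object@nHarvested))
})
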