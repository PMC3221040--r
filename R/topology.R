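# Topological feature extraction from lattice statistical maps.

# coerce a 1-3D numeric array to 3D; NA values are out of mask
.as3d <- function(map) {
    if (is.null(dim(map))) dim(map) <- length(map)
    d <- dim(map)
    if (length(d) > 3L) stop("map must have at most 3 dimensions")
    if (length(map) == 0L) stop("map is empty")
    dim(map) <- c(d, rep(1L, 3L - length(d)))
    map
}

#' Local maxima of a statistical map
#'
#' Finds the voxels above \code{u} that exceed all of their lattice
#' neighbours under the chosen connectivity. Missing neighbours (outside
#' the lattice or masked out with \code{NA}) are treated as \code{-Inf},
#' so boundary voxels can be maxima. Under \code{plateau = FALSE}
#' (default) a voxel tied with a neighbour is not a maximum -- ties have
#' measure zero in continuous fields; with \code{plateau = TRUE} the first
#' voxel (column-major order) of a flat plateau is reported instead.
#'
#' @param map numeric array (1-3 dimensions); \code{NA} = out of mask.
#' @param u harvest threshold: only voxels strictly above \code{u} qualify.
#' @param connectivity 6, 18 or 26 (default 26, the field's convention for
#'   maxima).
#' @param plateau report the first voxel of tied plateaus as a maximum.
#' @return data frame with columns \code{i, j, k} (1-based lattice
#'   indices) and \code{height}, ordered by decreasing height then
#'   lexicographic index; zero rows when nothing exceeds \code{u}.
#' @examples
#' m <- array(0, c(5, 5, 5)); m[2, 2, 2] <- 3; m[4, 4, 4] <- 5
#' findLocalMaxima(m, u = 1)
#' @export
findLocalMaxima <- function(map, u, connectivity = 26L, plateau = FALSE) {
    map <- .as3d(map)
    if (!connectivity %in% c(6L, 18L, 26L))
        stop("connectivity must be 6, 18 or 26")
    if (!is.finite(u)) stop("u must be finite")
    if (all(is.na(map))) stop("map contains no in-mask voxels")
    idx <- .cppLocalMaxima(as.numeric(map), dim(map), u,
                           as.integer(connectivity), !plateau)
    h <- map[idx]
    ord <- order(-h, idx[, 1L], idx[, 2L], idx[, 3L])
    data.frame(i = idx[ord, 1L], j = idx[ord, 2L], k = idx[ord, 3L],
               height = h[ord])
}

#' Excursion set: suprathreshold clusters and their peaks
#'
#' Labels the connected components of \code{\{map > u\}} and assigns each
#' local maximum to its component, returning an
#' \code{\link{ExcursionSet}}. Clusters use 18-connectivity by default and
#' maxima 26-connectivity, the conventions of SPM; both are configurable.
#'
#' @inheritParams findLocalMaxima
#' @param connectivity cluster connectivity (default 18).
#' @param peakConnectivity connectivity for maxima (default 26).
#' @return an \code{\link{ExcursionSet}}.
#' @examples
#' m <- array(0, c(5, 5, 5)); m[2, 2, 2] <- 3; m[4, 4, 4] <- 5
#' labelClusters(m, u = 1)
#' @export
labelClusters <- function(map, u, connectivity = 18L,
                          peakConnectivity = 26L, plateau = FALSE) {
    map <- .as3d(map)
    if (!connectivity %in% c(6L, 18L, 26L))
        stop("connectivity must be 6, 18 or 26")
    if (all(is.na(map))) stop("map contains no in-mask voxels")
    lab <- .cppLabelClusters(as.numeric(map), dim(map), u,
                             as.integer(connectivity))
    dim(lab) <- dim(map)
    pk <- findLocalMaxima(map, u, peakConnectivity, plateau)
    pk$cluster <- lab[as.matrix(pk[, c("i", "j", "k")])]
    M <- max(lab)
    cl <- if (M > 0L) {
        nv <- tabulate(lab, nbins = M)
        mh <- vapply(seq_len(M), function(g) {
            in.g <- pk$cluster == g
            if (any(in.g)) max(pk$height[in.g]) else max(map[lab == g])
        }, numeric(1))
        data.frame(cluster = seq_len(M), nVoxels = nv, maxHeight = mh)
    } else data.frame(cluster = integer(), nVoxels = integer(),
                      maxHeight = numeric())
    new("ExcursionSet", threshold = as.numeric(u),
        connectivity = as.integer(connectivity), peaks = pk,
        clusters = cl, labels = lab)
}

#' Stationary smoothness (FWHM) from residual fields
#'
#' Estimates the per-axis FWHM of the component fields from the variance
#' of the spatial derivatives of standardised residuals, via the
#' stationary identity \eqn{\mathrm{FWHM}_d = \sqrt{4\log 2 /
#' \mathrm{Var}(\partial r/\partial x_d)}} for a unit-variance field.
#' Derivatives are forward differences on the voxel lattice, pooled over
#' all supplied residual fields.
#'
#' @param residuals a list of residual arrays (same shape), or a 4D array
#'   with fields along the last dimension; at least 2 fields.
#' @param voxelSize mm per voxel, per axis (default 1: FWHM in voxels).
#' @return per-axis FWHM, in the units of \code{voxelSize}.
#' @examples
#' flds <- replicate(4, smoothNoiseField(c(24, 24, 12), fwhm = 4),
#'                   simplify = FALSE)
#' estimateFwhm(flds)
#' @export
estimateFwhm <- function(residuals, voxelSize = 1) {
    if (is.array(residuals) && length(dim(residuals)) == 4L)
        residuals <- lapply(seq_len(dim(residuals)[4L]),
                            function(i) residuals[, , , i])
    if (!is.list(residuals) || length(residuals) < 2L)
        stop("at least 2 residual fields are required")
    d <- dim(.as3d(residuals[[1L]]))
    D <- sum(d > 1L)
    voxelSize <- rep_len(as.numeric(voxelSize), D)
    ssq <- nn <- numeric(3)
    for (r in residuals) {
        r <- .as3d(r)
        s <- sd(as.numeric(r), na.rm = TRUE)
        if (!is.finite(s) || s == 0)
            stop("constant residual field: smoothness is not estimable")
        r <- r / s
        for (ax in which(d > 1L)) {
            g <- switch(ax,
                r[-1, , , drop = FALSE] - r[-d[1], , , drop = FALSE],
                r[, -1, , drop = FALSE] - r[, -d[2], , drop = FALSE],
                r[, , -1, drop = FALSE] - r[, , -d[3], drop = FALSE])
            ssq[ax] <- ssq[ax] + sum(g^2, na.rm = TRUE)
            nn[ax] <- nn[ax] + sum(!is.na(g))
        }
    }
    v <- ssq[seq_len(D)] / nn[seq_len(D)]
    fwhm <- sqrt(4 * log(2) / v) * voxelSize
    if (any(!is.finite(fwhm)))
        stop("smoothness estimate is not finite")
    fwhm
}
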