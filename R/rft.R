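# Closed-form random field theory: Euler characteristic (EC) densities,
# expected peak counts, peak p-values and cluster-extent p-values for
# stationary unit-variance Gaussian and Student t fields.

FOUR_LOG2 <- 4 * log(2)

# threshold below which the top-dimensional EC density changes sign; the
# conditional peak p-value is only defined above this root
.validityBound <- function(field) {
    d <- field@dim
    if (d <= 1) return(-Inf)
    if (field@family == "gaussian") {
        if (d == 2) 0 else 1                      # roots of z, z^2 - 1
    } else {
        v <- field@dof
        if (d == 2) 0 else sqrt(v / (v - 1))      # root of (v-1)z^2/v - 1
    }
}

#' Euler characteristic densities
#'
#' The d-dimensional EC density \eqn{\rho_d(z)} of a stationary
#' unit-variance Gaussian or t field, per resel. At high thresholds
#' \eqn{\rho_D(z)} is the expected rate of emission of local maxima per
#' D-dimensional resel; \eqn{\rho_0(z)} is the upper-tail probability of
#' the field's marginal distribution. Multiplied by the resel counts of a
#' search region and summed over d, these give the expected Euler
#' characteristic of the excursion set -- at high thresholds, the expected
#' number of peaks.
#'
#' @param field a \code{\link{FieldSpec}}.
#' @param d density dimension, 0 to 3.
#' @param z statistic value(s).
#' @return \eqn{\rho_d(z)}, vectorised over \code{z}.
#' @references Worsley, K.J. et al. (1996) A unified statistical approach
#'   for determining significant signals in images of cerebral activation.
#'   Human Brain Mapping 4, 58-73.
#' @examples
#' ecDensity(FieldSpec("gaussian"), 0, 0)    # 0.5
#' ecDensity(FieldSpec("t", dof = 15), 3, 3.5)
#' @export
ecDensity <- function(field, d, z) {
    stopifnot(is(field, "FieldSpec"))
    if (length(d) != 1L || !d %in% 0:3)
        stop("EC densities are implemented for d = 0, 1, 2, 3 only")
    if (any(!is.finite(z))) stop("z must be finite")
    if (field@family == "gaussian") {
        switch(d + 1L,
            pnorm(z, lower.tail = FALSE),
            sqrt(FOUR_LOG2) / (2 * pi) * exp(-z^2 / 2),
            FOUR_LOG2 / (2 * pi)^1.5 * z * exp(-z^2 / 2),
            FOUR_LOG2^1.5 / (2 * pi)^2 * (z^2 - 1) * exp(-z^2 / 2))
    } else if (field@family == "t") {
        v <- field@dof
        cz <- (1 + z^2 / v)^(-(v - 1) / 2)
        b <- exp(lgamma((v + 1) / 2) - lgamma(v / 2))
        switch(d + 1L,
            pt(z, df = v, lower.tail = FALSE),
            sqrt(FOUR_LOG2) / (2 * pi) * cz,
            FOUR_LOG2 / (2 * pi)^1.5 * b / sqrt(v / 2) * z * cz,
            FOUR_LOG2^1.5 / (2 * pi)^2 * ((v - 1) / v * z^2 - 1) * cz)
    } else stop("unsupported field family: ", field@family)
}

#' Uncorrected (conditional) peak p-value
#'
#' The p-value of a peak of height \code{z}, conditional on the peak
#' exceeding the feature-defining threshold \code{u}:
#' \deqn{p_u(z) = P(Z > z \mid Z > u) \approx \rho_D(z)/\rho_D(u),}
#' the ratio of the expected rates at which the field emits peaks above the
#' two heights, using the top-dimensional EC density only (resel counts
#' cancel in the ratio). The approximation requires the excursion set to
#' consist of simple regions, which holds only for sufficiently high
#' thresholds: a warning is issued for \code{u < 2.5}, and thresholds at or
#' below the sign-change root of the density polynomial are refused.
#'
#' @param z peak height(s), each \code{>= u}.
#' @param u feature-defining threshold.
#' @param field a \code{\link{FieldSpec}}.
#' @return conditional p-values in [0, 1], non-increasing in \code{z},
#'   with \eqn{p_u(u) = 1}.
#' @examples
#' peakPUncorrected(3.5, u = 2.5, FieldSpec("t", dof = 15))
#' @export
peakPUncorrected <- function(z, u, field) {
    stopifnot(is(field, "FieldSpec"))
    if (length(u) != 1L || !is.finite(u)) stop("u must be a finite scalar")
    bound <- .validityBound(field)
    if (u <= bound)
        stop(sprintf(
            "u = %g is at or below the validity bound %.4f where the %d-D EC density changes sign",
            u, bound, field@dim))
    if (u < 2.5)
        warning("u < 2.5: excursion-set regions may not be simple; ",
                "conditional peak p-values are approximate")
    if (any(z < u)) stop("peak heights must satisfy z >= u")
    p <- ecDensity(field, field@dim, z) / ecDensity(field, field@dim, u)
    pmin(pmax(p, 0), 1)
}

#' Expected number of peaks above a threshold
#'
#' The expected Euler characteristic of the excursion set above \code{u},
#' \eqn{\sum_{d=0}^{D} R_d \rho_d(u)}; at high thresholds this is the
#' expected number of local maxima in the search region.
#'
#' @param u threshold(s).
#' @param space a \code{\link{SearchSpace}}.
#' @param field a \code{\link{FieldSpec}}; its dimension must match the
#'   search space.
#' @return expected peak count, vectorised over \code{u}.
#' @examples
#' sp <- SearchSpace(c(64, 64, 32), fwhm = 4)
#' expectedPeaks(3, sp, FieldSpec("gaussian"))
#' @export
expectedPeaks <- function(u, space, field) {
    stopifnot(is(space, "SearchSpace"), is(field, "FieldSpec"))
    D <- field@dim
    if (length(space@shape) != D)
        stop("field dimension does not match search space")
    R <- space@resels
    out <- 0
    for (d in 0:D) out <- out + R[d + 1L] * ecDensity(field, d, u)
    out
}

#' Family-wise error corrected peak p-value
#'
#' The probability of observing any peak at or above height \code{z}
#' anywhere in the search region under the null, approximated by the
#' expected number of such peaks (accurate when that expectation is small)
#' and clipped at 1.
#'
#' @inheritParams expectedPeaks
#' @param z peak height(s).
#' @return FWE-corrected p-values in [0, 1], non-increasing in \code{z}.
#' @export
peakPFwe <- function(z, space, field) {
    e <- expectedPeaks(z, space, field)
    # the expected EC approximates P(any peak >= z) only where it is
    # small; at low thresholds (where the EC can even be negative, the
    # excursion set having handles) the exceedance probability is 1
    ifelse(e >= 1 | z <= .validityBound(field), 1, pmax(e, 0))
}

#' Peak FWE statistic threshold
#'
#' The statistic value whose FWE-corrected peak p-value equals
#' \code{alpha}: the height threshold controlling the family-wise error
#' rate of peaks at that level.
#'
#' @param alpha FWE level in (0, 1).
#' @inheritParams expectedPeaks
#' @param tol tolerance on the achieved probability.
#' @return the statistic threshold \eqn{z^*}.
#' @examples
#' sp <- SearchSpace(c(64, 64, 32), fwhm = 4)
#' fweThreshold(0.05, sp, FieldSpec("t", dof = 15))
#' @export
fweThreshold <- function(alpha, space, field, tol = 1e-8) {
    if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1)
        stop("alpha must lie strictly between 0 and 1")
    lo <- max(.validityBound(field) + 1e-6, 0.1)
    f <- function(z) expectedPeaks(z, space, field) - alpha
    if (f(lo) < 0) return(lo)  # even the lowest admissible height is rarer
    r <- uniroot(f, interval = c(lo, 50), tol = .Machine$double.eps^0.5)
    # polish in probability with bisection until within tol
    a <- r$root - 1e-4; b <- r$root + 1e-4
    while (f(a) < 0) a <- a - 1e-3
    while (f(b) > 0) b <- b + 1e-3
    while (abs(f((a + b) / 2)) > tol && (b - a) > .Machine$double.eps * 16) {
        m <- (a + b) / 2
        if (f(m) > 0) a <- m else b <- m
    }
    (a + b) / 2
}

#' Conditional cluster-extent p-value
#'
#' The probability that a cluster of the excursion set above \code{u} has
#' spatial extent at least \code{s} resels, conditional on a cluster
#' existing. Under the stationary-field approximation the extent has the
#' exponential-form tail \deqn{P(S \ge s) = \exp(-\beta s^{2/D}),} with
#' \eqn{\beta} calibrated so the expected extent equals the expected
#' suprathreshold volume divided by the expected number of clusters
#' (both from random field theory).
#'
#' @param s cluster extent(s) in resels (extent in voxels divided by the
#'   product of per-axis FWHMs in voxels), \code{>= 0}.
#' @inheritParams expectedPeaks
#' @param u the cluster-defining threshold.
#' @return conditional extent p-values in [0, 1], 1 at \code{s = 0}.
#' @references Friston, K.J. et al. (1994) Assessing the significance of
#'   focal activations using their spatial extent. Human Brain Mapping 1,
#'   210-220.
#' @export
clusterExtentP <- function(s, u, space, field) {
    stopifnot(is(space, "SearchSpace"), is(field, "FieldSpec"))
    if (any(s < 0)) stop("cluster extents must be non-negative")
    bound <- .validityBound(field)
    if (u <= bound)
        stop(sprintf(
            "u = %g is at or below the validity bound %.4f of the extent model",
            u, bound))
    D <- field@dim
    Em <- expectedPeaks(u, space, field)           # expected cluster count
    EN <- ecDensity(field, 0, u) * space@resels[D + 1L]  # expected volume
    beta <- (gamma(D / 2 + 1) * Em / EN)^(2 / D)
    exp(-beta * s^(2 / D))
}
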