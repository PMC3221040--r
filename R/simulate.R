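# Monte-Carlo generator: smooth Gaussian noise volumes, randomly placed
# smooth activations, and voxel-wise one-sample t maps with known truth.

.kernelCache <- new.env(parent = emptyenv())

# wrapped (circular) separable Gaussian kernel for a lattice: returns the
# real transfer function K = fft(kernel) and the l2 norm of the kernel,
# cached per (shape, fwhm)
.noiseKernel <- function(shape, fwhm) {
    key <- paste(c(shape, signif(fwhm, 12)), collapse = "_")
    hit <- .kernelCache[[key]]
    if (!is.null(hit)) return(hit)
    fwhm <- rep_len(fwhm, 3L)
    k1 <- lapply(1:3, function(ax) {
        n <- shape[ax]
        sigma <- fwhm[ax] / sqrt(8 * log(2))
        r <- min(ceiling(4 * sigma), floor((n - 1) / 2))  # +/- 4 SD support
        g <- exp(-(-r:r)^2 / (2 * sigma^2))
        k <- numeric(n)
        k[((-r:r) %% n) + 1L] <- k[((-r:r) %% n) + 1L] + g
        k
    })
    k3 <- outer(outer(k1[[1L]], k1[[2L]]), k1[[3L]])
    dim(k3) <- shape
    out <- list(K = Re(fft(k3)), norm = sqrt(sum(k3^2)))
    .kernelCache[[key]] <- out
    out
}

# smooth nvol independent white-noise volumes to unit marginal variance,
# two per FFT (packed as real/imaginary parts)
.smoothNoiseMany <- function(shape, fwhm, nvol) {
    ker <- .noiseKernel(shape, fwhm)
    N <- prod(shape)
    out <- vector("list", nvol)
    i <- 1L
    while (i <= nvol) {
        if (i < nvol) {
            z <- complex(real = rnorm(N), imaginary = rnorm(N))
            dim(z) <- shape
            sm <- fft(fft(z) * ker$K, inverse = TRUE) / (N * ker$norm)
            a <- Re(sm); dim(a) <- shape
            b <- Im(sm); dim(b) <- shape
            out[[i]] <- a; out[[i + 1L]] <- b
            i <- i + 2L
        } else {
            w <- array(rnorm(N), shape)
            sm <- Re(fft(fft(w) * ker$K, inverse = TRUE)) / (N * ker$norm)
            dim(sm) <- shape
            out[[i]] <- sm
            i <- i + 1L
        }
    }
    out
}

#' Smooth Gaussian noise field
#'
#' A stationary Gaussian random field on a voxel lattice with unit
#' marginal variance and Gaussian autocorrelation of the stated FWHM,
#' generated by circular convolution of white noise with a Gaussian
#' kernel (truncated at 4 SD). The variance is exact by construction
#' (the field is rescaled by the kernel's l2 norm), not estimated.
#'
#' @param shape voxels per axis (length 3).
#' @param fwhm smoothing kernel FWHM in voxels (default 4).
#' @param seed optional RNG seed for reproducibility.
#' @return a numeric array of the given shape.
#' @examples
#' f <- smoothNoiseField(c(32, 32, 16), fwhm = 4, seed = 1)
#' sd(f)  # close to 1
#' @export
smoothNoiseField <- function(shape, fwhm = 4, seed = NULL) {
    if (length(shape) != 3L || any(shape < 2L))
        stop("shape must give 3 axes of at least 2 voxels")
    if (any(fwhm <= 0)) stop("fwhm must be positive")
    if (!is.null(seed)) set.seed(seed)
    .smoothNoiseMany(as.integer(shape), fwhm, 1L)[[1L]]
}

# draws from Gamma(shape, scale) conditioned on exceeding `lower`, by
# rejection in batches
.truncGamma <- function(n, shape = 1, scale = 4, lower = 4) {
    out <- numeric(0)
    while (length(out) < n) {
        x <- rgamma(max(2L * n, 16L), shape = shape, scale = scale)
        out <- c(out, x[x >= lower])
    }
    out[seq_len(n)]
}

#' Sample a smooth activation pattern
#'
#' Places \code{nActivations} Gaussian bumps uniformly at random on the
#' lattice (keeping a margin from the border so every true peak is
#' interior). Each bump has unit peak height scaled by an amplitude drawn
#' from chi-squared with 1 degree of freedom, and a kernel FWHM drawn
#' from Gamma(shape 1, scale 4) truncated below at 4 voxels -- so
#' activation widths are bounded below by the noise smoothness.
#' Overlapping bumps sum.
#'
#' @param nActivations number of activations.
#' @param shape lattice shape (length 3).
#' @param seed optional RNG seed.
#' @param margin border margin in voxels within which no centre is placed
#'   (default 4; set 0 to allow boundary activations).
#' @param heights,widths optional fixed amplitude / FWHM vectors
#'   overriding the sampling distributions (recycled).
#' @return list with \code{signal} (numeric array) and \code{truth} (a
#'   \code{\link{SimulationTruth}}).
#' @examples
#' s <- sampleSignal(4, c(32, 32, 16), seed = 1)
#' s$truth
#' @export
sampleSignal <- function(nActivations, shape, seed = NULL, margin = 4L,
                         heights = NULL, widths = NULL) {
    if (length(shape) != 3L) stop("shape must have 3 axes")
    if (!is.null(seed)) set.seed(seed)
    shape <- as.integer(shape)
    n <- as.integer(nActivations)
    lo <- pmin(1L + margin, shape)
    hi <- pmax(shape - margin, lo)
    mu <- cbind(
        lo[1] + floor(runif(n) * (hi[1] - lo[1] + 1L)),
        lo[2] + floor(runif(n) * (hi[2] - lo[2] + 1L)),
        lo[3] + floor(runif(n) * (hi[3] - lo[3] + 1L)))
    storage.mode(mu) <- "integer"
    h <- if (is.null(heights)) rchisq(n, df = 1) else rep_len(heights, n)
    w <- if (is.null(widths)) .truncGamma(n) else rep_len(widths, n)
    signal <- array(0, shape)
    for (a in seq_len(n)) {
        sigma <- w[a] / sqrt(8 * log(2))
        r <- ceiling(4 * sigma)
        rng <- lapply(1:3, function(ax)
            max(1L, mu[a, ax] - r):min(shape[ax], mu[a, ax] + r))
        g1 <- lapply(1:3, function(ax)
            exp(-4 * log(2) * (rng[[ax]] - mu[a, ax])^2 / w[a]^2))
        bump <- h[a] * outer(outer(g1[[1L]], g1[[2L]]), g1[[3L]])
        signal[rng[[1L]], rng[[2L]], rng[[3L]]] <-
            signal[rng[[1L]], rng[[2L]], rng[[3L]]] + bump
    }
    truth <- new("SimulationTruth", mu = mu, widths = as.numeric(w),
                 heights = as.numeric(h), shape = shape,
                 seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
    list(signal = signal, truth = truth)
}

#' Simulate a statistical parametric map with known truth
#'
#' Generates \code{nVolumes} volumes, each the same activation signal plus
#' independent smooth unit-variance Gaussian noise, and forms the
#' voxel-wise one-sample t statistic: a t field with \code{nVolumes - 1}
#' degrees of freedom whose component-field smoothness equals the noise
#' FWHM. With \code{nActivations = 0} this yields a pure-noise SPM (the
#' global null).
#'
#' @inheritParams sampleSignal
#' @param nVolumes number of volumes entering the t statistic (default
#'   16, giving 15 degrees of freedom).
#' @param noiseFwhm noise smoothing kernel FWHM in voxels (default 4).
#' @param ... further arguments passed to \code{\link{sampleSignal}}.
#' @return list with \code{map} (the t statistic array), \code{truth},
#'   \code{field} (a \code{\link{FieldSpec}}) and \code{space} (a
#'   \code{\link{SearchSpace}} in voxel units with FWHM =
#'   \code{noiseFwhm}).
#' @examples
#' sim <- simulateSpm(nActivations = 8, shape = c(32, 32, 16), seed = 1)
#' sim$field
#' @export
simulateSpm <- function(nActivations, shape = c(64L, 64L, 32L),
                        nVolumes = 16L, noiseFwhm = 4, seed = NULL, ...) {
    if (nVolumes < 2L) stop("nVolumes must be at least 2")
    if (!is.null(seed)) set.seed(seed)
    shape <- as.integer(shape)
    sig <- sampleSignal(nActivations, shape, seed = NULL, ...)
    vols <- .smoothNoiseMany(shape, noiseFwhm, as.integer(nVolumes))
    s1 <- array(0, shape); s2 <- array(0, shape)
    for (v in vols) {
        x <- v + sig$signal
        s1 <- s1 + x
        s2 <- s2 + x * x
    }
    m <- s1 / nVolumes
    varHat <- pmax(s2 - nVolumes * m^2, 0) / (nVolumes - 1)
    tmap <- m / sqrt(varHat / nVolumes)
    list(map = tmap, truth = sig$truth,
         field = FieldSpec("t", dof = nVolumes - 1L),
         space = SearchSpace(shape, fwhm = noiseFwhm))
}
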