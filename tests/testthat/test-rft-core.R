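# Closed-form random-field-theory quantities against independent oracles.

fg <- FieldSpec("gaussian")
f15 <- FieldSpec("t", dof = 15)

test_that("EC density dimension 0 is the marginal upper-tail probability", {
    expect_equal(ecDensity(fg, 0, 0), 0.5)
    z <- c(-1, 0, 1.3, 2.5, 4)
    expect_equal(ecDensity(fg, 0, z), pnorm(z, lower.tail = FALSE))
    expect_equal(ecDensity(f15, 0, z), pt(z, 15, lower.tail = FALSE))
})

test_that("Gaussian EC densities match a numerical-differentiation oracle", {
    # rho_d(z) = (4 log 2)^{d/2} (2 pi)^{-(d+1)/2} (-1)^{d-1} phi^{(d-1)}(z)
    # with phi(z) = exp(-z^2/2); derivatives evaluated numerically with
    # pracma, an independent route to the Hermite-polynomial forms
    skip_if_not_installed("pracma")
    f <- function(z) exp(-z^2 / 2)
    for (z in c(1.2, 2.0, 3.0, 4.5)) {
        o1 <- sqrt(4 * log(2)) / (2 * pi) * f(z)
        o2 <- (4 * log(2)) / (2 * pi)^1.5 * -pracma::fderiv(f, z, n = 1)
        o3 <- (4 * log(2))^1.5 / (2 * pi)^2 * pracma::fderiv(f, z, n = 2)
        expect_equal(ecDensity(fg, 1, z), o1, tolerance = 1e-7)
        expect_equal(ecDensity(fg, 2, z), o2, tolerance = 1e-6)
        expect_equal(ecDensity(fg, 3, z), o3, tolerance = 1e-5)
    }
})

test_that("unsupported dimensions and families are refused", {
    expect_error(ecDensity(fg, 4, 2), "d = 0, 1, 2, 3")
    expect_error(ecDensity(fg, 2, Inf), "finite")
})

test_that("conditional peak p-value attains its bounds and is monotone", {
    # identity case: z = u makes numerator and denominator of the
    # EC-density ratio equal
    expect_equal(peakPUncorrected(2.5, 2.5, f15), 1)
    expect_equal(peakPUncorrected(3.2, 3.2, fg), 1)
    z <- seq(2.5, 12, by = 0.1)
    for (fld in list(fg, f15)) {
        p <- peakPUncorrected(z, 2.5, fld)
        expect_true(all(p >= 0 & p <= 1))
        expect_true(all(diff(p) <= 1e-12))
    }
    # tail limit
    expect_lt(peakPUncorrected(40, 2.5, f15), 1e-6)
})

test_that("conditional peak p-value guards its validity regime", {
    expect_error(peakPUncorrected(2.4, 2.5, f15), "z >= u")
    # below the sign-change root of the density polynomial: for t(15) in
    # 3D that root is sqrt(15/14)
    expect_error(peakPUncorrected(3, 1.0, f15), "1.03")
    expect_error(peakPUncorrected(3, 0.9, fg), "bound")
    expect_warning(peakPUncorrected(3, 2.2, f15), "2.5")
})

test_that("t conditional p converges to the Gaussian value as dof grows", {
    z <- seq(2.6, 4.0, by = 0.1)
    pg <- peakPUncorrected(z, 2.5, fg)
    err <- vapply(c(200, 500, 1000, 5000), function(nu)
        max(abs(peakPUncorrected(z, 2.5, FieldSpec("t", dof = nu)) / pg - 1)),
        numeric(1))
    # O(1/nu) decay: each 2.5-5x increase in dof shrinks the error
    expect_true(all(diff(err) < 0))
    expect_lt(err[2] / err[1], 0.5)
    expect_lt(err[4], 0.015)
})

test_that("expected peak count is linear in resels and decreasing in u", {
    sp <- SearchSpace(c(64, 64, 32), fwhm = 4)
    u <- seq(2, 6, by = 0.25)
    e <- expectedPeaks(u, sp, f15)
    expect_true(all(diff(e) < 0))
    expect_lt(expectedPeaks(50, sp, f15), 1e-8)
    expect_lt(expectedPeaks(50, sp, fg), 1e-10)
    # linearity in the resel counts
    sp3 <- sp; sp3@resels <- 3 * sp@resels
    expect_equal(expectedPeaks(4, sp3, fg), 3 * expectedPeaks(4, sp, fg))
    # doubling every axis: the top-dimensional term (x8) dominates high u
    sp2 <- SearchSpace(c(128, 128, 64), fwhm = 4)
    expect_equal(expectedPeaks(6, sp2, fg) / expectedPeaks(6, sp, fg), 8,
                 tolerance = 0.04)
})

test_that("FWE peak p-value clips to [0,1] and inverts to 1e-8", {
    sp <- SearchSpace(c(64, 64, 32), fwhm = 4)
    expect_equal(peakPFwe(0.5, sp, f15), 1)
    expect_lt(peakPFwe(15, sp, f15), 1e-3)
    z <- seq(1, 12, by = 0.25)
    p <- peakPFwe(z, sp, f15)
    expect_true(all(p >= 0 & p <= 1))
    expect_true(all(diff(p) <= 0))
    for (alpha in c(0.01, 0.05, 0.2)) {
        zs <- fweThreshold(alpha, sp, f15)
        expect_lt(abs(peakPFwe(zs, sp, f15) - alpha), 1e-8)
        # independent bisection oracle, 6 significant figures
        expect_equal(zs, bisectFwe(alpha, sp, f15), tolerance = 1e-6)
    }
    expect_error(fweThreshold(1.2, sp, f15), "alpha")
})

test_that("cluster extent p-value has exponential-form tail behaviour", {
    sp <- SearchSpace(c(64, 64, 32), fwhm = 4)
    expect_equal(clusterExtentP(0, 3, sp, fg), 1)
    s <- seq(0, 5, by = 0.05)
    p <- clusterExtentP(s, 3, sp, fg)
    expect_true(all(diff(p) < 0))
    expect_lt(clusterExtentP(50, 3, sp, fg), 1e-8)
    expect_error(clusterExtentP(-1, 3, sp, fg), "non-negative")
    # beta calibration: implied mean extent = expected suprathreshold
    # volume / expected cluster count
    EN <- pnorm(3, lower.tail = FALSE) * resels(sp)[4]
    Em <- expectedPeaks(3, sp, fg)
    meanModel <- integrate(function(x) clusterExtentP(x, 3, sp, fg),
                           0, Inf)$value
    expect_equal(meanModel, EN / Em, tolerance = 1e-6)
})

test_that("extent model is roughly calibrated against simulated clusters", {
    set.seed(22)
    ext <- c()
    for (i in 1:60)
        ext <- c(ext, clusters(labelClusters(
            smoothNoiseField(c(64, 64, 32), 4), 3))$nVoxels)
    sp <- SearchSpace(c(64, 64, 32), fwhm = 4)
    # the model's p at the empirical median extent should be a central
    # probability; the approximation is coarse on a discrete lattice, so a
    # wide central band is the honest requirement
    pm <- clusterExtentP(median(ext) / 64, 3, sp, fg)
    expect_gt(pm, 0.3)
    expect_lt(pm, 0.7)
})

test_that("search space resel counts follow the box geometry", {
    sp <- SearchSpace(c(64, 64, 32), fwhm = 4)
    expect_equal(resels(sp), c(1, 40, 512, 2048))
    # volume / prod(FWHM) in mm
    sp2 <- SearchSpace(c(64, 64, 32), fwhm = 12, voxelSize = 3)
    expect_equal(resels(sp2)[4], prod(c(64, 64, 32) * 3) / 12^3)
    expect_error(SearchSpace(c(10, 10), fwhm = 0), "positive")
})
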