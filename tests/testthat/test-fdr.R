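# BH selection, q-values and the four decision procedures.

test_that("BH step-up selection matches the hand-worked definition", {
    expect_equal(bhSelect(numeric(0), 0.05), list(k = 0L, threshold = 0))
    # 0.01 <= 1*0.05/3, 0.02 <= 2*0.05/3, 0.5 > 3*0.05/3
    expect_equal(bhSelect(c(0.01, 0.02, 0.5), 0.05),
                 list(k = 2L, threshold = 0.02))
    # m identical p-values just under alpha: p_(m) <= m*alpha/m
    expect_equal(bhSelect(rep(0.045, 7), 0.05)$k, 7L)
    expect_error(bhSelect(c(0.2, 1.4), 0.05), "\\[0, 1\\]")
    expect_error(bhSelect(0.2, 1.5), "alpha")
})

test_that("BH selection agrees exactly with brute-force enumeration", {
    set.seed(201)
    for (i in 1:2000) {
        m <- sample(0:20, 1)
        p <- runif(m)^sample(1:3, 1)
        a <- runif(1, 0.01, 0.3)
        got <- bhSelect(p, a)
        want <- bruteBH(p, a)
        expect_identical(got$k, as.integer(want$k))
        expect_equal(got$threshold, want$threshold)
    }
})

test_that("q-values are the step-up adjusted p-values", {
    expect_equal(qValues(0.37), 0.37)                     # m = 1
    expect_equal(qValues(c(0.01, 0.02, 0.5)), c(0.03, 0.03, 0.5))
    set.seed(202)
    for (i in 1:200) {
        p <- runif(sample(1:15, 1))
        q <- qValues(p)
        expect_equal(q, bruteQ(p))
        expect_true(all(q >= p))
        expect_true(all(diff(sort(q)) >= -1e-12))
        # rejection-set equivalence with bhSelect
        a <- runif(1, 0.02, 0.3)
        expect_equal(sum(q <= a), bhSelect(p, a)$k)
    }
    # BY variant is more conservative
    p <- runif(20)
    expect_true(all(qValues(p, "BY") >= qValues(p, "BH")))
})

test_that("all four procedures discover an overwhelming activation", {
    set.seed(203)
    shape <- c(32, 32, 16)
    sig <- sampleSignal(1, shape, heights = 30, widths = 5)
    map <- smoothNoiseField(shape, 4) * 0.5 + sig$signal
    sp <- SearchSpace(shape, fwhm = 4)
    fld <- FieldSpec("gaussian")
    for (proc in c("peak_fwe", "peak_fdr", "cluster_fdr", "voxel_fdr")) {
        r <- suppressWarnings(runProcedure(map, proc, u = 3, space = sp,
                                           field = fld))
        expect_gte(nrow(peaks(r)), 1L)
        expect_lte(min(minDistances(r, sig$truth)), 1.01)
        pk <- peaks(r)
        expect_true(all(pk$p_unc >= 0 & pk$p_unc <= 1))
        expect_true(all(is.na(pk$q) | (pk$q >= 0 & pk$q <= 1)))
    }
})

test_that("procedure preconditions and empty excursion sets are handled", {
    sp <- SearchSpace(c(16, 16, 8), fwhm = 4)
    fld <- FieldSpec("gaussian")
    m <- array(0.1, c(16, 16, 8)); m[3, 3, 3] <- 0.2
    expect_error(runProcedure(m, "peak_fdr", space = sp, field = fld),
                 "requires a feature-defining threshold")
    r <- runProcedure(m, "peak_fwe", u = 3, space = sp, field = fld)
    expect_equal(nrow(peaks(r)), 0L)
    expect_equal(r@nHarvested, 0L)
    expect_error(runProcedure(m, "peak_fdr", u = 3, space = sp,
                              field = FieldSpec("t", dof = 15),
                              alpha = 2), "alpha")
    expect_error(runProcedure(array(0, c(4, 4, 4)), "peak_fwe", u = 3,
                              space = sp, field = fld), "shape")
})

test_that("a warning is raised when too few peaks feed the FDR step", {
    set.seed(204)
    shape <- c(24, 24, 12)
    sig <- sampleSignal(1, shape, heights = 10, widths = 4)
    map <- smoothNoiseField(shape, 4) * 0.3 + sig$signal
    expect_warning(
        runProcedure(map, "peak_fdr", u = 3,
                     space = SearchSpace(shape, fwhm = 4),
                     field = FieldSpec("gaussian")),
        "peaks harvested")
})

test_that("procedure sensitivity nests as expected on a simulated SPM", {
    set.seed(205)
    sim <- simulateSpm(8, shape = c(48, 48, 24), seed = 205)
    res <- lapply(setNames(nm = c("peak_fwe", "peak_fdr", "voxel_fdr")),
        function(p) suppressWarnings(runProcedure(sim$map, p, u = 2.5,
            space = sim$space, field = sim$field)))
    nFwe <- nrow(peaks(res$peak_fwe))
    nFdr <- nrow(peaks(res$peak_fdr))
    nVox <- nrow(peaks(res$voxel_fdr))
    # peak-FDR rejects by an adaptive uncorrected-p cutoff; whenever that
    # cutoff is at least the FWE-implied one, FWE discoveries nest inside
    expect_gte(nFdr, nFwe)
    key <- function(p) paste(p$i, p$j, p$k)
    expect_true(all(key(peaks(res$peak_fwe)) %in% key(peaks(res$peak_fdr))))
    # voxel-FDR counts peaks among surviving voxels and is more liberal
    expect_gte(nVox, nFdr)
})

test_that("masked voxels are excluded from the voxel-FDR family", {
    set.seed(206)
    shape <- c(24, 24, 12)
    map <- smoothNoiseField(shape, 4)
    map[1:12, , ] <- NA
    r <- runProcedure(map, "voxel_fdr",
                      space = SearchSpace(shape, fwhm = 4),
                      field = FieldSpec("gaussian"))
    expect_equal(r@nHarvested, sum(!is.na(map)))
})
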