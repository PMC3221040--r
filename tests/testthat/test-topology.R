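# Feature extraction on lattices: maxima, clusters, smoothness.

test_that("local maxima on toy lattices match exhaustive comparison", {
    m <- toyTwoBumps()
    pk <- findLocalMaxima(m, u = 1)
    expect_equal(nrow(pk), 2L)
    expect_equal(pk$height, c(5, 3))            # descending height
    expect_equal(unlist(pk[1, 1:3]), c(i = 4, j = 4, k = 4))
    expect_equal(unlist(pk[2, 1:3]), c(i = 2, j = 2, k = 2))
    # constant map: no strict maxima anywhere
    expect_equal(nrow(findLocalMaxima(array(1, c(4, 4, 4)), 0)), 0L)
    # single spike
    s <- array(0, c(6, 6, 6)); s[3, 5, 2] <- 7
    expect_equal(unlist(findLocalMaxima(s, 0.5)[1, 1:3]),
                 c(i = 3, j = 5, k = 2))
    expect_error(findLocalMaxima(numeric(0), 0), "empty")
})

test_that("maxima agree with the brute-force oracle on random fields", {
    set.seed(101)
    for (conn in c(6L, 18L, 26L)) {
        for (r in 1:5) {
            m <- array(rnorm(6 * 6 * 5), c(6, 6, 5))
            pk <- findLocalMaxima(m, 0.2, connectivity = conn)
            o <- bruteMaxima(m, 0.2, conn)
            got <- as.matrix(pk[, 1:3]); dimnames(got) <- NULL
            expect_equal(got[order(got[, 1], got[, 2], got[, 3]), ,
                             drop = FALSE],
                         o[order(o[, 1], o[, 2], o[, 3]), , drop = FALSE])
        }
    }
})

test_that("plateaus are skipped under strict comparison, tie-broken by flag", {
    m <- array(0, c(5, 5, 3))
    m[2:3, 2, 2] <- 2                           # two-voxel plateau
    expect_equal(nrow(findLocalMaxima(m, 1)), 0L)
    pk <- findLocalMaxima(m, 1, plateau = TRUE)
    expect_equal(nrow(pk), 1L)
    expect_equal(unlist(pk[1, 1:3]), c(i = 2, j = 2, k = 2))
})

test_that("boundary voxels can be maxima", {
    m <- array(0, c(4, 4, 4)); m[1, 1, 1] <- 3
    expect_equal(nrow(findLocalMaxima(m, 1)), 1L)
})

test_that("cluster labels match a flood-fill oracle", {
    set.seed(102)
    for (conn in c(6L, 18L, 26L)) {
        m <- array(rnorm(7 * 6 * 5), c(7, 6, 5))
        es <- labelClusters(m, 0.8, connectivity = conn)
        o <- bruteLabels(m, 0.8, conn)
        # same partition: sizes of matched labels agree
        expect_equal(max(es@labels), max(o))
        expect_equal(sort(tabulate(es@labels[es@labels > 0])),
                     sort(tabulate(o[o > 0])))
        # identical membership up to label permutation
        expect_true(all((es@labels > 0) == (o > 0)))
        tab <- table(es@labels[es@labels > 0], o[o > 0])
        expect_true(all(rowSums(tab > 0) == 1))
    }
})

test_that("excursion-set structure: thresholds nest, peaks partition", {
    set.seed(103)
    m <- smoothNoiseField(c(32, 32, 16), fwhm = 4)
    e1 <- labelClusters(m, 1.5)
    e2 <- labelClusters(m, 2.2)
    # features at the higher threshold are a subset
    p1 <- peaks(e1); p2 <- peaks(e2)
    key <- function(p) paste(p$i, p$j, p$k)
    expect_true(all(key(p2) %in% key(p1)))
    expect_lte(sum(clusters(e2)$nVoxels), sum(clusters(e1)$nVoxels))
    # each peak carries exactly one cluster label; counts add up
    expect_false(any(is.na(p1$cluster)) || any(p1$cluster == 0))
    expect_equal(sum(table(p1$cluster)), nrow(p1))
    expect_equal(nClusters(e1), max(e1@labels))
    # above the global maximum: empty excursion set
    e3 <- labelClusters(m, max(m) + 1)
    expect_equal(nClusters(e3), 0L)
    expect_equal(nrow(peaks(e3)), 0L)
})

test_that("two separated spikes form two clusters", {
    m <- array(0, c(8, 8, 8))
    m[2, 2, 2] <- 5; m[6, 6, 6] <- 4
    es <- labelClusters(m, 1)
    expect_equal(nClusters(es), 2L)
    expect_equal(clusters(es)$nVoxels, c(1L, 1L))
})

test_that("smoothness estimation recovers the generating kernel", {
    set.seed(104)
    flds4 <- replicate(3, smoothNoiseField(c(64, 64, 32), 4),
                       simplify = FALSE)
    est4 <- estimateFwhm(flds4)
    expect_true(all(abs(est4 - 4) / 4 < 0.1))
    # isotropy: per-axis estimates agree
    expect_lt(diff(range(est4)) / mean(est4), 0.1)
    flds8 <- replicate(3, smoothNoiseField(c(64, 64, 32), 8),
                       simplify = FALSE)
    expect_true(all(abs(estimateFwhm(flds8) - 8) / 8 < 0.1))
    # white noise: the discrete-derivative identity gives
    # sqrt(4 log 2 / 2) because var of a first difference is 2
    wh <- replicate(2, array(rnorm(48 * 48 * 24), c(48, 48, 24)),
                    simplify = FALSE)
    expect_equal(mean(estimateFwhm(wh)), sqrt(2 * log(2)),
                 tolerance = 0.02)
    expect_error(estimateFwhm(list(array(1, c(4, 4, 4)),
                                   array(1, c(4, 4, 4)))), "constant")
    expect_error(estimateFwhm(flds4[1]), "at least 2")
})
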