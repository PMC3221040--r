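# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check.

# exhaustive neighbour comparison: strict local maxima above u
bruteMaxima <- function(map, u, connectivity = 26) {
    d <- dim(map)
    maxAbs <- switch(as.character(connectivity), "6" = 1, "18" = 2, "26" = 3)
    hits <- NULL
    for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
        v <- map[i, j, k]
        if (is.na(v) || v <= u) next
        ok <- TRUE
        for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
            s <- abs(dx) + abs(dy) + abs(dz)
            if (s == 0 || s > maxAbs) next
            ii <- i + dx; jj <- j + dy; kk <- k + dz
            if (ii < 1 || jj < 1 || kk < 1 ||
                ii > d[1] || jj > d[2] || kk > d[3]) next
            w <- map[ii, jj, kk]
            if (!is.na(w) && v <= w) ok <- FALSE
        }
        if (ok) hits <- rbind(hits, c(i, j, k))
    }
    hits
}

# recursive flood fill labelling of {map > u}
bruteLabels <- function(map, u, connectivity = 18) {
    d <- dim(map)
    maxAbs <- switch(as.character(connectivity), "6" = 1, "18" = 2, "26" = 3)
    lab <- array(0L, d)
    nxt <- 0L
    for (k0 in seq_len(d[3])) for (j0 in seq_len(d[2])) for (i0 in seq_len(d[1])) {
        if (is.na(map[i0, j0, k0]) || map[i0, j0, k0] <= u ||
            lab[i0, j0, k0] > 0L) next
        nxt <- nxt + 1L
        stack <- list(c(i0, j0, k0))
        lab[i0, j0, k0] <- nxt
        while (length(stack)) {
            p <- stack[[length(stack)]]
            stack[[length(stack)]] <- NULL
            for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
                s <- abs(dx) + abs(dy) + abs(dz)
                if (s == 0 || s > maxAbs) next
                q <- p + c(dx, dy, dz)
                if (any(q < 1) || any(q > d)) next
                if (!is.na(map[q[1], q[2], q[3]]) &&
                    map[q[1], q[2], q[3]] > u &&
                    lab[q[1], q[2], q[3]] == 0L) {
                    lab[q[1], q[2], q[3]] <- nxt
                    stack[[length(stack) + 1L]] <- q
                }
            }
        }
    }
    lab
}

# literal enumeration of the BH step-up definition
bruteBH <- function(p, alpha) {
    m <- length(p)
    if (m == 0) return(list(k = 0L, threshold = 0))
    ps <- sort(p)
    k <- 0L
    for (j in seq_len(m)) if (ps[j] <= j * alpha / m) k <- j
    list(k = k, threshold = if (k > 0) ps[k] else 0)
}

# literal step-up adjusted p-values: q_(i) = min_{j>=i} m p_(j)/j
bruteQ <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- pmin(rev(cummin(rev(m * ps / seq_len(m)))), 1)
    out <- numeric(m)
    out[o] <- q
    out
}

# plain bisection inverse of peakPFwe, independent of fweThreshold
bisectFwe <- function(alpha, space, field, lo = 1.5, hi = 50,
                      iter = 200) {
    for (i in seq_len(iter)) {
        mid <- (lo + hi) / 2
        if (peakPFwe(mid, space, field) > alpha) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
}

# small deterministic toy lattice with two separated bumps
toyTwoBumps <- function() {
    m <- array(0, c(5, 5, 5))
    m[2, 2, 2] <- 3
    m[2, 3, 2] <- 1.5        # shoulder of first bump
    m[4, 4, 4] <- 5
    m[4, 4, 3] <- 2          # shoulder of second bump
    m
}
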