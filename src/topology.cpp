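#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Neighbourhood offsets on the 3D lattice. Connectivity 6 = faces,
// 18 = faces + edges, 26 = full Moore neighbourhood.
static int buildOffsets(int connectivity, int off[26][3]) {
    int maxAbs = connectivity == 6 ? 1 : (connectivity == 18 ? 2 : 3);
    int n = 0;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (s == 0 || s > maxAbs) continue;
                off[n][0] = dx; off[n][1] = dy; off[n][2] = dz; ++n;
            }
    return n;
}

// Local maxima above u. Out-of-lattice (and NaN) neighbours count as -Inf,
// so boundary voxels can be maxima. strict = TRUE demands v > every
// neighbour; otherwise v >= all neighbours and v > every lexicographically
// earlier neighbour of equal value (first voxel of a plateau wins).
// [[Rcpp::export(name = ".cppLocalMaxima")]]
IntegerMatrix cppLocalMaxima(NumericVector map, IntegerVector dims,
                             double u, int connectivity, bool strict) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    int off[26][3];
    int noff = buildOffsets(connectivity, off);
    std::vector<int> hits;
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                R_xlen_t idx = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
                double v = map[idx];
                if (ISNAN(v) || !(v > u)) continue;
                bool isMax = true;
                for (int o = 0; o < noff && isMax; ++o) {
                    int xx = x + off[o][0], yy = y + off[o][1],
                        zz = z + off[o][2];
                    if (xx < 0 || yy < 0 || zz < 0 ||
                        xx >= nx || yy >= ny || zz >= nz) continue;
                    R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
                    double w = map[j];
                    if (ISNAN(w)) continue;
                    if (strict) {
                        if (!(v > w)) isMax = false;
                    } else {
                        if (v < w) isMax = false;
                        else if (v == w && j < idx) isMax = false;
                    }
                }
                if (isMax) hits.push_back((int)idx);
            }
    IntegerMatrix out(hits.size(), 3);
    for (size_t r = 0; r < hits.size(); ++r) {
        int idx = hits[r];
        out(r, 0) = idx % nx + 1;
        out(r, 1) = (idx / nx) % ny + 1;
        out(r, 2) = idx / (nx * ny) + 1;
    }
    return out;
}

// Connected-component labels of {map > u}; 0 elsewhere. Labels are
// assigned in order of the first (column-major) voxel of each component.
// [[Rcpp::export(name = ".cppLabelClusters")]]
IntegerVector cppLabelClusters(NumericVector map, IntegerVector dims,
                               double u, int connectivity) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    R_xlen_t n = (R_xlen_t)nx * ny * nz;
    int off[26][3];
    int noff = buildOffsets(connectivity, off);
    IntegerVector lab(n, 0);
    int next = 0;
    std::queue<int> q;
    for (R_xlen_t i = 0; i < n; ++i) {
        double v = map[i];
        if (ISNAN(v) || !(v > u) || lab[i]) continue;
        lab[i] = ++next;
        q.push((int)i);
        while (!q.empty()) {
            int c = q.front(); q.pop();
            int x = c % nx, y = (c / nx) % ny, z = c / (nx * ny);
            for (int o = 0; o < noff; ++o) {
                int xx = x + off[o][0], yy = y + off[o][1],
                    zz = z + off[o][2];
                if (xx < 0 || yy < 0 || zz < 0 ||
                    xx >= nx || yy >= ny || zz >= nz) continue;
                R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
                double w = map[j];
                if (ISNAN(w) || !(w > u) || lab[j]) continue;
                lab[j] = next;
                q.push((int)j);
            }
        }
    }
    return lab;
}
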