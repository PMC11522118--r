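// 3-D texture matrix builders operating on a dense integer level grid.
// Convention: `levels` is a column-major array of dims d1*d2*d3 holding
// discretised grey levels 1..ng inside the lesion mask and 0 outside.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 13 unique 3-D direction offsets at Chebyshev distance 1 (up to sign).
static const int OFFS13[13][3] = {
    {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
    {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
    {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}};

// all 26 neighbour offsets
static void offs26(int out[26][3]) {
    int k = 0;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                if (dx == 0 && dy == 0 && dz == 0) continue;
                out[k][0] = dx; out[k][1] = dy; out[k][2] = dz; ++k;
            }
}

static inline int idx3(int x, int y, int z, int d1, int d2) {
    return x + d1 * (y + d2 * z);
}

static inline bool inb(int x, int y, int z, int d1, int d2, int d3) {
    return x >= 0 && x < d1 && y >= 0 && y < d2 && z >= 0 && z < d3;
}

// Ordered co-occurrence counts per direction: ng x ng x 13 (not yet
// symmetrised or normalised -- that happens in R).
// [[Rcpp::export]]
NumericVector cpp_glcm_counts(IntegerVector levels, IntegerVector dims,
                              int ng, int distance) {
    int d1 = dims[0], d2 = dims[1], d3 = dims[2];
    NumericVector out(ng * ng * 13);
    for (int a = 0; a < 13; ++a) {
        int ox = OFFS13[a][0] * distance, oy = OFFS13[a][1] * distance,
            oz = OFFS13[a][2] * distance;
        for (int z = 0; z < d3; ++z)
            for (int y = 0; y < d2; ++y)
                for (int x = 0; x < d1; ++x) {
                    int li = levels[idx3(x, y, z, d1, d2)];
                    if (li <= 0) continue;
                    int nx = x + ox, ny = y + oy, nz = z + oz;
                    if (!inb(nx, ny, nz, d1, d2, d3)) continue;
                    int lj = levels[idx3(nx, ny, nz, d1, d2)];
                    if (lj <= 0) continue;
                    out[(li - 1) + ng * (lj - 1) + ng * ng * a] += 1.0;
                }
    }
    out.attr("dim") = IntegerVector::create(ng, ng, 13);
    return out;
}

// Run-length counts per direction: ng x maxlen x 13. A run starts at a
// voxel whose predecessor along the direction is outside the mask or has a
// different level; out-of-mask voxels break runs.
// [[Rcpp::export]]
NumericVector cpp_glrlm_counts(IntegerVector levels, IntegerVector dims,
                               int ng) {
    int d1 = dims[0], d2 = dims[1], d3 = dims[2];
    int maxlen = std::max(d1, std::max(d2, d3));
    NumericVector out(ng * maxlen * 13);
    for (int a = 0; a < 13; ++a) {
        int ox = OFFS13[a][0], oy = OFFS13[a][1], oz = OFFS13[a][2];
        for (int z = 0; z < d3; ++z)
            for (int y = 0; y < d2; ++y)
                for (int x = 0; x < d1; ++x) {
                    int li = levels[idx3(x, y, z, d1, d2)];
                    if (li <= 0) continue;
                    int px = x - ox, py = y - oy, pz = z - oz;
                    if (inb(px, py, pz, d1, d2, d3) &&
                        levels[idx3(px, py, pz, d1, d2)] == li)
                        continue;  // not a run start
                    int len = 1;
                    int cx = x + ox, cy = y + oy, cz = z + oz;
                    while (inb(cx, cy, cz, d1, d2, d3) &&
                           levels[idx3(cx, cy, cz, d1, d2)] == li) {
                        ++len; cx += ox; cy += oy; cz += oz;
                    }
                    out[(li - 1) + ng * (len - 1) + ng * maxlen * a] += 1.0;
                }
    }
    out.attr("dim") = IntegerVector::create(ng, maxlen, 13);
    return out;
}

// Dependence counts: ng x 27; column j holds voxels with (j-1) dependent
// 26-neighbours (|level difference| <= alpha, neighbour in mask).
// [[Rcpp::export]]
NumericVector cpp_gldm_counts(IntegerVector levels, IntegerVector dims,
                              int ng, double alpha) {
    int d1 = dims[0], d2 = dims[1], d3 = dims[2];
    int offs[26][3];
    offs26(offs);
    NumericVector out(ng * 27);
    for (int z = 0; z < d3; ++z)
        for (int y = 0; y < d2; ++y)
            for (int x = 0; x < d1; ++x) {
                int li = levels[idx3(x, y, z, d1, d2)];
                if (li <= 0) continue;
                int dep = 0;
                for (int k = 0; k < 26; ++k) {
                    int nx = x + offs[k][0], ny = y + offs[k][1],
                        nz = z + offs[k][2];
                    if (!inb(nx, ny, nz, d1, d2, d3)) continue;
                    int lj = levels[idx3(nx, ny, nz, d1, d2)];
                    if (lj <= 0) continue;
                    if (std::abs((double)(li - lj)) <= alpha) ++dep;
                }
                out[(li - 1) + ng * dep] += 1.0;
            }
    out.attr("dim") = IntegerVector::create(ng, 27);
    return out;
}

// Neighbouring grey-tone difference accumulators. Row i: n_i (count of
// voxels at level i having at least one in-mask 26-neighbour) and s_i
// (summed |level - mean neighbour level|).
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm_counts(IntegerVector levels, IntegerVector dims,
                               int ng) {
    int d1 = dims[0], d2 = dims[1], d3 = dims[2];
    int offs[26][3];
    offs26(offs);
    NumericMatrix out(ng, 2);
    for (int z = 0; z < d3; ++z)
        for (int y = 0; y < d2; ++y)
            for (int x = 0; x < d1; ++x) {
                int li = levels[idx3(x, y, z, d1, d2)];
                if (li <= 0) continue;
                int cnt = 0;
                double sum = 0.0;
                for (int k = 0; k < 26; ++k) {
                    int nx = x + offs[k][0], ny = y + offs[k][1],
                        nz = z + offs[k][2];
                    if (!inb(nx, ny, nz, d1, d2, d3)) continue;
                    int lj = levels[idx3(nx, ny, nz, d1, d2)];
                    if (lj <= 0) continue;
                    ++cnt; sum += lj;
                }
                if (cnt == 0) continue;
                out(li - 1, 0) += 1.0;
                out(li - 1, 1) += std::fabs((double)li - sum / cnt);
            }
    return out;
}

// 26-connected component labelling. by_value = true connects only equal
// positive values (size-zone semantics); false connects any positive
// voxels (binary blob splitting). Labels are assigned in raster-scan
// order of each component's first voxel, starting at 1.
// [[Rcpp::export]]
IntegerVector cpp_label26(IntegerVector values, IntegerVector dims,
                          bool by_value) {
    int d1 = dims[0], d2 = dims[1], d3 = dims[2];
    int n = d1 * d2 * d3;
    int offs[26][3];
    offs26(offs);
    IntegerVector lab(n, 0);
    std::vector<int> stack;
    int next = 0;
    for (int z = 0; z < d3; ++z)
        for (int y = 0; y < d2; ++y)
            for (int x = 0; x < d1; ++x) {
                int i0 = idx3(x, y, z, d1, d2);
                if (values[i0] <= 0 || lab[i0] != 0) continue;
                ++next;
                lab[i0] = next;
                stack.clear();
                stack.push_back(i0);
                while (!stack.empty()) {
                    int cur = stack.back();
                    stack.pop_back();
                    int cz = cur / (d1 * d2);
                    int cy = (cur / d1) % d2;
                    int cx = cur % d1;
                    for (int k = 0; k < 26; ++k) {
                        int nx = cx + offs[k][0], ny = cy + offs[k][1],
                            nz = cz + offs[k][2];
                        if (!inb(nx, ny, nz, d1, d2, d3)) continue;
                        int ni = idx3(nx, ny, nz, d1, d2);
                        if (lab[ni] != 0 || values[ni] <= 0) continue;
                        if (by_value && values[ni] != values[cur]) continue;
                        lab[ni] = next;
                        stack.push_back(ni);
                    }
                }
            }
    lab.attr("dim") = dims;
    return lab;
}
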