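#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Felzenszwalb & Huttenlocher separable squared Euclidean distance
// transform, generalised to anisotropic voxel spacing.  A large finite
// value stands in for +infinity so the lower-envelope arithmetic stays
// well defined on all-background lines.
static const double BIG = 1e15;

// 1D squared distance transform of sampled function f at spacing w.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, double w) {
    const int n = (int)f.size();
    const double w2 = w * w;
    int k = 0;
    v[0] = 0;
    z[0] = -BIG;
    z[1] = BIG;
    for (int q = 1; q < n; ++q) {
        double s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
                   (2.0 * w * (q - v[k]));
        while (s <= z[k]) {
            --k;
            s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
                (2.0 * w * (q - v[k]));
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = BIG;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (z[k + 1] < w * q) ++k;
        const double dq = w * (q - v[k]);
        d[q] = dq * dq + f[v[k]];
    }
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest TRUE
// voxel centre of `mask`.  dims = c(n1, n2, n3) with column-major layout;
// spacing in mm per axis.  Voxels with no reachable foreground get >= BIG.
// [[Rcpp::export(name = ".edt3d_sq")]]
NumericVector edt3d_sq(LogicalVector mask, IntegerVector dims,
                       NumericVector spacing) {
    const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
    const R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
    if (mask.size() != ntot)
        stop("mask length does not match dims");
    NumericVector g(ntot);
    for (R_xlen_t i = 0; i < ntot; ++i)
        g[i] = (mask[i] == TRUE) ? 0.0 : BIG;

    const int nmax = std::max(n1, std::max(n2, n3));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // pass along axis 1 (stride 1)
    for (int k = 0; k < n3; ++k)
        for (int j = 0; j < n2; ++j) {
            const R_xlen_t base = (R_xlen_t)k * n1 * n2 + (R_xlen_t)j * n1;
            for (int i = 0; i < n1; ++i) f[i] = g[base + i];
            f.resize(n1);
            dt1d(f, d, v, z, spacing[0]);
            for (int i = 0; i < n1; ++i) g[base + i] = d[i];
            f.resize(nmax);
        }
    // pass along axis 2 (stride n1)
    for (int k = 0; k < n3; ++k)
        for (int i = 0; i < n1; ++i) {
            const R_xlen_t base = (R_xlen_t)k * n1 * n2 + i;
            for (int j = 0; j < n2; ++j) f[j] = g[base + (R_xlen_t)j * n1];
            f.resize(n2);
            dt1d(f, d, v, z, spacing[1]);
            for (int j = 0; j < n2; ++j) g[base + (R_xlen_t)j * n1] = d[j];
            f.resize(nmax);
        }
    // pass along axis 3 (stride n1*n2)
    const R_xlen_t s3 = (R_xlen_t)n1 * n2;
    for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1; ++i) {
            const R_xlen_t base = (R_xlen_t)j * n1 + i;
            for (int k = 0; k < n3; ++k) f[k] = g[base + (R_xlen_t)k * s3];
            f.resize(n3);
            dt1d(f, d, v, z, spacing[2]);
            for (int k = 0; k < n3; ++k) g[base + (R_xlen_t)k * s3] = d[k];
            f.resize(nmax);
        }
    return g;
}
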