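#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();

// 1D squared-distance transform (Felzenszwalb & Huttenlocher lower envelope)
// with sample positions x_i = i * h, generalised to non-unit spacing so mixed
// voxel sizes stay exact.
void dt1d(const std::vector<double>& f, std::vector<double>& d, int n, double h) {
    std::vector<int> v(n);
    std::vector<double> z(n + 1);
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    for (int q = 1; q < n; ++q) {
        if (f[q] == INF) continue;
        if (f[v[0]] == INF) { v[0] = q; z[1] = INF; continue; }
        double xq = q * h;
        double s;
        while (true) {
            double xv = v[k] * h;
            s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
            if (s <= z[k]) { --k; } else break;
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = INF;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        if (f[v[0]] == INF) { d[q] = INF; continue; }
        double xq = q * h;
        while (z[k + 1] < xq) ++k;
        double xv = v[k] * h;
        d[q] = (xq - xv) * (xq - xv) + f[v[k]];
    }
}

} // namespace

// Exact Euclidean distance (mm) from every voxel center to the nearest
// mask-voxel center, by three separable squared-distance passes.
// [[Rcpp::export]]
NumericVector edt_mm_cpp(LogicalVector mask, IntegerVector dim,
                         NumericVector voxel_mm) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (mask.size() != n) stop("mask size does not match grid dimensions");

    std::vector<double> g(n);
    for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : INF;

    const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
    std::vector<double> f, d;

    // pass along x
    f.resize(nx); d.resize(nx);
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
            R_xlen_t base = j * sy + k * sz;
            for (int i = 0; i < nx; ++i) f[i] = g[base + i];
            dt1d(f, d, nx, voxel_mm[0]);
            for (int i = 0; i < nx; ++i) g[base + i] = d[i];
        }
    // pass along y
    f.resize(ny); d.resize(ny);
    for (int k = 0; k < nz; ++k)
        for (int i = 0; i < nx; ++i) {
            R_xlen_t base = i + k * sz;
            for (int j = 0; j < ny; ++j) f[j] = g[base + j * sy];
            dt1d(f, d, ny, voxel_mm[1]);
            for (int j = 0; j < ny; ++j) g[base + j * sy] = d[j];
        }
    // pass along z
    f.resize(nz); d.resize(nz);
    for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
            R_xlen_t base = i + j * sy;
            for (int k = 0; k < nz; ++k) f[k] = g[base + k * sz];
            dt1d(f, d, nz, voxel_mm[2]);
            for (int k = 0; k < nz; ++k) g[base + k * sz] = d[k];
        }

    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = (g[i] == INF) ? R_PosInf : std::sqrt(g[i]);
    return out;
}
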