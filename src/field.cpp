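#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sum of point-dipole off-resonance fields over a regular grid.
// Each row of `pts` is a source position (mm, isocenter frame) with amplitude
// coefficient `strength[p]` (Hz mm^3) and per-point exclusion radius
// `excl_mm[p]`. The main-field axis is z, so
//   df(r) = k * (3 dz^2 - |d|^2) / |d|^5  =  k (3 cos^2 theta - 1)/|d|^3.
// Contributions inside a point's exclusion radius are skipped and the voxel is
// flagged invalid (signal void: the model does not hold there).
// [[Rcpp::export]]
List dipole_sum_field_cpp(NumericMatrix pts, NumericVector strength,
                          NumericVector excl_mm,
                          NumericVector ax, NumericVector ay, NumericVector az) {
    const int nx = ax.size(), ny = ay.size(), nz = az.size();
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    const int np = pts.nrow();
    NumericVector val(n);
    LogicalVector invalid(n);

    for (int p = 0; p < np; ++p) {
        const double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
        const double s = strength[p];
        const double e2 = excl_mm[p] * excl_mm[p];
        R_xlen_t id = 0;
        for (int k = 0; k < nz; ++k) {
            const double dz = az[k] - pz, dz2 = dz * dz;
            for (int j = 0; j < ny; ++j) {
                const double dy = ay[j] - py, dyz = dy * dy + dz2;
                for (int i = 0; i < nx; ++i, ++id) {
                    const double dx = ax[i] - px;
                    const double r2 = dx * dx + dyz;
                    if (r2 < e2) { invalid[id] = true; continue; }
                    val[id] += s * (3.0 * dz2 - r2) / (r2 * r2 * std::sqrt(r2));
                }
            }
        }
    }
    return List::create(_["values_hz"] = val, _["invalid"] = invalid);
}
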