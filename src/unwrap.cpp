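#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const double TWO_PI = 6.283185307179586476925286766559;

struct Node {
    double q;     // quality (magnitude)
    R_xlen_t idx; // linear voxel index
};

// Max-heap on quality; ties broken towards the smaller linear index so the
// growth order is fully deterministic.
struct NodeCmp {
    bool operator()(const Node& a, const Node& b) const {
        if (a.q != b.q) return a.q < b.q;
        return a.idx > b.idx;
    }
};

} // namespace

// Quality-guided region-growing phase unwrapping on a 3D grid.
//
// Voxels with magnitude below `threshold_abs` are treated as signal void and
// excluded. Growth starts at `seed_idx` (0-based; -1 selects the
// highest-magnitude valid voxel) and maintains a priority front ordered by
// magnitude. Each popped voxel's unwrapped phase is its wrapped phase plus
// 2*pi*k with k chosen to minimise the distance to the mean of its already
// unwrapped 6-neighbours. Disconnected valid components are each grown from
// their own highest-magnitude seed and referenced to 0 wraps at that seed.
// [[Rcpp::export]]
List unwrap_rg_cpp(NumericVector phase, NumericVector magnitude,
                   IntegerVector dim, double threshold_abs,
                   R_xlen_t seed_idx) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (phase.size() != n || magnitude.size() != n)
        stop("phase/magnitude size does not match grid dimensions");

    NumericVector out(n);
    IntegerVector wraps(n);
    LogicalVector valid(n);
    // state: 0 untouched, 1 queued, 2 unwrapped
    std::vector<unsigned char> state(n, 0);

    R_xlen_t n_valid = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
        if (magnitude[i] >= threshold_abs) { valid[i] = true; ++n_valid; }
    }
    if (n_valid == 0) stop("all voxels are below the void threshold");
    if (seed_idx >= 0 && !valid[seed_idx])
        stop("seed voxel lies below the void threshold");

    const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
    std::priority_queue<Node, std::vector<Node>, NodeCmp> front;

    R_xlen_t n_done = 0;
    bool first_component = true;
    while (n_done < n_valid) {
        // seed for the next connected component
        R_xlen_t seed = -1;
        if (first_component && seed_idx >= 0) {
            seed = seed_idx;
        } else {
            double best = -1.0;
            for (R_xlen_t i = 0; i < n; ++i) {
                if (valid[i] && state[i] == 0 && magnitude[i] > best) {
                    best = magnitude[i];
                    seed = i;
                }
            }
        }
        first_component = false;
        front.push(Node{magnitude[seed], seed});
        state[seed] = 1;

        while (!front.empty()) {
            Node nd = front.top();
            front.pop();
            const R_xlen_t v = nd.idx;
            if (state[v] == 2) continue;

            const R_xlen_t i = v % nx;
            const R_xlen_t j = (v / nx) % ny;
            const R_xlen_t k = v / sz;

            // mean of already-unwrapped 6-neighbours (empty for the seed)
            double nbsum = 0.0;
            int nbcount = 0;
            R_xlen_t nb[6];
            int nnb = 0;
            if (i > 0)      nb[nnb++] = v - sx;
            if (i < nx - 1) nb[nnb++] = v + sx;
            if (j > 0)      nb[nnb++] = v - sy;
            if (j < ny - 1) nb[nnb++] = v + sy;
            if (k > 0)      nb[nnb++] = v - sz;
            if (k < nz - 1) nb[nnb++] = v + sz;
            for (int q = 0; q < nnb; ++q) {
                if (state[nb[q]] == 2) { nbsum += out[nb[q]]; ++nbcount; }
            }

            int kk = 0;
            if (nbcount > 0) {
                const double ref = nbsum / nbcount;
                kk = (int)std::lround((ref - phase[v]) / TWO_PI);
            }
            out[v] = phase[v] + TWO_PI * kk;
            wraps[v] = kk;
            state[v] = 2;
            ++n_done;

            for (int q = 0; q < nnb; ++q) {
                const R_xlen_t w = nb[q];
                if (valid[w] && state[w] == 0) {
                    state[w] = 1;
                    front.push(Node{magnitude[w], w});
                }
            }
        }
    }

    return List::create(_["phase_unwrapped"] = out,
                        _["wrap_count"] = wraps,
                        _["valid"] = valid);
}
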