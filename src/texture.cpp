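#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Per-voxel GLCM texture maps on three orthogonal planes.
//
// For every in-mask voxel a (2r+1)x(2r+1) in-plane patch is scanned in each
// of the three grid planes: axial = axes (1,2), coronal = axes (1,3),
// sagittal = axes (2,3) of the R array. Within the patch, ordered pairs of
// in-mask voxels separated by one of the four in-plane offsets at distance d
// (0, 45, 90, 135 degrees) are accumulated symmetrically into an Ng x Ng
// matrix, which is then normalized; the four Haralick-type features are
// computed per plane and averaged over planes with at least one pair.
//
// `levels` is the quantized volume: integers 1..ng, NA outside the mask.

static inline void plane_features(const int *lev, int d1, int d2, int d3,
                                  int i, int j, int k, int plane,
                                  int ng, int r, int d,
                                  double *feat, int *npairs) {
    // axis pair per plane (0-based array axes)
    int a1 = (plane == 0) ? 0 : (plane == 1) ? 0 : 1;
    int a2 = (plane == 0) ? 1 : (plane == 1) ? 2 : 2;
    const int dirs[4][2] = {{1, 0}, {1, 1}, {0, 1}, {-1, 1}};

    std::vector<double> p(ng * ng, 0.0);
    int pairs = 0;
    int c[3] = {i, j, k};
    int dim[3] = {d1, d2, d3};

    for (int u = -r; u <= r; ++u) {
        for (int v = -r; v <= r; ++v) {
            int x[3] = {c[0], c[1], c[2]};
            x[a1] = c[a1] + u;
            x[a2] = c[a2] + v;
            if (x[0] < 0 || x[0] >= dim[0] || x[1] < 0 || x[1] >= dim[1] ||
                x[2] < 0 || x[2] >= dim[2])
                continue;
            int la = lev[x[0] + (R_xlen_t)dim[0] * (x[1] + (R_xlen_t)dim[1] * x[2])];
            if (la == NA_INTEGER) continue;
            for (int q = 0; q < 4; ++q) {
                int uu = u + dirs[q][0] * d;
                int vv = v + dirs[q][1] * d;
                if (uu < -r || uu > r || vv < -r || vv > r) continue;
                int y[3] = {c[0], c[1], c[2]};
                y[a1] = c[a1] + uu;
                y[a2] = c[a2] + vv;
                if (y[0] < 0 || y[0] >= dim[0] || y[1] < 0 || y[1] >= dim[1] ||
                    y[2] < 0 || y[2] >= dim[2])
                    continue;
                int lb = lev[y[0] + (R_xlen_t)dim[0] * (y[1] + (R_xlen_t)dim[1] * y[2])];
                if (lb == NA_INTEGER) continue;
                p[(la - 1) * ng + (lb - 1)] += 1.0;
                p[(lb - 1) * ng + (la - 1)] += 1.0;
                ++pairs;
            }
        }
    }

    *npairs = pairs;
    if (pairs == 0) return;

    double tot = 2.0 * pairs;
    double auto_ = 0.0, mu = 0.0, savg = 0.0, sosv = 0.0, svar = 0.0;
    std::vector<double> psum(2 * ng + 1, 0.0); // index k = i + j, 2..2ng
    for (int a = 1; a <= ng; ++a) {
        for (int b = 1; b <= ng; ++b) {
            double w = p[(a - 1) * ng + (b - 1)] / tot;
            if (w == 0.0) continue;
            auto_ += (double)a * b * w;
            mu += (double)a * w;
            psum[a + b] += w;
        }
    }
    for (int a = 1; a <= ng; ++a)
        for (int b = 1; b <= ng; ++b) {
            double w = p[(a - 1) * ng + (b - 1)] / tot;
            if (w != 0.0) sosv += (a - mu) * (a - mu) * w;
        }
    for (int k2 = 2; k2 <= 2 * ng; ++k2) savg += k2 * psum[k2];
    for (int k2 = 2; k2 <= 2 * ng; ++k2)
        svar += (k2 - savg) * (k2 - savg) * psum[k2];

    feat[0] = auto_;
    feat[1] = savg;
    feat[2] = sosv;
    feat[3] = svar;
}

// [[Rcpp::export]]
List cpp_texture_maps(IntegerVector levels, IntegerVector dims,
                      int ng, int r, int d) {
    int d1 = dims[0], d2 = dims[1], d3 = dims[2];
    R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
    NumericVector auto_map(n, NA_REAL), savg_map(n, NA_REAL),
        sosv_map(n, NA_REAL), svar_map(n, NA_REAL);
    const int *lev = INTEGER(levels);

    for (int k = 0; k < d3; ++k) {
        for (int j = 0; j < d2; ++j) {
            for (int i = 0; i < d1; ++i) {
                R_xlen_t idx = i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
                if (lev[idx] == NA_INTEGER) continue;
                double acc[4] = {0, 0, 0, 0};
                int nplanes = 0;
                for (int pl = 0; pl < 3; ++pl) {
                    double f[4];
                    int np = 0;
                    plane_features(lev, d1, d2, d3, i, j, k, pl, ng, r, d, f, &np);
                    if (np > 0) {
                        for (int t = 0; t < 4; ++t) acc[t] += f[t];
                        ++nplanes;
                    }
                }
                if (nplanes > 0) {
                    auto_map[idx] = acc[0] / nplanes;
                    savg_map[idx] = acc[1] / nplanes;
                    sosv_map[idx] = acc[2] / nplanes;
                    svar_map[idx] = acc[3] / nplanes;
                }
            }
        }
    }

    IntegerVector dm = clone(dims);
    auto_map.attr("dim") = dm;
    savg_map.attr("dim") = dm;
    sosv_map.attr("dim") = dm;
    svar_map.attr("dim") = dm;
    return List::create(_["auto"] = auto_map, _["savg"] = savg_map,
                        _["sosv"] = sosv_map, _["svar"] = svar_map);
}

// Connected-component labelling of a 3D logical mask under 6-, 18- or
// 26-connectivity. Returns integer labels (0 = background), column-major.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
    int d1 = dims[0], d2 = dims[1], d3 = dims[2];
    R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
    IntegerVector labels(n, 0);
    const int *m = LOGICAL(mask);

    // neighbour offsets for the requested connectivity
    std::vector<std::array<int, 3>> offs;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                int nz = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (nz == 0) continue;
                if (connectivity == 6 && nz > 1) continue;
                if (connectivity == 18 && nz > 2) continue;
                offs.push_back({dx, dy, dz});
            }

    int next = 0;
    std::vector<R_xlen_t> queue;
    for (R_xlen_t s = 0; s < n; ++s) {
        if (m[s] != TRUE || labels[s] != 0) continue;
        ++next;
        labels[s] = next;
        queue.clear();
        queue.push_back(s);
        while (!queue.empty()) {
            R_xlen_t cur = queue.back();
            queue.pop_back();
            int i = cur % d1, j = (cur / d1) % d2, k = cur / ((R_xlen_t)d1 * d2);
            for (size_t t = 0; t < offs.size(); ++t) {
                int x = i + offs[t][0], y = j + offs[t][1], z = k + offs[t][2];
                if (x < 0 || x >= d1 || y < 0 || y >= d2 || z < 0 || z >= d3)
                    continue;
                R_xlen_t idx = x + (R_xlen_t)d1 * (y + (R_xlen_t)d2 * z);
                if (m[idx] == TRUE && labels[idx] == 0) {
                    labels[idx] = next;
                    queue.push_back(idx);
                }
            }
        }
    }
    labels.attr("dim") = clone(dims);
    return labels;
}
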