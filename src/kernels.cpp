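#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Amanatides & Woo voxel traversal along the segment p1 -> p2.
// For each voxel crossed, calls visit(linear_index, intersection_length_mm).
template <typename F>
static void traverse(const double* p1, const double* p2,
                     const int* dims, double vox, const double* origin,
                     F visit) {
    double d[3], len = 0.0;
    for (int k = 0; k < 3; ++k) d[k] = p2[k] - p1[k];
    len = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    if (len <= 0.0) return;
    double inv[3];
    for (int k = 0; k < 3; ++k) inv[k] = d[k] / len; // unit direction

    // clip segment to the grid box
    double t0 = 0.0, t1 = len;
    for (int k = 0; k < 3; ++k) {
        double lo = origin[k], hi = origin[k] + dims[k] * vox;
        if (std::fabs(inv[k]) < 1e-12) {
            if (p1[k] <= lo || p1[k] >= hi) return;
        } else {
            double ta = (lo - p1[k]) / inv[k];
            double tb = (hi - p1[k]) / inv[k];
            if (ta > tb) std::swap(ta, tb);
            if (ta > t0) t0 = ta;
            if (tb < t1) t1 = tb;
        }
    }
    if (t0 >= t1) return;

    double start[3];
    for (int k = 0; k < 3; ++k) start[k] = p1[k] + (t0 + 1e-9) * inv[k];
    int idx[3];
    for (int k = 0; k < 3; ++k) {
        idx[k] = (int)std::floor((start[k] - origin[k]) / vox);
        if (idx[k] < 0) idx[k] = 0;
        if (idx[k] >= dims[k]) idx[k] = dims[k] - 1;
    }
    int step[3];
    double tMax[3], tDelta[3];
    for (int k = 0; k < 3; ++k) {
        if (inv[k] > 1e-12) {
            step[k] = 1;
            tMax[k] = t0 + ((origin[k] + (idx[k] + 1) * vox) - start[k]) / inv[k];
            tDelta[k] = vox / inv[k];
        } else if (inv[k] < -1e-12) {
            step[k] = -1;
            tMax[k] = t0 + ((origin[k] + idx[k] * vox) - start[k]) / inv[k];
            tDelta[k] = -vox / inv[k];
        } else {
            step[k] = 0;
            tMax[k] = R_PosInf;
            tDelta[k] = R_PosInf;
        }
    }
    double t = t0;
    int nxny = dims[0] * dims[1];
    while (t < t1) {
        int kmin = 0;
        if (tMax[1] < tMax[kmin]) kmin = 1;
        if (tMax[2] < tMax[kmin]) kmin = 2;
        double tNext = tMax[kmin] < t1 ? tMax[kmin] : t1;
        double seg = tNext - t;
        if (seg > 0)
            visit(idx[0] + idx[1] * dims[0] + idx[2] * nxny, seg);
        t = tNext;
        if (tMax[kmin] >= t1) break;
        idx[kmin] += step[kmin];
        if (idx[kmin] < 0 || idx[kmin] >= dims[kmin]) break;
        tMax[kmin] += tDelta[kmin];
    }
}

// [[Rcpp::export]]
NumericVector cpp_line_integrals(NumericMatrix p1, NumericMatrix p2,
                                 NumericVector values, IntegerVector dims,
                                 double voxel_size, NumericVector origin) {
    int n = p1.nrow();
    NumericVector out(n);
    const double* vals = REAL(values);
    const int* dm = INTEGER(dims);
    const double* org = REAL(origin);
    for (int i = 0; i < n; ++i) {
        double a[3] = { p1(i, 0), p1(i, 1), p1(i, 2) };
        double b[3] = { p2(i, 0), p2(i, 1), p2(i, 2) };
        double acc = 0.0;
        traverse(a, b, dm, voxel_size, org,
                 [&](int v, double l) { acc += vals[v] * l; });
        out[i] = acc;
    }
    return out;
}

// [[Rcpp::export]]
NumericVector cpp_backproject(NumericMatrix p1, NumericMatrix p2,
                              NumericVector weights, IntegerVector dims,
                              double voxel_size, NumericVector origin) {
    int n = p1.nrow();
    const int* dm = INTEGER(dims);
    const double* org = REAL(origin);
    NumericVector img((R_xlen_t)dm[0] * dm[1] * dm[2]);
    double* im = REAL(img);
    for (int i = 0; i < n; ++i) {
        double a[3] = { p1(i, 0), p1(i, 1), p1(i, 2) };
        double b[3] = { p2(i, 0), p2(i, 1), p2(i, 2) };
        double w = weights[i];
        traverse(a, b, dm, voxel_size, org,
                 [&](int v, double l) { im[v] += w * l; });
    }
    img.attr("dim") = dims;
    return img;
}

// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericMatrix p1, NumericMatrix p2,
                                  NumericVector image, IntegerVector dims,
                                  double voxel_size, NumericVector origin) {
    int n = p1.nrow();
    NumericVector out(n);
    const double* im = REAL(image);
    const int* dm = INTEGER(dims);
    const double* org = REAL(origin);
    for (int i = 0; i < n; ++i) {
        double a[3] = { p1(i, 0), p1(i, 1), p1(i, 2) };
        double b[3] = { p2(i, 0), p2(i, 1), p2(i, 2) };
        double acc = 0.0;
        traverse(a, b, dm, voxel_size, org,
                 [&](int v, double l) { acc += im[v] * l; });
        out[i] = acc;
    }
    return out;
}

// List-mode MLEM with multiplicative per-event weights (attenuation) and
// additive expected background (randoms). Update:
//   lambda_v <- lambda_v / S_v * sum_l a_l c_lv / (a_l sum_v' c_lv' lambda_v' + r_l)
// Log-likelihood (up to a data constant): sum_l log f_l - sum_v S_v lambda_v.
// [[Rcpp::export]]
List cpp_mlem(NumericMatrix p1, NumericMatrix p2, NumericVector weights,
              NumericVector randoms, NumericVector sens, IntegerVector dims,
              double voxel_size, NumericVector origin, int n_iter,
              NumericVector init) {
    int n = p1.nrow();
    const int* dm = INTEGER(dims);
    const double* org = REAL(origin);
    R_xlen_t nv = (R_xlen_t)dm[0] * dm[1] * dm[2];
    std::vector<double> lambda(nv), acc(nv);
    for (R_xlen_t v = 0; v < nv; ++v) lambda[v] = init[v];
    const double* S = REAL(sens);
    NumericVector ll(n_iter);
    const double eps = 1e-30;

    for (int it = 0; it < n_iter; ++it) {
        std::fill(acc.begin(), acc.end(), 0.0);
        double loglik = 0.0;
        for (int i = 0; i < n; ++i) {
            double a[3] = { p1(i, 0), p1(i, 1), p1(i, 2) };
            double b[3] = { p2(i, 0), p2(i, 1), p2(i, 2) };
            double f = 0.0;
            traverse(a, b, dm, voxel_size, org,
                     [&](int v, double l) { f += lambda[v] * l; });
            f = weights[i] * f + randoms[i];
            if (f < eps) f = eps;
            loglik += std::log(f);
            double ratio = weights[i] / f;
            traverse(a, b, dm, voxel_size, org,
                     [&](int v, double l) { acc[v] += ratio * l; });
        }
        double slam = 0.0;
        for (R_xlen_t v = 0; v < nv; ++v) slam += S[v] * lambda[v];
        ll[it] = loglik - slam;
        for (R_xlen_t v = 0; v < nv; ++v) {
            if (S[v] > eps) lambda[v] *= acc[v] / S[v];
            else lambda[v] = 0.0; // zero-sensitivity voxels masked
        }
    }
    NumericVector img(nv);
    for (R_xlen_t v = 0; v < nv; ++v) img[v] = lambda[v];
    img.attr("dim") = dims;
    return List::create(_["image"] = img, _["loglik"] = ll);
}
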