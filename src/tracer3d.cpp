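#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Large-but-finite stand-in for +Inf: keeps the parabola intersection
// formula free of Inf - Inf NaNs while dominating any realistic distance.
static const double EDT_INF = 1e300;

// 1-D squared distance transform on a line with grid spacing s
// (lower envelope of parabolas). f holds input squared distances,
// d receives the output; v/z are scratch.
static void dt1d(const std::vector<double>& f, double s, int n,
                 std::vector<double>& d, std::vector<int>& v,
                 std::vector<double>& z) {
    const double s2 = s * s;
    int k = 0;
    v[0] = 0;
    z[0] = -EDT_INF;
    z[1] = EDT_INF;
    for (int q = 1; q < n; ++q) {
        double fq = f[q] + (double)q * q * s2;
        for (;;) {
            int p = v[k];
            double fp = f[p] + (double)p * p * s2;
            double inter = (fq - fp) / (2.0 * s2 * (q - p));
            if (inter <= z[k] && k > 0) {
                --k;
            } else {
                ++k;
                v[k] = q;
                z[k] = inter;
                z[k + 1] = EDT_INF;
                break;
            }
        }
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (z[k + 1] < q) ++k;
        int p = v[k];
        double dq = ((double)q - p) * s;
        d[q] = dq * dq + f[p];
    }
}

// Exact anisotropic Euclidean distance transform of a 3-D logical array.
// `positive` is a logical vector with dim attribute (n1, n2, n3) in R array
// order (first index fastest); `spacing` gives the physical step along each
// of the three array axes. Returns distances in the same physical units.
// [[Rcpp::export(name = ".edt_aniso_cpp")]]
NumericVector edt_aniso_cpp(LogicalVector positive, IntegerVector dim,
                            NumericVector spacing) {
    if (dim.size() != 3 || spacing.size() != 3)
        stop("dim and spacing must have length 3");
    const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
    const R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
    if (positive.size() != ntot) stop("array size mismatch");

    std::vector<double> g(ntot);
    for (R_xlen_t i = 0; i < ntot; ++i)
        g[i] = positive[i] ? 0.0 : EDT_INF;

    int nmax = std::max(n1, std::max(n2, n3));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // pass along each axis: gather the line, transform, scatter back
    const R_xlen_t strides[3] = {1, (R_xlen_t)n1, (R_xlen_t)n1 * n2};
    const int lens[3] = {n1, n2, n3};
    for (int ax = 0; ax < 3; ++ax) {
        const int len = lens[ax];
        const R_xlen_t stride = strides[ax];
        const double s = spacing[ax];
        // iterate over all lines orthogonal to ax
        int o1 = (ax == 0) ? 1 : 0;            // first orthogonal axis
        int o2 = (ax == 2) ? 1 : 2;            // second orthogonal axis
        for (int j2 = 0; j2 < lens[o2]; ++j2) {
            for (int j1 = 0; j1 < lens[o1]; ++j1) {
                R_xlen_t base = (R_xlen_t)j1 * strides[o1] +
                                (R_xlen_t)j2 * strides[o2];
                for (int q = 0; q < len; ++q) f[q] = g[base + q * stride];
                dt1d(f, s, len, d, v, z);
                for (int q = 0; q < len; ++q) g[base + q * stride] = d[q];
            }
        }
    }

    NumericVector out(ntot);
    for (R_xlen_t i = 0; i < ntot; ++i)
        out[i] = (g[i] >= EDT_INF) ? R_PosInf : std::sqrt(g[i]);
    out.attr("dim") = dim;
    return out;
}

// Rigid resampling of a 2-D image. The forward transform maps a point
// p = (x, y) (x = 0-based column, y = 0-based row) to
//     T(p) = R(theta) (p - c) + c + (dx, dy)
// with c the geometric image center and R a rotation by theta degrees
// (counter-clockwise in x-right / y-down display coordinates). The output
// image holds the transformed content: out(q) = img(T^{-1}(q)), sampled
// bilinearly; samples outside the source are set to `fill` (may be NA).
// [[Rcpp::export(name = ".warp_rigid_cpp")]]
NumericMatrix warp_rigid_cpp(NumericMatrix img, double angle_deg,
                             double dx, double dy, double fill) {
    const int nr = img.nrow(), nc = img.ncol();
    NumericMatrix out(nr, nc);
    const double th = angle_deg * M_PI / 180.0;
    const double ct = std::cos(th), st = std::sin(th);
    const double cx = (nc - 1) / 2.0, cy = (nr - 1) / 2.0;
    for (int r = 0; r < nr; ++r) {
        for (int c = 0; c < nc; ++c) {
            // inverse transform: R^T ((q - t) - c) + c
            double qx = c - dx - cx, qy = r - dy - cy;
            double sx = ct * qx + st * qy + cx;
            double sy = -st * qx + ct * qy + cy;
            double val;
            if (sx < 0.0 || sy < 0.0 || sx > nc - 1.0 || sy > nr - 1.0) {
                val = fill;
            } else {
                int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
                int x1 = std::min(x0 + 1, nc - 1);
                int y1 = std::min(y0 + 1, nr - 1);
                double fx = sx - x0, fy = sy - y0;
                double v00 = img(y0, x0), v01 = img(y0, x1);
                double v10 = img(y1, x0), v11 = img(y1, x1);
                val = (1 - fy) * ((1 - fx) * v00 + fx * v01) +
                      fy * ((1 - fx) * v10 + fx * v11);
            }
            out(r, c) = val;
        }
    }
    return out;
}
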