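#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear sample of img at 0-based subpixel (x, y); outside -> 0.
// R matrices are column-major with [row = y + 1, col = x + 1].
static inline double sample_bilinear(const NumericMatrix& img, double x, double y) {
    const int h = img.nrow(), w = img.ncol();
    if (x < 0.0 || y < 0.0 || x > w - 1.0 || y > h - 1.0) return 0.0;
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
    int x1 = x0 + 1 < w ? x0 + 1 : x0;
    int y1 = y0 + 1 < h ? y0 + 1 : y0;
    double fx = x - x0, fy = y - y0;
    double v00 = img(y0, x0), v01 = img(y0, x1), v10 = img(y1, x0), v11 = img(y1, x1);
    return (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11);
}

// Rigid warp implementing "apply motion (dx, dy, theta)" by inverse mapping:
// the output shows the input rotated by theta (degrees, CCW on a y-down
// display) about (cx, cy), then translated by (dx, dy). 0-based coordinates.
// [[Rcpp::export]]
NumericMatrix warp_rigid_cpp(const NumericMatrix& img, double dx, double dy,
                             double theta_deg, double cx, double cy) {
    const int h = img.nrow(), w = img.ncol();
    NumericMatrix out(h, w);
    const double th = theta_deg * M_PI / 180.0;
    // inverse rotation R(-theta) in y-down convention: R(t) = [c, s; -s, c]
    const double c = std::cos(th), s = std::sin(th);
    for (int j = 0; j < w; ++j) {
        for (int i = 0; i < h; ++i) {
            double px = j - dx - cx, py = i - dy - cy;
            // R(-theta) * p : [c, -s; s, c]
            double sx = c * px - s * py + cx;
            double sy = s * px + c * py + cy;
            out(i, j) = sample_bilinear(img, sx, sy);
        }
    }
    return out;
}

// Polar unwrap: rows = radius 0..(n_r - 1) px, cols = angle bins of width
// dtheta_bin degrees starting at 0; sample point is
// (cx + r cos(a), cy + r sin(a)) with a in degrees, y-down.
// [[Rcpp::export]]
NumericMatrix polar_unwrap_cpp(const NumericMatrix& img, double cx, double cy,
                               int n_r, double dtheta_bin) {
    const int n_a = (int)std::lround(360.0 / dtheta_bin);
    NumericMatrix out(n_r, n_a);
    for (int k = 0; k < n_a; ++k) {
        const double a = k * dtheta_bin * M_PI / 180.0;
        const double ca = std::cos(a), sa = std::sin(a);
        for (int r = 0; r < n_r; ++r) {
            out(r, k) = sample_bilinear(img, cx + r * ca, cy + r * sa);
        }
    }
    return out;
}

// Zero-normalised cross-correlation (TM_CCOEFF_NORMED-style) of a template
// against img over integer offsets in [-search, search]^2 relative to the
// template's original top-left (x0, y0) (0-based). Returns a
// (2*search+1) x (2*search+1) score matrix indexed [dy, dx]; offsets whose
// patch leaves the image get NA.
// [[Rcpp::export]]
NumericMatrix match_zncc_cpp(const NumericMatrix& img, const NumericMatrix& tpl,
                             int x0, int y0, int search) {
    const int h = img.nrow(), w = img.ncol();
    const int th_ = tpl.nrow(), tw = tpl.ncol();
    const int n = th_ * tw;
    double tmean = 0.0;
    for (int j = 0; j < tw; ++j) for (int i = 0; i < th_; ++i) tmean += tpl(i, j);
    tmean /= n;
    double tss = 0.0;
    for (int j = 0; j < tw; ++j) for (int i = 0; i < th_; ++i) {
        double d = tpl(i, j) - tmean; tss += d * d;
    }
    const int m = 2 * search + 1;
    NumericMatrix out(m, m);
    const double* ip = REAL(img);
    const double* tp = REAL(tpl);
    // single pass per offset using sum formulations:
    // num = sum(I*T') with T' = T - tmean; iss = sum(I^2) - (sum I)^2 / n
    for (int dyi = 0; dyi < m; ++dyi) {
        for (int dxi = 0; dxi < m; ++dxi) {
            int px = x0 + dxi - search, py = y0 + dyi - search;
            if (px < 0 || py < 0 || px + tw > w || py + th_ > h) {
                out(dyi, dxi) = NA_REAL;
                continue;
            }
            double si = 0.0, sii = 0.0, sit = 0.0;
            for (int j = 0; j < tw; ++j) {
                const double* ic = ip + (size_t)(px + j) * h + py;
                const double* tc = tp + (size_t)j * th_;
                for (int i = 0; i < th_; ++i) {
                    double v = ic[i];
                    si += v;
                    sii += v * v;
                    sit += v * tc[i];
                }
            }
            double num = sit - si * tmean;
            double iss = sii - si * si / n;
            if (iss < 0.0) iss = 0.0;
            double den = std::sqrt(tss * iss);
            out(dyi, dxi) = den > 0.0 ? num / den : 0.0;
        }
    }
    return out;
}

// Normalised squared difference (TM_SQDIFF_NORMED-style) of a region of a
// polar image against another polar image, over circular column shifts in
// [-max_shift, max_shift]. The region spans rows [r0, r0+rh) and columns
// [c0, c0+cw) of ref (0-based); both images share dimensions; the angular
// axis wraps. Returns score vector indexed by shift (lower = better).
// [[Rcpp::export]]
NumericVector match_ssd_polar_cpp(const NumericMatrix& ref, const NumericMatrix& mov,
                                  int r0, int rh, int c0, int cw, int max_shift) {
    const int n_a = ref.ncol();
    const int m = 2 * max_shift + 1;
    NumericVector out(m);
    double tss = 0.0;
    for (int j = 0; j < cw; ++j) {
        int cj = (c0 + j) % n_a;
        for (int i = 0; i < rh; ++i) {
            double v = ref(r0 + i, cj); tss += v * v;
        }
    }
    for (int si = 0; si < m; ++si) {
        int s = si - max_shift;
        double ssd = 0.0, iss = 0.0;
        for (int j = 0; j < cw; ++j) {
            int cj = ((c0 + j + s) % n_a + n_a) % n_a;
            int rj = (c0 + j) % n_a;
            for (int i = 0; i < rh; ++i) {
                double t = ref(r0 + i, rj);
                double v = mov(r0 + i, cj);
                double d = t - v;
                ssd += d * d;
                iss += v * v;
            }
        }
        double den = std::sqrt(tss * iss);
        out[si] = den > 0.0 ? ssd / den : (ssd > 0.0 ? R_PosInf : 0.0);
    }
    return out;
}

// Render 2D isotropic Gaussian spots additively into an image.
// xs, ys are 0-based centres; amp peak amplitudes; sigma shared width.
// [[Rcpp::export]]
NumericMatrix render_spots_cpp(int h, int w, const NumericVector& xs,
                               const NumericVector& ys, const NumericVector& amp,
                               double sigma) {
    NumericMatrix out(h, w);
    const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
    const int rad = (int)std::ceil(4.0 * sigma);
    for (int k = 0; k < xs.size(); ++k) {
        int jx0 = std::max(0, (int)std::floor(xs[k]) - rad);
        int jx1 = std::min(w - 1, (int)std::ceil(xs[k]) + rad);
        int iy0 = std::max(0, (int)std::floor(ys[k]) - rad);
        int iy1 = std::min(h - 1, (int)std::ceil(ys[k]) + rad);
        for (int j = jx0; j <= jx1; ++j) {
            for (int i = iy0; i <= iy1; ++i) {
                double ddx = j - xs[k], ddy = i - ys[k];
                out(i, j) += amp[k] * std::exp(-(ddx * ddx + ddy * ddy) * inv2s2);
            }
        }
    }
    return out;
}
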