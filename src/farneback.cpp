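// Dense optical flow by polynomial expansion (Farneback 2003) and a
// footprint-averaging kernel used by superpixel track propagation.
//
// Each image neighbourhood is approximated by a quadratic polynomial
// f(x) ~ x'Ax + b'x + c under Gaussian weighting; equating the expansions
// of two frames gives A d = -(b2 - b1)/2 for the local displacement d,
// which is solved per pixel after averaging the normal equations over a
// spatial window, iterated with warping over an image pyramid.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// invert a small dense matrix in place (Gauss-Jordan, partial pivoting)
void invert_small(std::vector<double>& m, int n) {
  std::vector<double> inv(n * n, 0.0);
  for (int i = 0; i < n; ++i) inv[i * n + i] = 1.0;
  for (int col = 0; col < n; ++col) {
    int piv = col;
    for (int r = col + 1; r < n; ++r)
      if (std::fabs(m[r * n + col]) > std::fabs(m[piv * n + col])) piv = r;
    if (piv != col)
      for (int k = 0; k < n; ++k) {
        std::swap(m[col * n + k], m[piv * n + k]);
        std::swap(inv[col * n + k], inv[piv * n + k]);
      }
    double d = m[col * n + col];
    if (std::fabs(d) < 1e-300) stop("singular basis Gram matrix");
    for (int k = 0; k < n; ++k) { m[col * n + k] /= d; inv[col * n + k] /= d; }
    for (int r = 0; r < n; ++r) {
      if (r == col) continue;
      double f = m[r * n + col];
      if (f == 0.0) continue;
      for (int k = 0; k < n; ++k) {
        m[r * n + k] -= f * m[col * n + k];
        inv[r * n + k] -= f * inv[col * n + k];
      }
    }
  }
  m = inv;
}

// Per-pixel quadratic expansion. img is H x W (row-major vectors used
// internally). Output: five planes b1, b2, a11, a22, a12.
struct PolyExp {
  int H, W;
  std::vector<double> b1, b2, a11, a22, a12;
};

void poly_expansion(const std::vector<double>& img, int H, int W, int n,
                    double sigma, PolyExp& out) {
  const int win = 2 * n + 1;
  std::vector<double> g(win), xg(win), xxg(win);
  double gsum = 0.0;
  for (int i = -n; i <= n; ++i) gsum += std::exp(-0.5 * i * i / (sigma * sigma));
  for (int i = -n; i <= n; ++i) {
    double gi = std::exp(-0.5 * i * i / (sigma * sigma)) / gsum;
    g[i + n] = gi;
    xg[i + n] = i * gi;
    xxg[i + n] = double(i) * i * gi;
  }
  // Gram matrix of basis (1, x, y, x^2, y^2, xy) under weights g(x)g(y)
  std::vector<double> G(36, 0.0);
  for (int y = -n; y <= n; ++y)
    for (int x = -n; x <= n; ++x) {
      double w = g[x + n] * g[y + n];
      double b[6] = {1.0, double(x), double(y), double(x) * x, double(y) * y,
                     double(x) * y};
      for (int i = 0; i < 6; ++i)
        for (int j = 0; j < 6; ++j) G[i * 6 + j] += w * b[i] * b[j];
    }
  invert_small(G, 6);

  // separable correlations; border handled by index clamping
  std::vector<double> t0(size_t(H) * W), t1(size_t(H) * W), t2(size_t(H) * W);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      double s0 = 0, s1 = 0, s2 = 0;
      for (int i = -n; i <= n; ++i) {
        double v = img[size_t(y) * W + clampi(x + i, 0, W - 1)];
        s0 += g[i + n] * v;
        s1 += xg[i + n] * v;
        s2 += xxg[i + n] * v;
      }
      t0[size_t(y) * W + x] = s0;
      t1[size_t(y) * W + x] = s1;
      t2[size_t(y) * W + x] = s2;
    }
  out.H = H; out.W = W;
  out.b1.assign(size_t(H) * W, 0.0);
  out.b2.assign(size_t(H) * W, 0.0);
  out.a11.assign(size_t(H) * W, 0.0);
  out.a22.assign(size_t(H) * W, 0.0);
  out.a12.assign(size_t(H) * W, 0.0);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      double s1v = 0, sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
      for (int j = -n; j <= n; ++j) {
        int yy = clampi(y + j, 0, H - 1);
        double v0 = t0[size_t(yy) * W + x];
        double v1 = t1[size_t(yy) * W + x];
        double v2 = t2[size_t(yy) * W + x];
        s1v += g[j + n] * v0;
        sx  += g[j + n] * v1;
        sy  += xg[j + n] * v0;
        sxx += g[j + n] * v2;
        syy += xxg[j + n] * v0;
        sxy += xg[j + n] * v1;
      }
      double s[6] = {s1v, sx, sy, sxx, syy, sxy};
      double r[6];
      for (int i = 0; i < 6; ++i) {
        double acc = 0;
        for (int j = 0; j < 6; ++j) acc += G[i * 6 + j] * s[j];
        r[i] = acc;
      }
      size_t p = size_t(y) * W + x;
      out.b1[p] = r[1];
      out.b2[p] = r[2];
      out.a11[p] = r[3];
      out.a22[p] = r[4];
      out.a12[p] = r[5] * 0.5;
    }
}

// box filter with clamped borders via integral image (mean over window)
void box_blur(std::vector<double>& src, int H, int W, int half) {
  std::vector<double> ii(size_t(H + 1) * (W + 1), 0.0);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x)
      ii[size_t(y + 1) * (W + 1) + (x + 1)] =
          src[size_t(y) * W + x] + ii[size_t(y) * (W + 1) + (x + 1)] +
          ii[size_t(y + 1) * (W + 1) + x] - ii[size_t(y) * (W + 1) + x];
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      int y0 = std::max(0, y - half), y1 = std::min(H - 1, y + half);
      int x0 = std::max(0, x - half), x1 = std::min(W - 1, x + half);
      double s = ii[size_t(y1 + 1) * (W + 1) + (x1 + 1)] -
                 ii[size_t(y0) * (W + 1) + (x1 + 1)] -
                 ii[size_t(y1 + 1) * (W + 1) + x0] +
                 ii[size_t(y0) * (W + 1) + x0];
      src[size_t(y) * W + x] = s / (double(y1 - y0 + 1) * (x1 - x0 + 1));
    }
}

inline double bilinear(const std::vector<double>& p, int H, int W, double fy,
                       double fx) {
  fy = std::min(std::max(fy, 0.0), double(H - 1));
  fx = std::min(std::max(fx, 0.0), double(W - 1));
  int y0 = int(fy), x0 = int(fx);
  int y1 = std::min(y0 + 1, H - 1), x1 = std::min(x0 + 1, W - 1);
  double ay = fy - y0, ax = fx - x0;
  return (1 - ay) * ((1 - ax) * p[size_t(y0) * W + x0] + ax * p[size_t(y0) * W + x1]) +
         ay * ((1 - ax) * p[size_t(y1) * W + x0] + ax * p[size_t(y1) * W + x1]);
}

// one flow refinement pass at a single scale; flow planes fx, fy updated
void update_flow(const PolyExp& e1, const PolyExp& e2, std::vector<double>& fx,
                 std::vector<double>& fy, int winsize) {
  int H = e1.H, W = e1.W;
  int half = winsize / 2;
  std::vector<double> G11(size_t(H) * W), G12(size_t(H) * W), G22(size_t(H) * W),
      h1(size_t(H) * W), h2(size_t(H) * W);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      size_t p = size_t(y) * W + x;
      double dx = fx[p], dy = fy[p];
      double wx = x + dx, wy = y + dy;
      double a11 = 0.5 * (e1.a11[p] + bilinear(e2.a11, H, W, wy, wx));
      double a22 = 0.5 * (e1.a22[p] + bilinear(e2.a22, H, W, wy, wx));
      double a12 = 0.5 * (e1.a12[p] + bilinear(e2.a12, H, W, wy, wx));
      double db1 = -0.5 * (bilinear(e2.b1, H, W, wy, wx) - e1.b1[p]) +
                   a11 * dx + a12 * dy;
      double db2 = -0.5 * (bilinear(e2.b2, H, W, wy, wx) - e1.b2[p]) +
                   a12 * dx + a22 * dy;
      G11[p] = a11 * a11 + a12 * a12;
      G12[p] = a12 * (a11 + a22);
      G22[p] = a12 * a12 + a22 * a22;
      h1[p] = a11 * db1 + a12 * db2;
      h2[p] = a12 * db1 + a22 * db2;
    }
  box_blur(G11, H, W, half);
  box_blur(G12, H, W, half);
  box_blur(G22, H, W, half);
  box_blur(h1, H, W, half);
  box_blur(h2, H, W, half);
  for (size_t p = 0; p < size_t(H) * W; ++p) {
    double det = G11[p] * G22[p] - G12[p] * G12[p];
    double tr = G11[p] + G22[p];
    if (std::fabs(det) > 1e-9 * (tr * tr + 1e-12)) {
      fx[p] = (G22[p] * h1[p] - G12[p] * h2[p]) / det;
      fy[p] = (G11[p] * h2[p] - G12[p] * h1[p]) / det;
    } else {
      fx[p] = 0.0;
      fy[p] = 0.0;
    }
  }
}

// 5-tap Gaussian smooth + 2x decimation
void downsample(const std::vector<double>& src, int H, int W,
                std::vector<double>& dst, int& h2, int& w2) {
  static const double k[5] = {0.0625, 0.25, 0.375, 0.25, 0.0625};
  std::vector<double> tmp(size_t(H) * W);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      double s = 0;
      for (int i = -2; i <= 2; ++i)
        s += k[i + 2] * src[size_t(y) * W + clampi(x + i, 0, W - 1)];
      tmp[size_t(y) * W + x] = s;
    }
  std::vector<double> sm(size_t(H) * W);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      double s = 0;
      for (int i = -2; i <= 2; ++i)
        s += k[i + 2] * tmp[size_t(clampi(y + i, 0, H - 1)) * W + x];
      sm[size_t(y) * W + x] = s;
    }
  h2 = (H + 1) / 2;
  w2 = (W + 1) / 2;
  dst.assign(size_t(h2) * w2, 0.0);
  for (int y = 0; y < h2; ++y)
    for (int x = 0; x < w2; ++x)
      dst[size_t(y) * w2 + x] = sm[size_t(std::min(2 * y, H - 1)) * W +
                                   std::min(2 * x, W - 1)];
}

}  // namespace

// [[Rcpp::export(name = ".farneback_flow")]]
NumericVector farneback_flow_cpp(NumericMatrix frame_a, NumericMatrix frame_b,
                                 int levels, int winsize, int iterations,
                                 int poly_n, double poly_sigma) {
  int H = frame_a.nrow(), W = frame_a.ncol();
  // column-major R matrix -> row-major vector
  std::vector<double> ia(size_t(H) * W), ib(size_t(H) * W);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      ia[size_t(y) * W + x] = frame_a(y, x);
      ib[size_t(y) * W + x] = frame_b(y, x);
    }
  // image pyramid (factor 2 per level); drop levels too small for the
  // expansion window
  std::vector<std::vector<double>> pa{ia}, pb{ib};
  std::vector<int> ph{H}, pw{W};
  for (int l = 1; l < levels; ++l) {
    int h2, w2;
    std::vector<double> da, db;
    downsample(pa.back(), ph.back(), pw.back(), da, h2, w2);
    int h2b, w2b;
    downsample(pb.back(), ph.back(), pw.back(), db, h2b, w2b);
    if (h2 < 2 * poly_n + 1 || w2 < 2 * poly_n + 1) break;
    pa.push_back(da);
    pb.push_back(db);
    ph.push_back(h2);
    pw.push_back(w2);
  }
  int top = int(pa.size()) - 1;
  std::vector<double> fx(size_t(ph[top]) * pw[top], 0.0), fy = fx;
  for (int l = top; l >= 0; --l) {
    PolyExp e1, e2;
    poly_expansion(pa[l], ph[l], pw[l], poly_n, poly_sigma, e1);
    poly_expansion(pb[l], ph[l], pw[l], poly_n, poly_sigma, e2);
    for (int it = 0; it < iterations; ++it)
      update_flow(e1, e2, fx, fy, winsize);
    if (l > 0) {  // upsample flow to the next finer level, double values
      int Hn = ph[l - 1], Wn = pw[l - 1];
      std::vector<double> nfx(size_t(Hn) * Wn), nfy(size_t(Hn) * Wn);
      for (int y = 0; y < Hn; ++y)
        for (int x = 0; x < Wn; ++x) {
          double sy = y * (double(ph[l]) / Hn), sx = x * (double(pw[l]) / Wn);
          nfx[size_t(y) * Wn + x] = 2.0 * bilinear(fx, ph[l], pw[l], sy, sx);
          nfy[size_t(y) * Wn + x] = 2.0 * bilinear(fy, ph[l], pw[l], sy, sx);
        }
      fx.swap(nfx);
      fy.swap(nfy);
    }
  }
  NumericVector out(size_t(H) * W * 2);
  out.attr("dim") = IntegerVector::create(H, W, 2);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      out[size_t(x) * H + y] = fx[size_t(y) * W + x];                       // dx
      out[size_t(H) * W + size_t(x) * H + y] = fy[size_t(y) * W + x];      // dy
    }
  return out;
}

// Mean flow over translated superpixel footprints. flow is an (H, W, 2)
// array; rows/cols are frame-0 footprint pixel coordinates (1-based) per
// superpixel; offset is the integer cumulative displacement (dx, dy).
// Returns n x 3: mean dx, mean dy, in-frame pixel count.
// [[Rcpp::export(name = ".footprint_mean_flow")]]
NumericMatrix footprint_mean_flow_cpp(NumericVector flow, List rows, List cols,
                                      IntegerMatrix offset) {
  IntegerVector dim = flow.attr("dim");
  int H = dim[0], W = dim[1];
  int n = rows.size();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    IntegerVector rr = rows[i], cc = cols[i];
    int dx = offset(i, 0), dy = offset(i, 1);
    double sx = 0, sy = 0;
    int cnt = 0;
    for (int k = 0; k < rr.size(); ++k) {
      int r = rr[k] + dy, c = cc[k] + dx;  // 1-based
      if (r < 1 || r > H || c < 1 || c > W) continue;
      sx += flow[size_t(c - 1) * H + (r - 1)];
      sy += flow[size_t(H) * W + size_t(c - 1) * H + (r - 1)];
      ++cnt;
    }
    out(i, 0) = cnt ? sx / cnt : 0.0;
    out(i, 1) = cnt ? sy / cnt : 0.0;
    out(i, 2) = cnt;
  }
  return out;
}
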