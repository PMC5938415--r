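// Difference-of-Gaussians keypoint detector with 128-d gradient-orientation
// descriptors (Lowe-style SIFT), plus brute-force ratio-test matching.
// Everything here is deterministic: no RNG, scan-order tie-breaking.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <array>
#include <limits>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Img {
  int h = 0, w = 0;
  std::vector<float> px;  // row-major
  Img() = default;
  Img(int h_, int w_) : h(h_), w(w_), px((size_t)h_ * w_, 0.f) {}
  inline float at(int r, int c) const { return px[(size_t)r * w + c]; }
  inline float &at(int r, int c) { return px[(size_t)r * w + c]; }
};

inline int clampi(int v, int lo, int hi) { return v < lo ? lo : (v > hi ? hi : v); }

// separable Gaussian blur, replicate borders
Img gauss_blur(const Img &src, double sigma) {
  if (sigma <= 0.01) return src;
  int rad = (int)std::ceil(4.0 * sigma);
  std::vector<float> k(2 * rad + 1);
  double s2 = 2.0 * sigma * sigma, sum = 0.0;
  for (int i = -rad; i <= rad; ++i) { k[i + rad] = (float)std::exp(-i * i / s2); sum += k[i + rad]; }
  for (auto &v : k) v = (float)(v / sum);
  Img tmp(src.h, src.w), dst(src.h, src.w);
  for (int r = 0; r < src.h; ++r)
    for (int c = 0; c < src.w; ++c) {
      float acc = 0.f;
      for (int i = -rad; i <= rad; ++i) acc += k[i + rad] * src.at(r, clampi(c + i, 0, src.w - 1));
      tmp.at(r, c) = acc;
    }
  for (int c = 0; c < src.w; ++c)
    for (int r = 0; r < src.h; ++r) {
      float acc = 0.f;
      for (int i = -rad; i <= rad; ++i) acc += k[i + rad] * tmp.at(clampi(r + i, 0, src.h - 1), c);
      dst.at(r, c) = acc;
    }
  return dst;
}

Img downsample2(const Img &src) {
  Img dst(src.h / 2, src.w / 2);
  for (int r = 0; r < dst.h; ++r)
    for (int c = 0; c < dst.w; ++c) dst.at(r, c) = src.at(2 * r, 2 * c);
  return dst;
}

struct Kp {
  double row, col;     // full-resolution pixel coordinates (0-based)
  double scale;        // absolute sigma
  double ori;          // radians [0, 2pi)
  int octave, layer;
  double row_o, col_o; // octave-local coordinates
  double scl_octv;     // octave-local sigma
};

const int N_BINS = 36;
const int D_DESC = 4, N_ORI = 8;

// dominant orientation(s) from a gradient-orientation histogram
void calc_orientations(const Img &img, const Kp &kp, std::vector<double> &oris) {
  double scl = kp.scl_octv;
  int radius = (int)std::lround(4.5 * scl);
  double wsig = 2.0 * (1.5 * scl) * (1.5 * scl);
  int r0 = (int)std::lround(kp.row_o), c0 = (int)std::lround(kp.col_o);
  double hist[N_BINS] = {0.0};
  for (int dr = -radius; dr <= radius; ++dr) {
    int r = r0 + dr;
    if (r <= 0 || r >= img.h - 1) continue;
    for (int dc = -radius; dc <= radius; ++dc) {
      int c = c0 + dc;
      if (c <= 0 || c >= img.w - 1) continue;
      double gx = img.at(r, c + 1) - img.at(r, c - 1);
      double gy = img.at(r - 1, c) - img.at(r + 1, c);  // y up
      double mag = std::sqrt(gx * gx + gy * gy);
      double ang = std::atan2(gy, gx);
      double wgt = std::exp(-(dr * dr + dc * dc) / wsig);
      int bin = (int)std::lround(N_BINS * (ang + M_PI) / (2 * M_PI)) % N_BINS;
      if (bin < 0) bin += N_BINS;
      hist[bin] += wgt * mag;
    }
  }
  // circular smoothing, two passes of [1 4 6 4 1]/16
  for (int pass = 0; pass < 2; ++pass) {
    double tmp[N_BINS];
    for (int i = 0; i < N_BINS; ++i) {
      tmp[i] = (hist[(i - 2 + N_BINS) % N_BINS] + hist[(i + 2) % N_BINS]) * (1.0 / 16) +
               (hist[(i - 1 + N_BINS) % N_BINS] + hist[(i + 1) % N_BINS]) * (4.0 / 16) +
               hist[i] * (6.0 / 16);
    }
    std::copy(tmp, tmp + N_BINS, hist);
  }
  double mx = *std::max_element(hist, hist + N_BINS);
  if (mx <= 0) return;
  for (int i = 0; i < N_BINS; ++i) {
    int l = (i - 1 + N_BINS) % N_BINS, r = (i + 1) % N_BINS;
    if (hist[i] > hist[l] && hist[i] > hist[r] && hist[i] >= 0.8 * mx) {
      double bin = i + 0.5 * (hist[l] - hist[r]) / (hist[l] - 2 * hist[i] + hist[r]);
      bin = bin < 0 ? bin + N_BINS : (bin >= N_BINS ? bin - N_BINS : bin);
      double ang = bin * 2 * M_PI / N_BINS - M_PI;
      if (ang < 0) ang += 2 * M_PI;
      oris.push_back(ang);
    }
  }
}

// 4x4x8 gradient-orientation histogram descriptor, trilinear interpolation
void calc_descriptor(const Img &img, const Kp &kp, double ori, float *dst) {
  const int d = D_DESC, n = N_ORI;
  double cos_t = std::cos(-ori), sin_t = std::sin(-ori);
  double hist_width = 3.0 * kp.scl_octv;
  int radius = (int)std::lround(hist_width * std::sqrt(2.0) * (d + 1) * 0.5);
  radius = std::min(radius, (int)std::sqrt((double)img.h * img.h + (double)img.w * img.w));
  double exp_scale = -1.0 / (d * d * 0.5);
  int r0 = (int)std::lround(kp.row_o), c0 = (int)std::lround(kp.col_o);
  std::vector<double> hist((d + 2) * (d + 2) * (n + 2), 0.0);
  for (int dr = -radius; dr <= radius; ++dr) {
    for (int dc = -radius; dc <= radius; ++dc) {
      // rotate offset into the keypoint frame (x right, y up)
      double x = dc, y = -dr;
      double xr = (x * cos_t - y * sin_t) / hist_width;
      double yr = (x * sin_t + y * cos_t) / hist_width;
      double rbin = -yr + d / 2.0 - 0.5;  // row bin grows downward in the rotated frame
      double cbin = xr + d / 2.0 - 0.5;
      if (rbin <= -1 || rbin >= d || cbin <= -1 || cbin >= d) continue;
      int r = r0 + dr, c = c0 + dc;
      if (r <= 0 || r >= img.h - 1 || c <= 0 || c >= img.w - 1) continue;
      double gx = img.at(r, c + 1) - img.at(r, c - 1);
      double gy = img.at(r - 1, c) - img.at(r + 1, c);
      double mag = std::sqrt(gx * gx + gy * gy);
      double ang = std::atan2(gy, gx) - ori;
      while (ang < 0) ang += 2 * M_PI;
      while (ang >= 2 * M_PI) ang -= 2 * M_PI;
      double obin = ang * n / (2 * M_PI);
      double wgt = std::exp((xr * xr + yr * yr) * exp_scale) * mag;
      int ri = (int)std::floor(rbin), ci = (int)std::floor(cbin), oi = (int)std::floor(obin);
      double fr = rbin - ri, fc = cbin - ci, fo = obin - oi;
      for (int ir = 0; ir < 2; ++ir) {
        int rr = ri + ir + 1;
        if (rr < 0 || rr >= d + 2) continue;
        double wr = wgt * (ir ? fr : 1 - fr);
        for (int ic = 0; ic < 2; ++ic) {
          int cc = ci + ic + 1;
          if (cc < 0 || cc >= d + 2) continue;
          double wc = wr * (ic ? fc : 1 - fc);
          for (int io = 0; io < 2; ++io) {
            int oo = (oi + io) % n;
            hist[(rr * (d + 2) + cc) * (n + 2) + oo] += wc * (io ? fo : 1 - fo);
          }
        }
      }
    }
  }
  // collapse interior cells to the 128 vector
  std::vector<double> raw(d * d * n);
  for (int ri = 0; ri < d; ++ri)
    for (int ci = 0; ci < d; ++ci)
      for (int oi = 0; oi < n; ++oi)
        raw[(ri * d + ci) * n + oi] = hist[((ri + 1) * (d + 2) + (ci + 1)) * (n + 2) + oi];
  double nrm = 0;
  for (double v : raw) nrm += v * v;
  nrm = std::sqrt(nrm);
  if (nrm < 1e-12) nrm = 1e-12;
  for (auto &v : raw) v = std::min(v / nrm, 0.2);
  nrm = 0;
  for (double v : raw) nrm += v * v;
  nrm = std::sqrt(nrm);
  if (nrm < 1e-12) nrm = 1e-12;
  for (int i = 0; i < d * d * n; ++i)
    dst[i] = (float)std::min(255.0, std::floor(raw[i] * 512.0 / nrm + 0.5));
}

}  // namespace

// [[Rcpp::export(name = ".sift_detect")]]
List sift_detect(NumericMatrix image, int n_octave_layers = 3,
                 double contrast_threshold = 0.04, double edge_threshold = 10.0,
                 double sigma = 1.6, double init_blur = 0.5) {
  const int h = image.nrow(), w = image.ncol();
  const int S = n_octave_layers;
  Img base(h, w);
  for (int r = 0; r < h; ++r)
    for (int c = 0; c < w; ++c) base.at(r, c) = (float)image(r, c);
  double add = std::sqrt(std::max(sigma * sigma - init_blur * init_blur, 0.01));
  base = gauss_blur(base, add);

  int n_oct = (int)std::floor(std::log2((double)std::min(h, w))) - 4;
  n_oct = std::max(1, std::min(n_oct, 8));

  // per-octave Gaussian and DoG stacks
  std::vector<double> sig(S + 3);
  sig[0] = sigma;
  double k = std::pow(2.0, 1.0 / S);
  for (int i = 1; i < S + 3; ++i) {
    double prev = sigma * std::pow(k, i - 1), total = prev * k;
    sig[i] = std::sqrt(total * total - prev * prev);  // incremental
  }
  std::vector<std::vector<Img>> gpyr(n_oct), dpyr(n_oct);
  for (int o = 0; o < n_oct; ++o) {
    gpyr[o].resize(S + 3);
    gpyr[o][0] = (o == 0) ? base : downsample2(gpyr[o - 1][S]);
    for (int i = 1; i < S + 3; ++i) gpyr[o][i] = gauss_blur(gpyr[o][i - 1], sig[i]);
    dpyr[o].resize(S + 2);
    for (int i = 0; i < S + 2; ++i) {
      const Img &a = gpyr[o][i], &b = gpyr[o][i + 1];
      Img d(a.h, a.w);
      for (size_t p = 0; p < d.px.size(); ++p) d.px[p] = b.px[p] - a.px[p];
      dpyr[o][i] = std::move(d);
    }
  }

  const double prelim = 0.5 * contrast_threshold / S;
  const int border = 5;
  std::vector<Kp> kps;
  for (int o = 0; o < n_oct; ++o) {
    int oh = dpyr[o][0].h, ow = dpyr[o][0].w;
    if (oh <= 2 * border || ow <= 2 * border) continue;
    for (int j = 1; j <= S; ++j) {
      const Img &dn = dpyr[o][j - 1], &d0 = dpyr[o][j], &dp = dpyr[o][j + 1];
      for (int r = border; r < oh - border; ++r) {
        for (int c = border; c < ow - border; ++c) {
          float v = d0.at(r, c);
          if (std::fabs(v) <= prelim) continue;
          bool mx = true, mn = true;
          for (int dl = -1; dl <= 1 && (mx || mn); ++dl) {
            const Img &D = (dl < 0) ? dn : (dl > 0 ? dp : d0);
            for (int dr = -1; dr <= 1; ++dr)
              for (int dc = -1; dc <= 1; ++dc) {
                if (dl == 0 && dr == 0 && dc == 0) continue;
                float nv = D.at(r + dr, c + dc);
                if (v <= nv) mx = false;
                if (v >= nv) mn = false;
              }
          }
          if (!(mx || mn)) continue;
          // iterative subpixel refinement
          int rr = r, cc = c, jj = j;
          double xr = 0, xc = 0, xs = 0, contr = 0;
          bool ok = false;
          for (int it = 0; it < 5; ++it) {
            const Img &Dn = dpyr[o][jj - 1], &D0 = dpyr[o][jj], &Dp = dpyr[o][jj + 1];
            double dx = 0.5 * (D0.at(rr, cc + 1) - D0.at(rr, cc - 1));
            double dy = 0.5 * (D0.at(rr + 1, cc) - D0.at(rr - 1, cc));
            double ds = 0.5 * (Dp.at(rr, cc) - Dn.at(rr, cc));
            double dxx = D0.at(rr, cc + 1) + D0.at(rr, cc - 1) - 2.0 * D0.at(rr, cc);
            double dyy = D0.at(rr + 1, cc) + D0.at(rr - 1, cc) - 2.0 * D0.at(rr, cc);
            double dss = Dp.at(rr, cc) + Dn.at(rr, cc) - 2.0 * D0.at(rr, cc);
            double dxy = 0.25 * (D0.at(rr + 1, cc + 1) - D0.at(rr + 1, cc - 1) -
                                 D0.at(rr - 1, cc + 1) + D0.at(rr - 1, cc - 1));
            double dxs = 0.25 * (Dp.at(rr, cc + 1) - Dp.at(rr, cc - 1) -
                                 Dn.at(rr, cc + 1) + Dn.at(rr, cc - 1));
            double dys = 0.25 * (Dp.at(rr + 1, cc) - Dp.at(rr - 1, cc) -
                                 Dn.at(rr + 1, cc) + Dn.at(rr - 1, cc));
            // solve H * x = -g (3x3, Cramer)
            double det = dxx * (dyy * dss - dys * dys) - dxy * (dxy * dss - dys * dxs) +
                         dxs * (dxy * dys - dyy * dxs);
            if (std::fabs(det) < 1e-12) break;
            double bx = -dx, by = -dy, bs = -ds;
            xc = (bx * (dyy * dss - dys * dys) - dxy * (by * dss - dys * bs) +
                  dxs * (by * dys - dyy * bs)) / det;
            xr = (dxx * (by * dss - bs * dys) - bx * (dxy * dss - dys * dxs) +
                  dxs * (dxy * bs - by * dxs)) / det;
            xs = (dxx * (dyy * bs - by * dys) - dxy * (dxy * bs - by * dxs) +
                  bx * (dxy * dys - dyy * dxs)) / det;
            if (std::fabs(xr) < 0.5 && std::fabs(xc) < 0.5 && std::fabs(xs) < 0.5) {
              contr = D0.at(rr, cc) + 0.5 * (dx * xc + dy * xr + ds * xs);
              // edge response on the 2D Hessian
              double tr = dxx + dyy, det2 = dxx * dyy - dxy * dxy;
              double et = edge_threshold;
              if (det2 > 0 && tr * tr / det2 < (et + 1) * (et + 1) / et &&
                  std::fabs(contr) * S >= contrast_threshold) ok = true;
              break;
            }
            rr += (int)std::lround(xr);
            cc += (int)std::lround(xc);
            jj += (int)std::lround(xs);
            if (jj < 1 || jj > S || rr < border || rr >= oh - border ||
                cc < border || cc >= ow - border) break;
          }
          if (!ok) continue;
          Kp kp;
          kp.octave = o; kp.layer = jj;
          kp.row_o = rr + xr; kp.col_o = cc + xc;
          kp.row = kp.row_o * (1 << o); kp.col = kp.col_o * (1 << o);
          kp.scl_octv = sigma * std::pow(2.0, (jj + xs) / S);
          kp.scale = kp.scl_octv * (1 << o);
          if (kp.row < 0 || kp.row > h - 1 || kp.col < 0 || kp.col > w - 1) continue;
          kps.push_back(kp);
        }
      }
    }
  }

  // orientations + descriptors
  std::vector<Kp> out;
  std::vector<std::array<float, 128>> descs;
  for (const Kp &kp : kps) {
    const Img &img = gpyr[kp.octave][kp.layer];
    std::vector<double> oris;
    calc_orientations(img, kp, oris);
    for (double ori : oris) {
      Kp k2 = kp;
      k2.ori = ori;
      std::array<float, 128> d;
      calc_descriptor(img, kp, ori, d.data());
      out.push_back(k2);
      descs.push_back(d);
    }
  }

  int n = (int)out.size();
  NumericMatrix kmat(n, 4), dmat(n, 128);
  for (int i = 0; i < n; ++i) {
    kmat(i, 0) = out[i].row + 1;  // 1-based for R
    kmat(i, 1) = out[i].col + 1;
    kmat(i, 2) = out[i].scale;
    kmat(i, 3) = out[i].ori;
    for (int jx = 0; jx < 128; ++jx) dmat(i, jx) = descs[i][jx];
  }
  colnames(kmat) = CharacterVector::create("row", "col", "scale", "orientation");
  return List::create(_["keypoints"] = kmat, _["descriptors"] = dmat);
}

// [[Rcpp::export(name = ".match_bruteforce")]]
IntegerMatrix match_bruteforce(NumericMatrix a, NumericMatrix b,
                               double ratio, double abs_threshold) {
  const int na = a.nrow(), nb = b.nrow(), d = a.ncol();
  std::vector<int> ri, ti;
  std::vector<double> dd;
  for (int i = 0; i < na; ++i) {
    double d1 = R_PosInf, d2 = R_PosInf;
    int j1 = -1;
    for (int j = 0; j < nb; ++j) {
      double s = 0;
      for (int c = 0; c < d; ++c) {
        double df = a(i, c) - b(j, c);
        s += df * df;
        if (s >= d2) break;
      }
      if (s < d1) { d2 = d1; d1 = s; j1 = j; }
      else if (s < d2) { d2 = s; }
    }
    double e1 = std::sqrt(d1), e2 = std::sqrt(d2);
    bool pass_abs = e1 < abs_threshold;
    bool pass_ratio = (e1 == 0.0) || (e2 > 0.0 && e1 / e2 < ratio);
    if (j1 >= 0 && pass_abs && pass_ratio) {
      ri.push_back(i + 1); ti.push_back(j1 + 1); dd.push_back(e1);
    }
  }
  IntegerMatrix m((int)ri.size(), 2);
  NumericVector dv((int)ri.size());
  for (size_t i = 0; i < ri.size(); ++i) { m(i, 0) = ri[i]; m(i, 1) = ti[i]; dv[i] = dd[i]; }
  m.attr("distances") = dv;
  return m;
}
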