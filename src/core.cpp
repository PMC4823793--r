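#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <unordered_map>
using namespace Rcpp;

// Pixel layout: R array with dim c(h, w, 3), column-major, 8-bit raw.
// idx(y, x, c) = y + h * (x + w * c), 0-based.

static inline int pidx(int y, int x, int c, int h, int w) {
  return y + h * (x + (size_t)w * c);
}

// ---------------------------------------------------------------------------
// separable Gaussian blur on a float buffer (sigma small, radius 3*sigma)
// ---------------------------------------------------------------------------
static void gauss_blur(std::vector<float>& img, std::vector<float>& tmp,
                       int h, int w, double sigma) {
  int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<float> k(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = (float)std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (auto& v : k) v = (float)(v / s);
  // horizontal pass (across columns), written column-at-a-time so every
  // inner loop walks contiguous memory
  for (int x = 0; x < w; ++x) {
    float* out = &tmp[(size_t)h * x];
    std::fill(out, out + h, 0.f);
    for (int i = -rad; i <= rad; ++i) {
      int xx = x + i;
      if (xx < 0) xx = 0; else if (xx >= w) xx = w - 1;
      const float* src = &img[(size_t)h * xx];
      float kv = k[i + rad];
      for (int y = 0; y < h; ++y) out[y] += kv * src[y];
    }
  }
  // vertical pass (within a column, stride 1)
  for (int x = 0; x < w; ++x) {
    const float* src = &tmp[(size_t)h * x];
    float* out = &img[(size_t)h * x];
    for (int y = 0; y < h; ++y) {
      float acc = 0.f;
      int lo = y - rad, hi = y + rad;
      if (lo >= 0 && hi < h) {
        for (int i = 0; i <= 2 * rad; ++i) acc += k[i] * src[lo + i];
      } else {
        for (int i = -rad; i <= rad; ++i) {
          int yy = y + i;
          if (yy < 0) yy = 0; else if (yy >= h) yy = h - 1;
          acc += k[i + rad] * src[yy];
        }
      }
      out[y] = acc;
    }
  }
}

// ---------------------------------------------------------------------------
// contrast channels
// mode 1 = inverted_luminance, 2 = red_chroma, 3 = combined (max of both)
// ---------------------------------------------------------------------------
static void fill_channel(const unsigned char* px, int h, int w, int mode,
                         std::vector<float>& ch) {
  size_t n = (size_t)h * w;
  for (size_t i = 0; i < n; ++i) {
    float r = px[i] / 255.f;
    float g = px[i + n] / 255.f;
    float b = px[i + 2 * n] / 255.f;
    float invlum = 1.f - (0.299f * r + 0.587f * g + 0.114f * b);
    float redchr = r - 0.5f * (g + b);
    if (redchr < 0.f) redchr = 0.f;
    float v;
    if (mode == 1) v = invlum;
    else if (mode == 2) v = redchr;
    else v = std::max(invlum, redchr);
    if (v < 0.f) v = 0.f; else if (v > 1.f) v = 1.f;
    ch[i] = v;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_contrast_channel(RawVector px, int h, int w, int mode) {
  std::vector<float> ch((size_t)h * w);
  fill_channel(RAW(px), h, w, mode, ch);
  NumericMatrix out(h, w);
  for (size_t i = 0; i < ch.size(); ++i) out[i] = ch[i];
  return out;
}

// ---------------------------------------------------------------------------
// greedy non-maximum suppression with spatial hashing
// order: strength desc, then x asc, then y asc
// ---------------------------------------------------------------------------
struct Pt { double x, y, s; int idx; };

static std::vector<int> nms_core(std::vector<Pt>& pts, double minsep) {
  std::sort(pts.begin(), pts.end(), [](const Pt& a, const Pt& b) {
    if (a.s != b.s) return a.s > b.s;
    if (a.x != b.x) return a.x < b.x;
    return a.y < b.y;
  });
  double cell = std::max(minsep, 1.0);
  double ms2 = minsep * minsep;
  std::unordered_map<long long, std::vector<int>> grid;
  std::vector<int> keep;
  std::vector<Pt> kept;
  for (auto& p : pts) {
    int cx = (int)std::floor(p.x / cell), cy = (int)std::floor(p.y / cell);
    bool ok = true;
    for (int dx = -1; dx <= 1 && ok; ++dx)
      for (int dy = -1; dy <= 1 && ok; ++dy) {
        auto it = grid.find(((long long)(cx + dx) << 32) ^ (unsigned int)(cy + dy));
        if (it == grid.end()) continue;
        for (int j : it->second) {
          double ddx = kept[j].x - p.x, ddy = kept[j].y - p.y;
          if (ddx * ddx + ddy * ddy < ms2) { ok = false; break; }
        }
      }
    if (ok) {
      grid[((long long)cx << 32) ^ (unsigned int)cy].push_back((int)kept.size());
      kept.push_back(p);
      keep.push_back(p.idx);
    }
  }
  return keep;
}

// [[Rcpp::export]]
IntegerVector cpp_nms(NumericVector x, NumericVector y, NumericVector s,
                      double minsep) {
  int n = x.size();
  std::vector<Pt> pts(n);
  for (int i = 0; i < n; ++i) pts[i] = {x[i], y[i], s[i], i + 1};
  std::vector<int> keep = nms_core(pts, minsep);
  return wrap(keep);
}

// ---------------------------------------------------------------------------
// two-stage gradient-voting circular Hough transform
// ---------------------------------------------------------------------------
struct Det { double x, y, r, s; };

static void hough_channel(std::vector<float>& ch, int h, int w,
                          int rmin, int rmax, double gthresh, double vthresh,
                          double minsep, std::vector<Det>& out) {
  std::vector<float> tmp((size_t)h * w);
  gauss_blur(ch, tmp, h, w, 1.1);
  // voting
  std::vector<float>& acc = tmp;           // reuse as accumulator
  std::fill(acc.begin(), acc.end(), 0.f);
  int nr = rmax - rmin + 1;
  for (int x = 1; x < w - 1; ++x) {
    size_t col = (size_t)h * x;
    for (int y = 1; y < h - 1; ++y) {
      float gx = 0.5f * (ch[col + h + y] - ch[col - h + y]);
      float gy = 0.5f * (ch[col + y + 1] - ch[col + y - 1]);
      float gm = std::sqrt(gx * gx + gy * gy);
      if (gm <= gthresh) continue;
      float ux = gx / gm, uy = gy / gm;
      for (int r = rmin; r <= rmax; ++r) {
        int cx = (int)std::lround(x + ux * r);
        int cy = (int)std::lround(y + uy * r);
        if (cx < 0 || cx >= w || cy < 0 || cy >= h) continue;
        acc[cy + (size_t)h * cx] += gm;
      }
    }
  }
  // smooth the accumulator into a fresh buffer (keep ch for radius estimation)
  std::vector<float> accs = acc;
  {
    std::vector<float> t2((size_t)h * w);
    gauss_blur(accs, t2, h, w, 1.0);
  }
  // peak picking: strict-ish 3x3 local maxima above threshold
  std::vector<Pt> peaks;
  float vt = (float)vthresh;
  for (int x = 1; x < w - 1; ++x) {
    for (int y = 1; y < h - 1; ++y) {
      float v = accs[y + (size_t)h * x];
      if (v < vt) continue;
      bool mx = true;
      for (int dx = -1; dx <= 1 && mx; ++dx)
        for (int dy = -1; dy <= 1 && mx; ++dy) {
          if (!dx && !dy) continue;
          float nv = accs[(y + dy) + (size_t)h * (x + dx)];
          if (nv > v) mx = false;
          else if (nv == v && (dx < 0 || (dx == 0 && dy < 0))) mx = false;
        }
      if (!mx) continue;
      // subpixel: 3x3 intensity centroid
      double sw = 0, sx = 0, sy = 0;
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy) {
          double nv = accs[(y + dy) + (size_t)h * (x + dx)];
          sw += nv; sx += nv * dx; sy += nv * dy;
        }
      double px = x + (sw > 0 ? sx / sw : 0.0);
      double py = y + (sw > 0 ? sy / sw : 0.0);
      peaks.push_back({px, py, v, (int)peaks.size()});
    }
  }
  std::vector<int> keep = nms_core(peaks, minsep);
  // radius estimation per kept peak from gradient support in the annulus
  std::sort(peaks.begin(), peaks.end(), [](const Pt& a, const Pt& b) {
    if (a.s != b.s) return a.s > b.s;
    if (a.x != b.x) return a.x < b.x;
    return a.y < b.y;
  });
  // after sort, kept peaks are the first |keep| in sorted order (nms_core sorts
  // identically), so re-walk sorted peaks and test membership via keep set
  std::vector<char> inkeep(peaks.size() + 1, 0);
  for (int k : keep) inkeep[k] = 1;
  std::vector<double> bins(rmax + 3);
  for (auto& p : peaks) {
    if (!inkeep[p.idx]) continue;
    std::fill(bins.begin(), bins.end(), 0.0);
    int x0 = std::max(1, (int)p.x - rmax - 2), x1 = std::min(w - 2, (int)p.x + rmax + 2);
    int y0 = std::max(1, (int)p.y - rmax - 2), y1 = std::min(h - 2, (int)p.y + rmax + 2);
    for (int x = x0; x <= x1; ++x) {
      size_t col = (size_t)h * x;
      for (int y = y0; y <= y1; ++y) {
        float gx = 0.5f * (ch[col + h + y] - ch[col - h + y]);
        float gy = 0.5f * (ch[col + y + 1] - ch[col + y - 1]);
        float gm = std::sqrt(gx * gx + gy * gy);
        if (gm <= gthresh) continue;
        double dx = p.x - x, dy = p.y - y;
        double d = std::sqrt(dx * dx + dy * dy);
        if (d < rmin - 1.0 || d > rmax + 1.0 || d < 1e-9) continue;
        double cosang = (gx * dx + gy * dy) / (gm * d);
        if (cosang < 0.7) continue;   // gradient must point at the centre
        int b = (int)std::lround(d);
        if (b >= 0 && b <= rmax + 2) bins[b] += gm;
      }
    }
    int best = rmin; double bv = -1.0;
    for (int r = rmin; r <= rmax; ++r)
      if (bins[r] > bv) { bv = bins[r]; best = r; }
    // parabolic refinement
    double rr = best;
    if (best > 0 && best < rmax + 2) {
      double a = bins[best - 1], b = bins[best], c = bins[best + 1];
      double den = a - 2 * b + c;
      if (den < -1e-12) rr = best + 0.5 * (a - c) / den;
    }
    if (rr < rmin) rr = rmin;
    if (rr > rmax) rr = rmax;
    out.push_back({p.x, p.y, rr, p.s});
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_hough_raw(RawVector px, int h, int w, int mode,
                            int rmin, int rmax, double gthresh,
                            double vthresh, double minsep) {
  std::vector<float> ch((size_t)h * w);
  fill_channel(RAW(px), h, w, mode, ch);
  std::vector<Det> dets;
  hough_channel(ch, h, w, rmin, rmax, gthresh, vthresh, minsep, dets);
  NumericMatrix out(dets.size(), 4);
  for (size_t i = 0; i < dets.size(); ++i) {
    out(i, 0) = dets[i].x; out(i, 1) = dets[i].y;
    out(i, 2) = dets[i].r; out(i, 3) = dets[i].s;
  }
  return out;
}

// ---------------------------------------------------------------------------
// bicubic (Catmull-Rom, a = -0.5) resize of an 8-bit RGB array
// ---------------------------------------------------------------------------
static inline double cubw(double t) {
  t = std::fabs(t);
  if (t <= 1.0) return 1.5 * t * t * t - 2.5 * t * t + 1.0;
  if (t < 2.0)  return -0.5 * t * t * t + 2.5 * t * t - 4.0 * t + 2.0;
  return 0.0;
}

// [[Rcpp::export]]
RawVector cpp_resize_bicubic(RawVector px, int h, int w, int nh, int nw) {
  RawVector out((size_t)nh * nw * 3);
  const unsigned char* in = RAW(px);
  unsigned char* o = RAW(out);
  double sy = (double)h / nh, sx = (double)w / nw;
  std::vector<int> xidx(nw * 4); std::vector<double> xw(nw * 4);
  for (int x = 0; x < nw; ++x) {
    double src = (x + 0.5) * sx - 0.5;
    int x0 = (int)std::floor(src) - 1;
    for (int i = 0; i < 4; ++i) {
      int xx = x0 + i;
      if (xx < 0) xx = 0; else if (xx >= w) xx = w - 1;
      xidx[x * 4 + i] = xx;
      xw[x * 4 + i] = cubw(src - (x0 + i));
    }
  }
  for (int c = 0; c < 3; ++c) {
    size_t ci = (size_t)h * w * c, co = (size_t)nh * nw * c;
    for (int x = 0; x < nw; ++x) {
      for (int y = 0; y < nh; ++y) {
        double srcy = (y + 0.5) * sy - 0.5;
        int y0 = (int)std::floor(srcy) - 1;
        double v = 0.0, wsum = 0.0;
        for (int j = 0; j < 4; ++j) {
          int yy = y0 + j;
          if (yy < 0) yy = 0; else if (yy >= h) yy = h - 1;
          double wy = cubw(srcy - (y0 + j));
          for (int i = 0; i < 4; ++i) {
            double wt = wy * xw[x * 4 + i];
            v += wt * in[ci + yy + (size_t)h * xidx[x * 4 + i]];
            wsum += wt;
          }
        }
        v /= wsum;
        if (v < 0) v = 0; else if (v > 255) v = 255;
        o[co + y + (size_t)nh * x] = (unsigned char)std::lround(v);
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// per-signal appearance features (14 dims)
// ---------------------------------------------------------------------------
static void rgb2lab(double r, double g, double b, double& L, double& A, double& B) {
  auto f = [](double t) {
    return t > 0.04045 ? std::pow((t + 0.055) / 1.055, 2.4) : t / 12.92;
  };
  r = f(r); g = f(g); b = f(b);
  double X = (0.4124 * r + 0.3576 * g + 0.1805 * b) / 0.95047;
  double Y =  0.2126 * r + 0.7152 * g + 0.0722 * b;
  double Z = (0.0193 * r + 0.1192 * g + 0.9505 * b) / 1.08883;
  auto ff = [](double t) {
    return t > 0.008856 ? std::cbrt(t) : 7.787 * t + 16.0 / 116.0;
  };
  X = ff(X); Y = ff(Y); Z = ff(Z);
  L = 116.0 * Y - 16.0;
  A = 500.0 * (X - Y);
  B = 200.0 * (Y - Z);
}

// [[Rcpp::export]]
NumericMatrix cpp_extract_features(RawVector px, int h, int w,
                                   NumericVector xs, NumericVector ys,
                                   NumericVector rs) {
  int n = xs.size();
  NumericMatrix out(n, 14);
  const unsigned char* in = RAW(px);
  size_t np = (size_t)h * w;
  for (int i = 0; i < n; ++i) {
    double cx = xs[i], cy = ys[i], r = std::max(1.0, rs[i]);
    int x0 = std::max(0, (int)std::floor(cx - r - 5)), x1 = std::min(w - 1, (int)std::ceil(cx + r + 5));
    int y0 = std::max(0, (int)std::floor(cy - r - 5)), y1 = std::min(h - 1, (int)std::ceil(cy + r + 5));
    double sr = 0, sg = 0, sb = 0, sr2 = 0, sg2 = 0, sb2 = 0, nd = 0;
    double sA = 0, sB = 0, slum = 0, slum2 = 0, ssat = 0;
    double ring = 0, nring = 0, sgrad = 0, ngrad = 0;
    for (int x = x0; x <= x1; ++x) {
      for (int y = y0; y <= y1; ++y) {
        double dx = x - cx, dy = y - cy;
        double d = std::sqrt(dx * dx + dy * dy);
        size_t ii = y + (size_t)h * x;
        double R = in[ii] / 255.0, G = in[ii + np] / 255.0, B = in[ii + 2 * np] / 255.0;
        double lum = 0.299 * R + 0.587 * G + 0.114 * B;
        if (d <= r) {
          sr += R; sg += G; sb += B;
          sr2 += R * R; sg2 += G * G; sb2 += B * B;
          double LL, AA, BB; rgb2lab(R, G, B, LL, AA, BB);
          sA += AA; sB += BB;
          slum += lum; slum2 += lum * lum;
          double mx = std::max(R, std::max(G, B)), mn = std::min(R, std::min(G, B));
          ssat += (mx > 1e-9 ? (mx - mn) / mx : 0.0);
          nd += 1;
        } else if (d >= r + 2 && d <= r + 5) {
          ring += lum; nring += 1;
        }
        if (std::fabs(d - r) <= 1.5 && x > 0 && x < w - 1 && y > 0 && y < h - 1) {
          double lxp = 0.299 * in[ii + h] / 255.0 + 0.587 * in[ii + np + h] / 255.0 + 0.114 * in[ii + 2 * np + h] / 255.0;
          double lxm = 0.299 * in[ii - h] / 255.0 + 0.587 * in[ii + np - h] / 255.0 + 0.114 * in[ii + 2 * np - h] / 255.0;
          double lyp = 0.299 * in[ii + 1] / 255.0 + 0.587 * in[ii + np + 1] / 255.0 + 0.114 * in[ii + 2 * np + 1] / 255.0;
          double lym = 0.299 * in[ii - 1] / 255.0 + 0.587 * in[ii + np - 1] / 255.0 + 0.114 * in[ii + 2 * np - 1] / 255.0;
          double gx = 0.5 * (lxp - lxm), gy = 0.5 * (lyp - lym);
          sgrad += std::sqrt(gx * gx + gy * gy); ngrad += 1;
        }
      }
    }
    if (nd < 1) nd = 1;
    double mr = sr / nd, mg = sg / nd, mb = sb / nd;
    double vlum = slum2 / nd - (slum / nd) * (slum / nd);
    out(i, 0) = mr; out(i, 1) = mg; out(i, 2) = mb;
    out(i, 3) = std::sqrt(std::max(0.0, sr2 / nd - mr * mr));
    out(i, 4) = std::sqrt(std::max(0.0, sg2 / nd - mg * mg));
    out(i, 5) = std::sqrt(std::max(0.0, sb2 / nd - mb * mb));
    out(i, 6) = sA / nd;
    out(i, 7) = sB / nd;
    out(i, 8) = r;
    out(i, 9) = (nring > 0 ? ring / nring : 0.0) - slum / nd;
    out(i, 10) = slum / nd;
    out(i, 11) = (ngrad > 0 ? sgrad / ngrad : 0.0);
    out(i, 12) = ssat / nd;
    out(i, 13) = std::sqrt(std::max(0.0, vlum));
  }
  return out;
}

// ---------------------------------------------------------------------------
// neighbourhood counts and sequential nearest-unused snapping
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_disk_counts(NumericVector ax, NumericVector ay,
                              NumericVector px, NumericVector py,
                              double radius) {
  int na = ax.size(), n = px.size();
  IntegerVector out(na);
  double r2 = radius * radius;
  for (int i = 0; i < na; ++i) {
    int c = 0;
    for (int j = 0; j < n; ++j) {
      double dx = px[j] - ax[i], dy = py[j] - ay[i];
      if (dx * dx + dy * dy <= r2) ++c;
    }
    out[i] = c;
  }
  return out;
}

// sequentially snap each query to its nearest not-yet-used target (1-based)
// [[Rcpp::export]]
IntegerVector cpp_nearest_unused(NumericVector qx, NumericVector qy,
                                 NumericVector tx, NumericVector ty) {
  int nq = qx.size(), nt = tx.size();
  std::vector<char> used(nt, 0);
  IntegerVector out(nq);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf; int bj = -1;
    for (int j = 0; j < nt; ++j) {
      if (used[j]) continue;
      double dx = tx[j] - qx[i], dy = ty[j] - qy[i];
      double d = dx * dx + dy * dy;
      if (d < best) { best = d; bj = j; }
    }
    if (bj < 0) { out[i] = NA_INTEGER; continue; }
    used[bj] = 1;
    out[i] = bj + 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// hard-core point processes (uses the R RNG; seed via set.seed in R)
// ---------------------------------------------------------------------------
struct HCGrid {
  double cell; double d2;
  std::unordered_map<long long, std::vector<int>> grid;
  std::vector<double> xs, ys;
  HCGrid(double min_sep) : cell(std::max(min_sep, 1.0)), d2(min_sep * min_sep) {}
  bool ok(double x, double y) const {
    int cx = (int)std::floor(x / cell), cy = (int)std::floor(y / cell);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        auto it = grid.find(((long long)(cx + dx) << 32) ^ (unsigned int)(cy + dy));
        if (it == grid.end()) continue;
        for (int j : it->second) {
          double ddx = xs[j] - x, ddy = ys[j] - y;
          if (ddx * ddx + ddy * ddy < d2) return false;
        }
      }
    return true;
  }
  void add(double x, double y) {
    int cx = (int)std::floor(x / cell), cy = (int)std::floor(y / cell);
    grid[((long long)cx << 32) ^ (unsigned int)cy].push_back((int)xs.size());
    xs.push_back(x); ys.push_back(y);
  }
};

// place n cell centres inside a disk with a minimum pairwise distance;
// with parents, scatters around weighted parent points (Thomas-like nests),
// otherwise uniform over the disk
// [[Rcpp::export]]
NumericMatrix cpp_hardcore_disk(int n, double cx, double cy, double R,
                                double min_sep, int max_tries,
                                NumericMatrix parents, NumericVector parent_w,
                                double cluster_sd) {
  RNGScope scope;
  HCGrid hc(min_sep);
  int npar = parents.nrow();
  std::vector<double> cw(npar);
  double tot = 0.0;
  for (int j = 0; j < npar; ++j) { tot += parent_w[j]; cw[j] = tot; }
  NumericMatrix out(n, 2);
  int placed = 0, tries = 0;
  while (placed < n && tries < max_tries) {
    ++tries;
    double x, y;
    if (npar > 0) {
      double u = unif_rand() * tot;
      int j = (int)(std::lower_bound(cw.begin(), cw.end(), u) - cw.begin());
      if (j >= npar) j = npar - 1;
      x = parents(j, 0) + norm_rand() * cluster_sd;
      y = parents(j, 1) + norm_rand() * cluster_sd;
      if ((x - cx) * (x - cx) + (y - cy) * (y - cy) > R * R) continue;
    } else {
      double r = R * std::sqrt(unif_rand()), th = 2.0 * M_PI * unif_rand();
      x = cx + r * std::cos(th); y = cy + r * std::sin(th);
    }
    if (!hc.ok(x, y)) continue;
    hc.add(x, y);
    out(placed, 0) = x; out(placed, 1) = y;
    ++placed;
  }
  if (placed < n) {
    NumericMatrix part(placed, 2);
    for (int i = 0; i < placed; ++i) { part(i, 0) = out(i, 0); part(i, 1) = out(i, 1); }
    return part;
  }
  return out;
}

// scatter dots around their centres subject to a global minimum separation;
// returns x, y, placed(0/1) per input dot
// [[Rcpp::export]]
NumericMatrix cpp_place_dots(NumericVector cx, NumericVector cy,
                             NumericVector scatter, double min_sep,
                             double w, double h) {
  RNGScope scope;
  int n = cx.size();
  HCGrid hc(min_sep);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    bool done = false;
    for (int t = 0; t < 40 && !done; ++t) {
      double a = 2.0 * M_PI * unif_rand();
      double rr = scatter[i] * std::sqrt(unif_rand());
      double x = cx[i] + rr * std::cos(a), y = cy[i] + rr * std::sin(a);
      if (x < 2 || y < 2 || x > w - 3 || y > h - 3) continue;
      if (hc.ok(x, y)) {
        hc.add(x, y);
        out(i, 0) = x; out(i, 1) = y; out(i, 2) = 1;
        done = true;
      }
    }
    if (!done) out(i, 2) = 0;
  }
  return out;
}

// ---------------------------------------------------------------------------
// synthetic core renderer
// pts columns: x, y, radius, class (1 GENE, 2 CEP, 3 MIXED, 4 NOISE, 5 STAIN),
// angle (mixed-pair orientation). Uses the R RNG (seed via set.seed in R).
// ---------------------------------------------------------------------------
static void draw_soft_disk(unsigned char* o, int h, int w, double cx, double cy,
                           double r, double colr, double colg, double colb,
                           double maxalpha, bool gaussian) {
  int pad = gaussian ? (int)std::ceil(2.0 * r) : (int)std::ceil(r + 2.0);
  int x0 = std::max(0, (int)std::floor(cx) - pad), x1 = std::min(w - 1, (int)std::ceil(cx) + pad);
  int y0 = std::max(0, (int)std::floor(cy) - pad), y1 = std::min(h - 1, (int)std::ceil(cy) + pad);
  size_t np = (size_t)h * w;
  for (int x = x0; x <= x1; ++x) {
    for (int y = y0; y <= y1; ++y) {
      double dx = x - cx, dy = y - cy;
      double d = std::sqrt(dx * dx + dy * dy);
      double a;
      if (gaussian) {
        a = maxalpha * std::exp(-2.0 * (d / r) * (d / r));
      } else {
        a = (r + 0.7 - d) / 1.4;
        if (a > 1.0) a = 1.0;
        if (a < 0.0) a = 0.0;
        a *= maxalpha;
      }
      if (a <= 0.003) continue;
      size_t ii = y + (size_t)h * x;
      o[ii]          = (unsigned char)std::lround((1 - a) * o[ii]          + a * colr);
      o[ii + np]     = (unsigned char)std::lround((1 - a) * o[ii + np]     + a * colg);
      o[ii + 2 * np] = (unsigned char)std::lround((1 - a) * o[ii + 2 * np] + a * colb);
    }
  }
}

// [[Rcpp::export]]
RawVector cpp_render_core(int h, int w, NumericMatrix pts,
                          double mcx, double mcy, double mrad,
                          double noise_sd) {
  RawVector out((size_t)h * w * 3);
  unsigned char* o = RAW(out);
  size_t np = (size_t)h * w;
  RNGScope scope;
  // coarse multiplicative texture grid (33 x 33), bilinear upsampled
  const int G = 33;
  std::vector<double> grid(G * G);
  for (auto& v : grid) v = R::norm_rand() * 7.0;
  double mr2 = mrad * mrad;
  double base[3] = {229.0, 221.0, 236.0};   // pale hematoxylin background
  for (int x = 0; x < w; ++x) {
    double gx = (double)x / (w - 1) * (G - 1);
    int gx0 = std::min(G - 2, (int)gx); double fx = gx - gx0;
    for (int y = 0; y < h; ++y) {
      double gy = (double)y / (h - 1) * (G - 1);
      int gy0 = std::min(G - 2, (int)gy); double fy = gy - gy0;
      double t = (1 - fx) * ((1 - fy) * grid[gy0 + G * gx0] + fy * grid[gy0 + 1 + G * gx0])
               + fx * ((1 - fy) * grid[gy0 + G * (gx0 + 1)] + fy * grid[gy0 + 1 + G * (gx0 + 1)]);
      double dx = x - mcx, dy = y - mcy;
      bool inside = (dx * dx + dy * dy) <= mr2;
      size_t ii = y + (size_t)h * x;
      if (inside) {
        for (int c = 0; c < 3; ++c) {
          double v = base[c] + t;
          if (v < 0) v = 0; else if (v > 255) v = 255;
          o[ii + np * c] = (unsigned char)v;
        }
      } else {
        o[ii] = 252; o[ii + np] = 252; o[ii + 2 * np] = 253;
      }
    }
  }
  int n = pts.nrow();
  // stains first (underneath), then noise, then signals
  for (int pass = 0; pass < 3; ++pass) {
    for (int i = 0; i < n; ++i) {
      int cls = (int)pts(i, 3);
      int want = (cls == 5) ? 0 : (cls == 4 ? 1 : 2);
      if (want != pass) continue;
      double x = pts(i, 0), y = pts(i, 1), r = pts(i, 2), ang = pts(i, 4);
      double j1 = R::norm_rand(), j2 = R::norm_rand();  // colour jitter
      switch (cls) {
      case 1:   // GENE: silver-black dot
        draw_soft_disk(o, h, w, x, y, r, 33 + 4 * j1, 29 + 4 * j1, 34 + 4 * j2, 0.97, false);
        break;
      case 2:   // CEP: red dot
        draw_soft_disk(o, h, w, x, y, r, 186 + 6 * j1, 40 + 5 * j2, 50 + 5 * j2, 0.95, false);
        break;
      case 3: { // MIXED: overlapping black + red pair, truth point at midpoint
        double off = 0.5 * r;
        double ox = off * std::cos(ang), oy = off * std::sin(ang);
        draw_soft_disk(o, h, w, x - ox, y - oy, r * 0.92, 33 + 4 * j1, 29 + 4 * j1, 34, 0.97, false);
        draw_soft_disk(o, h, w, x + ox, y + oy, r * 0.92, 186 + 6 * j2, 40, 50, 0.92, false);
        break;
      }
      case 4:   // NOISE: grey-blue speckle
        draw_soft_disk(o, h, w, x, y, r, 142 + 7 * j1, 138 + 7 * j1, 153 + 7 * j2, 0.9, false);
        break;
      case 5:   // CELL_STAIN: large diffuse hematoxylin blob
        draw_soft_disk(o, h, w, x, y, r, 168 + 10 * j1, 158 + 10 * j1, 201 + 8 * j2, 0.45, true);
        break;
      }
    }
  }
  // sensor noise over everything
  for (size_t c = 0; c < 3; ++c) {
    for (size_t i = 0; i < np; ++i) {
      double v = o[i + np * c] + R::norm_rand() * noise_sd;
      if (v < 0) v = 0; else if (v > 255) v = 255;
      o[i + np * c] = (unsigned char)std::lround(v);
    }
  }
  return out;
}
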