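#include <Rcpp.h>
#include <cstring>
#include <cmath>
#include <climits>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// 16-pixel Bresenham circle of radius 3, clockwise from 12 o'clock.
// x = column (rightward), y = row (downward); images indexed (y, x).
static const int CX[16] = {0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3, -3, -3, -2, -1};
static const int CY[16] = {-3, -3, -2, -1, 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3};

struct FastRes {
  bool corner;
  double score;
  int runlen;
};

// Segment test at (x, y): a corner iff >= eta contiguous arc pixels are all
// brighter than centre + lambda, or all darker than centre - lambda, with
// wrap-around. Score: max over qualifying maximal runs of sum |I - centre|.
static FastRes fast_eval(const NumericMatrix &I, int x, int y,
                         double lambda, int eta) {
  const double c = I(y, x);
  bool br[16], dk[16];
  double ad[16];
  for (int i = 0; i < 16; ++i) {
    double v = I(y + CY[i], x + CX[i]);
    ad[i] = std::fabs(v - c);
    br[i] = v > c + lambda;
    dk[i] = v < c - lambda;
  }
  FastRes r;
  r.corner = false;
  r.score = 0.0;
  r.runlen = 0;
  for (int pass = 0; pass < 2; ++pass) {
    const bool *f = pass ? dk : br;
    bool all = true;
    for (int i = 0; i < 16; ++i)
      if (!f[i]) { all = false; break; }
    if (all) {
      double s = 0;
      for (int i = 0; i < 16; ++i) s += ad[i];
      r.runlen = 16;
      if (16 >= eta) { r.corner = true; if (s > r.score) r.score = s; }
      continue;
    }
    // maximal runs start where the predecessor (wrapped) is false
    for (int s0 = 0; s0 < 16; ++s0) {
      if (f[s0] && !f[(s0 + 15) % 16]) {
        int len = 0;
        double sum = 0;
        int i = s0;
        while (f[i % 16] && len < 16) {
          sum += ad[i % 16];
          ++len;
          ++i;
        }
        if (len > r.runlen) r.runlen = len;
        if (len >= eta) {
          r.corner = true;
          if (sum > r.score) r.score = sum;
        }
      }
    }
  }
  if (!r.corner) r.score = 0.0;
  return r;
}

// [[Rcpp::export]]
List fast_corner_cpp(NumericMatrix img, int x, int y, double lambda, int eta) {
  FastRes r = fast_eval(img, x, y, lambda, eta);
  return List::create(_["is_corner"] = r.corner,
                      _["score"] = r.score,
                      _["run_length"] = r.runlen);
}

// Scan the whole image inside `margin`, then 3x3 non-maximum suppression on
// the segment-test score (raster-order tie break: earlier pixel wins).
// [[Rcpp::export]]
DataFrame fast_detect_cpp(NumericMatrix img, double lambda, int eta, int margin) {
  const int h = img.nrow(), w = img.ncol();
  NumericMatrix score(h, w);
  for (int y = margin; y < h - margin; ++y)
    for (int x = margin; x < w - margin; ++x) {
      FastRes r = fast_eval(img, x, y, lambda, eta);
      if (r.corner) score(y, x) = r.score;
    }
  std::vector<int> xs, ys;
  std::vector<double> sc;
  for (int y = margin; y < h - margin; ++y)
    for (int x = margin; x < w - margin; ++x) {
      const double s = score(y, x);
      if (s <= 0) continue;
      bool keep = true;
      for (int dy = -1; dy <= 1 && keep; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0) continue;
          const int ny = y + dy, nx = x + dx;
          if (ny < 0 || ny >= h || nx < 0 || nx >= w) continue;
          const double ns = score(ny, nx);
          const bool before = (dy < 0) || (dy == 0 && dx < 0);
          if (before ? (ns >= s) : (ns > s)) { keep = false; break; }
        }
      if (keep) {
        xs.push_back(x);
        ys.push_back(y);
        sc.push_back(s);
      }
    }
  return DataFrame::create(_["x"] = xs, _["y"] = ys, _["fast_score"] = sc);
}

// Harris corner measure at each (x, y): det(M) - k tr(M)^2 over a 7x7 window
// of central-difference gradients weighted by a Gaussian of sigma = 1.
// [[Rcpp::export]]
NumericVector harris_cpp(NumericMatrix img, IntegerVector xs, IntegerVector ys,
                         double k) {
  const int n = xs.size();
  NumericVector out(n);
  double wgt[7][7];
  for (int a = -3; a <= 3; ++a)
    for (int b = -3; b <= 3; ++b)
      wgt[a + 3][b + 3] = std::exp(-(a * a + b * b) / 2.0);
  for (int i = 0; i < n; ++i) {
    const int x = xs[i], y = ys[i];
    double A = 0, B = 0, C = 0;
    for (int dy = -3; dy <= 3; ++dy)
      for (int dx = -3; dx <= 3; ++dx) {
        const int yy = y + dy, xx = x + dx;
        const double ix = (img(yy, xx + 1) - img(yy, xx - 1)) / 2.0;
        const double iy = (img(yy + 1, xx) - img(yy - 1, xx)) / 2.0;
        const double wv = wgt[dx + 3][dy + 3];
        A += wv * ix * ix;
        B += wv * iy * iy;
        C += wv * ix * iy;
      }
    out[i] = (A * B - C * C) - k * (A + B) * (A + B);
  }
  return out;
}

// Intensity-centroid orientation: atan2(m01, m10) over the disc of `radius`,
// with moments m_pq = sum a^p b^q I(a, b) (a = x offset, b = y offset).
// [[Rcpp::export]]
NumericVector orientation_cpp(NumericMatrix img, IntegerVector xs,
                              IntegerVector ys, int radius) {
  const int n = xs.size();
  NumericVector out(n);
  const int r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    const int x = xs[i], y = ys[i];
    double m10 = 0, m01 = 0;
    for (int b = -radius; b <= radius; ++b)
      for (int a = -radius; a <= radius; ++a) {
        if (a * a + b * b > r2) continue;
        const double v = img(y + b, x + a);
        m10 += a * v;
        m01 += b * v;
      }
    double th = (m10 == 0.0 && m01 == 0.0) ? 0.0 : std::atan2(m01, m10);
    if (th >= M_PI) th = -M_PI;  // canonical range [-pi, pi)
    out[i] = th;
  }
  return out;
}

// Rotated binary descriptors. Pattern rows: (x1, y1, x2, y2) offsets in a
// 31x31 patch. Orientation is quantized to `nbins` bins; each bin's rotated
// pattern uses offsets rounded to the nearest pixel. Bit i = 1 iff
// I(p1') < I(p2'). Bits are packed LSB-first per byte (matches rawToBits).
// Keypoints whose rotated pattern escapes the image get ok = FALSE.
// [[Rcpp::export]]
List descriptors_cpp(NumericMatrix img, IntegerVector xs, IntegerVector ys,
                     NumericVector orient, IntegerMatrix pattern, int nbins) {
  const int npairs = pattern.nrow();
  const int nbytes = (npairs + 7) / 8;
  const double binw = 2.0 * M_PI / nbins;
  std::vector<std::vector<int>> rx1(nbins), ry1(nbins), rx2(nbins), ry2(nbins);
  std::vector<int> maxoff(nbins, 0);
  for (int b = 0; b < nbins; ++b) {
    const double th = binw * b, co = std::cos(th), si = std::sin(th);
    rx1[b].resize(npairs); ry1[b].resize(npairs);
    rx2[b].resize(npairs); ry2[b].resize(npairs);
    for (int i = 0; i < npairs; ++i) {
      const int x1 = pattern(i, 0), y1 = pattern(i, 1);
      const int x2 = pattern(i, 2), y2 = pattern(i, 3);
      rx1[b][i] = (int)std::lround(co * x1 - si * y1);
      ry1[b][i] = (int)std::lround(si * x1 + co * y1);
      rx2[b][i] = (int)std::lround(co * x2 - si * y2);
      ry2[b][i] = (int)std::lround(si * x2 + co * y2);
      int m = std::abs(rx1[b][i]);
      m = std::max(m, std::abs(ry1[b][i]));
      m = std::max(m, std::abs(rx2[b][i]));
      m = std::max(m, std::abs(ry2[b][i]));
      if (m > maxoff[b]) maxoff[b] = m;
    }
  }
  const int n = xs.size(), h = img.nrow(), w = img.ncol();
  RawMatrix desc(nbytes, n);
  LogicalVector ok(n);
  IntegerVector bin_used(n);
  for (int j = 0; j < n; ++j) {
    const int x = xs[j], y = ys[j];
    double th = orient[j];
    int b = (int)std::lround(th / binw);
    b %= nbins;
    if (b < 0) b += nbins;
    bin_used[j] = b;
    const int m = maxoff[b];
    if (x - m < 0 || x + m >= w || y - m < 0 || y + m >= h) {
      ok[j] = false;
      continue;
    }
    ok[j] = true;
    for (int i = 0; i < npairs; ++i) {
      const double v1 = img(y + ry1[b][i], x + rx1[b][i]);
      const double v2 = img(y + ry2[b][i], x + rx2[b][i]);
      if (v1 < v2) desc(i >> 3, j) |= (Rbyte)(1 << (i & 7));
    }
  }
  return List::create(_["descriptors"] = desc, _["ok"] = ok,
                      _["bin"] = bin_used);
}

static inline int hamdist(const Rbyte *a, const Rbyte *b, int nbytes) {
  int d = 0;
  int k = 0;
  for (; k + 8 <= nbytes; k += 8) {
    uint64_t u, v;
    std::memcpy(&u, a + k, 8);
    std::memcpy(&v, b + k, 8);
    d += __builtin_popcountll(u ^ v);
  }
  for (; k < nbytes; ++k) d += __builtin_popcount((unsigned)(a[k] ^ b[k]));
  return d;
}

// [[Rcpp::export]]
int hamming_cpp(RawVector a, RawVector b) {
  return hamdist(&a[0], &b[0], a.size());
}

// Exact 2-NN by Hamming distance; ties broken by lower (earlier) index.
// Output columns: best_idx (1-based), best_dist, second_idx, second_dist.
// [[Rcpp::export]]
IntegerMatrix brute2nn_cpp(RawMatrix train, RawMatrix query) {
  const int n = train.ncol(), m = query.ncol(), nb = train.nrow();
  IntegerMatrix out(m, 4);
  for (int q = 0; q < m; ++q) {
    const Rbyte *qp = &query(0, q);
    int b1 = -1, d1 = INT_MAX, b2 = -1, d2 = INT_MAX;
    for (int j = 0; j < n; ++j) {
      const int d = hamdist(qp, &train(0, j), nb);
      if (d < d1) {
        b2 = b1; d2 = d1;
        b1 = j; d1 = d;
      } else if (d < d2) {
        b2 = j; d2 = d;
      }
    }
    out(q, 0) = b1 >= 0 ? b1 + 1 : NA_INTEGER;
    out(q, 1) = b1 >= 0 ? d1 : NA_INTEGER;
    out(q, 2) = b2 >= 0 ? b2 + 1 : NA_INTEGER;
    out(q, 3) = b2 >= 0 ? d2 : NA_INTEGER;
  }
  return out;
}

// Bit-sampling LSH keys. bitpos: key_bits x b matrix of 0-based bit indices;
// bit i of a descriptor lives at byte i >> 3, position i & 7 (LSB-first).
// [[Rcpp::export]]
IntegerMatrix lsh_keys_cpp(RawMatrix desc, IntegerMatrix bitpos) {
  const int n = desc.ncol(), kb = bitpos.nrow(), b = bitpos.ncol();
  IntegerMatrix keys(n, b);
  for (int j = 0; j < n; ++j)
    for (int t = 0; t < b; ++t) {
      int key = 0;
      for (int k = 0; k < kb; ++k) {
        const int pos = bitpos(k, t);
        const int bit = (desc(pos >> 3, j) >> (pos & 7)) & 1;
        key = (key << 1) | bit;
      }
      keys(j, t) = key;
    }
  return keys;
}

// Approximate 2-NN: candidate set is the union of the query's buckets across
// all tables; exhaustive Hamming comparison within that set.
// [[Rcpp::export]]
IntegerMatrix lsh2nn_cpp(RawMatrix train, IntegerMatrix train_keys,
                         RawMatrix query, IntegerMatrix query_keys) {
  const int n = train.ncol(), m = query.ncol(), nb = train.nrow();
  const int b = train_keys.ncol();
  std::vector<std::unordered_map<int, std::vector<int>>> tables(b);
  for (int t = 0; t < b; ++t) {
    tables[t].reserve(n);
    for (int j = 0; j < n; ++j) tables[t][train_keys(j, t)].push_back(j);
  }
  std::vector<int> stamp(n, -1);
  IntegerMatrix out(m, 4);
  for (int q = 0; q < m; ++q) {
    const Rbyte *qp = &query(0, q);
    int b1 = -1, d1 = INT_MAX, b2 = -1, d2 = INT_MAX;
    for (int t = 0; t < b; ++t) {
      auto it = tables[t].find(query_keys(q, t));
      if (it == tables[t].end()) continue;
      for (int j : it->second) {
        if (stamp[j] == q) continue;
        stamp[j] = q;
        const int d = hamdist(qp, &train(0, j), nb);
        if (d < d1 || (d == d1 && j < b1)) {
          if (b1 != j) { b2 = b1; d2 = d1; }
          b1 = j; d1 = d;
        } else if (d < d2 || (d == d2 && j < b2)) {
          b2 = j; d2 = d;
        }
      }
    }
    out(q, 0) = b1 >= 0 ? b1 + 1 : NA_INTEGER;
    out(q, 1) = b1 >= 0 ? d1 : NA_INTEGER;
    out(q, 2) = b2 >= 0 ? b2 + 1 : NA_INTEGER;
    out(q, 3) = b2 >= 0 ? d2 : NA_INTEGER;
  }
  return out;
}

// RANSAC consensus scan for a pure translation model. `cand` holds 1-based
// match indices to try as the minimal (single-correspondence) sample; returns
// the first candidate attaining the maximum inlier count (<= delta, inclusive).
// [[Rcpp::export]]
List ransac_scan_cpp(NumericVector sx, NumericVector sy, NumericVector dx,
                     NumericVector dy, IntegerVector cand, double delta) {
  const int n = sx.size(), m = cand.size();
  const double d2 = delta * delta;
  int best = -1, bestc = -1;
  for (int k = 0; k < m; ++k) {
    const int j = cand[k] - 1;
    const double tx = dx[j] - sx[j], ty = dy[j] - sy[j];
    int cnt = 0;
    for (int i = 0; i < n; ++i) {
      const double ex = sx[i] + tx - dx[i], ey = sy[i] + ty - dy[i];
      if (ex * ex + ey * ey <= d2) ++cnt;
    }
    if (cnt > bestc) {
      bestc = cnt;
      best = k;
    }
  }
  return List::create(_["best_k"] = best + 1, _["count"] = bestc);
}
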