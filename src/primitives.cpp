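#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Pixel-level primitives for the image-processing layer. All functions treat
// matrices in R's column-major layout and replicate edge pixels where a
// neighbourhood extends beyond the image.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// ---- grayscale morphology with an arbitrary non-flat structuring element ----
// se_dr/se_dc: integer offsets of SE support; se_h: SE height at each offset.
// Erosion:  out(p) = min_q f(p+q) - h(q);  Dilation: out(p) = max_q f(p-q) + h(q).

// Pad with edge replication by (pr, pc); returns (nr+2pr) x (nc+2pc) buffer.
static std::vector<double> pad_replicate(const NumericMatrix &img, int pr,
                                         int pc, int &pnr, int &pnc) {
  int nr = img.nrow(), nc = img.ncol();
  pnr = nr + 2 * pr;
  pnc = nc + 2 * pc;
  std::vector<double> pad((size_t)pnr * pnc);
  for (int c = 0; c < pnc; ++c) {
    int cc = clampi(c - pc, 0, nc - 1);
    for (int r = 0; r < pnr; ++r) {
      int rr = clampi(r - pr, 0, nr - 1);
      pad[(size_t)c * pnr + r] = img(rr, cc);
    }
  }
  return pad;
}

// Offset-outer / pixel-inner morphology: for every SE offset one contiguous
// sweep over the padded image, so the hot loop vectorizes.

// [[Rcpp::export]]
NumericMatrix cpp_erode_gray(NumericMatrix img, IntegerVector se_dr,
                             IntegerVector se_dc, NumericVector se_h) {
  int nr = img.nrow(), nc = img.ncol(), ns = se_dr.size();
  int rmax = 0, cmax = 0;
  for (int k = 0; k < ns; ++k) {
    rmax = std::max(rmax, std::abs(se_dr[k]));
    cmax = std::max(cmax, std::abs(se_dc[k]));
  }
  int pnr, pnc;
  std::vector<double> pad = pad_replicate(img, rmax, cmax, pnr, pnc);
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(),
            std::numeric_limits<double>::infinity());
  double *o = out.begin();
  for (int k = 0; k < ns; ++k) {
    double h = se_h[k];
    for (int c = 0; c < nc; ++c) {
      const double *p = &pad[(size_t)(c + cmax + se_dc[k]) * pnr +
                             rmax + se_dr[k]];
      double *oc = o + (size_t)c * nr;
      for (int r = 0; r < nr; ++r) {
        double v = p[r] - h;
        if (v < oc[r]) oc[r] = v;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_dilate_gray(NumericMatrix img, IntegerVector se_dr,
                              IntegerVector se_dc, NumericVector se_h) {
  int nr = img.nrow(), nc = img.ncol(), ns = se_dr.size();
  int rmax = 0, cmax = 0;
  for (int k = 0; k < ns; ++k) {
    rmax = std::max(rmax, std::abs(se_dr[k]));
    cmax = std::max(cmax, std::abs(se_dc[k]));
  }
  int pnr, pnc;
  std::vector<double> pad = pad_replicate(img, rmax, cmax, pnr, pnc);
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(),
            -std::numeric_limits<double>::infinity());
  double *o = out.begin();
  for (int k = 0; k < ns; ++k) {
    double h = se_h[k];
    for (int c = 0; c < nc; ++c) {
      const double *p = &pad[(size_t)(c + cmax - se_dc[k]) * pnr +
                             rmax - se_dr[k]];
      double *oc = o + (size_t)c * nr;
      for (int r = 0; r < nr; ++r) {
        double v = p[r] + h;
        if (v > oc[r]) oc[r] = v;
      }
    }
  }
  return out;
}

// ---- binary majority (median) filter over a disc neighbourhood ----
// Disc neighbourhoods centred on a pixel have odd cardinality, so the median
// of {0,1} values is the majority vote.

// [[Rcpp::export]]
IntegerMatrix cpp_median_binary(IntegerMatrix mask, IntegerVector se_dr,
                                IntegerVector se_dc) {
  int nr = mask.nrow(), nc = mask.ncol(), ns = se_dr.size();
  IntegerMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int cnt = 0;
      for (int k = 0; k < ns; ++k) {
        int rr = clampi(r + se_dr[k], 0, nr - 1);
        int cc = clampi(c + se_dc[k], 0, nc - 1);
        cnt += mask(rr, cc);
      }
      out(r, c) = (2 * cnt > ns) ? 1 : 0;
    }
  }
  return out;
}

// ---- connected-component labelling (4- or 8-connectivity), BFS in scan order ----

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> dr, dc;
  dr.assign({-1, 1, 0, 0}); dc.assign({0, 0, -1, 1});
  if (connectivity == 8) {
    dr.insert(dr.end(), {-1, -1, 1, 1});
    dc.insert(dc.end(), {-1, 1, -1, 1});
  }
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) != 0 && lab(r, c) == 0) {
        lab(r, c) = ++next;
        q.push(std::make_pair(r, c));
        while (!q.empty()) {
          std::pair<int, int> p = q.front(); q.pop();
          for (size_t k = 0; k < dr.size(); ++k) {
            int rr = p.first + dr[k], cc = p.second + dc[k];
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              q.push(std::make_pair(rr, cc));
            }
          }
        }
      }
    }
  }
  return lab;
}

// ---- exact squared Euclidean distance transform (Felzenszwalb-Huttenlocher) ----
// Distance of each foreground pixel to the nearest background pixel.

static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e18;
  NumericMatrix g(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      g(r, c) = mask(r, c) != 0 ? INF : 0.0;
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // columns
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = g(r, c);
    dt1d(f, d, nr);
    for (int r = 0; r < nr; ++r) g(r, c) = d[r];
  }
  // rows
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = g(r, c);
    dt1d(f, d, nc);
    for (int c = 0; c < nc; ++c) g(r, c) = d[c];
  }
  return g;
}

// ---- grayscale reconstruction by dilation (marker under mask), hybrid algorithm ----

// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilate(NumericMatrix marker, NumericMatrix mask) {
  int nr = marker.nrow(), nc = marker.ncol();
  NumericMatrix J(clone(marker));
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  // raster pass (N+ neighbours), then anti-raster with queue seeding
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double m = J(r, c);
      for (int k = 0; k < 4; ++k) { // neighbours already visited in scan order
        int rr = r + dr8[k], cc = c + dc8[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        // visited iff cc < c, or (cc == c and rr < r)
        if (cc < c || (cc == c && rr < r)) {
          if (J(rr, cc) > m) m = J(rr, cc);
        }
      }
      J(r, c) = std::min(m, mask(r, c));
    }
  }
  std::queue<std::pair<int, int> > q;
  for (int c = nc - 1; c >= 0; --c) {
    for (int r = nr - 1; r >= 0; --r) {
      double m = J(r, c);
      for (int k = 0; k < 8; ++k) {
        int rr = r + dr8[k], cc = c + dc8[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (cc > c || (cc == c && rr > r)) {
          if (J(rr, cc) > m) m = J(rr, cc);
        }
      }
      J(r, c) = std::min(m, mask(r, c));
      for (int k = 0; k < 8; ++k) {
        int rr = r + dr8[k], cc = c + dc8[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if ((cc > c || (cc == c && rr > r)) &&
            J(rr, cc) < J(r, c) && J(rr, cc) < mask(rr, cc))
          q.push(std::make_pair(r, c));
      }
    }
  }
  while (!q.empty()) {
    std::pair<int, int> p = q.front(); q.pop();
    for (int k = 0; k < 8; ++k) {
      int rr = p.first + dr8[k], cc = p.second + dc8[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (J(rr, cc) < J(p.first, p.second) && mask(rr, cc) != J(rr, cc)) {
        double v = std::min(J(p.first, p.second), mask(rr, cc));
        if (v > J(rr, cc)) {
          J(rr, cc) = v;
          q.push(std::make_pair(rr, cc));
        }
      }
    }
  }
  return J;
}

// ---- regional maxima: labelled plateaus with no strictly greater neighbour ----
// Restricted to pixels where fg != 0. 8-connectivity.

// [[Rcpp::export]]
IntegerMatrix cpp_regional_maxima(NumericMatrix img, IntegerMatrix fg) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc); // 0 unvisited, -1 visited non-max, k>0 max plateau
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  int next = 0;
  std::vector<std::pair<int, int> > plateau;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (fg(r, c) == 0 || lab(r, c) != 0) continue;
      double v = img(r, c);
      bool is_max = true;
      plateau.clear();
      q.push(std::make_pair(r, c));
      lab(r, c) = -2; // in-queue marker
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        plateau.push_back(p);
        for (int k = 0; k < 8; ++k) {
          int rr = p.first + dr8[k], cc = p.second + dc8[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          double w = fg(rr, cc) != 0 ? img(rr, cc) : -std::numeric_limits<double>::infinity();
          if (w > v) is_max = false;
          else if (w == v && lab(rr, cc) == 0) {
            lab(rr, cc) = -2;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
      int tag = is_max ? ++next : -1;
      for (size_t i = 0; i < plateau.size(); ++i)
        lab(plateau[i].first, plateau[i].second) = tag;
    }
  }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) < 0) lab(r, c) = 0;
  return lab;
}

// ---- seeded watershed flooding (Meyer) on a priority surface ----
// Floods foreground pixels from labelled seeds in order of decreasing
// `height` (the distance transform); every foreground pixel ends up with
// exactly one label, so foreground area is conserved. FIFO order breaks ties
// deterministically.

struct WsItem {
  double h;
  long order;
  int r, c, lab;
};
struct WsCmp {
  bool operator()(const WsItem &a, const WsItem &b) const {
    if (a.h != b.h) return a.h < b.h;  // larger height popped first
    return a.order > b.order;           // then FIFO
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_watershed_seeded(NumericMatrix height, IntegerMatrix seeds,
                                   IntegerMatrix fg, int connectivity) {
  int nr = height.nrow(), nc = height.ncol();
  IntegerMatrix lab(clone(seeds));
  std::vector<int> dr, dc;
  dr.assign({-1, 1, 0, 0}); dc.assign({0, 0, -1, 1});
  if (connectivity == 8) {
    dr.insert(dr.end(), {-1, -1, 1, 1});
    dc.insert(dc.end(), {-1, 1, -1, 1});
  }
  std::priority_queue<WsItem, std::vector<WsItem>, WsCmp> pq;
  long order = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) > 0)
        for (size_t k = 0; k < dr.size(); ++k) {
          int rr = r + dr[k], cc = c + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (fg(rr, cc) != 0 && lab(rr, cc) == 0) {
            WsItem it = {height(rr, cc), order++, rr, cc, lab(r, c)};
            pq.push(it);
          }
        }
  while (!pq.empty()) {
    WsItem it = pq.top(); pq.pop();
    if (lab(it.r, it.c) != 0) continue;
    lab(it.r, it.c) = it.lab;
    for (size_t k = 0; k < dr.size(); ++k) {
      int rr = it.r + dr[k], cc = it.c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (fg(rr, cc) != 0 && lab(rr, cc) == 0) {
        WsItem nx = {height(rr, cc), order++, rr, cc, it.lab};
        pq.push(nx);
      }
    }
  }
  return lab;
}
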