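#include <Rcpp.h>
#include <queue>
#include <vector>
#include <tuple>
using namespace Rcpp;

// Index helpers: R matrices are column-major, (r, c) 0-based -> r + c*H.
static inline int idx(int r, int c, int H) { return r + c * H; }

// Connected-component labelling of a binary mask.
// Scan order is raster (row-major), so component k is the k-th component
// encountered when reading the image row by row; this fixes label order.
// connectivity: 4 or 8.
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerMatrix cc_label_cpp(LogicalMatrix mask, int connectivity) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  stack.reserve(256);
  int next = 0;
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  int nn = (connectivity == 8) ? 8 : 4;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(idx(r, c, H));
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pr = p % H, pc = p / H;
        for (int k = 0; k < nn; ++k) {
          int qr = pr + dr[k], qc = pc + dc[k];
          if (qr < 0 || qr >= H || qc < 0 || qc >= W) continue;
          if (mask(qr, qc) && lab(qr, qc) == 0) {
            lab(qr, qc) = next;
            stack.push_back(idx(qr, qc, H));
          }
        }
      }
    }
  }
  return lab;
}

struct WsEntry {
  double d;
  long order;
  int index;
  int label;
};
// Max-heap on distance; ties resolved first-in-first-out (insertion order),
// so fronts advance alternately across distance plateaus and meet midway,
// then by linear index for full determinism.
struct WsCompare {
  bool operator()(const WsEntry &a, const WsEntry &b) const {
    if (a.d != b.d) return a.d < b.d;
    if (a.order != b.order) return a.order > b.order;
    return a.index > b.index;
  }
};

// Marker-based watershed by priority flooding of the distance map from the
// markers downhill (Meyer's algorithm on the negated distance map).
// Growth is 4-connected and restricted to `allowed` pixels; a pixel whose
// already-assigned neighbours carry two distinct labels becomes a ridge
// pixel (label 0), so basins never touch.
// [[Rcpp::export(name = ".marker_watershed_cpp")]]
IntegerMatrix marker_watershed_cpp(NumericMatrix dist, IntegerMatrix markers,
                                   LogicalMatrix allowed) {
  int H = dist.nrow(), W = dist.ncol();
  IntegerMatrix out(H, W); // 0 unassigned, -1 ridge, >0 basin
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCompare> pq;
  long order = 0;
  const int dr[4] = {-1, 0, 0, 1};
  const int dc[4] = {0, -1, 1, 0};
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (markers(r, c) > 0) {
        out(r, c) = markers(r, c);
      }
    }
  }
  // Seed the queue with the markers' free neighbours.
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (out(r, c) <= 0) continue;
      for (int k = 0; k < 4; ++k) {
        int qr = r + dr[k], qc = c + dc[k];
        if (qr < 0 || qr >= H || qc < 0 || qc >= W) continue;
        if (allowed(qr, qc) && out(qr, qc) == 0) {
          pq.push({dist(qr, qc), order++, idx(qr, qc, H), out(r, c)});
        }
      }
    }
  }
  while (!pq.empty()) {
    WsEntry e = pq.top();
    pq.pop();
    int r = e.index % H, c = e.index / H;
    if (out(r, c) != 0) continue;
    // Labels of already-assigned neighbours decide basin vs ridge.
    int lab = 0;
    bool ridge = false;
    for (int k = 0; k < 4; ++k) {
      int qr = r + dr[k], qc = c + dc[k];
      if (qr < 0 || qr >= H || qc < 0 || qc >= W) continue;
      int ql = out(qr, qc);
      if (ql > 0) {
        if (lab == 0) lab = ql;
        else if (lab != ql) { ridge = true; break; }
      }
    }
    if (ridge) {
      out(r, c) = -1;
      continue;
    }
    if (lab == 0) lab = e.label; // front arrived before any neighbour settled
    out(r, c) = lab;
    for (int k = 0; k < 4; ++k) {
      int qr = r + dr[k], qc = c + dc[k];
      if (qr < 0 || qr >= H || qc < 0 || qc >= W) continue;
      if (allowed(qr, qc) && out(qr, qc) == 0) {
        pq.push({dist(qr, qc), order++, idx(qr, qc, H), lab});
      }
    }
  }
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (out(r, c) < 0) out(r, c) = 0;
  return out;
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// 8-connected binary dilation / erosion with replicated boundary.
static void dil8(const std::vector<int> &u, std::vector<int> &v, int H, int W) {
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int m = 0;
      for (int dr = -1; dr <= 1 && !m; ++dr)
        for (int dc = -1; dc <= 1; ++dc) {
          int qr = r + dr, qc = c + dc;
          if (qr < 0 || qr >= H || qc < 0 || qc >= W) continue;
          if (u[idx(qr, qc, H)]) { m = 1; break; }
        }
      v[idx(r, c, H)] = m;
    }
  }
}
static void ero8(const std::vector<int> &u, std::vector<int> &v, int H, int W) {
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int m = 1;
      for (int dr = -1; dr <= 1 && m; ++dr)
        for (int dc = -1; dc <= 1; ++dc) {
          int qr = r + dr, qc = c + dc;
          if (qr < 0 || qr >= H || qc < 0 || qc >= W) continue;
          if (!u[idx(qr, qc, H)]) { m = 0; break; }
        }
      v[idx(r, c, H)] = m;
    }
  }
}

// Curvature morphology on line segments of length 3 in 4 orientations
// (the sup-inf / inf-sup operators of the morphological GAC solver).
static const int ORI[4][2] = {{0, 1}, {1, 0}, {1, 1}, {1, -1}};

// SI: sup over orientations of inf along segment (keeps pixels lying on a
// fully-set line); IS: inf over orientations of sup along segment.
static void si_op(const std::vector<int> &u, std::vector<int> &v, int H, int W) {
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int best = 0;
      for (int o = 0; o < 4 && !best; ++o) {
        int all = 1;
        for (int s = -1; s <= 1; ++s) {
          int qr = clampi(r + s * ORI[o][0], 0, H - 1);
          int qc = clampi(c + s * ORI[o][1], 0, W - 1);
          if (!u[idx(qr, qc, H)]) { all = 0; break; }
        }
        if (all) best = 1;
      }
      v[idx(r, c, H)] = best;
    }
  }
}
static void is_op(const std::vector<int> &u, std::vector<int> &v, int H, int W) {
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int worst = 1;
      for (int o = 0; o < 4 && worst; ++o) {
        int any = 0;
        for (int s = -1; s <= 1; ++s) {
          int qr = clampi(r + s * ORI[o][0], 0, H - 1);
          int qc = clampi(c + s * ORI[o][1], 0, W - 1);
          if (u[idx(qr, qc, H)]) { any = 1; break; }
        }
        if (!any) worst = 0;
      }
      v[idx(r, c, H)] = worst;
    }
  }
}

// Morphological geodesic active contour evolution.
// Per iteration: (i) balloon force: dilation (nu=+1) or erosion (nu=-1)
// applied where the attraction field g exceeds theta; (ii) image attraction:
// flip pixels where grad(g) . grad(u) is decisive; (iii) mu alternating
// curvature-smoothing passes. The discrete operators can settle into short
// limit cycles rather than a fixed point, so the mask is compared against a
// short history (6 states); it must keep repeating for conv_window
// consecutive iterations to stop, else it runs to max_iter.
// [[Rcpp::export(name = ".gac_evolve_cpp")]]
List gac_evolve_cpp(IntegerMatrix seed, NumericMatrix g, int nu, double theta,
                    int mu, int max_iter, int conv_window) {
  int H = seed.nrow(), W = seed.ncol(), N = H * W;
  const int HIST = 6;
  std::vector<int> u(N), tmp(N);
  for (int i = 0; i < N; ++i) u[i] = seed[i] != 0;
  std::vector<std::vector<int>> hist(HIST, u);
  // gradient of g, central differences with replicated boundary
  std::vector<double> dgr(N), dgc(N);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int rp = clampi(r + 1, 0, H - 1), rm = clampi(r - 1, 0, H - 1);
      int cp = clampi(c + 1, 0, W - 1), cm = clampi(c - 1, 0, W - 1);
      dgr[idx(r, c, H)] = (g(rp, c) - g(rm, c)) / 2.0;
      dgc[idx(r, c, H)] = (g(r, cp) - g(r, cm)) / 2.0;
    }
  }
  int stable = 0, it = 0, pass_id = 0, hpos = 0;
  for (it = 1; it <= max_iter; ++it) {
    // balloon
    if (nu != 0) {
      if (nu > 0) dil8(u, tmp, H, W); else ero8(u, tmp, H, W);
      for (int i = 0; i < N; ++i)
        if (g[i] > theta) u[i] = tmp[i];
    }
    // attraction: grad(g) . grad(u)
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        int rp = clampi(r + 1, 0, H - 1), rm = clampi(r - 1, 0, H - 1);
        int cp = clampi(c + 1, 0, W - 1), cm = clampi(c - 1, 0, W - 1);
        int i = idx(r, c, H);
        double dur = (u[idx(rp, c, H)] - u[idx(rm, c, H)]) / 2.0;
        double duc = (u[idx(r, cp, H)] - u[idx(r, cm, H)]) / 2.0;
        double dot = dgr[i] * dur + dgc[i] * duc;
        tmp[i] = dot > 0 ? 1 : (dot < 0 ? 0 : u[i]);
      }
    }
    std::swap(u, tmp);
    // smoothing: mu alternating SIoIS / ISoSI passes
    for (int m = 0; m < mu; ++m) {
      if (pass_id % 2 == 0) {
        is_op(u, tmp, H, W);
        si_op(tmp, u, H, W);
      } else {
        si_op(u, tmp, H, W);
        is_op(tmp, u, H, W);
      }
      ++pass_id;
    }
    bool same = false;
    for (int h = 0; h < HIST && !same; ++h) same = (u == hist[h]);
    stable = same ? stable + 1 : 0;
    hist[hpos] = u;
    hpos = (hpos + 1) % HIST;
    if (stable >= conv_window) break;
  }
  IntegerMatrix out(H, W);
  for (int i = 0; i < N; ++i) out[i] = u[i];
  return List::create(_["mask"] = out, _["iterations"] = std::min(it, max_iter));
}
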