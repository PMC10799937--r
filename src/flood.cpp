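// Connected-component labelling and marker flood for the watershed decode.
// Both use synchronous minimum-label propagation (deterministic: ties go to
// the smallest label), 8- or 4-neighbour connectivity.

#include <Rcpp.h>
using namespace Rcpp;

static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// [[Rcpp::export]]
IntegerMatrix cc_label(const IntegerMatrix& mask, const int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  const int nn = (connectivity >= 2) ? 8 : 4;
  static const int DR4[4] = {-1, 0, 0, 1};
  static const int DC4[4] = {0, -1, 1, 0};
  std::vector<int> lab(static_cast<size_t>(H) * W, 0);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (mask(r, c)) lab[c * H + r] = c * H + r + 1;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        const int p = c * H + r;
        if (!lab[p]) continue;
        int best = lab[p];
        for (int k = 0; k < nn; ++k) {
          const int r2 = r + ((nn == 8) ? DR8[k] : DR4[k]);
          const int c2 = c + ((nn == 8) ? DC8[k] : DC4[k]);
          if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
          const int q = lab[c2 * H + r2];
          if (q && q < best) best = q;
        }
        if (best < lab[p]) { lab[p] = best; changed = true; }
      }
    }
  }
  // densify label ids in first-occurrence (column-major) order
  std::map<int, int> remap;
  IntegerMatrix out(H, W);
  int next = 0;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      const int v = lab[c * H + r];
      if (!v) continue;
      auto it = remap.find(v);
      if (it == remap.end()) { remap[v] = ++next; out(r, c) = next; }
      else out(r, c) = it->second;
    }
  }
  return out;
}

// Marker flood over descending energy levels: for L = K..1, repeatedly
// grow labels into unlabelled pixels with level >= L (8-neighbour,
// synchronous passes, smallest neighbouring label wins ties).
// [[Rcpp::export]]
IntegerMatrix ws_flood(const IntegerMatrix& lev, const IntegerMatrix& seeds,
                       const int K) {
  const int H = lev.nrow(), W = lev.ncol();
  IntegerMatrix lab = clone(seeds);
  for (int L = K; L >= 1; --L) {
    bool changed = true;
    while (changed) {
      changed = false;
      std::vector<std::pair<int, int>> updates;
      for (int c = 0; c < W; ++c) {
        for (int r = 0; r < H; ++r) {
          if (lab(r, c) || lev(r, c) < L) continue;
          int best = 0;
          for (int k = 0; k < 8; ++k) {
            const int r2 = r + DR8[k], c2 = c + DC8[k];
            if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
            const int q = lab(r2, c2);
            if (q && (!best || q < best)) best = q;
          }
          if (best) updates.emplace_back(c * H + r, best);
        }
      }
      for (auto& u : updates) {
        lab[u.first] = u.second;
        changed = true;
      }
    }
  }
  return lab;
}
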