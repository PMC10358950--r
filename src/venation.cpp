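#include <Rcpp.h>
using namespace Rcpp;

// 8-neighborhood in circular order starting East, counter-clockwise:
// E, NE, N, NW, W, SW, S, SE (row offsets, col offsets)
static const int DR[8] = { 0, -1, -1, -1,  0,  1,  1,  1};
static const int DC[8] = { 1,  1,  0, -1, -1, -1,  0,  1};

static inline int at(const LogicalMatrix &m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return 0;
  return m(r, c) ? 1 : 0;
}

// Yokoi connectivity number for 8-connected foreground. A foreground pixel is
// 8-simple (deletable without changing local topology) iff this equals 1.
static inline int yokoi8(const LogicalMatrix &m, int r, int c) {
  int x[9];
  for (int k = 0; k < 8; ++k) x[k] = at(m, r + DR[k], c + DC[k]);
  x[8] = x[0];
  int n = 0;
  for (int k = 0; k < 8; k += 2) {
    int a = 1 - x[k], b = 1 - x[k + 1], d = 1 - x[(k + 2) % 8 == 0 ? 8 : k + 2];
    n += a - a * b * d;
  }
  return n;
}

static inline int nforeground(const LogicalMatrix &m, int r, int c) {
  int b = 0;
  for (int k = 0; k < 8; ++k) b += at(m, r + DR[k], c + DC[k]);
  return b;
}

// Sequential simple-point thinning with endpoint preservation.
// Four directional sub-passes (N, S, E, W border pixels) repeated until
// stable; each deletion is applied immediately, so every single deletion
// provably preserves the number of 8-connected components and the cycle
// rank of the foreground.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix input) {
  LogicalMatrix m = clone(input);
  const int nr = m.nrow(), nc = m.ncol();
  // border direction offsets: N, S, E, W neighbor that must be background
  const int bdr[4] = {-1, 1, 0, 0};
  const int bdc[4] = {0, 0, 1, -1};
  bool changed = true;
  std::vector<int> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 4; ++d) {
      // two-phase subpass: collect this direction's border pixels first, so
      // deletions cannot cascade along the scan order and erode open curves
      cand.clear();
      for (int r = 0; r < nr; ++r)
        for (int c = 0; c < nc; ++c)
          if (m(r, c) && !at(m, r + bdr[d], c + bdc[d]))
            cand.push_back(r * nc + c);
      for (size_t i = 0; i < cand.size(); ++i) {
        int r = cand[i] / nc, c = cand[i] % nc;
        int b = nforeground(m, r, c);
        if (b < 2) continue;                 // keep endpoints and isolated pixels
        if (yokoi8(m, r, c) != 1) continue;  // not simple (re-checked at deletion time)
        m(r, c) = false;
        changed = true;
      }
    }
  }
  return m;
}

// 4-connected component labelling (used for background/hole analysis, the
// complement connectivity of 8-connected foreground).
// [[Rcpp::export]]
IntegerMatrix cpp_label4(LogicalMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  static const int D4R[4] = {-1, 1, 0, 0};
  static const int D4C[4] = {0, 0, -1, 1};
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!m(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r * nc + c);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p / nc, pc = p % nc;
        for (int k = 0; k < 4; ++k) {
          int qr = pr + D4R[k], qc = pc + D4C[k];
          if (qr < 0 || qc < 0 || qr >= nr || qc >= nc) continue;
          if (!m(qr, qc) || lab(qr, qc) != 0) continue;
          lab(qr, qc) = next;
          stack.push_back(qr * nc + qc);
        }
      }
    }
  }
  return lab;
}

// 8-connected component labelling, labels 1..K assigned in raster-scan
// (row-major) order of each component's first-encountered pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!m(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r * nc + c);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p / nc, pc = p % nc;
        for (int k = 0; k < 8; ++k) {
          int qr = pr + DR[k], qc = pc + DC[k];
          if (qr < 0 || qc < 0 || qr >= nr || qc >= nc) continue;
          if (!m(qr, qc) || lab(qr, qc) != 0) continue;
          lab(qr, qc) = next;
          stack.push_back(qr * nc + qc);
        }
      }
    }
  }
  return lab;
}
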