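#include <Rcpp.h>
using namespace Rcpp;

// Gray-level texture matrices for one quantized window (values 1..L).
// 2-D adaptation of the standard radiomics conventions: distance-1
// neighbors in 4 in-plane directions for GLCM/GLRLM (counts pooled across
// directions), 8-connectivity for GLSZM zones, 8-neighborhood means for
// NGTDM. The feature statistics themselves are computed in R.

static const int DR4[4] = {0, -1, -1, -1};   // 0, 45, 90, 135 degrees
static const int DC4[4] = {1, 1, 0, -1};

// symmetric pooled co-occurrence counts, normalized to sum 1
// [[Rcpp::export]]
NumericMatrix glcm_pooled(IntegerMatrix q, int L) {
  int H = q.nrow(), W = q.ncol();
  NumericMatrix m(L, L);
  double total = 0.0;
  for (int d = 0; d < 4; ++d) {
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        int rr = r + DR4[d], cc = c + DC4[d];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        int a = q(r, c) - 1, b = q(rr, cc) - 1;
        m(a, b) += 1.0;
        m(b, a) += 1.0;
        total += 2.0;
      }
    }
  }
  if (total > 0) for (int i = 0; i < L * L; ++i) m[i] /= total;
  return m;
}

// run-length counts pooled over 4 directions; columns = run length
// [[Rcpp::export]]
NumericMatrix glrlm_pooled(IntegerMatrix q, int L) {
  int H = q.nrow(), W = q.ncol();
  int maxlen = std::max(H, W);
  NumericMatrix m(L, maxlen);
  for (int d = 0; d < 4; ++d) {
    int dr = -DR4[d], dc = -DC4[d];  // scan along the direction
    // collect line starts: cells with no predecessor along (dr, dc)
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        int pr = r - dr, pc = c - dc;
        bool is_start = (pr < 0 || pr >= H || pc < 0 || pc >= W);
        if (!is_start) continue;
        int rr = r, cc = c;
        int level = q(rr, cc), len = 0;
        while (rr >= 0 && rr < H && cc >= 0 && cc < W) {
          int v = q(rr, cc);
          if (v == level) {
            ++len;
          } else {
            m(level - 1, len - 1) += 1.0;
            level = v;
            len = 1;
          }
          rr += dr; cc += dc;
        }
        m(level - 1, len - 1) += 1.0;
      }
    }
  }
  return m;
}

// 8-connected constant-level zones: rows of (level, size)
// [[Rcpp::export]]
IntegerMatrix glszm_zones(IntegerMatrix q) {
  int H = q.nrow(), W = q.ncol();
  std::vector<int> lab(H * W, 0);
  std::vector<int> levels, sizes;
  std::vector<int> stack;
  int nz = 0;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int p = c * H + r;
      if (lab[p]) continue;
      int level = q(r, c);
      ++nz;
      int size = 0;
      stack.push_back(p);
      lab[p] = nz;
      while (!stack.empty()) {
        int cur = stack.back();
        stack.pop_back();
        ++size;
        int cr = cur % H, cc = cur / H;
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            int rr = cr + dr, ccc = cc + dc;
            if (rr < 0 || rr >= H || ccc < 0 || ccc >= W) continue;
            int pp = ccc * H + rr;
            if (lab[pp] || q(rr, ccc) != level) continue;
            lab[pp] = nz;
            stack.push_back(pp);
          }
        }
      }
      levels.push_back(level);
      sizes.push_back(size);
    }
  }
  IntegerMatrix out(nz, 2);
  for (int i = 0; i < nz; ++i) {
    out(i, 0) = levels[i];
    out(i, 1) = sizes[i];
  }
  return out;
}

// NGTDM over interior pixels (full 8-neighborhood): per level i returns
// the occurrence count n_i and the summed absolute deviation s_i from the
// neighborhood mean
// [[Rcpp::export]]
NumericMatrix ngtdm_counts(IntegerMatrix q, int L) {
  int H = q.nrow(), W = q.ncol();
  NumericMatrix out(L, 2);
  for (int c = 1; c < W - 1; ++c) {
    for (int r = 1; r < H - 1; ++r) {
      double nb = 0.0;
      for (int dr = -1; dr <= 1; ++dr)
        for (int dc = -1; dc <= 1; ++dc) {
          if (dr == 0 && dc == 0) continue;
          nb += q(r + dr, c + dc);
        }
      nb /= 8.0;
      int i = q(r, c) - 1;
      out(i, 0) += 1.0;
      out(i, 1) += std::fabs(q(r, c) - nb);
    }
  }
  return out;
}
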