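#include <Rcpp.h>
using namespace Rcpp;

// Grid-binned collision classification for cluster resolvability.
//
// A cluster is usable iff no other cluster lies within r_hard (any tag)
// and no same-tag cluster lies within r_soft. Cells are at least r_soft
// wide, so every neighbour within r_soft sits in the 3x3 cell block; the
// result is exactly equivalent to the all-pairs evaluation.
//
// tag: integer tag index per point; a value of -1 means "unique tag"
// (unbiased sentinel) and never triggers the soft rule.

// [[Rcpp::export(name = ".classify_grid")]]
LogicalVector classify_grid(NumericVector x, NumericVector y,
                            IntegerVector tag,
                            double r_hard, double r_soft,
                            double width, double height,
                            bool periodic) {
  const int n = x.size();
  LogicalVector usable(n, true);
  if (n == 0) return usable;

  int ncx = std::max(1, (int)std::floor(width / r_soft));
  int ncy = std::max(1, (int)std::floor(height / r_soft));
  const double cw = width / ncx;
  const double ch = height / ncy;
  const double rh2 = r_hard * r_hard;
  const double rs2 = r_soft * r_soft;

  std::vector<int> cell(n);
  std::vector<int> count(ncx * ncy + 1, 0);
  for (int i = 0; i < n; ++i) {
    int cxi = std::min((int)(x[i] / cw), ncx - 1);
    int cyi = std::min((int)(y[i] / ch), ncy - 1);
    cell[i] = cyi * ncx + cxi;
    ++count[cell[i] + 1];
  }
  for (size_t c = 1; c < count.size(); ++c) count[c] += count[c - 1];
  std::vector<int> order(n);
  {
    std::vector<int> cursor(count.begin(), count.end() - 1);
    for (int i = 0; i < n; ++i) order[cursor[cell[i]]++] = i;
  }

  for (int i = 0; i < n; ++i) {
    const int cxi = cell[i] % ncx;
    const int cyi = cell[i] / ncx;
    bool hard = false, soft = false;
    for (int dy = -1; dy <= 1 && !hard; ++dy) {
      int gy = cyi + dy;
      if (periodic) gy = (gy + ncy) % ncy;
      else if (gy < 0 || gy >= ncy) continue;
      for (int dx = -1; dx <= 1 && !hard; ++dx) {
        int gx = cxi + dx;
        if (periodic) gx = (gx + ncx) % ncx;
        else if (gx < 0 || gx >= ncx) continue;
        const int c = gy * ncx + gx;
        for (int s = count[c]; s < count[c + 1]; ++s) {
          const int j = order[s];
          if (j == i) continue;
          double ddx = x[i] - x[j];
          double ddy = y[i] - y[j];
          if (periodic) {
            if (ddx > width / 2) ddx -= width; else if (ddx < -width / 2) ddx += width;
            if (ddy > height / 2) ddy -= height; else if (ddy < -height / 2) ddy += height;
          }
          const double d2 = ddx * ddx + ddy * ddy;
          if (d2 <= rh2) { hard = true; break; }
          if (d2 <= rs2 && tag[i] >= 0 && tag[i] == tag[j]) soft = true;
        }
      }
    }
    usable[i] = !(hard || soft);
  }
  return usable;
}
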