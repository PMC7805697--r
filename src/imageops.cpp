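#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Binary-image primitives for the frame-differencing tracker.  Masks are
// integer matrices with entries 0/1; connectivity is 8-neighbour for
// foreground and 4-neighbour for the background hole fill (the standard
// complementary pairing).

// [[Rcpp::export]]
IntegerMatrix bc_dilate_cpp(IntegerMatrix m, int radius) {
  const int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; j++)
    for (int i = 0; i < nr; i++) {
      if (!m(i, j)) continue;
      const int i0 = std::max(0, i - radius), i1 = std::min(nr - 1, i + radius);
      const int j0 = std::max(0, j - radius), j1 = std::min(nc - 1, j + radius);
      for (int jj = j0; jj <= j1; jj++)
        for (int ii = i0; ii <= i1; ii++) out(ii, jj) = 1;
    }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix bc_erode_cpp(IntegerMatrix m, int radius) {
  const int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; j++)
    for (int i = 0; i < nr; i++) {
      const int i0 = std::max(0, i - radius), i1 = std::min(nr - 1, i + radius);
      const int j0 = std::max(0, j - radius), j1 = std::min(nc - 1, j + radius);
      int keep = 1;
      for (int jj = j0; jj <= j1 && keep; jj++)
        for (int ii = i0; ii <= i1; ii++)
          if (!m(ii, jj)) { keep = 0; break; }
      out(i, j) = keep;
    }
  return out;
}

// Fill background regions not connected to the image border.
// [[Rcpp::export]]
IntegerMatrix bc_fill_holes_cpp(IntegerMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix outside(nr, nc);  // background reachable from the border
  std::queue<std::pair<int, int> > q;
  for (int i = 0; i < nr; i++) {
    if (!m(i, 0))      { if (!outside(i, 0))      { outside(i, 0) = 1;      q.push(std::make_pair(i, 0)); } }
    if (!m(i, nc - 1)) { if (!outside(i, nc - 1)) { outside(i, nc - 1) = 1; q.push(std::make_pair(i, nc - 1)); } }
  }
  for (int j = 0; j < nc; j++) {
    if (!m(0, j))      { if (!outside(0, j))      { outside(0, j) = 1;      q.push(std::make_pair(0, j)); } }
    if (!m(nr - 1, j)) { if (!outside(nr - 1, j)) { outside(nr - 1, j) = 1; q.push(std::make_pair(nr - 1, j)); } }
  }
  const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    const int ci = q.front().first, cj = q.front().second;
    q.pop();
    for (int k = 0; k < 4; k++) {
      const int ii = ci + di[k], jj = cj + dj[k];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (!m(ii, jj) && !outside(ii, jj)) {
        outside(ii, jj) = 1;
        q.push(std::make_pair(ii, jj));
      }
    }
  }
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; j++)
    for (int i = 0; i < nr; i++) out(i, j) = (m(i, j) || !outside(i, j)) ? 1 : 0;
  return out;
}

// 8-connected component labelling; labels 1..k in scan order.
// [[Rcpp::export]]
IntegerMatrix bc_label_cpp(IntegerMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; j++)
    for (int i = 0; i < nr; i++) {
      if (!m(i, j) || lab(i, j)) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        const int ci = q.front().first, cj = q.front().second;
        q.pop();
        for (int dj2 = -1; dj2 <= 1; dj2++)
          for (int di2 = -1; di2 <= 1; di2++) {
            const int ii = ci + di2, jj = cj + dj2;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (m(ii, jj) && !lab(ii, jj)) {
              lab(ii, jj) = next;
              q.push(std::make_pair(ii, jj));
            }
          }
      }
    }
  return lab;
}
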