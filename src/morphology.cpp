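#include <Rcpp.h>
#include <vector>
#include <deque>
using namespace Rcpp;

// Offsets of the exact Euclidean disk {(dy,dx): dy^2+dx^2 <= r^2}.
static std::vector<std::pair<int,int>> disk_offsets(int r) {
  std::vector<std::pair<int,int>> off;
  for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx)
      if (dy * dy + dx * dx <= r * r) off.push_back({dy, dx});
  return off;
}

// Binary dilation; pixels outside the image count as background.
// [[Rcpp::export]]
LogicalMatrix cpp_dilate_disk(LogicalMatrix mask, int radius) {
  int H = mask.nrow(), W = mask.ncol();
  LogicalMatrix out(H, W);
  auto off = disk_offsets(radius);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      if (!mask(y, x)) continue;
      for (auto &o : off) {
        int yy = y + o.first, xx = x + o.second;
        if (yy >= 0 && yy < H && xx >= 0 && xx < W) out(yy, xx) = true;
      }
    }
  }
  return out;
}

// Binary erosion; pixels outside the image count as foreground, so closing
// does not eat blobs that touch the border.
// [[Rcpp::export]]
LogicalMatrix cpp_erode_disk(LogicalMatrix mask, int radius) {
  int H = mask.nrow(), W = mask.ncol();
  LogicalMatrix out(H, W);
  auto off = disk_offsets(radius);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      bool keep = true;
      for (auto &o : off) {
        int yy = y + o.first, xx = x + o.second;
        if (yy >= 0 && yy < H && xx >= 0 && xx < W && !mask(yy, xx)) {
          keep = false;
          break;
        }
      }
      out(y, x) = keep;
    }
  }
  return out;
}

// 8-connected component labeling. Labels are assigned in raster-scan order
// (column-major, matching R matrix layout) starting from 1; 0 = background.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int,int>> stack;
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      if (!mask(y, x) || lab(y, x) != 0) continue;
      ++next;
      stack.push_back({y, x});
      lab(y, x) = next;
      while (!stack.empty()) {
        auto p = stack.back();
        stack.pop_back();
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dx = -1; dx <= 1; ++dx) {
            if (dy == 0 && dx == 0) continue;
            int yy = p.first + dy, xx = p.second + dx;
            if (yy >= 0 && yy < H && xx >= 0 && xx < W &&
                mask(yy, xx) && lab(yy, xx) == 0) {
              lab(yy, xx) = next;
              stack.push_back({yy, xx});
            }
          }
        }
      }
    }
  }
  return lab;
}

// Per-pixel minimum over a forward time window [i, min(n - 1, i + window)]
// (0-based frame i, window in frames). `frames` is H*W x n, one frame per
// column. Block prefix/suffix sliding minimum, O(H*W*n), column-contiguous.
// [[Rcpp::export]]
NumericMatrix cpp_forward_window_min(NumericMatrix frames, int window) {
  int P = frames.nrow(), n = frames.ncol();
  int L = window + 1;
  NumericMatrix out(P, n);
  // suffix-min within blocks [kL, (k+1)L - 1] (truncated at n - 1)
  NumericMatrix suff(P, n), pref(P, n);
  for (int i = n - 1; i >= 0; --i) {
    const double* f = &frames(0, i);
    double* s = &suff(0, i);
    if (i == n - 1 || (i + 1) % L == 0) {
      for (int p = 0; p < P; ++p) s[p] = f[p];
    } else {
      const double* nx = &suff(0, i + 1);
      for (int p = 0; p < P; ++p) s[p] = f[p] < nx[p] ? f[p] : nx[p];
    }
  }
  // prefix-min within blocks
  for (int i = 0; i < n; ++i) {
    const double* f = &frames(0, i);
    double* q = &pref(0, i);
    if (i % L == 0) {
      for (int p = 0; p < P; ++p) q[p] = f[p];
    } else {
      const double* pv = &pref(0, i - 1);
      for (int p = 0; p < P; ++p) q[p] = f[p] < pv[p] ? f[p] : pv[p];
    }
  }
  for (int i = 0; i < n; ++i) {
    int j = i + window < n - 1 ? i + window : n - 1;
    const double* a = &suff(0, i);
    double* o = &out(0, i);
    if (i / L == j / L) {
      // same block: the truncated suffix [i .. min(block end, n-1)] is the
      // exact window because j is the last frame
      for (int p = 0; p < P; ++p) o[p] = a[p];
    } else {
      const double* b = &pref(0, j);
      for (int p = 0; p < P; ++p) o[p] = a[p] < b[p] ? a[p] : b[p];
    }
  }
  return out;
}

// True where the mask is 8-adjacent to (or overlaps) the other mask.
// [[Rcpp::export]]
LogicalMatrix cpp_adjacent8(LogicalMatrix mask) {
  // returns mask dilated by one pixel of 8-neighborhood (3x3 square)
  int H = mask.nrow(), W = mask.ncol();
  LogicalMatrix out(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      if (!mask(y, x)) continue;
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int yy = y + dy, xx = x + dx;
          if (yy >= 0 && yy < H && xx >= 0 && xx < W) out(yy, xx) = true;
        }
    }
  return out;
}
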