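// Incremental production path of the hot-blob detector: the whole per-frame
// stage loop (mouse mask, inpainting, running background, floor median,
// difference, cooldown, blob mask, closing, component filtering) in one
// pass. The exported R stage operations implement the same arithmetic
// one step at a time; tests hold the two paths exactly equal.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

namespace {

struct DiskOffsets {
  std::vector<int> dy, dx;
  DiskOffsets(int r) {
    for (int ddy = -r; ddy <= r; ++ddy)
      for (int ddx = -r; ddx <= r; ++ddx)
        if (ddy * ddy + ddx * ddx <= r * r) { dy.push_back(ddy); dx.push_back(ddx); }
  }
};

void dilate_mask(const std::vector<uint8_t>& in, std::vector<uint8_t>& out,
                 int H, int W, const DiskOffsets& off) {
  std::fill(out.begin(), out.end(), 0);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      if (!in[x * H + y]) continue;
      for (size_t k = 0; k < off.dy.size(); ++k) {
        int yy = y + off.dy[k], xx = x + off.dx[k];
        if (yy >= 0 && yy < H && xx >= 0 && xx < W) out[xx * H + yy] = 1;
      }
    }
}

void erode_mask(const std::vector<uint8_t>& in, std::vector<uint8_t>& out,
                int H, int W, const DiskOffsets& off) {
  // out-of-image counts as foreground (so border blobs survive closing)
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      uint8_t keep = 1;
      for (size_t k = 0; k < off.dy.size(); ++k) {
        int yy = y + off.dy[k], xx = x + off.dx[k];
        if (yy >= 0 && yy < H && xx >= 0 && xx < W && !in[xx * H + yy]) {
          keep = 0; break;
        }
      }
      out[x * H + y] = keep;
    }
}

// 8-connected labeling, raster scan in column-major order (labels from 1).
int label8(const std::vector<uint8_t>& mask, std::vector<int>& lab,
           int H, int W) {
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      int p = x * H + y;
      if (!mask[p] || lab[p]) continue;
      ++next;
      lab[p] = next;
      stack.push_back(p);
      while (!stack.empty()) {
        int q = stack.back(); stack.pop_back();
        int qy = q % H, qx = q / H;
        for (int ddx = -1; ddx <= 1; ++ddx)
          for (int ddy = -1; ddy <= 1; ++ddy) {
            if (!ddx && !ddy) continue;
            int yy = qy + ddy, xx = qx + ddx;
            if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
            int r = xx * H + yy;
            if (mask[r] && !lab[r]) { lab[r] = next; stack.push_back(r); }
          }
      }
    }
  return next;
}

// forward sliding window minimum over [i, min(n-1, i+window)], P x n
void forward_window_min(const double* f, double* out, int P, int n, int window) {
  int L = window + 1;
  std::vector<double> pref((size_t)P * n), suff((size_t)P * n);
  for (int i = n - 1; i >= 0; --i) {
    const double* fi = f + (size_t)P * i;
    double* s = suff.data() + (size_t)P * i;
    if (i == n - 1 || (i + 1) % L == 0) std::memcpy(s, fi, sizeof(double) * P);
    else {
      const double* nx = s + P;
      for (int p = 0; p < P; ++p) s[p] = fi[p] < nx[p] ? fi[p] : nx[p];
    }
  }
  for (int i = 0; i < n; ++i) {
    const double* fi = f + (size_t)P * i;
    double* q = pref.data() + (size_t)P * i;
    if (i % L == 0) std::memcpy(q, fi, sizeof(double) * P);
    else {
      const double* pv = q - P;
      for (int p = 0; p < P; ++p) q[p] = fi[p] < pv[p] ? fi[p] : pv[p];
    }
  }
  for (int i = 0; i < n; ++i) {
    int j = std::min(i + window, n - 1);
    const double* a = suff.data() + (size_t)P * i;
    double* o = out + (size_t)P * i;
    if (i / L == j / L) std::memcpy(o, a, sizeof(double) * P);
    else {
      const double* b = pref.data() + (size_t)P * j;
      for (int p = 0; p < P; ++p) o[p] = a[p] < b[p] ? a[p] : b[p];
    }
  }
}

double lower_median_of(std::vector<double>& v) {
  size_t k = (v.size() + 1) / 2 - 1;  // 0-based index of the lower median
  std::nth_element(v.begin(), v.begin() + k, v.end());
  return v[k];
}

} // namespace

// Runs the detector stage loop over `frames` (H*W x n, column = frame).
// Returns per-frame candidate blobs (1-based column-major pixel indices,
// peak difference intensity and its row-major-first argmax pixel) and,
// when keep_intermediates, every per-frame intermediate.
// [[Rcpp::export]]
List cpp_run_stage(NumericMatrix frames, int H, int W,
                   LogicalMatrix floor_mask,
                   double dT_threshold, double mouse_threshold,
                   int mouse_dilate_radius, int close_radius,
                   int min_blob_px, int max_blob_px,
                   double cooldown_min_C, double cooldown_frac,
                   int bg_init_frames, int lag_lo, int lag_hi,
                   int horizon_frames,
                   bool keep_intermediates) {
  int P = H * W, n = frames.ncol();
  if (n < bg_init_frames) stop("Video shorter than the background init window.");
  const double* F = REAL(frames);

  std::vector<uint8_t> floorv(P);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) floorv[x * H + y] = floor_mask(y, x) ? 1 : 0;

  // B0 = per-pixel min of the first bg_init_frames frames
  std::vector<double> B0(F, F + P);
  for (int i = 1; i < bg_init_frames; ++i) {
    const double* fi = F + (size_t)P * i;
    for (int p = 0; p < P; ++p) if (fi[p] < B0[p]) B0[p] = fi[p];
  }

  std::vector<double> fmin((size_t)P * n);
  forward_window_min(F, fmin.data(), P, n, horizon_frames);

  int buf_len = lag_hi + 1;
  std::vector<std::vector<double>> Nbuf(buf_len, std::vector<double>(P));
  std::vector<uint8_t> M(P, 0), Mprev(P, 0), warm(P), dil(P), adj(P);
  std::vector<double> Bprev(B0), B(P), D(P), CD(P);
  std::vector<uint8_t> BM(P), closedm(P);
  std::vector<int> lab(P);
  DiskOffsets d_mouse(mouse_dilate_radius), d_close(close_radius);
  DiskOffsets d_adj(1);
  std::vector<double> medbuf; medbuf.reserve(P);

  List cand_frames;  // list of candidate records
  NumericMatrix kM, kN, kB, kD, kCD, kBM;
  NumericVector kT;
  if (keep_intermediates) {
    kM = NumericMatrix(P, n); kN = NumericMatrix(P, n); kB = NumericMatrix(P, n);
    kD = NumericMatrix(P, n); kCD = NumericMatrix(P, n); kBM = NumericMatrix(P, n);
    kT = NumericVector(n);
  }

  for (int i = 0; i < n; ++i) {
    const double* fi = F + (size_t)P * i;

    // mouse mask: dilate((F - Bprev) > mouse_threshold), component with
    // maximal floor overlap (ties to the smallest label)
    for (int p = 0; p < P; ++p) warm[p] = (fi[p] - Bprev[p]) > mouse_threshold;
    dilate_mask(warm, dil, H, W, d_mouse);
    int ncomp = label8(dil, lab, H, W);
    std::fill(M.begin(), M.end(), 0);
    if (ncomp > 0) {
      std::vector<int> overlap(ncomp + 1, 0);
      for (int p = 0; p < P; ++p) if (lab[p] && floorv[p]) ++overlap[lab[p]];
      int best = 1;
      for (int c = 2; c <= ncomp; ++c) if (overlap[c] > overlap[best]) best = c;
      for (int p = 0; p < P; ++p) M[p] = lab[p] == best;
    }

    // inpainted frame
    const std::vector<double>& Nprev =
      (i == 0) ? B0 : Nbuf[(i - 1) % buf_len];
    std::vector<double>& Ni = Nbuf[i % buf_len];
    // careful: Ni may alias a slot still needed for B below only if
    // buf_len <= lag_hi, which it is not (buf_len = lag_hi + 1)
    for (int p = 0; p < P; ++p) Ni[p] = M[p] ? Nprev[p] : fi[p];

    // running background: min over inpainted frames at lags lag_lo..lag_hi
    bool first = true;
    for (int lag = lag_lo; lag <= lag_hi; ++lag) {
      int j = i - lag;
      const std::vector<double>& Nj = (j < 0) ? B0 : Nbuf[j % buf_len];
      if (first) { B = Nj; first = false; }
      else for (int p = 0; p < P; ++p) if (Nj[p] < B[p]) B[p] = Nj[p];
    }

    // floor median over eligible pixels
    medbuf.clear();
    for (int p = 0; p < P; ++p)
      if (floorv[p] && !M[p] && !Mprev[p]) medbuf.push_back(B[p]);
    if (medbuf.empty()) stop("No eligible floor pixels for the floor median.");
    double T = lower_median_of(medbuf);

    const double* fm = fmin.data() + (size_t)P * i;
    bool any_bm = false;
    for (int p = 0; p < P; ++p) {
      double b = B[p] > T ? B[p] : T;
      D[p] = fi[p] - b;
      CD[p] = fi[p] - fm[p];
      BM[p] = (D[p] > dT_threshold) && !M[p] && !Mprev[p] &&
              (CD[p] > cooldown_min_C) && (CD[p] > cooldown_frac * D[p]);
      if (BM[p]) any_bm = true;
    }

    if (any_bm) {
      dilate_mask(BM, dil, H, W, d_close);
      erode_mask(dil, closedm, H, W, d_close);
      int nb = label8(closedm, lab, H, W);
      if (nb > 0) {
        std::vector<uint8_t> mm(P);
        for (int p = 0; p < P; ++p) mm[p] = M[p] || Mprev[p];
        dilate_mask(mm, adj, H, W, d_adj);
        std::vector<std::vector<int>> comp(nb);
        for (int p = 0; p < P; ++p) if (lab[p]) comp[lab[p] - 1].push_back(p);
        for (int c = 0; c < nb; ++c) {
          const std::vector<int>& px = comp[c];
          int sz = (int)px.size();
          if (sz < min_blob_px || sz > max_blob_px) continue;
          bool bad = false;
          for (int p : px) if (!floorv[p] || adj[p]) { bad = true; break; }
          if (bad) continue;
          // peak difference intensity; row-major-first argmax
          double peak = D[px[0]]; int rep = px[0];
          for (int p : px) {
            if (D[p] > peak) { peak = D[p]; rep = p; }
            else if (D[p] == peak) {
              int py = p % H, pxx = p / H, ry = rep % H, rx = rep / H;
              if (py < ry || (py == ry && pxx < rx)) rep = p;
            }
          }
          IntegerVector pxv(px.size());
          for (size_t k = 0; k < px.size(); ++k) pxv[k] = px[k] + 1;
          cand_frames.push_back(List::create(
            _["frame"] = i, _["px"] = pxv, _["peak"] = peak,
            _["rep_px"] = rep + 1));
        }
      }
    }

    if (keep_intermediates) {
      double* c;
      c = &kM(0, i); for (int p = 0; p < P; ++p) c[p] = M[p];
      c = &kN(0, i); std::memcpy(c, Ni.data(), sizeof(double) * P);
      c = &kB(0, i); std::memcpy(c, B.data(), sizeof(double) * P);
      c = &kD(0, i); std::memcpy(c, D.data(), sizeof(double) * P);
      c = &kCD(0, i); std::memcpy(c, CD.data(), sizeof(double) * P);
      c = &kBM(0, i); for (int p = 0; p < P; ++p) c[p] = BM[p];
      kT[i] = T;
    }

    Mprev = M;
    Bprev = B;
  }

  List out = List::create(_["candidates"] = cand_frames);
  if (keep_intermediates) {
    out["M"] = kM; out["N"] = kN; out["B"] = kB; out["T_floor"] = kT;
    out["D"] = kD; out["CD"] = kCD; out["BM"] = kBM;
  }
  return out;
}
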