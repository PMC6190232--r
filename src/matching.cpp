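#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Patch geometry convention: a rectangle centred at (u, v) (row, col, 1-based
// from R) spans rows u-H .. u+H and cols v-W .. v+W, i.e. width 2W+1 and
// height 2H+1. Callers guarantee the rectangle lies inside the frame.

static inline double patch_sum(const NumericMatrix &f, int u0, int v0,
                               int W, int H) {
  double s = 0.0;
  for (int n = -W; n <= W; ++n)
    for (int m = -H; m <= H; ++m)
      s += f(u0 + m, v0 + n);
  return s;
}

// [[Rcpp::export(name = ".patch_mean_cpp")]]
double patch_mean_cpp(const NumericMatrix &f, int u, int v, int W, int H) {
  const int u0 = u - 1, v0 = v - 1;
  return patch_sum(f, u0, v0, W, H) / ((2.0 * W + 1.0) * (2.0 * H + 1.0));
}

// Normalized correlation coefficient between the patch of fi centred at
// (ui, vi) and the patch of fj centred at (uj, vj). Zero-variance operands
// yield 0 by definition (a blank patch carries no orientation information).
// [[Rcpp::export(name = ".ncc_cpp")]]
double ncc_cpp(const NumericMatrix &fi, int ui, int vi,
               const NumericMatrix &fj, int uj, int vj, int W, int H) {
  const int ui0 = ui - 1, vi0 = vi - 1, uj0 = uj - 1, vj0 = vj - 1;
  const double npx = (2.0 * W + 1.0) * (2.0 * H + 1.0);
  const double mi = patch_sum(fi, ui0, vi0, W, H) / npx;
  const double mj = patch_sum(fj, uj0, vj0, W, H) / npx;
  double sii = 0.0, sjj = 0.0, sij = 0.0;
  for (int n = -W; n <= W; ++n) {
    for (int m = -H; m <= H; ++m) {
      const double di = fi(ui0 + m, vi0 + n) - mi;
      const double dj = fj(uj0 + m, vj0 + n) - mj;
      sii += di * di;
      sjj += dj * dj;
      sij += di * dj;
    }
  }
  if (sii <= 0.0 || sjj <= 0.0) return 0.0;
  return sij / std::sqrt(sii * sjj);
}

// Exhaustive correlation search: evaluates the NCC against a fixed template
// patch at every candidate centre (u, v) with u in [u_lo, u_hi], v in
// [v_lo, v_hi] (1-based, already clipped so every rectangle fits), returning
// the first maximiser in raster-scan order (rows outer, cols inner) and its
// coefficient. Patch means and variances come from summed-area tables, so
// the per-candidate cost is the cross term alone. Returns c(u, v, C).
// [[Rcpp::export(name = ".best_match_cpp")]]
NumericVector best_match_cpp(const NumericMatrix &frame,
                             const NumericMatrix &tframe, int tu, int tv,
                             int W, int H, int u_lo, int u_hi, int v_lo,
                             int v_hi) {
  const int tu0 = tu - 1, tv0 = tv - 1;
  const int tw = 2 * W + 1, th = 2 * H + 1;
  const double npx = static_cast<double>(tw) * th;
  const double tmean = patch_sum(tframe, tu0, tv0, W, H) / npx;
  // centre the template once
  std::vector<double> tc(static_cast<size_t>(tw) * th);
  double stt = 0.0, sum_tc = 0.0;
  {
    size_t k = 0;
    for (int n = -W; n <= W; ++n)
      for (int m = -H; m <= H; ++m, ++k) {
        const double d = tframe(tu0 + m, tv0 + n) - tmean;
        tc[k] = d;
        stt += d * d;
        sum_tc += d;
      }
  }
  // summed-area tables of frame and frame^2, with a zero top row/left col
  const int nr = frame.nrow(), nc = frame.ncol();
  const double *fp = REAL(frame);
  const int snr = nr + 1;
  std::vector<double> S1(static_cast<size_t>(snr) * (nc + 1), 0.0);
  std::vector<double> S2(static_cast<size_t>(snr) * (nc + 1), 0.0);
  for (int c = 0; c < nc; ++c) {
    const double *col = fp + static_cast<size_t>(c) * nr;
    double acc1 = 0.0, acc2 = 0.0;
    const size_t off = static_cast<size_t>(c + 1) * snr;
    const size_t offp = static_cast<size_t>(c) * snr;
    for (int r = 0; r < nr; ++r) {
      acc1 += col[r];
      acc2 += col[r] * col[r];
      S1[off + r + 1] = S1[offp + r + 1] + acc1;
      S2[off + r + 1] = S2[offp + r + 1] + acc2;
    }
  }
  const double var_eps = 1e-7;  // treat tinier patch variances as blank
  double best_c = -2.0;
  int best_u = u_lo, best_v = v_lo;
  for (int u = u_lo; u <= u_hi; ++u) {
    const int r0 = u - 1 - H, r1 = u + H;  // SAT row bounds [r0, r1)
    for (int v = v_lo; v <= v_hi; ++v) {
      const int c0 = v - 1 - W, c1 = v + W;
      const size_t a = static_cast<size_t>(c0) * snr,
                   b = static_cast<size_t>(c1) * snr;
      const double psum = S1[b + r1] - S1[b + r0] - S1[a + r1] + S1[a + r0];
      const double psq = S2[b + r1] - S2[b + r0] - S2[a + r1] + S2[a + r0];
      const double pmean = psum / npx;
      const double spp = psq - psum * pmean;
      // cross term: sum tc * (p - pmean) = sum tc*p - pmean * sum tc
      double spt = 0.0;
      size_t k = 0;
      for (int c = c0; c <= c1 - 1; ++c) {
        const double *col = fp + static_cast<size_t>(c) * nr + r0;
        for (int r = 0; r < th; ++r, ++k) spt += col[r] * tc[k];
      }
      spt -= pmean * sum_tc;
      double cval;
      if (stt <= var_eps || spp <= var_eps)
        cval = 0.0;
      else
        cval = spt / std::sqrt(stt * spp);
      if (cval > best_c) {
        best_c = cval;
        best_u = u;
        best_v = v;
      }
    }
  }
  return NumericVector::create(static_cast<double>(best_u),
                               static_cast<double>(best_v), best_c);
}

// 8-connected component labelling. Components are numbered 1, 2, ... in the
// raster-scan order (row by row) of their first-encountered pixel, so the
// "smallest label" tie-break used by the tracker is deterministic.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(const LogicalMatrix &mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        const int cr = q.front().first, cc = q.front().second;
        q.pop();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            const int rr = cr + dr, c2 = cc + dc;
            if (rr < 0 || rr >= nr || c2 < 0 || c2 >= nc) continue;
            if (mask(rr, c2) && lab(rr, c2) == 0) {
              lab(rr, c2) = next;
              q.push(std::make_pair(rr, c2));
            }
          }
        }
      }
    }
  }
  return lab;
}
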