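#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Stauffer-Grimson adaptive mixture background model, run online over a
// frame sequence. Each pixel keeps k weighted Gaussians over intensity,
// stored in decreasing order of reliability w/sd; a pixel is foreground
// when the component explaining it is not among the leading components
// whose cumulative weight reaches background_ratio (or when no component
// explains it). The ranking is maintained incrementally: uniform weight
// decay does not change the order, so only the updated (or replaced)
// component is bubbled to its place.
//
// frames: list of numeric matrices, identical dims, any intensity scale.
// Returns a list of integer 0/1 masks, one per frame (the first frame
// seeds the model and yields an all-zero mask).
// [[Rcpp::export(name = ".mog_masks")]]
List mog_masks(List frames, int k, double var_threshold, double history,
               double background_ratio, double init_var, double min_var,
               double max_var) {
  int T = frames.size();
  if (T == 0) return List(0);
  NumericMatrix f0 = frames[0];
  int nr = f0.nrow(), nc = f0.ncol(), np = nr * nc;

  // interleaved per-pixel storage: [w0..wk-1, mu0.., var0.., fit0..]
  int stride = 4 * k;
  std::vector<double> st(np * stride);
  for (int p = 0; p < np; ++p) {
    double *s = &st[p * stride];
    s[0] = 1.0;                       // w
    s[k] = f0[p];                     // mu
    for (int i = 0; i < k; ++i) s[2 * k + i] = init_var;
    s[3 * k] = 1.0 / std::sqrt(init_var);  // fit of comp 0; rest 0
  }

  List out(T);
  IntegerMatrix m0(nr, nc);
  out[0] = m0;

  for (int t = 1; t < T; ++t) {
    NumericMatrix fr = frames[t];
    if (fr.nrow() != nr || fr.ncol() != nc)
      stop("frame %d has different dimensions than frame 1", t + 1);
    double alpha = 1.0 / std::min((double)(t + 1), history);
    double decay = 1.0 - alpha;
    IntegerMatrix mask(nr, nc);
    int *mp_out = INTEGER(mask);
    const double *xp = REAL(fr);

    for (int p = 0; p < np; ++p) {
      double x = xp[p];
      double *w = &st[p * stride];
      double *mu = w + k, *var = w + 2 * k, *fit = w + 3 * k;

      // match: components are kept sorted by fitness, scan in order
      int match = -1;
      for (int i = 0; i < k; ++i) {
        if (w[i] <= 0) break;
        double d = x - mu[i];
        if (d * d < var_threshold * var[i]) { match = i; break; }
      }

      if (match >= 0) {
        // foreground test before update: cumulative weight of components
        // ranked above (and including) the matched one
        double cum = 0.0;
        bool fg = false;
        for (int i = 0; i < match; ++i) cum += w[i];
        if (cum > background_ratio) fg = true;
        mp_out[p] = fg ? 1 : 0;

        for (int i = 0; i < k; ++i) { w[i] *= decay; fit[i] *= decay; }
        w[match] += alpha;
        double rho = alpha / w[match];
        if (rho > 1.0) rho = 1.0;
        double d = x - mu[match];
        mu[match] += rho * d;
        var[match] += rho * (d * d - var[match]);
        if (var[match] < min_var) var[match] = min_var;
        if (var[match] > max_var) var[match] = max_var;
        fit[match] = w[match] / std::sqrt(var[match]);
        // bubble the updated component toward the front
        int i = match;
        while (i > 0 && fit[i] > fit[i - 1]) {
          std::swap(w[i], w[i - 1]); std::swap(mu[i], mu[i - 1]);
          std::swap(var[i], var[i - 1]); std::swap(fit[i], fit[i - 1]);
          --i;
        }
      } else {
        // replace the weakest (last) component with one centred on x
        mp_out[p] = 1;
        int last = k - 1;
        w[last] = alpha;
        mu[last] = x;
        var[last] = init_var;
        double s = 0.0;
        for (int i = 0; i < k; ++i) s += w[i];
        for (int i = 0; i < k; ++i) w[i] /= s;
        for (int i = 0; i < k; ++i)
          fit[i] = w[i] > 0 ? w[i] / std::sqrt(var[i]) : 0.0;
        int i = last;
        while (i > 0 && fit[i] > fit[i - 1]) {
          std::swap(w[i], w[i - 1]); std::swap(mu[i], mu[i - 1]);
          std::swap(var[i], var[i - 1]); std::swap(fit[i], fit[i - 1]);
          --i;
        }
      }
    }
    out[t] = mask;
  }
  return out;
}

// Connected-component labelling of a binary mask with 4- or 8-connectivity.
// Returns the label matrix plus per-component pixel counts and bounding
// boxes (0-based pixel coordinates, x = column, y = row).
// [[Rcpp::export(name = ".label_components")]]
List label_components(IntegerMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> count, rmin, rmax, cmin, cmax;
  std::vector<int> stack;
  stack.reserve(256);

  int next = 0;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (mask(r0, c0) == 0 || lab(r0, c0) != 0) continue;
      ++next;
      count.push_back(0);
      rmin.push_back(r0); rmax.push_back(r0);
      cmin.push_back(c0); cmax.push_back(c0);
      stack.clear();
      stack.push_back(r0 * nc + c0);
      lab(r0, c0) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int r = idx / nc, c = idx % nc;
        int gi = next - 1;
        ++count[gi];
        if (r < rmin[gi]) rmin[gi] = r;
        if (r > rmax[gi]) rmax[gi] = r;
        if (c < cmin[gi]) cmin[gi] = c;
        if (c > cmax[gi]) cmax[gi] = c;
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            if (connectivity == 4 && dr != 0 && dc != 0) continue;
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              stack.push_back(rr * nc + cc);
            }
          }
        }
      }
    }
  }

  int n = next;
  IntegerVector lbl(n), cnt(n), xmin(n), xmax(n), ymin(n), ymax(n);
  for (int i = 0; i < n; ++i) {
    lbl[i] = i + 1;
    cnt[i] = count[i];
    xmin[i] = cmin[i];
    xmax[i] = cmax[i];
    ymin[i] = rmin[i];
    ymax[i] = rmax[i];
  }
  return List::create(_["labels"] = lab,
                      _["stats"] = DataFrame::create(
                          _["label"] = lbl, _["count"] = cnt,
                          _["xmin"] = xmin, _["xmax"] = xmax,
                          _["ymin"] = ymin, _["ymax"] = ymax));
}

// Separable zero-padded box count: number of foreground pixels in the
// k x k window around each pixel.
static void box_count(const int *in, int nr, int nc, int r,
                      std::vector<int> &tmp, std::vector<int> &out) {
  // vertical pass (within columns; column-major layout)
  for (int c = 0; c < nc; ++c) {
    const int *col = in + (size_t)c * nr;
    int *tc = tmp.data() + (size_t)c * nr;
    int s = 0;
    for (int i = 0; i <= r && i < nr; ++i) s += col[i] != 0;
    for (int i = 0; i < nr; ++i) {
      tc[i] = s;
      int add = i + r + 1, rem = i - r;
      if (add < nr) s += col[add] != 0;
      if (rem >= 0) s -= col[rem] != 0;
    }
  }
  // horizontal pass (across columns)
  for (int i = 0; i < nr; ++i) {
    int s = 0;
    for (int c = 0; c <= r && c < nc; ++c) s += tmp[(size_t)c * nr + i];
    for (int c = 0; c < nc; ++c) {
      out[(size_t)c * nr + i] = s;
      int add = c + r + 1, rem = c - r;
      if (add < nc) s += tmp[(size_t)add * nr + i];
      if (rem >= 0) s -= tmp[(size_t)rem * nr + i];
    }
  }
}

// Binary k x k majority (median) filter; out-of-image neighbours count as
// background (zero padding).
// [[Rcpp::export(name = ".binary_median")]]
IntegerMatrix binary_median(IntegerMatrix mask, int k) {
  int nr = mask.nrow(), nc = mask.ncol(), r = k / 2;
  int need = (k * k) / 2 + 1;
  std::vector<int> tmp((size_t)nr * nc), cnt((size_t)nr * nc);
  box_count(INTEGER(mask), nr, nc, r, tmp, cnt);
  IntegerMatrix out(nr, nc);
  int *op = INTEGER(out);
  for (size_t p = 0; p < (size_t)nr * nc; ++p) op[p] = cnt[p] >= need;
  return out;
}

// Morphological opening (erosion then dilation) of a binary mask with a
// k x k square structuring element, zero-padded at the image border.
// [[Rcpp::export(name = ".binary_opening")]]
IntegerMatrix binary_opening(IntegerMatrix mask, int k) {
  int nr = mask.nrow(), nc = mask.ncol(), r = k / 2;
  int full = k * k;
  size_t np = (size_t)nr * nc;
  std::vector<int> tmp(np), cnt(np), ero(np);
  box_count(INTEGER(mask), nr, nc, r, tmp, cnt);
  for (size_t p = 0; p < np; ++p) ero[p] = cnt[p] == full;
  box_count(ero.data(), nr, nc, r, tmp, cnt);
  IntegerMatrix out(nr, nc);
  int *op = INTEGER(out);
  for (size_t p = 0; p < np; ++p) op[p] = cnt[p] >= 1;
  return out;
}
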