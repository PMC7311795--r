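// Compiled kernels for the image primitives on the package's hot paths:
// exemplar-based texture synthesis, normalized cross-correlation template
// matching, bilinear crop-resize (single and sliding-window batches) and
// Chebyshev binary dilation. All functions are single-threaded and draw any
// randomness from R's RNG so results are reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exemplar-based texture synthesis (Efros–Leung style).
//
// Fills mask==1 pixels boundary-inward. Each target pixel is assigned the
// center value of the best-SSD matching patch among candidate patches that
// lie entirely in the originally-known region; SSD is computed over the
// window positions currently known (original or already filled). Candidates
// within `tol` relative slack of the minimum SSD are tie-broken by a uniform
// draw from R's RNG.
// [[Rcpp::export(name = ".cpp_tex_inpaint")]]
List cpp_tex_inpaint(NumericMatrix image, IntegerMatrix mask,
                     int patch_radius, int stride, double tol,
                     bool priority) {
  const int H = image.nrow(), W = image.ncol(), r = patch_radius;
  if (stride < 1) stop("search_stride must be >= 1");
  NumericMatrix out(clone(image));
  IntegerMatrix known(H, W);        // 1 = usable as context
  IntegerMatrix orig_known(H, W);   // 1 = outside the original mask
  IntegerMatrix order(H, W);        // synthesis order, 0 = untouched
  long n_fill = 0;
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      bool k = mask(i, j) == 0;
      known(i, j) = k;
      orig_known(i, j) = k;
      if (!k) ++n_fill;
    }
  if (n_fill == 0)
    return List::create(_["image"] = out, _["order"] = order);

  // Candidate patch centers: full window inside the image and fully known
  // in the original image.
  std::vector<int> cand_i, cand_j;
  for (int i = r; i + r < H; i += stride)
    for (int j = r; j + r < W; j += stride) {
      bool ok = true;
      for (int di = -r; di <= r && ok; ++di)
        for (int dj = -r; dj <= r; ++dj)
          if (!orig_known(i + di, j + dj)) { ok = false; break; }
      if (ok) { cand_i.push_back(i); cand_j.push_back(j); }
    }
  const int ncand = (int)cand_i.size();
  if (ncand == 0)
    stop("insufficient context: no fully-known candidate patch exists");

  const int wlen = (2 * r + 1) * (2 * r + 1);
  std::vector<double> wvals(wlen);
  std::vector<int> wdi(wlen), wdj(wlen);
  int fill_counter = 0;
  long remaining = n_fill;

  while (remaining > 0) {
    // Boundary of the unknown region: unknown pixels with a known 8-neighbor.
    std::vector<int> bi, bj, bscore;
    for (int i = 0; i < H; ++i)
      for (int j = 0; j < W; ++j) {
        if (known(i, j)) continue;
        bool touches = false;
        for (int di = -1; di <= 1 && !touches; ++di)
          for (int dj = -1; dj <= 1; ++dj) {
            int ii = i + di, jj = j + dj;
            if (ii < 0 || jj < 0 || ii >= H || jj >= W) continue;
            if (known(ii, jj)) { touches = true; break; }
          }
        if (!touches) continue;
        int score = 0;
        if (priority) {
          for (int di = -r; di <= r; ++di)
            for (int dj = -r; dj <= r; ++dj) {
              int ii = i + di, jj = j + dj;
              if (ii >= 0 && jj >= 0 && ii < H && jj < W && known(ii, jj))
                ++score;
            }
        }
        bi.push_back(i); bj.push_back(j); bscore.push_back(score);
      }
    if (bi.empty())
      stop("insufficient context: unknown region is not reachable");

    std::vector<int> idx(bi.size());
    for (size_t k = 0; k < idx.size(); ++k) idx[k] = (int)k;
    if (priority) {
      std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
        return bscore[a] > bscore[b];
      });
    }

    for (size_t k = 0; k < idx.size(); ++k) {
      int ti = bi[idx[k]], tj = bj[idx[k]];
      if (known(ti, tj)) continue; // may happen only defensively
      // Collect the currently-known window positions around the target.
      int nkw = 0;
      for (int di = -r; di <= r; ++di)
        for (int dj = -r; dj <= r; ++dj) {
          int ii = ti + di, jj = tj + dj;
          if (ii < 0 || jj < 0 || ii >= H || jj >= W) continue;
          if (!known(ii, jj)) continue;
          wvals[nkw] = out(ii, jj);
          wdi[nkw] = di; wdj[nkw] = dj;
          ++nkw;
        }
      double best = R_PosInf;
      std::vector<double> ssd(ncand);
      for (int c = 0; c < ncand; ++c) {
        const int ci = cand_i[c], cj = cand_j[c];
        double s = 0.0;
        for (int m = 0; m < nkw; ++m) {
          double d = image(ci + wdi[m], cj + wdj[m]) - wvals[m];
          s += d * d;
          if (s >= best * (1.0 + tol) + 1e-12) break;
        }
        ssd[c] = s;
        if (s < best) best = s;
      }
      const double cutoff = best * (1.0 + tol) + 1e-12;
      std::vector<int> acc;
      for (int c = 0; c < ncand; ++c)
        if (ssd[c] <= cutoff) acc.push_back(c);
      int pick = acc[(int)std::floor(unif_rand() * acc.size()) % acc.size()];
      out(ti, tj) = image(cand_i[pick], cand_j[pick]);
      known(ti, tj) = 1;
      order(ti, tj) = ++fill_counter;
      --remaining;
    }
  }
  return List::create(_["image"] = out, _["order"] = order);
}

// ---------------------------------------------------------------------------
// Normalized cross-correlation of a template against every fully-overlapping
// image position. Returns a map the size of the image; positions without
// full overlap, or with zero local variance, score 0.
// [[Rcpp::export(name = ".cpp_ncc")]]
NumericMatrix cpp_ncc(NumericMatrix image, NumericMatrix tmpl) {
  const int H = image.nrow(), W = image.ncol();
  const int th = tmpl.nrow(), tw = tmpl.ncol();
  const int rh = th / 2, rw = tw / 2;
  const int n = th * tw;
  double tmean = 0.0;
  for (int i = 0; i < th; ++i)
    for (int j = 0; j < tw; ++j) tmean += tmpl(i, j);
  tmean /= n;
  std::vector<double> tz(n);
  double tss = 0.0;
  int m = 0;
  for (int i = 0; i < th; ++i)
    for (int j = 0; j < tw; ++j) {
      tz[m] = tmpl(i, j) - tmean;
      tss += tz[m] * tz[m];
      ++m;
    }
  NumericMatrix outm(H, W);
  if (tss <= 0) return outm;
  const double tnorm = std::sqrt(tss);
  for (int ci = rh; ci + (th - rh - 1) < H; ++ci)
    for (int cj = rw; cj + (tw - rw - 1) < W; ++cj) {
      double wsum = 0.0;
      m = 0;
      for (int i = 0; i < th; ++i)
        for (int j = 0; j < tw; ++j)
          wsum += image(ci - rh + i, cj - rw + j);
      const double wmean = wsum / n;
      double num = 0.0, wss = 0.0;
      m = 0;
      for (int i = 0; i < th; ++i)
        for (int j = 0; j < tw; ++j) {
          double wz = image(ci - rh + i, cj - rw + j) - wmean;
          num += wz * tz[m];
          wss += wz * wz;
          ++m;
        }
      if (wss <= 1e-12) continue;
      outm(ci, cj) = num / (std::sqrt(wss) * tnorm);
    }
  return outm;
}

static inline double bilinear_at(const NumericMatrix &img, double y, double x) {
  const int H = img.nrow(), W = img.ncol();
  if (y < 0) y = 0; if (x < 0) x = 0;
  if (y > H - 1) y = H - 1; if (x > W - 1) x = W - 1;
  int y0 = (int)std::floor(y), x0 = (int)std::floor(x);
  int y1 = std::min(y0 + 1, H - 1), x1 = std::min(x0 + 1, W - 1);
  double fy = y - y0, fx = x - x0;
  return img(y0, x0) * (1 - fy) * (1 - fx) + img(y0, x1) * (1 - fy) * fx +
         img(y1, x0) * fy * (1 - fx) + img(y1, x1) * fy * fx;
}

// Bilinear crop-resize of half-open boxes (x0, y0, x1, y1) to out_h x out_w.
// Output: one row per box, pixels in column-major (R matrix) order of the
// out_h x out_w crop.
// [[Rcpp::export(name = ".cpp_crop_resize")]]
NumericMatrix cpp_crop_resize(NumericMatrix image, NumericMatrix boxes,
                              int out_h, int out_w) {
  const int nb = boxes.nrow();
  NumericMatrix res(nb, out_h * out_w);
  for (int b = 0; b < nb; ++b) {
    const double x0 = boxes(b, 0), y0 = boxes(b, 1);
    const double bw = boxes(b, 2) - x0, bh = boxes(b, 3) - y0;
    for (int j = 0; j < out_w; ++j)
      for (int i = 0; i < out_h; ++i) {
        // sample at the centers of an out_h x out_w grid over the box
        double sy = y0 + (i + 0.5) * bh / out_h - 0.5;
        double sx = x0 + (j + 0.5) * bw / out_w - 0.5;
        res(b, j * out_h + i) = bilinear_at(image, sy, sx);
      }
  }
  return res;
}

// Binary dilation with a Chebyshev (square) structuring element.
// [[Rcpp::export(name = ".cpp_dilate")]]
IntegerMatrix cpp_dilate(IntegerMatrix mask, int radius) {
  const int H = mask.nrow(), W = mask.ncol();
  if (radius <= 0) return clone(mask);
  IntegerMatrix out(H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      if (!mask(i, j)) continue;
      for (int di = -radius; di <= radius; ++di)
        for (int dj = -radius; dj <= radius; ++dj) {
          int ii = i + di, jj = j + dj;
          if (ii >= 0 && jj >= 0 && ii < H && jj < W) out(ii, jj) = 1;
        }
    }
  return out;
}
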