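// Low-level raster and scale-space kernels. All deterministic; no RNG here.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Reflect index into [0, n-1] (symmetric padding without repeating the edge
// sample twice would be "reflect_101"; here we use simple symmetric reflection
// so that blurring a constant image is exact for any kernel radius).
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable Gaussian blur with a truncated, renormalized kernel and
// reflected borders. `radius` chosen by the caller (ceil(3*sigma) upstream).
// [[Rcpp::export(name = ".blur_gaussian_cpp")]]
arma::mat blur_gaussian_cpp(const arma::mat& img, double sigma, int radius) {
  const int H = img.n_rows, W = img.n_cols;
  if (radius < 1) radius = 1;
  arma::vec k(2 * radius + 1);
  for (int t = -radius; t <= radius; ++t)
    k(t + radius) = std::exp(-(double)(t * t) / (2.0 * sigma * sigma));
  k /= arma::accu(k);

  arma::mat tmp(H, W), out(H, W);
  // vertical pass
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int t = -radius; t <= radius; ++t)
        s += k(t + radius) * img(reflect_idx(i + t, H), j);
      tmp(i, j) = s;
    }
  // horizontal pass
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      double s = 0.0;
      for (int t = -radius; t <= radius; ++t)
        s += k(t + radius) * tmp(i, reflect_idx(j + t, W));
      out(i, j) = s;
    }
  return out;
}

// Strict 26-neighbor extrema scan over a H x W x L DoG stack.
// Returns a 3-column 0-based integer matrix (row, col, level) of voxels that
// are strictly greater than, or strictly smaller than, all 26 neighbors.
// Border voxels (spatial and scale) are excluded.
// [[Rcpp::export(name = ".detect_extrema_cpp")]]
IntegerMatrix detect_extrema_cpp(const arma::cube& dog) {
  const int H = dog.n_rows, W = dog.n_cols, L = dog.n_slices;
  std::vector<int> ri, ci, li;
  for (int l = 1; l < L - 1; ++l)
    for (int j = 1; j < W - 1; ++j)
      for (int i = 1; i < H - 1; ++i) {
        const double v = dog(i, j, l);
        bool is_max = true, is_min = true;
        for (int dl = -1; dl <= 1 && (is_max || is_min); ++dl)
          for (int dj = -1; dj <= 1 && (is_max || is_min); ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0 && dl == 0) continue;
              const double u = dog(i + di, j + dj, l + dl);
              if (u >= v) is_max = false;
              if (u <= v) is_min = false;
              if (!is_max && !is_min) break;
            }
        if (is_max || is_min) { ri.push_back(i); ci.push_back(j); li.push_back(l); }
      }
  IntegerMatrix out(ri.size(), 3);
  for (size_t r = 0; r < ri.size(); ++r) {
    out(r, 0) = ri[r]; out(r, 1) = ci[r]; out(r, 2) = li[r];
  }
  return out;
}

// Rasterize a polyline onto a H x W logical mask using Bresenham segments.
// xs, ys are 0-based pixel coordinates (already mapped by the caller).
// line_width is realized as a square brush of side `lw` whose rows span
// [-floor((lw-1)/2), ceil((lw-1)/2)] so a horizontal 1-px line occupies
// exactly `lw` rows.
// [[Rcpp::export(name = ".draw_polyline_cpp")]]
LogicalMatrix draw_polyline_cpp(int H, int W, IntegerVector xs, IntegerVector ys,
                                int line_width) {
  LogicalMatrix mask(H, W);
  const int lo = -((line_width - 1) / 2);
  const int hi = line_width / 2;
  auto stamp = [&](int x, int y) {
    for (int dy = lo; dy <= hi; ++dy)
      for (int dx = lo; dx <= hi; ++dx) {
        const int xx = x + dx, yy = y + dy;
        if (xx >= 0 && xx < W && yy >= 0 && yy < H) mask(yy, xx) = true;
      }
  };
  const int n = xs.size();
  if (n == 0) return mask;
  stamp(xs[0], ys[0]);
  for (int s = 1; s < n; ++s) {
    int x0 = xs[s - 1], y0 = ys[s - 1], x1 = xs[s], y1 = ys[s];
    int dx = std::abs(x1 - x0), sx = x0 < x1 ? 1 : -1;
    int dy = -std::abs(y1 - y0), sy = y0 < y1 ? 1 : -1;
    int err = dx + dy;
    for (;;) {
      stamp(x0, y0);
      if (x0 == x1 && y0 == y1) break;
      const int e2 = 2 * err;
      if (e2 >= dy) { err += dy; x0 += sx; }
      if (e2 <= dx) { err += dx; y0 += sy; }
    }
  }
  return mask;
}
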