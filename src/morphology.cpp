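// Grayscale erosion/dilation with a disc structuring element.
//
// The disc of radius r is decomposed into vertical runs: for each column
// offset dx in [-r, r] the run has half-height h(dx) = floor(sqrt(r^2-dx^2)).
// Erosion is a vertical sliding-window minimum per distinct half-height
// (monotonic deque, O(n) per column, contiguous in R's column-major
// layout) followed by a pointwise combine over column offsets. Windows
// are clamped at the image border (in-bounds neighborhood), so a constant
// image is a fixed point of both operations.

#include <Rcpp.h>
#include <deque>
#include <cmath>
using namespace Rcpp;

// sliding-window extremum over a contiguous array, window [i-h, i+h]
// clamped to [0, n-1]; sign = +1 for min (erosion), -1 for max (dilation)
static void window_extremum(const double* in, double* out, int n, int h,
                            double sign) {
  std::deque<int> q;
  for (int i = 0; i < n + h; ++i) {
    if (i < n) {
      while (!q.empty() && sign * in[q.back()] >= sign * in[i]) q.pop_back();
      q.push_back(i);
    }
    int pos = i - h;
    if (pos >= 0 && pos < n) {
      while (q.front() < pos - h) q.pop_front();
      out[pos] = in[q.front()];
    }
  }
}

static NumericMatrix disc_morph(const NumericMatrix& img, int radius,
                                bool dilate) {
  const int nr = img.nrow(), nc = img.ncol(), r = radius;
  const double sign = dilate ? -1.0 : 1.0;

  // vertical-run half-heights per |dx| and the distinct set
  std::vector<int> h_of_dx(r + 1);
  std::vector<int> heights;
  for (int dx = 0; dx <= r; ++dx) {
    h_of_dx[dx] = (int)std::floor(std::sqrt((double)r * r - (double)dx * dx));
    heights.push_back(h_of_dx[dx]);
  }
  std::sort(heights.begin(), heights.end());
  heights.erase(std::unique(heights.begin(), heights.end()), heights.end());
  std::vector<int> h_index(r + 1);
  for (int dx = 0; dx <= r; ++dx)
    h_index[dx] = std::lower_bound(heights.begin(), heights.end(),
                                   h_of_dx[dx]) - heights.begin();

  // pass 1: vertical filter per distinct half-height, column-contiguous
  const size_t npx = (size_t)nr * nc;
  const size_t nh = heights.size();
  std::vector<double> H(nh * npx);
  const double* src = img.begin();
  for (size_t k = 0; k < nh; ++k)
    for (int x = 0; x < nc; ++x)
      window_extremum(src + (size_t)x * nr, H.data() + k * npx + (size_t)x * nr,
                      nr, heights[k], sign);

  // pass 2: combine columns x+dx, pointwise over y (contiguous)
  NumericMatrix out(nr, nc);
  double* dst = out.begin();
  for (int x = 0; x < nc; ++x) {
    double* o = dst + (size_t)x * nr;
    const double* c0 = H.data() + (size_t)h_index[0] * npx + (size_t)x * nr;
    std::copy(c0, c0 + nr, o);
    for (int adx = 1; adx <= r; ++adx) {
      const double* base = H.data() + (size_t)h_index[adx] * npx;
      for (int s = -1; s <= 1; s += 2) {
        int xx = x + s * adx;
        if (xx < 0 || xx >= nc) continue;
        const double* c = base + (size_t)xx * nr;
        if (sign > 0) {
          for (int y = 0; y < nr; ++y) if (c[y] < o[y]) o[y] = c[y];
        } else {
          for (int y = 0; y < nr; ++y) if (c[y] > o[y]) o[y] = c[y];
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".gray_erode_disc")]]
NumericMatrix gray_erode_disc(NumericMatrix img, int radius) {
  return disc_morph(img, radius, false);
}

// [[Rcpp::export(name = ".gray_dilate_disc")]]
NumericMatrix gray_dilate_disc(NumericMatrix img, int radius) {
  return disc_morph(img, radius, true);
}
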