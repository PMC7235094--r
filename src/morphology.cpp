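#include <Rcpp.h>
using namespace Rcpp;

// Grayscale erosion/dilation with a non-flat hemispherical ("ball")
// structuring element of the given radius (in pixels). The ball height is
// measured in intensity units numerically equal to pixel units, i.e. the
// classical rolling-ball construction in (x, y, intensity) space.
// Out-of-image offsets are ignored, which makes opening exact on constant
// images up to the border.
// [[Rcpp::export]]
NumericMatrix morph_ball_cpp(const NumericMatrix& img, double radius, bool dilate) {
  const int nr = img.nrow(), nc = img.ncol();
  const int r = (int)std::floor(radius);
  std::vector<int> dr, dc;
  std::vector<double> h;
  for (int i = -r; i <= r; ++i) {
    for (int j = -r; j <= r; ++j) {
      double d2 = (double)i * i + (double)j * j;
      if (d2 <= radius * radius) {
        dr.push_back(i);
        dc.push_back(j);
        h.push_back(std::sqrt(radius * radius - d2) - radius); // <= 0, 0 at centre
      }
    }
  }
  const int m = (int)dr.size();
  NumericMatrix out(nr, nc);
  const double init = dilate ? -std::numeric_limits<double>::infinity()
                             : std::numeric_limits<double>::infinity();
  std::fill(out.begin(), out.end(), init);
  // one contiguous sweep per structuring-element offset
  for (int k = 0; k < m; ++k) {
    const int di = dr[k], dj = dc[k];
    const double hk = h[k];
    const int c0 = std::max(0, -dj), c1 = std::min(nc, nc - dj);
    const int r0 = std::max(0, -di), r1 = std::min(nr, nr - di);
    for (int c = c0; c < c1; ++c) {
      const double* src = &img(0, c + dj);
      double* dst = &out(0, c);
      if (dilate) {
        for (int r = r0; r < r1; ++r) {
          double v = src[r + di] + hk;
          if (v > dst[r]) dst[r] = v;
        }
      } else {
        for (int r = r0; r < r1; ++r) {
          double v = src[r + di] - hk;
          if (v < dst[r]) dst[r] = v;
        }
      }
    }
  }
  return out;
}

// 8-connected component labelling of a logical mask. Labels are dense
// 1..N and assigned in raster scan order (top-to-bottom, left-to-right),
// matching the ordering convention of standard particle analysis.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc); // zero-initialised
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int rI = 0; rI < nr; ++rI) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(rI, c) || lab(rI, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(rI, c));
      lab(rI, c) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int di = -1; di <= 1; ++di) {
          for (int dj = -1; dj <= 1; ++dj) {
            if (di == 0 && dj == 0) continue;
            int rr = p.first + di, cc = p.second + dj;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              stack.push_back(std::make_pair(rr, cc));
            }
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}
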