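#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Neighbor offsets: first 4 are the 4-connected set, all 8 the 8-connected.
static const int DR[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
static const int DC[8] = {0, 0, -1, 1, -1, 1, -1, 1};

// Seeded region growing by breadth-first expansion from (seed_r, seed_c),
// both 1-based. A frontier pixel is tested once, on first encounter, against
// the current reference mean mu: accepted iff |I(p) - mu| <= tol. With
// running_mean = true, mu is the mean intensity of the region accepted so
// far (initialized to ref before the seed is absorbed); otherwise mu stays
// at ref. Pixels where allowed == 0 are never accepted. Growth stops when
// the frontier empties or the region reaches max_pixels.
// [[Rcpp::export]]
LogicalMatrix region_grow_cpp(NumericMatrix img, int seed_r, int seed_c,
                              double ref, double tol, int connectivity,
                              bool running_mean, int max_pixels,
                              LogicalMatrix allowed) {
  int nr = img.nrow(), nc = img.ncol();
  LogicalMatrix out(nr, nc);
  std::vector<char> visited((size_t)nr * nc, 0);
  int r0 = seed_r - 1, c0 = seed_c - 1;
  if (r0 < 0 || r0 >= nr || c0 < 0 || c0 >= nc)
    stop("seed position outside image");
  if (!allowed(r0, c0)) return out;  // seed on an excluded pixel: empty region

  int nnb = (connectivity == 4) ? 4 : 8;
  std::queue<int> q;
  double mu = ref, sum = 0.0;
  long n = 0;

  // absorb the seed unconditionally
  visited[(size_t)r0 * nc + c0] = 1;
  out(r0, c0) = true;
  sum += img(r0, c0); n += 1;
  if (running_mean) mu = sum / n;
  q.push(r0 * nc + c0);

  while (!q.empty() && n < max_pixels) {
    int cur = q.front(); q.pop();
    int r = cur / nc, c = cur % nc;
    for (int k = 0; k < nnb; ++k) {
      int rr = r + DR[k], cc = c + DC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      size_t idx = (size_t)rr * nc + cc;
      if (visited[idx]) continue;
      visited[idx] = 1;
      if (!allowed(rr, cc)) continue;
      double v = img(rr, cc);
      if (std::abs(v - mu) <= tol) {
        out(rr, cc) = true;
        sum += v; n += 1;
        if (running_mean) mu = sum / n;
        q.push(rr * nc + cc);
        if (n >= max_pixels) break;
      }
    }
  }
  return out;
}

// Connected-component labeling of a binary mask (1-based labels in
// first-encounter row-major order), 4- or 8-connectivity.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int nnb = (connectivity == 4) ? 4 : 8;
  int next = 0;
  std::queue<int> q;
  // row-major scan over (row, col): iterate rows outer so equal-size ties
  // downstream resolve by row-major first pixel
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      q.push(r * nc + c);
      while (!q.empty()) {
        int cur = q.front(); q.pop();
        int cr = cur / nc, ccol = cur % nc;
        for (int k = 0; k < nnb; ++k) {
          int rr = cr + DR[k], cc = ccol + DC[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            q.push(rr * nc + cc);
          }
        }
      }
    }
  }
  return lab;
}

// Fill holes: background regions (4-connectivity) not reachable from the
// image border become foreground. Foreground never shrinks.
// [[Rcpp::export]]
LogicalMatrix fill_holes_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> reach((size_t)nr * nc, 0);
  std::queue<int> q;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if ((r == 0 || r == nr - 1 || c == 0 || c == nc - 1) && !mask(r, c) &&
          !reach[(size_t)r * nc + c]) {
        reach[(size_t)r * nc + c] = 1;
        q.push(r * nc + c);
        while (!q.empty()) {
          int cur = q.front(); q.pop();
          int cr = cur / nc, ccol = cur % nc;
          for (int k = 0; k < 4; ++k) {
            int rr = cr + DR[k], cc = ccol + DC[k];
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            size_t idx = (size_t)rr * nc + cc;
            if (!mask(rr, cc) && !reach[idx]) {
              reach[idx] = 1;
              q.push(rr * nc + cc);
            }
          }
        }
      }
  LogicalMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      out(r, c) = mask(r, c) || !reach[(size_t)r * nc + c];
  return out;
}
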