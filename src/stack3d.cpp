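#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Shared rigid-rotation convention (must stay in sync with the R helpers):
// pixel coordinates are 0-based, x = column (rightward), y = row (downward);
// rotating the tissue by theta (degrees, +x toward +y) means the output pixel
// p takes the input pixel at R(-theta) * (p - c) + c, nearest neighbour,
// with out-of-frame sources exactly black so the "tissue <=> not (0,0,0)"
// predicate survives resampling.

// Difference metric d(theta) between a rotated luminance image and a fixed
// reference, evaluated over a grid of angles. metric: 0 = L1, 1 = SSD.
// [[Rcpp::export]]
NumericVector cpp_rotation_curve(IntegerMatrix lum, IntegerMatrix ref,
                                 NumericVector angles_deg,
                                 double cx, double cy, int metric) {
  const int H = lum.nrow(), W = lum.ncol();
  if (ref.nrow() != H || ref.ncol() != W)
    stop("image and reference dimensions differ");
  const int na = angles_deg.size();
  NumericVector d(na);
  for (int a = 0; a < na; ++a) {
    const double th = angles_deg[a] * M_PI / 180.0;
    const double ct = std::cos(th), st = std::sin(th);
    double acc = 0.0;
    for (int y = 0; y < H; ++y) {
      const double dy = y - cy;
      for (int x = 0; x < W; ++x) {
        const double dx = x - cx;
        const double sx = ct * dx + st * dy + cx;
        const double sy = -st * dx + ct * dy + cy;
        const int xi = (int)std::lround(sx);
        const int yi = (int)std::lround(sy);
        int v = 0;
        if (xi >= 0 && xi < W && yi >= 0 && yi < H) v = lum(yi, xi);
        const double diff = (double)v - (double)ref(y, x);
        acc += (metric == 1) ? diff * diff : std::fabs(diff);
      }
    }
    d[a] = acc;
  }
  return d;
}

// Nearest-neighbour rotation of an H x W x 3 integer raster (same mapping as
// cpp_rotation_curve). theta == 0 returns an identical copy.
// [[Rcpp::export]]
IntegerVector cpp_rotate_raster(IntegerVector raster, double theta_deg,
                                double cx, double cy) {
  IntegerVector dims = raster.attr("dim");
  if (dims.size() != 3 || dims[2] != 3) stop("raster must be H x W x 3");
  const int H = dims[0], W = dims[1];
  IntegerVector out(raster.size(), 0);
  out.attr("dim") = dims;
  if (theta_deg == 0.0) {
    std::copy(raster.begin(), raster.end(), out.begin());
    return out;
  }
  const double th = theta_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const int plane = H * W;
  for (int y = 0; y < H; ++y) {
    const double dy = y - cy;
    for (int x = 0; x < W; ++x) {
      const double dx = x - cx;
      const double sx = ct * dx + st * dy + cx;
      const double sy = -st * dx + ct * dy + cy;
      const int xi = (int)std::lround(sx);
      const int yi = (int)std::lround(sy);
      if (xi >= 0 && xi < W && yi >= 0 && yi < H) {
        const int src = yi + xi * H, dst = y + x * H;
        out[dst] = raster[src];
        out[dst + plane] = raster[src + plane];
        out[dst + 2 * plane] = raster[src + 2 * plane];
      }
    }
  }
  return out;
}

// Flood fill over `open` cells (4-neighbourhood) seeded from every frame
// border cell; returns the reachability mask. Used to separate exterior
// background from enclosed cavities, one z-slab at a time.
// [[Rcpp::export]]
LogicalMatrix cpp_flood_from_border(LogicalMatrix open) {
  const int H = open.nrow(), W = open.ncol();
  LogicalMatrix reach(H, W);
  std::vector<int> stack;
  stack.reserve((size_t)H * W / 4 + 16);
  auto push = [&](int y, int x) {
    if (open(y, x) && !reach(y, x)) {
      reach(y, x) = true;
      stack.push_back(y + x * H);
    }
  };
  for (int x = 0; x < W; ++x) { push(0, x); push(H - 1, x); }
  for (int y = 0; y < H; ++y) { push(y, 0); push(y, W - 1); }
  while (!stack.empty()) {
    const int cell = stack.back();
    stack.pop_back();
    const int y = cell % H, x = cell / H;
    if (y > 0) push(y - 1, x);
    if (y < H - 1) push(y + 1, x);
    if (x > 0) push(y, x - 1);
    if (x < W - 1) push(y, x + 1);
  }
  return reach;
}
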