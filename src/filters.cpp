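#include <Rcpp.h>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// Reflective ("symmetric") border index: mirror including the edge pixel.
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Rank filter over a disk footprint of the given radius (offsets with
// dr^2 + dc^2 <= radius^2). type: 0 = median, 1 = min (erosion),
// 2 = max (dilation). Borders are handled by reflection.
// [[Rcpp::export]]
NumericMatrix disk_rank_filter(NumericMatrix img, int radius, int type) {
  int H = img.nrow(), W = img.ncol();
  std::vector<int> dr, dc;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= radius * radius) { dr.push_back(a); dc.push_back(b); }
  int m = (int) dr.size();
  NumericMatrix out(H, W);
  std::vector<double> buf(m);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (type == 0) {
        for (int k = 0; k < m; ++k)
          buf[k] = img(reflect_idx(i + dr[k], H), reflect_idx(j + dc[k], W));
        int mid = m / 2;
        std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
        double v = buf[mid];
        if (m % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + mid);
          v = 0.5 * (v + lo);
        }
        out(i, j) = v;
      } else if (type == 1) {
        double v = R_PosInf;
        for (int k = 0; k < m; ++k) {
          double x = img(reflect_idx(i + dr[k], H), reflect_idx(j + dc[k], W));
          if (x < v) v = x;
        }
        out(i, j) = v;
      } else {
        double v = R_NegInf;
        for (int k = 0; k < m; ++k) {
          double x = img(reflect_idx(i + dr[k], H), reflect_idx(j + dc[k], W));
          if (x > v) v = x;
        }
        out(i, j) = v;
      }
    }
  }
  return out;
}

// Grayscale morphological reconstruction by dilation, 8-connectivity:
// repeated geodesic dilation of `marker` under `mask` to stability.
// Hybrid raster/anti-raster sweep followed by FIFO propagation
// (Vincent's algorithm); exact fixed point of
// marker <- pmin(dilate3x3(marker), mask).
// [[Rcpp::export]]
NumericMatrix reconstruct_dilation(NumericMatrix marker, NumericMatrix mask) {
  int H = marker.nrow(), W = marker.ncol();
  if (mask.nrow() != H || mask.ncol() != W)
    stop("marker and mask dimensions differ");
  NumericMatrix J(clone(marker));
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (J(i, j) > mask(i, j)) stop("marker must be <= mask everywhere");

  // raster scan: neighbours already visited (N+)
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double v = J(i, j);
      if (i > 0)          v = std::max(v, J(i - 1, j));
      if (j > 0)          v = std::max(v, J(i, j - 1));
      if (i > 0 && j > 0) v = std::max(v, J(i - 1, j - 1));
      if (i < H - 1 && j > 0) v = std::max(v, J(i + 1, j - 1));
      J(i, j) = std::min(v, mask(i, j));
    }
  }
  // anti-raster scan (N-), queueing boundary pixels
  std::queue<std::pair<int, int> > q;
  for (int j = W - 1; j >= 0; --j) {
    for (int i = H - 1; i >= 0; --i) {
      double v = J(i, j);
      if (i < H - 1)              v = std::max(v, J(i + 1, j));
      if (j < W - 1)              v = std::max(v, J(i, j + 1));
      if (i < H - 1 && j < W - 1) v = std::max(v, J(i + 1, j + 1));
      if (i > 0 && j < W - 1)     v = std::max(v, J(i - 1, j + 1));
      J(i, j) = std::min(v, mask(i, j));
      // queue if some N- neighbour could still grow
      double c = J(i, j);
      bool push = false;
      if (i < H - 1 && J(i + 1, j) < c && J(i + 1, j) < mask(i + 1, j)) push = true;
      if (!push && j < W - 1 && J(i, j + 1) < c && J(i, j + 1) < mask(i, j + 1)) push = true;
      if (!push && i < H - 1 && j < W - 1 && J(i + 1, j + 1) < c && J(i + 1, j + 1) < mask(i + 1, j + 1)) push = true;
      if (!push && i > 0 && j < W - 1 && J(i - 1, j + 1) < c && J(i - 1, j + 1) < mask(i - 1, j + 1)) push = true;
      if (push) q.push(std::make_pair(i, j));
    }
  }
  const int di[8] = { -1, -1, -1, 0, 0, 1, 1, 1 };
  const int dj[8] = { -1, 0, 1, -1, 1, -1, 0, 1 };
  while (!q.empty()) {
    std::pair<int, int> p = q.front(); q.pop();
    double c = J(p.first, p.second);
    for (int k = 0; k < 8; ++k) {
      int ni = p.first + di[k], nj = p.second + dj[k];
      if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
      if (J(ni, nj) < c && J(ni, nj) < mask(ni, nj)) {
        J(ni, nj) = std::min(c, mask(ni, nj));
        q.push(std::make_pair(ni, nj));
      }
    }
  }
  return J;
}

// NBRF inpainting core: iterative boundary peeling. At each iteration
// every masked pixel with at least one unmasked 8-neighbour takes the
// per-channel mean of its unmasked 8-neighbours; the layer is removed
// from the mask and the process repeats until the mask is empty.
// img: H x W x C array; mask: H x W logical.
// [[Rcpp::export]]
NumericVector nbrf_fill(NumericVector img, LogicalMatrix mask) {
  IntegerVector dims = img.attr("dim");
  int H = dims[0], W = dims[1], C = dims.size() > 2 ? dims[2] : 1;
  if (mask.nrow() != H || mask.ncol() != W)
    stop("mask dimensions differ from image");
  if (C > 16) stop("at most 16 channels supported");
  NumericVector out(clone(img));
  out.attr("dim") = dims;
  LogicalMatrix M(clone(mask));
  long remaining = 0;
  for (int j = 0; j < W; ++j) for (int i = 0; i < H; ++i) if (M(i, j)) ++remaining;
  if (remaining == (long) H * W)
    stop("mask covers the entire image; no background to estimate");
  const int di[8] = { -1, -1, -1, 0, 0, 1, 1, 1 };
  const int dj[8] = { -1, 0, 1, -1, 1, -1, 0, 1 };
  const long plane = (long) H * W;
  while (remaining > 0) {
    std::vector<int> li, lj;
    std::vector<double> lv;
    lv.reserve(64);
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        if (!M(i, j)) continue;
        int n = 0;
        double acc[16];
        for (int c = 0; c < C; ++c) acc[c] = 0.0;
        for (int k = 0; k < 8; ++k) {
          int ni = i + di[k], nj = j + dj[k];
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          if (M(ni, nj)) continue;
          ++n;
          for (int c = 0; c < C; ++c) acc[c] += out[ni + (long) nj * H + c * plane];
        }
        if (n > 0) {
          li.push_back(i); lj.push_back(j);
          for (int c = 0; c < C; ++c) lv.push_back(acc[c] / n);
        }
      }
    }
    if (li.empty())
      stop("inpainting stalled: masked region unreachable under 8-connectivity");
    for (size_t t = 0; t < li.size(); ++t) {
      for (int c = 0; c < C; ++c)
        out[li[t] + (long) lj[t] * H + c * plane] = lv[t * C + c];
      M(li[t], lj[t]) = false;
    }
    remaining -= (long) li.size();
  }
  return out;
}

// 8-connected component labelling of a logical mask. Labels are
// 1..n in discovery (column-major raster) order; background is 0.
// [[Rcpp::export]]
IntegerMatrix label_components8(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int di[8] = { -1, -1, -1, 0, 0, 1, 1, 1 };
  const int dj[8] = { -1, 0, 1, -1, 1, -1, 0, 1 };
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int k = 0; k < 8; ++k) {
          int ni = p.first + di[k], nj = p.second + dj[k];
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            q.push(std::make_pair(ni, nj));
          }
        }
      }
    }
  }
  return lab;
}
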