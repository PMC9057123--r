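#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// k-nearest-neighbour inverse-distance-weighted interpolation on 2D points.
// Uniform grid hash over the point extent; per query, buckets are scanned in
// expanding rings until the k-th best distance is closed out by the ring
// lower bound. A query coincident with a point (d < 1e-12) returns that
// point's value exactly.
// [[Rcpp::export]]
NumericVector knn_idw_cpp(NumericVector px, NumericVector py, NumericVector pz,
                          NumericVector qx, NumericVector qy,
                          int k, double power) {
  const int n = px.size(), nq = qx.size();
  if (n < k) stop("fewer points than k");

  double xmin = px[0], xmax = px[0], ymin = py[0], ymax = py[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, px[i]); xmax = std::max(xmax, px[i]);
    ymin = std::min(ymin, py[i]); ymax = std::max(ymax, py[i]);
  }
  // target ~2 points per bucket
  double ext = std::max(xmax - xmin, ymax - ymin);
  if (ext <= 0) ext = 1.0;
  int nb = std::max(1, (int)std::floor(std::sqrt((double)n / 2.0)));
  double h = ext / nb;
  int nbx = (int)std::floor((xmax - xmin) / h) + 1;
  int nby = (int)std::floor((ymax - ymin) / h) + 1;

  std::vector<std::vector<int> > buckets((size_t)nbx * nby);
  for (int i = 0; i < n; ++i) {
    int bx = std::min(nbx - 1, (int)std::floor((px[i] - xmin) / h));
    int by = std::min(nby - 1, (int)std::floor((py[i] - ymin) / h));
    buckets[(size_t)by * nbx + bx].push_back(i);
  }

  NumericVector out(nq);
  std::vector<std::pair<double,int> > best; best.reserve(4 * k);

  for (int q = 0; q < nq; ++q) {
    best.clear();
    int bx = (int)std::floor((qx[q] - xmin) / h);
    int by = (int)std::floor((qy[q] - ymin) / h);
    bx = std::max(0, std::min(nbx - 1, bx));
    by = std::max(0, std::min(nby - 1, by));
    double kth = R_PosInf;
    int maxring = std::max(nbx, nby);
    for (int ring = 0; ring <= maxring; ++ring) {
      // ring lower bound on distance: (ring-1)*h from the query's bucket
      if ((int)best.size() >= k) {
        double lb = (ring - 1.0) * h;
        if (lb > 0 && lb * lb > kth) break;
      }
      int x0 = bx - ring, x1 = bx + ring, y0 = by - ring, y1 = by + ring;
      for (int yy = y0; yy <= y1; ++yy) {
        if (yy < 0 || yy >= nby) continue;
        for (int xx = x0; xx <= x1; ++xx) {
          if (xx < 0 || xx >= nbx) continue;
          if (ring > 0 && xx != x0 && xx != x1 && yy != y0 && yy != y1) continue;
          const std::vector<int>& b = buckets[(size_t)yy * nbx + xx];
          for (size_t j = 0; j < b.size(); ++j) {
            int i = b[j];
            double dx = px[i] - qx[q], dy = py[i] - qy[q];
            double d2 = dx * dx + dy * dy;
            best.push_back(std::make_pair(d2, i));
          }
        }
      }
      if ((int)best.size() >= k) {
        std::nth_element(best.begin(), best.begin() + (k - 1), best.end());
        kth = best[k - 1].first;
        best.resize(k);
      }
    }
    std::sort(best.begin(), best.end());
    if (best[0].first < 1e-24) { out[q] = pz[best[0].second]; continue; }
    double wsum = 0, vsum = 0;
    for (int j = 0; j < k; ++j) {
      double w = 1.0 / std::pow(std::sqrt(best[j].first), power);
      wsum += w; vsum += w * pz[best[j].second];
    }
    out[q] = vsum / wsum;
  }
  return out;
}
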