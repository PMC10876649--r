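#include <Rcpp.h>
using namespace Rcpp;

// Discrete Voronoi labelling: every ROI pixel (at its 1-based pixel-centre
// coordinate) gets the id of the Euclidean-nearest centroid. Centroids must
// arrive sorted by increasing id; strict '<' then breaks exact distance ties
// toward the smallest id, matching the pure-R oracle which takes the first
// minimum in id order.
// [[Rcpp::export]]
IntegerMatrix voronoi_label_cpp(IntegerMatrix roi, NumericVector crow,
                                NumericVector ccol, IntegerVector ids) {
  const int H = roi.nrow(), W = roi.ncol(), n = crow.size();
  IntegerMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    const double cx = j + 1;
    for (int i = 0; i < H; ++i) {
      if (roi(i, j) <= 0) continue;
      const double cy = i + 1;
      double best = R_PosInf;
      int bid = 0;
      for (int k = 0; k < n; ++k) {
        const double dr = cy - crow[k];
        const double dc = cx - ccol[k];
        const double d = dr * dr + dc * dc;
        if (d < best) { best = d; bid = ids[k]; }
      }
      out(i, j) = bid;
    }
  }
  return out;
}
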