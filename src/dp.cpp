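#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Global alignment of two C-alpha traces in a common frame, minimising the
// sum of squared match distances plus gapCost per gap column. Tie-breaking in
// the traceback is deterministic: match is preferred over a gap in the
// moving trace, which is preferred over a gap in the fixed trace.
// [[Rcpp::export]]
List dp_align_cpp(NumericMatrix fixed, NumericMatrix moving, double gapCost) {
  const int n = fixed.nrow(), m = moving.nrow();
  if (n < 1 || m < 1) stop("both traces must be non-empty");
  std::vector<double> D(static_cast<size_t>(n + 1) * (m + 1));
  std::vector<unsigned char> mv(static_cast<size_t>(n + 1) * (m + 1));
  const int W = m + 1;
  D[0] = 0.0;
  for (int i = 1; i <= n; ++i) { D[i * W] = i * gapCost; mv[i * W] = 1; }
  for (int j = 1; j <= m; ++j) { D[j] = j * gapCost; mv[j] = 2; }
  for (int i = 1; i <= n; ++i) {
    const double fx = fixed(i - 1, 0), fy = fixed(i - 1, 1),
                 fz = fixed(i - 1, 2);
    for (int j = 1; j <= m; ++j) {
      const double dx = fx - moving(j - 1, 0), dy = fy - moving(j - 1, 1),
                   dz = fz - moving(j - 1, 2);
      double best = D[(i - 1) * W + (j - 1)] + dx * dx + dy * dy + dz * dz;
      unsigned char b = 0;
      const double up = D[(i - 1) * W + j] + gapCost;    // gap in moving
      if (up < best) { best = up; b = 1; }
      const double left = D[i * W + (j - 1)] + gapCost;  // gap in fixed
      if (left < best) { best = left; b = 2; }
      D[i * W + j] = best;
      mv[i * W + j] = b;
    }
  }
  std::vector<int> fi, mi;
  fi.reserve(n + m); mi.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const unsigned char b = mv[i * W + j];
    if (b == 0)      { fi.push_back(i); mi.push_back(j); --i; --j; }
    else if (b == 1) { fi.push_back(i); mi.push_back(NA_INTEGER); --i; }
    else             { fi.push_back(NA_INTEGER); mi.push_back(j); --j; }
  }
  std::reverse(fi.begin(), fi.end());
  std::reverse(mi.begin(), mi.end());
  return List::create(_["fixedIdx"] = IntegerVector(fi.begin(), fi.end()),
                      _["movingIdx"] = IntegerVector(mi.begin(), mi.end()),
                      _["cost"] = D[static_cast<size_t>(n) * W + m]);
}
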