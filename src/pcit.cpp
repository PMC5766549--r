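#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// PCIT trio scan. For every unordered trio (x, y, z) the three first-order
// partial correlations are computed; the trio tolerance eps is the mean of
// the |partial/direct| ratios (terms with |direct| < 1e-12 skipped). Within
// the trio, edge (x, y) is locally non-significant when
// |r_xy| < |eps * r_xz| AND |r_xy| < |eps * r_yz|; an edge is globally
// significant iff no trio renders it locally non-significant. Denominators
// of the partials are clamped at 1e-12 so |r| = 1 off-diagonals are handled.
// [[Rcpp::export]]
LogicalMatrix pcit_flags_cpp(NumericMatrix r) {
  const int n = r.nrow();
  const double tiny = 1e-12;
  LogicalMatrix sig(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) sig(i, j) = (i != j);

  for (int x = 0; x < n - 2; ++x) {
    for (int y = x + 1; y < n - 1; ++y) {
      const double rxy = r(x, y);
      for (int z = y + 1; z < n; ++z) {
        const double rxz = r(x, z), ryz = r(y, z);
        double dxy = std::sqrt((1.0 - rxz * rxz) * (1.0 - ryz * ryz));
        double dxz = std::sqrt((1.0 - rxy * rxy) * (1.0 - ryz * ryz));
        double dyz = std::sqrt((1.0 - rxy * rxy) * (1.0 - rxz * rxz));
        if (dxy < tiny) dxy = tiny;
        if (dxz < tiny) dxz = tiny;
        if (dyz < tiny) dyz = tiny;
        const double pxy = (rxy - rxz * ryz) / dxy;
        const double pxz = (rxz - rxy * ryz) / dxz;
        const double pyz = (ryz - rxy * rxz) / dyz;

        double s = 0.0;
        int cnt = 0;
        if (std::fabs(rxy) >= tiny) { s += std::fabs(pxy / rxy); ++cnt; }
        if (std::fabs(rxz) >= tiny) { s += std::fabs(pxz / rxz); ++cnt; }
        if (std::fabs(ryz) >= tiny) { s += std::fabs(pyz / ryz); ++cnt; }
        if (cnt == 0) continue;  // degenerate trio cannot discriminate
        const double eps = s / cnt;

        if (std::fabs(rxy) < std::fabs(eps * rxz) &&
            std::fabs(rxy) < std::fabs(eps * ryz)) {
          sig(x, y) = sig(y, x) = false;
        }
        if (std::fabs(rxz) < std::fabs(eps * rxy) &&
            std::fabs(rxz) < std::fabs(eps * ryz)) {
          sig(x, z) = sig(z, x) = false;
        }
        if (std::fabs(ryz) < std::fabs(eps * rxy) &&
            std::fabs(ryz) < std::fabs(eps * rxz)) {
          sig(y, z) = sig(z, y) = false;
        }
      }
    }
  }
  return sig;
}
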