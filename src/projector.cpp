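#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Joseph-method parallel-beam projector for an isotropic in-plane grid.
// Returns sparse triplets (1-based) of the system matrix whose entry (row,
// col) is the intersection length (mm, bilinear-interpolated) of ray `row`
// with pixel `col`. Rows are ordered angle-major: row = a * n_radial + r.
// Angles span [0, pi); pixel columns are R column-major: col = ix + iy * nx.
// [[Rcpp::export]]
List joseph_triplets(int nx, int ny, double dx, int n_angles, int n_radial,
                     double bin_width) {
  std::vector<int> ri, ci;
  std::vector<double> val;
  ri.reserve((size_t)n_angles * n_radial * (nx + ny));
  ci.reserve(ri.capacity());
  val.reserve(ri.capacity());
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  const double rc = (n_radial - 1) / 2.0;
  for (int a = 0; a < n_angles; ++a) {
    const double th = M_PI * a / n_angles;
    const double dxc = std::cos(th), dyc = std::sin(th);
    const double nxv = -std::sin(th), nyv = std::cos(th);
    const bool x_major = std::fabs(dxc) >= std::fabs(dyc);
    const double L = dx / (x_major ? std::fabs(dxc) : std::fabs(dyc));
    for (int r = 0; r < n_radial; ++r) {
      const double rr = (r - rc) * bin_width;
      const int row = a * n_radial + r;
      if (x_major) {
        for (int i = 0; i < nx; ++i) {
          const double x = (i - cx) * dx;
          const double t = (x - rr * nxv) / dxc;
          const double y = rr * nyv + t * dyc;
          const double fy = y / dx + cy;
          const int j0 = (int)std::floor(fy);
          const double w = fy - j0;
          if (j0 >= 0 && j0 < ny && 1.0 - w > 1e-12) {
            ri.push_back(row + 1); ci.push_back(i + j0 * nx + 1);
            val.push_back((1.0 - w) * L);
          }
          if (j0 + 1 >= 0 && j0 + 1 < ny && w > 1e-12) {
            ri.push_back(row + 1); ci.push_back(i + (j0 + 1) * nx + 1);
            val.push_back(w * L);
          }
        }
      } else {
        for (int j = 0; j < ny; ++j) {
          const double y = (j - cy) * dx;
          const double t = (y - rr * nyv) / dyc;
          const double x = rr * nxv + t * dxc;
          const double fx = x / dx + cx;
          const int i0 = (int)std::floor(fx);
          const double w = fx - i0;
          if (i0 >= 0 && i0 < nx && 1.0 - w > 1e-12) {
            ri.push_back(row + 1); ci.push_back(i0 + j * nx + 1);
            val.push_back((1.0 - w) * L);
          }
          if (i0 + 1 >= 0 && i0 + 1 < nx && w > 1e-12) {
            ri.push_back(row + 1); ci.push_back(i0 + 1 + j * nx + 1);
            val.push_back(w * L);
          }
        }
      }
    }
  }
  return List::create(_["i"] = wrap(ri), _["j"] = wrap(ci),
                      _["x"] = wrap(val));
}
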