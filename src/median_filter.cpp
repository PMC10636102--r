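#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// 3D median filter with nearest-border (replicate) padding.
// Neighbourhood is the full (2r+1)^3 cube, which has an odd voxel count,
// so the median is the middle order statistic (nth_element).
// [[Rcpp::export]]
NumericVector median_filter3d_cpp(NumericVector vol, IntegerVector dims, int radius) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const int r = radius;
    const int side = 2 * r + 1;
    const int nnb = side * side * side;
    NumericVector out(vol.size());
    std::vector<double> buf(nnb);
    for (int z = 0; z < nz; ++z) {
        for (int y = 0; y < ny; ++y) {
            for (int x = 0; x < nx; ++x) {
                int k = 0;
                for (int dz = -r; dz <= r; ++dz) {
                    int zz = std::min(std::max(z + dz, 0), nz - 1);
                    for (int dy = -r; dy <= r; ++dy) {
                        int yy = std::min(std::max(y + dy, 0), ny - 1);
                        for (int dx = -r; dx <= r; ++dx) {
                            int xx = std::min(std::max(x + dx, 0), nx - 1);
                            buf[k++] = vol[xx + nx * (yy + (R_xlen_t)ny * zz)];
                        }
                    }
                }
                std::nth_element(buf.begin(), buf.begin() + nnb / 2, buf.end());
                out[x + nx * (y + (R_xlen_t)ny * z)] = buf[nnb / 2];
            }
        }
    }
    return out;
}
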