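#include <Rcpp.h>
using namespace Rcpp;

// Volumes are R arrays dim c(Z, Y, X): linear index z + Z*(y + Y*x).
// Voxel index refers to the voxel centre; sampling clamps to the border
// (resampling) or fills a constant (affine augmentation).

static inline double sample_trilinear(const double* v, int Z, int Y, int X,
                                      double z, double y, double x,
                                      bool clamp, double fill) {
  if (!clamp && (z < -0.5 || y < -0.5 || x < -0.5 ||
                 z > Z - 0.5 || y > Y - 0.5 || x > X - 0.5))
    return fill;
  if (z < 0) z = 0; if (y < 0) y = 0; if (x < 0) x = 0;
  if (z > Z - 1) z = Z - 1; if (y > Y - 1) y = Y - 1; if (x > X - 1) x = X - 1;
  const int z0 = static_cast<int>(std::floor(z));
  const int y0 = static_cast<int>(std::floor(y));
  const int x0 = static_cast<int>(std::floor(x));
  const int z1 = std::min(z0 + 1, Z - 1);
  const int y1 = std::min(y0 + 1, Y - 1);
  const int x1 = std::min(x0 + 1, X - 1);
  const double fz = z - z0, fy = y - y0, fx = x - x0;
  double acc = 0.0;
  for (int dx = 0; dx <= 1; ++dx)
    for (int dy = 0; dy <= 1; ++dy)
      for (int dz = 0; dz <= 1; ++dz) {
        const double w = (dz ? fz : 1 - fz) * (dy ? fy : 1 - fy) * (dx ? fx : 1 - fx);
        if (w == 0.0) continue;
        const int zi = dz ? z1 : z0, yi = dy ? y1 : y0, xi = dx ? x1 : x0;
        acc += w * v[zi + static_cast<size_t>(Z) * (yi + static_cast<size_t>(Y) * xi)];
      }
  return acc;
}

// Isotropic grid resampling: input continuous index = output index * scale,
// scale = target_spacing / input_spacing per axis (both grids share origin,
// voxel-centre convention).
// [[Rcpp::export]]
NumericVector resample_grid_cpp(const NumericVector& vol, IntegerVector in_dim,
                                NumericVector scale, IntegerVector out_dim) {
  const int Z = in_dim[0], Y = in_dim[1], X = in_dim[2];
  const int Zo = out_dim[0], Yo = out_dim[1], Xo = out_dim[2];
  NumericVector out(static_cast<R_xlen_t>(Zo) * Yo * Xo);
  const double* v = vol.begin();
  double* o = out.begin();
  for (int x = 0; x < Xo; ++x)
    for (int y = 0; y < Yo; ++y)
      for (int z = 0; z < Zo; ++z)
        o[z + static_cast<size_t>(Zo) * (y + static_cast<size_t>(Yo) * x)] =
          sample_trilinear(v, Z, Y, X, z * scale[0], y * scale[1], x * scale[2],
                           true, 0.0);
  out.attr("dim") = out_dim;
  return out;
}

// General affine pullback: for each output voxel p (z,y,x), sample the input
// at q = A %*% (p - centre) + centre, trilinear, constant fill outside.
// A is the inverse transform (output -> input), row-major 3x3 in (z,y,x).
// [[Rcpp::export]]
NumericVector affine_sample_cpp(const NumericVector& vol, IntegerVector dim,
                                NumericVector A, NumericVector centre,
                                double fill) {
  const int Z = dim[0], Y = dim[1], X = dim[2];
  NumericVector out(static_cast<R_xlen_t>(Z) * Y * X);
  const double* v = vol.begin();
  double* o = out.begin();
  const double cz = centre[0], cy = centre[1], cx = centre[2];
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y)
      for (int z = 0; z < Z; ++z) {
        const double pz = z - cz, py = y - cy, px = x - cx;
        const double qz = A[0] * pz + A[1] * py + A[2] * px + cz;
        const double qy = A[3] * pz + A[4] * py + A[5] * px + cy;
        const double qx = A[6] * pz + A[7] * py + A[8] * px + cx;
        o[z + static_cast<size_t>(Z) * (y + static_cast<size_t>(Y) * x)] =
          sample_trilinear(v, Z, Y, X, qz, qy, qx, false, fill);
      }
  out.attr("dim") = dim;
  return out;
}
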