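#include <Rcpp.h>
using namespace Rcpp;

// Column-major linear index for a 0-based voxel (i,j,k).
static inline R_xlen_t lin(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Trilinear sampling of a 3D image at continuous 0-based voxel coordinates.
// Points outside [0, n-1] on any axis get `fill` and inside = FALSE, unless
// `clamp` is true: then coordinates are clamped to the grid (constant
// extrapolation, keeps the interpolant continuous) and only `inside` marks
// out-of-FOV points. If want_grad, also returns the analytic derivative of
// the interpolant with respect to the voxel coordinate (zero outside).
// [[Rcpp::export]]
List cpp_trilinear(NumericVector img, IntegerVector dim, NumericMatrix pts,
                   double fill, bool want_grad, bool clamp = false) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = pts.nrow();
  NumericVector val(n);
  LogicalVector inside(n);
  NumericMatrix grad = want_grad ? NumericMatrix(n, 3) : NumericMatrix(0, 3);
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    bool in = (x >= 0.0 && x <= nx - 1.0 && y >= 0.0 && y <= ny - 1.0 &&
               z >= 0.0 && z <= nz - 1.0);
    inside[p] = in;
    bool cx = false, cy = false, cz = false;
    if (!in) {
      if (!clamp) {
        val[p] = fill;
        continue;
      }
      if (x < 0) { x = 0; cx = true; } else if (x > nx - 1.0) { x = nx - 1.0; cx = true; }
      if (y < 0) { y = 0; cy = true; } else if (y > ny - 1.0) { y = ny - 1.0; cy = true; }
      if (z < 0) { z = 0; cz = true; } else if (z > nz - 1.0) { z = nz - 1.0; cz = true; }
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 > nx - 2) i0 = nx - 2;
    if (j0 > ny - 2) j0 = ny - 2;
    if (k0 > nz - 2) k0 = nz - 2;
    if (i0 < 0) i0 = 0;
    if (j0 < 0) j0 = 0;
    if (k0 < 0) k0 = 0;
    // Degenerate axes (n == 1): stay at index 0 with zero fraction.
    double fx = nx > 1 ? x - i0 : 0.0;
    double fy = ny > 1 ? y - j0 : 0.0;
    double fz = nz > 1 ? z - k0 : 0.0;
    int i1 = nx > 1 ? i0 + 1 : i0;
    int j1 = ny > 1 ? j0 + 1 : j0;
    int k1 = nz > 1 ? k0 + 1 : k0;
    double c000 = img[lin(i0, j0, k0, nx, ny)], c100 = img[lin(i1, j0, k0, nx, ny)];
    double c010 = img[lin(i0, j1, k0, nx, ny)], c110 = img[lin(i1, j1, k0, nx, ny)];
    double c001 = img[lin(i0, j0, k1, nx, ny)], c101 = img[lin(i1, j0, k1, nx, ny)];
    double c011 = img[lin(i0, j1, k1, nx, ny)], c111 = img[lin(i1, j1, k1, nx, ny)];
    double c00 = c000 + fx * (c100 - c000);
    double c10 = c010 + fx * (c110 - c010);
    double c01 = c001 + fx * (c101 - c001);
    double c11 = c011 + fx * (c111 - c011);
    double c0 = c00 + fy * (c10 - c00);
    double c1 = c01 + fy * (c11 - c01);
    val[p] = c0 + fz * (c1 - c0);
    if (want_grad) {
      // d/dfx
      double dx00 = c100 - c000, dx10 = c110 - c010, dx01 = c101 - c001, dx11 = c111 - c011;
      double dx0 = dx00 + fy * (dx10 - dx00);
      double dx1 = dx01 + fy * (dx11 - dx01);
      // the clamped interpolant is constant along a clamped axis
      grad(p, 0) = cx ? 0.0 : dx0 + fz * (dx1 - dx0);
      grad(p, 1) = cy ? 0.0 : (c10 - c00) + fz * ((c11 - c01) - (c10 - c00));
      grad(p, 2) = cz ? 0.0 : c1 - c0;
    }
  }
  return List::create(_["value"] = val, _["grad"] = grad, _["inside"] = inside);
}

// Image gradient in world mm: central differences in the interior,
// one-sided at the boundary faces. Returns an N x 3 matrix.
// [[Rcpp::export]]
NumericMatrix cpp_gradient(NumericVector img, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericMatrix g(n, 3);
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t id = lin(i, j, k, nx, ny);
        if (nx > 1) {
          if (i == 0) g(id, 0) = (img[lin(1, j, k, nx, ny)] - img[id]) / hx;
          else if (i == nx - 1) g(id, 0) = (img[id] - img[lin(nx - 2, j, k, nx, ny)]) / hx;
          else g(id, 0) = (img[lin(i + 1, j, k, nx, ny)] - img[lin(i - 1, j, k, nx, ny)]) / (2 * hx);
        }
        if (ny > 1) {
          if (j == 0) g(id, 1) = (img[lin(i, 1, k, nx, ny)] - img[id]) / hy;
          else if (j == ny - 1) g(id, 1) = (img[id] - img[lin(i, ny - 2, k, nx, ny)]) / hy;
          else g(id, 1) = (img[lin(i, j + 1, k, nx, ny)] - img[lin(i, j - 1, k, nx, ny)]) / (2 * hy);
        }
        if (nz > 1) {
          if (k == 0) g(id, 2) = (img[lin(i, j, 1, nx, ny)] - img[id]) / hz;
          else if (k == nz - 1) g(id, 2) = (img[id] - img[lin(i, j, nz - 2, nx, ny)]) / hz;
          else g(id, 2) = (img[lin(i, j, k + 1, nx, ny)] - img[lin(i, j, k - 1, nx, ny)]) / (2 * hz);
        }
      }
  return g;
}

// Exact adjoint of cpp_gradient: maps an N x 3 cotangent back onto the image.
// [[Rcpp::export]]
NumericVector cpp_gradient_adjoint(NumericMatrix g, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t id = lin(i, j, k, nx, ny);
        if (nx > 1) {
          double w = g(id, 0);
          if (i == 0) {
            out[lin(1, j, k, nx, ny)] += w / hx;
            out[id] -= w / hx;
          } else if (i == nx - 1) {
            out[id] += w / hx;
            out[lin(nx - 2, j, k, nx, ny)] -= w / hx;
          } else {
            out[lin(i + 1, j, k, nx, ny)] += w / (2 * hx);
            out[lin(i - 1, j, k, nx, ny)] -= w / (2 * hx);
          }
        }
        if (ny > 1) {
          double w = g(id, 1);
          if (j == 0) {
            out[lin(i, 1, k, nx, ny)] += w / hy;
            out[id] -= w / hy;
          } else if (j == ny - 1) {
            out[id] += w / hy;
            out[lin(i, ny - 2, k, nx, ny)] -= w / hy;
          } else {
            out[lin(i, j + 1, k, nx, ny)] += w / (2 * hy);
            out[lin(i, j - 1, k, nx, ny)] -= w / (2 * hy);
          }
        }
        if (nz > 1) {
          double w = g(id, 2);
          if (k == 0) {
            out[lin(i, j, 1, nx, ny)] += w / hz;
            out[id] -= w / hz;
          } else if (k == nz - 1) {
            out[id] += w / hz;
            out[lin(i, j, nz - 2, nx, ny)] -= w / hz;
          } else {
            out[lin(i, j, k + 1, nx, ny)] += w / (2 * hz);
            out[lin(i, j, k - 1, nx, ny)] -= w / (2 * hz);
          }
        }
      }
  return out;
}

// NGF distance D = mean over selected voxels of
//   d(x) = 1 - (<gF,gM> + eta^2)^2 / ((|gF|^2 + eta^2) (|gM|^2 + eta^2))
// and, optionally, dD/dgM.
// [[Rcpp::export]]
List cpp_ngf(NumericMatrix gF, NumericMatrix gM, double eta, LogicalVector sel,
             bool want_grad) {
  const R_xlen_t n = gF.nrow();
  const double e2 = eta * eta;
  double acc = 0.0;
  R_xlen_t nsel = 0;
  NumericMatrix dgM = want_grad ? NumericMatrix(n, 3) : NumericMatrix(0, 3);
  for (R_xlen_t p = 0; p < n; ++p) {
    if (!sel[p]) continue;
    ++nsel;
    double fx = gF(p, 0), fy = gF(p, 1), fz = gF(p, 2);
    double mx = gM(p, 0), my = gM(p, 1), mz = gM(p, 2);
    double r = fx * mx + fy * my + fz * mz + e2;
    double q1 = fx * fx + fy * fy + fz * fz + e2;
    double q2 = mx * mx + my * my + mz * mz + e2;
    acc += 1.0 - (r * r) / (q1 * q2);
    if (want_grad) {
      double a = -2.0 * r / (q1 * q2);
      double b = 2.0 * r * r / (q1 * q2 * q2);
      dgM(p, 0) = a * fx + b * mx;
      dgM(p, 1) = a * fy + b * my;
      dgM(p, 2) = a * fz + b * mz;
    }
  }
  if (nsel == 0) stop("NGF distance over an empty voxel selection");
  if (want_grad) {
    for (R_xlen_t p = 0; p < n; ++p)
      for (int c = 0; c < 3; ++c) dgM(p, c) /= (double)nsel;
  }
  return List::create(_["value"] = acc / (double)nsel, _["dgM"] = dgM,
                      _["n"] = (double)nsel);
}

// Discrete Laplacian of a scalar grid function, in mm^-2 units: second-order
// central differences summed per axis, evaluated only where the stencil fits
// (a node on a boundary face contributes zero along that axis).
// [[Rcpp::export]]
NumericVector cpp_laplacian(NumericVector u, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector v(n);
  const double ihx2 = 1.0 / (spacing[0] * spacing[0]);
  const double ihy2 = 1.0 / (spacing[1] * spacing[1]);
  const double ihz2 = 1.0 / (spacing[2] * spacing[2]);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t id = lin(i, j, k, nx, ny);
        double s = 0.0;
        if (i > 0 && i < nx - 1)
          s += (u[lin(i - 1, j, k, nx, ny)] - 2 * u[id] + u[lin(i + 1, j, k, nx, ny)]) * ihx2;
        if (j > 0 && j < ny - 1)
          s += (u[lin(i, j - 1, k, nx, ny)] - 2 * u[id] + u[lin(i, j + 1, k, nx, ny)]) * ihy2;
        if (k > 0 && k < nz - 1)
          s += (u[lin(i, j, k - 1, nx, ny)] - 2 * u[id] + u[lin(i, j, k + 1, nx, ny)]) * ihz2;
        v[id] = s;
      }
  return v;
}

// Exact adjoint of cpp_laplacian.
// [[Rcpp::export]]
NumericVector cpp_laplacian_adjoint(NumericVector w, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const double ihx2 = 1.0 / (spacing[0] * spacing[0]);
  const double ihy2 = 1.0 / (spacing[1] * spacing[1]);
  const double ihz2 = 1.0 / (spacing[2] * spacing[2]);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t id = lin(i, j, k, nx, ny);
        double ww = w[id];
        if (ww == 0.0) continue;
        if (i > 0 && i < nx - 1) {
          out[lin(i - 1, j, k, nx, ny)] += ww * ihx2;
          out[id] -= 2 * ww * ihx2;
          out[lin(i + 1, j, k, nx, ny)] += ww * ihx2;
        }
        if (j > 0 && j < ny - 1) {
          out[lin(i, j - 1, k, nx, ny)] += ww * ihy2;
          out[id] -= 2 * ww * ihy2;
          out[lin(i, j + 1, k, nx, ny)] += ww * ihy2;
        }
        if (k > 0 && k < nz - 1) {
          out[lin(i, j, k - 1, nx, ny)] += ww * ihz2;
          out[id] -= 2 * ww * ihz2;
          out[lin(i, j, k + 1, nx, ny)] += ww * ihz2;
        }
      }
  return out;
}

// Binary dilation/erosion with an arbitrary offset list (voxel units).
// Outside the image counts as background.
// [[Rcpp::export]]
LogicalVector cpp_morph(LogicalVector mask, IntegerVector dim, IntegerMatrix offsets,
                        bool dilate) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int no = offsets.nrow();
  LogicalVector out((R_xlen_t)nx * ny * nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t id = lin(i, j, k, nx, ny);
        bool acc = dilate ? false : true;
        for (int o = 0; o < no; ++o) {
          int ii = i + offsets(o, 0), jj = j + offsets(o, 1), kk = k + offsets(o, 2);
          bool v = (ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz)
                       ? (bool)mask[lin(ii, jj, kk, nx, ny)]
                       : false;
          if (dilate) {
            if (v) { acc = true; break; }
          } else {
            if (!v) { acc = false; break; }
          }
        }
        out[id] = acc;
      }
  return out;
}

static inline double det3(const double a[3], const double b[3], const double c[3]) {
  return a[0] * (b[1] * c[2] - b[2] * c[1]) - a[1] * (b[0] * c[2] - b[2] * c[0]) +
         a[2] * (b[0] * c[1] - b[1] * c[0]);
}

// Folding detection: every grid cell (8 neighboring voxel centers) is split
// into 8 corner tetrahedra (corner + its 3 edge-adjacent corners, each of
// volume cell/6); a tetrahedron is folded iff the sign of its deformed
// signed volume differs from the undeformed one, or is zero.
// u: N x 3 world-mm displacements; A: 4x4 voxel-to-world affine.
// [[Rcpp::export]]
List cpp_foldings(NumericMatrix u, IntegerVector dim, NumericMatrix A, int max_loc) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if (nx < 2 || ny < 2 || nz < 2) stop("folding detection needs >= 2 nodes per axis");
  double col[3][3];
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r) col[c][r] = A(r, c);
  double detA = det3(col[0], col[1], col[2]);
  if (detA == 0.0) stop("degenerate affine");
  R_xlen_t count = 0, total = 0;
  std::vector<int> loc;
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        // world positions of the 8 deformed corners
        double phi[8][3];
        for (int c = 0; c < 8; ++c) {
          int di = c & 1, dj = (c >> 1) & 1, dk = (c >> 2) & 1;
          int vi = i + di, vj = j + dj, vk = k + dk;
          R_xlen_t id = lin(vi, vj, vk, nx, ny);
          for (int r = 0; r < 3; ++r)
            phi[c][r] = A(r, 0) * vi + A(r, 1) * vj + A(r, 2) * vk + A(r, 3) + u(id, r);
        }
        for (int c = 0; c < 8; ++c) {
          ++total;
          int a1 = c ^ 1, a2 = c ^ 2, a3 = c ^ 4;
          double e1[3], e2[3], e3[3];
          for (int r = 0; r < 3; ++r) {
            e1[r] = phi[a1][r] - phi[c][r];
            e2[r] = phi[a2][r] - phi[c][r];
            e3[r] = phi[a3][r] - phi[c][r];
          }
          double d = det3(e1, e2, e3);
          int di = c & 1, dj = (c >> 1) & 1, dk = (c >> 2) & 1;
          double sgn = ((di + dj + dk) % 2 == 0) ? 1.0 : -1.0;
          double ref = sgn * detA; // undeformed signed volume (x6)
          bool folded = (d == 0.0) || ((d > 0) != (ref > 0));
          if (folded) {
            ++count;
            if ((int)loc.size() / 4 < max_loc) {
              loc.push_back(i); loc.push_back(j); loc.push_back(k); loc.push_back(c);
            }
          }
        }
      }
  IntegerMatrix locs(loc.size() / 4, 4);
  for (R_xlen_t r = 0; r < locs.nrow(); ++r)
    for (int c = 0; c < 4; ++c) locs(r, c) = loc[4 * r + c];
  return List::create(_["count"] = (double)count, _["total"] = (double)total,
                      _["locations"] = locs);
}
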