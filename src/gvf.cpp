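#include <Rcpp.h>
using namespace Rcpp;

// Gradient vector flow by explicit gradient descent on
//   E(v) = sum mu * |grad v|^2 + |g|^2 |v - g|^2
// with forward-difference gradients, zero-flux (Neumann) boundaries and the
// matching 6-neighbour Laplacian, so each step with
// dt = 1 / (6 mu + max|g|^2) decreases E monotonically.

static inline int idx3(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// [[Rcpp::export]]
List gvf_iterate_cpp(NumericVector gx, NumericVector gy, NumericVector gz,
                     IntegerVector dims, double mu, int n_iter) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;

  NumericVector g2(n);
  double g2max = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    g2[i] = gx[i] * gx[i] + gy[i] * gy[i] + gz[i] * gz[i];
    if (g2[i] > g2max) g2max = g2[i];
  }
  const double dt = 1.0 / (6.0 * mu + g2max);

  std::vector<NumericVector> v{clone(gx), clone(gy), clone(gz)};
  std::vector<NumericVector> g{gx, gy, gz};
  std::vector<NumericVector> lap{NumericVector(n), NumericVector(n),
                                 NumericVector(n)};
  NumericVector energy(n_iter + 1);

  auto compute_energy = [&]() {
    double e = 0.0;
    for (int c = 0; c < 3; ++c) {
      NumericVector &vc = v[c];
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y)
          for (int z = 0; z < nz; ++z) {
            const int i = idx3(z, y, x, nz, ny);
            const double vi = vc[i];
            if (z + 1 < nz) { double d = vc[idx3(z + 1, y, x, nz, ny)] - vi; e += mu * d * d; }
            if (y + 1 < ny) { double d = vc[idx3(z, y + 1, x, nz, ny)] - vi; e += mu * d * d; }
            if (x + 1 < nx) { double d = vc[idx3(z, y, x + 1, nz, ny)] - vi; e += mu * d * d; }
            const double dv = vi - g[c][i];
            e += g2[i] * dv * dv;
          }
    }
    return e;
  };

  energy[0] = compute_energy();
  for (int it = 0; it < n_iter; ++it) {
    for (int c = 0; c < 3; ++c) {
      NumericVector &vc = v[c];
      NumericVector &lc = lap[c];
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y)
          for (int z = 0; z < nz; ++z) {
            const int i = idx3(z, y, x, nz, ny);
            const double vi = vc[i];
            double l = 0.0;
            l += (z + 1 < nz ? vc[idx3(z + 1, y, x, nz, ny)] : vi) - vi;
            l += (z > 0 ? vc[idx3(z - 1, y, x, nz, ny)] : vi) - vi;
            l += (y + 1 < ny ? vc[idx3(z, y + 1, x, nz, ny)] : vi) - vi;
            l += (y > 0 ? vc[idx3(z, y - 1, x, nz, ny)] : vi) - vi;
            l += (x + 1 < nx ? vc[idx3(z, y, x + 1, nz, ny)] : vi) - vi;
            l += (x > 0 ? vc[idx3(z, y, x - 1, nz, ny)] : vi) - vi;
            lc[i] = l;
          }
    }
    for (int c = 0; c < 3; ++c) {
      NumericVector &vc = v[c];
      NumericVector &lc = lap[c];
      for (R_xlen_t i = 0; i < n; ++i) {
        vc[i] += dt * (mu * lc[i] - g2[i] * (vc[i] - g[c][i]));
      }
    }
    energy[it + 1] = compute_energy();
  }

  for (int c = 0; c < 3; ++c) v[c].attr("dim") = dims;
  return List::create(_["vx"] = v[0], _["vy"] = v[1], _["vz"] = v[2],
                      _["dt"] = dt, _["energy"] = energy);
}
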