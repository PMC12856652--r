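#include <Rcpp.h>
using namespace Rcpp;

// Metropolis random walk on a periodic 1-degree grid with nearest-neighbor
// proposals. `log_density` holds the log stationary density per grid point
// (-Inf marks the excluded window); `attempts_per_frame` may be fractional
// (the fractional part is realized as a Bernoulli extra attempt). Uses R's
// RNG so runs are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector cpp_dihedral_metropolis(NumericVector log_density,
                                      int n_frames,
                                      double attempts_per_frame,
                                      int start_index) {
  const int n = log_density.size();
  IntegerVector out(n_frames);
  int pos = start_index;
  const int base = (int)std::floor(attempts_per_frame);
  const double frac = attempts_per_frame - base;
  RNGScope scope;
  for (int t = 0; t < n_frames; ++t) {
    int n_att = base + ((frac > 0.0 && unif_rand() < frac) ? 1 : 0);
    for (int a = 0; a < n_att; ++a) {
      int prop = pos + ((unif_rand() < 0.5) ? -1 : 1);
      if (prop < 0) prop += n;
      if (prop >= n) prop -= n;
      double dl = log_density[prop] - log_density[pos];
      if (dl >= 0.0 || (std::isfinite(dl) && unif_rand() < std::exp(dl)))
        pos = prop;
    }
    out[t] = pos;
  }
  return out;
}

// Isotropic rotational random walk: per frame rotate by a Gaussian angle of
// scale `sigma_step` (radians) about a uniformly random axis. Quaternions
// are stored (w, x, y, z), unit norm; the per-frame increment acts as an
// active rotation composed on the left.
// [[Rcpp::export]]
NumericMatrix cpp_orientation_walk(int n_frames, double sigma_step,
                                   NumericVector q0) {
  NumericMatrix out(n_frames, 4);
  double qw = q0[0], qx = q0[1], qy = q0[2], qz = q0[3];
  RNGScope scope;
  for (int t = 0; t < n_frames; ++t) {
    if (sigma_step > 0.0) {
      double ax = norm_rand(), ay = norm_rand(), az = norm_rand();
      double nrm = std::sqrt(ax * ax + ay * ay + az * az);
      if (nrm < 1e-12) { ax = 1.0; ay = 0.0; az = 0.0; nrm = 1.0; }
      ax /= nrm; ay /= nrm; az /= nrm;
      double ang = norm_rand() * sigma_step;
      double c = std::cos(ang / 2.0), s = std::sin(ang / 2.0);
      double dw = c, dx = s * ax, dy = s * ay, dz = s * az;
      double nw = dw * qw - dx * qx - dy * qy - dz * qz;
      double nx = dw * qx + dx * qw + dy * qz - dz * qy;
      double ny = dw * qy - dx * qz + dy * qw + dz * qx;
      double nz = dw * qz + dx * qy - dy * qx + dz * qw;
      double qn = std::sqrt(nw * nw + nx * nx + ny * ny + nz * nz);
      qw = nw / qn; qx = nx / qn; qy = ny / qn; qz = nz / qn;
    }
    out(t, 0) = qw; out(t, 1) = qx; out(t, 2) = qy; out(t, 3) = qz;
  }
  return out;
}

static inline void quat_to_rot(const double *q, double R[9]) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0] = 1 - 2 * (y * y + z * z); R[1] = 2 * (x * y - z * w);
  R[2] = 2 * (x * z + y * w);
  R[3] = 2 * (x * y + z * w);     R[4] = 1 - 2 * (x * x + z * z);
  R[5] = 2 * (y * z - x * w);
  R[6] = 2 * (x * z - y * w);     R[7] = 2 * (y * z + x * w);
  R[8] = 1 - 2 * (x * x + y * y);
}

// Rotate fragment-frame tensors into the lab frame per frame:
// T_lab = R T_frag R^T (active rotation). `idx` gives the (1-based) mapping
// table row per frame; `table` is n_grid x 9 row-major tensors.
// [[Rcpp::export]]
NumericMatrix cpp_rotate_tensor_trajectory(IntegerVector idx,
                                           NumericMatrix quat,
                                           NumericMatrix table) {
  const int n = idx.size();
  if (quat.nrow() != n) stop("frame count mismatch");
  NumericMatrix out(n, 9);
  double R[9], T[9], RT[9];
  for (int t = 0; t < n; ++t) {
    const double q[4] = {quat(t, 0), quat(t, 1), quat(t, 2), quat(t, 3)};
    quat_to_rot(q, R);
    const int row = idx[t] - 1;
    for (int k = 0; k < 9; ++k) T[k] = table(row, k);
    // RT = R * T
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double s = 0.0;
        for (int k = 0; k < 3; ++k) s += R[3 * i + k] * T[3 * k + j];
        RT[3 * i + j] = s;
      }
    // out = RT * R^T
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double s = 0.0;
        for (int k = 0; k < 3; ++k) s += RT[3 * i + k] * R[3 * j + k];
        out(t, 3 * i + j) = s;
      }
  }
  return out;
}
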