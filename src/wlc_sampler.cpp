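#include <Rcpp.h>
using namespace Rcpp;

// Discrete worm-like chain tethered to a hard surface, with a bead at the
// distal end.  State: N unit tangent vectors (segment length ell) plus, for
// the swivel attachment, the bead orientation unit vector u.  Bending energy
// (kT units) is sum over interior joints of kappa * (1 - t_i . t_{i+1}) with
// kappa = Lp / ell; the anchor joint is free.  Constraints: every chain
// vertex has z >= 0 and the bead centre has z >= R (hard half-space for both
// chain and bead).  attachment = 0: rigid, centre = end + R * t_N;
// attachment = 1: free swivel, centre = end + R * u with u a thermal degree
// of freedom (its allowed-orientation entropy weights each chain state).
//
// Uses R's RNG (unif_rand) so set.seed() in R governs reproducibility.

static inline void rotate(double ax, double ay, double az, double ang,
                          double &x, double &y, double &z) {
  // Rodrigues rotation about unit axis (ax, ay, az)
  const double c = std::cos(ang), s = std::sin(ang);
  const double dot = ax * x + ay * y + az * z;
  const double cx = ay * z - az * y;
  const double cy = az * x - ax * z;
  const double cz = ax * y - ay * x;
  const double nx = x * c + cx * s + ax * dot * (1 - c);
  const double ny = y * c + cy * s + ay * dot * (1 - c);
  const double nz = z * c + cz * s + az * dot * (1 - c);
  x = nx; y = ny; z = nz;
}

static inline void random_axis(double &ax, double &ay, double &az) {
  double n2;
  do {
    ax = 2 * unif_rand() - 1;
    ay = 2 * unif_rand() - 1;
    az = 2 * unif_rand() - 1;
    n2 = ax * ax + ay * ay + az * az;
  } while (n2 > 1.0 || n2 < 1e-12);
  const double inv = 1.0 / std::sqrt(n2);
  ax *= inv; ay *= inv; az *= inv;
}

// [[Rcpp::export]]
List wlc_sample_cpp(int n_samples, double contour, double lp, double ell_target,
                    double bead_r, int attachment, int burnin_sweeps,
                    int thin_sweeps, double max_angle) {
  const int N = std::max(2, (int)std::lround(contour / ell_target));
  const double ell = contour / N;
  const double kappa = lp / ell;

  std::vector<double> tx(N, 0.0), ty(N, 0.0), tz(N, 1.0);
  std::vector<double> px(N), py(N), pz(N);
  double ux = 0.0, uy = 0.0, uz = 1.0;  // bead orientation (swivel mode)

  auto energy = [&](const std::vector<double> &x, const std::vector<double> &y,
                    const std::vector<double> &z) {
    double e = 0.0;
    for (int i = 0; i + 1 < N; ++i)
      e += kappa * (1.0 - (x[i] * x[i + 1] + y[i] * y[i + 1] + z[i] * z[i + 1]));
    return e;
  };
  auto feasible = [&](const std::vector<double> &x, const std::vector<double> &y,
                      const std::vector<double> &z, double buz) {
    double vx = 0.0, vy = 0.0, vz = 0.0;
    for (int i = 0; i < N; ++i) {
      vx += ell * x[i]; vy += ell * y[i]; vz += ell * z[i];
      if (vz < 0.0) return false;
    }
    const double cz = (attachment == 0) ? vz + bead_r * z[N - 1]
                                        : vz + bead_r * buz;
    return cz >= bead_r;
  };

  double E = energy(tx, ty, tz);
  NumericVector ox(n_samples), oy(n_samples), oz(n_samples);
  const long total = burnin_sweeps + (long)n_samples * thin_sweeps;
  int taken = 0;
  long acc = 0, att = 0;

  for (long sweep = 0; sweep < total; ++sweep) {
    const int moves = (attachment == 1) ? N + 1 : N;
    for (int m = 0; m < moves; ++m) {
      double ax, ay, az;
      random_axis(ax, ay, az);
      const double ang = (2 * unif_rand() - 1) * max_angle;

      if (attachment == 1 && m == moves - 1) {
        // bead swivel move: no bending energy, accept on feasibility
        double qx = ux, qy = uy, qz = uz;
        rotate(ax, ay, az, ang, qx, qy, qz);
        if (feasible(tx, ty, tz, qz)) { ux = qx; uy = qy; uz = qz; }
        continue;
      }

      // pivot: rotate tangents j..N-1 about a random axis
      int j = (int)(unif_rand() * N);
      if (j >= N) j = N - 1;
      px = tx; py = ty; pz = tz;
      for (int i = j; i < N; ++i) rotate(ax, ay, az, ang, px[i], py[i], pz[i]);
      const double Ep = energy(px, py, pz);
      ++att;
      if ((Ep <= E || unif_rand() < std::exp(E - Ep)) && feasible(px, py, pz, uz)) {
        tx = px; ty = py; tz = pz; E = Ep;
        ++acc;
      }
    }
    if (sweep >= burnin_sweeps &&
        ((sweep - burnin_sweeps) % thin_sweeps) == 0 && taken < n_samples) {
      double vx = 0.0, vy = 0.0, vz = 0.0;
      for (int i = 0; i < N; ++i) { vx += ell * tx[i]; vy += ell * ty[i]; vz += ell * tz[i]; }
      if (attachment == 0) {
        ox[taken] = vx + bead_r * tx[N - 1];
        oy[taken] = vy + bead_r * ty[N - 1];
        oz[taken] = vz + bead_r * tz[N - 1];
      } else {
        ox[taken] = vx + bead_r * ux;
        oy[taken] = vy + bead_r * uy;
        oz[taken] = vz + bead_r * uz;
      }
      ++taken;
    }
  }

  return List::create(_["x"] = ox, _["y"] = oy, _["z"] = oz,
                      _["n_segments"] = N, _["segment_length"] = ell,
                      _["acceptance_rate"] = att > 0 ? (double)acc / att : NA_REAL);
}
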