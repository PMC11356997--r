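#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Capsule vs cylindrical wall: the radial distance from the channel axis is
// convex along the core segment, so the maximum is attained at an endpoint.
static inline bool capsule_hits_wall(double x, double y,
                                     double ux, double uy,
                                     double h, double r, double R) {
  double e1x = x + h * ux, e1y = y + h * uy;
  double e2x = x - h * ux, e2y = y - h * uy;
  double q1 = e1x * e1x + e1y * e1y;
  double q2 = e2x * e2x + e2y * e2y;
  return std::sqrt(q1 > q2 ? q1 : q2) + r > R;
}

// One full trajectory of the confined random walk. Consumes R's global RNG
// stream (set.seed upstream) in a fixed per-step order: translation normals
// (3), rotation axis normals (3, redrawn if degenerate), rotation angle (1).
// The absorbing step skips the rotation sub-step entirely so that trajectories
// replay identically against the pure-R reference stepper.
// [[Rcpp::export]]
List run_trajectory_cpp(double l, double r, double L, double sigma_x,
                        double Mxx, double Mzz,
                        double max_steps, int record_stride,
                        bool record_positions) {
  const double h = l / 2.0, R = 0.5;
  double x = 0.0, y = 0.0, z = 0.0;
  double ux = 0.0, uy = 0.0, uz = 1.0;
  long long t = 0;
  const long long tmax = (long long)max_steps;
  long long acc_t = 0, acc_r = 0;
  bool absorbed = false;

  std::vector<double> rec;
  if (record_positions) {
    rec.reserve(7 * (size_t)(tmax / record_stride < 4096 ? tmax / record_stride + 2
                                                         : 4096));
    double r0[7] = {0, 0, 0, 0, 0, 0, 1};
    rec.insert(rec.end(), r0, r0 + 7);
  }

  while (t < tmax) {
    // translation attempt: reject wall hits and centre z < 0 (reflecting end)
    double nx = x + sigma_x * norm_rand();
    double ny = y + sigma_x * norm_rand();
    double nz = z + sigma_x * norm_rand();
    if (nz >= 0.0 && !capsule_hits_wall(nx, ny, ux, uy, h, r, R)) {
      x = nx; y = ny; z = nz;
      ++acc_t;
      if (z >= L) {        // absorbed at the exit; this step still counts
        ++t;
        absorbed = true;
        break;
      }
    }

    // rotation attempt: uniform axis, equipartition-scaled normal angle
    double ax, ay, az, an;
    do {
      ax = norm_rand(); ay = norm_rand(); az = norm_rand();
      an = std::sqrt(ax * ax + ay * ay + az * az);
    } while (an < 1e-12);
    ax /= an; ay /= an; az /= an;
    double ca = ax * ux + ay * uy + az * uz;
    double mom = Mxx + (Mzz - Mxx) * ca * ca;
    double phi = (sigma_x / std::sqrt(mom)) * norm_rand();
    double c = std::cos(phi), s = std::sin(phi);
    double cx = ay * uz - az * uy;
    double cy = az * ux - ax * uz;
    double cz = ax * uy - ay * ux;
    double k = ca * (1.0 - c);
    double vx = ux * c + cx * s + ax * k;
    double vy = uy * c + cy * s + ay * k;
    double vz = uz * c + cz * s + az * k;
    double vn = std::sqrt(vx * vx + vy * vy + vz * vz);
    vx /= vn; vy /= vn; vz /= vn;
    if (!capsule_hits_wall(x, y, vx, vy, h, r, R)) {
      ux = vx; uy = vy; uz = vz;
      ++acc_r;
    }

    ++t;  // rejected jumps count toward time too
    if (record_positions && t % record_stride == 0) {
      double ri[7] = {(double)t, x, y, z, ux, uy, uz};
      rec.insert(rec.end(), ri, ri + 7);
    }
  }

  double theta = NA_REAL, fpt = NA_REAL;
  if (absorbed) {
    double cz_ = uz;
    if (cz_ > 1.0) cz_ = 1.0;
    if (cz_ < -1.0) cz_ = -1.0;
    theta = std::acos(cz_);
    fpt = (double)t;
  }

  NumericMatrix positions(0, 7);
  if (record_positions) {
    size_t nrec = rec.size() / 7;
    positions = NumericMatrix((int)nrec, 7);
    for (size_t i = 0; i < nrec; ++i)
      for (int j = 0; j < 7; ++j)
        positions(i, j) = rec[7 * i + j];
    colnames(positions) = CharacterVector::create("t", "x", "y", "z",
                                                  "ux", "uy", "uz");
  }

  return List::create(
    _["fpt"] = fpt,
    _["censored"] = !absorbed,
    _["exit_theta"] = theta,
    _["steps"] = (double)t,
    _["accepted_translations"] = (double)acc_t,
    _["accepted_rotations"] = (double)acc_r,
    _["final_state"] = NumericVector::create(x, y, z, ux, uy, uz),
    _["positions"] = positions
  );
}
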