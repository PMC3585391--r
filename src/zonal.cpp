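#include <Rcpp.h>
using namespace Rcpp;

// Constant-speed zonal model: repulsion / orientation / attraction zones,
// a blind sector behind each agent, a turn-rate limit and Gaussian angular
// noise on the desired direction. Synchronous update; uses R's RNG so runs
// are reproducible with set.seed().

// [[Rcpp::export]]
List zonal_run_cpp(NumericMatrix pos0, NumericMatrix head0, int steps,
                   double speed, double dt, double r_rep, double r_ori,
                   double r_att, double cos_blind, double turn_max,
                   double noise_sd, bool record) {
  const int n = pos0.nrow();
  std::vector<double> x(n), y(n), hx(n), hy(n), nhx(n), nhy(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1);
    hx[i] = head0(i, 0); hy[i] = head0(i, 1);
  }
  const double rr2 = r_rep * r_rep, ro2 = r_ori * r_ori, ra2 = r_att * r_att;
  NumericMatrix series(record ? steps : 0, 2);

  for (int t = 0; t < steps; ++t) {
    for (int i = 0; i < n; ++i) {
      double repx = 0, repy = 0, orix = 0, oriy = 0, attx = 0, atty = 0;
      bool has_rep = false, has_ori = false, has_att = false;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        const double dx = x[j] - x[i], dy = y[j] - y[i];
        const double d2 = dx * dx + dy * dy;
        if (d2 > ra2 || d2 < 1e-18) continue;
        const double d = std::sqrt(d2);
        // blind sector applies to every zone: unseen fish trigger nothing
        if (hx[i] * dx + hy[i] * dy < cos_blind * d) continue;
        if (d2 <= rr2) {
          repx -= dx / d; repy -= dy / d; has_rep = true;
        } else if (d2 <= ro2) {
          orix += hx[j]; oriy += hy[j]; has_ori = true;
        } else {
          attx += dx / d; atty += dy / d; has_att = true;
        }
      }
      double ddx = 0, ddy = 0;
      bool have = false;
      if (has_rep) {             // repulsion overrides everything
        ddx = repx; ddy = repy;
        have = ddx * ddx + ddy * ddy > 1e-18;
      } else if (has_ori || has_att) {
        // normalized alignment and attraction responses, averaged when both
        // zones are populated
        if (has_ori) {
          const double m = std::sqrt(orix * orix + oriy * oriy);
          if (m > 1e-12) { ddx += orix / m; ddy += oriy / m; }
        }
        if (has_att) {
          const double m = std::sqrt(attx * attx + atty * atty);
          if (m > 1e-12) { ddx += attx / m; ddy += atty / m; }
        }
        have = ddx * ddx + ddy * ddy > 1e-18;
      }
      const double cur = std::atan2(hy[i], hx[i]);
      double target = have ? std::atan2(ddy, ddx) : cur;
      target += R::rnorm(0.0, noise_sd);
      double dth = target - cur;
      while (dth > M_PI) dth -= 2 * M_PI;
      while (dth < -M_PI) dth += 2 * M_PI;
      if (dth > turn_max) dth = turn_max;
      else if (dth < -turn_max) dth = -turn_max;
      const double na = cur + dth;
      nhx[i] = std::cos(na); nhy[i] = std::sin(na);
    }
    for (int i = 0; i < n; ++i) {
      hx[i] = nhx[i]; hy[i] = nhy[i];
      x[i] += speed * hx[i] * dt;
      y[i] += speed * hy[i] * dt;
    }
    if (record) {
      double sx = 0, sy = 0, cx = 0, cy = 0;
      for (int i = 0; i < n; ++i) { sx += hx[i]; sy += hy[i]; cx += x[i]; cy += y[i]; }
      cx /= n; cy /= n;
      double cr = 0;
      for (int i = 0; i < n; ++i) {
        const double rx = x[i] - cx, ry = y[i] - cy;
        const double d = std::sqrt(rx * rx + ry * ry);
        if (d > 0) cr += (rx * hy[i] - ry * hx[i]) / d;
      }
      series(t, 0) = std::sqrt(sx * sx + sy * sy) / n;  // O_p
      series(t, 1) = cr / n;                            // signed rotation
    }
  }
  NumericMatrix pos_out(n, 2), head_out(n, 2);
  for (int i = 0; i < n; ++i) {
    pos_out(i, 0) = x[i]; pos_out(i, 1) = y[i];
    head_out(i, 0) = hx[i]; head_out(i, 1) = hy[i];
  }
  return List::create(_["positions"] = pos_out, _["headings"] = head_out,
                      _["series"] = series);
}
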