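#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter with initial state zi.
// b, a are padded to equal length in R; a[0] == 1 assumed after normalisation.
// [[Rcpp::export]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x,
                         NumericVector zi) {
  int m = std::max(b.size(), a.size()) - 1;
  std::vector<double> bb(m + 1, 0.0), aa(m + 1, 0.0), z(m + 1, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  double a0 = aa[0];
  for (int i = 0; i <= m; ++i) { bb[i] /= a0; aa[i] /= a0; }
  for (int i = 0; i < zi.size() && i < m; ++i) z[i] = zi[i];
  int n = x.size();
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xn = x[i];
    double yn = bb[0] * xn + z[0];
    for (int j = 0; j < m; ++j)
      z[j] = bb[j + 1] * xn + z[j + 1] - aa[j + 1] * yn;
    y[i] = yn;
  }
  return y;
}

// Feedback-controlled single-link inverted pendulum standing on a tilting
// platform, integrated with fixed-step classical RK4. Units: rad, s, N*m.
//
//   J * theta'' = mgh * theta - T(t)
//   T(t) = Kp * e(t - tau) + Kd * de/dt(t - tau) + noise(t)
//   e(t) = w_prop * (theta_leg - theta_platform) + w_vv * theta
//   theta_leg = r_ankle * theta + wiggle
//
// platform_mode: 0 fixed (theta_p = 0), 1 sway-referenced (first-order lag
// tracking theta_leg, coefficient servo_alpha per step; alpha = 1 means
// perfect tracking), 2 prescribed tilt (stimulus vector).
// The delayed error and its derivative come from a sample ring buffer.
// Throws if |theta| exceeds fall_threshold, reporting the time.
// [[Rcpp::export]]
List simulate_pendulum_cpp(int n, double dt, double J, double mgh,
                           double Kp, double Kd, int delay_steps,
                           double w_prop, double w_vv, double r_ankle,
                           int platform_mode, double servo_alpha,
                           NumericVector stimulus, NumericVector wiggle,
                           NumericVector noise,
                           double theta0, double omega0,
                           double fall_threshold) {
  NumericVector theta(n), omega(n), theta_p(n), torque(n), err(n);
  double th = theta0, om = omega0, tp = 0.0;
  for (int i = 0; i < n; ++i) {
    double wig = (wiggle.size() == n) ? wiggle[i] : 0.0;
    double th_leg = r_ankle * th + wig;
    if (platform_mode == 1) {
      tp += servo_alpha * (th_leg - tp);
    } else if (platform_mode == 2) {
      tp = stimulus[i];
    } else {
      tp = 0.0;
    }
    double e = w_prop * (th_leg - tp) + w_vv * th;
    theta[i] = th; omega[i] = om; theta_p[i] = tp; err[i] = e;

    double e_del = 0.0, edot_del = 0.0;
    int k = i - delay_steps;
    if (k >= 0) {
      e_del = err[k];
      if (k >= 1) edot_del = (err[k] - err[k - 1]) / dt;
    }
    double T = Kp * e_del + Kd * edot_del + noise[i];
    torque[i] = T;

    // RK4 with torque held constant over the step
    double k1t = om,                      k1o = (mgh * th - T) / J;
    double k2t = om + 0.5 * dt * k1o,     k2o = (mgh * (th + 0.5 * dt * k1t) - T) / J;
    double k3t = om + 0.5 * dt * k2o,     k3o = (mgh * (th + 0.5 * dt * k2t) - T) / J;
    double k4t = om + dt * k3o,           k4o = (mgh * (th + dt * k3t) - T) / J;
    th += dt / 6.0 * (k1t + 2 * k2t + 2 * k3t + k4t);
    om += dt / 6.0 * (k1o + 2 * k2o + 2 * k3o + k4o);

    if (std::abs(th) > fall_threshold) {
      stop("simulated stander fell at t = %.2f s (|theta| > %.3g rad): unstable configuration",
           (i + 1) * dt, fall_threshold);
    }
  }
  return List::create(_["theta"] = theta, _["omega"] = omega,
                      _["theta_platform"] = theta_p, _["torque"] = torque);
}
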