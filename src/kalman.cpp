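#include <Rcpp.h>
using namespace Rcpp;

// State-space evaluation of the exact Gaussian likelihood of stationary
// movement processes observed with independent per-fix measurement error.
// Axes are filtered independently and share parameters (isotropy), so all
// routines work on one coordinate axis; the R wrappers sum over axes.
//
// Models:
//   OU  : scalar state, transition phi = exp(-dt/tau_pos),
//         innovation variance sigma2 * (1 - phi^2).
//   OUF : CAR(2) position+velocity state with characteristic roots
//         -1/tau_pos and -1/tau_vel; stationary position ACF
//         sigma2 * (tau_p e^(-h/tau_p) - tau_v e^(-h/tau_v)) / (tau_p - tau_v).
// IID is handled in closed form on the R side.

static const double LOG2PI = 1.8378770664093454836;

// [[Rcpp::export]]
double kalman_ou_loglik(NumericVector y, NumericVector dt, double mu,
                        double sigma2, double tau, NumericVector obsvar) {
  int n = y.size();
  double ll = 0.0;
  double xhat = 0.0;      // state mean, centered on mu
  double P = sigma2;      // stationary prior variance
  for (int k = 0; k < n; k++) {
    double v = (y[k] - mu) - xhat;
    double S = P + obsvar[k];
    if (!(S > 0.0) || !R_finite(S)) return R_NegInf;
    ll -= 0.5 * (LOG2PI + std::log(S) + v * v / S);
    double K = P / S;
    xhat += K * v;
    P *= (1.0 - K);
    if (k < n - 1) {
      double phi = std::exp(-dt[k] / tau);
      xhat *= phi;
      P = phi * phi * P + sigma2 * (1.0 - phi * phi);
    }
  }
  return ll;
}

// [[Rcpp::export]]
double kalman_ouf_loglik(NumericVector y, NumericVector dt, double mu,
                         double sigma2, double tau_pos, double tau_vel,
                         NumericVector obsvar) {
  int n = y.size();
  if (tau_vel >= tau_pos) return R_NegInf;
  double r1 = -1.0 / tau_pos, r2 = -1.0 / tau_vel;
  double a0 = 1.0 / (tau_pos * tau_vel);
  double sv = sigma2 * a0;  // stationary velocity variance
  double ll = 0.0;
  // state mean (x, v) centered on (mu, 0); covariance P
  double m0 = 0.0, m1 = 0.0;
  double P00 = sigma2, P01 = 0.0, P11 = sv;
  for (int k = 0; k < n; k++) {
    double v = (y[k] - mu) - m0;
    double S = P00 + obsvar[k];
    if (!(S > 0.0) || !R_finite(S)) return R_NegInf;
    ll -= 0.5 * (LOG2PI + std::log(S) + v * v / S);
    double K0 = P00 / S, K1 = P01 / S;
    m0 += K0 * v;
    m1 += K1 * v;
    double nP00 = P00 - K0 * P00;
    double nP01 = P01 - K0 * P01;
    double nP11 = P11 - K1 * P01;
    P00 = nP00; P01 = nP01; P11 = nP11;
    if (k < n - 1) {
      double t = dt[k];
      double e1 = std::exp(r1 * t), e2 = std::exp(r2 * t);
      double d = r1 - r2;
      double F00 = (r1 * e2 - r2 * e1) / d;
      double F01 = (e1 - e2) / d;
      double F10 = -a0 * F01;
      double F11 = (r1 * e1 - r2 * e2) / d;
      double nm0 = F00 * m0 + F01 * m1;
      double nm1 = F10 * m0 + F11 * m1;
      // Phi P Phi^T
      double A00 = F00 * P00 + F01 * P01;
      double A01 = F00 * P01 + F01 * P11;
      double A10 = F10 * P00 + F11 * P01;
      double A11 = F10 * P01 + F11 * P11;
      double PP00 = A00 * F00 + A01 * F01;
      double PP01 = A00 * F10 + A01 * F11;
      double PP11 = A10 * F10 + A11 * F11;
      // Q = Pinf - Phi Pinf Phi^T, Pinf = diag(sigma2, sv)
      double Q00 = sigma2 - (F00 * F00 * sigma2 + F01 * F01 * sv);
      double Q01 = 0.0 - (F00 * F10 * sigma2 + F01 * F11 * sv);
      double Q11 = sv - (F10 * F10 * sigma2 + F11 * F11 * sv);
      m0 = nm0; m1 = nm1;
      P00 = PP00 + Q00;
      P01 = PP01 + Q01;
      P11 = PP11 + Q11;
    }
  }
  return ll;
}

// Exact stationary simulation of one axis of an OU position process.
// z: iid standard normals, length n (z[0] seeds the stationary start).
// [[Rcpp::export]]
NumericVector sim_ou_axis(NumericVector z, NumericVector dt, double mu,
                          double sigma2, double tau) {
  int n = z.size();
  NumericVector x(n);
  double sd0 = std::sqrt(sigma2);
  x[0] = mu + sd0 * z[0];
  for (int k = 1; k < n; k++) {
    double phi = std::exp(-dt[k - 1] / tau);
    double s = std::sqrt(sigma2 * (1.0 - phi * phi));
    x[k] = mu + phi * (x[k - 1] - mu) + s * z[k];
  }
  return x;
}

// Exact stationary simulation of one axis of the CAR(2) (OUF) process.
// z1, z2: iid standard normals, length n. Returns positions.
// [[Rcpp::export]]
NumericVector sim_ouf_axis(NumericVector z1, NumericVector z2,
                           NumericVector dt, double mu, double sigma2,
                           double tau_pos, double tau_vel) {
  int n = z1.size();
  NumericVector x(n);
  double r1 = -1.0 / tau_pos, r2 = -1.0 / tau_vel;
  double a0 = 1.0 / (tau_pos * tau_vel);
  double sv = sigma2 * a0;
  // stationary start
  double s0 = std::sqrt(sigma2) * z1[0];
  double v0 = std::sqrt(sv) * z2[0];
  x[0] = mu + s0;
  for (int k = 1; k < n; k++) {
    double t = dt[k - 1];
    double e1 = std::exp(r1 * t), e2 = std::exp(r2 * t);
    double d = r1 - r2;
    double F00 = (r1 * e2 - r2 * e1) / d;
    double F01 = (e1 - e2) / d;
    double F10 = -a0 * F01;
    double F11 = (r1 * e1 - r2 * e2) / d;
    double Q00 = sigma2 - (F00 * F00 * sigma2 + F01 * F01 * sv);
    double Q01 = 0.0 - (F00 * F10 * sigma2 + F01 * F11 * sv);
    double Q11 = sv - (F10 * F10 * sigma2 + F11 * F11 * sv);
    // Cholesky of Q (2x2)
    double L00 = std::sqrt(std::max(Q00, 0.0));
    double L10 = (L00 > 0.0) ? Q01 / L00 : 0.0;
    double L11 = std::sqrt(std::max(Q11 - L10 * L10, 0.0));
    double ns = F00 * s0 + F01 * v0 + L00 * z1[k];
    double nv = F10 * s0 + F11 * v0 + L10 * z1[k] + L11 * z2[k];
    s0 = ns; v0 = nv;
    x[k] = mu + s0;
  }
  return x;
}
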