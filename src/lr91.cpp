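// Fused pointwise Luo-Rudy 1991 update: advances the gate/calcium state at
// every nodal point by one step (forward Euler or Rush-Larsen) and returns
// the ionic current evaluated at the updated state, in one pass. This is
// the hot path of the tissue time loop; the R implementation in
// cell-models.R defines the model and serves as its cross-check.

#include <Rcpp.h>
using namespace Rcpp;

static inline double sigmoid(double x) {
  return 1.0 / (1.0 + std::exp(-x));
}

// [[Rcpp::export]]
List lr91_fused_step(NumericVector u, NumericMatrix W, double dt, bool noble,
                     double blend_k, int method) {
  const int n = u.size();
  if (W.nrow() != n || W.ncol() != 7)
    stop("u and W are not congruent");
  NumericMatrix Wn(n, 7);
  NumericVector I(n);

  const double RTF = 8314.0 * 310.0 / 96484.6;
  const double E_Na = RTF * std::log(140.0 / 18.0);
  const double E_K = RTF * std::log((5.4 + 0.01833 * 140.0) /
                                    (145.0 + 0.01833 * 18.0));
  const double E_K1 = RTF * std::log(5.4 / 145.0);
  const double g_K = 0.282;   // sqrt(Ko/5.4) = 1
  const double g_K1 = 0.6047;

  for (int i = 0; i < n; ++i) {
    const double V = u[i];
    // gate rates --------------------------------------------------------
    double x = V + 47.13;
    double a_m = (std::fabs(x) < 1e-7)
      ? 0.32 * (10.0 + x / 2.0)
      : 0.32 * x / (1.0 - std::exp(-0.1 * x));
    double b_m = 0.08 * std::exp(-V / 11.0);

    double a_h_lo = 0.135 * std::exp(-(80.0 + V) / 6.8);
    double b_h_lo = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
    double b_h_hi = 1.0 / (0.13 * (1.0 + std::exp((V + 10.66) / -11.1)));
    double a_j_lo = (-1.2714e5 * std::exp(0.2444 * V) -
                     3.474e-5 * std::exp(-0.04391 * V)) *
      (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    double b_j_lo = 0.1212 * std::exp(-0.01052 * V) /
      (1.0 + std::exp(-0.1378 * (V + 40.14)));
    double b_j_hi = 0.3 * std::exp(-2.535e-7 * V) /
      (1.0 + std::exp(-0.1 * (V + 32.0)));

    double a_h, b_h, a_j, b_j;
    if (!noble) {
      if (V < -40.0) {
        a_h = a_h_lo; b_h = b_h_lo; a_j = a_j_lo; b_j = b_j_lo;
      } else {
        a_h = 0.0; b_h = b_h_hi; a_j = 0.0; b_j = b_j_hi;
      }
    } else {
      double s = sigmoid((V + 40.0) / blend_k);
      double sm = 1.0 - s;
      a_h = sm * a_h_lo;
      b_h = sm * b_h_lo + s * b_h_hi;
      a_j = sm * a_j_lo;
      b_j = sm * b_j_lo + s * b_j_hi;
    }

    double a_d = 0.095 * std::exp(-0.01 * (V - 5.0)) /
      (1.0 + std::exp(-0.072 * (V - 5.0)));
    double b_d = 0.07 * std::exp(-0.017 * (V + 44.0)) /
      (1.0 + std::exp(0.05 * (V + 44.0)));
    double a_f = 0.012 * std::exp(-0.008 * (V + 28.0)) /
      (1.0 + std::exp(0.15 * (V + 28.0)));
    double b_f = 0.0065 * std::exp(-0.02 * (V + 30.0)) /
      (1.0 + std::exp(-0.2 * (V + 30.0)));
    double a_X = 0.0005 * std::exp(0.083 * (V + 50.0)) /
      (1.0 + std::exp(0.057 * (V + 50.0)));
    double b_X = 0.0013 * std::exp(-0.06 * (V + 20.0)) /
      (1.0 + std::exp(-0.04 * (V + 20.0)));

    // state update ------------------------------------------------------
    const double m = W(i, 0), h = W(i, 1), j = W(i, 2), d = W(i, 3),
      f = W(i, 4), X = W(i, 5), Cai = W(i, 6);
    if (Cai <= 0)
      stop("non-positive intracellular calcium in slow-inward reversal");
    double E_si = 7.7 - 13.0287 * std::log(Cai);
    double i_si_old = 0.09 * d * f * (V - E_si);

    double mn, hn, jn, dn, fn, Xn;
    if (method == 0) {  // forward Euler
      mn = m + dt * (a_m * (1.0 - m) - b_m * m);
      hn = h + dt * (a_h * (1.0 - h) - b_h * h);
      jn = j + dt * (a_j * (1.0 - j) - b_j * j);
      dn = d + dt * (a_d * (1.0 - d) - b_d * d);
      fn = f + dt * (a_f * (1.0 - f) - b_f * f);
      Xn = X + dt * (a_X * (1.0 - X) - b_X * X);
    } else {            // Rush-Larsen exponential update
      auto rl = [dt](double w, double a, double b) {
        double ab = a + b;
        double winf = (ab > 1e-300) ? a / ab : 0.0;
        return winf + (w - winf) * std::exp(-dt * ab);
      };
      mn = rl(m, a_m, b_m); hn = rl(h, a_h, b_h); jn = rl(j, a_j, b_j);
      dn = rl(d, a_d, b_d); fn = rl(f, a_f, b_f); Xn = rl(X, a_X, b_X);
    }
    double Cain = Cai + dt * (-1e-4 * i_si_old + 0.07 * (1e-4 - Cai));
    Wn(i, 0) = mn; Wn(i, 1) = hn; Wn(i, 2) = jn;
    Wn(i, 3) = dn; Wn(i, 4) = fn; Wn(i, 5) = Xn; Wn(i, 6) = Cain;
    if (Cain <= 0)
      stop("non-positive intracellular calcium in slow-inward reversal");

    // ionic current at (u, w_new) --------------------------------------
    double E_si_n = 7.7 - 13.0287 * std::log(Cain);
    double i_Na = 23.0 * mn * mn * mn * hn * jn * (V - E_Na);
    double i_si = 0.09 * dn * fn * (V - E_si_n);
    double Xi;
    if (V <= -100.0) {
      Xi = 1.0;
    } else if (std::fabs(V + 77.0) < 1e-7) {
      Xi = 2.837 * 0.04 / std::exp(0.04 * (V + 35.0));
    } else {
      Xi = 2.837 * (std::exp(0.04 * (V + 77.0)) - 1.0) /
        ((V + 77.0) * std::exp(0.04 * (V + 35.0)));
    }
    double i_K = g_K * Xn * Xi * (V - E_K);
    double aK1 = 1.02 / (1.0 + std::exp(0.2385 * (V - E_K1 - 59.215)));
    double bK1 = (0.49124 * std::exp(0.08032 * (V - E_K1 + 5.476)) +
                  std::exp(0.06175 * (V - E_K1 - 594.31))) /
      (1.0 + std::exp(-0.5143 * (V - E_K1 + 4.753)));
    double i_K1 = g_K1 * aK1 / (aK1 + bK1) * (V - E_K1);
    double Kp = 1.0 / (1.0 + std::exp((7.488 - V) / 5.98));
    double i_Kp = 0.0183 * Kp * (V - E_K1);
    double i_b = 0.03921 * (V + 59.87);
    I[i] = -(i_Na + i_si + i_K + i_K1 + i_Kp + i_b);

    if (!std::isfinite(I[i]) || !std::isfinite(mn))
      stop("non-finite cell state at point %d", i + 1);
  }
  return List::create(_["W"] = Wn, _["I"] = I);
}
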