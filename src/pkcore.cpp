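#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// One-compartment, first-order absorption and elimination, single oral dose.
// Internal units: mg, L, h -> mg/L. The Ka == k removable singularity is
// bridged by the limiting form D*k*t/V * exp(-k t) inside a relative band.
static inline double conc1(double dose, double t, double cl, double v,
                           double ka) {
  if (t <= 0.0) return 0.0;
  double k = cl / v;
  if (std::fabs(ka - k) < 1e-8 * k) {
    return dose / v * k * t * std::exp(-k * t);
  }
  return dose / v * ka / (ka - k) * (std::exp(-k * t) - std::exp(-ka * t));
}

// [[Rcpp::export(name = ".cpp_profile")]]
NumericVector cpp_profile(NumericVector dose_time, NumericVector dose_amt,
                          NumericVector times, double cl, double v,
                          double ka) {
  int n = times.size(), m = dose_time.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int d = 0; d < m; ++d) {
      double tau = times[i] - dose_time[d];
      if (tau > 0.0) s += conc1(dose_amt[d], tau, cl, v, ka);
    }
    out[i] = s;
  }
  return out;
}

static const double LOG_FLOOR = 1e-12;  // mg/L; far below any observed level
static const double PERIOD = 24.0;      // h; repeat interval of dose groups

// Dosing histories reach the likelihood as dose groups: a first dose at t0
// of amount D repeated nrep times at 24 h intervals (nrep = 1 recovers a
// plain dose event). Within a group the exponentials at successive repeats
// differ by the constant factors q_k = e^{-24k}, q_ka = e^{-24ka}, so the
// superposition sums S = sum_l e^{-k tau_l} etc. accumulate with one
// multiply per repeat instead of one exp per dose. This is exactly the
// naive superposition, just factored.

struct DoseGroups {
  const double* t0;
  const double* amt;
  const int* nrep;
  int m;
};

// Concentration C, first derivatives dC/dk, dC/dka and (optionally) the
// second derivatives d2C/dk2, d2C/dkdka, d2C/dka2 at one time point.
// Per dose group (sums over past repeats l, tau_l = taumin + 24 l):
//   general:  T  = (D/v) ka (S1 - S2)/delta,          delta = ka - k
//             dT/dk  = (D/v) ka (-T1/delta + (S1 - S2)/delta^2)
//             dT/dka = (D/v) ((S1 - S2)(1/delta - ka/delta^2) + ka T2/delta)
//   ka -> k:  T = (D/v) k T1;  dT/dk = -(D/v)(k/2) U1;
//             dT/dka = (D/v)(T1 - (k/2) U1)
// with S = sum e^{-rate tau_l}, T = sum tau_l e^{-rate tau_l},
// U1 = sum tau_l^2 e^{-k tau_l}.
static inline void conc_groups(const DoseGroups& dg, double t, double k,
                               double ka, double v, double qk, double qka,
                               bool want_grad, double& C, double& dCdk,
                               double& dCdka, bool want_hess = false,
                               double* d2C = 0) {
  C = 0.0;
  dCdk = 0.0;
  dCdka = 0.0;
  if (want_hess) d2C[0] = d2C[1] = d2C[2] = 0.0;
  bool singular = std::fabs(ka - k) < 1e-8 * k;
  double del = ka - k;
  for (int g = 0; g < dg.m; ++g) {
    double dt = t - dg.t0[g];
    if (dt <= 0.0) continue;
    int jmax = (int)std::floor(dt / PERIOD - 1e-12);
    if (jmax < 0) jmax = 0;           // 0 < dt < 24
    int jl = jmax < dg.nrep[g] - 1 ? jmax : dg.nrep[g] - 1;
    int r = jl + 1;
    double taumin = dt - PERIOD * jl;
    double w1 = std::exp(-k * taumin);
    double w2 = std::exp(-ka * taumin);
    double S1 = 0.0, S2 = 0.0, T1 = 0.0, T2 = 0.0, U1 = 0.0, U2 = 0.0;
    double tau = taumin;
    for (int l = 0; l < r; ++l) {
      S1 += w1;
      S2 += w2;
      T1 += tau * w1;
      if (want_grad) {
        T2 += tau * w2;
        U1 += tau * tau * w1;
        if (want_hess) U2 += tau * tau * w2;
      }
      w1 *= qk;
      w2 *= qka;
      tau += PERIOD;
    }
    double Dv = dg.amt[g] / v;
    if (singular) {
      C += Dv * k * T1;
      if (want_grad) {
        dCdk += -Dv * k * U1 / 2.0;
        dCdka += Dv * (T1 - k * U1 / 2.0);
      }
      // second derivatives in the removable-singularity band are obtained
      // by finite differences of the Jacobian at the caller level
    } else {
      double B = S1 - S2;
      double id1 = 1.0 / del, id2 = id1 * id1, id3 = id2 * id1;
      C += Dv * ka * B * id1;
      if (want_grad) {
        dCdk += Dv * ka * (-T1 * id1 + B * id2);
        double A1 = id1 - ka * id2;
        dCdka += Dv * (B * A1 + ka * T2 * id1);
        if (want_hess) {
          d2C[0] += Dv * ka * (U1 * id1 - 2.0 * T1 * id2 + 2.0 * B * id3);
          d2C[1] += Dv * ((-T1 * id1 + B * id2) +
                          ka * (T1 * id2 + T2 * id2 - 2.0 * B * id3));
          double A1p = -2.0 * id2 + 2.0 * ka * id3;
          d2C[2] += Dv * (2.0 * T2 * A1 + B * A1p - ka * U2 * id1);
        }
      }
    }
  }
}

// log-predictions for one subject at eta (length 3: CL, V, Ka effects)
static void logpred_eta(const DoseGroups& dg, const double* ot, int n,
                        double tcl, double tv, double tka,
                        const arma::vec& eta, double* out) {
  double cl = tcl * std::exp(eta[0]);
  double v = tv * std::exp(eta[1]);
  double ka = tka * std::exp(eta[2]);
  double k = cl / v;
  double qk = std::exp(-PERIOD * k), qka = std::exp(-PERIOD * ka);
  double C, d1, d2;
  for (int i = 0; i < n; ++i) {
    conc_groups(dg, ot[i], k, ka, v, qk, qka, false, C, d1, d2);
    out[i] = std::log(C > LOG_FLOOR ? C : LOG_FLOOR);
  }
}

// log-predictions plus the analytic Jacobian d log C / d eta.
// Chain rule: dC/dcl = dC/dk / v; dC/dv = -C/v - (k/v) dC/dk;
// d log C / d eta = (param/C) dC/dparam.
static void logpred_grad(const DoseGroups& dg, const double* ot, int n,
                         double tcl, double tv, double tka,
                         const arma::vec& eta, double* logf, arma::mat& J) {
  double cl = tcl * std::exp(eta[0]);
  double v = tv * std::exp(eta[1]);
  double ka = tka * std::exp(eta[2]);
  double k = cl / v;
  double qk = std::exp(-PERIOD * k), qka = std::exp(-PERIOD * ka);
  double C, dCdk, dCdka;
  for (int i = 0; i < n; ++i) {
    conc_groups(dg, ot[i], k, ka, v, qk, qka, true, C, dCdk, dCdka);
    if (C > LOG_FLOOR) {
      logf[i] = std::log(C);
      J(i, 0) = cl * (dCdk / v) / C;
      J(i, 1) = -1.0 - k * dCdk / C;   // v * dC/dv / C
      J(i, 2) = ka * dCdka / C;
    } else {
      logf[i] = std::log(LOG_FLOOR);
      J(i, 0) = J(i, 1) = J(i, 2) = 0.0;
    }
  }
}

// log-prediction, Jacobian and second-derivative tensor K_{i,kl} =
// d2 log C_i / du_k du_l for u = (log CL, log V, log Ka). With
// p = (dC/dk)/C, q = (dC/dka)/C, P = (d2C/dk2)/C - p^2,
// Rm = (d2C/dkdka)/C - p q, Q = (d2C/dka2)/C - q^2, the chain rule for
// k = e^{u1-u2}, ka = e^{u3}, C = (1/v) G(k, ka) gives
//   K11 = P k^2 + p k,  K12 = -(P k^2 + p k),  K22 = P k^2 + p k,
//   K13 = Rm k ka,      K23 = -Rm k ka,        K33 = Q ka^2 + q ka.
// K columns are packed (11, 21, 22, 31, 32, 33). Near the Ka = k
// singularity (relative 1e-4 band, wider than the value band because the
// closed forms lose precision there first) K falls back to central
// differences of the analytic Jacobian.
static void logpred_hess(const DoseGroups& dg, const double* ot, int n,
                         double tcl, double tv, double tka,
                         const arma::vec& eta, double* logf, arma::mat& J,
                         arma::mat& K) {
  double cl = tcl * std::exp(eta[0]);
  double v = tv * std::exp(eta[1]);
  double ka = tka * std::exp(eta[2]);
  double k = cl / v;
  if (std::fabs(ka - k) < 1e-4 * k) {
    logpred_grad(dg, ot, n, tcl, tv, tka, eta, logf, J);
    const double h = 1e-5;
    arma::mat Jp(n, 3), Jm(n, 3);
    arma::vec scratch(n);
    for (int l = 0; l < 3; ++l) {
      arma::vec ep = eta, em = eta;
      ep[l] += h;
      em[l] -= h;
      logpred_grad(dg, ot, n, tcl, tv, tka, ep, scratch.memptr(), Jp);
      logpred_grad(dg, ot, n, tcl, tv, tka, em, scratch.memptr(), Jm);
      arma::mat dJ = (Jp - Jm) / (2.0 * h);
      if (l == 0) {
        K.col(0) = dJ.col(0);
        K.col(1) = dJ.col(1);
        K.col(3) = dJ.col(2);
      } else if (l == 1) {
        K.col(2) = dJ.col(1);
        K.col(4) = dJ.col(2);
      } else {
        K.col(5) = dJ.col(2);
      }
    }
    return;
  }
  double qk = std::exp(-PERIOD * k), qka = std::exp(-PERIOD * ka);
  double C, dCdk, dCdka, d2C[3];
  for (int i = 0; i < n; ++i) {
    conc_groups(dg, ot[i], k, ka, v, qk, qka, true, C, dCdk, dCdka, true,
                d2C);
    if (C > LOG_FLOOR) {
      logf[i] = std::log(C);
      double p = dCdk / C, q = dCdka / C;
      double P = d2C[0] / C - p * p;
      double Rm = d2C[1] / C - p * q;
      double Q = d2C[2] / C - q * q;
      J(i, 0) = cl * (dCdk / v) / C;
      J(i, 1) = -1.0 - k * dCdk / C;
      J(i, 2) = ka * dCdka / C;
      double a = P * k * k + p * k;
      double c = Rm * k * ka;
      K(i, 0) = a;
      K(i, 1) = -a;
      K(i, 2) = a;
      K(i, 3) = c;
      K(i, 4) = -c;
      K(i, 5) = Q * ka * ka + q * ka;
    } else {
      logf[i] = std::log(LOG_FLOOR);
      for (int c2 = 0; c2 < 3; ++c2) J(i, c2) = 0.0;
      for (int c2 = 0; c2 < 6; ++c2) K(i, c2) = 0.0;
    }
  }
}

// [[Rcpp::export(name = ".cpp_logpred_grad")]]
List cpp_logpred_grad(NumericVector dose_t0, NumericVector dose_amt,
                      IntegerVector dose_nrep, NumericVector times,
                      double tcl, double tv, double tka, NumericVector eta) {
  int n = times.size();
  arma::vec e(eta.begin(), 3);
  arma::mat J(n, 3);
  NumericVector lf(n);
  DoseGroups dg{dose_t0.begin(), dose_amt.begin(), dose_nrep.begin(),
                (int)dose_t0.size()};
  logpred_grad(dg, times.begin(), n, tcl, tv, tka, e, lf.begin(), J);
  return List::create(Named("logf") = lf, Named("J") = wrap(J));
}

struct SubjResult {
  arma::vec eta;     // length 3, zeros on inactive effects
  double ofv;
  bool converged;
  arma::vec grad_a;    // dOFV/d log(typical CL, V, Ka)
  double grad_ls2;     // dOFV/d log sigma^2
  arma::vec grad_lw2;  // dOFV/d log omega^2 (zeros on inactive effects)
};

// Inner MAP-eta problem and FOCE/Laplace per-subject objective contribution.
// g(eta) = sum r^2/s2 + sum_active eta_k^2/w2_k, minimized by damped
// Gauss-Newton with the analytic Jacobian, started from eta0 (0 when null).
// OFV_i = g(eta_hat) + n log(2 pi s2) + sum_active log w2 + log det(H),
// H = J'J/s2 + diag(1/w2_active).
// When want_grad is set the exact gradient of the per-subject OFV with
// respect to (log typical params, log sigma^2, log omega^2) is assembled
// at the inner optimum by implicit differentiation of the mode condition
// J'r/s2 = Omega^{-1} eta_hat:
//   d eta_hat/dp = Ht^{-1} dm/dp,  Ht = (J'J - K.r)_AA/s2 + Omega_A^{-1}
// (the exact curvature), while d log det H uses the Gauss-Newton H that
// defines the objective. The g-part collapses by the envelope identity
// to -2 (J'r)_j / s2 for every typical-parameter direction.
static SubjResult subject_foce(const DoseGroups& dg, const double* ot,
                               const double* ly, int n, double tcl,
                               double tv, double tka,
                               const arma::vec& omega2, double sigma2,
                               const double* eta0, bool want_grad = false) {
  SubjResult res;
  res.converged = true;

  std::vector<unsigned int> act;
  for (unsigned int k = 0; k < 3; ++k)
    if (omega2[k] > 0.0) act.push_back(k);
  const int q = act.size();

  arma::vec f(n), ftry(n);
  arma::mat J3(n, 3);
  arma::vec eta = arma::zeros<arma::vec>(3);
  if (eta0) {
    for (int k = 0; k < q; ++k) eta[act[k]] = eta0[act[k]];
  }

  auto objective = [&](const arma::vec& e, arma::vec& fout) {
    logpred_eta(dg, ot, n, tcl, tv, tka, e, fout.memptr());
    double g = 0.0;
    for (int i = 0; i < n; ++i) {
      double ri = ly[i] - fout[i];
      g += ri * ri;
    }
    g /= sigma2;
    for (int k = 0; k < q; ++k)
      g += e[act[k]] * e[act[k]] / omega2[act[k]];
    return g;
  };

  double g = objective(eta, f);

  if (q > 0) {
    double lambda = 1e-4;
    for (int iter = 0; iter < 100; ++iter) {
      logpred_grad(dg, ot, n, tcl, tv, tka, eta, f.memptr(), J3);
      arma::mat J(n, q);
      for (int k = 0; k < q; ++k) J.col(k) = J3.col(act[k]);
      arma::vec r(n);
      for (int i = 0; i < n; ++i) r[i] = ly[i] - f[i];
      arma::vec b = J.t() * r / sigma2;
      arma::mat A = J.t() * J / sigma2;
      for (int k = 0; k < q; ++k) {
        A(k, k) += 1.0 / omega2[act[k]];
        b[k] -= eta[act[k]] / omega2[act[k]];
      }
      bool stepped = false;
      for (int tries = 0; tries < 30; ++tries) {
        arma::mat Ad = A;
        for (int k = 0; k < q; ++k) Ad(k, k) += lambda * A(k, k);
        arma::vec delta;
        if (!arma::solve(delta, Ad, b, arma::solve_opts::likely_sympd)) {
          lambda *= 10.0;
          continue;
        }
        arma::vec etan = eta;
        for (int k = 0; k < q; ++k) etan[act[k]] += delta[k];
        double gn = objective(etan, ftry);
        if (gn <= g) {
          double drop = g - gn;
          eta = etan;
          f = ftry;
          g = gn;
          lambda = std::max(lambda / 3.0, 1e-10);
          stepped = true;
          if (drop < 1e-13 * (1.0 + std::fabs(g))) iter = 100;  // converged
          break;
        }
        lambda *= 10.0;
      }
      if (!stepped) break;  // no downhill step found: at (numerical) optimum
    }
  }

  double ofv = g + n * std::log(2.0 * M_PI * sigma2);
  res.grad_a = arma::zeros<arma::vec>(3);
  res.grad_lw2 = arma::zeros<arma::vec>(3);
  res.grad_ls2 = 0.0;

  arma::mat K6;
  if (want_grad) {
    K6.set_size(n, 6);
    logpred_hess(dg, ot, n, tcl, tv, tka, eta, f.memptr(), J3, K6);
  } else {
    logpred_grad(dg, ot, n, tcl, tv, tka, eta, f.memptr(), J3);
  }
  arma::vec r(n);
  double R = 0.0;
  for (int i = 0; i < n; ++i) {
    r[i] = ly[i] - f[i];
    R += r[i] * r[i];
  }

  if (q > 0) {
    arma::mat J(n, q);
    for (int k = 0; k < q; ++k) J.col(k) = J3.col(act[k]);
    arma::mat H = J.t() * J / sigma2;
    for (int k = 0; k < q; ++k) {
      H(k, k) += 1.0 / omega2[act[k]];
      ofv += std::log(omega2[act[k]]);
    }
    double ldet, sign;
    if (!arma::log_det(ldet, sign, H) || sign <= 0.0) {
      res.converged = false;
      ldet = 0.0;
    }
    ofv += ldet;

    if (want_grad && res.converged) {
      // symmetric-packed K -> full 3x3 per-pair products
      auto Kel = [&](int i, int a, int l) -> double {
        static const int idx[3][3] = {{0, 1, 3}, {1, 2, 4}, {3, 4, 5}};
        return K6(i, idx[a][l]);
      };
      arma::mat JtJ = J3.t() * J3;
      arma::vec Jtr = J3.t() * r;
      arma::mat Kr(3, 3, arma::fill::zeros);
      arma::cube M(3, 3, 3, arma::fill::zeros);  // M(a,b,l)=sum K_{ial}J_{ib}
      for (int i = 0; i < n; ++i) {
        for (int a = 0; a < 3; ++a) {
          for (int l = 0; l < 3; ++l) {
            double kk = Kel(i, a, l);
            Kr(a, l) += kk * r[i];
            for (int b = 0; b < 3; ++b) M(a, b, l) += kk * J3(i, b);
          }
        }
      }
      arma::mat Hinv;
      arma::mat Ht(q, q);
      for (int a = 0; a < q; ++a) {
        for (int b = 0; b < q; ++b) {
          Ht(a, b) = (JtJ(act[a], act[b]) - Kr(act[a], act[b])) / sigma2;
        }
        Ht(a, a) += 1.0 / omega2[act[a]];
      }
      bool ok = arma::inv_sympd(Hinv, H);
      arma::mat HtUse = Ht;
      if (!ok) {
        res.converged = false;
      } else if (arma::rcond(Ht) < 1e-12) {
        HtUse = H;  // exact curvature degenerate: fall back to GN
      }
      if (ok) {
        arma::vec tr3(3);
        for (int l = 0; l < 3; ++l) {
          arma::mat dH(q, q);
          for (int a = 0; a < q; ++a) {
            for (int b = 0; b < q; ++b) {
              dH(a, b) = (M(act[a], act[b], l) + M(act[b], act[a], l)) /
                         sigma2;
            }
          }
          tr3[l] = arma::trace(Hinv * dH);
        }
        arma::mat G3 = Kr - JtJ;
        for (int j = 0; j < 3; ++j) {
          arma::vec rhs(q);
          for (int a = 0; a < q; ++a) rhs[a] = G3(act[a], j) / sigma2;
          arma::vec de = arma::solve(HtUse, rhs);
          double gj = -2.0 * Jtr[j] / sigma2 + tr3[j];
          for (int a = 0; a < q; ++a) gj += tr3[act[a]] * de[a];
          res.grad_a[j] = gj;
        }
        // log sigma^2
        arma::mat JtJA(q, q);
        for (int a = 0; a < q; ++a) {
          for (int b = 0; b < q; ++b) JtJA(a, b) = JtJ(act[a], act[b]);
        }
        arma::vec rhs(q);
        for (int a = 0; a < q; ++a) {
          rhs[a] = -eta[act[a]] / omega2[act[a]];
        }
        arma::vec de = arma::solve(HtUse, rhs);
        double gs = -R / sigma2 + n - arma::trace(Hinv * JtJA) / sigma2;
        for (int a = 0; a < q; ++a) gs += tr3[act[a]] * de[a];
        res.grad_ls2 = gs;
        // log omega^2 (active)
        for (int kk = 0; kk < q; ++kk) {
          int kg = act[kk];
          arma::vec rhs2(q, arma::fill::zeros);
          rhs2[kk] = eta[kg] / omega2[kg];
          arma::vec de2 = arma::solve(HtUse, rhs2);
          double gw = -eta[kg] * eta[kg] / omega2[kg] + 1.0 -
                      Hinv(kk, kk) / omega2[kg];
          for (int a = 0; a < q; ++a) gw += tr3[act[a]] * de2[a];
          res.grad_lw2[kg] = gw;
        }
      }
    }
  } else if (want_grad) {
    for (int j = 0; j < 3; ++j) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += J3(i, j) * r[i];
      res.grad_a[j] = -2.0 * s / sigma2;
    }
    res.grad_ls2 = -R / sigma2 + n;
  }
  res.eta = eta;
  res.ofv = ofv;
  return res;
}

// Whole-dataset FOCE objective. Subjects are passed flattened with 0-based
// offset pointers (dose_ptr/obs_ptr of length n_subjects + 1); the dose
// arrays are dose groups (first-dose time, amount, number of 24 h repeats).
// eta_init (ns x 3), when given, is a FIXED per-subject starting point for
// the inner solver (e.g. the parent fit's EBEs when refitting bootstrap
// resamples); it must not depend on the evaluation history so the
// objective stays a pure function of its arguments.
// [[Rcpp::export(name = ".cpp_foce_ofv")]]
List cpp_foce_ofv(NumericVector dose_t0, NumericVector dose_amt,
                  IntegerVector dose_nrep, IntegerVector dose_ptr,
                  NumericVector obs_time, NumericVector logy,
                  IntegerVector obs_ptr, NumericVector tcl,
                  NumericVector tv, NumericVector tka,
                  NumericVector omega2, double sigma2, bool want_eta,
                  Nullable<NumericMatrix> eta_init = R_NilValue) {
  const int ns = tcl.size();
  arma::vec w2(3);
  for (int k = 0; k < 3; ++k) w2[k] = omega2[k];
  NumericMatrix ei = eta_init.isNotNull() ? NumericMatrix(eta_init)
                                          : NumericMatrix(0, 3);
  double total = 0.0;
  NumericMatrix etas(want_eta ? ns : 0, 3);
  LogicalVector conv(want_eta ? ns : 0);
  bool all_ok = true;
  for (int s = 0; s < ns; ++s) {
    int d0 = dose_ptr[s], d1 = dose_ptr[s + 1];
    int o0 = obs_ptr[s], o1 = obs_ptr[s + 1];
    DoseGroups dg{dose_t0.begin() + d0, dose_amt.begin() + d0,
                  dose_nrep.begin() + d0, d1 - d0};
    double e0[3];
    if (ei.nrow() == ns) {
      for (int k = 0; k < 3; ++k) e0[k] = ei(s, k);
    }
    SubjResult r = subject_foce(dg, obs_time.begin() + o0,
                                logy.begin() + o0, o1 - o0, tcl[s], tv[s],
                                tka[s], w2, sigma2,
                                ei.nrow() == ns ? e0 : (double*)nullptr);
    total += r.ofv;
    all_ok = all_ok && r.converged;
    if (want_eta) {
      for (int k = 0; k < 3; ++k) etas(s, k) = r.eta[k];
      conv[s] = r.converged;
    }
  }
  List out = List::create(Named("ofv") = total, Named("ok") = all_ok);
  if (want_eta) {
    out["eta"] = etas;
    out["subject_ok"] = conv;
  }
  return out;
}

// Exact analytic gradient of the whole-dataset FOCE objective. Returns the
// per-subject gradient with respect to the log individual typical
// parameters (for the covariate chain rule in R) plus the summed gradients
// for log sigma^2 and log omega^2.
// [[Rcpp::export(name = ".cpp_foce_grad")]]
List cpp_foce_grad(NumericVector dose_t0, NumericVector dose_amt,
                   IntegerVector dose_nrep, IntegerVector dose_ptr,
                   NumericVector obs_time, NumericVector logy,
                   IntegerVector obs_ptr, NumericVector tcl,
                   NumericVector tv, NumericVector tka,
                   NumericVector omega2, double sigma2,
                   Nullable<NumericMatrix> eta_init = R_NilValue) {
  const int ns = tcl.size();
  arma::vec w2(3);
  for (int k = 0; k < 3; ++k) w2[k] = omega2[k];
  NumericMatrix ei = eta_init.isNotNull() ? NumericMatrix(eta_init)
                                          : NumericMatrix(0, 3);
  double total = 0.0, gls2 = 0.0;
  arma::vec glw2(3, arma::fill::zeros);
  NumericMatrix ga(ns, 3);
  bool all_ok = true;
  for (int s = 0; s < ns; ++s) {
    int d0 = dose_ptr[s], d1 = dose_ptr[s + 1];
    int o0 = obs_ptr[s], o1 = obs_ptr[s + 1];
    DoseGroups dg{dose_t0.begin() + d0, dose_amt.begin() + d0,
                  dose_nrep.begin() + d0, d1 - d0};
    double e0[3];
    if (ei.nrow() == ns) {
      for (int k = 0; k < 3; ++k) e0[k] = ei(s, k);
    }
    SubjResult r = subject_foce(dg, obs_time.begin() + o0,
                                logy.begin() + o0, o1 - o0, tcl[s], tv[s],
                                tka[s], w2, sigma2,
                                ei.nrow() == ns ? e0 : (double*)nullptr,
                                true);
    total += r.ofv;
    all_ok = all_ok && r.converged;
    for (int k = 0; k < 3; ++k) ga(s, k) = r.grad_a[k];
    gls2 += r.grad_ls2;
    glw2 += r.grad_lw2;
  }
  return List::create(Named("ofv") = total, Named("ok") = all_ok,
                      Named("grad_a") = ga, Named("grad_ls2") = gls2,
                      Named("grad_lw2") = wrap(glw2));
}
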