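// Numerical two-state Bloch-McConnell propagators for CPMG and spin-lock
// relaxation dispersion.  The 2x2 single-quantum / multiple-quantum blocks
// use an analytic complex matrix exponential; the 6x6 rotating-frame
// evolution uses Armadillo's expmat / eig_gen.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

typedef std::complex<double> cx;

// row-major 2x2 complex matrix: [[a, b], [c, d]]
struct M2 {
  cx a, b, c, d;
};

static inline M2 mmul(const M2 &x, const M2 &y) {
  M2 r;
  r.a = x.a * y.a + x.b * y.c;
  r.b = x.a * y.b + x.b * y.d;
  r.c = x.c * y.a + x.d * y.c;
  r.d = x.c * y.b + x.d * y.d;
  return r;
}

static inline M2 mconj(const M2 &x) {
  M2 r;
  r.a = std::conj(x.a);
  r.b = std::conj(x.b);
  r.c = std::conj(x.c);
  r.d = std::conj(x.d);
  return r;
}

// analytic exp(A) for 2x2 complex A via eigenvalue decomposition,
// with a first-order fallback at (near-)degenerate eigenvalues
static M2 expm2(const M2 &A) {
  cx tr = A.a + A.d;
  cx det = A.a * A.d - A.b * A.c;
  cx disc = std::sqrt(tr * tr - 4.0 * det);
  cx l1 = 0.5 * (tr + disc);
  cx l2 = 0.5 * (tr - disc);
  M2 r;
  double scale = std::abs(l1) + std::abs(l2) + 1.0;
  if (std::abs(l1 - l2) < 1e-12 * scale) {
    // exp(A) = e^l (I + (A - l I)), exact when A - l I is nilpotent
    cx e = std::exp(l1);
    r.a = e * (1.0 + A.a - l1);
    r.b = e * A.b;
    r.c = e * A.c;
    r.d = e * (1.0 + A.d - l1);
    return r;
  }
  cx e1 = std::exp(l1), e2 = std::exp(l2);
  cx w = (e1 - e2) / (l1 - l2);
  // exp(A) = w * A + (e1 - w*l1) * I
  cx k = e1 - w * l1;
  r.a = w * A.a + k;
  r.b = w * A.b;
  r.c = w * A.c;
  r.d = w * A.d + k;
  return r;
}

// eigenvalue of 2x2 with largest modulus
static cx dominant_eig(const M2 &V) {
  cx tr = V.a + V.d;
  cx det = V.a * V.d - V.b * V.c;
  cx disc = std::sqrt(tr * tr - 4.0 * det);
  cx l1 = 0.5 * (tr + disc);
  cx l2 = 0.5 * (tr - disc);
  return (std::abs(l1) >= std::abs(l2)) ? l1 : l2;
}

// refocusing pulse count under the nu_cpmg = 1/(2 tau) convention
static int pulse_count(double Tcp, double nu) {
  double x = 2.0 * Tcp * nu;
  int n = (int)std::lround(x);
  if (n < 1 || std::fabs(x - n) > 0.05)
    stop("CPMG frequency %g Hz does not give an integer pulse count for T_CPMG = %g s",
         nu, Tcp);
  return n;
}

// single-quantum evolution matrix (transverse magnetization of G and E)
static M2 sq_matrix(double pG, double kex, double dw, double R2G, double R2E) {
  double kGE = (1.0 - pG) * kex; // ground -> excited
  double kEG = pG * kex;         // excited -> ground
  M2 L;
  L.a = cx(-R2G - kGE, 0.0);
  L.b = cx(kEG, 0.0);
  L.c = cx(kGE, 0.0);
  L.d = cx(-R2E - kEG, dw);
  return L;
}

static M2 scale2(const M2 &A, double s) {
  M2 r;
  r.a = A.a * s;
  r.b = A.b * s;
  r.c = A.c * s;
  r.d = A.d * s;
  return r;
}

// [[Rcpp::export]]
NumericVector cpp_sq_cpmg(double pG, double kex, double dw, double R2G,
                          double R2E, double Tcp, NumericVector nu,
                          int detection) {
  M2 L = sq_matrix(pG, kex, dw, R2G, R2E);
  int m = nu.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    int N = pulse_count(Tcp, nu[i]);
    double tau = Tcp / N;
    M2 E = expm2(scale2(L, tau / 2.0));
    if (detection == 0) {
      // dominant mode of the two-echo cycle E E* E* E
      M2 Ec = mconj(E);
      M2 V = mmul(mmul(E, Ec), mmul(Ec, E));
      cx lam = dominant_eig(V);
      out[i] = -(N / (2.0 * Tcp)) * std::log(std::abs(lam));
    } else {
      // explicit propagation; 180-degree pulses as complex conjugation
      cx mG(pG, 0.0), mE(1.0 - pG, 0.0);
      for (int j = 0; j < N; ++j) {
        cx g = E.a * mG + E.b * mE;
        cx e = E.c * mG + E.d * mE;
        g = std::conj(g);
        e = std::conj(e);
        mG = E.a * g + E.b * e;
        mE = E.c * g + E.d * e;
      }
      double s = std::abs(mG + mE);
      if (s <= 0.0) stop("non-positive propagated signal");
      out[i] = -std::log(s) / Tcp;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_mq_cpmg(double pG, double kex, double dwH, double dwC,
                          double R2, double Tcp, NumericVector nu,
                          int detection) {
  // zero-quantum evolves at dwH - dwC in the excited state, double-quantum
  // at dwH + dwC; each carbon refocusing pulse interconverts ZQ <-> DQ
  M2 LZ = sq_matrix(pG, kex, dwH - dwC, R2, R2);
  M2 LD = sq_matrix(pG, kex, dwH + dwC, R2, R2);
  int m = nu.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    int N = pulse_count(Tcp, nu[i]);
    double tau = Tcp / N;
    M2 EZ = expm2(scale2(LZ, tau / 2.0));
    M2 ED = expm2(scale2(LD, tau / 2.0));
    if (detection == 0) {
      // dominant mode of the two-echo cycle in the ZQ channel
      M2 V = mmul(mmul(EZ, ED), mmul(ED, EZ));
      cx lam = dominant_eig(V);
      out[i] = -(N / (2.0 * Tcp)) * std::log(std::abs(lam));
    } else {
      if (N % 2 != 0)
        stop("signal detection of the MQ element needs an even pulse count (got %d)", N);
      cx zG(pG, 0.0), zE(1.0 - pG, 0.0), dG(pG, 0.0), dE(1.0 - pG, 0.0);
      for (int half = 0; half < 2; ++half) {
        for (int j = 0; j < N / 2; ++j) {
          cx z1G = EZ.a * zG + EZ.b * zE, z1E = EZ.c * zG + EZ.d * zE;
          cx d1G = ED.a * dG + ED.b * dE, d1E = ED.c * dG + ED.d * dE;
          // carbon refocusing pulse: ZQ <-> DQ
          zG = EZ.a * d1G + EZ.b * d1E;
          zE = EZ.c * d1G + EZ.d * d1E;
          dG = ED.a * z1G + ED.b * z1E;
          dE = ED.c * z1G + ED.d * z1E;
        }
        if (half == 0) {
          // proton refocusing pulse at T_CPMG / 2: DQ <-> conj(ZQ)
          cx tG = zG, tE = zE;
          zG = std::conj(dG);
          zE = std::conj(dE);
          dG = std::conj(tG);
          dE = std::conj(tE);
        }
      }
      double s = 0.5 * std::abs(zG + zE + dG + dE);
      if (s <= 0.0) stop("non-positive propagated signal");
      out[i] = -std::log(s) / Tcp;
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_free_precession(double pG, double kex, double dw, double R2G,
                         double R2E) {
  M2 L = sq_matrix(pG, kex, dw, R2G, R2E);
  arma::cx_mat A(2, 2);
  A(0, 0) = L.a; A(0, 1) = L.b; A(1, 0) = L.c; A(1, 1) = L.d;
  arma::cx_vec eval;
  arma::cx_mat evec;
  if (!arma::eig_gen(eval, evec, A)) stop("eigendecomposition failed");
  arma::cx_vec m0(2);
  m0(0) = cx(pG, 0.0);
  m0(1) = cx(1.0 - pG, 0.0);
  arma::cx_vec co = arma::solve(evec, m0);
  NumericVector offset(2), rate(2), amp(2);
  for (int i = 0; i < 2; ++i) {
    offset[i] = eval(i).imag();
    rate[i] = -eval(i).real();
    cx a = co(i) * (evec(0, i) + evec(1, i));
    amp[i] = a.real(); // amplitudes sum to sum(m0) = 1
  }
  int dom = (std::fabs(amp[0]) >= std::fabs(amp[1])) ? 0 : 1;
  return List::create(_["offset"] = offset, _["rate"] = rate,
                      _["amplitude"] = amp, _["dominant"] = dom + 1);
}

// 6x6 two-state rotating-frame matrix; spin lock of strength w1 along x,
// offsets OmG / OmE about z, decay-to-zero form
static arma::mat r1rho_matrix(double pG, double kex, double OmG, double OmE,
                              double R2, double R1, double w1) {
  double kGE = (1.0 - pG) * kex;
  double kEG = pG * kex;
  arma::mat A(6, 6, arma::fill::zeros);
  double Om[2] = {OmG, OmE};
  double kout[2] = {kGE, kEG};
  for (int s = 0; s < 2; ++s) {
    int o = 3 * s;
    A(o + 0, o + 0) = -R2 - kout[s];
    A(o + 0, o + 1) = -Om[s];
    A(o + 1, o + 0) = Om[s];
    A(o + 1, o + 1) = -R2 - kout[s];
    A(o + 1, o + 2) = w1;
    A(o + 2, o + 1) = -w1;
    A(o + 2, o + 2) = -R1 - kout[s];
  }
  for (int k = 0; k < 3; ++k) {
    A(k, 3 + k) = kEG;     // E -> G
    A(3 + k, k) = kGE;     // G -> E
  }
  return A;
}

// observed-peak offset used for carrier placement
static double observed_offset(double pG, double kex, double dw, double R2) {
  M2 L = sq_matrix(pG, kex, dw, R2, R2);
  arma::cx_mat A(2, 2);
  A(0, 0) = L.a; A(0, 1) = L.b; A(1, 0) = L.c; A(1, 1) = L.d;
  arma::cx_vec eval;
  arma::cx_mat evec;
  if (!arma::eig_gen(eval, evec, A)) stop("eigendecomposition failed");
  arma::cx_vec m0(2);
  m0(0) = cx(pG, 0.0);
  m0(1) = cx(1.0 - pG, 0.0);
  arma::cx_vec co = arma::solve(evec, m0);
  double best = -1.0;
  double off = 0.0;
  for (int i = 0; i < 2; ++i) {
    double a = std::abs(co(i) * (evec(0, i) + evec(1, i)));
    if (a > best) {
      best = a;
      off = eval(i).imag();
    }
  }
  return off;
}

static void tilt_vectors(double pG, double OmG, double OmE, double w1,
                         arma::vec &m0, arma::vec &obs) {
  double pE = 1.0 - pG;
  double Ombar = pG * OmG + pE * OmE;
  double theta = std::atan2(w1, Ombar);
  double sx = std::sin(theta), cz = std::cos(theta);
  m0 = {pG * sx, 0.0, pG * cz, pE * sx, 0.0, pE * cz};
  obs = {sx, 0.0, cz, sx, 0.0, cz};
}

// [[Rcpp::export]]
NumericVector cpp_r1rho(double pG, double kex, double dw, double R2, double R1,
                        NumericVector nu_SL, int method, NumericVector T_SL,
                        double carrier, bool carrier_auto) {
  double car = carrier_auto ? observed_offset(pG, kex, dw, R2) : carrier;
  double OmG = 0.0 - car;
  double OmE = dw - car;
  int m = nu_SL.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double w1 = 2.0 * M_PI * nu_SL[i];
    arma::mat A = r1rho_matrix(pG, kex, OmG, OmE, R2, R1, w1);
    arma::vec m0, obs;
    tilt_vectors(pG, OmG, OmE, w1, m0, obs);
    if (method == 0) {
      // slowest-decaying mode with dominant overlap with the lock axis
      arma::cx_vec eval;
      arma::cx_mat evec;
      if (!arma::eig_gen(eval, evec, A)) stop("eigendecomposition failed");
      arma::cx_vec co = arma::solve(evec, arma::cx_vec(m0, arma::vec(6, arma::fill::zeros)));
      double best = -1.0;
      double rate = NA_REAL;
      for (int k = 0; k < 6; ++k) {
        cx proj = 0.0;
        for (int r = 0; r < 6; ++r) proj += obs(r) * evec(r, k);
        double contrib = std::abs(co(k)) * std::abs(proj);
        if (contrib > best) {
          best = contrib;
          rate = -eval(k).real();
        }
      }
      out[i] = rate;
    } else {
      // piecewise matrix-exponential propagation + mono-exponential fit
      int nT = T_SL.size();
      if (nT < 2) stop("propagation detection needs at least two spin-lock times");
      arma::vec lt(nT), tt(nT);
      for (int j = 0; j < nT; ++j) {
        arma::vec mt = (T_SL[j] > 0.0) ? arma::vec(arma::expmat(A * T_SL[j]) * m0) : m0;
        double s = arma::dot(obs, mt);
        if (s <= 0.0)
          stop("non-decaying or non-positive spin-lock signal; exponential fit is degenerate");
        lt(j) = std::log(s);
        tt(j) = T_SL[j];
      }
      double tbar = arma::mean(tt), lbar = arma::mean(lt);
      double sxx = arma::dot(tt - tbar, tt - tbar);
      if (sxx <= 0.0) stop("degenerate spin-lock time grid");
      out[i] = -arma::dot(tt - tbar, lt - lbar) / sxx;
    }
  }
  return out;
}

// spin-lock decay curves, used by the synthetic-data generator
// [[Rcpp::export]]
NumericMatrix cpp_r1rho_decay(double pG, double kex, double dw, double R2,
                              double R1, NumericVector nu_SL,
                              NumericVector T_SL) {
  double car = observed_offset(pG, kex, dw, R2);
  double OmG = 0.0 - car;
  double OmE = dw - car;
  int m = nu_SL.size(), nT = T_SL.size();
  NumericMatrix out(m, nT);
  for (int i = 0; i < m; ++i) {
    double w1 = 2.0 * M_PI * nu_SL[i];
    arma::mat A = r1rho_matrix(pG, kex, OmG, OmE, R2, R1, w1);
    arma::vec m0, obs;
    tilt_vectors(pG, OmG, OmE, w1, m0, obs);
    for (int j = 0; j < nT; ++j) {
      arma::vec mt = (T_SL[j] > 0.0) ? arma::vec(arma::expmat(A * T_SL[j]) * m0) : m0;
      out(i, j) = arma::dot(obs, mt);
    }
  }
  return out;
}
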