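// Batch GMLVQ training core.
//
// Minimizes the GLVQ cost E = sum_i Phi(mu_i), mu = (dJ - dK)/(dJ + dK),
// over prototypes W and the metric factor Omega (Lambda = Omega' Omega),
// by steepest descent with per-epoch step halving: a step is accepted only
// if the cost does not increase, and Omega is rescaled to Tr(Lambda) = 1
// after every trial step (cost-neutral: mu is invariant to a positive
// rescaling of Lambda). Mirrors the reference R implementation
// (.trainBatch); the R engine remains available for cross-checking.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct EvalState {
  double E;
  uvec J, K;
  vec dJ, dK, mu;
};

inline double phiOf(double mu, bool sigmoid, double gamma) {
  if (!sigmoid) return mu;
  return 1.0 / (1.0 + std::exp(-gamma * mu));
}

inline double dphiOf(double mu, bool sigmoid, double gamma) {
  if (!sigmoid) return 1.0;
  double s = 1.0 / (1.0 + std::exp(-gamma * mu));
  return gamma * s * (1.0 - s);
}

// distances of all samples to all prototypes under Omega' Omega,
// then per-sample closest correct (J) / wrong (K) prototype and cost
void evalConfig(const mat& X, const mat& W, const mat& Omega,
                const umat& sameClass, bool sigmoid, double gamma,
                EvalState& st) {
  const uword n = X.n_rows, p = W.n_rows;
  mat XO = X * Omega.t();
  mat WO = W * Omega.t();
  vec xn = sum(square(XO), 1);
  vec wn = sum(square(WO), 1);
  mat D2 = -2.0 * (XO * WO.t());
  D2.each_col() += xn;
  D2.each_row() += wn.t();
  st.J.set_size(n); st.K.set_size(n);
  st.dJ.set_size(n); st.dK.set_size(n); st.mu.set_size(n);
  double E = 0.0;
  for (uword i = 0; i < n; ++i) {
    double bestJ = datum::inf, bestK = datum::inf;
    uword aJ = 0, aK = 0;
    for (uword k = 0; k < p; ++k) {
      double d = D2(i, k);
      if (d < 0) d = 0;
      if (sameClass(i, k)) {
        if (d < bestJ) { bestJ = d; aJ = k; }
      } else {
        if (d < bestK) { bestK = d; aK = k; }
      }
    }
    st.J(i) = aJ; st.K(i) = aK;
    st.dJ(i) = bestJ; st.dK(i) = bestK;
    double denom = bestJ + bestK;
    double mu = denom > 0 ? (bestJ - bestK) / denom : 0.0;
    st.mu(i) = mu;
    E += phiOf(mu, sigmoid, gamma);
  }
  st.E = E;
}

} // namespace

// penalty term -regAlpha * ln det(Omega' Omega); +Inf for singular Omega
static double regPenalty(const mat& omega, double regAlpha) {
  if (regAlpha == 0) return 0.0;
  double val, sign;
  log_det(val, sign, omega);
  if (sign == 0 || !std::isfinite(val)) return datum::inf;
  return -regAlpha * 2.0 * val;
}

// [[Rcpp::export(name = ".cppTrainBatch")]]
Rcpp::List cppTrainBatch(const arma::mat& x, const arma::umat& sameClass,
                         arma::mat w, arma::mat omega,
                         const bool sigmoid, const double gamma,
                         const int epochs, const double lrW,
                         const double lrOmega, const double tol,
                         const bool diagnostics, const double regAlpha) {
  const uword n = x.n_rows, d = x.n_cols, p = w.n_rows;
  EvalState st, stTrial;
  evalConfig(x, w, omega, sameClass, sigmoid, gamma, st);
  double E = st.E + regPenalty(omega, regAlpha);
  std::vector<double> trace;
  trace.push_back(E);
  std::vector<double> trLambda, minEig;
  if (diagnostics) {
    trLambda.push_back(accu(square(omega)));
    vec ev;
    eig_sym(ev, omega.t() * omega);
    minEig.push_back(ev.min());
  }
  mat VJ(n, d), VK(n, d);
  vec gJ(n), gK(n);
  double step = 1.0;  // persistent backtracking factor
  for (int epoch = 0; epoch < epochs; ++epoch) {
    // gradients at the current (already evaluated) configuration,
    // assembled in matrix form so the heavy products go through BLAS
    mat lambda = omega.t() * omega;
    for (uword i = 0; i < n; ++i) {
      double denom = st.dJ(i) + st.dK(i);
      VJ.row(i) = x.row(i) - w.row(st.J(i));
      VK.row(i) = x.row(i) - w.row(st.K(i));
      if (denom <= 0) { gJ(i) = 0; gK(i) = 0; continue; }
      double chain = dphiOf(st.mu(i), sigmoid, gamma);
      gJ(i) = chain * 2.0 * st.dK(i) / (denom * denom);
      gK(i) = chain * 2.0 * st.dJ(i) / (denom * denom);
    }
    mat AJ(p, d, fill::zeros), AK(p, d, fill::zeros);
    for (uword i = 0; i < n; ++i) {
      AJ.row(st.J(i)) += gJ(i) * VJ.row(i);
      AK.row(st.K(i)) += gK(i) * VK.row(i);
    }
    mat gradW = 2.0 * ((AK - AJ) * lambda);  // -2 sum gJ L vJ + 2 sum gK L vK
    mat M = (VJ.each_col() % gJ).t() * VJ - (VK.each_col() % gK).t() * VK;
    mat gradOmega = 2.0 * (omega * M);
    if (regAlpha > 0) {
      mat omegaInv;
      if (!inv(omegaInv, omega))
        Rcpp::stop("singular Omega at epoch %d", epoch + 1);
      gradOmega -= 2.0 * regAlpha * omegaInv.t();
    }
    if (!gradW.is_finite() || !gradOmega.is_finite())
      Rcpp::stop("non-finite gradient at epoch %d", epoch + 1);
    // normalized steepest-descent directions (see .trainBatch)
    double nW = std::sqrt(accu(square(gradW)));
    double nO = std::sqrt(accu(square(gradOmega)));
    if (nW > 0) gradW /= nW;
    if (nO > 0) gradOmega /= nO;
    bool accepted = false;
    double En = 0.0;
    mat wn, on;
    while (step >= std::ldexp(1.0, -40)) {
      wn = w - (lrW * step) * gradW;
      on = omega - (lrOmega * step) * gradOmega;
      on /= std::sqrt(accu(square(on)));
      evalConfig(x, wn, on, sameClass, sigmoid, gamma, stTrial);
      En = stTrial.E + regPenalty(on, regAlpha);
      if (std::isfinite(En) && En <= E) {
        accepted = true;
        break;
      }
      step *= 0.5;
    }
    if (!accepted) break;
    double improvement = E - En;
    w = wn;
    omega = on;
    st = stTrial;
    E = En;
    trace.push_back(E);
    if (diagnostics) {
      trLambda.push_back(accu(square(omega)));
      vec ev;
      eig_sym(ev, omega.t() * omega);
      minEig.push_back(ev.min());
    }
    if (improvement < tol) break;
    step = std::min(1.0, step * 2.0);
  }
  Rcpp::List diag;
  if (diagnostics)
    diag = Rcpp::List::create(Rcpp::Named("trLambda") = trLambda,
                              Rcpp::Named("minEigenLambda") = minEig);
  return Rcpp::List::create(Rcpp::Named("w") = w,
                            Rcpp::Named("omega") = omega,
                            Rcpp::Named("trace") = trace,
                            Rcpp::Named("diag") = diag);
}
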