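#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// FRAPPE-style EM for the admixture likelihood
//   l(Q,F) = sum_{i,l observed} g_il log p_il + (2 - g_il) log(1 - p_il),
//   p_il = sum_k q_ik f_kl,
// with Q rows on the simplex and F clamped to [1e-6, 1 - 1e-6].
//
// Matrix form of the exact EM updates (responsibilities folded in):
//   R = (G / P) .* W,  S = ((2W - G) / (1 - P)) .* W
//   Q' = Q .* (R F' + S (1 - F)') / (2 nObs_i), renormalized per row
//   F' = F .* (Q' num) ... specifically
//   Fnum = F .* (Q^T R), Fden = Fnum + (1 - F) .* (Q^T S), F' = Fnum / Fden
// Both updates use the old (Q, F); the log-likelihood trace is evaluated
// before each update and is non-decreasing by the EM guarantee.
//
// Gz: I x L dosages with 0 at missing entries; W: 1/0 observed mask.
// [[Rcpp::export(name = ".emFit")]]
List emFit(arma::mat Gz, arma::mat W, arma::mat Q0, arma::mat F0,
           int maxIter, double tol) {
  const double fmin = 1e-6, fmax = 1.0 - 1e-6;
  arma::mat Q = Q0, F = F0;
  const arma::vec nObs = arma::sum(W, 1);
  const arma::mat G2 = 2.0 * W - Gz;  // (2 - g) on observed entries, else 0
  std::vector<double> ll;
  ll.reserve(maxIter);
  bool converged = false;
  int it = 0;
  double prev = -arma::datum::inf;
  for (it = 0; it < maxIter; ++it) {
    arma::mat P = Q * F;                       // I x L
    P.clamp(fmin, fmax);
    double loglik = arma::accu(W % (Gz % arma::log(P) +
                                    G2 % arma::log1p(-P)));
    if (!std::isfinite(loglik)) stop("non-finite log-likelihood in EM");
    ll.push_back(loglik);
    arma::mat R = (Gz / P) % W;                // alt-allele weights
    arma::mat S = (G2 / (1.0 - P)) % W;        // ref-allele weights
    arma::mat Qn = Q % (R * F.t() + S * (1.0 - F).t());
    Qn.each_col() /= (2.0 * nObs);
    Qn.each_col() /= arma::sum(Qn, 1);         // guard drift off simplex
    arma::mat Fnum = F % (Q.t() * R);
    arma::mat Fden = Fnum + (1.0 - F) % (Q.t() * S);
    arma::mat Fn = Fnum / Fden;
    Fn.replace(arma::datum::nan, 0.5);         // loci with no evidence
    Fn.clamp(fmin, fmax);
    Q = Qn;
    F = Fn;
    if (it > 0 && loglik - prev < tol) { converged = true; ++it; break; }
    prev = loglik;
  }
  return List::create(_["Q"] = Q, _["F"] = F,
                      _["logLik"] = NumericVector(ll.begin(), ll.end()),
                      _["nIterations"] = it,
                      _["converged"] = converged);
}
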