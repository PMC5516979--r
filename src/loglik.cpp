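#include <Rcpp.h>
using namespace Rcpp;

// Session log-likelihood of first-stage choices under the hybrid
// value-update model: both values decay by gamma each trial, then the
// valence- and transition-specific increments are attributed (common:
// chosen gets mf + mb; rare: chosen gets mf, unchosen gets mb). Choice
// probability is the logistic of the value difference.
//
// choice:   1 or 2 (observed first-stage action)
// common:   1 if the transition was common, 0 if rare
// rewarded: 1 if the outcome was rewarded, 0 otherwise
// d:        increments in order d_plus_mf, d_plus_mb, d_minus_mf, d_minus_mb
// [[Rcpp::export]]
double loglik_session_cpp(const IntegerVector& choice,
                          const IntegerVector& common,
                          const IntegerVector& rewarded,
                          double gamma,
                          const NumericVector& d,
                          const NumericVector& v0) {
  const int n = choice.size();
  if (common.size() != n || rewarded.size() != n)
    stop("choice, common and rewarded must have equal length");
  if (d.size() != 4) stop("d must hold four increments");
  if (v0.size() != 2) stop("v0 must have length 2");

  double v1 = v0[0], v2 = v0[1];
  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    const int ch = choice[t];
    if (ch != 1 && ch != 2) stop("choice must be coded 1 or 2");
    const double diff = (ch == 1) ? (v1 - v2) : (v2 - v1);
    // log(plogis(diff)) computed stably
    ll += (diff >= 0) ? -log1p(std::exp(-diff)) : diff - log1p(std::exp(diff));

    const double dmf = rewarded[t] ? d[0] : d[2];
    const double dmb = rewarded[t] ? d[1] : d[3];
    v1 *= gamma;
    v2 *= gamma;
    if (common[t]) {
      if (ch == 1) v1 += dmf + dmb; else v2 += dmf + dmb;
    } else {
      if (ch == 1) { v1 += dmf; v2 += dmb; } else { v2 += dmf; v1 += dmb; }
    }
  }
  return ll;
}

// Evaluate the session log-likelihood on a grid of parameter vectors
// (rows of theta: gamma, d_plus_mf, d_plus_mb, d_minus_mf, d_minus_mb).
// Used by the grid-search oracle in tests and diagnostics.
// [[Rcpp::export]]
NumericVector loglik_grid_cpp(const NumericMatrix& theta,
                              const IntegerVector& choice,
                              const IntegerVector& common,
                              const IntegerVector& rewarded,
                              const NumericVector& v0) {
  const int m = theta.nrow();
  if (theta.ncol() != 5) stop("theta must have five columns");
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    NumericVector d = NumericVector::create(theta(i, 1), theta(i, 2),
                                            theta(i, 3), theta(i, 4));
    out[i] = loglik_session_cpp(choice, common, rewarded, theta(i, 0), d, v0);
  }
  return out;
}
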