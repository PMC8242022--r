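#include <Rcpp.h>
using namespace Rcpp;

// log(p) of the logistic at linear predictor x, stable for |x| ~ 700+
static inline double log_logis(double x) {
  return (x > 0.0) ? -log1p(std::exp(-x)) : x - log1p(std::exp(x));
}

// truncated-normal (0, Inf) log-density, including the normalizer
static inline double dtnorm0_log(double x, double mu, double sd) {
  if (x <= 0.0) return R_NegInf;
  return R::dnorm(x, mu, sd, 1) - R::pnorm(0.0, mu, sd, 0, 1);
}

static double log_post(const NumericVector& par, int n,
                       const IntegerVector& pid, const NumericVector& t,
                       const NumericVector& sgn, const IntegerVector& lying,
                       const NumericVector& r, const NumericVector& l,
                       double max_mean, double max_sd, double max_delta) {
  const int npar = par.size();
  for (int j = 0; j < npar; ++j) {
    if (par[j] <= 0.0) return R_NegInf;
  }
  if (par[0] > max_mean || par[1] > max_mean ||
      par[2] > max_sd || par[3] > max_sd ||
      par[4] > max_delta || par[5] > max_delta) {
    return R_NegInf;
  }
  double lp = 0.0;
  for (int i = 0; i < n; ++i) {
    lp += dtnorm0_log(par[6 + i], par[0], par[2]);
    lp += dtnorm0_log(par[6 + n + i], par[1], par[3]);
  }
  if (!std::isfinite(lp)) return R_NegInf;
  const int ncell = pid.size();
  for (int c = 0; c < ncell; ++c) {
    double wi = par[6 + (pid[c] - 1)];
    double we = par[6 + n + (pid[c] - 1)];
    if (lying[c]) {
      wi *= par[4];
      we *= par[5];
    }
    double x = (wi + sgn[c] * we) * t[c];
    lp += r[c] * log_logis(x) + l[c] * log_logis(-x);
  }
  return lp;
}

// Random-walk Metropolis-Hastings over the 6 + 2N hypothesis vector.
// Consumes R's RNG in exactly the order of the reference R loop
// (npar Gaussian steps per iteration; one uniform only when the
// proposal has finite posterior), so both engines match draw for draw.
// [[Rcpp::export(.mh_chain_cpp)]]
List mh_chain_cpp(NumericVector init, NumericVector sds, int n_iter,
                  int burn_in, int thin, int n,
                  IntegerVector pid, NumericVector t, NumericVector sgn,
                  IntegerVector lying, NumericVector r, NumericVector l,
                  double max_mean, double max_sd, double max_delta) {
  const int npar = init.size();
  NumericVector par = clone(init);
  NumericVector prop(npar);
  double lp = log_post(par, n, pid, t, sgn, lying, r, l,
                       max_mean, max_sd, max_delta);
  if (!std::isfinite(lp)) {
    stop("initial hypothesis lies outside the posterior support");
  }
  const int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix samples(n_keep, npar);
  int n_accepted = 0, row = 0;

  RNGScope scope;
  for (int i = 1; i <= n_iter; ++i) {
    for (int j = 0; j < npar; ++j) prop[j] = par[j] + R::rnorm(0.0, sds[j]);
    double lp_prop = log_post(prop, n, pid, t, sgn, lying, r, l,
                              max_mean, max_sd, max_delta);
    if (std::isfinite(lp_prop) && std::log(R::runif(0.0, 1.0)) < lp_prop - lp) {
      std::copy(prop.begin(), prop.end(), par.begin());
      lp = lp_prop;
      ++n_accepted;
    }
    if (i > burn_in && (i - burn_in) % thin == 0 && row < n_keep) {
      samples(row++, _) = par;
    }
  }
  return List::create(_["samples"] = samples,
                      _["n_accepted"] = n_accepted);
}
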