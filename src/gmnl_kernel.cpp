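#include <Rcpp.h>
using namespace Rcpp;

// Simulated log-likelihood of the generalized multinomial logit and its
// analytic gradient, with common draws across respondents.
//
// For draw d the coefficient on attribute k is
//   c_dk = sigma_d * beta_k + (gamma + (1 - gamma) * sigma_d) * s_k * H(d,k)
// with sigma_d = exp(-tau^2/2 + tau * eps0_d) (so E[sigma] = 1) and
// s_k = 0 for non-random attributes. Alternative-specific constants are
// position effects and are not scaled. Per respondent the situation
// probabilities multiply across situations and average over draws; all
// products are kept in log space with max-subtraction.
//
// theta layout: beta[0..K-1], asc_free[0..J-2], s[one per random attr,
// in attribute order], tau (present iff estimate_tau). s and tau are
// estimated unconstrained (the likelihood is symmetric in their signs)
// and reported as absolute values by the R wrapper.
//
// Gradient, with w_nd the posterior draw weights, p the within-situation
// probabilities and g_i = w_nd (y_i - p_i):
//   d/d beta_k = sum_d sigma_d * (g . X[,k])
//   d/d s_r    = sum_d mixw_d H(d,k_r) * (g . X[,k_r])
//   d/d tau    = sum_d sum_k dc_dk/dtau * (g . X[,k])
//   d/d asc_j  = sum_d sum_{i: alt_i = j} g_i
// so each draw costs a handful of contiguous column sweeps over X.
//
// Rows must be sorted so that each situation's rows are contiguous and
// situation indices are nondecreasing.
// [[Rcpp::export]]
List gmnl_loglik_cpp(NumericVector theta,
                     NumericMatrix X,
                     IntegerVector alt,       // 1-based position per row
                     IntegerVector sit,       // 0-based situation per row
                     IntegerVector sit_resp,  // 0-based respondent per situation
                     IntegerVector chosen,    // 0/1 per row
                     NumericMatrix H,         // D x K standard-normal draws
                     NumericVector eps0,      // D
                     LogicalVector is_random, // K
                     int n_alt,
                     double gamma,
                     bool estimate_tau,
                     double tau_fixed,
                     bool want_grad) {
  const int rows = X.nrow();
  const int K = X.ncol();
  const int D = H.nrow();
  const int S = sit_resp.size();
  int N = 0;
  for (int s = 0; s < S; ++s) N = std::max(N, sit_resp[s] + 1);

  int n_random = 0;
  std::vector<int> sd_index(K, -1);
  for (int k = 0; k < K; ++k) {
    if (is_random[k]) sd_index[k] = n_random++;
  }
  const int n_asc = n_alt - 1;
  const int npar = K + n_asc + n_random + (estimate_tau ? 1 : 0);
  if (theta.size() != npar) stop("theta has wrong length");

  std::vector<double> beta(K), asc(n_alt, 0.0), sdv(n_random, 0.0);
  for (int k = 0; k < K; ++k) beta[k] = theta[k];
  for (int j = 0; j < n_asc; ++j) asc[j + 1] = theta[K + j];
  for (int r = 0; r < n_random; ++r) sdv[r] = theta[K + n_asc + r];
  const double tau = estimate_tau ? theta[K + n_asc + n_random] : tau_fixed;

  // situation row ranges (rows are contiguous per situation)
  std::vector<int> sit_start(S + 1, 0);
  {
    int cur = -1;
    for (int i = 0; i < rows; ++i) {
      if (sit[i] != cur) {
        cur = sit[i];
        sit_start[cur] = i;
      }
    }
    sit_start[S] = rows;
  }

  std::vector<double> ls(static_cast<size_t>(N) * D, 0.0);
  std::vector<double> u(rows), coef(K), asc_row(rows);
  for (int i = 0; i < rows; ++i) asc_row[i] = asc[alt[i] - 1];

  // utilities for draw d by contiguous column sweeps over X
  auto fill_utilities = [&](int d) {
    const double sigma = std::exp(-0.5 * tau * tau + tau * eps0[d]);
    const double mixw = gamma + (1.0 - gamma) * sigma;
    for (int k = 0; k < K; ++k) {
      coef[k] = sigma * beta[k];
      if (sd_index[k] >= 0) coef[k] += mixw * sdv[sd_index[k]] * H(d, k);
    }
    std::copy(asc_row.begin(), asc_row.end(), u.begin());
    for (int k = 0; k < K; ++k) {
      const double c = coef[k];
      if (c == 0.0) continue;
      const double* xk = &X(0, k);
      for (int i = 0; i < rows; ++i) u[i] += c * xk[i];
    }
    return sigma;
  };

  for (int d = 0; d < D; ++d) {
    fill_utilities(d);
    for (int s = 0; s < S; ++s) {
      double mx = R_NegInf, se = 0.0, uch = 0.0;
      for (int i = sit_start[s]; i < sit_start[s + 1]; ++i) {
        if (u[i] > mx) mx = u[i];
      }
      for (int i = sit_start[s]; i < sit_start[s + 1]; ++i) {
        se += std::exp(u[i] - mx);
        if (chosen[i]) uch = u[i];
      }
      ls[static_cast<size_t>(sit_resp[s]) * D + d] +=
        uch - mx - std::log(se);
    }
  }

  double loglik = 0.0;
  std::vector<double> w(static_cast<size_t>(N) * D);
  for (int n = 0; n < N; ++n) {
    double mx = R_NegInf;
    for (int d = 0; d < D; ++d) {
      mx = std::max(mx, ls[static_cast<size_t>(n) * D + d]);
    }
    double se = 0.0;
    for (int d = 0; d < D; ++d) {
      const double e = std::exp(ls[static_cast<size_t>(n) * D + d] - mx);
      w[static_cast<size_t>(n) * D + d] = e;
      se += e;
    }
    for (int d = 0; d < D; ++d) {
      w[static_cast<size_t>(n) * D + d] /= se;
    }
    loglik += mx + std::log(se) - std::log(static_cast<double>(D));
  }

  if (!want_grad) {
    return List::create(_["loglik"] = loglik, _["grad"] = R_NilValue);
  }

  std::vector<double> grad(npar, 0.0), g(rows);
  for (int d = 0; d < D; ++d) {
    const double sigma = fill_utilities(d);
    const double mixw = gamma + (1.0 - gamma) * sigma;
    const double dsigma = sigma * (eps0[d] - tau);
    for (int s = 0; s < S; ++s) {
      double mx = R_NegInf, se = 0.0;
      const int i0 = sit_start[s], i1 = sit_start[s + 1];
      for (int i = i0; i < i1; ++i) {
        if (u[i] > mx) mx = u[i];
      }
      for (int i = i0; i < i1; ++i) {
        g[i] = std::exp(u[i] - mx);
        se += g[i];
      }
      const double wnd = w[static_cast<size_t>(sit_resp[s]) * D + d];
      for (int i = i0; i < i1; ++i) {
        g[i] = wnd * (chosen[i] - g[i] / se);
      }
    }
    for (int i = 0; i < rows; ++i) {
      if (alt[i] > 1) grad[K + alt[i] - 2] += g[i];
    }
    for (int k = 0; k < K; ++k) {
      const double* xk = &X(0, k);
      double dot = 0.0;
      for (int i = 0; i < rows; ++i) dot += g[i] * xk[i];
      grad[k] += sigma * dot;
      double dck = dsigma * beta[k];
      if (sd_index[k] >= 0) {
        grad[K + n_asc + sd_index[k]] += mixw * H(d, k) * dot;
        dck += (1.0 - gamma) * dsigma * sdv[sd_index[k]] * H(d, k);
      }
      if (estimate_tau) grad[K + n_asc + n_random] += dck * dot;
    }
  }

  return List::create(_["loglik"] = loglik,
                      _["grad"] = NumericVector(grad.begin(), grad.end()));
}
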