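#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Median with R's convention: mean of the two middle order statistics for
// even-sized windows (shrinking edge windows can be even-sized).
static double window_median(std::vector<double>& buf) {
  const size_t n = buf.size();
  const size_t mid = n / 2;
  std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
  const double hi = buf[mid];
  if (n % 2 == 1) return hi;
  const double lo = *std::max_element(buf.begin(), buf.begin() + mid);
  return 0.5 * (lo + hi);
}

static void median_filter_vec(const double* s, double* out, int n, int window) {
  const int half = (window - 1) / 2;
  std::vector<double> buf;
  for (int i = 0; i < n; ++i) {
    const int lo = std::max(0, i - half);
    const int hi = std::min(n - 1, i + half);
    buf.assign(s + lo, s + hi + 1);
    out[i] = window_median(buf);
  }
}

// [[Rcpp::export]]
NumericVector cpp_median_filter(NumericVector s, int window) {
  if (window < 1 || window % 2 == 0)
    stop("window must be an odd integer >= 1");
  const int n = s.size();
  NumericVector out(n);
  if (n == 0) return out;
  median_filter_vec(REAL(s), REAL(out), n, window);
  return out;
}

// Clip a window to the largest odd value <= len (>= 1).
static int clip_window(int w, int len) {
  if (w > len) w = (len % 2 == 1) ? len : len - 1;
  if (w < 1) w = 1;
  return w;
}

static void multilevel_vec(const double* s, double* out, int n,
                           const std::vector<int>& windows, int final_window,
                           bool across_scale) {
  std::vector<double> cur(s, s + n), tmp(n);
  if (across_scale && windows.size() > 1) {
    // one pass per window over the *original* sequence, then a per-position
    // median across scales
    const size_t k = windows.size();
    std::vector<std::vector<double> > outs(k, std::vector<double>(n));
    for (size_t w = 0; w < k; ++w)
      median_filter_vec(s, outs[w].data(), n, clip_window(windows[w], n));
    std::vector<double> col(k);
    for (int i = 0; i < n; ++i) {
      for (size_t w = 0; w < k; ++w) col[w] = outs[w][i];
      std::vector<double> cb(col);
      cur[i] = window_median(cb);
    }
  } else {
    for (size_t w = 0; w < windows.size(); ++w) {
      median_filter_vec(cur.data(), tmp.data(), n, clip_window(windows[w], n));
      cur.swap(tmp);
    }
  }
  median_filter_vec(cur.data(), out, n, clip_window(final_window, n));
}

// [[Rcpp::export]]
NumericVector cpp_multilevel_filter(NumericVector s, IntegerVector windows,
                                    int final_window, bool across_scale) {
  const int n = s.size();
  NumericVector out(n);
  if (n == 0) return out;
  std::vector<int> ws(windows.begin(), windows.end());
  multilevel_vec(REAL(s), REAL(out), n, ws, final_window, across_scale);
  return out;
}

// Smooth every (spot, arm) sequence of a spots x genes matrix in one call.
// arm_cols holds 1-based column indices of each arm in genomic order.
// [[Rcpp::export]]
NumericMatrix cpp_smooth_matrix(NumericMatrix X, List arm_cols,
                                IntegerVector windows, int final_window,
                                bool across_scale) {
  const int nspot = X.nrow();
  NumericMatrix out(nspot, X.ncol());
  std::vector<int> ws(windows.begin(), windows.end());
  for (int a = 0; a < arm_cols.size(); ++a) {
    IntegerVector cols = arm_cols[a];
    const int len = cols.size();
    std::vector<double> s(len), sm(len);
    for (int i = 0; i < nspot; ++i) {
      for (int g = 0; g < len; ++g) s[g] = X(i, cols[g] - 1);
      multilevel_vec(s.data(), sm.data(), len, ws, final_window, across_scale);
      for (int g = 0; g < len; ++g) out(i, cols[g] - 1) = sm[g];
    }
  }
  return out;
}

static const double LOG2PI = 1.8378770664093454836;

static inline double norm_logdens(double x, double mu, double sigma) {
  const double z = (x - mu) / sigma;
  return -0.5 * LOG2PI - std::log(sigma) - 0.5 * z * z;
}

// One scaled forward-backward pass over one sequence; accumulates the EM
// sufficient statistics into the caller's buffers. Per-position emission
// renormalisation (subtracting the max log-density) keeps the scaled
// recursion finite even for extreme outliers. Returns the log-likelihood.
static double fb_accumulate(const double* x, int L, const double* pi,
                            const double* T, const double* mu,
                            const double* sigma, double* start_acc,
                            double* trans_acc, double* w_acc, double* wx_acc,
                            double* wx2_acc) {
  const int K = 3;
  std::vector<double> b(L * K), alpha(L * K), beta(L * K), c(L), mx(L);
  for (int t = 0; t < L; ++t) {
    double m = -INFINITY;
    for (int j = 0; j < K; ++j) {
      const double lb = norm_logdens(x[t], mu[j], sigma[j]);
      b[t * K + j] = lb;
      if (lb > m) m = lb;
    }
    mx[t] = m;
    for (int j = 0; j < K; ++j) b[t * K + j] = std::exp(b[t * K + j] - m);
  }
  // forward
  double s0 = 0.0;
  for (int j = 0; j < K; ++j) {
    alpha[j] = pi[j] * b[j];
    s0 += alpha[j];
  }
  c[0] = s0;
  for (int j = 0; j < K; ++j) alpha[j] /= s0;
  for (int t = 1; t < L; ++t) {
    double st = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int i = 0; i < K; ++i) a += alpha[(t - 1) * K + i] * T[i * K + j];
      a *= b[t * K + j];
      alpha[t * K + j] = a;
      st += a;
    }
    c[t] = st;
    for (int j = 0; j < K; ++j) alpha[t * K + j] /= st;
  }
  // backward
  for (int j = 0; j < K; ++j) beta[(L - 1) * K + j] = 1.0;
  for (int t = L - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double s = 0.0;
      for (int j = 0; j < K; ++j)
        s += T[i * K + j] * b[(t + 1) * K + j] * beta[(t + 1) * K + j];
      beta[t * K + i] = s / c[t + 1];
    }
  }
  // posteriors
  for (int t = 0; t < L; ++t) {
    for (int j = 0; j < K; ++j) {
      const double g = alpha[t * K + j] * beta[t * K + j];
      if (t == 0) start_acc[j] += g;
      w_acc[j] += g;
      wx_acc[j] += g * x[t];
      wx2_acc[j] += g * x[t] * x[t];
    }
    if (t < L - 1) {
      for (int i = 0; i < K; ++i)
        for (int j = 0; j < K; ++j)
          trans_acc[i * K + j] += alpha[t * K + i] * T[i * K + j] *
                                  b[(t + 1) * K + j] * beta[(t + 1) * K + j] /
                                  c[t + 1];
    }
  }
  double ll = 0.0;
  for (int t = 0; t < L; ++t) ll += std::log(c[t]) + mx[t];
  return ll;
}

// E-step over a list of sequences: total log-likelihood plus the pooled
// sufficient statistics for the M-step.
// [[Rcpp::export]]
List cpp_em_step(List seqs, NumericVector pi, NumericMatrix T,
                 NumericVector mu, NumericVector sigma) {
  const int K = 3;
  std::vector<double> Trow(K * K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) Trow[i * K + j] = T(i, j);
  NumericVector start(K), w(K), wx(K), wx2(K);
  NumericMatrix trans(K, K);
  std::vector<double> trans_acc(K * K, 0.0);
  double ll = 0.0;
  for (int s = 0; s < seqs.size(); ++s) {
    NumericVector x = seqs[s];
    if (x.size() < 1) continue;
    ll += fb_accumulate(REAL(x), x.size(), REAL(pi), Trow.data(), REAL(mu),
                        REAL(sigma), REAL(start), trans_acc.data(), REAL(w),
                        REAL(wx), REAL(wx2));
  }
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) trans(i, j) = trans_acc[i * K + j];
  return List::create(_["loglik"] = ll, _["start"] = start,
                      _["trans"] = trans, _["w"] = w, _["wx"] = wx,
                      _["wx2"] = wx2);
}

// Viterbi decoding in log space; ties broken toward the lower state index
// (strict improvement required to switch).
// [[Rcpp::export]]
List cpp_viterbi(NumericVector x, NumericVector pi, NumericMatrix T,
                 NumericVector mu, NumericVector sigma) {
  const int K = 3, L = x.size();
  if (L == 0)
    return List::create(_["path"] = IntegerVector(0), _["log_prob"] = 0.0);
  std::vector<double> lT(K * K), delta(L * K);
  std::vector<int> psi(L * K, 0);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) lT[i * K + j] = std::log(T(i, j));
  for (int j = 0; j < K; ++j)
    delta[j] = std::log(pi[j]) + norm_logdens(x[0], mu[j], sigma[j]);
  for (int t = 1; t < L; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = delta[(t - 1) * K] + lT[j];
      int arg = 0;
      for (int i = 1; i < K; ++i) {
        const double v = delta[(t - 1) * K + i] + lT[i * K + j];
        if (v > best) {
          best = v;
          arg = i;
        }
      }
      delta[t * K + j] = best + norm_logdens(x[t], mu[j], sigma[j]);
      psi[t * K + j] = arg;
    }
  }
  double best = delta[(L - 1) * K];
  int arg = 0;
  for (int j = 1; j < K; ++j)
    if (delta[(L - 1) * K + j] > best) {
      best = delta[(L - 1) * K + j];
      arg = j;
    }
  IntegerVector path(L);
  path[L - 1] = arg;
  for (int t = L - 1; t > 0; --t) path[t - 1] = psi[t * K + path[t]];
  for (int t = 0; t < L; ++t) path[t] += 1;  // 1-based states
  return List::create(_["path"] = path, _["log_prob"] = best);
}
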