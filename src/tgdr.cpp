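#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Breslow risk-set layout over subjects sorted by decreasing follow-up time:
// the risk set of the subject at sorted position p is positions 0..last[p],
// where last[p] extends over ties so that subjects censored exactly at an
// event time stay at risk for that event.
struct SortedCox {
  int n = 0, d = 0;
  std::vector<double> X;     // n x d, column-major, rows in sorted order
  std::vector<int> last;     // per sorted position
  std::vector<int> ev;       // sorted positions of events
};

static SortedCox sort_design(const NumericMatrix& Xfull,
                             const NumericVector& time,
                             const IntegerVector& status,
                             const IntegerVector& rows) {
  SortedCox sc;
  int n = rows.size(), d = Xfull.ncol();
  sc.n = n; sc.d = d;
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    return time[rows[a]] > time[rows[b]];
  });
  sc.X.resize((size_t)n * d);
  for (int j = 0; j < d; ++j)
    for (int p = 0; p < n; ++p)
      sc.X[(size_t)j * n + p] = Xfull(rows[ord[p]], j);
  sc.last.resize(n);
  for (int p = 0; p < n; ++p) sc.last[p] = p;
  for (int p = n - 2; p >= 0; --p)
    if (time[rows[ord[p]]] == time[rows[ord[p + 1]]]) sc.last[p] = sc.last[p + 1];
  for (int p = 0; p < n; ++p)
    if (status[rows[ord[p]]] == 1) sc.ev.push_back(p);
  return sc;
}

// log partial likelihood from a linear predictor on the sorted order
static double loglik_sorted(const std::vector<double>& eta, const SortedCox& sc) {
  if (sc.ev.empty()) return 0.0;
  int n = sc.n;
  double shift = *std::max_element(eta.begin(), eta.end());
  std::vector<double> cs(n);
  double acc = 0.0;
  for (int p = 0; p < n; ++p) { acc += std::exp(eta[p] - shift); cs[p] = acc; }
  double ll = 0.0;
  for (int e : sc.ev) ll += eta[e] - (std::log(cs[sc.last[e]]) + shift);
  return ll;
}

static double loglik_beta(const std::vector<double>& beta, const SortedCox& sc) {
  int n = sc.n;
  std::vector<double> eta(n, 0.0);
  for (int j = 0; j < sc.d; ++j) {
    double b = beta[j];
    if (b == 0.0) continue;
    const double* col = &sc.X[(size_t)j * n];
    for (int p = 0; p < n; ++p) eta[p] += b * col[p];
  }
  return loglik_sorted(eta, sc);
}

// The dual-thresholded iterative gradient algorithm. From beta = 0, each of K
// iterations computes the Cox partial-likelihood gradient g, the gradient
// mask f1 (|g_j| >= tau1 * max|g|), the connectivity mask f2
// (conn_j >= tau2 * max conn; tau2 = 0 switches the connectivity level off,
// which is plain TGDR), and updates beta += dnu * f1 * f2 * g.
//
// Runs on the `train` rows (0-based) of X. At k = 0, stride, 2*stride, ...,
// K it records beta (optional), the training log partial likelihood, and
// (optional) the log partial likelihood on all rows of X, used for
// cross-validated scoring. restrict_f2 takes the connectivity maximum over
// the f1-passing genes only instead of all genes.
// [[Rcpp::export]]
List tgdr_path_engine(const NumericMatrix& X, const NumericVector& time,
                      const IntegerVector& status, const NumericVector& conn,
                      const IntegerVector& train,
                      double tau1, double tau2, double dnu, int K, int stride,
                      bool restrict_f2, bool record_beta, bool score_full) {
  int d = X.ncol(), nfull = X.nrow(), ntr = train.size();
  if (conn.size() != d) stop("connectivity length must equal gene count");
  if (K < 0 || stride < 1) stop("K must be >= 0 and stride >= 1");
  SortedCox tr = sort_design(X, time, status, train);
  SortedCox full;
  if (score_full) {
    IntegerVector all(nfull);
    for (int i = 0; i < nfull; ++i) all[i] = i;
    full = sort_design(X, time, status, all);
  }

  std::vector<double> beta(d, 0.0), g(d, 0.0), eta(ntr, 0.0);
  std::vector<double> w(ntr), cs(ntr), contrib(ntr), v(ntr);
  // the event-side gradient term sum_e x_ej never changes along the path
  std::vector<double> ev_sum(d, 0.0);
  for (int j = 0; j < d; ++j) {
    const double* col = &tr.X[(size_t)j * ntr];
    double a = 0.0;
    for (int e : tr.ev) a += col[e];
    ev_sum[j] = a;
  }

  int nchk = K / stride + 1 + ((K % stride) ? 1 : 0);
  NumericMatrix betas = record_beta ? NumericMatrix(d, nchk) : NumericMatrix(0, 0);
  IntegerVector ks(nchk);
  NumericVector ll_train(nchk), ll_full(nchk);
  int chk = 0;
  auto checkpoint = [&](int k) {
    ks[chk] = k;
    ll_train[chk] = loglik_sorted(eta, tr);
    if (score_full) ll_full[chk] = loglik_beta(beta, full);
    if (record_beta) for (int j = 0; j < d; ++j) betas(j, chk) = beta[j];
    ++chk;
  };
  checkpoint(0);

  double cmax_global = 0.0;
  for (int j = 0; j < d; ++j) if (conn[j] > cmax_global) cmax_global = conn[j];

  std::vector<int> upd; upd.reserve(d);
  for (int k = 1; k <= K; ++k) {
    // gradient: g_j = sum_events [ x_ej - S1_j(e) / S0(e) ]. Exchanging the
    // sums, sum_e S1_j(e)/S0(e) = sum_p x_pj * w_p * r_p with
    // r_p = sum over events whose risk set reaches position p of 1/S0(e),
    // so each gene needs only one dot product per iteration.
    if (!tr.ev.empty()) {
      double shift = *std::max_element(eta.begin(), eta.end());
      double acc = 0.0;
      for (int p = 0; p < ntr; ++p) {
        w[p] = std::exp(eta[p] - shift);
        acc += w[p];
        cs[p] = acc;
      }
      std::fill(contrib.begin(), contrib.end(), 0.0);
      for (int e : tr.ev) contrib[tr.last[e]] += 1.0 / cs[tr.last[e]];
      double r = 0.0;
      for (int p = ntr - 1; p >= 0; --p) { r += contrib[p]; v[p] = w[p] * r; }
      for (int j = 0; j < d; ++j) {
        const double* col = &tr.X[(size_t)j * ntr];
        double dot = 0.0;
        for (int p = 0; p < ntr; ++p) dot += col[p] * v[p];
        g[j] = ev_sum[j] - dot;
      }
    } else {
      std::fill(g.begin(), g.end(), 0.0);
    }
    double gmax = 0.0;
    for (int j = 0; j < d; ++j) { double a = std::fabs(g[j]); if (a > gmax) gmax = a; }
    if (!std::isfinite(gmax))
      stop("non-finite partial likelihood gradient at iteration %d", k);
    upd.clear();
    if (gmax > 0.0) {
      double gthr = tau1 * gmax;
      double cmax = cmax_global;
      if (restrict_f2 && tau2 > 0.0) {
        cmax = 0.0;
        for (int j = 0; j < d; ++j)
          if (std::fabs(g[j]) >= gthr && conn[j] > cmax) cmax = conn[j];
      }
      double cthr = tau2 * cmax;
      for (int j = 0; j < d; ++j) {
        if (std::fabs(g[j]) >= gthr && (tau2 == 0.0 || conn[j] >= cthr))
          upd.push_back(j);
      }
      // tau2 > 0 with an all-zero connectivity vector selects nothing
      if (tau2 > 0.0 && cmax == 0.0) upd.clear();
    }
    for (int j : upd) {
      double step = dnu * g[j];
      beta[j] += step;
      const double* col = &tr.X[(size_t)j * ntr];
      for (int p = 0; p < ntr; ++p) eta[p] += step * col[p];
    }
    if (k % stride == 0 || k == K) checkpoint(k);
  }
  if (chk < nchk) {
    ks = IntegerVector(ks.begin(), ks.begin() + chk);
    ll_train = NumericVector(ll_train.begin(), ll_train.begin() + chk);
    ll_full = NumericVector(ll_full.begin(), ll_full.begin() + chk);
    if (record_beta) betas = betas(Range(0, d - 1), Range(0, chk - 1));
  }
  return List::create(_["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["k"] = ks, _["loglik_train"] = ll_train,
                      _["loglik_full"] = ll_full, _["betas"] = betas);
}
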