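#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Bin index (1-based) of a lag under the (low, high] convention on the grid
// with first edge `lo` and `n_bins` bins of width `w`; 0 if outside.
// A small epsilon keeps exact-boundary lags in their right-closed bin despite
// floating-point round-off.
static inline int lag_bin(double lag, double lo, double w, int nb) {
  double q = (lag - lo) / w;
  int k = (int)std::ceil(q - 1e-9);
  return (k >= 1 && k <= nb) ? k : 0;
}

// [[Rcpp::export]]
IntegerVector cpp_count_lags(NumericVector ref, NumericVector tgt, double lo,
                             double bin_width, int n_bins, bool exclude_self) {
  IntegerVector counts(n_bins);
  const double hi = lo + n_bins * bin_width;
  const int nr = ref.size(), nt = tgt.size();
  int j0 = 0;
  for (int i = 0; i < nr; ++i) {
    const double r = ref[i];
    while (j0 < nt && tgt[j0] - r <= lo) ++j0;
    for (int j = j0; j < nt; ++j) {
      const double lag = tgt[j] - r;
      if (lag > hi) break;
      if (exclude_self && i == j) continue;
      const int k = lag_bin(lag, lo, bin_width, n_bins);
      if (k) counts[k - 1]++;
    }
  }
  return counts;
}

// Binary spike-lag matrix: one row per reference spike, one column per lag
// bin; entry 1 when at least one target spike falls in that bin.
// [[Rcpp::export]]
IntegerMatrix cpp_lag_matrix(NumericVector ref, NumericVector tgt, double lo,
                             double bin_width, int n_bins) {
  const int nr = ref.size(), nt = tgt.size();
  IntegerMatrix M(nr, n_bins);
  const double hi = lo + n_bins * bin_width;
  int j0 = 0;
  for (int i = 0; i < nr; ++i) {
    const double r = ref[i];
    while (j0 < nt && tgt[j0] - r <= lo) ++j0;
    for (int j = j0; j < nt; ++j) {
      const double lag = tgt[j] - r;
      if (lag > hi) break;
      const int k = lag_bin(lag, lo, bin_width, n_bins);
      if (k) M(i, k - 1) = 1;
    }
  }
  return M;
}

static void hollowed_median_core(const double* x, int n, int h, double* out) {
  std::vector<double> buf;
  buf.reserve(2 * h);
  for (int i = 0; i < n; ++i) {
    buf.clear();
    const int a = std::max(0, i - h), b = std::min(n - 1, i + h);
    for (int j = a; j <= b; ++j)
      if (j != i) buf.push_back(x[j]);
    const int m = (int)buf.size();
    std::sort(buf.begin(), buf.end());
    out[i] = (m % 2) ? buf[m / 2] : 0.5 * (buf[m / 2 - 1] + buf[m / 2]);
  }
}

// [[Rcpp::export]]
NumericVector cpp_hollowed_median(NumericVector x, int h) {
  const int n = x.size();
  NumericVector out(n);
  hollowed_median_core(REAL(x), n, h, REAL(out));
  return out;
}

// Area under the causal peak: peak bin within the ROI
// [first0, first0 + n_roi) (0-based), extended left (not below first0) and
// right until the curve first drops to <= 0.
static double stg_region_core(const double* c, int nb, int first0, int n_roi) {
  int peak = -1;
  double best = 0.0;
  const int lim = std::min(nb, first0 + n_roi);
  for (int i = first0; i < lim; ++i)
    if (c[i] > best) { best = c[i]; peak = i; }
  if (peak < 0) return 0.0;
  double s = 0.0;
  for (int i = peak; i >= first0 && c[i] > 0; --i) s += c[i];
  for (int i = peak + 1; i < nb && c[i] > 0; ++i) s += c[i];
  return s;
}

// [[Rcpp::export]]
double cpp_stg_region(NumericVector curve, int first0, int n_roi) {
  return stg_region_core(REAL(curve), curve.size(), first0, n_roi);
}

// [[Rcpp::export]]
NumericVector cpp_enforce_refractory(NumericVector times, double refractory) {
  const int n = times.size();
  std::vector<double> keep;
  keep.reserve(n);
  double last = -1e300;
  for (int i = 0; i < n; ++i) {
    if (times[i] - last >= refractory) {
      keep.push_back(times[i]);
      last = times[i];
    }
  }
  return NumericVector(keep.begin(), keep.end());
}

// Row-label permutation core for the STG-change test.
//
// M: binary lag matrix (rows = presyn spikes from Before + After).
// before: original row labels. P: deconvolution solve operator such that
// curve = P %*% ((counts - hollowed_median(counts, h)) / n_rows_in_partition).
// Observed statistic and every shuffle run through the identical path.
// Shuffles whose Before or After STG is non-positive (log ratio undefined)
// are discarded and resampled, up to max_attempts draws in total.
// [[Rcpp::export]]
List cpp_perm_stg_change(IntegerMatrix M, LogicalVector before, arma::mat P,
                         int h, int first0, int n_roi, int n_shuffles,
                         int max_attempts) {
  const int nrow = M.nrow(), nb = M.ncol();
  std::vector<std::vector<int> > nz(nrow);
  arma::vec total(nb, arma::fill::zeros);
  for (int c = 0; c < nb; ++c)
    for (int r = 0; r < nrow; ++r)
      if (M(r, c)) { nz[r].push_back(c); total[c] += 1.0; }

  int nB = 0;
  for (int r = 0; r < nrow; ++r) nB += before[r] ? 1 : 0;
  const int nA = nrow - nB;
  if (nB < 1 || nA < 1) stop("both epochs need at least one presyn spike");

  std::vector<double> baseB(nb), baseA(nb);
  arma::vec cb(nb), ca(nb), bb(nb), ba(nb);

  // returns true and writes the log2 STG ratio when both STGs are positive
  std::vector<int> lab(nrow);
  auto eval = [&](double& out) -> bool {
    cb.zeros();
    for (int r = 0; r < nrow; ++r)
      if (lab[r])
        for (size_t k = 0; k < nz[r].size(); ++k) cb[nz[r][k]] += 1.0;
    ca = total - cb;
    hollowed_median_core(cb.memptr(), nb, h, baseB.data());
    hollowed_median_core(ca.memptr(), nb, h, baseA.data());
    for (int i = 0; i < nb; ++i) {
      bb[i] = (cb[i] - baseB[i]) / (double)nB;
      ba[i] = (ca[i] - baseA[i]) / (double)nA;
    }
    arma::vec curB = P * bb;
    arma::vec curA = P * ba;
    const double sB = stg_region_core(curB.memptr(), nb, first0, n_roi);
    const double sA = stg_region_core(curA.memptr(), nb, first0, n_roi);
    if (sB <= 0.0 || sA <= 0.0) return false;
    out = std::log2(sA / sB);
    return true;
  };

  for (int r = 0; r < nrow; ++r) lab[r] = before[r] ? 1 : 0;
  double obs = NA_REAL;
  const bool obs_ok = eval(obs);

  std::vector<double> nullv;
  nullv.reserve(n_shuffles);
  int attempts = 0;
  while ((int)nullv.size() < n_shuffles && attempts < max_attempts) {
    ++attempts;
    for (int i = nrow - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(lab[i], lab[j]);
    }
    double ch;
    if (eval(ch)) nullv.push_back(ch);
  }

  return List::create(_["observed"] = obs_ok ? obs : NA_REAL,
                      _["null"] = NumericVector(nullv.begin(), nullv.end()),
                      _["attempts"] = attempts);
}
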