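#include <Rcpp.h>
using namespace Rcpp;

// Tabular (recursive) kinship for a pedigree already sorted so that every
// parent precedes its offspring. `father` and `mother` are 0-based indices
// into the sorted order, or NA for unknown parents. Founders are assumed
// unrelated and non-inbred; an unknown parent contributes 0 to the
// recursion.
//
// K(i,i) = 0.5 * (1 + K(fa_i, mo_i))
// K(i,j) = 0.5 * (K(fa_i, j) + K(mo_i, j))   for j earlier than i

// [[Rcpp::export]]
NumericMatrix kinship_cpp(IntegerVector father, IntegerVector mother) {
  int n = father.size();
  NumericMatrix K(n, n);
  for (int i = 0; i < n; ++i) {
    int fa = father[i], mo = mother[i];
    bool has_fa = fa != NA_INTEGER, has_mo = mo != NA_INTEGER;
    if (has_fa && fa >= i) stop("pedigree not in parent-first order");
    if (has_mo && mo >= i) stop("pedigree not in parent-first order");
    for (int j = 0; j < i; ++j) {
      double k = 0.0;
      if (has_fa) k += K(fa, j);
      if (has_mo) k += K(mo, j);
      k *= 0.5;
      K(i, j) = k;
      K(j, i) = k;
    }
    double f = (has_fa && has_mo) ? K(fa, mo) : 0.0;
    K(i, i) = 0.5 * (1.0 + f);
  }
  return K;
}

// Summary statistics that would otherwise require materialising the full
// kinship matrix per simulation replicate: mean additive relatedness
// (2K) over unordered distinct pairs, the inbreeding coefficient vector,
// and counts of nonzero and close (f >= 0.125) inbreeding events.
// Single O(n^2) pass over the same recursion as kinship_cpp.

// [[Rcpp::export]]
List kinship_stats_cpp(IntegerVector father, IntegerVector mother) {
  int n = father.size();
  NumericMatrix K(n, n);
  NumericVector f(n);
  double off_sum = 0.0;
  for (int i = 0; i < n; ++i) {
    int fa = father[i], mo = mother[i];
    bool has_fa = fa != NA_INTEGER, has_mo = mo != NA_INTEGER;
    if (has_fa && fa >= i) stop("pedigree not in parent-first order");
    if (has_mo && mo >= i) stop("pedigree not in parent-first order");
    for (int j = 0; j < i; ++j) {
      double k = 0.0;
      if (has_fa) k += K(fa, j);
      if (has_mo) k += K(mo, j);
      k *= 0.5;
      K(i, j) = k;
      K(j, i) = k;
      off_sum += k;
    }
    double fi = (has_fa && has_mo) ? K(fa, mo) : 0.0;
    f[i] = fi;
    K(i, i) = 0.5 * (1.0 + fi);
  }
  int n_nonzero = 0, n_close = 0;
  double f_sum = 0.0;
  for (int i = 0; i < n; ++i) {
    f_sum += f[i];
    if (f[i] > 0) ++n_nonzero;
    if (f[i] >= 0.125) ++n_close;
  }
  double n_pairs = (double)n * (n - 1.0) / 2.0;
  double mean_r = n_pairs > 0 ? 2.0 * off_sum / n_pairs : NA_REAL;
  return List::create(
    _["mean_relatedness"] = mean_r,
    _["f"] = f,
    _["mean_f"] = n > 0 ? f_sum / n : NA_REAL,
    _["n_f_nonzero"] = n_nonzero,
    _["n_f_close"] = n_close);
}

// Batch variant for simulation ensembles: for each replicate column of
// `sires`, the focal individuals' fathers are replaced and the four
// kinship-derived summary statistics recomputed, reusing one K buffer
// across replicates. `father`, `mother`, `focal` and `sires` are
// 0-based positions in the sorted (parent-first) order.

// [[Rcpp::export]]
List kinship_stats_batch_cpp(IntegerVector father, IntegerVector mother,
                             IntegerVector focal, IntegerMatrix sires) {
  int n = father.size(), nf = focal.size(), R = sires.ncol();
  if (sires.nrow() != nf) stop("sires/focal dimension mismatch");
  std::vector<double> K((size_t)n * n);
  std::vector<int> fa(father.begin(), father.end());
  std::vector<double> f(n);
  NumericVector mean_r(R), mean_f(R);
  IntegerVector n_nonzero(R), n_close(R);
  double n_pairs = (double)n * (n - 1.0) / 2.0;
  for (int r = 0; r < R; ++r) {
    for (int k = 0; k < nf; ++k) fa[focal[k]] = sires(k, r);
    double off_sum = 0.0, f_sum = 0.0;
    int nz = 0, ncl = 0;
    for (int i = 0; i < n; ++i) {
      int fi = fa[i], mi = mother[i];
      bool has_f = fi != NA_INTEGER, has_m = mi != NA_INTEGER;
      if ((has_f && fi >= i) || (has_m && mi >= i))
        stop("pedigree not in parent-first order");
      double *Ki = &K[(size_t)i * n];
      const double *Kf = has_f ? &K[(size_t)fi * n] : nullptr;
      const double *Km = has_m ? &K[(size_t)mi * n] : nullptr;
      for (int j = 0; j < i; ++j) {
        double k2 = 0.0;
        if (Kf) k2 += Kf[j];
        if (Km) k2 += Km[j];
        k2 *= 0.5;
        Ki[j] = k2;
        K[(size_t)j * n + i] = k2;
        off_sum += k2;
      }
      double fi_coef = (has_f && has_m) ? Kf[mi] : 0.0;
      f[i] = fi_coef;
      Ki[i] = 0.5 * (1.0 + fi_coef);
      f_sum += fi_coef;
      if (fi_coef > 0) ++nz;
      if (fi_coef >= 0.125) ++ncl;
    }
    mean_r[r] = n_pairs > 0 ? 2.0 * off_sum / n_pairs : NA_REAL;
    mean_f[r] = n > 0 ? f_sum / n : NA_REAL;
    n_nonzero[r] = nz;
    n_close[r] = ncl;
  }
  return List::create(
    _["mean_relatedness"] = mean_r,
    _["mean_f"] = mean_f,
    _["n_f_nonzero"] = n_nonzero,
    _["n_f_close"] = n_close);
}
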