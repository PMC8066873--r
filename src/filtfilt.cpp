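#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with zero initial conditions,
// applied in place to one column.
static void iir_col(const std::vector<double>& b, const std::vector<double>& a,
                    std::vector<double>& x) {
  // b and a arrive zero-padded to equal length (nz + 1)
  const int nz = (int)b.size() - 1;
  std::vector<double> z(nz + 1, 0.0);
  const double* bp = b.data();
  const double* ap = a.data();
  double* zp = z.data();
  const size_t n = x.size();
  for (size_t i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bp[0] * xi + zp[0];
    for (int k = 1; k <= nz; ++k)
      zp[k - 1] = bp[k] * xi + zp[k] - ap[k] * yi;
    x[i] = yi;
  }
}

static void normalize_coefs(NumericVector b, NumericVector a,
                            std::vector<double>& bb, std::vector<double>& aa) {
  bb.assign(b.begin(), b.end());
  aa.assign(a.begin(), a.end());
  const double a0 = aa[0];
  for (double& v : bb) v /= a0;
  for (double& v : aa) v /= a0;
  const size_t nmax = std::max(bb.size(), aa.size());
  bb.resize(nmax, 0.0);
  aa.resize(nmax, 0.0);
}

// Forward-backward (zero-phase) filtering of every column of X, with
// 2 * max(filter length) zeros appended before the forward pass (zero
// initial conditions).
// [[Rcpp::export(name = ".filtfilt_cols_cpp")]]
NumericMatrix filtfilt_cols_cpp(NumericVector b, NumericVector a, NumericMatrix X) {
  const int n = X.nrow(), m = X.ncol();
  std::vector<double> bb, aa;
  normalize_coefs(b, a, bb, aa);
  const int pad = 2 * (int)bb.size();
  NumericMatrix out(n, m);
  std::vector<double> col(n + pad);
  for (int j = 0; j < m; ++j) {
    std::fill(col.begin(), col.end(), 0.0);
    for (int i = 0; i < n; ++i) col[i] = X(i, j);
    iir_col(bb, aa, col);
    std::reverse(col.begin(), col.end());
    iir_col(bb, aa, col);
    std::reverse(col.begin(), col.end());
    for (int i = 0; i < n; ++i) out(i, j) = col[i];
  }
  return out;
}

// Row-wise variant: filters each row of X (channels x samples layout)
// without materializing transposes on the R side.
// [[Rcpp::export(name = ".filtfilt_rows_cpp")]]
NumericMatrix filtfilt_rows_cpp(NumericVector b, NumericVector a, NumericMatrix X) {
  const int m = X.nrow(), n = X.ncol();
  std::vector<double> bb, aa;
  normalize_coefs(b, a, bb, aa);
  const int pad = 2 * (int)bb.size();
  NumericMatrix out(m, n);
  std::vector<double> row(n + pad);
  for (int j = 0; j < m; ++j) {
    std::fill(row.begin(), row.end(), 0.0);
    for (int i = 0; i < n; ++i) row[i] = X(j, i);
    iir_col(bb, aa, row);
    std::reverse(row.begin(), row.end());
    iir_col(bb, aa, row);
    std::reverse(row.begin(), row.end());
    for (int i = 0; i < n; ++i) out(j, i) = row[i];
  }
  return out;
}
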