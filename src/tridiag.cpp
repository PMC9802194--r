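#include <Rcpp.h>
using namespace Rcpp;

// Thomas factorization of a constant tridiagonal system M x = rhs.
// dl: sub-diagonal (length n-1), d: diagonal (n), du: super-diagonal (n-1).
// Factor once, then forward/backward sweeps per right-hand side.
struct ThomasFactor {
  int n;
  std::vector<double> cp;     // modified super-diagonal
  std::vector<double> denom;  // pivots
  const double *dl;

  ThomasFactor(const NumericVector &dl_, const NumericVector &d_,
               const NumericVector &du_)
      : n(d_.size()), cp(d_.size()), denom(d_.size()), dl(dl_.begin()) {
    denom[0] = d_[0];
    if (denom[0] == 0.0) stop("singular tridiagonal system (zero pivot)");
    cp[0] = (n > 1) ? du_[0] / denom[0] : 0.0;
    for (int i = 1; i < n; ++i) {
      denom[i] = d_[i] - dl_[i - 1] * cp[i - 1];
      if (denom[i] == 0.0) stop("singular tridiagonal system (zero pivot)");
      cp[i] = (i < n - 1) ? du_[i] / denom[i] : 0.0;
    }
  }

  void solve(const double *rhs, double *x) const {
    x[0] = rhs[0] / denom[0];
    for (int i = 1; i < n; ++i)
      x[i] = (rhs[i] - dl[i - 1] * x[i - 1]) / denom[i];
    for (int i = n - 2; i >= 0; --i) x[i] -= cp[i] * x[i + 1];
  }
};

// [[Rcpp::export]]
NumericVector tridiag_solve_cpp(NumericVector dl, NumericVector d,
                                NumericVector du, NumericVector rhs) {
  ThomasFactor f(dl, d, du);
  NumericVector out(d.size());
  f.solve(rhs.begin(), out.begin());
  return out;
}

// Backward-Euler march of M x_{k+1} = x_k + b for a constant system,
// returning snapshots at the (1-based) step indices in `keep`.
// [[Rcpp::export]]
NumericMatrix tridiag_march_cpp(NumericVector dl, NumericVector d,
                                NumericVector du, NumericVector b,
                                NumericVector x0, int n_steps,
                                IntegerVector keep) {
  int n = d.size();
  ThomasFactor f(dl, d, du);
  NumericMatrix out(n, keep.size());
  std::vector<double> x(x0.begin(), x0.end()), rhs(n);
  int ki = 0;
  for (int s = 1; s <= n_steps; ++s) {
    for (int i = 0; i < n; ++i) rhs[i] = x[i] + b[i];
    f.solve(rhs.data(), x.data());
    while (ki < keep.size() && keep[ki] == s) {
      for (int i = 0; i < n; ++i) out(i, ki) = x[i];
      ++ki;
    }
  }
  if (ki != keep.size()) stop("internal error: snapshot schedule not consumed");
  return out;
}

// Coupled pigment march: chlorophyll a decays (implicitly) and feeds
// pheopigment through yield * k_chl * chl evaluated at the new time level.
// Mc chl_{k+1} = chl_k + bc ; Mp pheo_{k+1} = pheo_k + bp + src * chl_{k+1}.
// src = dt * yield * k_chl (per cell).
// [[Rcpp::export]]
List pigment_march_cpp(NumericVector dlc, NumericVector dc, NumericVector duc,
                       NumericVector bc, NumericVector dlp, NumericVector dp,
                       NumericVector dup, NumericVector bp, NumericVector src,
                       NumericVector chl0, NumericVector pheo0, int n_steps,
                       IntegerVector keep) {
  int n = dc.size();
  ThomasFactor fc(dlc, dc, duc), fp(dlp, dp, dup);
  NumericMatrix chl_out(n, keep.size()), pheo_out(n, keep.size());
  std::vector<double> chl(chl0.begin(), chl0.end()),
      pheo(pheo0.begin(), pheo0.end()), rhs(n);
  int ki = 0;
  for (int s = 1; s <= n_steps; ++s) {
    for (int i = 0; i < n; ++i) rhs[i] = chl[i] + bc[i];
    fc.solve(rhs.data(), chl.data());
    for (int i = 0; i < n; ++i) rhs[i] = pheo[i] + bp[i] + src[i] * chl[i];
    fp.solve(rhs.data(), pheo.data());
    while (ki < keep.size() && keep[ki] == s) {
      for (int i = 0; i < n; ++i) {
        chl_out(i, ki) = chl[i];
        pheo_out(i, ki) = pheo[i];
      }
      ++ki;
    }
  }
  if (ki != keep.size()) stop("internal error: snapshot schedule not consumed");
  return List::create(_["chl"] = chl_out, _["pheo"] = pheo_out);
}
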