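#include <Rcpp.h>
using namespace Rcpp;

// One direct-form-II-transposed pass.  Specialized small-order loops keep
// the state in registers; the IIR recurrence is otherwise latency-bound.
template <int M>
static void filt_fixed(const double* b, const double* a, double* x, int n) {
  double z[M - 1] = {0.0};
  for (int t = 0; t < n; ++t) {
    const double xt = x[t];
    const double yt = b[0] * xt + z[0];
    for (int k = 1; k < M - 1; ++k)
      z[k - 1] = b[k] * xt - a[k] * yt + z[k];
    z[M - 2] = b[M - 1] * xt - a[M - 1] * yt;
    x[t] = yt;
  }
}

static void filt_generic(const std::vector<double>& b,
                         const std::vector<double>& a, double* x, int n) {
  const int m = (int)b.size();
  switch (m) {
    case 3: filt_fixed<3>(b.data(), a.data(), x, n); return;
    case 5: filt_fixed<5>(b.data(), a.data(), x, n); return;
    case 7: filt_fixed<7>(b.data(), a.data(), x, n); return;
    case 9: filt_fixed<9>(b.data(), a.data(), x, n); return;
  }
  std::vector<double> z(m, 0.0);
  for (int t = 0; t < n; ++t) {
    const double xt = x[t];
    const double yt = b[0] * xt + z[0];
    for (int k = 1; k < m; ++k)
      z[k - 1] = b[k] * xt - a[k] * yt + z[k];
    x[t] = yt;
  }
}

// Zero-phase IIR filtering of each row of a channels x samples matrix:
// odd-reflection end padding (3 * filter order), forward pass, backward
// pass.  Coefficients come from signal::butter upstream (normalized a[0]=1,
// b and a padded to equal length).
// [[Rcpp::export(name = ".filtfilt_rows")]]
NumericMatrix filtfilt_rows(NumericVector b, NumericVector a, NumericMatrix x) {
  const int nch = x.nrow(), n = x.ncol();
  const int m = (int)std::max(a.size(), b.size());
  if (n < 2) stop("signal too short to filter");
  if (a.size() == 0 || a[0] == 0.0) stop("invalid filter: a[1] must be nonzero");
  std::vector<double> bv(m, 0.0), av(m, 0.0);
  for (int i = 0; i < b.size(); ++i) bv[i] = b[i] / a[0];
  for (int i = 0; i < a.size(); ++i) av[i] = a[i] / a[0];
  const int pad = std::min(3 * (m - 1) > 0 ? 3 * (m - 1) : 1, n - 1);
  NumericMatrix out(nch, n);
  const int nw = n + 2 * pad;
  std::vector<double> w(nw);
  for (int c = 0; c < nch; ++c) {
    for (int i = 0; i < pad; ++i) w[i] = 2.0 * x(c, 0) - x(c, pad - i);
    for (int i = 0; i < n; ++i) w[pad + i] = x(c, i);
    for (int i = 0; i < pad; ++i)
      w[pad + n + i] = 2.0 * x(c, n - 1) - x(c, n - 2 - i);
    filt_generic(bv, av, w.data(), nw);
    std::reverse(w.begin(), w.end());
    filt_generic(bv, av, w.data(), nw);
    std::reverse(w.begin(), w.end());
    for (int i = 0; i < n; ++i) out(c, i) = w[pad + i];
  }
  return out;
}

struct SinCos {
  std::vector<double> s, c;
  int nch, n;
  SinCos(const NumericMatrix& phi)
      : s(phi.nrow() * phi.ncol()), c(phi.nrow() * phi.ncol()),
        nch(phi.nrow()), n(phi.ncol()) {
    for (int j = 0; j < nch; ++j)
      for (int t = 0; t < n; ++t) {
        s[j * n + t] = std::sin(phi(j, t));
        c[j * n + t] = std::cos(phi(j, t));
      }
  }
  const double* srow(int j) const { return s.data() + j * n; }
  const double* crow(int j) const { return c.data() + j * n; }
};

// wPLI and PLV matrices for one hyper-epoch from the two members' phase
// series.  phim: mother channels x samples, phii: infant channels x samples.
// Entry (j, k) uses the phase difference phi_mother_j - phi_infant_k.
// wPLI = |mean(sin dphi)| / mean(|sin dphi|)   (0 when the denominator is 0)
// PLV  = |mean(exp(i dphi))|
// [[Rcpp::export(name = ".wpli_plv_matrices")]]
List wpli_plv_matrices(NumericMatrix phim, NumericMatrix phii) {
  const int nm = phim.nrow(), ni = phii.nrow(), n = phim.ncol();
  if (phii.ncol() != n) stop("phase series lengths differ between members");
  SinCos M(phim), I(phii);
  NumericMatrix wpli(nm, ni), plv(nm, ni);
  for (int j = 0; j < nm; ++j) {
    const double *sm = M.srow(j), *cm = M.crow(j);
    for (int k = 0; k < ni; ++k) {
      const double *si = I.srow(k), *ci = I.crow(k);
      double s = 0.0, sa = 0.0, re = 0.0;
      for (int t = 0; t < n; ++t) {
        const double x = sm[t] * ci[t] - cm[t] * si[t]; // sin(phi_m - phi_i)
        s += x; sa += std::fabs(x);
        re += cm[t] * ci[t] + sm[t] * si[t];            // cos(phi_m - phi_i)
      }
      wpli(j, k) = (sa > 0.0) ? std::fabs(s) / sa : 0.0;
      plv(j, k) = std::sqrt(re * re + s * s) / n;
    }
  }
  return List::create(_["wpli"] = wpli, _["plv"] = plv);
}

// Permutation surrogate test for one hyper-epoch.  For every channel pair a
// fresh uniform permutation of the time order of the mother's phase series
// is drawn per surrogate (using R's RNG, so seeding upstream makes the
// result deterministic), the statistic recomputed, and the number of
// surrogates strictly below the observed value counted.  Returns observed
// wPLI and PLV matrices plus the strict-exceedance counts for both.
// [[Rcpp::export(name = ".surrogate_counts")]]
List surrogate_counts(NumericMatrix phim, NumericMatrix phii, int n_surrogates,
                      bool count_plv) {
  const int nm = phim.nrow(), ni = phii.nrow(), n = phim.ncol();
  if (phii.ncol() != n) stop("phase series lengths differ between members");
  if (n_surrogates < 0) stop("n_surrogates must be >= 0");
  RNGScope scope;
  SinCos M(phim), I(phii);
  NumericMatrix wpli(nm, ni), plv(nm, ni);
  IntegerMatrix wpli_below(nm, ni), plv_below(nm, ni);
  std::vector<int> perm(n);
  for (int j = 0; j < nm; ++j) {
    const double *sm = M.srow(j), *cm = M.crow(j);
    for (int k = 0; k < ni; ++k) {
      const double *si = I.srow(k), *ci = I.crow(k);
      double s = 0.0, sa = 0.0, re = 0.0;
      for (int t = 0; t < n; ++t) {
        const double x = sm[t] * ci[t] - cm[t] * si[t];
        s += x; sa += std::fabs(x);
        re += cm[t] * ci[t] + sm[t] * si[t];
      }
      const double obs_w = (sa > 0.0) ? std::fabs(s) / sa : 0.0;
      const double obs_p = std::sqrt(re * re + s * s) / n;
      wpli(j, k) = obs_w; plv(j, k) = obs_p;
      int bw = 0, bp = 0;
      for (int su = 0; su < n_surrogates; ++su) {
        for (int t = 0; t < n; ++t) perm[t] = t;
        for (int t = n - 1; t > 0; --t) {          // Fisher-Yates, R RNG
          int r = (int)(unif_rand() * (t + 1));
          if (r > t) r = t;
          std::swap(perm[t], perm[r]);
        }
        double ss = 0.0, ssa = 0.0, sre = 0.0;
        for (int t = 0; t < n; ++t) {
          const int p = perm[t];
          const double x = sm[p] * ci[t] - cm[p] * si[t];
          ss += x; ssa += std::fabs(x);
          if (count_plv) sre += cm[p] * ci[t] + sm[p] * si[t];
        }
        const double sw = (ssa > 0.0) ? std::fabs(ss) / ssa : 0.0;
        if (sw < obs_w) ++bw;
        if (count_plv) {
          const double sp = std::sqrt(sre * sre + ss * ss) / n;
          if (sp < obs_p) ++bp;
        }
      }
      wpli_below(j, k) = bw;
      if (count_plv) plv_below(j, k) = bp;
    }
  }
  return List::create(_["wpli"] = wpli, _["plv"] = plv,
                      _["wpli_below"] = wpli_below, _["plv_below"] = plv_below);
}
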