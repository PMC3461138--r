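#include <Rcpp.h>
using namespace Rcpp;

// Pseudo-likelihood core for the temporal method.
//
// Each allele class at a locus is treated as one biallelic chain: its
// frequency evolves on a grid of states `pgrid` (exact count states
// j/2Ne when exact = true, 401 equispaced frequencies otherwise). One
// generation applies a deterministic migration pull
// p' = (1-m) p + m ps toward a fixed (infinite) source frequency, then
// binomial Wright-Fisher drift with 2Ne draws. The earlier sample (a0
// copies out of n0) enters via its binomial sampling posterior under a
// uniform grid prior; the later sample's (at out of nt) binomial
// likelihood is integrated over the propagated distribution.
//
// The transition kernel is time-homogeneous, so its (sparse) rows are
// built once per chain and re-applied tgen times. On the exact grid rows
// come from the binomial recursion around the mode (relative cutoff
// 1e-12); on the equispaced grid from a normal approximation integrated
// over cell boundaries within +/- 6 sd (tails absorbed at the window
// edges).

namespace {

struct Kernel {
  std::vector<int> start, len;
  std::vector<double> val;   // concatenated row values
  std::vector<int> offset;   // row start positions in val
};

void build_kernel(const NumericVector& pgrid, double twoNe, double m,
                  double ps, bool exact, Kernel& K) {
  const int S = pgrid.size();
  K.start.assign(S, 0); K.len.assign(S, 0); K.offset.assign(S, 0);
  K.val.clear();
  std::vector<double> row;
  for (int i = 0; i < S; ++i) {
    double pp = (1.0 - m) * pgrid[i] + m * ps;
    K.offset[i] = (int)K.val.size();
    if (pp <= 0.0) {
      K.start[i] = 0; K.len[i] = 1; K.val.push_back(1.0); continue;
    }
    if (pp >= 1.0) {
      K.start[i] = S - 1; K.len[i] = 1; K.val.push_back(1.0); continue;
    }
    if (exact) {
      int n = S - 1;                    // n = 2Ne
      int j0 = (int)std::floor(n * pp);
      double peak = std::exp(R::dbinom(j0, n, pp, 1));
      double cut = 1e-12 * peak;
      double r = pp / (1.0 - pp);
      int jlo = j0, jhi = j0;
      double b = peak;
      for (int j = j0; j > 0; --j) {    // find lower extent
        b *= (double)j / (r * (double)(n - j + 1));
        if (b < cut) break;
        jlo = j - 1;
      }
      row.clear();
      // rebuild from jlo upward
      b = std::exp(R::dbinom(jlo, n, pp, 1));
      for (int j = jlo; j <= n; ++j) {
        row.push_back(b);
        jhi = j;
        b *= r * (double)(n - j) / (double)(j + 1);
        if (j > j0 && b < cut) break;
      }
      K.start[i] = jlo; K.len[i] = jhi - jlo + 1;
      for (double x : row) K.val.push_back(x);
    } else {
      double sdev = std::sqrt(pp * (1.0 - pp) / twoNe);
      double h = pgrid[1] - pgrid[0];
      int jc = (int)std::lround(pp / h);
      int hw = (int)std::ceil(6.0 * sdev / h) + 1;
      int jlo = std::max(0, jc - hw), jhi = std::min(S - 1, jc + hw);
      K.start[i] = jlo; K.len[i] = jhi - jlo + 1;
      // midpoint-rule normal density, normalised to a probability row
      double inv2v = 1.0 / (2.0 * sdev * sdev);
      size_t base = K.val.size();
      double rowsum = 0.0;
      for (int j = jlo; j <= jhi; ++j) {
        double d = pgrid[j] - pp;
        double mass = std::exp(-d * d * inv2v);
        K.val.push_back(mass);
        rowsum += mass;
      }
      for (size_t j = base; j < K.val.size(); ++j) K.val[j] /= rowsum;
    }
  }
}

double chain_loglik(const Kernel& K, const NumericVector& pgrid,
                    int a0, int n0, int at, int nt, int tgen) {
  const int S = pgrid.size();
  std::vector<double> v(S), w(S);
  double tot = 0.0;
  for (int j = 0; j < S; ++j) {
    v[j] = R::dbinom(a0, n0, pgrid[j], 0);
    tot += v[j];
  }
  if (tot <= 0.0) return -690.0;
  for (int j = 0; j < S; ++j) v[j] /= tot;
  for (int g = 0; g < tgen; ++g) {
    std::fill(w.begin(), w.end(), 0.0);
    for (int i = 0; i < S; ++i) {
      double vi = v[i];
      if (vi <= 0.0) continue;
      const double* rv = &K.val[K.offset[i]];
      double* wt = &w[K.start[i]];
      int L = K.len[i];
      for (int j = 0; j < L; ++j) wt[j] += vi * rv[j];
    }
    std::swap(v, w);
  }
  double lik = 0.0;
  for (int j = 0; j < S; ++j)
    if (v[j] > 0.0) lik += v[j] * R::dbinom(at, nt, pgrid[j], 0);
  if (lik < 1e-300) lik = 1e-300;
  return std::log(lik);
}

} // namespace

// Log-likelihood of one allele chain (exposed for oracle comparisons).
// [[Rcpp::export]]
double pml_chain_loglik_cpp(int a0, int n0, int at, int nt, int tgen,
                            double twoNe, double m, double ps,
                            NumericVector pgrid, bool exact) {
  Kernel K;
  build_kernel(pgrid, twoNe, m, ps, exact, K);
  return chain_loglik(K, pgrid, a0, n0, at, nt, tgen);
}

// Summed log-likelihood over all chains at one (Ne, m) grid point.
// When m = 0 the kernel is shared across chains.
// [[Rcpp::export]]
double pml_loglik_cpp(IntegerVector a0, IntegerVector n0,
                      IntegerVector at, IntegerVector nt,
                      NumericVector ps, int tgen,
                      double twoNe, double m,
                      NumericVector pgrid, bool exact) {
  const int nchain = a0.size();
  double total = 0.0;
  Kernel K;
  if (m == 0.0) {
    build_kernel(pgrid, twoNe, 0.0, 0.0, exact, K);
    for (int c = 0; c < nchain; ++c)
      total += chain_loglik(K, pgrid, a0[c], n0[c], at[c], nt[c], tgen);
  } else {
    for (int c = 0; c < nchain; ++c) {
      build_kernel(pgrid, twoNe, m, ps[c], exact, K);
      total += chain_loglik(K, pgrid, a0[c], n0[c], at[c], nt[c], tgen);
    }
  }
  return total;
}
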