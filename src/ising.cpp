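#include <Rcpp.h>
using namespace Rcpp;

// Metropolis Monte Carlo for the generalized Ising model
//   E(s) = -sum_{i,j} J_ij s_i s_j   (full double sum, J symmetric, zero diag)
// Single-flip energy change: dE = 4 * s_k * h_k with local field h = J s.
// J is traversed through per-site neighbour lists, so sparse couplings
// (lattices, lesioned connectomes) cost O(degree) per update, and the
// recorded energy is recomputed exactly from the neighbour lists at every
// sample. All randomness comes from R's RNG (unif_rand), so set.seed() on
// the R side makes every trajectory reproducible.

struct Couplings {
  int n;
  std::vector<std::vector<int> > nbr;
  std::vector<std::vector<double> > w;
  explicit Couplings(const NumericMatrix& J) : n(J.nrow()), nbr(n), w(n) {
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        if (J(i, j) != 0.0) { nbr[i].push_back(j); w[i].push_back(J(i, j)); }
  }
  void local_field(const std::vector<double>& s, std::vector<double>& h) const {
    for (int i = 0; i < n; ++i) {
      double hi = 0.0;
      const std::vector<int>& ni = nbr[i];
      const std::vector<double>& wi = w[i];
      for (size_t t = 0; t < ni.size(); ++t) hi += wi[t] * s[ni[t]];
      h[i] = hi;
    }
  }
  double energy(const std::vector<double>& s) const {
    double e = 0.0;
    for (int i = 0; i < n; ++i) {
      double hi = 0.0;
      const std::vector<int>& ni = nbr[i];
      const std::vector<double>& wi = w[i];
      for (size_t t = 0; t < ni.size(); ++t) hi += wi[t] * s[ni[t]];
      e += s[i] * hi;
    }
    return -e;
  }
};

static inline int pick_site(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static inline void flip(const Couplings& C, std::vector<double>& s,
                        std::vector<double>& h, int k) {
  double old = s[k];
  s[k] = -old;
  const std::vector<int>& nk = C.nbr[k];
  const std::vector<double>& wk = C.w[k];
  for (size_t t = 0; t < nk.size(); ++t) h[nk[t]] -= 2.0 * old * wk[t];
}

// One or more sweeps (N proposals each, random site with replacement).
// [[Rcpp::export]]
IntegerVector cpp_metropolis_sweeps(NumericMatrix J, IntegerVector spins,
                                    double temperature, int n_sweeps) {
  Couplings C(J);
  const int n = C.n;
  std::vector<double> s(n), h(n);
  for (int i = 0; i < n; ++i) s[i] = (double)spins[i];
  C.local_field(s, h);
  GetRNGstate();
  for (int sw = 0; sw < n_sweeps; ++sw) {
    for (int p = 0; p < n; ++p) {
      int k = pick_site(n);
      double dE = 4.0 * s[k] * h[k];
      if (dE <= 0.0 || unif_rand() < std::exp(-dE / temperature))
        flip(C, s, h, k);
    }
  }
  PutRNGstate();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = (int)s[i];
  return out;
}

// Full single-temperature simulation: equilibrate, then record n_samples
// configurations every sample_interval sweeps.
// [[Rcpp::export]]
List cpp_ising_simulate(NumericMatrix J, IntegerVector init,
                        double temperature, int n_equil_sweeps,
                        int n_samples, int sample_interval) {
  Couplings C(J);
  const int n = C.n;
  std::vector<double> s(n), h(n);
  for (int i = 0; i < n; ++i) s[i] = (double)init[i];
  C.local_field(s, h);

  IntegerMatrix samples(n_samples, n);
  NumericVector mag(n_samples), energy(n_samples);
  long long proposals = 0, accepts = 0;

  GetRNGstate();
  long long total_sweeps = (long long)n_equil_sweeps +
                           (long long)n_samples * sample_interval;
  int recorded = 0;
  for (long long sw = 0; sw < total_sweeps; ++sw) {
    for (int p = 0; p < n; ++p) {
      int k = pick_site(n);
      double dE = 4.0 * s[k] * h[k];
      ++proposals;
      if (dE <= 0.0 || unif_rand() < std::exp(-dE / temperature)) {
        ++accepts;
        flip(C, s, h, k);
      }
    }
    if (sw >= n_equil_sweeps &&
        (sw - n_equil_sweeps) % sample_interval == (sample_interval - 1) &&
        recorded < n_samples) {
      double m = 0.0;
      for (int i = 0; i < n; ++i) {
        samples(recorded, i) = (int)s[i];
        m += s[i];
      }
      mag[recorded] = m / n;
      energy[recorded] = C.energy(s);
      ++recorded;
    }
  }
  PutRNGstate();

  return List::create(_["samples"] = samples, _["magnetization"] = mag,
                      _["energy"] = energy,
                      _["acceptance_rate"] = (double)accepts / (double)proposals);
}
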