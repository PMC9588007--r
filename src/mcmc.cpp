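// Metropolis-Hastings sampling from a Potts model.
//
// Hot loops for the two samplers: independent equilibrium chains, and
// branch evolution with a fixed quota of *accepted* mutations.  Sequences
// are 0-based integer vectors here; R wrappers shift to 1-based codes.
//
// Couplings arrive as the R array J[L, L, q, q] flattened column-major:
// element (i, j, a, b) sits at i + L*j + L*L*a + L*L*q*b (all 0-based),
// with J[i,j,a,b] = e_ij(a, b) and the symmetry J[j,i,b,a] = J[i,j,a,b]
// already enforced on the R side.  Each unordered pair enters H once.

#include <Rcpp.h>
#include <random>
using namespace Rcpp;

namespace {

struct PottsView {
  const double *h;   // L x q, column-major: h[i + L*a]
  const double *J;   // L x L x q x q
  int L, q;

  inline double coup(int i, int j, int a, int b) const {
    return J[i + (size_t)L * j + (size_t)L * L * a + (size_t)L * L * q * b];
  }

  // Energy change for flipping site s from state a to state b.
  inline double delta_h(const int *x, int s, int a, int b) const {
    double d = -(h[s + (size_t)L * b] - h[s + (size_t)L * a]);
    for (int j = 0; j < L; ++j) {
      if (j == s) continue;
      d -= coup(s, j, b, x[j]) - coup(s, j, a, x[j]);
    }
    return d;
  }
};

inline std::mt19937_64 make_rng(double seed, int stream) {
  std::seed_seq ss{(unsigned long long)seed, (unsigned long long)stream,
                   0x9e3779b97f4a7c15ULL};
  return std::mt19937_64(ss);
}

// One proposed mutation; returns true if accepted (x updated in place).
inline bool metropolis_once(const PottsView &m, int *x, std::mt19937_64 &rng,
                            std::uniform_real_distribution<double> &unif) {
  int s = (int)(unif(rng) * m.L);
  if (s == m.L) s = m.L - 1;
  int a = x[s];
  // proposal uniform over the q-1 states other than the current one
  int b = (int)(unif(rng) * (m.q - 1));
  if (b == m.q - 1) b = m.q - 2;
  if (b >= a) ++b;
  double dH = m.delta_h(x, s, a, b);
  if (dH <= 0.0 || unif(rng) < std::exp(-dH)) {
    x[s] = b;
    return true;
  }
  return false;
}

} // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_sample_equilibrium(NumericMatrix fields, NumericVector couplings,
                                     int M, double n_steps, double seed) {
  const int L = fields.nrow(), q = fields.ncol();
  PottsView m{REAL(fields), REAL(couplings), L, q};
  IntegerMatrix out(M, L);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<int> x(L);
  for (int chain = 0; chain < M; ++chain) {
    std::mt19937_64 rng = make_rng(seed, chain + 1);
    for (int i = 0; i < L; ++i) {
      int a = (int)(unif(rng) * q);
      x[i] = a == q ? q - 1 : a;
    }
    for (double step = 0; step < n_steps; ++step)
      metropolis_once(m, x.data(), rng, unif);
    for (int i = 0; i < L; ++i) out(chain, i) = x[i];
  }
  return out;
}

// Evolve a sequence until `n_accept` proposed mutations have been accepted,
// or fail after `max_proposals` proposals.
// [[Rcpp::export]]
List cpp_evolve_branch(NumericMatrix fields, NumericVector couplings,
                       IntegerVector x0, double n_accept, double max_proposals,
                       double seed) {
  const int L = fields.nrow(), q = fields.ncol();
  PottsView m{REAL(fields), REAL(couplings), L, q};
  std::vector<int> x(x0.begin(), x0.end());
  std::mt19937_64 rng = make_rng(seed, 0);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  double accepted = 0, proposed = 0;
  while (accepted < n_accept) {
    if (proposed >= max_proposals) {
      return List::create(_["x"] = IntegerVector(x.begin(), x.end()),
                          _["accepted"] = accepted, _["proposed"] = proposed,
                          _["ok"] = false);
    }
    ++proposed;
    if (metropolis_once(m, x.data(), rng, unif)) ++accepted;
  }
  return List::create(_["x"] = IntegerVector(x.begin(), x.end()),
                      _["accepted"] = accepted, _["proposed"] = proposed,
                      _["ok"] = true);
}

// Advance a single chain by n_steps proposals (used for root sequences and
// for energy-trace diagnostics).
// [[Rcpp::export]]
List cpp_run_chain(NumericMatrix fields, NumericVector couplings,
                   IntegerVector x0, double n_steps, double seed) {
  const int L = fields.nrow(), q = fields.ncol();
  PottsView m{REAL(fields), REAL(couplings), L, q};
  std::vector<int> x(x0.begin(), x0.end());
  std::mt19937_64 rng = make_rng(seed, 0);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  double accepted = 0;
  for (double step = 0; step < n_steps; ++step)
    if (metropolis_once(m, x.data(), rng, unif)) ++accepted;
  return List::create(_["x"] = IntegerVector(x.begin(), x.end()),
                      _["accepted"] = accepted);
}
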