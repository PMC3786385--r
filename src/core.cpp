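#include <Rcpp.h>
using namespace Rcpp;

// Hypercube convention: nodes are 0-based integers 0 .. 2^L-1; locus k
// (1-based in R) is bit k-1 of the node index, so locus 1 is the least
// significant bit. Weights live in a (2^L x L) matrix W where W(v, b) is the
// weight of the monotone edge acquiring trait b+1 from node v; entries where
// bit b of v is already set are structurally absent and never read.

static const double W_MIN = 1e-300, W_MAX = 1e300;

static inline bool bit_set(int v, int b) { return (v >> b) & 1; }

// sample next acquired locus from node v; returns locus in 0..L-1
static inline int sample_step(const NumericMatrix& W, int L, int v) {
  double tot = 0.0;
  for (int b = 0; b < L; ++b) if (!bit_set(v, b)) tot += W(v, b);
  double u = unif_rand() * tot;
  int last = -1;
  for (int b = 0; b < L; ++b) {
    if (bit_set(v, b)) continue;
    last = b;
    u -= W(v, b);
    if (u <= 0.0) return b;
  }
  return last;  // numerical guard
}

// core ensemble pass: simulates n_chain monotone trajectories, accumulating
// per-species compatibility sums over intermediate nodes (steps 1..L-1) and
// acquisition-order counts pi_counts(trait, step). Intermediate visits are
// histogrammed first (visit/touched are caller-provided zeroed workspaces,
// left zeroed on return) so each distinct node is scored once per species.
static void ensemble_pass(const NumericMatrix& W, int L,
                          const IntegerVector& m1, const IntegerVector& m0,
                          int n_chain,
                          std::vector<double>& S, std::vector<int>& pi_counts,
                          std::vector<int>& visit, std::vector<int>& touched) {
  const int ns = m1.size();
  touched.clear();
  for (int c = 0; c < n_chain; ++c) {
    int v = 0;
    for (int step = 1; step <= L; ++step) {
      int b = sample_step(W, L, v);
      v |= (1 << b);
      pi_counts[(size_t)b * L + (step - 1)] += 1;
      if (step <= L - 1 && visit[v]++ == 0) touched.push_back(v);
    }
  }
  for (size_t k = 0; k < touched.size(); ++k) {
    const int v = touched[k];
    const double cnt = visit[v];
    visit[v] = 0;
    for (int i = 0; i < ns; ++i) {
      if ((v & m1[i]) == m1[i] && (v & m0[i]) == 0) S[i] += cnt;
    }
  }
}

static double loglik_from_S(const std::vector<double>& S, int n_chain) {
  double ll = 0.0;
  for (size_t i = 0; i < S.size(); ++i) {
    if (S[i] <= 0.0) return R_NegInf;
    ll += std::log(S[i]) - std::log((double)n_chain);
  }
  return ll;
}

// [[Rcpp::export]]
List cpp_ensemble(NumericMatrix W, int L, IntegerVector m1, IntegerVector m0,
                  int n_chain) {
  std::vector<double> S(m1.size(), 0.0);
  std::vector<int> pc((size_t)L * L, 0);
  std::vector<int> visit((size_t)1 << L, 0), touched;
  ensemble_pass(W, L, m1, m0, n_chain, S, pc, visit, touched);
  NumericMatrix pi(L, L);
  for (int i = 0; i < L; ++i)
    for (int n = 0; n < L; ++n)
      pi(i, n) = (double)pc[(size_t)i * L + n] / n_chain;
  return List::create(_["S"] = wrap(S),
                      _["loglik"] = loglik_from_S(S, n_chain),
                      _["pi"] = pi);
}

// [[Rcpp::export]]
IntegerMatrix cpp_simulate_orders(NumericMatrix W, int L, int n) {
  IntegerMatrix orders(n, L);
  for (int c = 0; c < n; ++c) {
    int v = 0;
    for (int step = 0; step < L; ++step) {
      int b = sample_step(W, L, v);
      v |= (1 << b);
      orders(c, step) = b + 1;
    }
  }
  return orders;
}

// multiplicative log-normal kernel on every structural edge weight
// [[Rcpp::export]]
NumericMatrix cpp_perturb(NumericMatrix W, int L, double sigma) {
  const int N = W.nrow();
  NumericMatrix out(N, L);
  for (int b = 0; b < L; ++b) {
    for (int v = 0; v < N; ++v) {
      if (bit_set(v, b)) { out(v, b) = W(v, b); continue; }
      double w = W(v, b) * std::exp(norm_rand() * sigma);
      int tries = 0;
      while (!R_finite(w) && tries++ < 100)
        w = W(v, b) * std::exp(norm_rand() * sigma);
      if (w < W_MIN) w = W_MIN;
      if (w > W_MAX) w = W_MAX;
      out(v, b) = w;
    }
  }
  return out;
}

// Metropolis MCMC over edge weights. Pseudo-marginal style by default: the
// incumbent's Monte-Carlo log-likelihood estimate is stored, not refreshed.
// [[Rcpp::export]]
List cpp_mcmc(NumericMatrix W0, double ll0, int L,
              IntegerVector m1, IntegerVector m0,
              int n_chain, double sigma,
              int n_burn, int n_sample, int thin,
              bool keep_networks, bool refresh_incumbent) {
  NumericMatrix W = clone(W0);
  double ll = ll0;
  const int n_iter = n_burn + n_sample;
  const int n_kept = n_sample / thin;
  NumericVector ll_trace(n_iter);
  LogicalVector acc_trace(n_iter);
  NumericVector pi_samples((size_t)L * L * std::max(n_kept, 0));
  NumericVector kept_ll(std::max(n_kept, 0));
  List kept_W(keep_networks ? std::max(n_kept, 0) : 0);
  int kept = 0;
  long n_acc = 0;
  std::vector<int> visit((size_t)1 << L, 0), touched;

  for (int it = 0; it < n_iter; ++it) {
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
    NumericMatrix Wp = cpp_perturb(W, L, sigma);
    std::vector<double> S(m1.size(), 0.0);
    std::vector<int> pc((size_t)L * L, 0);
    ensemble_pass(Wp, L, m1, m0, n_chain, S, pc, visit, touched);
    double llp = loglik_from_S(S, n_chain);
    if (refresh_incumbent && m1.size() > 0) {
      std::vector<double> Si(m1.size(), 0.0);
      std::vector<int> pci((size_t)L * L, 0);
      ensemble_pass(W, L, m1, m0, n_chain, Si, pci, visit, touched);
      ll = loglik_from_S(Si, n_chain);
    }
    double lr = std::log(unif_rand());  // r ~ U(0,1), open interval in practice
    bool accept = R_finite(llp) && (llp - ll > lr);
    if (accept) { W = Wp; ll = llp; ++n_acc; }
    ll_trace[it] = ll;
    acc_trace[it] = accept;

    int post = it - n_burn + 1;
    if (post >= 1 && post % thin == 0 && kept < n_kept) {
      // fresh ensemble on the current network for the summary sample
      std::vector<double> Ss(m1.size(), 0.0);
      std::vector<int> pcs((size_t)L * L, 0);
      ensemble_pass(W, L, m1, m0, n_chain, Ss, pcs, visit, touched);
      for (int i = 0; i < L; ++i)
        for (int n = 0; n < L; ++n)
          pi_samples[(size_t)kept * L * L + (size_t)n * L + i] =
            (double)pcs[(size_t)i * L + n] / n_chain;
      kept_ll[kept] = ll;
      if (keep_networks) kept_W[kept] = clone(W);
      ++kept;
    }
  }
  pi_samples.attr("dim") = IntegerVector::create(L, L, n_kept);
  return List::create(_["pi_samples"] = pi_samples,
                      _["sample_loglik"] = kept_ll,
                      _["networks"] = kept_W,
                      _["loglik_trace"] = ll_trace,
                      _["accept_trace"] = acc_trace,
                      _["acceptance_rate"] = (double)n_acc / n_iter,
                      _["n_kept"] = kept,
                      _["final_W"] = W,
                      _["final_loglik"] = ll);
}

// prediction tallies: for one species, over an ensemble, count encounters of
// compatible intermediate nodes and how often each missing locus carried a 1
// [[Rcpp::export]]
List cpp_predict_counts(NumericMatrix W, int L, int m1, int m0,
                        IntegerVector missing_loci, int n_chain) {
  const int nm = missing_loci.size();
  long encounters = 0;
  std::vector<long> ones(nm, 0);
  std::vector<int> visit((size_t)1 << L, 0), touched;
  for (int c = 0; c < n_chain; ++c) {
    int v = 0;
    for (int step = 1; step <= L; ++step) {
      int b = sample_step(W, L, v);
      v |= (1 << b);
      if (step <= L - 1 && visit[v]++ == 0) touched.push_back(v);
    }
  }
  for (size_t k = 0; k < touched.size(); ++k) {
    const int v = touched[k];
    const long cnt = visit[v];
    visit[v] = 0;
    if ((v & m1) == m1 && (v & m0) == 0) {
      encounters += cnt;
      for (int j = 0; j < nm; ++j)
        if (bit_set(v, missing_loci[j] - 1)) ones[j] += cnt;
    }
  }
  return List::create(_["encounters"] = (double)encounters,
                      _["ones"] = wrap(ones));
}

// single conditioned step: from start_node, sample the next acquisition
// n_chain times; returns counts per locus
// [[Rcpp::export]]
IntegerVector cpp_first_step_counts(NumericMatrix W, int L, int start_node,
                                    int n_chain) {
  IntegerVector counts(L);
  for (int c = 0; c < n_chain; ++c) {
    int b = sample_step(W, L, start_node);
    counts[b] += 1;
  }
  return counts;
}

// Dynamic programme over trait subsets for the single-deterministic-ordering
// search. A species (masks m1 observed-present, m0 observed-absent) is
// accounted for by an ordering iff every m1 trait precedes every m0 trait;
// along the chain of prefix sets it is counted exactly once, at the step that
// completes m1 while the prefix still avoids m0.
// [[Rcpp::export]]
List cpp_ordering_dp(int L, IntegerVector m1, IntegerVector m0) {
  const int N = 1 << L, ns = m1.size();
  std::vector<int> f(N, -1), parent(N, -1);
  int base = 0;
  for (int i = 0; i < ns; ++i) if (m1[i] == 0) ++base;
  f[0] = base;
  for (int S = 1; S < N; ++S) {
    if ((S & 0xFFF) == 0) Rcpp::checkUserInterrupt();
    int best = -1, bp = -1;
    for (int x = 0; x < L; ++x) {
      if (!bit_set(S, x)) continue;
      int T = S & ~(1 << x);
      int gain = 0;
      for (int i = 0; i < ns; ++i) {
        if ((m1[i] & (1 << x)) && (S & m1[i]) == m1[i] && (S & m0[i]) == 0)
          ++gain;
      }
      if (f[T] + gain > best) { best = f[T] + gain; bp = x; }
    }
    f[S] = best;
    parent[S] = bp;
  }
  // backtrack one optimal ordering (last acquisition first)
  IntegerVector ordering(L);
  int S = N - 1;
  for (int pos = L - 1; pos >= 0; --pos) {
    int x = parent[S];
    ordering[pos] = x + 1;
    S &= ~(1 << x);
  }
  return List::create(_["max_accounted"] = f[N - 1],
                      _["ordering"] = ordering);
}
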