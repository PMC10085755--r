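// Coalescent machinery shared by the simulators and the expected-AFS solver.
//
// Time conventions: t is backwards time in units of 2*Ne generations; the
// relative population size nu(t) = N(t)/Ne rescales the pairwise coalescent
// intensity to choose(k,2)/nu(t).  tau = Lambda(t) = int_0^t ds/nu(s) is the
// standard-coalescent timescale on which waiting times with k lineages are
// Exp(choose(k,2)).  Demographies are passed as a numeric vector:
//   [0] type: 0 = constant, 1 = growth(T0, lambda),
//             2 = three_epoch(T1, T2, lambda1, lambda2)
//   growth:      [1] T0, [2] lambda  (size lambda*Ne now, Ne before T0,
//                exponential in between)
//   three_epoch: [1] T1, [2] T2, [3] lambda1, [4] lambda2
//                (lambda2*Ne for t < T2, lambda1*Ne for T2 <= t < T2+T1,
//                 Ne earlier)
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double GROWTH_EPS = 1e-8;

struct Demog {
  int type;
  double T0, lam;              // growth
  double T1, T2, lam1, lam2;   // three-epoch
  double r, Lam0;              // growth derived: rate, Lambda(T0)
  double Lam2, Lam21;          // three-epoch derived: Lambda(T2), Lambda(T2+T1)
};

static Demog parse_demog(const NumericVector& d) {
  Demog g;
  g.type = (int) d[0];
  if (g.type == 1) {
    g.T0 = d[1]; g.lam = d[2];
    if (g.T0 < GROWTH_EPS || std::fabs(g.lam - 1.0) < GROWTH_EPS) {
      g.type = 0;  // degenerate growth is constant size
    } else {
      g.r = std::log(g.lam) / g.T0;
      g.Lam0 = (g.lam - 1.0) / (g.lam * g.r);
    }
  } else if (g.type == 2) {
    g.T1 = d[1]; g.T2 = d[2]; g.lam1 = d[3]; g.lam2 = d[4];
    if (g.lam1 <= 0 || g.lam2 <= 0) stop("three-epoch sizes must be positive");
    g.Lam2 = g.T2 / g.lam2;
    g.Lam21 = g.Lam2 + g.T1 / g.lam1;
  }
  return g;
}

// t(tau): inverse of Lambda, mapping standard-coalescent time back to
// 2*Ne-generation time.
static double t_of_tau(double tau, const Demog& g) {
  switch (g.type) {
  case 0:
    return tau;
  case 1:
    if (tau < g.Lam0) return std::log1p(g.lam * g.r * tau) / g.r;
    return g.T0 + (tau - g.Lam0);
  default:  // three-epoch
    if (tau < g.Lam2) return tau * g.lam2;
    if (tau < g.Lam21) return g.T2 + (tau - g.Lam2) * g.lam1;
    return g.T2 + g.T1 + (tau - g.Lam21);
  }
}

// nu(t(tau)) expressed directly in tau; closed form in every regime.
static double nu_at_tau(double tau, const Demog& g) {
  switch (g.type) {
  case 0:
    return 1.0;
  case 1:
    if (tau < g.Lam0) return g.lam / (1.0 + g.lam * g.r * tau);
    return 1.0;
  default:
    if (tau < g.Lam2) return g.lam2;
    if (tau < g.Lam21) return g.lam1;
    return 1.0;
  }
}

// Draw standard-coalescent intervals and convert to t-scale durations.
// Fills tk[0..n-2] with the time (2*Ne units) spent with k = n..2 lineages.
static void draw_interval_times(int n, const Demog& g, std::vector<double>& tk) {
  double tau = 0.0, t_prev = 0.0;
  for (int k = n; k >= 2; --k) {
    double ck = 0.5 * k * (k - 1);
    tau += R::rexp(1.0 / ck);
    double t_now = t_of_tau(tau, g);
    tk[n - k] = t_now - t_prev;
    t_prev = t_now;
  }
}

// [[Rcpp::export(name = ".cpp_sim_linked_spectra")]]
IntegerMatrix cpp_sim_linked_spectra(int n, double theta, int reps,
                                     NumericVector demog) {
  if (n < 2) stop("n must be >= 2");
  Demog g = parse_demog(demog);
  IntegerMatrix eta(n - 1, reps);
  std::vector<double> tk(n - 1);
  std::vector<int> size(n);
  for (int r = 0; r < reps; ++r) {
    draw_interval_times(n, g, tk);
    for (int i = 0; i < n; ++i) size[i] = 1;
    int k = n;
    for (; k >= 2; --k) {
      double len = tk[n - k];
      double lam_mut = 0.5 * theta * len;
      for (int i = 0; i < k; ++i) {
        int m = (int) R::rpois(lam_mut);
        if (m > 0) eta(size[i] - 1, r) += m;
      }
      // merge two uniformly chosen lineages
      int a = (int) (R::unif_rand() * k);
      int b = (int) (R::unif_rand() * (k - 1));
      if (b >= a) ++b;
      int lo = a < b ? a : b, hi = a < b ? b : a;
      size[lo] += size[hi];
      size[hi] = size[k - 1];
    }
  }
  return eta;
}

// Total branch length subtending i leaves (t-scale), one column per tree.
// theta/2 * colMeans gives a Monte-Carlo estimate of the expected AFS.
// [[Rcpp::export(name = ".cpp_sim_branch_lengths")]]
NumericMatrix cpp_sim_branch_lengths(int n, int reps, NumericVector demog) {
  if (n < 2) stop("n must be >= 2");
  Demog g = parse_demog(demog);
  NumericMatrix L(n - 1, reps);
  std::vector<double> tk(n - 1);
  std::vector<int> size(n);
  for (int r = 0; r < reps; ++r) {
    draw_interval_times(n, g, tk);
    for (int i = 0; i < n; ++i) size[i] = 1;
    for (int k = n; k >= 2; --k) {
      double len = tk[n - k];
      for (int i = 0; i < k; ++i) L(size[i] - 1, r) += len;
      int a = (int) (R::unif_rand() * k);
      int b = (int) (R::unif_rand() * (k - 1));
      if (b >= a) ++b;
      int lo = a < b ? a : b, hi = a < b ? b : a;
      size[lo] += size[hi];
      size[hi] = size[k - 1];
    }
  }
  return L;
}

// Per-site genealogies with Poisson mutation.  Finite-sites mode marks every
// mutated branch and a leaf is derived iff any mutation sits on its root
// path (union of carriers); with back mutation each event toggles the
// allele, so a leaf is derived iff its root path carries an odd number of
// mutations.  Infinite-sites mode keeps only the mutation closest to the
// present.
// [[Rcpp::export(name = ".cpp_sim_site_spectrum")]]
IntegerVector cpp_sim_site_spectrum(int n, double theta_site, double L_sites,
                                    NumericVector demog, bool recurrent,
                                    bool back_mutation = false) {
  if (n < 2) stop("n must be >= 2");
  Demog g = parse_demog(demog);
  IntegerVector eta(n - 1);
  std::vector<double> tk(n - 1), cumlen(n - 1);
  std::vector<int> node(n), size(n), parent(2 * n - 1);
  std::vector<char> mut(2 * n - 1);
  long L = (long) L_sites;
  for (long s = 0; s < L; ++s) {
    draw_interval_times(n, g, tk);
    double tot = 0.0;
    for (int k = n; k >= 2; --k) { tot += k * tk[n - k]; cumlen[n - k] = tot; }
    int m = (int) R::rpois(0.5 * theta_site * tot);
    if (m == 0) continue;
    // build the topology, assigning mutations interval-by-interval
    for (int i = 0; i < n; ++i) { node[i] = i; size[i] = 1; }
    std::fill(parent.begin(), parent.end(), -1);
    std::fill(mut.begin(), mut.end(), 0);
    // draw each mutation's interval index by total length, then lineage
    // uniformly within the interval; for infinite sites track the earliest
    std::vector<int> m_int(m);
    for (int j = 0; j < m; ++j) {
      double u = R::unif_rand() * tot;
      int idx = 0;
      while (cumlen[idx] < u) ++idx;
      m_int[j] = idx;
    }
    if (!recurrent) {
      // earliest mutation = one in the interval nearest the present, and
      // within that interval time order is uniform so any one of them works
      int best = m_int[0];
      for (int j = 1; j < m; ++j) if (m_int[j] < best) best = m_int[j];
      m_int.assign(1, best);
      m = 1;
    }
    int next_id = n;
    // bucket mutations by interval (processed from present, k = n, backwards)
    std::vector<int> per_int(n - 1, 0);
    for (int j = 0; j < m; ++j) per_int[m_int[j]]++;
    int derived = -1;
    for (int k = n; k >= 2; --k) {
      int idx = n - k;
      for (int j = 0; j < per_int[idx]; ++j) {
        int lin = (int) (R::unif_rand() * k);
        if (back_mutation) mut[node[lin]] ^= 1; else mut[node[lin]] = 1;
        if (!recurrent) derived = size[lin];
      }
      int a = (int) (R::unif_rand() * k);
      int b = (int) (R::unif_rand() * (k - 1));
      if (b >= a) ++b;
      int lo = a < b ? a : b, hi = a < b ? b : a;
      parent[node[lo]] = next_id;
      parent[node[hi]] = next_id;
      node[lo] = next_id;
      size[lo] += size[hi];
      node[hi] = node[k - 1];
      size[hi] = size[k - 1];
      ++next_id;
    }
    if (!recurrent) {
      if (derived >= 1 && derived <= n - 1) eta[derived - 1]++;
      continue;
    }
    // propagate marks root-down: parents always have larger ids
    std::vector<char> flag(2 * n - 1, 0);
    for (int id = 2 * n - 2; id >= 0; --id) {
      int p = parent[id];
      char up = (p >= 0) ? flag[p] : 0;
      flag[id] = back_mutation ? (char) (mut[id] ^ up) : (char) (mut[id] || up);
    }
    int d = 0;
    for (int i = 0; i < n; ++i) d += flag[i];
    if (d >= 1 && d <= n - 1) eta[d - 1]++;
  }
  return eta;
}

// Expected time with k = 2..n ancestral lineages under the demography, by
// RK4 integration of the lineage-count pure-death process on the standard
// timescale (dp_k/dtau = c_{k+1} p_{k+1} - c_k p_k), with the time spent
// accumulated as int p_k(tau) nu(tau) dtau.  The constant ancestral epoch is
// handled analytically from the survival probabilities at its boundary.
// [[Rcpp::export(name = ".cpp_expected_Tk")]]
NumericVector cpp_expected_Tk(int n, NumericVector demog) {
  if (n < 2) stop("n must be >= 2");
  Demog g = parse_demog(demog);
  NumericVector ET(n - 1);  // ET[k-2] for k = 2..n
  std::vector<double> c(n + 1);
  for (int k = 2; k <= n; ++k) c[k] = 0.5 * (double) k * (k - 1);
  if (g.type == 0) {
    for (int k = 2; k <= n; ++k) ET[k - 2] = 1.0 / c[k];
    return ET;
  }
  // segment boundaries in tau over the non-ancestral epochs
  std::vector<double> bounds;
  if (g.type == 1) {
    bounds.push_back(g.Lam0);
  } else {
    bounds.push_back(g.Lam2);
    bounds.push_back(g.Lam21);
  }
  std::vector<double> p(n + 1, 0.0), acc(n + 1, 0.0);
  std::vector<double> k1(n + 1), k2(n + 1), k3(n + 1), k4(n + 1), tmp(n + 1);
  std::vector<double> da1(n + 1), da2(n + 1), da3(n + 1), da4(n + 1);
  p[n] = 1.0;
  int kmax = n;
  double tau = 0.0;
  bool absorbed = false;
  // RK4 at h*c <= 0.1 keeps the fastest active mode's local error ~1e-7;
  // modes are dropped once their mass cannot influence the accumulators
  const double HMAX = 0.002, DROP = 1e-22, ABS_TOL = 1e-15;
  int seg = 0;
  // nu evaluated with the current segment's regime so stage points at a
  // segment boundary never pick up the next epoch's population size
  auto deriv = [&](const std::vector<double>& pp, double tau_loc,
                   std::vector<double>& dp, std::vector<double>& da) {
    double nu;
    if (g.type == 1) {
      nu = g.lam / (1.0 + g.lam * g.r * tau_loc);  // continuous at Lam0
    } else {
      nu = (seg == 0) ? g.lam2 : g.lam1;
    }
    for (int k = 2; k <= kmax; ++k) {
      double in = (k < kmax) ? c[k + 1] * pp[k + 1] : 0.0;
      dp[k] = in - c[k] * pp[k];
      da[k] = pp[k] * nu;
    }
  };
  for (seg = 0; seg < (int) bounds.size() && !absorbed; ++seg) {
    double tau_end = bounds[seg];
    while (tau < tau_end - 1e-15) {
      double h = 0.1 / c[kmax];
      if (h > HMAX) h = HMAX;
      if (h > tau_end - tau) h = tau_end - tau;
      deriv(p, tau, k1, da1);
      for (int k = 2; k <= kmax; ++k) tmp[k] = p[k] + 0.5 * h * k1[k];
      deriv(tmp, tau + 0.5 * h, k2, da2);
      for (int k = 2; k <= kmax; ++k) tmp[k] = p[k] + 0.5 * h * k2[k];
      deriv(tmp, tau + 0.5 * h, k3, da3);
      for (int k = 2; k <= kmax; ++k) tmp[k] = p[k] + h * k3[k];
      deriv(tmp, tau + h, k4, da4);
      double mass = 0.0;
      for (int k = 2; k <= kmax; ++k) {
        p[k] += h / 6.0 * (k1[k] + 2 * k2[k] + 2 * k3[k] + k4[k]);
        if (p[k] < 0) p[k] = 0;
        acc[k] += h / 6.0 * (da1[k] + 2 * da2[k] + 2 * da3[k] + da4[k]);
        mass += p[k];
      }
      tau += h;
      while (kmax > 2 && p[kmax] < DROP) --kmax;
      if (mass < ABS_TOL) { absorbed = true; break; }
    }
  }
  for (int k = 2; k <= n; ++k) ET[k - 2] = acc[k];
  if (!absorbed) {
    // analytic constant-size tail: E[extra T_k] = P(A(tau_b) >= k) / c_k
    double cum = 0.0;
    for (int k = n; k >= 2; --k) {
      cum += (k <= kmax) ? p[k] : 0.0;
      ET[k - 2] += cum / c[k];
    }
  }
  return ET;
}

// Wright-Fisher sojourn histogram for a new derived allele with genic
// transmission bias b: from count x of 2N gene copies, the next generation
// is Binomial(2N, x(1+b) / (2N + x b)).  K independent trajectories from
// x = 1; H[x] counts generations spent at count x before absorption.
// [[Rcpp::export(name = ".cpp_wf_sojourn")]]
NumericVector cpp_wf_sojourn(int twoN, double b, int K) {
  if (twoN < 4) stop("2N must be >= 4");
  NumericVector H(twoN - 1);
  for (int r = 0; r < K; ++r) {
    int x = 1;
    while (x > 0 && x < twoN) {
      H[x - 1] += 1.0;
      double p = x * (1.0 + b) / ((double) twoN + x * b);
      if (p < 0) p = 0; else if (p > 1) p = 1;
      x = (int) R::rbinom(twoN, p);
    }
  }
  return H;
}
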