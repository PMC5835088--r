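#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <map>
using namespace Rcpp;

// Structured-coalescent genealogy under piecewise-constant diploid sizes.
//
// Demography is encoded as an event table (rows sorted by time, generations
// ago): type 0 = size change (pop a takes diploid size b from that time
// backwards), type 1 = merge (all lineages of pop a move into pop b; pop a
// ceases to exist further back in time). `mig` is a symmetric island-model
// migration rate per lineage per generation among the populations still
// alive (0 for split models). Coalescence in a population of diploid size N
// occurs at rate k(k-1)/(4N) per generation among its k lineages.
//
// Tips are 0..n-1 (time 0); internal nodes are appended in coalescence
// order; the root has parent -1. Uses R's RNG throughout so set.seed()
// governs reproducibility.

struct Genealogy {
  std::vector<int> parent;
  std::vector<double> time;
};

static Genealogy sim_genealogy(const IntegerVector& tip_pop,
                               std::vector<double> N,
                               const NumericMatrix& events,
                               double mig) {
  int n = tip_pop.size();
  int npop = N.size();
  Genealogy g;
  g.parent.assign(2 * n - 1, -1);
  g.time.assign(2 * n - 1, 0.0);

  std::vector<std::vector<int>> act(npop);  // active lineage node ids per pop
  for (int i = 0; i < n; ++i) {
    int p = tip_pop[i];
    if (p < 0 || p >= npop) stop("tip population index out of range");
    act[p].push_back(i);
  }
  std::vector<bool> alive(npop, true);
  int next_node = n, remaining = n;
  double t = 0.0;
  int ev = 0, nev = events.nrow();

  while (remaining > 1) {
    // total rates
    double coal_tot = 0.0;
    for (int p = 0; p < npop; ++p) {
      double k = (double)act[p].size();
      if (k >= 2) coal_tot += k * (k - 1.0) / (4.0 * N[p]);
    }
    int nalive = 0;
    for (int p = 0; p < npop; ++p) if (alive[p]) ++nalive;
    double mig_tot = (mig > 0.0 && nalive > 1) ? mig * (double)remaining : 0.0;
    double rate = coal_tot + mig_tot;

    double t_next = (rate > 0.0) ? t + R::rexp(1.0 / rate) : R_PosInf;
    if (ev < nev && events(ev, 0) <= t_next) {
      // process demographic event
      t = std::max(t, events(ev, 0));
      int type = (int)events(ev, 1);
      int a = (int)events(ev, 2);
      if (type == 0) {
        N[a] = events(ev, 3);
        if (N[a] <= 0) stop("non-positive population size in event table");
      } else {
        int b = (int)events(ev, 3);
        for (size_t i = 0; i < act[a].size(); ++i) act[b].push_back(act[a][i]);
        act[a].clear();
        alive[a] = false;
      }
      ++ev;
      continue;
    }
    if (!R_FINITE(t_next)) stop("lineages in isolated populations share no common ancestor");
    t = t_next;

    double u = unif_rand() * rate;
    if (u < coal_tot) {
      // coalescence: pick pop proportional to its rate
      double acc = 0.0; int pp = -1;
      for (int p = 0; p < npop; ++p) {
        double k = (double)act[p].size();
        if (k >= 2) {
          acc += k * (k - 1.0) / (4.0 * N[p]);
          if (u < acc) { pp = p; break; }
        }
      }
      if (pp < 0) continue;
      int k = act[pp].size();
      int i = (int)(unif_rand() * k); if (i >= k) i = k - 1;
      int j = (int)(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
      if (j >= i) ++j;
      int ni = act[pp][i], nj = act[pp][j];
      int anc = next_node++;
      g.parent[ni] = anc; g.parent[nj] = anc;
      g.time[anc] = t;
      // replace i by anc, drop j
      act[pp][i] = anc;
      act[pp].erase(act[pp].begin() + j);
      --remaining;
    } else {
      // migration: uniform lineage moves to a uniformly chosen other live pop
      int idx = (int)(unif_rand() * remaining); if (idx >= remaining) idx = remaining - 1;
      int pp = 0, off = idx;
      for (int p = 0; p < npop; ++p) {
        if (off < (int)act[p].size()) { pp = p; break; }
        off -= act[p].size();
      }
      int dest = pp;
      while (dest == pp || !alive[dest]) {
        dest = (int)(unif_rand() * npop); if (dest >= npop) dest = npop - 1;
      }
      act[dest].push_back(act[pp][off]);
      act[pp].erase(act[pp].begin() + off);
    }
  }
  return g;
}

// [[Rcpp::export]]
List cpp_genealogy(IntegerVector tip_pop, NumericVector pop_size,
                   NumericMatrix events, double mig) {
  std::vector<double> N(pop_size.begin(), pop_size.end());
  Genealogy g = sim_genealogy(tip_pop, N, events, mig);
  return List::create(_["parent"] = IntegerVector(g.parent.begin(), g.parent.end()),
                      _["time"] = NumericVector(g.time.begin(), g.time.end()));
}

// GSM mutation along a genealogy. Root state sits at the centre of the
// bounded ladder [0, arange-1]; each mutation moves the repeat count by a
// geometric(P)-distributed magnitude (P = continuation probability, support
// 1,2,3,...) with random sign, redrawing steps that would leave the window.
// Single-nucleotide indels (rate `sni`) toggle a +/-1 bp off-ladder offset.
static void mutate_tips(const Genealogy& g, int n_tips,
                        double mu, double P, double sni, int arange,
                        std::vector<int>& state, std::vector<int>& offset) {
  int nn = g.parent.size();
  std::vector<int> st(nn, arange / 2), off(nn, 0);
  // nodes are created in increasing time order, so iterating from the root
  // (last node) downwards visits parents before children
  for (int v = nn - 2; v >= 0; --v) {
    int pa = g.parent[v];
    st[v] = st[pa]; off[v] = off[pa];
    double len = g.time[pa] - g.time[v];
    if (len <= 0) continue;
    int nm = (int)R::rpois(mu * len);
    for (int m = 0; m < nm; ++m) {
      for (int tries = 0; tries < 1000; ++tries) {
        int step = 1;
        while (unif_rand() < P) ++step;
        if (unif_rand() < 0.5) step = -step;
        int ns = st[v] + step;
        if (ns >= 0 && ns < arange) { st[v] = ns; break; }
      }
    }
    int nsni = (int)R::rpois(sni * len);
    for (int m = 0; m < nsni; ++m) {
      if (off[v] == 0) off[v] = (unif_rand() < 0.5) ? -1 : 1;
      else off[v] = 0;
    }
  }
  state.assign(st.begin(), st.begin() + n_tips);
  offset.assign(off.begin(), off.begin() + n_tips);
}

// [[Rcpp::export]]
List cpp_mutate(IntegerVector parent, NumericVector node_time, int n_tips,
                double mu, double P, double sni, int arange) {
  Genealogy g;
  g.parent.assign(parent.begin(), parent.end());
  g.time.assign(node_time.begin(), node_time.end());
  std::vector<int> st, off;
  mutate_tips(g, n_tips, mu, P, sni, arange, st, off);
  return List::create(_["state"] = IntegerVector(st.begin(), st.end()),
                      _["offset"] = IntegerVector(off.begin(), off.end()));
}

// Whole multi-locus dataset: independent genealogy + mutation per locus.
// [[Rcpp::export]]
List cpp_sim_dataset(IntegerVector tip_pop, NumericVector pop_size,
                     NumericMatrix events, double mig,
                     NumericVector mu, NumericVector P, NumericVector sni,
                     int arange) {
  int n = tip_pop.size(), L = mu.size();
  IntegerMatrix state(n, L), offset(n, L);
  for (int l = 0; l < L; ++l) {
    std::vector<double> N(pop_size.begin(), pop_size.end());
    Genealogy g = sim_genealogy(tip_pop, N, events, mig);
    std::vector<int> st, off;
    mutate_tips(g, n, mu[l], P[l], sni[l], arange, st, off);
    for (int i = 0; i < n; ++i) { state(i, l) = st[i]; offset(i, l) = off[i]; }
  }
  return List::create(_["state"] = state, _["offset"] = offset);
}

// ---- two-phase-model mutation-drift equilibrium (bottleneck test) --------
//
// Kingman coalescent for n gene copies on the 2N-generation timescale;
// mutations at rate theta/2 per lineage per unit time. A fraction p_smm of
// mutations are single-step ladder moves; the remainder create a brand-new
// allelic lineage (infinite-allele component). Alleles are identified by
// (origin id, ladder position) pairs so stepwise moves on an IAM-derived
// allele stay distinct from the ancestral ladder.

static void eq_locus(int n, double theta, double p_smm,
                     std::vector<long long>& alleles) {
  std::vector<double> ctime(2 * n - 1, 0.0);
  std::vector<int> parent(2 * n - 1, -1);
  std::vector<int> act(n);
  for (int i = 0; i < n; ++i) act[i] = i;
  int next_node = n;
  double t = 0.0;
  while ((int)act.size() > 1) {
    int k = act.size();
    t += R::rexp(2.0 / ((double)k * (k - 1.0)));
    int i = (int)(unif_rand() * k); if (i >= k) i = k - 1;
    int j = (int)(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
    if (j >= i) ++j;
    int anc = next_node++;
    parent[act[i]] = anc; parent[act[j]] = anc;
    ctime[anc] = t;
    act[i] = anc;
    act.erase(act.begin() + j);
  }
  int nn = 2 * n - 1;
  std::vector<long long> origin(nn, 0);
  std::vector<int> pos(nn, 0);
  long long counter = 0;
  for (int v = nn - 2; v >= 0; --v) {
    int pa = parent[v];
    origin[v] = origin[pa]; pos[v] = pos[pa];
    double len = ctime[pa] - ctime[v];
    int nm = (int)R::rpois(0.5 * theta * len);
    for (int m = 0; m < nm; ++m) {
      if (unif_rand() < p_smm) pos[v] += (unif_rand() < 0.5) ? -1 : 1;
      else { origin[v] = ++counter; pos[v] = 0; }
    }
  }
  alleles.resize(n);
  for (int i = 0; i < n; ++i)
    alleles[i] = origin[i] * 1000000LL + (long long)(pos[i] + 500000);
}

// Raw composite labels: origin * 1e6 + ladder position + 5e5, so that for
// the pure-SMM case (origin 0) the label minus 5e5 IS the ladder position
// and allele-size geometry is preserved for M-ratio style uses.
// [[Rcpp::export]]
NumericVector cpp_eq_locus(int n, double theta, double p_smm) {
  std::vector<long long> al;
  eq_locus(n, theta, p_smm, al);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = (double)al[i];
  return out;
}

static int count_k(const std::vector<long long>& al, double& he) {
  std::vector<long long> s(al);
  std::sort(s.begin(), s.end());
  int n = s.size(), k = 0;
  double sump2 = 0.0;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && s[j] == s[i]) ++j;
    ++k;
    double p = (double)(j - i) / (double)n;
    sump2 += p * p;
    i = j;
  }
  he = ((double)n / (n - 1.0)) * (1.0 - sump2);
  return k;
}

// Mean allele count and acceptance probability of k_target over nsim draws.
// [[Rcpp::export]]
NumericVector cpp_eq_kmean(int n, double theta, double p_smm, int k_target,
                           int nsim) {
  double ksum = 0.0; int hits = 0;
  std::vector<long long> al;
  for (int s = 0; s < nsim; ++s) {
    eq_locus(n, theta, p_smm, al);
    double he;
    int k = count_k(al, he);
    ksum += k;
    if (k == k_target) ++hits;
  }
  return NumericVector::create(ksum / nsim, (double)hits / nsim);
}

// Gene diversities of simulations accepted on allele count == k_target.
// [[Rcpp::export]]
List cpp_eq_heq(int n, double theta, double p_smm, int k_target,
                int n_accept, int max_tries) {
  std::vector<double> acc;
  std::vector<long long> al;
  int tries = 0;
  while ((int)acc.size() < n_accept && tries < max_tries) {
    ++tries;
    eq_locus(n, theta, p_smm, al);
    double he;
    if (count_k(al, he) == k_target) acc.push_back(he);
  }
  return List::create(_["heq"] = NumericVector(acc.begin(), acc.end()),
                      _["tries"] = tries);
}
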