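#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gibbs sampler for the independent-allele-frequency admixture model.
//
// Data: two integer matrices (n x L) of 1-based allele indices per gene
// copy, 0 = missing. Latent variables: z (cluster of origin of every allele
// copy), P (cluster x locus allele frequencies, Dirichlet(lambda) prior),
// Q (per-individual membership, Dirichlet(alpha) prior). alpha is updated
// by a Metropolis random walk with a uniform prior on (0, alpha_max]; with
// location labels, each sampling location carries its own alpha vector
// (a location-informed admixture prior for weakly structured data).
//
// The data log-likelihood sum_{i,l,c} log(sum_k q_ik p_kla) is accumulated
// during z sampling; the model-evidence proxy mean(lnL) - var(lnL)/2 is
// computed in R from the returned trace.

static void rdirichlet(std::vector<double>& out, const std::vector<double>& a) {
  double s = 0.0;
  for (size_t i = 0; i < a.size(); ++i) { out[i] = R::rgamma(a[i], 1.0); s += out[i]; }
  if (s <= 0) { for (size_t i = 0; i < a.size(); ++i) out[i] = 1.0 / a.size(); return; }
  for (size_t i = 0; i < a.size(); ++i) out[i] /= s;
}

// [[Rcpp::export]]
List cpp_admixture(IntegerMatrix g1, IntegerMatrix g2, IntegerVector n_alleles,
                   int K, int burnin, int iters, double alpha0,
                   double alpha_max, IntegerVector locgroup, double lambda) {
  int n = g1.nrow(), L = g1.ncol();
  bool useloc = locgroup.size() == n && K > 1;
  int G = 1;
  if (useloc) { for (int i = 0; i < n; ++i) G = std::max(G, locgroup[i] + 1); }

  // flattened P: offsets per locus
  std::vector<int> offs(L + 1, 0);
  for (int l = 0; l < L; ++l) offs[l + 1] = offs[l] + n_alleles[l];
  int A = offs[L];

  std::vector<double> P(K * A), Pa(0);
  std::vector<double> Q(n * K, 1.0 / K);
  std::vector<double> alpha(G * K, alpha0);
  std::vector<double> clcount(K * A);
  std::vector<double> mcount(n * K);
  std::vector<double> tmpK(K), tmpA;

  // init P from pooled frequencies + noise
  {
    std::vector<double> pool(A, lambda);
    for (int i = 0; i < n; ++i)
      for (int l = 0; l < L; ++l) {
        if (g1(i, l) > 0) pool[offs[l] + g1(i, l) - 1] += 1.0;
        if (g2(i, l) > 0) pool[offs[l] + g2(i, l) - 1] += 1.0;
      }
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l) {
        int na = n_alleles[l];
        tmpA.assign(pool.begin() + offs[l], pool.begin() + offs[l] + na);
        std::vector<double> dr(na);
        rdirichlet(dr, tmpA);
        for (int a = 0; a < na; ++a) P[k * A + offs[l] + a] = dr[a];
      }
  }

  int nkeep = iters;
  NumericVector lnL_trace(nkeep), alpha_trace(nkeep);
  NumericMatrix Qsum(n, K);
  std::vector<double> Psum(K * A, 0.0);
  int kept = 0;

  for (int sweep = 0; sweep < burnin + iters; ++sweep) {
    std::fill(clcount.begin(), clcount.end(), 0.0);
    std::fill(mcount.begin(), mcount.end(), 0.0);
    double lnL = 0.0;

    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        for (int copy = 0; copy < 2; ++copy) {
          int a = copy == 0 ? g1(i, l) : g2(i, l);
          if (a <= 0) continue;
          int pos = offs[l] + a - 1;
          double tot = 0.0;
          for (int k = 0; k < K; ++k) {
            tmpK[k] = Q[i * K + k] * P[k * A + pos];
            tot += tmpK[k];
          }
          if (tot <= 0) { tot = 1e-300; tmpK[0] = tot; }
          lnL += std::log(tot);
          double u = unif_rand() * tot, acc = 0.0;
          int zk = K - 1;
          for (int k = 0; k < K; ++k) { acc += tmpK[k]; if (u < acc) { zk = k; break; } }
          clcount[zk * A + pos] += 1.0;
          mcount[i * K + zk] += 1.0;
        }
      }
    }

    // update P | z
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l) {
        int na = n_alleles[l];
        tmpA.resize(na);
        for (int a = 0; a < na; ++a) tmpA[a] = lambda + clcount[k * A + offs[l] + a];
        std::vector<double> dr(na);
        rdirichlet(dr, tmpA);
        for (int a = 0; a < na; ++a) P[k * A + offs[l] + a] = dr[a];
      }

    // update Q | z
    if (K == 1) {
      for (int i = 0; i < n; ++i) Q[i] = 1.0;
    } else {
      std::vector<double> apar(K);
      for (int i = 0; i < n; ++i) {
        int g = useloc ? locgroup[i] : 0;
        for (int k = 0; k < K; ++k) apar[k] = alpha[g * K + k] + mcount[i * K + k];
        std::vector<double> dr(K);
        rdirichlet(dr, apar);
        for (int k = 0; k < K; ++k) Q[i * K + k] = std::max(dr[k], 1e-12);
      }
    }

    // update alpha | Q (Metropolis random walk, one component at a time)
    if (K > 1) {
      for (int g = 0; g < G; ++g) {
        // individuals in this location group
        for (int k = 0; k < K; ++k) {
          double cur = alpha[g * K + k];
          double prop = cur + norm_rand() * 0.1;
          if (prop <= 0 || prop > alpha_max) continue;
          // Dirichlet log-density ratio over rows of this group
          double lr = 0.0;
          double asum_cur = 0.0, asum_prop = 0.0;
          for (int kk = 0; kk < K; ++kk) {
            asum_cur += alpha[g * K + kk];
            asum_prop += (kk == k) ? prop : alpha[g * K + kk];
          }
          int ng = 0;
          double slogq = 0.0;
          for (int i = 0; i < n; ++i) {
            int gi = useloc ? locgroup[i] : 0;
            if (gi != g) continue;
            ++ng;
            slogq += std::log(Q[i * K + k]);
          }
          if (ng == 0) continue;
          lr = ng * (std::lgamma(asum_prop) - std::lgamma(asum_cur)
                     - std::lgamma(prop) + std::lgamma(cur))
               + (prop - cur) * slogq;
          if (std::log(unif_rand()) < lr) alpha[g * K + k] = prop;
        }
      }
    }

    if (sweep >= burnin) {
      lnL_trace[kept] = lnL;
      alpha_trace[kept] = alpha[0];
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q[i * K + k];
      for (int j = 0; j < K * A; ++j) Psum[j] += P[j];
      ++kept;
    }
  }

  NumericMatrix Qmean(n, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Qmean(i, k) = Qsum(i, k) / std::max(kept, 1);
  NumericMatrix Pmean(K, A);
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < A; ++j) Pmean(k, j) = Psum[k * A + j] / std::max(kept, 1);

  return List::create(_["Q"] = Qmean, _["lnL"] = lnL_trace,
                      _["alpha"] = alpha_trace, _["P"] = Pmean,
                      _["offsets"] = IntegerVector(offs.begin(), offs.end()));
}
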