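// Structured-coalescent simulator for microsatellite loci under the strict
// stepwise mutation model, for three-deme domestication scenarios:
// topology 0 ("A"): deme 3 founded at T2 by admixture, each of its lineages
//   moving (backwards in time) to deme 1 with probability alpha, else deme 2;
// topology 1 ("B"): deme 3 splits from deme 1 at T2;
// topology 2 ("C"): deme 3 splits from deme 2 at T2.
// At T1 deme 2 merges into deme 1, which then has size ne_anc.
// Continuous-time Kingman coalescent within demes (pair rate 1/(2*Ne) per
// generation); mutations Poisson(mu * branch length), each +-1 repeat unit.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<double> time;    // node times, tips at 0
  std::vector<int> parent;     // -1 for root
  int n_tips;
};

// simulate the genealogy of the given tip counts per deme; tips are numbered
// deme-major (all deme-1 tips, then deme-2, then deme-3)
Tree sim_genealogy(int topology, const std::vector<double>& ne, double ne_anc,
                   double t1, double t2, double alpha,
                   const std::vector<int>& genes) {
  int tot = genes[0] + genes[1] + genes[2];
  if (tot < 2) stop("need at least 2 sampled genes in total");
  for (double n : ne) if (n <= 0) stop("effective sizes must be positive");
  if (ne_anc <= 0) stop("ancestral effective size must be positive");
  if (!(t1 > t2) || t2 <= 0) stop("require T1 > T2 > 0");

  Tree tr;
  tr.n_tips = tot;
  tr.time.assign(tot, 0.0);
  tr.parent.assign(tot, -1);

  std::vector<std::vector<int> > act(3);
  int id = 0;
  for (int d = 0; d < 3; ++d)
    for (int k = 0; k < genes[d]; ++k) act[d].push_back(id++);

  double t = 0.0;
  double sz[3] = { ne[0], ne[1], ne[2] };
  int phase = 0;  // 0: before T2, 1: between T2 and T1, 2: after T1

  while (act[0].size() + act[1].size() + act[2].size() > 1) {
    double rate = 0.0, rd[3];
    for (int d = 0; d < 3; ++d) {
      double k = (double)act[d].size();
      rd[d] = k * (k - 1.0) / 2.0 / (2.0 * sz[d]);
      rate += rd[d];
    }
    double bound = (phase == 0) ? t2 : (phase == 1 ? t1 : R_PosInf);
    double dt = (rate > 0) ? R::exp_rand() / rate : R_PosInf;
    if (t + dt >= bound) {
      t = bound;
      if (phase == 0) {
        // move deme-3 lineages at T2
        for (size_t i = 0; i < act[2].size(); ++i) {
          int v = act[2][i];
          int dest;
          if (topology == 0) dest = (R::unif_rand() < alpha) ? 0 : 1;
          else if (topology == 1) dest = 0;
          else dest = 1;
          act[dest].push_back(v);
        }
        act[2].clear();
        phase = 1;
      } else if (phase == 1) {
        for (size_t i = 0; i < act[1].size(); ++i) act[0].push_back(act[1][i]);
        act[1].clear();
        sz[0] = ne_anc;
        phase = 2;
      } else {
        stop("internal error: no coalescence possible after root phase");
      }
      continue;
    }
    t += dt;
    // choose deme proportional to its coalescence rate
    double u = R::unif_rand() * rate;
    int d = 0;
    while (d < 2 && u > rd[d]) { u -= rd[d]; ++d; }
    // choose an unordered pair uniformly
    int k = (int)act[d].size();
    int i = (int)(R::unif_rand() * k); if (i == k) i = k - 1;
    int j = (int)(R::unif_rand() * (k - 1)); if (j == k - 1) j = k - 2;
    if (j >= i) ++j;
    int vi = act[d][i], vj = act[d][j];
    int np = (int)tr.time.size();
    tr.time.push_back(t);
    tr.parent.push_back(-1);
    tr.parent[vi] = np;
    tr.parent[vj] = np;
    // remove the two children, add the parent
    if (i > j) std::swap(i, j);
    act[d].erase(act[d].begin() + j);
    act[d].erase(act[d].begin() + i);
    act[d].push_back(np);
  }
  return tr;
}

// drop SMM mutations on the genealogy; returns tip allele sizes
std::vector<int> drop_mutations(const Tree& tr, double mu, int anc_size) {
  int m = (int)tr.time.size();
  std::vector<int> size(m, anc_size);
  // nodes are created in increasing time order; every parent has a larger
  // index than its children, so a downward pass assigns parents first
  for (int v = m - 2; v >= 0; --v) {
    int p = tr.parent[v];
    double bl = tr.time[p] - tr.time[v];
    int k = (mu > 0 && bl > 0) ? (int)R::rpois(mu * bl) : 0;
    int s = size[p];
    for (int x = 0; x < k; ++x) s += (R::unif_rand() < 0.5) ? 1 : -1;
    size[v] = s;
  }
  return std::vector<int>(size.begin(), size.begin() + tr.n_tips);
}

} // namespace

// [[Rcpp::export]]
List sim_locus_cpp(int topology, NumericVector ne, double ne_anc,
                   double t1, double t2, double alpha,
                   IntegerVector genes, double mu, int anc_size) {
  std::vector<double> nev(ne.begin(), ne.end());
  std::vector<int> gv(genes.begin(), genes.end());
  Tree tr = sim_genealogy(topology, nev, ne_anc, t1, t2, alpha, gv);
  std::vector<int> sizes = drop_mutations(tr, mu, anc_size);
  IntegerVector deme(tr.n_tips);
  int id = 0;
  for (int d = 0; d < 3; ++d)
    for (int k = 0; k < gv[d]; ++k) deme[id++] = d + 1;
  return List::create(_["sizes"] = wrap(sizes), _["deme"] = deme,
                      _["tmrca"] = tr.time.back());
}

// [[Rcpp::export]]
List sim_replicate_geno_cpp(int topology, NumericVector ne, double ne_anc,
                            double t1, double t2, double alpha,
                            IntegerVector n_dip, NumericVector mus,
                            int anc_size) {
  int L = mus.size();
  int N = n_dip[0] + n_dip[1] + n_dip[2];
  IntegerMatrix a1(N, L), a2(N, L);
  IntegerVector deme(N);
  {
    int i = 0;
    for (int d = 0; d < 3; ++d)
      for (int k = 0; k < n_dip[d]; ++k) deme[i++] = d + 1;
  }
  std::vector<double> nev(ne.begin(), ne.end());
  std::vector<int> gv(3);
  for (int d = 0; d < 3; ++d) gv[d] = 2 * n_dip[d];
  for (int l = 0; l < L; ++l) {
    Tree tr = sim_genealogy(topology, nev, ne_anc, t1, t2, alpha, gv);
    std::vector<int> sizes = drop_mutations(tr, mus[l], anc_size);
    // consecutive genes within a deme form a diploid (tips exchangeable)
    for (int i = 0; i < N; ++i) {
      a1(i, l) = sizes[2 * i];
      a2(i, l) = sizes[2 * i + 1];
    }
  }
  return List::create(_["a1"] = a1, _["a2"] = a2, _["deme"] = deme);
}

// Weir & Cockerham variance components for one locus and one pair of demes,
// accumulated into (sum_a, sum_abc) over alleles.
static void wc_accumulate(const std::vector<int>& al1a, const std::vector<int>& al1b,
                          const std::vector<int>& al2a, const std::vector<int>& al2b,
                          double& sum_a, double& sum_abc) {
  double n1 = (double)al1a.size(), n2 = (double)al2a.size();
  if (n1 < 1 || n2 < 1) return;
  std::unordered_map<int, bool> alleles;
  for (size_t i = 0; i < al1a.size(); ++i) { alleles[al1a[i]] = true; alleles[al1b[i]] = true; }
  for (size_t i = 0; i < al2a.size(); ++i) { alleles[al2a[i]] = true; alleles[al2b[i]] = true; }
  if (alleles.size() < 2) return;  // monomorphic locus contributes nothing
  const double r = 2.0;
  double nbar = (n1 + n2) / r;
  double nc = (r * nbar - (n1 * n1 + n2 * n2) / (r * nbar)) / (r - 1.0);
  for (std::unordered_map<int, bool>::iterator it = alleles.begin();
       it != alleles.end(); ++it) {
    int A = it->first;
    double c1 = 0, h1 = 0, c2 = 0, h2 = 0;
    for (size_t i = 0; i < al1a.size(); ++i) {
      int k = (al1a[i] == A) + (al1b[i] == A);
      c1 += k; if (k == 1) h1 += 1;
    }
    for (size_t i = 0; i < al2a.size(); ++i) {
      int k = (al2a[i] == A) + (al2b[i] == A);
      c2 += k; if (k == 1) h2 += 1;
    }
    double p1 = c1 / (2 * n1), p2 = c2 / (2 * n2);
    double pbar = (n1 * p1 + n2 * p2) / (r * nbar);
    double s2 = (n1 * (p1 - pbar) * (p1 - pbar) + n2 * (p2 - pbar) * (p2 - pbar)) /
                ((r - 1.0) * nbar);
    double hbar = (h1 + h2) / (r * nbar);
    if (nbar <= 1.0 || nc <= 0.0) continue;
    double a = nbar / nc *
      (s2 - 1.0 / (nbar - 1.0) * (pbar * (1 - pbar) - (r - 1.0) / r * s2 - hbar / 4.0));
    double b = nbar / (nbar - 1.0) *
      (pbar * (1 - pbar) - (r - 1.0) / r * s2 - (2.0 * nbar - 1.0) / (4.0 * nbar) * hbar);
    double c = hbar / 2.0;
    sum_a += a;
    sum_abc += a + b + c;
  }
}

// The 11-statistic summary vector, computed from a complete (no missing
// calls) diploid genotype matrix with deme labels in 1..3:
// [1-3] mean distinct alleles per locus, per deme;
// [4-6] unbiased expected heterozygosity per deme (gene-level Nei,
//       ng/(ng-1)*(1-sum p^2), averaged over loci);
// [7-9] pairwise Weir-Cockerham theta for deme pairs (1,2), (1,3), (2,3),
//       multilocus ratio-of-sums;
// [10]  mean over loci of the pooled allele-size variance;
// [11]  total distinct alleles pooled over demes, summed over loci.
// [[Rcpp::export]]
NumericVector stats_from_geno_cpp(IntegerMatrix a1, IntegerMatrix a2,
                                  IntegerVector deme) {
  int N = a1.nrow(), L = a1.ncol();
  NumericVector out(11);
  double ka[3] = {0, 0, 0}, he[3] = {0, 0, 0};
  double fst_num[3] = {0, 0, 0}, fst_den[3] = {0, 0, 0};
  double sizevar = 0.0;
  double tot_alleles = 0.0;
  std::vector<std::vector<int> > idx(3);
  for (int i = 0; i < N; ++i) idx[deme[i] - 1].push_back(i);

  for (int l = 0; l < L; ++l) {
    std::unordered_map<int, int> pooled;
    double sum = 0, sum2 = 0; int ng_all = 0;
    for (int d = 0; d < 3; ++d) {
      std::unordered_map<int, int> cnt;
      int ng = 0;
      for (size_t k = 0; k < idx[d].size(); ++k) {
        int i = idx[d][k];
        cnt[a1(i, l)]++; cnt[a2(i, l)]++;
        pooled[a1(i, l)]++; pooled[a2(i, l)]++;
        sum += a1(i, l) + a2(i, l);
        sum2 += (double)a1(i, l) * a1(i, l) + (double)a2(i, l) * a2(i, l);
        ng += 2; ng_all += 2;
      }
      ka[d] += (double)cnt.size();
      double sp2 = 0;
      for (std::unordered_map<int, int>::iterator it = cnt.begin();
           it != cnt.end(); ++it) {
        double p = (double)it->second / ng;
        sp2 += p * p;
      }
      if (ng > 1) he[d] += (double)ng / (ng - 1.0) * (1.0 - sp2);
    }
    tot_alleles += (double)pooled.size();
    if (ng_all > 1)
      sizevar += (sum2 - sum * sum / ng_all) / (ng_all - 1.0);
    // pairwise theta
    int pair = 0;
    for (int d1 = 0; d1 < 2; ++d1) for (int d2 = d1 + 1; d2 < 3; ++d2) {
      std::vector<int> x1a, x1b, x2a, x2b;
      for (size_t k = 0; k < idx[d1].size(); ++k) {
        x1a.push_back(a1(idx[d1][k], l)); x1b.push_back(a2(idx[d1][k], l));
      }
      for (size_t k = 0; k < idx[d2].size(); ++k) {
        x2a.push_back(a1(idx[d2][k], l)); x2b.push_back(a2(idx[d2][k], l));
      }
      wc_accumulate(x1a, x1b, x2a, x2b, fst_num[pair], fst_den[pair]);
      ++pair;
    }
  }
  for (int d = 0; d < 3; ++d) {
    out[d] = ka[d] / L;
    out[3 + d] = he[d] / L;
  }
  for (int p = 0; p < 3; ++p)
    out[6 + p] = (fst_den[p] > 0) ? fst_num[p] / fst_den[p] : 0.0;
  out[9] = sizevar / L;
  out[10] = tot_alleles;
  return out;
}

// [[Rcpp::export]]
NumericVector sim_replicate_stats_cpp(int topology, NumericVector ne,
                                      double ne_anc, double t1, double t2,
                                      double alpha, IntegerVector n_dip,
                                      NumericVector mus, int anc_size) {
  List g = sim_replicate_geno_cpp(topology, ne, ne_anc, t1, t2, alpha,
                                  n_dip, mus, anc_size);
  return stats_from_geno_cpp(g["a1"], g["a2"], g["deme"]);
}

// [[Rcpp::export]]
NumericVector sim_tmrca_cpp(int n_reps, NumericVector ne, double ne_anc,
                            double t1, double t2, IntegerVector genes) {
  NumericVector out(n_reps);
  std::vector<double> nev(ne.begin(), ne.end());
  std::vector<int> gv(genes.begin(), genes.end());
  for (int r = 0; r < n_reps; ++r) {
    Tree tr = sim_genealogy(2, nev, ne_anc, t1, t2, 0.0, gv);
    out[r] = tr.time.back();
  }
  return out;
}
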