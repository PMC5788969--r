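// Gibbs sampler for Bayesian assignment of diploid individuals to
// genealogical classes (P1, P2, F1, F2, BC1, BC2) from unlinked co-dominant
// loci, in the style of NewHybrids (Anderson & Thompson). Each class is a
// triple phi = (both alleles from the P1 gene pool, one from each, both from
// P2). The sampler alternates: (i) class of each candidate given parental
// allele frequencies; (ii) latent per-locus gene-pool origin of each allele;
// (iii) parental frequencies from Dirichlet(1 + assigned counts), reference
// individuals contributing both alleles to their own pool.
//
// Alleles arrive recoded to 0-based indices per locus; -1 marks a missing
// call (whole-call missing).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

inline void rdirichlet(std::vector<double>& p, const std::vector<double>& a) {
  double s = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    p[i] = R::rgamma(a[i], 1.0);
    s += p[i];
  }
  for (size_t i = 0; i < a.size(); ++i) p[i] /= s;
}

// P(genotype (a,b) | gene-pool category) for one locus
inline void cat_probs(int a, int b, const std::vector<double>& p1,
                      const std::vector<double>& p2, double out[3]) {
  if (a == b) {
    out[0] = p1[a] * p1[a];
    out[1] = p1[a] * p2[a];
    out[2] = p2[a] * p2[a];
  } else {
    out[0] = 2.0 * p1[a] * p1[b];
    out[1] = p1[a] * p2[b] + p1[b] * p2[a];
    out[2] = 2.0 * p2[a] * p2[b];
  }
}

} // namespace

// [[Rcpp::export]]
List gibbs_newhybrids_cpp(IntegerMatrix ca1, IntegerMatrix ca2,
                          IntegerMatrix r1a1, IntegerMatrix r1a2,
                          IntegerMatrix r2a1, IntegerMatrix r2a2,
                          IntegerVector n_alleles, NumericMatrix phi,
                          int sweeps, int burnin) {
  if (sweeps <= burnin) stop("sweeps must exceed burnin");
  int n = ca1.nrow(), L = ca1.ncol(), C = phi.nrow();

  // fixed reference counts per locus/pool
  std::vector<std::vector<double> > ref1(L), ref2(L);
  for (int l = 0; l < L; ++l) {
    ref1[l].assign(n_alleles[l], 0.0);
    ref2[l].assign(n_alleles[l], 0.0);
    for (int i = 0; i < r1a1.nrow(); ++i)
      if (r1a1(i, l) >= 0) { ref1[l][r1a1(i, l)] += 1; ref1[l][r1a2(i, l)] += 1; }
    for (int i = 0; i < r2a1.nrow(); ++i)
      if (r2a1(i, l) >= 0) { ref2[l][r2a1(i, l)] += 1; ref2[l][r2a2(i, l)] += 1; }
  }

  std::vector<std::vector<double> > p1(L), p2(L);
  std::vector<double> alpha;
  for (int l = 0; l < L; ++l) {
    p1[l].assign(n_alleles[l], 0.0);
    p2[l].assign(n_alleles[l], 0.0);
    alpha.assign(n_alleles[l], 0.0);
    for (int a = 0; a < n_alleles[l]; ++a) alpha[a] = 1.0 + ref1[l][a];
    rdirichlet(p1[l], alpha);
    for (int a = 0; a < n_alleles[l]; ++a) alpha[a] = 1.0 + ref2[l][a];
    rdirichlet(p2[l], alpha);
  }

  std::vector<int> z(n);
  for (int i = 0; i < n; ++i) z[i] = (int)(R::unif_rand() * C) % C;

  NumericMatrix post(n, C);
  std::vector<double> ll(C), pr(C);
  std::vector<std::vector<double> > c1(L), c2(L);
  int kept = 0;

  for (int s = 0; s < sweeps; ++s) {
    // (i) class update
    for (int i = 0; i < n; ++i) {
      for (int c = 0; c < C; ++c) ll[c] = 0.0;
      for (int l = 0; l < L; ++l) {
        int a = ca1(i, l), b = ca2(i, l);
        if (a < 0) continue;
        double cp[3];
        cat_probs(a, b, p1[l], p2[l], cp);
        for (int c = 0; c < C; ++c) {
          double v = phi(c, 0) * cp[0] + phi(c, 1) * cp[1] + phi(c, 2) * cp[2];
          ll[c] += std::log(v > 1e-300 ? v : 1e-300);
        }
      }
      double mx = ll[0];
      for (int c = 1; c < C; ++c) if (ll[c] > mx) mx = ll[c];
      double tot = 0;
      for (int c = 0; c < C; ++c) { pr[c] = std::exp(ll[c] - mx); tot += pr[c]; }
      double u = R::unif_rand() * tot;
      int c = 0;
      while (c < C - 1 && u > pr[c]) { u -= pr[c]; ++c; }
      z[i] = c;
    }
    // (ii) latent origins -> counts, (iii) frequency update
    for (int l = 0; l < L; ++l) {
      c1[l] = ref1[l];
      c2[l] = ref2[l];
    }
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        int a = ca1(i, l), b = ca2(i, l);
        if (a < 0) continue;
        double cp[3], w[3];
        cat_probs(a, b, p1[l], p2[l], cp);
        double tot = 0;
        for (int c = 0; c < 3; ++c) { w[c] = phi(z[i], c) * cp[c]; tot += w[c]; }
        if (tot <= 0) continue;
        double u = R::unif_rand() * tot;
        int cat = 0;
        while (cat < 2 && u > w[cat]) { u -= w[cat]; ++cat; }
        if (cat == 0) { c1[l][a] += 1; c1[l][b] += 1; }
        else if (cat == 2) { c2[l][a] += 1; c2[l][b] += 1; }
        else if (a == b) { c1[l][a] += 1; c2[l][a] += 1; }
        else {
          double wa = p1[l][a] * p2[l][b];
          double wb = p1[l][b] * p2[l][a];
          if (R::unif_rand() * (wa + wb) < wa) { c1[l][a] += 1; c2[l][b] += 1; }
          else { c1[l][b] += 1; c2[l][a] += 1; }
        }
      }
    }
    for (int l = 0; l < L; ++l) {
      alpha.assign(n_alleles[l], 0.0);
      for (int a = 0; a < n_alleles[l]; ++a) alpha[a] = 1.0 + c1[l][a];
      rdirichlet(p1[l], alpha);
      for (int a = 0; a < n_alleles[l]; ++a) alpha[a] = 1.0 + c2[l][a];
      rdirichlet(p2[l], alpha);
    }
    if (s >= burnin) {
      for (int i = 0; i < n; ++i) post(i, z[i]) += 1.0;
      ++kept;
    }
  }
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < C; ++c) post(i, c) /= kept;
  return List::create(_["posterior"] = post, _["kept"] = kept);
}
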