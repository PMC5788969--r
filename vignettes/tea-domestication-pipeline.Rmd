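---
title: "Inferring tea domestication history from microsatellites and cpDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring tea domestication history from microsatellites and cpDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teapopgen)
```

## The scientific problem

Domesticated tea (*Camellia sinensis*) comprises three deeply structured
lineages — China type tea, Chinese Assam type tea and Indian Assam type tea —
alongside wild relatives such as *C. taliensis*. Two questions drive the
analyses in this package: *when* did these lineages diverge (and under which
branching scenario), and *how much of today's germplasm is of hybrid origin,
and of what kind*? The raw material is modest by genomic standards — a
couple of dozen co-dominant nuclear microsatellite (nSSR) loci scored as
integer repeat sizes across a few hundred accessions, plus a few hundred
maternally inherited chloroplast (cpDNA) sequences — which is exactly why
the statistical machinery matters: coalescent simulation, approximate
Bayesian computation (ABC), Bayesian genealogical-class assignment, and
haplotype network methods squeeze history out of allele frequencies.

This vignette explains the models behind each stage, the tunable parameters
and their defaults, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely open.

## Data model

Genotypes live in a `genotype_matrix`: an unordered pair of integer repeat
sizes per individual and locus, with whole-call missingness only (a
half-missing genotype cannot be represented; missing cells are excluded
locus-wise from every statistic). Allele states are never recoded at the
container level because stepwise-mutation arithmetic — allele-size variances,
SMM distances — needs the raw sizes; consumers that want dense indices
(the Gibbs sampler, the EM clustering) recode internally.

Two interchange formats are supported: STRUCTURE-style whitespace text (two
rows per individual by default, one-row dialect by flag, missing code -9)
and a GenAlEx-style CSV (two adjacent columns per locus, missing code 0).
Group labels follow the 12 subgroup codes (CT, CCL, CCC, CCCM, CIC, CICM,
ACL, ACLM, ACC, ACCM, AIC, AICM); a trailing `M` marks a Mosaic (admixed)
group, and the code table maps each group to lineage and category
(landrace / cultivar / wild). Aligned cpDNA arrives as FASTA with optional
region boundaries for the concatenated spacers.

## Diversity statistics

Per group, `diversity_table()` reports N, total alleles A, the percentage
of rare alleles (within-group frequency at or below 0.05, the boundary
counting as rare), rarefied allelic richness, observed heterozygosity Ho,
Nei's unbiased gene diversity

$$H_s = \frac{n}{n-1}\Bigl(1 - \sum_i \hat p_i^2 - \frac{H_o}{2n}\Bigr),$$

and the inbreeding coefficient reported at group level as
$F_{is} = 1 - \bar H_o / \bar H_s$ from the locus-averaged means. Three
conventions are deliberate, because they reproduce how FSTAT-era tables
were assembled: per-locus statistics are averaged unweighted over loci;
the rarefaction size is a single global gene count (the smallest per-group,
per-locus count across compared groups) so allelic richness is comparable
across rows; and the `Total` row pools all samples and *recomputes* every
statistic rather than averaging rows (which is why the pooled allele count
is far below the sum of group counts). Rarefied richness is the exact
hypergeometric expectation
$A_r = \sum_i \bigl[1 - \binom{N_g - N_i}{g}/\binom{N_g}{g}\bigr]$,
computed on a log scale for large counts; the test suite checks it against
exhaustive enumeration of all gene subsamples up to $N_g = 12$.

## The coalescent simulator

`simulate_locus()` implements a continuous-time structured Kingman
coalescent for three demes with piecewise-constant diploid sizes
(pairwise coalescence rate $1/(2N_e)$ per generation). Three topologies
share an old split at $T_1$ between China type and the Assam stock and
differ at the younger time $T_2$: under scenario A, Indian Assam tea is
founded by admixture (each lineage moves to the China-type deme with
probability $\alpha$, else to Chinese Assam); under B it splits from China
type; under C from Chinese Assam. Mutations are dropped as
Poisson($\mu\,\times$ branch length), each one a strict single-step change
of $\pm 1$ repeat unit with equal probability, from an ancestral size of 20
repeats (arbitrary — every downstream statistic depends only on size
differences). The simulator is calibrated in the tests against analytic
results: the two-gene mean TMRCA equals $2N$ generations, and the pairwise
allele-size-difference variance equals
$\mu \, E[\text{total tree length}] = 2\mu\,E[T_{MRCA}] = 4N\mu$.
Scenario A reduces exactly to C at $\alpha = 0$ and to B at $\alpha = 1$,
which the suite verifies distributionally.

The full-scale analysis uses $10^6$ replicates per model; priors are not
recoverable from the source, so the package declares its own and logs them
with every run: log-uniform $N_e$ on $[10^2, 10^5]$ (each deme and the
ancestor), uniform $T_1$ on $[10, 10^5]$ generations, $T_2$ conditionally
uniform on $[10, T_1]$, uniform $\alpha$, and per-locus mutation rates
log-uniform on $[10^{-5}, 10^{-3}]$ — a range containing the
$0.515\times10^{-3}$ mean rate reported for these loci. Generation time
defaults to 12 years (seed-to-seed under pre-modern cultivation), entering
only the final conversion `divergence_time_years()`, which reports at 3
significant figures (231 generations → 2,770 years).

## ABC: summary statistics, PLS, rejection, adjustment

The original analysis used "11 summary statistics" without enumerating
them; the package fixes a default set spanning within-deme diversity and
between-deme differentiation: mean alleles per locus (3 demes), unbiased
expected heterozygosity (3), pairwise Weir–Cockerham $\theta$ as multilocus
ratio-of-sums (3), mean pooled allele-size variance (1), and total distinct
alleles (1). The same formulas are implemented twice — vectorized R for
observed data, C++ for the simulation loop — and the two paths are tested
for exact agreement.

For parameter estimation the statistics are shifted to positivity, Box-Cox
transformed (per-statistic maximum-likelihood exponent), standardized, and
reduced to 6 partial-least-squares components fitted with parameters as
responses (NIPALS; the component scores are checked against the mixOmics
implementation). Rejection keeps the closest fraction of simulations by
Euclidean distance in component space with Epanechnikov weights, and a
Beaumont-style weighted local-linear regression moves each retained draw to
the fitted value at the observed statistics plus its own residual;
positive parameters are adjusted on the log scale and proportions on the
logit scale, then back-transformed. Posterior summaries use the Gaussian
kernel density mode (Silverman bandwidth) and the shortest 95% interval.

Model choice is by acceptance-ratio Bayes factors under one absolute
distance threshold, the chosen quantile of the pooled distances. One design
choice deserves emphasis: **model choice does not use the parameter-PLS
space.** Components trained to predict parameters can be blind to exactly
the feature separating the scenarios — *which* pairwise FST is the small
one predicts no parameter — and in pilot experiments that projection drove
all Bayes factors to 1. `bayes_factors()` therefore operates in the
standardized full-statistic space (`fit_stat_scaler()`), while PLS remains
the space for within-model parameter posteriors.

### What the desk-scale experiments can and cannot show

The published Bayes factor (75.3 for scenario C) came from $3\times10^6$
simulations of the full 276-sample design under undisclosed priors; it is
not reproducible at desk scale, and the package does not pretend to. The
acceptance experiments instead check *self-consistency* at a reduced,
documented scale chosen once: 20,000 simulations per model on a
60/60/60-diploid, 23-locus design. Pseudo-observed data generated under
scenario C with well-separated parameters (a deep old split, $T_1 = 25000$
generations, a shallow recent one, $T_2 = 150$, $N_e = 2000$,
$\mu = 5\times10^{-4}$) must yield $BF_C > 3$ in at least 80% of trials
(acceptance fraction 0.002, i.e. 120 of 60,000 pooled); with truths drawn
from the priors, the regression-adjusted 95% HPDI must cover the true
$T_2$ in at least 85% of trials (tolerance 0.01). Pilot runs at weaker
separation showed rejection-ABC simply cannot separate these scenarios at
desk scale — a property of the method's information budget, not of any
implementation.

## Hybrid classes: the six-category model

Two generations after admixture between pools P1 and P2, an individual's
loci fall into three origin categories — both alleles from P1, one from
each, both from P2 — with class-specific expected proportions
$\phi$: P1 (1,0,0), P2 (0,0,1), F1 (0,1,0), F2 (¼,½,¼), BC1 (½,½,0),
BC2 (0,½,½). The genotype likelihood at a locus is
$\sum_c \phi_c \Pr(g \mid c)$ with heterozygote terms doubled.
`gibbs_newhybrids()` samples, per sweep: each candidate's class given the
parental frequencies (uniform class prior); the latent origin of each
allele; and the parental frequencies from Dirichlet(1 + assigned counts),
with designated reference individuals always counting toward their own
pool. Defaults are 10,000 sweeps with 1,000 burn-in; the recovery
experiments use 2,000/500, where the chains mix in seconds because the
class conditionals are nearly deterministic once frequencies stabilize.
`classify_mosaics()` labels an individual `complex` when no class reaches
the posterior threshold (default 0.5) — the analogue of samples drawing on
more than two parental pools.

A calibration point discovered while validating the sampler: with 23 loci
and 8-allele frequency profiles at lineage FST near 0.15, even the
Bayes-optimal classifier *given the true pool frequencies* tops out near
83% F1 and 67% F2 recall — the recovery targets (90% F1, 75% F2/BC) are
information-theoretically out of reach there. The recovery roster therefore
uses well-differentiated pools (Balding–Nichols divergence 0.4, empirical
FST ≈ 0.39), where the Gibbs sampler empirically matches the oracle bound.
F2↔backcross confusion remains the dominant error mode at any divergence,
mirroring how most real hybrid accessions resolve as F2/BC rather than F1.

## Admixture clustering and ΔK

STRUCTURE's Bayesian MCMC is replaced by a maximum-likelihood EM for the
same admixture likelihood
$\sum_{i,l,\text{copies}} \log \sum_k q_{ik}\, p_{kl}(\text{allele})$,
from random Dirichlet starts; replicate starts stand in for the "20
permutations per K" protocol, and their converged log-likelihoods feed the
Evanno table
$\Delta K = \overline{|L(K{+}1) - 2L(K) + L(K{-}1)|}\,/\,\mathrm{sd}[L(K)]$.
EM monotonicity is asserted on every iteration of every run. Mosaic calls
use a 0.9 ancestry purity threshold (the source never states its cut-off;
this one is declared and configurable).

## cpDNA: haplotypes, K2P, NJ, median-joining

Haplotype collapsing treats each contiguous gap run as a single mutation
event (simple indel coding: one binary presence/absence character per
distinct run, with runs of different extents as distinct characters);
substitution characters come from variable columns, and sites where a
sequence carries N are excluded from its identity comparisons. Distances
between sequences use the Kimura two-parameter model with pairwise
deletion, $d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$, saturated pairs
reported as infinite; the matrix is verified against ape's implementation.
Trees are Saitou–Nei neighbor joining (via ape), with negative branch
lengths clamped to zero and the magnitude moved to the adjacent branch so
tip-to-tip path lengths are preserved (the MEGA convention; disable by
flag). Both haplotype-level and sample-level trees are supported, since
either reading of the published tree is defensible.

The median-joining network follows Bandelt's construction on the event
characters: the minimum spanning network (union of all minimum spanning
trees, tolerance ε = 0 by default) is iteratively augmented with median
(majority consensus) vectors of mutually adjacent node triples; medians
with degree below 3 are pruned; and the final edge set keeps only links
present in at least one minimum spanning tree — the maximum-parsimony
simplification — so the network provably contains an MST, every edge
weight being the recomputed character difference.

## The synthetic-data generator

`generate_synthetic_dataset()` emulates the study's assumed structure:
three domesticated lineages plus the wild relative with the published
group sizes (CT 10, CCL 36, CCC 89, CIC 6, ACL 45, ACC 51, AIC 46), a
hybrid roster with the observed class totals (6 F1, 64 F2, 23 BC1, 7 BC2),
and 31 cpDNA haplotypes over ~101 sequenced samples with lineage-private
cores. Lineage allele frequencies come from a Balding–Nichols Dirichlet
hierarchy whose divergence parameter is approximately the expected lineage
FST (default 0.2); a coalescent pathway through the demographic simulator
is available when the ABC stage itself is under test. Hybrids are bred by
explicit Mendelian crossing (an F2 is the offspring of two simulated F1s),
with unlinked loci, no null alleles, no selfing and no mutation during the
one or two generations of crossing. What passing tests on this material
show is that the *inference machinery* is correct under its own model
assumptions; they cannot certify behavior under genotyping error,
null-allele segregation or linkage, which real microsatellite panels do
exhibit.

Fixed seeds make every output byte-identical, and each dataset carries its
seed and specification as provenance.

## Pipeline and problem sizes

`run_pipeline()` sequences the stages under one master seed, writes every
table alongside the YAML configuration and its MD5 hash, and refuses to
overwrite an identical earlier run unless forced. The exported stage
functions plus this orchestrator *are* the interface: users of such
panels drive the analysis from R scripts, so the package ships no separate
shell tool. Stages run standalone on
prior artifacts, because ABC is the slow stage and everything else iterates
fast. The problem sizes used by the shipped tests and the acceptance
script — 20,000 simulations per model, 60 diploids per deme, 2,000 Gibbs
sweeps, rosters of 200 candidates — are the package's chosen desk scale:
large enough for the recovery properties to be stable, small enough to
iterate on.

## Known limitations

The 11-statistic set and the priors are declared stand-ins for
unrecoverable originals, so posterior *values* on real data will not match
the published ones even at full scale; model-choice behavior is the tested
claim. The Gibbs sampler implements the six two-parent classes only — true
three-pool mosaics are flagged `complex`, not decomposed. The EM admixture
fit gives point estimates of ancestry, not posterior uncertainty. Indel
coding scores exact run identity, so partially overlapping gap runs become
distinct characters rather than nested events. And the median-joining
implementation targets the small haplotype sets typical of chloroplast
data; it refuses inputs beyond $10^4$ haplotypes.
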