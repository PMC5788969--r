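test_that("observed heterozygosity hits its boundary values", {
  g_hom <- gm_uniform(5, c(10L, 12L), c(10L, 12L))
  expect_equal(observed_heterozygosity(g_hom, rep("x", 5), "x")$mean, 0)
  g_het <- gm_uniform(5, c(10L, 12L), c(11L, 13L))
  expect_equal(observed_heterozygosity(g_het, rep("x", 5), "x")$mean, 1)
  expect_error(observed_heterozygosity(g_het, rep("x", 5), "nope"),
               "group not present")
})

test_that("all-missing loci are excluded with a warning", {
  g <- gm_uniform(4, c(10L, 11L), c(11L, 12L))
  g$a1[, 2] <- NA; g$a2[, 2] <- NA
  g <- genotype_matrix(g$a1, g$a2)
  expect_warning(ho <- observed_heterozygosity(g, rep("x", 4), "x"),
                 "all-missing")
  expect_equal(ho$mean, 1)  # the surviving locus is fully heterozygous
})

test_that("Nei unbiased gene diversity matches the hand-computed estimator", {
  # two alleles at 0.5/0.5, fully heterozygous, n = 10:
  # Hs = (10/9) (1 - 0.5 - 0.05) = 0.5
  g <- gm_uniform(10, 10L, 11L)
  expect_equal(gene_diversity(g, rep("x", 10), "x")$mean, 0.5)
  # monomorphic locus
  g1 <- gm_uniform(8, 10L, 10L)
  expect_equal(gene_diversity(g1, rep("x", 8), "x")$mean, 0)
})

test_that("rarefied allelic richness matches closed form and brute force", {
  # Ng = 4 genes with counts (3,1), g_genes = 2:
  # Ar = [1 - C(1,2)/C(4,2)] + [1 - C(3,2)/C(4,2)] = 1 + 0.5 = 1.5
  g <- gm_from_calls(matrix(c(10L, 10L), 2, 1), matrix(c(10L, 11L), 2, 1))
  expect_equal(allelic_richness(g, rep("x", 2), "x", g_genes = 2)$mean, 1.5)
  # monomorphic locus: Ar = 1 for any rarefaction size
  gm <- gm_uniform(6, 10L, 10L)
  for (gg in c(2, 5, 12))
    expect_equal(allelic_richness(gm, rep("x", 6), "x", gg)$mean, 1)
  expect_error(allelic_richness(g, rep("x", 2), "x", g_genes = 1), ">= 2")

  # random small cases against exhaustive subsample enumeration
  set.seed(11)
  for (trial in 1:10) {
    counts <- as.vector(stats::rmultinom(1, sample(4:6, 1) * 2,
                                         prob = runif(sample(2:4, 1)) + .1))
    counts <- counts[counts > 0]
    if (length(counts) < 1) next
    ng <- sum(counts)
    # build ng/2 diploids carrying exactly these allele counts
    genes <- rep(seq_along(counts) + 9L, counts)
    a1 <- matrix(genes[seq(1, ng, 2)], ncol = 1)
    a2 <- matrix(genes[seq(2, ng, 2)], ncol = 1)
    gg_obj <- genotype_matrix(a1, a2)
    for (gsz in 2:min(6, ng)) {
      expect_equal(allelic_richness(gg_obj, rep("x", ng / 2), "x", gsz)$mean,
                   brute_ar(counts, gsz), tolerance = 1e-10)
    }
  }
})

test_that("Ar is monotone in the rarefaction size and exact at Ng", {
  set.seed(12)
  fr <- generate_lineage_frequencies(n_loci = 3, lineages = "X",
                                     n_alleles = 5)
  g <- sample_individuals(fr$X, 8)
  ar <- vapply(2:16, function(gg)
    allelic_richness(g, rep("x", 8), "x", gg)$mean, numeric(1))
  expect_true(all(diff(ar) >= -1e-12))
  distinct <- mean(vapply(1:3, function(l)
    length(unique(c(g$a1[, l], g$a2[, l]))), numeric(1)))
  expect_equal(ar[length(ar)], distinct)
})

test_that("rare-allele percentage applies the <= cutoff convention", {
  # 25 individuals, frequencies 0.9 / 0.06 / 0.04 at the only locus
  a1 <- matrix(c(rep(10L, 25)), ncol = 1)
  a2 <- matrix(c(rep(10L, 20), rep(11L, 3), rep(12L, 2)), ncol = 1)
  g <- genotype_matrix(a1, a2)
  expect_equal(rare_allele_pct(g, rep("x", 25), "x"), 100 / 3)
  # an allele at exactly the cutoff counts as rare
  a2b <- matrix(c(rep(10L, 24), 11L), ncol = 1)  # p = 1/40 < 0.05
  g2 <- genotype_matrix(a1, a2b)
  expect_equal(rare_allele_pct(g2, rep("x", 25), "x", cutoff = 1 / 40), 50)
  expect_equal(rare_allele_pct(g2, rep("x", 25), "x", cutoff = 0.01), 0)
})

test_that("Fis follows 1 - Ho/Hs with a missing value at Hs = 0", {
  expect_equal(inbreeding_coefficient(0.5, 0.5), 0)
  expect_equal(inbreeding_coefficient(0, 0.7), 1)
  expect_true(is.na(inbreeding_coefficient(0.2, 0)))
})

test_that("diversity_table matches hand computation on a known group", {
  # 10 individuals, 1 locus, all heterozygous 10/11 -> Ho=1, Hs=0.5 (above),
  # A=2, no rare alleles, Ar(2) = 2 - (C(10,2)+C(10,2))/C(20,2)
  g <- gm_uniform(10, 10L, 11L)
  md <- sample_metadata(g$samples, "CCL")
  tab <- diversity_table(g, md, include_total = FALSE, g_genes = 2)
  expect_equal(tab$N, 10)
  expect_equal(tab$A, 2)
  expect_equal(tab$Ho, 1)
  expect_equal(tab$Hs, 0.5)
  expect_equal(tab$Fis, -1)
  expect_equal(tab$RA_pct, 0)
  expect_equal(tab$Ar, 2 * (1 - choose(10, 2) / choose(20, 2)))
})

test_that("diversity_table pools the Total row and excludes mosaics", {
  set.seed(13)
  fr <- generate_lineage_frequencies(n_loci = 4, lineages = c("A1", "B1"),
                                     divergence = 0.3)
  g <- rbind_genotypes(sample_individuals(fr$A1, 10, "ccl"),
                       sample_individuals(fr$B1, 10, "acl"),
                       make_hybrid("F1", fr$A1, fr$B1, 5, "accm"))
  md <- sample_metadata(g$samples, rep(c("CCL", "ACL", "ACCM"), c(10, 10, 5)))
  tab <- diversity_table(g, md)
  expect_identical(tab$Group, c("CCL", "ACL", "Total"))  # ACCM (Mosaic) out
  expect_equal(tab$N[3], 20)
  # pooled recomputation: Total A <= sum of group A, >= max of group A
  expect_lte(tab$A[3], tab$A[1] + tab$A[2])
  expect_gte(tab$A[3], max(tab$A[1:2]))
  # empty group list -> empty table
  empty <- diversity_table(g, md, groups = character(0))
  expect_equal(nrow(empty), 0)
})

test_that("every statistic is invariant to individual order", {
  set.seed(14)
  fr <- generate_lineage_frequencies(n_loci = 5, lineages = "X")
  g <- sample_individuals(fr$X, 12)
  md <- sample_metadata(g$samples, "AIC")
  perm <- sample(12)
  gp <- g[perm]
  tab1 <- diversity_table(g, md, include_total = FALSE)
  tab2 <- diversity_table(gp, md, include_total = FALSE)
  expect_equal(tab1, tab2)
})
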