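test_that("class likelihoods reproduce Mendelian expectations", {
  pa <- stats::setNames(1, "10"); pb <- stats::setNames(1, "20")
  expect_equal(class_likelihood(c(10, 20), "F1", pa, pb), 1, tolerance = 1e-4)
  expect_equal(class_likelihood(c(10, 10), "F1", pa, pb), 0, tolerance = 1e-4)
  expect_equal(class_likelihood(c(10, 10), "F2", pa, pb), 0.25,
               tolerance = 1e-4)
  expect_equal(class_likelihood(c(10, 20), "F2", pa, pb), 0.5,
               tolerance = 1e-4)
  expect_equal(class_likelihood(c(10, 10), "BC1", pa, pb), 0.5,
               tolerance = 1e-4)
  expect_error(class_likelihood(c(10, 10), "F9", pa, pb), "unknown class")
  # an allele absent from both pools is never impossible
  expect_gt(class_likelihood(c(99, 99), "F2", pa, pb), 0)
})

test_that("class likelihood equals exhaustive gamete enumeration", {
  set.seed(40)
  p1 <- stats::setNames(c(0.5, 0.3, 0.2), c("10", "11", "12"))
  p2 <- stats::setNames(c(0.1, 0.6, 0.3), c("10", "11", "12"))
  phi <- genealogical_classes()
  alleles <- c("10", "11", "12")
  # brute force: enumerate ordered gamete pairs within each origin category
  brute <- function(g, cl) {
    gs <- sort(as.character(g))
    tot <- 0
    for (cat_i in 1:3) {
      fa <- if (cat_i <= 2) p1 else p2        # origin of first allele
      fb <- if (cat_i == 1) p1 else p2        # origin of second allele
      pcat <- 0
      for (x in alleles) for (y in alleles) {
        if (identical(sort(c(x, y)), gs)) pcat <- pcat + fa[[x]] * fb[[y]]
      }
      tot <- tot + phi[cl, cat_i] * pcat
    }
    tot
  }
  for (cl in rownames(phi)) {
    for (g in list(c(10, 10), c(10, 11), c(11, 12), c(12, 12))) {
      expect_equal(class_likelihood(g, cl, p1, p2, pseudo = 0),
                   brute(g, cl), tolerance = 1e-12,
                   label = paste(cl, paste(g, collapse = "/")))
    }
  }
})

test_that("reference-like candidates are assigned to their own parent class", {
  r <- make_roster(divergence = 0.4, n_ref = 25, n_hyb = 0, seed = 41)
  set.seed(41)
  post <- gibbs_newhybrids(r$g, candidates = c(1:5, 26:30),
                           reference_p1 = r$ref1, reference_p2 = r$ref2,
                           sweeps = 800, burnin = 200)
  expect_identical(post$map_class[1:5], rep("P1", 5))
  expect_identical(post$map_class[6:10], rep("P2", 5))
  # posteriors are normalized
  expect_equal(rowSums(as.matrix(post[, rownames(genealogical_classes())])),
               rep(1, 10), tolerance = 1e-9)
})

test_that("the Gibbs sampler is deterministic under a fixed seed", {
  r <- make_roster(divergence = 0.3, n_ref = 10, n_hyb = 5, seed = 42)
  run <- function() {
    set.seed(99)
    gibbs_newhybrids(r$g, candidates = r$cand, reference_p1 = r$ref1,
                     reference_p2 = r$ref2, sweeps = 300, burnin = 100)
  }
  expect_identical(run(), run())
  expect_error(gibbs_newhybrids(r$g, r$cand, r$ref1, r$ref2,
                                sweeps = 100, burnin = 100),
               "exceed burnin")
})

test_that("classify_mosaics applies the posterior threshold", {
  post <- data.frame(sample_id = c("a", "b", "c"),
                     P1 = c(0, 1 / 6, 0), P2 = c(0, 1 / 6, 0),
                     F1 = c(0.05, 1 / 6, 0.4), F2 = c(0.9, 1 / 6, 0.6),
                     BC1 = c(0.05, 1 / 6, 0), BC2 = c(0, 1 / 6, 0))
  post$map_class <- c("F2", "P1", "F2")
  post$map_prob <- c(0.9, 1 / 6, 0.6)
  out <- classify_mosaics(post)
  expect_identical(out$class, c("F2", "complex", "F2"))
  out0 <- classify_mosaics(post, threshold = 0)
  expect_false(any(out0$complex))
  out1 <- classify_mosaics(post, threshold = 0.99)
  expect_true(all(out1$complex))
})

test_that("K = 1 admixture EM equals the closed-form frequency model", {
  set.seed(43)
  fr <- generate_lineage_frequencies(n_loci = 4, lineages = "X")
  g <- sample_individuals(fr$X, 30)
  fit <- admixture_em(g, K = 1, n_starts = 2)
  expect_true(all(fit$Q == 1))
  # direct likelihood at the observed allele frequencies
  ll <- 0
  for (l in 1:4) {
    al <- c(g$a1[, l], g$a2[, l])
    p <- table(al) / length(al)
    ll <- ll + sum(log(p[as.character(al)]))
  }
  expect_equal(fit$loglik, ll, tolerance = 1e-6)
})

test_that("EM separates two fully differentiated demes at K = 2", {
  set.seed(44)
  # disjoint allele pools: genuinely fixed differences at every locus
  mk <- function(states) replicate(23, {
    p <- stats::rgamma(4, 1); stats::setNames(p / sum(p), states)
  }, simplify = FALSE)
  frA <- mk(10:13); frB <- mk(20:23)
  g <- rbind_genotypes(sample_individuals(frA, 30, "a"),
                       sample_individuals(frB, 30, "b"))
  fit <- admixture_em(g, K = 2, n_starts = 5)
  expect_true(all(apply(fit$Q, 1, max) > 0.95))
  # the two demes land in different clusters
  expect_false(which.max(fit$Q[1, ]) == which.max(fit$Q[31, ]))
  # Q rows normalized; model-selection sanity: K=2 beats K=1
  expect_equal(unname(rowSums(fit$Q)), rep(1, 60), tolerance = 1e-9)
  fit1 <- admixture_em(g, K = 1, n_starts = 1)
  expect_gt(fit$loglik, fit1$loglik)
})

test_that("Evanno delta-K reproduces the hand-computed example", {
  # replicate log-likelihoods with SD exactly 1 at every K and
  # means (-100, -50, -49, -48): deltaK(2) = |-49 + 100 - 2(-50)|/1 = 49
  delta <- 1 / sqrt(2)
  ll <- rbind(c(-100, -50, -49, -48) - delta,
              c(-100, -50, -49, -48) + delta)
  colnames(ll) <- paste0("K", 1:4)
  dk <- evanno_delta_k(ll)
  expect_equal(dk$sd_loglik, rep(1, 4))
  expect_equal(dk$delta_k[2], 49)
  expect_true(is.na(dk$delta_k[1]) && is.na(dk$delta_k[4]))
  # perfectly linear means give zero at interior K
  ll_lin <- rbind(c(-30, -20, -10, 0) - delta, c(-30, -20, -10, 0) + delta)
  expect_equal(evanno_delta_k(ll_lin)$delta_k[2:3], c(0, 0))
  # replicate order is irrelevant
  expect_equal(evanno_delta_k(ll[2:1, ]), dk)
  # zero SD flagged as infinite
  ll0 <- rbind(c(-100, -50, -49), c(-100, -50, -49))
  expect_warning(dk0 <- evanno_delta_k(ll0), "Inf")
  expect_true(is.infinite(dk0$delta_k[2]))
  expect_error(evanno_delta_k(ll[, 1:2]), ">= 3")
})

test_that("mosaic labels respect the purity threshold", {
  Q <- rbind(c(0.95, 0.05), c(0.5, 0.5), c(1, 0))
  rownames(Q) <- c("a", "b", "c")
  lab <- mosaic_from_q(Q)
  expect_identical(lab$label, c("pure", "mosaic", "pure"))
  expect_equal(lab$cluster[1], 1)
  lab1 <- mosaic_from_q(Q, purity_threshold = 1)
  expect_identical(lab1$label, c("mosaic", "mosaic", "pure"))
})

test_that("align_clusters undoes a label permutation", {
  set.seed(45)
  Q <- matrix(stats::rgamma(60, 1), 20, 3)
  Q <- Q / rowSums(Q)
  expect_equal(align_clusters(Q[, c(3, 1, 2)], Q), Q)
})
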