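test_that("summary statistics behave at the differentiation extremes", {
  set.seed(30)
  fr <- generate_lineage_frequencies(n_loci = 10, lineages = "X",
                                     n_alleles = 6)
  g <- do.call(rbind_genotypes, lapply(1:3, function(d)
    sample_individuals(fr$X, 100, paste0("d", d))))
  s <- summarize_stats(g, rep(1:3, each = 100))
  expect_true(all(abs(s[7:9]) < 0.02))  # same pool: theta ~ 0
  expect_length(s, 11)

  # fixed different alleles in each deme: theta -> 1
  fix_col <- rep(c(10L, 30L, 50L), each = 10)
  gfix <- genotype_matrix(matrix(fix_col, 30, 1), matrix(fix_col, 30, 1),
                          samples = paste0("i", 1:30))
  sfix <- summarize_stats(gfix, rep(1:3, each = 10))
  expect_true(all(sfix[7:9] > 0.99))
  expect_error(summarize_stats(gfix, rep(1:2, 15)), "3 demes")
})

test_that("Weir-Cockerham theta matches an independent hand computation", {
  # deme 1: 4 individuals (10/10, 10/10, 10/11, 11/11)
  # deme 2: 4 individuals (11/11, 10/11, 11/11, 11/11); third deme far away
  g <- gm_from_calls(matrix(c(10L, 10L), 2), matrix(c(10L, 10L), 2),
                     matrix(c(10L, 11L), 2), matrix(c(11L, 11L), 2),
                     matrix(c(11L, 11L), 2), matrix(c(10L, 11L), 2),
                     matrix(c(11L, 11L), 2), matrix(c(11L, 11L), 2),
                     matrix(c(50L, 50L), 2), matrix(c(50L, 50L), 2))
  s <- summarize_stats(g, c(rep(1, 4), rep(2, 4), 3, 3))
  # independent arithmetic, straight from the variance-component formulas
  wc_oracle <- function(p1, p2, h1, h2, n1, n2) {
    r <- 2; nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    tot <- 0; num <- 0
    for (al in 1:2) {
      p <- c(p1[al], p2[al]); h <- c(h1[al], h2[al])
      pbar <- sum(c(n1, n2) * p) / (r * nbar)
      s2 <- sum(c(n1, n2) * (p - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(c(n1, n2) * h) / (r * nbar)
      a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                          (nbar - 1))
      b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
      num <- num + a; tot <- tot + a + b + hbar / 2
    }
    num / tot
  }
  theta12 <- wc_oracle(p1 = c(5 / 8, 3 / 8), p2 = c(1 / 8, 7 / 8),
                       h1 = c(1 / 4, 1 / 4), h2 = c(1 / 4, 1 / 4),
                       n1 = 4, n2 = 4)
  expect_equal(unname(s["S7"]), theta12, tolerance = 1e-12)
})

test_that("the R and C++ statistic paths agree on complete data", {
  set.seed(31)
  rep1 <- simulate_replicate("A", design = list(n_dip = c(8L, 8L, 8L),
                                                n_loci = 6L),
                             params = list(ne = c(2000, 2000, 2000),
                                           ne_anc = 2000, t1 = 4000,
                                           t2 = 300, alpha = 0.4,
                                           mus = rep(5e-4, 6)))
  sR <- summarize_stats(rep1$genotypes, rep1$deme)
  sC <- teapopgen:::stats_from_geno_cpp(rep1$genotypes$a1, rep1$genotypes$a2,
                                        rep1$deme)
  expect_equal(unname(sR), as.numeric(sC), tolerance = 1e-12)
})

test_that("PLS recovers constructed linear structure and is idempotent", {
  set.seed(32)
  n <- 300
  P <- cbind(t1 = runif(n, 1, 10), t2 = runif(n, 5, 50))
  X <- P %*% matrix(rnorm(22), 2, 11) +
    matrix(rnorm(n * 11, sd = 0.01), n, 11)
  colnames(X) <- paste0("S", 1:11)
  tr <- fit_pls(X, P, n_components = 4, boxcox = FALSE)
  sc <- pls_scores(tr, X)
  # first two components carry essentially all parameter variance
  for (j in 1:2) {
    fit <- stats::lm(P[, j] ~ sc[, 1:2])
    expect_gt(summary(fit)$r.squared, 0.999)
  }
  # training-sample orthogonality of scores
  cp <- crossprod(sc)
  expect_lt(max(abs(cp - diag(diag(cp)))) / max(diag(cp)), 1e-8)
  # applying the stored transform is deterministic/idempotent
  expect_identical(sc, pls_scores(tr, X))
  expect_equal(as.numeric(pls_scores(tr, X[3, ])), as.numeric(sc[3, ]))
  # a constant column is dropped with a warning
  X2 <- cbind(abs(X) + 0.5, S12 = 1)
  expect_warning(fit_pls(X2, P, 3), "constant")
})

test_that("PLS components match the mixOmics NIPALS implementation", {
  set.seed(33)
  n <- 200
  P <- cbind(runif(n), runif(n, 2, 3))
  X <- abs(P %*% matrix(rnorm(22), 2, 11) +
             matrix(rnorm(n * 11, sd = 0.3), n, 11)) + 0.2
  colnames(X) <- paste0("S", 1:11)
  tr <- fit_pls(X, P, n_components = 3)
  sc <- pls_scores(tr, X)
  # rebuild the Box-Cox-standardized design and hand it to the oracle
  Xb <- sapply(seq_len(ncol(X)), function(j)
    teapopgen:::.bc_transform(X[, j] + tr$shift[j], tr$lambda[j]))
  X0 <- scale(Xb, center = tr$center, scale = tr$scale)
  mo <- mixOmics::pls(X0, scale(P), ncomp = 3, mode = "regression",
                      scale = FALSE)
  for (h in 1:3)
    expect_gt(abs(stats::cor(mo$variates$X[, h], sc[, h])), 0.999)
})

test_that("rejection retains the nearest simulations with proper weights", {
  set.seed(34)
  sims <- simulate_table("C", 60, design = list(n_dip = c(5L, 5L, 5L),
                                                n_loci = 4L))
  pcols <- c("ne1", "t1", "t2")
  tr <- fit_stat_scaler(sims[, paste0("S", 1:11)])
  obs <- unlist(sims[17, paste0("S", 1:11)])
  rej <- abc_reject(obs, sims, tr, tolerance_frac = 0.1)
  # the matching row is retained with the maximal weight
  expect_true(17 %in% as.integer(rownames(rej$retained)))
  expect_equal(rej$distances[1], 0)
  expect_equal(rej$weights[1], max(rej$weights))
  # tolerance 1 retains everything
  expect_equal(nrow(abc_reject(obs, sims, tr, 1)$retained), 60)
  expect_error(abc_reject(obs, sims[0, ], tr, 0.1), "empty")
  expect_error(abc_reject(obs, sims, tr, 0), "tolerance_frac")

  # brute-force k-nearest oracle with independently recomputed distances
  Z <- scale(as.matrix(sims[, paste0("S", 1:11)]))
  zo <- (obs - attr(Z, "scaled:center")) / attr(Z, "scaled:scale")
  d_oracle <- sqrt(colSums((t(Z) - zo)^2))
  k <- ceiling(0.1 * 60)
  expect_setequal(as.integer(rownames(rej$retained)),
                  order(d_oracle)[seq_len(k)])
})

test_that("regression adjustment fixes what it should and nothing else", {
  set.seed(35)
  n <- 400
  S <- matrix(rnorm(n * 3), n, 3)
  # hand-built rejection object: scores ARE the statistics here
  rej <- list(scores_retained = S, scores_obs = matrix(0, 1, 3),
              weights = rep(1, n),
              retained = data.frame(indep = rnorm(n, 5),
                                    linear = 2 + 3 * S[, 1]))
  adj <- regression_adjust(rej, param_cols = c("indep", "linear"),
                           bounds = list(indep = NULL, linear = NULL))
  # independent parameter: essentially untouched
  expect_lt(abs(mean(adj$indep) - mean(rej$retained$indep)),
            0.05 * stats::sd(rej$retained$indep))
  # exact linear parameter: collapses onto the fitted value at the observed
  expect_lt(max(abs(adj$linear - 2)), 1e-9)

  # equal weights + one statistic reproduces plain OLS adjustment
  S1 <- matrix(c(-2, -1, 0, 1, 2), 5, 1)
  y <- c(3, 4, 6, 7, 10)
  rej5 <- list(scores_retained = S1, scores_obs = matrix(1, 1, 1),
               weights = rep(1, 5), retained = data.frame(p = y))
  adj5 <- regression_adjust(rej5, "p", bounds = list(p = NULL))
  fit <- stats::lm(y ~ I(S1 - 1))
  expect_equal(adj5$p, unname(stats::coef(fit)[1] + stats::resid(fit)),
               tolerance = 1e-10)
})

test_that("Bayes factors are symmetric and degrade to 1 at full tolerance", {
  set.seed(36)
  sims <- simulate_table("C", 80, design = list(n_dip = c(5L, 5L, 5L),
                                                n_loci = 4L))
  tr <- fit_stat_scaler(sims[, paste0("S", 1:11)])
  obs <- unlist(sims[3, paste0("S", 1:11)])
  # identical tables for two models: BF exactly 1
  bf <- bayes_factors(obs, list(B = sims, C = sims), tr,
                      tolerance_frac = 0.1, reference_model = "B")
  expect_equal(bf$bayes_factor, c(1, 1))
  # tolerance 1: everything accepted, all BF 1
  bf1 <- bayes_factors(obs, list(B = sims, C = sims[1:40, ]), tr,
                       tolerance_frac = 1, reference_model = "B")
  expect_equal(bf1$bayes_factor, c(1, 1))
})

test_that("posterior summaries match analytic expectations", {
  set.seed(37)
  x <- rnorm(50000)
  ps <- posterior_summary(x)
  expect_lt(abs(ps$mode - stats::median(x)), 0.1 * stats::sd(x))
  u <- runif(20000)
  hp <- posterior_summary(u)$hpdi
  expect_equal(hp[2] - hp[1], 0.95, tolerance = 0.02)
  pm <- posterior_summary(rep(3.7, 200))
  expect_equal(pm$hpdi[1], pm$hpdi[2])
  expect_error(posterior_summary(rnorm(50)), "100 draws")
  ps2 <- posterior_summary(rep(231, 150) + rnorm(150, sd = 1e-6),
                           generation_time = 12)
  expect_equal(ps2$mode_years, 2770)
})
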