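#' @name abc_inference
#' @title ABC model choice and parameter estimation
#'
#' @description
#' Approximate Bayesian computation over the three demographic scenarios:
#' an 11-statistic summary of the observed genotypes, Box-Cox +
#' partial-least-squares (PLS) reduction of the statistics fitted on
#' simulated training data, rejection sampling in PLS space with
#' Epanechnikov weights, Beaumont-style weighted local-linear regression
#' adjustment of the retained parameter draws, and acceptance-ratio Bayes
#' factors under a common distance threshold.
NULL

# Weir & Cockerham theta for one pair of sample index sets, multilocus
# ratio of sums over loci and alleles; NA-aware
.wc_theta_pair <- function(g, idx1, idx2) {
  num <- 0; den <- 0
  for (l in seq_len(n_loci(g))) {
    x1 <- cbind(g$a1[idx1, l], g$a2[idx1, l]); x1 <- x1[!is.na(x1[, 1]), , drop = FALSE]
    x2 <- cbind(g$a1[idx2, l], g$a2[idx2, l]); x2 <- x2[!is.na(x2[, 1]), , drop = FALSE]
    n1 <- nrow(x1); n2 <- nrow(x2)
    if (n1 < 1 || n2 < 1) next
    alleles <- unique(c(x1, x2))
    if (length(alleles) < 2) next
    r <- 2
    nbar <- (n1 + n2) / r
    if (nbar <= 1) next
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    if (nc <= 0) next
    for (A in alleles) {
      k1 <- (x1[, 1] == A) + (x1[, 2] == A)
      k2 <- (x2[, 1] == A) + (x2[, 2] == A)
      p1 <- sum(k1) / (2 * n1); p2 <- sum(k2) / (2 * n2)
      pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
      s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
      hbar <- (sum(k1 == 1) + sum(k2 == 1)) / (r * nbar)
      a <- nbar / nc *
        (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
      b <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  if (den == 0) return(0)
  num / den
}

#' The 11-statistic ABC summary vector
#'
#' Computed on a diploid genotype matrix partitioned into exactly three
#' demes: mean number of distinct alleles per locus for each deme (3),
#' unbiased expected heterozygosity per deme (3, gene-level Nei estimator
#' `ng/(ng-1) * (1 - sum p^2)` averaged over loci), pairwise
#' Weir-Cockerham theta for the three deme pairs (3, multilocus
#' ratio-of-sums), mean pooled allele-size variance over loci (1), and
#' total distinct alleles pooled over demes and loci (1).
#'
#' @param g a [genotype_matrix()].
#' @param deme integer vector in 1..3 (or factor with 3 levels) assigning
#'   each individual to a deme; every deme needs at least 2 individuals.
#' @return named numeric vector of length 11 (`S1..S11`).
#' @export
summarize_stats <- function(g, deme) {
  deme <- as.integer(factor(deme))
  if (length(unique(deme)) != 3) stop("exactly 3 demes required")
  if (any(table(deme) < 2)) stop("every deme needs >= 2 individuals")
  L <- n_loci(g)
  ka <- he <- numeric(3)
  sizevar <- 0; tot_alleles <- 0
  for (l in seq_len(L)) {
    al_all <- c(g$a1[, l], g$a2[, l]); al_all <- al_all[!is.na(al_all)]
    tot_alleles <- tot_alleles + length(unique(al_all))
    if (length(al_all) > 1) sizevar <- sizevar + stats::var(al_all)
    for (d in 1:3) {
      idx <- which(deme == d)
      al <- c(g$a1[idx, l], g$a2[idx, l]); al <- al[!is.na(al)]
      ng <- length(al)
      ka[d] <- ka[d] + length(unique(al))
      if (ng > 1) {
        p <- as.numeric(table(al)) / ng
        he[d] <- he[d] + ng / (ng - 1) * (1 - sum(p^2))
      }
    }
  }
  fst <- c(.wc_theta_pair(g, which(deme == 1), which(deme == 2)),
           .wc_theta_pair(g, which(deme == 1), which(deme == 3)),
           .wc_theta_pair(g, which(deme == 2), which(deme == 3)))
  stats::setNames(c(ka / L, he / L, fst, sizevar / L, tot_alleles),
                  paste0("S", 1:11))
}

# ---- Box-Cox + PLS ---------------------------------------------------------

.bc_transform <- function(x, lambda) {
  if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
}

.bc_mle <- function(x) {
  n <- length(x)
  ll <- function(lam) {
    y <- .bc_transform(x, lam)
    v <- stats::var(y)
    if (!is.finite(v) || v <= 0) return(-Inf)
    -n / 2 * log(v) + (lam - 1) * sum(log(x))
  }
  stats::optimize(ll, c(-2, 2), maximum = TRUE)$maximum
}

#' Fit a Box-Cox + PLS reduction of the summary statistics
#'
#' Each statistic is shifted to strict positivity, Box-Cox transformed with
#' its maximum-likelihood exponent, standardized, and the matrix is reduced
#' by a PLS2 (NIPALS) regression of the model parameters on the statistics.
#' Constant statistic columns are dropped with a warning. The stored
#' transform maps any new statistic vector into the component space.
#'
#' @param stats matrix or data.frame of training statistics (rows =
#'   simulations).
#' @param params matrix or data.frame of the corresponding parameter draws
#'   (the PLS responses).
#' @param n_components number of PLS components (default 6).
#' @param boxcox apply the per-statistic Box-Cox step (default `TRUE`); turn
#'   off to reduce on the raw standardized scale, e.g. when the statistics
#'   are already near-Gaussian or exact linearity must be preserved.
#' @return object of class `pls_transform`.
#' @export
fit_pls <- function(stats, params, n_components = 6L, boxcox = TRUE) {
  X <- as.matrix(stats); Y <- as.matrix(params)
  if (nrow(X) < 10 * n_components)
    stop("need at least 10 x n_components training rows")
  keep <- which(apply(X, 2, stats::sd) > 1e-12)
  if (length(keep) < ncol(X))
    warning("dropping constant statistic column(s): ",
            paste(colnames(X)[-keep], collapse = ", "))
  X <- X[, keep, drop = FALSE]
  n_components <- min(n_components, ncol(X))
  shift <- apply(X, 2, function(x) if (min(x) <= 0) 1 - min(x) else 0)
  Xs <- sweep(X, 2, -shift)  # x + shift
  lambda <- if (boxcox) apply(Xs, 2, .bc_mle) else rep(1, ncol(Xs))
  Xb <- sapply(seq_len(ncol(Xs)), function(j) .bc_transform(Xs[, j], lambda[j]))
  center <- colMeans(Xb); scale <- apply(Xb, 2, stats::sd)
  X0 <- sweep(sweep(Xb, 2, center), 2, scale, "/")
  Yc <- sweep(Y, 2, colMeans(Y))
  ys <- apply(Yc, 2, stats::sd); ys[ys == 0] <- 1
  Y0 <- sweep(Yc, 2, ys, "/")
  p <- ncol(X0)
  W <- P <- matrix(0, p, n_components)
  Xd <- X0; Yd <- Y0
  for (h in seq_len(n_components)) {
    u <- Yd[, which.max(apply(Yd, 2, stats::var))]
    t_old <- rep(0, nrow(Xd))
    for (it in 1:500) {
      w <- crossprod(Xd, u); w <- w / sqrt(sum(w^2))
      tt <- Xd %*% w
      cvec <- crossprod(Yd, tt); cvec <- cvec / sqrt(sum(cvec^2))
      u <- Yd %*% cvec
      if (sum((tt - t_old)^2) < 1e-12 * sum(tt^2)) break
      t_old <- tt
    }
    pvec <- crossprod(Xd, tt) / sum(tt^2)
    Xd <- Xd - tt %*% t(pvec)
    Yd <- Yd - tt %*% t(crossprod(Yd, tt) / sum(tt^2))
    W[, h] <- w; P[, h] <- pvec
  }
  R <- W %*% solve(crossprod(P, W))
  structure(list(keep = keep, shift = shift, lambda = lambda,
                 center = center, scale = scale, W = W, P = P, rotation = R,
                 n_components = n_components,
                 stat_names = colnames(stats)[keep]),
            class = "pls_transform")
}

#' Project statistics into fitted PLS component space
#'
#' @param transform a fitted `pls_transform` from [fit_pls()].
#' @param stats a statistic vector, matrix or data.frame (columns as in
#'   training).
#' @return score matrix (rows x components).
#' @export
pls_scores <- function(transform, stats) {
  X <- if (is.null(dim(stats))) matrix(stats, nrow = 1,
                                       dimnames = list(NULL, names(stats)))
       else as.matrix(stats)
  X <- X[, transform$keep, drop = FALSE]
  Xs <- sweep(X, 2, -transform$shift)
  if (any(Xs <= 0))
    Xs[Xs <= 0] <- 1e-12  # outside the training range; clamp into domain
  Xb <- sapply(seq_len(ncol(Xs)),
               function(j) .bc_transform(Xs[, j], transform$lambda[j]))
  if (is.null(dim(Xb))) Xb <- matrix(Xb, nrow = 1)
  X0 <- sweep(sweep(Xb, 2, transform$center), 2, transform$scale, "/")
  X0 %*% transform$rotation
}

#' Standardization-only statistic transform
#'
#' Returns an object with the same interface as [fit_pls()] whose component
#' space is simply the z-scored statistics (identity rotation, no Box-Cox).
#' This is the recommended distance space for *model choice*: PLS components
#' targeted at the model parameters can be blind to between-model
#' information (for example, which pairwise FST is the small one), because
#' that signal predicts no parameter. Parameter estimation within a model
#' keeps the PLS space.
#'
#' @param stats training statistic matrix or data.frame.
#' @return a `pls_transform` whose scores are standardized statistics.
#' @export
fit_stat_scaler <- function(stats) {
  X <- as.matrix(stats)
  keep <- which(apply(X, 2, stats::sd) > 1e-12)
  X <- X[, keep, drop = FALSE]
  p <- ncol(X)
  structure(list(keep = keep, shift = rep(1, p), lambda = rep(1, p),
                 center = colMeans(X), scale = apply(X, 2, stats::sd),
                 W = diag(p), P = diag(p), rotation = diag(p),
                 n_components = p, stat_names = colnames(stats)[keep]),
            class = "pls_transform")
}

# ---- rejection, adjustment, model choice ----------------------------------

.stat_cols <- function(tab) grep("^S[0-9]+$", names(tab), value = TRUE)

#' ABC rejection step
#'
#' Euclidean distances between the observed and simulated statistics in PLS
#' component space; retains the `tolerance_frac` closest simulations with
#' Epanechnikov weights `1 - (d/d_max)^2`.
#'
#' @param observed named statistic vector (`S1..S11`) for the observed data.
#' @param sims simulation table from [simulate_table()].
#' @param transform a `pls_transform`.
#' @param tolerance_frac fraction of simulations to retain, in (0, 1].
#' @return list with `retained` (rows of `sims`), `distances` (retained),
#'   `weights`, `threshold` and `scores_obs`.
#' @export
abc_reject <- function(observed, sims, transform, tolerance_frac = 0.01) {
  if (!nrow(sims)) stop("empty simulation table")
  if (tolerance_frac <= 0 || tolerance_frac > 1)
    stop("tolerance_frac must be in (0, 1]")
  sc <- pls_scores(transform, sims[, .stat_cols(sims), drop = FALSE])
  so <- pls_scores(transform, observed)
  d <- sqrt(rowSums(sweep(sc, 2, so)^2))
  k <- max(1L, ceiling(tolerance_frac * nrow(sims)))
  ord <- order(d)[seq_len(k)]
  dmax <- d[ord[k]]
  w <- if (dmax > 0) 1 - (d[ord] / dmax)^2 else rep(1, k)
  w[w <= 0] <- min(w[w > 0], 1e-8)  # keep the boundary row with tiny weight
  list(retained = sims[ord, , drop = FALSE], distances = d[ord],
       weights = w, threshold = dmax, scores_obs = so,
       scores_retained = sc[ord, , drop = FALSE])
}

# parameter transforms for bounded supports
.par_fwd <- function(x, b) {
  if (is.null(b)) x
  else if (all(is.finite(b))) stats::qlogis(pmin(pmax((x - b[1]) / (b[2] - b[1]),
                                                      1e-9), 1 - 1e-9))
  else log(pmax(x - b[1], 1e-300))
}
.par_bwd <- function(y, b) {
  if (is.null(b)) y
  else if (all(is.finite(b))) b[1] + (b[2] - b[1]) * stats::plogis(y)
  else b[1] + exp(y)
}

#' Default support bounds for the demographic parameters
#'
#' Positive parameters are adjusted on a log scale, the admixture
#' proportion on a logit scale.
#' @return named list of length-2 bounds (`Inf` upper = log scale).
#' @export
default_param_bounds <- function() {
  list(ne1 = c(0, Inf), ne2 = c(0, Inf), ne3 = c(0, Inf), ne_anc = c(0, Inf),
       t1 = c(0, Inf), t2 = c(0, Inf), alpha = c(0, 1), mu_mean = c(0, Inf))
}

#' Local-linear regression adjustment of retained draws
#'
#' Beaumont-style correction: each (transformed) parameter is regressed on
#' the PLS statistics over the retained simulations with the Epanechnikov
#' weights, and each draw is replaced by the regression's fitted value at
#' the observed statistics plus its own residual; bounded parameters are
#' adjusted on a log or logit scale and back-transformed. A singular or
#' underdetermined design falls back to the unadjusted rejection posterior
#' with a warning.
#'
#' @param rej output of [abc_reject()].
#' @param param_cols parameter column names to adjust.
#' @param bounds named list of support bounds, see
#'   [default_param_bounds()]; `NULL` entries mean no transform.
#' @return data.frame of adjusted posterior draws.
#' @export
regression_adjust <- function(rej, param_cols = c("ne1", "ne2", "ne3",
                                                  "ne_anc", "t1", "t2",
                                                  "mu_mean"),
                              bounds = default_param_bounds()) {
  S <- sweep(rej$scores_retained, 2, as.numeric(rej$scores_obs))
  n <- nrow(S)
  out <- rej$retained[, param_cols, drop = FALSE]
  if (n < ncol(S) + 2) {
    warning("too few retained rows for regression adjustment; ",
            "returning unadjusted rejection posterior")
    return(out)
  }
  X <- cbind(1, S)
  for (pc in param_cols) {
    b <- bounds[[pc]]
    y <- .par_fwd(rej$retained[[pc]], b)
    fit <- tryCatch(stats::lm.wfit(X, y, rej$weights), error = function(e) NULL)
    if (is.null(fit) || any(is.na(fit$coefficients))) {
      warning("singular design; parameter ", pc, " left unadjusted")
      next
    }
    adj <- fit$coefficients[1] + fit$residuals
    out[[pc]] <- .par_bwd(adj, b)
  }
  rownames(out) <- NULL
  out
}

#' Acceptance-ratio Bayes factors under a common threshold
#'
#' The absolute distance threshold is the `tolerance_frac` quantile of the
#' pooled distances across models; each model's marginal support is its
#' acceptance fraction under that threshold, and
#' `BF_m = accept_m / accept_reference`.
#'
#' @param observed named statistic vector.
#' @param sims_by_model named list of simulation tables, one per model.
#' @param transform a `pls_transform`.
#' @param tolerance_frac pooled acceptance fraction.
#' @param reference_model name of the reference model (its BF is 1).
#' @return data.frame with `model`, `accepted`, `total`, `accept_rate`,
#'   `bayes_factor`.
#' @export
bayes_factors <- function(observed, sims_by_model, transform,
                          tolerance_frac = 0.01, reference_model = "B") {
  so <- pls_scores(transform, observed)
  dists <- lapply(sims_by_model, function(tab) {
    sc <- pls_scores(transform, tab[, .stat_cols(tab), drop = FALSE])
    sqrt(rowSums(sweep(sc, 2, as.numeric(so))^2))
  })
  thr <- stats::quantile(unlist(dists), tolerance_frac, names = FALSE)
  acc <- vapply(dists, function(d) sum(d <= thr), numeric(1))
  tot <- vapply(dists, length, numeric(1))
  rate <- acc / tot
  if (rate[[reference_model]] == 0)
    stop("reference model has zero acceptances; increase tolerance_frac")
  data.frame(model = names(sims_by_model), accepted = acc, total = tot,
             accept_rate = rate,
             bayes_factor = rate / rate[[reference_model]],
             row.names = NULL, stringsAsFactors = FALSE)
}

# shortest interval containing prob mass of the draws
.hpdi <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(c(x[1], x[n]))
  starts <- seq_len(n - k)
  widths <- x[starts + k] - x[starts]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

#' Summarize a posterior sample
#'
#' Point estimate = mode of a Gaussian kernel density (Silverman's
#' bandwidth); interval = highest-posterior-density interval (shortest
#' interval containing the requested mass). Refuses fewer than 100 draws.
#'
#' @param draws numeric vector of posterior draws.
#' @param prob interval mass (default 0.95).
#' @param generation_time if not `NULL`, also report `mode_years` and
#'   `hpdi_years` via [divergence_time_years()].
#' @return list with `mode`, `hpdi`, `n` (and years fields when requested).
#' @export
posterior_summary <- function(draws, prob = 0.95, generation_time = NULL) {
  draws <- draws[is.finite(draws)]
  if (length(draws) < 100) stop("refusing to summarize fewer than 100 draws")
  if (stats::sd(draws) == 0) {
    mode <- draws[1]
    hp <- c(draws[1], draws[1])
  } else {
    den <- stats::density(draws, bw = "nrd0")
    mode <- den$x[which.max(den$y)]
    hp <- .hpdi(draws, prob)
  }
  out <- list(mode = mode, hpdi = hp, n = length(draws))
  if (!is.null(generation_time)) {
    out$mode_years <- divergence_time_years(max(mode, 0), generation_time)
    out$hpdi_years <- divergence_time_years(pmax(hp, 0), generation_time)
  }
  out
}
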