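#' Maximum-likelihood admixture clustering by EM
#'
#' Fits the admixture model likelihood
#' `sum_i sum_l sum_copies log( sum_k q_ik * p_kl(allele) )` by
#' expectation-maximization from random Dirichlet starts, the
#' maximum-likelihood counterpart of the Bayesian admixture clustering of
#' STRUCTURE. Replicate starts play the role of MCMC permutations: the
#' per-replicate converged log-likelihoods feed [evanno_delta_k()].
#'
#' @param g a [genotype_matrix()]; missing calls are skipped.
#' @param K number of clusters (>= 1).
#' @param n_starts number of random restarts (default 20).
#' @param max_iter maximum EM iterations per start.
#' @param tol stop when the log-likelihood gain drops below `tol`.
#' @return list (class `admixture_result`) with `Q` (N x K ancestry
#'   proportions of the best start), `P` (per-locus cluster allele
#'   frequencies), `loglik`, `loglik_replicates` (one converged value per
#'   start), `K`, `n_iter`.
#' @export
admixture_em <- function(g, K, n_starts = 20L, max_iter = 500L, tol = 1e-4) {
  if (K < 1) stop("K must be >= 1")
  L <- n_loci(g); N <- n_samples(g)
  rec <- .recode_alleles(list(g))
  x1 <- rec$mats[[1]]$a1 + 1L; x2 <- rec$mats[[1]]$a2 + 1L  # 0 = missing
  x1[x1 == 0L] <- NA_integer_; x2[x2 == 0L] <- NA_integer_
  nA <- rec$n_alleles
  n_copies <- rowSums(!is.na(x1)) * 2
  best <- NULL
  ll_reps <- numeric(n_starts)
  for (s in seq_len(n_starts)) {
    Q <- matrix(stats::rgamma(N * K, 1), N, K)
    Q <- Q / rowSums(Q)
    P <- lapply(seq_len(L), function(l) {
      m <- matrix(stats::rgamma(K * nA[l], 1), K, nA[l])
      m / rowSums(m)
    })
    ll_old <- -Inf; ll <- -Inf; it <- 0
    repeat {
      it <- it + 1
      Qnum <- matrix(0, N, K)
      Pnum <- lapply(seq_len(L), function(l) matrix(0, K, nA[l]))
      ll <- 0
      for (l in seq_len(L)) {
        Pl <- P[[l]]
        for (copy in list(x1[, l], x2[, l])) {
          ok <- which(!is.na(copy))
          if (!length(ok)) next
          num <- Q[ok, , drop = FALSE] * t(Pl)[copy[ok], , drop = FALSE]
          den <- rowSums(num)
          ll <- ll + sum(log(pmax(den, 1e-300)))
          r <- num / den
          Qnum[ok, ] <- Qnum[ok, ] + r
          agg <- rowsum(r, group = copy[ok])
          cols <- as.integer(rownames(agg))
          Pnum[[l]][, cols] <- Pnum[[l]][, cols] + t(agg)
        }
      }
      if (!is.finite(ll)) stop("non-finite admixture log-likelihood")
      if (ll < ll_old - 1e-8 * (abs(ll_old) + 1))
        stop("EM log-likelihood decreased; numerical failure")
      gain <- ll - ll_old
      ll_old <- ll
      # M-step
      Q <- Qnum / n_copies
      Q[n_copies == 0, ] <- 1 / K
      for (l in seq_len(L)) {
        rs <- rowSums(Pnum[[l]])
        P[[l]] <- (Pnum[[l]] + 1e-12) / (rs + nA[l] * 1e-12)
      }
      if (gain < tol || it >= max_iter) break
    }
    ll_reps[s] <- ll
    if (is.null(best) || ll > best$loglik)
      best <- list(Q = Q, P = P, loglik = ll, n_iter = it)
  }
  rownames(best$Q) <- g$samples
  structure(list(Q = best$Q, P = best$P, loglik = best$loglik,
                 loglik_replicates = ll_reps, K = K, n_iter = best$n_iter),
            class = "admixture_result")
}

#' @export
print.admixture_result <- function(x, ...) {
  cat(sprintf("admixture_result: K = %d, logLik = %.2f (%d starts)\n",
              x$K, x$loglik, length(x$loglik_replicates)))
  invisible(x)
}

#' Run admixture EM over a range of K
#'
#' @inheritParams admixture_em
#' @param k_range integer vector of K values (default 1:5).
#' @return list with `fits` (best fit per K) and `loglik` (matrix, starts x
#'   K) ready for [evanno_delta_k()].
#' @export
admixture_scan <- function(g, k_range = 1:5, n_starts = 10L,
                           max_iter = 500L, tol = 1e-4) {
  fits <- lapply(k_range, function(K)
    admixture_em(g, K, n_starts = n_starts, max_iter = max_iter, tol = tol))
  ll <- vapply(fits, function(f) f$loglik_replicates, numeric(n_starts))
  colnames(ll) <- paste0("K", k_range)
  list(fits = stats::setNames(fits, paste0("K", k_range)),
       loglik = ll, k_range = k_range)
}

#' Evanno delta-K table
#'
#' For interior K, `deltaK(K) = mean(|L(K+1) - 2 L(K) + L(K-1)|) / sd(L(K))`
#' with the mean of the absolute second difference taken over replicate
#' runs and the standard deviation over the replicates at K. Undefined at
#' the boundary K values; a zero replicate SD yields `Inf` with a warning.
#'
#' @param loglik matrix of converged log-likelihoods, replicates x K
#'   (columns in increasing K order, >= 3 columns, >= 2 replicates).
#' @param k_values the K value of each column (default parsed from column
#'   names `K2` etc., else `1:ncol`).
#' @return data.frame with `K`, `mean_loglik`, `sd_loglik`, `abs_l2`,
#'   `delta_k` (NA at the boundaries).
#' @export
evanno_delta_k <- function(loglik, k_values = NULL) {
  loglik <- as.matrix(loglik)
  if (ncol(loglik) < 3) stop("need >= 3 consecutive K values")
  if (nrow(loglik) < 2) stop("need >= 2 replicates per K")
  if (is.null(k_values)) {
    k_values <- suppressWarnings(as.integer(sub("^K", "", colnames(loglik))))
    if (!length(k_values) || anyNA(k_values)) k_values <- seq_len(ncol(loglik))
  }
  mean_l <- colMeans(loglik)
  sd_l <- apply(loglik, 2, stats::sd)
  n <- ncol(loglik)
  abs_l2 <- delta <- rep(NA_real_, n)
  for (j in 2:(n - 1)) {
    abs_l2[j] <- mean(abs(loglik[, j + 1] - 2 * loglik[, j] + loglik[, j - 1]))
    if (sd_l[j] == 0) {
      warning("zero replicate SD at K = ", k_values[j],
              "; delta K reported as Inf")
      delta[j] <- Inf
    } else delta[j] <- abs_l2[j] / sd_l[j]
  }
  data.frame(K = k_values, mean_loglik = mean_l, sd_loglik = sd_l,
             abs_l2 = abs_l2, delta_k = delta, row.names = NULL)
}

#' Pure/mosaic labels from ancestry proportions
#'
#' An individual is "pure" for cluster k when `q_ik >= purity_threshold`,
#' otherwise mosaic (admixed).
#'
#' @param Q ancestry-proportion matrix (individuals x clusters).
#' @param purity_threshold minimum ancestry for a pure call (default 0.9).
#' @return data.frame with `sample_id`, `label` (`"pure"`/`"mosaic"`),
#'   `cluster` (NA for mosaics), `max_q`.
#' @export
mosaic_from_q <- function(Q, purity_threshold = 0.9) {
  Q <- as.matrix(Q)
  mx <- apply(Q, 1, max)
  k <- max.col(Q, ties.method = "first")
  pure <- mx >= purity_threshold
  data.frame(sample_id = rownames(Q) %||% as.character(seq_len(nrow(Q))),
             label = ifelse(pure, "pure", "mosaic"),
             cluster = ifelse(pure, k, NA_integer_), max_q = mx,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Greedily align cluster labels to a reference Q matrix
#'
#' Resolves label switching between replicate runs: clusters are matched to
#' the reference one at a time by the largest remaining column correlation.
#'
#' @param Q matrix to relabel.
#' @param reference reference Q matrix with the same dimensions.
#' @return `Q` with its columns permuted to match `reference`.
#' @export
align_clusters <- function(Q, reference) {
  K <- ncol(Q)
  co <- suppressWarnings(stats::cor(reference, Q))
  co[!is.finite(co)] <- -1
  perm <- integer(K)
  for (step in seq_len(K)) {
    i <- which(co == max(co), arr.ind = TRUE)[1, ]
    perm[i[1]] <- i[2]
    co[i[1], ] <- -Inf; co[, i[2]] <- -Inf
  }
  Q[, perm, drop = FALSE]
}
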