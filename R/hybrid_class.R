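#' Genealogical hybrid classes
#'
#' The six classes distinguishable from unlinked co-dominant loci two
#' generations after admixture, each defined by its expected proportions of
#' locus genotypes drawing (both alleles from the P1 pool, one from each,
#' both from P2): P1 (1,0,0), P2 (0,0,1), F1 (0,1,0), F2 (1/4,1/2,1/4),
#' BC1 (1/2,1/2,0), BC2 (0,1/2,1/2).
#'
#' @return a 6 x 3 numeric matrix with rownames `P1, P2, F1, F2, BC1, BC2`.
#' @export
genealogical_classes <- function() {
  m <- rbind(P1 = c(1, 0, 0), P2 = c(0, 0, 1), F1 = c(0, 1, 0),
             F2 = c(0.25, 0.5, 0.25), BC1 = c(0.5, 0.5, 0),
             BC2 = c(0, 0.5, 0.5))
  colnames(m) <- c("bothP1", "oneEach", "bothP2")
  m
}

# smooth a parental frequency vector over a target allele set with a
# Dirichlet-style pseudo-count so no observable genotype has probability 0
.smooth_freq <- function(freq, alleles, pseudo = 1e-6) {
  p <- stats::setNames(rep(pseudo, length(alleles)), alleles)
  p[names(freq)] <- p[names(freq)] + freq
  p / sum(p)
}

#' Likelihood of one locus genotype under a genealogical class
#'
#' `Pr(genotype | class) = sum_c phi_c * Pr(genotype | category c)` where
#' the categories draw both alleles from P1, one from each pool, or both
#' from P2, with heterozygote terms doubled. Alleles absent from both
#' parental pools receive a pseudo-count, never probability zero.
#'
#' @param genotype length-2 vector of allele states at one locus.
#' @param class class name, see [genealogical_classes()].
#' @param p1_freqs,p2_freqs named allele-frequency vectors of the parental
#'   pools at this locus.
#' @param pseudo pseudo-count mass per allele state.
#' @return the genotype probability.
#' @export
class_likelihood <- function(genotype, class, p1_freqs, p2_freqs,
                             pseudo = 1e-6) {
  phi <- genealogical_classes()
  if (!class %in% rownames(phi)) stop("unknown class: ", class)
  alleles <- unique(c(names(p1_freqs), names(p2_freqs), as.character(genotype)))
  p1 <- .smooth_freq(p1_freqs, alleles, pseudo)
  p2 <- .smooth_freq(p2_freqs, alleles, pseudo)
  a <- as.character(genotype[1]); b <- as.character(genotype[2])
  cat_p <- if (a == b)
    c(p1[a]^2, p1[a] * p2[a], p2[a]^2)
  else
    c(2 * p1[a] * p1[b], p1[a] * p2[b] + p1[b] * p2[a], 2 * p2[a] * p2[b])
  unname(sum(phi[class, ] * cat_p))
}

# recode allele sizes to 0-based dense indices per locus over a set of
# genotype matrices; returns list(mats = recoded list, n_alleles)
.recode_alleles <- function(gs) {
  L <- n_loci(gs[[1]])
  n_alleles <- integer(L)
  maps <- vector("list", L)
  for (l in seq_len(L)) {
    al <- sort(unique(unlist(lapply(gs, function(g)
      c(g$a1[, l], g$a2[, l])))))
    al <- al[!is.na(al)]
    maps[[l]] <- al
    n_alleles[l] <- length(al)
  }
  rec <- lapply(gs, function(g) {
    a1 <- g$a1; a2 <- g$a2
    for (l in seq_len(L)) {
      a1[, l] <- match(g$a1[, l], maps[[l]]) - 1L
      a2[, l] <- match(g$a2[, l], maps[[l]]) - 1L
    }
    a1[is.na(a1)] <- -1L; a2[is.na(a2)] <- -1L
    list(a1 = a1, a2 = a2)
  })
  list(mats = rec, n_alleles = n_alleles)
}

#' Bayesian genealogical-class assignment by Gibbs sampling
#'
#' NewHybrids-style sampler: alternates (i) the class of every candidate
#' given the current parental allele frequencies (uniform prior over the
#' six classes), (ii) the latent gene-pool origin of each candidate allele,
#' and (iii) the parental frequencies from Dirichlet(1 + assigned counts),
#' with reference individuals contributing their alleles to their own pool
#' in every sweep. The posterior for each candidate is its post-burn-in
#' class visit frequency.
#'
#' @param g a [genotype_matrix()] holding candidates and references.
#' @param candidates sample IDs (or indices) to classify.
#' @param reference_p1,reference_p2 sample IDs (or indices) of known
#'   parental individuals; optional but strongly recommended.
#' @param sweeps total Gibbs sweeps (default 10000).
#' @param burnin discarded initial sweeps (default 1000).
#' @return data.frame (class `hybrid_posterior`) with `sample_id`, one
#'   posterior column per class, `map_class` and `map_prob`.
#' @export
gibbs_newhybrids <- function(g, candidates, reference_p1 = NULL,
                             reference_p2 = NULL, sweeps = 10000L,
                             burnin = 1000L) {
  if (sweeps <= burnin) stop("sweeps must exceed burnin")
  as_idx <- function(x) if (is.character(x)) match(x, g$samples) else x
  ci <- as_idx(candidates)
  if (!length(ci)) stop("need at least one candidate")
  r1 <- as_idx(reference_p1); r2 <- as_idx(reference_p2)
  sub <- function(idx) if (length(idx)) g[idx] else g[integer(0)]
  rec <- .recode_alleles(list(sub(ci), sub(r1), sub(r2)))
  phi <- genealogical_classes()
  res <- gibbs_newhybrids_cpp(rec$mats[[1]]$a1, rec$mats[[1]]$a2,
                              rec$mats[[2]]$a1, rec$mats[[2]]$a2,
                              rec$mats[[3]]$a1, rec$mats[[3]]$a2,
                              rec$n_alleles, unname(phi),
                              as.integer(sweeps), as.integer(burnin))
  post <- res$posterior
  colnames(post) <- rownames(phi)
  map <- rownames(phi)[max.col(post, ties.method = "first")]
  out <- data.frame(sample_id = g$samples[ci], post,
                    map_class = map,
                    map_prob = post[cbind(seq_len(nrow(post)),
                                          match(map, colnames(post)))],
                    stringsAsFactors = FALSE)
  class(out) <- c("hybrid_posterior", "data.frame")
  out
}

#' Label candidates from their class posteriors
#'
#' The maximum-a-posteriori class when its posterior reaches `threshold`,
#' otherwise `"complex"` (no single two-parent genealogical class explains
#' the genotype well enough).
#'
#' @param posteriors a `hybrid_posterior` from [gibbs_newhybrids()].
#' @param threshold minimum posterior for a definite call (default 0.5).
#' @return data.frame with `sample_id`, `class`, `posterior`, `complex`.
#' @export
classify_mosaics <- function(posteriors, threshold = 0.5) {
  cls <- ifelse(posteriors$map_prob >= threshold, posteriors$map_class,
                "complex")
  data.frame(sample_id = posteriors$sample_id, class = cls,
             posterior = posteriors$map_prob,
             complex = cls == "complex", stringsAsFactors = FALSE)
}
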