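# small builders shared across test files; everything is generated in code

# genotype matrix from a list of per-individual calls:
# calls[[i]] = 2 x L matrix (allele rows)
gm_from_calls <- function(..., loci = NULL) {
  inds <- list(...)
  a1 <- do.call(rbind, lapply(inds, function(x) x[1, ]))
  a2 <- do.call(rbind, lapply(inds, function(x) x[2, ]))
  genotype_matrix(a1, a2, loci = loci)
}

# n copies of the same diploid genotype (one locus per column)
gm_uniform <- function(n, a1_row, a2_row) {
  genotype_matrix(matrix(rep(a1_row, each = n), n),
                  matrix(rep(a2_row, each = n), n))
}

# two-pool roster with known hybrid classes; returns genotypes, truth labels
# and the reference index ranges
make_roster <- function(divergence, n_ref = 30, n_hyb = 40, n_loci = 23,
                        n_alleles = 8, seed = 1) {
  set.seed(seed)
  fr <- generate_lineage_frequencies(n_loci = n_loci,
                                     lineages = c("poolA", "poolB"),
                                     n_alleles = n_alleles,
                                     divergence = divergence)
  parts <- list(P1 = sample_individuals(fr$poolA, n_ref, "p1"),
                P2 = sample_individuals(fr$poolB, n_ref, "p2"),
                F1 = make_hybrid("F1", fr$poolA, fr$poolB, n_hyb),
                F2 = make_hybrid("F2", fr$poolA, fr$poolB, n_hyb),
                BC1 = make_hybrid("BC1", fr$poolA, fr$poolB, n_hyb),
                BC2 = make_hybrid("BC2", fr$poolA, fr$poolB, n_hyb))
  g <- do.call(rbind_genotypes, parts)
  truth <- rep(names(parts), vapply(parts, n_samples, integer(1)))
  list(g = g, truth = truth, freqs = fr,
       ref1 = seq_len(n_ref), ref2 = n_ref + seq_len(n_ref),
       cand = (2 * n_ref + 1):n_samples(g))
}

# random additive (ultrametric-free) tree and its exact leaf distance matrix
random_additive_tree <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.05, 1)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# alignment object from a character vector of strings
aln_from_strings <- function(x, ids = NULL) {
  m <- do.call(rbind, strsplit(x, ""))
  rownames(m) <- ids %||% paste0("s", seq_along(x))
  seq_alignment(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force rarefied richness: mean distinct alleles over all gene
# subsamples of size g (exhaustive enumeration)
brute_ar <- function(counts, g) {
  genes <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(genes), g)
  mean(apply(subs, 2, function(ix) length(unique(genes[ix]))))
}

# minimal total weight connecting a set of character vectors (MST over the
# complete graph, own Kruskal implementation)
mst_weight <- function(chars) {
  n <- nrow(chars)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- sum(chars[i, ] != chars[j, ])
  edges <- which(upper.tri(D), arr.ind = TRUE)
  ord <- order(D[upper.tri(D)])
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  w <- 0
  for (e in ord) {
    i <- edges[e, 1]; j <- edges[e, 2]
    ri <- find(i); rj <- find(j)
    if (ri != rj) { parent[ri] <- rj; w <- w + D[i, j] }
  }
  w
}
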