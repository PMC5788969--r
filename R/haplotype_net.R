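#' @name haplotype_net
#' @title cpDNA haplotype collapsing, K2P distances, NJ tree and
#'   median-joining network
#'
#' @description
#' Aligned chloroplast sequences are collapsed to haplotypes with each
#' contiguous indel treated as a single mutation event (simple indel
#' coding), pairwise distances use the Kimura two-parameter model with
#' pairwise deletion, trees are built by neighbor joining, and haplotype
#' relationships by a median-joining network under a maximum-parsimony
#' criterion.
NULL

# encode an alignment as mutation-event characters: one multistate
# character per variable substitution column (gap positions missing there)
# plus one binary presence/absence character per distinct contiguous gap run
.encode_characters <- function(aln) {
  seqs <- aln$seqs
  all_gap <- apply(seqs, 2, function(col) all(col == "-"))
  if (any(all_gap)) {
    warning("dropping ", sum(all_gap), " all-gap column(s)")
    seqs <- seqs[, !all_gap, drop = FALSE]
  }
  n <- nrow(seqs); len <- ncol(seqs)
  # gap runs per sequence
  runs <- list()
  run_of <- vector("list", n)
  for (i in seq_len(n)) {
    r <- rle(seqs[i, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gi <- which(r$values)
    run_of[[i]] <- cbind(starts[gi], ends[gi])
  }
  run_keys <- unique(do.call(rbind, run_of))
  if (is.null(run_keys)) run_keys <- matrix(integer(0), 0, 2)
  if (nrow(run_keys))
    run_keys <- run_keys[order(run_keys[, 1], run_keys[, 2]), , drop = FALSE]
  indel <- matrix("0", n, nrow(run_keys))
  for (i in seq_len(n)) {
    if (!nrow(run_of[[i]])) next
    hit <- match(paste(run_of[[i]][, 1], run_of[[i]][, 2]),
                 paste(run_keys[, 1], run_keys[, 2]))
    indel[i, hit] <- "1"
  }
  if (nrow(run_keys))
    colnames(indel) <- paste0("indel", run_keys[, 1], "_", run_keys[, 2])
  # substitution characters on variable columns, gaps/N missing
  base <- seqs
  base[base == "-" | base == "N"] <- NA_character_
  var_cols <- which(apply(base, 2, function(col)
    length(unique(col[!is.na(col)])) > 1))
  subst <- base[, var_cols, drop = FALSE]
  if (length(var_cols)) colnames(subst) <- paste0("site", var_cols)
  chars <- cbind(subst, indel)
  rownames(chars) <- rownames(seqs)
  chars
}

# pairwise character mismatch count, missing states excluded
.char_dist <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  sum(a[ok] != b[ok])
}

#' Collapse aligned sequences into haplotypes
#'
#' Sequences identical over all mutation-event characters (substitution
#' sites plus indel events, each contiguous gap run scored as one binary
#' character) share a haplotype. Sites where a sequence carries `N` are
#' excluded from its identity comparisons (a sequence joins the first
#' existing haplotype it matches at every comparable character). Haplotype
#' IDs `H1, H2, ...` follow order of first occurrence.
#'
#' @param aln a [seq_alignment()].
#' @return object of class `haplotype_set`: `ids`, `chars` (haplotype x
#'   character states), `freq`, `members` (list of sample IDs),
#'   `assignment` (named vector sample -> haplotype), `representative`
#'   (matrix of representative sequences).
#' @export
collapse_haplotypes <- function(aln) {
  chars <- .encode_characters(aln)
  n <- nrow(chars)
  hap_of <- integer(n)
  reps <- integer(0)  # representative row per haplotype
  for (i in seq_len(n)) {
    hit <- 0L
    for (h in seq_along(reps)) {
      if (.char_dist(chars[i, ], chars[reps[h], ]) == 0L) { hit <- h; break }
    }
    if (hit == 0L) { reps <- c(reps, i); hit <- length(reps) }
    hap_of[i] <- hit
  }
  ids <- paste0("H", seq_along(reps))
  members <- split(rownames(aln$seqs), factor(hap_of, levels = seq_along(reps)))
  names(members) <- ids
  hchars <- chars[reps, , drop = FALSE]
  rownames(hchars) <- ids
  structure(list(ids = ids, chars = hchars,
                 freq = stats::setNames(as.integer(lengths(members)), ids),
                 members = members,
                 assignment = stats::setNames(ids[hap_of], rownames(aln$seqs)),
                 representative = structure(aln$seqs[reps, , drop = FALSE],
                                            dimnames = list(ids, NULL))),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d haplotypes from %d samples\n",
              length(x$ids), sum(x$freq)))
  invisible(x)
}

#' Haplotype frequency table
#'
#' @param h a `haplotype_set`.
#' @return data.frame with `haplotype`, `frequency`, `members`.
#' @export
haplotype_table <- function(h) {
  data.frame(haplotype = h$ids, frequency = as.integer(h$freq),
             members = vapply(h$members, paste, "", collapse = ";"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' Pairwise deletion: sites where either sequence carries a gap or `N` are
#' excluded. With `P` the transition and `Q` the transversion proportion
#' over the retained sites, `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`.
#' Saturated pairs (a log argument <= 0) return `Inf` with a warning.
#'
#' @param seq_a,seq_b character vectors over `A,C,G,T,-,N` of equal length.
#' @return the K2P distance (substitutions per site).
#' @export
k2p_distance <- function(seq_a, seq_b) {
  if (length(seq_a) != length(seq_b)) stop("sequences must have equal length")
  ok <- seq_a %in% c("A", "C", "G", "T") & seq_b %in% c("A", "C", "G", "T")
  n <- sum(ok)
  if (n == 0) stop("no comparable sites after pairwise deletion")
  a <- seq_a[ok]; b <- seq_b[ok]
  diff <- a != b
  purine <- c("A", "G")
  transition <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    warning("K2P distance saturated; reporting Inf")
    return(Inf)
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' K2P distance matrix over sequences or haplotypes
#'
#' @param x a [seq_alignment()] (leaves = samples) or a `haplotype_set`
#'   (leaves = representative haplotype sequences).
#' @return symmetric numeric matrix with a zero diagonal.
#' @export
k2p_matrix <- function(x) {
  seqs <- if (inherits(x, "haplotype_set")) x$representative
          else if (inherits(x, "seq_alignment")) x$seqs
          else stop("x must be a seq_alignment or haplotype_set")
  n <- nrow(seqs)
  D <- matrix(0, n, n, dimnames = list(rownames(seqs), rownames(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- k2p_distance(seqs[i, ], seqs[j, ])
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via the standard implementation in
#' \pkg{ape}). Negative branch lengths, a known NJ artifact, are by
#' default clamped to zero with the magnitude transferred to the adjacent
#' branch at the same node so tip-to-tip path lengths are preserved.
#'
#' @param D symmetric distance matrix (>= 3 taxa, all entries finite).
#' @param clamp_negative clamp negative branch lengths (default `TRUE`).
#' @return an \pkg{ape} `phylo` tree (unrooted).
#' @export
nj_tree <- function(D, clamp_negative = TRUE) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("need at least 3 taxa")
  bad <- which(!is.finite(D) & upper.tri(D), arr.ind = TRUE)
  if (nrow(bad))
    stop("undefined distance(s): ",
         paste(apply(bad, 1, function(r)
           paste(rownames(D)[r[1]], colnames(D)[r[2]], sep = "-")),
           collapse = ", "))
  tr <- ape::nj(stats::as.dist(D))
  if (clamp_negative && any(tr$edge.length < 0)) {
    for (e in which(tr$edge.length < 0)) {
      parent <- tr$edge[e, 1]
      sib <- setdiff(which(tr$edge[, 1] == parent), e)
      if (length(sib)) {
        tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + tr$edge.length[e]
      }
      tr$edge.length[e] <- 0
    }
  }
  tr
}

# minimum spanning network: union of all minimum spanning trees, with an
# optional epsilon relaxation on the connection threshold
.msn_edges <- function(D, epsilon = 0) {
  n <- nrow(D)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  edges <- NULL
  iu <- which(upper.tri(D), arr.ind = TRUE)
  w <- D[upper.tri(D)]
  for (lev in sort(unique(w))) {
    at <- which(w <= lev + epsilon & w >= lev)
    # components as of before this level
    comp_before <- vapply(seq_len(n), find, integer(1))
    keep <- at[comp_before[iu[at, 1]] != comp_before[iu[at, 2]]]
    if (length(keep))
      edges <- rbind(edges, cbind(iu[keep, , drop = FALSE], w[keep]))
    for (e in keep) {
      ri <- find(iu[e, 1]); rj <- find(iu[e, 2])
      if (ri != rj) parent[ri] <- rj
    }
    if (length(unique(vapply(seq_len(n), find, integer(1)))) == 1 &&
        epsilon == 0)
      break
  }
  if (is.null(edges)) edges <- matrix(numeric(0), 0, 3)
  edges <- unique(edges)
  colnames(edges) <- c("from", "to", "weight")
  edges
}

#' Median-joining haplotype network
#'
#' Bandelt et al. (1999)-style construction on the mutation-event
#' characters: nodes are iteratively connected by the minimum spanning
#' network within tolerance `epsilon`; median (consensus) vectors of node
#' triples adjacent in the network are added when new; obsolete medians
#' (degree < 3 in the final network) are pruned. The final edge set keeps
#' only links present in at least one minimum spanning tree of the node
#' set (the maximum-parsimony simplification), so the network always
#' contains a minimum spanning tree. Edge weights are the recomputed
#' character differences.
#'
#' @param h a `haplotype_set` (from [collapse_haplotypes()]) or a character
#'   state matrix (rows = haplotypes).
#' @param epsilon minimum-spanning-network tolerance (default 0).
#' @param max_iter safety cap on median-addition rounds.
#' @return object of class `mj_network`: `nodes` (data.frame `id`, `type`,
#'   `freq`), `chars`, `edges` (data.frame `from`, `to`, `weight` with node
#'   IDs).
#' @export
median_joining <- function(h, epsilon = 0, max_iter = 25L) {
  chars <- if (inherits(h, "haplotype_set")) h$chars else as.matrix(h)
  if (nrow(chars) > 1e4) stop("more than 10^4 haplotypes; refusing")
  if (anyNA(chars))
    stop("median-joining requires complete character states")
  freq <- if (inherits(h, "haplotype_set")) h$freq
          else stats::setNames(rep(1L, nrow(chars)), rownames(chars))
  nodes <- chars
  n_obs <- nrow(chars)
  if (is.null(rownames(nodes))) rownames(nodes) <- paste0("H", seq_len(n_obs))
  node_key <- apply(nodes, 1, paste, collapse = "\r")
  dist_all <- function(m) {
    n <- nrow(m)
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      D[i, j] <- D[j, i] <- sum(m[i, ] != m[j, ])
    D
  }
  med_count <- 0L
  for (iter in seq_len(max_iter)) {
    D <- dist_all(nodes)
    ed <- .msn_edges(D, epsilon)
    adj <- vector("list", nrow(nodes))
    for (e in seq_len(nrow(ed))) {
      adj[[ed[e, 1]]] <- c(adj[[ed[e, 1]]], ed[e, 2])
      adj[[ed[e, 2]]] <- c(adj[[ed[e, 2]]], ed[e, 1])
    }
    new_meds <- NULL
    for (u in seq_len(nrow(nodes))) {
      nb <- adj[[u]]
      if (length(nb) < 2) next
      prs <- utils::combn(nb, 2)
      for (cidx in seq_len(ncol(prs))) {
        v <- prs[1, cidx]; wv <- prs[2, cidx]
        trip <- nodes[c(u, v, wv), , drop = FALSE]
        med <- apply(trip, 2, function(s) {
          tb <- table(s)
          if (max(tb) >= 2) names(tb)[which.max(tb)] else s[1]
        })
        key <- paste(med, collapse = "\r")
        if (!(key %in% node_key) &&
            !(key %in% vapply(new_meds %||% list(),
                              function(m) paste(m, collapse = "\r"), "")))
          new_meds <- c(new_meds, list(med))
      }
    }
    if (is.null(new_meds)) break
    for (m in new_meds) {
      med_count <- med_count + 1L
      nodes <- rbind(nodes, m)
      rownames(nodes)[nrow(nodes)] <- paste0("mv", med_count)
      node_key <- c(node_key, paste(m, collapse = "\r"))
    }
  }
  # prune medians of degree < 3 (repeat until stable)
  repeat {
    D <- dist_all(nodes)
    ed <- .msn_edges(D, epsilon)
    deg <- tabulate(c(ed[, 1], ed[, 2]), nbins = nrow(nodes))
    drop <- which(deg < 3 & seq_len(nrow(nodes)) > n_obs)
    if (!length(drop)) break
    nodes <- nodes[-drop, , drop = FALSE]
  }
  D <- dist_all(nodes)
  ed <- .msn_edges(D, epsilon)
  ids <- rownames(nodes)
  edges <- data.frame(from = ids[ed[, 1]], to = ids[ed[, 2]],
                      weight = as.integer(ed[, 3]),
                      stringsAsFactors = FALSE)
  nodes_df <- data.frame(
    id = ids,
    type = c(rep("observed", n_obs), rep("median", nrow(nodes) - n_obs)),
    freq = c(as.integer(freq), rep(0L, nrow(nodes) - n_obs)),
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes_df, chars = nodes, edges = edges),
            class = "mj_network")
}

#' @export
print.mj_network <- function(x, ...) {
  cat(sprintf("mj_network: %d observed + %d median nodes, %d edges (total length %d)\n",
              sum(x$nodes$type == "observed"), sum(x$nodes$type == "median"),
              nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

#' Write a median-joining network
#'
#' Edge list as TSV and the full network as GML.
#'
#' @param net an `mj_network`.
#' @param tsv_path,gml_path output paths (`NULL` to skip either).
#' @export
write_mj_network <- function(net, tsv_path = NULL, gml_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(net$edges, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(gml_path)) {
    con <- file(gml_path, "w"); on.exit(close(con))
    writeLines("graph [", con)
    idn <- stats::setNames(seq_len(nrow(net$nodes)) - 1L, net$nodes$id)
    for (i in seq_len(nrow(net$nodes)))
      writeLines(sprintf('  node [ id %d label "%s" type "%s" freq %d ]',
                         idn[i], net$nodes$id[i], net$nodes$type[i],
                         net$nodes$freq[i]), con)
    for (e in seq_len(nrow(net$edges)))
      writeLines(sprintf("  edge [ source %d target %d weight %d ]",
                         idn[[net$edges$from[e]]], idn[[net$edges$to[e]]],
                         net$edges$weight[e]), con)
    writeLines("]", con)
  }
  invisible(net)
}
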