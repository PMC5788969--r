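test_that("identical sequences collapse to one haplotype", {
  aln <- aln_from_strings(c("ACGTACGT", "ACGTACGT", "ACCTACGT"))
  hs <- collapse_haplotypes(aln)
  expect_equal(length(hs$ids), 2)
  expect_equal(unname(hs$freq["H1"]), 2)
  expect_identical(unname(hs$assignment),
                   c("H1", "H1", "H2"))
  expect_equal(sum(hs$freq), 3)
})

test_that("a contiguous gap run counts as a single mutation event", {
  aln <- aln_from_strings(c("ACGTACGTAC", "ACG---GTAC"))
  hs <- collapse_haplotypes(aln)
  expect_equal(length(hs$ids), 2)
  # exactly one character separates them (the indel), despite 3 gap sites
  expect_equal(sum(hs$chars[1, ] != hs$chars[2, ], na.rm = TRUE), 1)
  net <- median_joining(hs)
  expect_equal(net$edges$weight, 1L)
})

test_that("N sites are excluded from haplotype identity", {
  aln <- aln_from_strings(c("ACGTAC", "ACGTAN", "ACGTAG"))
  hs <- collapse_haplotypes(aln)
  # seq2 matches H1 at every comparable site -> joins it; seq3 differs
  expect_equal(length(hs$ids), 2)
  expect_equal(unname(hs$freq["H1"]), 2)
})

test_that("all-gap columns are dropped with a warning", {
  aln <- aln_from_strings(c("A-GT", "A-GT", "A-CT"))
  expect_warning(hs <- collapse_haplotypes(aln), "all-gap")
  expect_equal(length(hs$ids), 2)
})

test_that("K2P distance matches its closed form", {
  a <- rep("A", 100)
  expect_equal(k2p_distance(a, a), 0)
  # one transition in 100 sites: -1/2 log(1 - 0.02)
  b <- a; b[1] <- "G"
  expect_equal(k2p_distance(a, b), -0.5 * log(0.98), tolerance = 1e-12)
  # transversions only: P = 0 reduction, d = -1/2 log(1-Q) - 1/4 log(1-2Q)
  d <- a; d[1:2] <- "C"
  expect_equal(k2p_distance(a, d), -0.5 * log(1 - 0.02) - 0.25 * log(1 - 0.04),
               tolerance = 1e-12)
  # pairwise deletion: gaps and N excluded from the denominator
  e <- b; e[3:4] <- c("-", "N")
  expect_equal(k2p_distance(a, e), -0.5 * log(1 - 2 / 98), tolerance = 1e-12)
  expect_error(k2p_distance(a, rep("A", 99)), "equal length")
  expect_warning(ds <- k2p_distance(rep(c("A", "C"), 50), rep(c("G", "A"), 50)),
                 "saturated")
  expect_true(is.infinite(ds))
})

test_that("K2P matrix agrees with the ape reference implementation", {
  set.seed(50)
  anc <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
  m <- t(replicate(8, {
    s <- anc
    pos <- sample(200, 12)
    for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
    s
  }))
  rownames(m) <- paste0("s", 1:8)
  aln <- seq_alignment(m)
  D <- k2p_matrix(aln)
  bin <- ape::as.DNAbin(t(sapply(rownames(m), function(i) tolower(m[i, ]))))
  Dape <- as.matrix(ape::dist.dna(bin, model = "K80",
                                  pairwise.deletion = TRUE))
  expect_equal(unname(D), unname(Dape[rownames(D), rownames(D)]),
               tolerance = 1e-10)
})

test_that("NJ reconstructs additive trees exactly", {
  set.seed(51)
  for (trial in 1:20) {
    n <- sample(4:10, 1)
    ref <- random_additive_tree(n)
    tr <- nj_tree(ref$D)
    expect_equal(ape::dist.topo(ape::unroot(ref$tree), tr), 0,
                 ignore_attr = TRUE)
    # branch lengths: leaf-to-leaf path lengths match the input metric
    expect_equal(ape::cophenetic.phylo(tr)[rownames(ref$D), colnames(ref$D)],
                 ref$D, tolerance = 1e-8)
  }
})

test_that("three taxa solve the three-point equations", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  # x_a = (d_ab + d_ac - d_bc)/2 = 1, x_b = 2, x_c = 3
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("a", "b", "c")]), c(1, 2, 3))
})

test_that("taxon input order does not change the NJ splits", {
  set.seed(52)
  ref <- random_additive_tree(8)
  tr1 <- nj_tree(ref$D)
  perm <- sample(8)
  tr2 <- nj_tree(ref$D[perm, perm])
  expect_equal(ape::dist.topo(tr1, tr2), 0, ignore_attr = TRUE)
})

test_that("NJ input validation and negative-branch clamping work", {
  D <- matrix(1, 2, 2) - diag(2)
  expect_error(nj_tree(D), "at least 3")
  Dbad <- matrix(c(0, 1, Inf, 1, 0, 1, Inf, 1, 0), 3,
                 dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(Dbad), "undefined")
  # a metric known to produce a negative NJ branch
  Dn <- matrix(c(0, 2, 2, 2.8,
                 2, 0, 2.8, 2,
                 2, 2.8, 0, 2,
                 2.8, 2, 2, 0), 4,
               dimnames = list(letters[1:4], letters[1:4]))
  raw <- nj_tree(Dn, clamp_negative = FALSE)
  if (any(raw$edge.length < 0)) {
    cl <- nj_tree(Dn)
    expect_true(all(cl$edge.length >= 0))
    expect_equal(sum(cl$edge.length), sum(raw$edge.length), tolerance = 1e-9)
  }
})

test_that("median joining resolves the classic star case", {
  # two haplotypes one step apart: a single edge, no medians
  h2 <- rbind(H1 = c("0", "0"), H2 = c("1", "0"))
  net2 <- median_joining(h2)
  expect_equal(nrow(net2$edges), 1)
  expect_equal(net2$edges$weight, 1L)
  expect_false(any(net2$nodes$type == "median"))

  # three haplotypes pairwise 2 apart with a consistent median:
  # star with one median node, total length 3
  h3 <- rbind(H1 = c("1", "0", "0"), H2 = c("0", "1", "0"),
              H3 = c("0", "0", "1"))
  net3 <- median_joining(h3)
  expect_equal(sum(net3$nodes$type == "median"), 1)
  expect_equal(nrow(net3$edges), 3)
  expect_equal(sum(net3$edges$weight), 3)
  # all three edges touch the median
  expect_true(all(net3$edges$from == "mv1" | net3$edges$to == "mv1"))
})

test_that("the network always contains a minimum spanning tree", {
  set.seed(53)
  for (trial in 1:10) {
    chars <- matrix(as.character(stats::rbinom(6 * 10, 1, 0.4)), 6, 10)
    rownames(chars) <- paste0("H", 1:6)
    chars <- chars[!duplicated(chars), , drop = FALSE]
    if (nrow(chars) < 3) next
    net <- median_joining(chars)
    # MST weight over the final node set, restricted to network edges,
    # equals the unrestricted MST weight
    ids <- net$nodes$id
    n <- length(ids)
    D_net <- matrix(Inf, n, n, dimnames = list(ids, ids))
    diag(D_net) <- 0
    for (e in seq_len(nrow(net$edges)))
      D_net[net$edges$from[e], net$edges$to[e]] <-
        D_net[net$edges$to[e], net$edges$from[e]] <- net$edges$weight[e]
    # Prim on the network graph
    intree <- 1L; key <- D_net[1, ]; w_net <- 0
    while (length(intree) < n) {
      j <- setdiff(order(key), intree)[1]
      w_net <- w_net + unname(key[j])
      intree <- c(intree, j)
      key <- pmin(key, D_net[j, ])
    }
    expect_equal(w_net, mst_weight(net$chars))
    # edge weights are the recomputed character differences
    for (e in seq_len(nrow(net$edges)))
      expect_equal(net$edges$weight[e],
                   sum(net$chars[net$edges$from[e], ] !=
                         net$chars[net$edges$to[e], ]))
  }
})

test_that("haplotype tables and network files are written", {
  set.seed(54)
  smp <- data.frame(sample_id = paste0("s", 1:20),
                    lineage = rep(c("L1", "L2"), each = 10))
  cp <- generate_cpdna(smp, haplotypes = c(L1 = 2L, L2 = 3L), core_steps = 4,
                       region_lengths = c(200L))
  hs <- collapse_haplotypes(cp$alignment)
  tab <- haplotype_table(hs)
  expect_equal(sum(tab$frequency), 20)
  net <- median_joining(hs)
  tsv <- withr::local_tempfile(); gml <- withr::local_tempfile()
  write_mj_network(net, tsv, gml)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(net$edges))
  expect_true(any(grepl("graph", readLines(gml))))
})
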