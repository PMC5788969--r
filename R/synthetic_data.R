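#' @name synthetic_data
#' @title Synthetic microsatellite and cpDNA data with tea-like lineage
#'   structure
#'
#' @description
#' Generators that emulate the assumed structure of the study system: three
#' diverged domesticated lineages (ChinaType, ChineseAssam, IndianAssam)
#' plus a wild relative (Taliensis), hybrids of known genealogical class
#' between chosen parent lineages, and lineage-structured chloroplast
#' haplotypes. Two pathways produce lineage allele frequencies: a fast
#' Balding-Nichols Dirichlet shortcut (default) and the coalescent
#' simulator of [demographic_model()].
NULL

#' Generate per-lineage allele-frequency tables
#'
#' Dirichlet pathway: one ancestral frequency vector per locus is drawn from
#' a symmetric Dirichlet(`concentration`), then each lineage draws its own
#' frequencies from Dirichlet(`p_anc * (1 - F) / F`) with `F = divergence`
#' (the Balding-Nichols model, so `divergence` is approximately the expected
#' FST between lineages). `divergence = 0` returns identical frequencies for
#' every lineage. Coalescent pathway: supply `model`; empirical per-deme
#' frequencies are taken from one large simulated replicate, and `lineages`
#' must then name at most the three model demes.
#'
#' @param n_loci number of loci (default 23).
#' @param lineages character vector of lineage names.
#' @param n_alleles number of allele states per locus (Dirichlet pathway).
#' @param allele_start smallest allele repeat size (default 16).
#' @param concentration symmetric Dirichlet concentration for the ancestral
#'   frequencies (default 1).
#' @param divergence divergence scaling in `[0, 1)`; approximately the
#'   expected lineage FST (default 0.2).
#' @param model optional [demographic_model()] for the coalescent pathway.
#' @param n_sim diploids per deme used to estimate frequencies when `model`
#'   is given.
#' @param mu mutation rate per locus for the coalescent pathway.
#' @return named list (per lineage) of lists (per locus) of named frequency
#'   vectors over integer allele states, each summing to 1.
#' @export
generate_lineage_frequencies <- function(n_loci = 23L,
                                         lineages = c("ChinaType",
                                                      "ChineseAssam",
                                                      "IndianAssam",
                                                      "Taliensis"),
                                         n_alleles = 8L, allele_start = 16L,
                                         concentration = 1, divergence = 0.2,
                                         model = NULL, n_sim = 200L,
                                         mu = 5e-4) {
  if (n_loci < 1) stop("n_loci must be >= 1")
  if (!is.null(model)) {
    if (length(lineages) > 3)
      stop("coalescent pathway provides at most the 3 model demes")
    rep <- simulate_replicate(model$topology, params = list(
      ne = model$ne, ne_anc = model$ne_anc, t1 = model$t1, t2 = model$t2,
      alpha = model$alpha, mus = rep(mu, n_loci)),
      design = list(n_dip = rep(n_sim, 3L), n_loci = n_loci))
    out <- lapply(seq_along(lineages), function(d) {
      idx <- which(rep$deme == d)
      lapply(seq_len(n_loci), function(l) {
        al <- c(rep$genotypes$a1[idx, l], rep$genotypes$a2[idx, l])
        tab <- table(al)
        p <- as.numeric(tab) / sum(tab)
        names(p) <- names(tab)
        p
      })
    })
    names(out) <- lineages
    return(out)
  }
  if (n_alleles < 1) stop("need at least 1 allele state")
  if (divergence < 0 || divergence >= 1) stop("divergence must be in [0, 1)")
  states <- allele_start + seq_len(n_alleles) - 1L
  rdir <- function(a) { x <- stats::rgamma(length(a), a, 1); x / sum(x) }
  anc <- lapply(seq_len(n_loci), function(l) rdir(rep(concentration, n_alleles)))
  out <- lapply(lineages, function(lin) {
    lapply(anc, function(p) {
      q <- if (divergence == 0) p else rdir(p * (1 - divergence) / divergence)
      names(q) <- states
      q
    })
  })
  names(out) <- lineages
  out
}

.draw_allele <- function(freq, n = 1L) {
  as.integer(sample(names(freq), n, replace = TRUE, prob = freq))
}

#' Sample diploid individuals from lineage allele frequencies
#'
#' Each call is two independent draws from the lineage-locus frequency
#' vector (Hardy-Weinberg proportions, unlinked loci).
#'
#' @param freqs per-locus frequency list for one lineage (one element of
#'   [generate_lineage_frequencies()] output).
#' @param n number of individuals (`n = 0` gives an empty matrix).
#' @param prefix sample-ID prefix.
#' @return a [genotype_matrix()].
#' @export
sample_individuals <- function(freqs, n, prefix = "ind") {
  if (n < 0) stop("n must be >= 0")
  L <- length(freqs)
  a1 <- matrix(NA_integer_, n, L)
  a2 <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    if (n > 0) {
      a1[, l] <- .draw_allele(freqs[[l]], n)
      a2[, l] <- .draw_allele(freqs[[l]], n)
    }
  }
  genotype_matrix(a1, a2, samples = if (n > 0) paste0(prefix, seq_len(n))
                  else character(0))
}

# one gamete from a diploid genotype (one allele per locus, Mendelian)
.gamete <- function(a1, a2) {
  pick <- stats::runif(length(a1)) < 0.5
  ifelse(pick, a1, a2)
}

.f1_pair <- function(p1_freqs, p2_freqs) {
  L <- length(p1_freqs)
  list(a1 = vapply(p1_freqs, .draw_allele, integer(1)),
       a2 = vapply(p2_freqs, .draw_allele, integer(1)))
}

#' Simulate hybrids of a known genealogical class
#'
#' Classes: `F1` draws one allele per locus from each parental gene pool;
#' `F2` is the offspring of two independently simulated F1 individuals;
#' `BC1` crosses an F1 back to the P1 pool and `BC2` to the P2 pool.
#' Mendelian segregation per locus, unlinked loci, no mutation during the
#' crosses.
#'
#' @param class one of `"F1"`, `"F2"`, `"BC1"`, `"BC2"`.
#' @param p1_freqs,p2_freqs per-locus frequency lists of the two parental
#'   lineages.
#' @param n number of hybrids.
#' @param prefix sample-ID prefix.
#' @return a [genotype_matrix()].
#' @export
make_hybrid <- function(class, p1_freqs, p2_freqs, n, prefix = class) {
  if (!class %in% c("F1", "F2", "BC1", "BC2"))
    stop("unknown hybrid class: ", class)
  if (n < 0) stop("n must be >= 0")
  L <- length(p1_freqs)
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) {
    if (class == "F1") {
      f1 <- .f1_pair(p1_freqs, p2_freqs)
      a1[i, ] <- f1$a1; a2[i, ] <- f1$a2
    } else if (class == "F2") {
      ma <- .f1_pair(p1_freqs, p2_freqs)
      pa <- .f1_pair(p1_freqs, p2_freqs)
      a1[i, ] <- .gamete(ma$a1, ma$a2)
      a2[i, ] <- .gamete(pa$a1, pa$a2)
    } else {
      f1 <- .f1_pair(p1_freqs, p2_freqs)
      pool <- if (class == "BC1") p1_freqs else p2_freqs
      a1[i, ] <- .gamete(f1$a1, f1$a2)
      a2[i, ] <- vapply(pool, .draw_allele, integer(1))
    }
  }
  genotype_matrix(a1, a2, samples = if (n > 0) paste0(prefix, "_", seq_len(n))
                  else character(0))
}

#' Generate lineage-structured cpDNA haplotype sequences
#'
#' Builds a random ancestral sequence, gives every lineage a core haplotype
#' separated from the other cores by about `core_steps` mutation events
#' (substitutions, plus one multi-base gap run per lineage when
#' `with_indels`), and derives the remaining within-lineage haplotypes 1-2
#' substitution steps from their core. Each sample receives one haplotype of
#' its (maternal) lineage; a hybrid's maternal lineage is whatever lineage
#' it is listed under.
#'
#' @param samples data.frame with columns `sample_id` and `lineage`.
#' @param haplotypes named integer vector: haplotype count per lineage.
#' @param core_steps mutation steps separating two lineage cores (pairwise;
#'   exact for two lineages, to within one step otherwise).
#' @param region_lengths lengths of the concatenated regions (default the
#'   three intergenic spacers 662, 692, 581 bp).
#' @param within_steps range of extra steps for non-core haplotypes.
#' @param with_indels also give each lineage core a private 3-bp gap run.
#' @return list with `alignment` (a [seq_alignment()]) and `haplotype`
#'   (character vector of true haplotype labels per sample).
#' @export
generate_cpdna <- function(samples,
                           haplotypes = c(ChinaType = 7L, ChineseAssam = 10L,
                                          IndianAssam = 8L, Taliensis = 6L),
                           core_steps = 6L,
                           region_lengths = c(662L, 692L, 581L),
                           within_steps = 1:2, with_indels = TRUE) {
  lineages <- names(haplotypes)
  if (any(haplotypes < 1)) stop("need >= 1 haplotype per lineage")
  if (!all(samples$lineage %in% lineages))
    stop("sample lineage(s) without haplotype spec: ",
         paste(setdiff(samples$lineage, lineages), collapse = ", "))
  len <- sum(region_lengths)
  per_core <- ceiling(core_steps / 2)
  need <- length(lineages) * (per_core + 3L) +
    sum(haplotypes - 1L) * max(within_steps)
  if (need > len) stop("requested mutation steps exceed sequence length")
  anc <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  free <- sample(len)          # pool of positions never mutated twice
  take <- function(k) { p <- free[seq_len(k)]; free <<- free[-seq_len(k)]; p }
  mutate <- function(seq, pos) {
    for (p in pos) seq[p] <- sample(setdiff(bases, seq[p]), 1)
    seq
  }
  # private per-lineage mutations => cores pairwise ~core_steps apart
  steps_i <- rep(core_steps %/% 2, length(lineages)) +
    rep_len(c(core_steps %% 2, 0L), length(lineages))
  hap_seqs <- list(); hap_lineage <- character(0)
  for (i in seq_along(lineages)) {
    core <- mutate(anc, take(steps_i[i]))
    if (with_indels && steps_i[i] > 0) {
      # a 3-bp gap run on positions that are never used as substitution
      # sites anywhere else, so each indel stays one clean event
      cand <- free[free <= len - 2L & (free + 1L) %in% free &
                     (free + 2L) %in% free]
      if (!length(cand)) stop("requested mutation steps exceed sequence length")
      run_start <- cand[1]
      free <- setdiff(free, run_start + 0:2)
      core[run_start + 0:2] <- "-"
    }
    hs <- list(core)
    for (h in seq_len(haplotypes[i] - 1L)) {
      k <- if (length(within_steps) == 1) within_steps
           else sample(within_steps, 1)
      hs[[h + 1L]] <- mutate(core, take(k))
    }
    hap_seqs <- c(hap_seqs, hs)
    hap_lineage <- c(hap_lineage, rep(lineages[i], haplotypes[i]))
  }
  hap_ids <- paste0("H", seq_along(hap_seqs))
  # assign each sample a haplotype of its lineage: every designed haplotype
  # is used once first (so the design is always recoverable when the
  # lineage has enough samples), then the core dominates the remainder
  lab <- character(nrow(samples))
  for (lin in lineages) {
    at <- which(samples$lineage == lin)
    cand <- which(hap_lineage == lin)
    k <- length(cand)
    first <- seq_len(min(k, length(at)))
    lab[at[first]] <- hap_ids[cand[first]]
    rest <- at[-first]
    if (length(rest)) {
      w <- c(3, rep(1, k - 1L))  # core haplotype dominates
      pick <- cand[sample.int(k, length(rest), replace = TRUE, prob = w)]
      lab[rest] <- hap_ids[pick]
    }
  }
  m <- do.call(rbind, hap_seqs[match(lab, hap_ids)])
  rownames(m) <- samples$sample_id
  ends <- cumsum(region_lengths)
  regions <- data.frame(name = paste0("region", seq_along(region_lengths)),
                        start = c(1L, utils::head(ends, -1) + 1L), end = ends)
  list(alignment = seq_alignment(m, regions = regions), haplotype = lab,
       haplotype_lineage = stats::setNames(hap_lineage, hap_ids))
}

#' Specification for a full synthetic dataset
#'
#' Defaults emulate the study design: 23 loci; pure groups CT(10), CCL(36),
#' CCC(89), CIC(6), ACL(45), ACC(51), AIC(46); a mosaic roster with the
#' observed class totals (6 F1, 64 F2, 23 BC1, 7 BC2) between
#' ChineseAssam x ChinaType; lineage divergence 0.2 (approximate expected
#' FST); 31 cpDNA haplotypes.
#'
#' @param n_loci,n_alleles,divergence,concentration see
#'   [generate_lineage_frequencies()].
#' @param groups named integer vector of pure-group sizes; names must be
#'   known group codes (see [sample_metadata()]).
#' @param hybrids data.frame with columns `class`, `p1`, `p2`, `group`,
#'   `n`.
#' @param cpdna_n number of samples sequenced for cpDNA (subsampled across
#'   lineages), 0 to skip.
#' @param rng_seed integer seed recorded in the output provenance.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(n_loci = 23L, n_alleles = 8L, divergence = 0.2,
                       concentration = 1,
                       groups = c(CT = 10L, CCL = 36L, CCC = 89L, CIC = 6L,
                                  ACL = 45L, ACC = 51L, AIC = 46L),
                       hybrids = data.frame(
                         class = c("F1", "F2", "BC1", "BC2"),
                         p1 = "ChineseAssam", p2 = "ChinaType",
                         group = "ACCM", n = c(6L, 64L, 23L, 7L),
                         stringsAsFactors = FALSE),
                       cpdna_n = 101L, rng_seed = 1L) {
  if (any(groups < 0) || (!is.null(hybrids) && any(hybrids$n < 0)))
    stop("all counts must be >= 0")
  structure(list(n_loci = n_loci, n_alleles = n_alleles,
                 divergence = divergence, concentration = concentration,
                 groups = groups, hybrids = hybrids, cpdna_n = cpdna_n,
                 rng_seed = as.integer(rng_seed)),
            class = "synth_spec")
}

#' Generate a complete synthetic dataset
#'
#' Draws lineage frequencies, samples the pure groups, simulates the hybrid
#' roster, and (optionally) generates cpDNA sequences for a subset of
#' samples. Fully deterministic given `spec$rng_seed`.
#'
#' @param spec a [synth_spec()].
#' @return list with `genotypes`, `metadata`, `truth` (true class per
#'   hybrid and parent pair), `freqs`, `cpdna` (or `NULL`) and `provenance`
#'   (seed and spec echo).
#' @export
generate_synthetic_dataset <- function(spec = synth_spec()) {
  set.seed(spec$rng_seed)
  grp_lineage <- stats::setNames(.known_groups$lineage, .known_groups$group)
  lineages <- unique(c(grp_lineage[names(spec$groups)],
                       if (!is.null(spec$hybrids))
                         c(spec$hybrids$p1, spec$hybrids$p2)))
  lineages <- lineages[!is.na(lineages) & lineages != "Mosaic"]
  freqs <- generate_lineage_frequencies(
    n_loci = spec$n_loci, lineages = lineages, n_alleles = spec$n_alleles,
    concentration = spec$concentration, divergence = spec$divergence)
  gs <- list(); metas <- list()
  for (grp in names(spec$groups)) {
    n <- spec$groups[[grp]]
    if (n == 0) next
    lin <- grp_lineage[[grp]]
    gm <- sample_individuals(freqs[[lin]], n, prefix = grp)
    gs <- c(gs, list(gm))
    metas <- c(metas, list(sample_metadata(gm$samples, grp)))
  }
  truth <- NULL
  if (!is.null(spec$hybrids) && nrow(spec$hybrids)) {
    for (r in seq_len(nrow(spec$hybrids))) {
      h <- spec$hybrids[r, ]
      if (h$n == 0) next
      gm <- make_hybrid(h$class, freqs[[h$p1]], freqs[[h$p2]], h$n,
                        prefix = paste0(h$group, "_", h$class))
      gs <- c(gs, list(gm))
      metas <- c(metas, list(sample_metadata(gm$samples, h$group)))
      truth <- rbind(truth, data.frame(sample_id = gm$samples,
                                       class = h$class, p1 = h$p1, p2 = h$p2,
                                       stringsAsFactors = FALSE))
    }
  }
  genotypes <- do.call(rbind_genotypes, gs)
  metadata <- do.call(rbind, metas)
  cpdna <- NULL
  if (spec$cpdna_n > 0) {
    lin_of <- metadata$lineage
    lin_of[lin_of == "Mosaic"] <- grp_lineage[
      sub("M$", "", metadata$group[lin_of == "Mosaic"])]
    lin_of[is.na(lin_of)] <- lineages[1]
    pick <- sort(sample(nrow(metadata), min(spec$cpdna_n, nrow(metadata))))
    hap_counts <- stats::setNames(
      pmax(2L, round(31 * table(lin_of[pick]) / length(pick))),
      names(table(lin_of[pick])))
    cpdna <- generate_cpdna(
      data.frame(sample_id = metadata$sample_id[pick],
                 lineage = lin_of[pick], stringsAsFactors = FALSE),
      haplotypes = hap_counts)
  }
  list(genotypes = genotypes, metadata = metadata, truth = truth,
       freqs = freqs, cpdna = cpdna,
       provenance = list(rng_seed = spec$rng_seed, spec = unclass(spec)))
}
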