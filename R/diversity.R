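#' @name diversity
#' @title Per-group microsatellite diversity statistics
#'
#' @description
#' Statistics reported per tea group: observed heterozygosity (Ho), Nei's
#' unbiased gene diversity (Hs), rarefied allelic richness (Ar), percentage
#' of rare alleles (RA%, within-group frequency at or below a cutoff), and
#' the inbreeding coefficient Fis = 1 - Ho/Hs. Per-locus values are averaged
#' unweighted over loci (FSTAT convention); missing calls are excluded
#' locus-wise.
NULL

.sel_group <- function(g, groups, group) {
  groups <- rep_len(as.character(groups), n_samples(g))
  idx <- which(groups == group)
  if (!length(idx)) stop("group not present: ", group)
  idx
}

# per-locus allele count tables for a set of individuals; NULL for loci with
# no non-missing calls
.locus_counts <- function(g, idx) {
  lapply(seq_len(n_loci(g)), function(l) {
    al <- c(g$a1[idx, l], g$a2[idx, l])
    al <- al[!is.na(al)]
    if (!length(al)) return(NULL)
    table(al)
  })
}

#' Observed heterozygosity
#'
#' Per-locus fraction of heterozygous individuals among those with a
#' non-missing call; unweighted mean over loci. Loci with no data in the
#' group are excluded with a warning.
#'
#' @param g a [genotype_matrix()].
#' @param groups per-sample group labels.
#' @param group the group to evaluate.
#' @return list with `per_locus` (named numeric) and `mean`.
#' @export
observed_heterozygosity <- function(g, groups, group) {
  idx <- .sel_group(g, groups, group)
  per <- vapply(seq_len(n_loci(g)), function(l) {
    a1 <- g$a1[idx, l]; a2 <- g$a2[idx, l]
    ok <- !is.na(a1)
    if (!any(ok)) return(NA_real_)
    mean(a1[ok] != a2[ok])
  }, numeric(1))
  names(per) <- g$loci
  if (anyNA(per))
    warning("excluding all-missing locus(es): ",
            paste(g$loci[is.na(per)], collapse = ", "))
  list(per_locus = per, mean = mean(per, na.rm = TRUE))
}

#' Nei's unbiased gene diversity
#'
#' Per locus, with `n` the number of individuals carrying data,
#' `Hs = n/(n-1) * (1 - sum(p^2) - Ho/(2n))` (Nei 1987); unweighted mean
#' over loci. Loci with fewer than 2 genotyped individuals are excluded with
#' a warning.
#'
#' @inheritParams observed_heterozygosity
#' @return list with `per_locus` and `mean`.
#' @export
gene_diversity <- function(g, groups, group) {
  idx <- .sel_group(g, groups, group)
  per <- vapply(seq_len(n_loci(g)), function(l) {
    a1 <- g$a1[idx, l]; a2 <- g$a2[idx, l]
    ok <- !is.na(a1)
    n <- sum(ok)
    if (n < 2) return(NA_real_)
    al <- c(a1[ok], a2[ok])
    p <- as.numeric(table(al)) / (2 * n)
    ho <- mean(a1[ok] != a2[ok])
    n / (n - 1) * (1 - sum(p^2) - ho / (2 * n))
  }, numeric(1))
  names(per) <- g$loci
  if (anyNA(per))
    warning("excluding locus(es) with < 2 genotyped individuals: ",
            paste(g$loci[is.na(per)], collapse = ", "))
  list(per_locus = per, mean = mean(per, na.rm = TRUE))
}

#' Rarefied allelic richness
#'
#' FSTAT-style hypergeometric rarefaction to a common number of gene copies
#' `g_genes`: per locus, `Ar = sum_i [1 - C(Ng - Ni, g) / C(Ng, g)]` where
#' `Ng` is the number of genes sampled at the locus and `Ni` the number of
#' copies of allele i. Equals the expected number of distinct alleles in a
#' random subsample of `g_genes` genes.
#'
#' @inheritParams observed_heterozygosity
#' @param g_genes rarefaction size in gene copies; default the smallest
#'   per-locus gene count within the group. Must be >= 2 and no larger than
#'   the gene count at every retained locus.
#' @return list with `per_locus`, `mean` and the `g_genes` used.
#' @export
allelic_richness <- function(g, groups, group, g_genes = NULL) {
  idx <- .sel_group(g, groups, group)
  cnts <- .locus_counts(g, idx)
  ngs <- vapply(cnts, function(ct) if (is.null(ct)) 0L else sum(ct), integer(1))
  if (is.null(g_genes)) g_genes <- min(ngs[ngs > 0])
  if (g_genes < 2) stop("g_genes must be >= 2")
  per <- vapply(seq_along(cnts), function(l) {
    ct <- cnts[[l]]
    if (is.null(ct)) return(NA_real_)
    ng <- sum(ct)
    if (g_genes > ng)
      stop("g_genes (", g_genes, ") exceeds gene count (", ng,
           ") at locus ", g$loci[l])
    # log-scale hypergeometric terms to stay stable at large Ng
    sum(1 - exp(lchoose(ng - as.numeric(ct), g_genes) - lchoose(ng, g_genes)))
  }, numeric(1))
  names(per) <- g$loci
  list(per_locus = per, mean = mean(per, na.rm = TRUE), g_genes = g_genes)
}

#' Percentage of rare alleles
#'
#' 100 x (number of alleles with within-group frequency <= `cutoff`,
#' summed over loci) / (total distinct alleles in the group over all loci).
#' An allele exactly at the cutoff counts as rare.
#'
#' @inheritParams observed_heterozygosity
#' @param cutoff frequency cutoff (default 0.05).
#' @return percentage in `[0, 100]`.
#' @export
rare_allele_pct <- function(g, groups, group, cutoff = 0.05) {
  idx <- .sel_group(g, groups, group)
  cnts <- .locus_counts(g, idx)
  n_rare <- 0L; n_tot <- 0L
  for (ct in cnts) {
    if (is.null(ct)) next
    p <- as.numeric(ct) / sum(ct)
    n_rare <- n_rare + sum(p <= cutoff)
    n_tot <- n_tot + length(p)
  }
  if (n_tot == 0L) stop("no alleles observed in group ", group)
  100 * n_rare / n_tot
}

#' Inbreeding coefficient from mean heterozygosities
#'
#' `Fis = 1 - Ho/Hs`; reported as `NA` (not an error) when `Hs` is 0.
#'
#' @param ho mean observed heterozygosity.
#' @param hs mean gene diversity.
#' @return Fis, or `NA` when `hs == 0`.
#' @examples
#' inbreeding_coefficient(0.517, 0.624)  # 0.171 at 3 decimals
#' @export
inbreeding_coefficient <- function(ho, hs) {
  ifelse(hs == 0, NA_real_, 1 - ho / hs)
}

#' Per-group diversity table
#'
#' One row per group (Mosaic groups excluded by default, since admixed
#' samples would inflate within-group diversity) plus a pooled `Total` row
#' that treats all listed samples as one group and recomputes (not averages)
#' every statistic. Allelic richness uses a single global rarefaction size:
#' the smallest per-group, per-locus gene count across the compared groups,
#' so Ar is comparable across rows.
#'
#' @param g a [genotype_matrix()].
#' @param metadata data.frame from [sample_metadata()], rows aligned with or
#'   matched by `sample_id` to the genotype samples.
#' @param groups character vector of groups to tabulate; default all
#'   non-Mosaic groups present, in order of first appearance.
#' @param include_total add the pooled `Total` row (default `TRUE`).
#' @param cutoff rare-allele frequency cutoff.
#' @param g_genes rarefaction size; default the global minimum gene count.
#' @return data.frame with columns `Group`, `N`, `A`, `RA_pct`, `Ar`, `Ho`,
#'   `Hs`, `Fis`.
#' @export
diversity_table <- function(g, metadata, groups = NULL, include_total = TRUE,
                            cutoff = 0.05, g_genes = NULL) {
  m <- match(g$samples, metadata$sample_id)
  if (anyNA(m)) stop("metadata missing for sample(s): ",
                     paste(g$samples[is.na(m)][1:min(3, sum(is.na(m)))],
                           collapse = ", "))
  glab <- metadata$group[m]
  lin <- metadata$lineage[m]
  if (is.null(groups)) {
    keep <- !is.na(lin) & lin != "Mosaic"
    groups <- unique(glab[keep])
  }
  if (!length(groups))
    return(data.frame(Group = character(), N = integer(), A = integer(),
                      RA_pct = numeric(), Ar = numeric(), Ho = numeric(),
                      Hs = numeric(), Fis = numeric()))
  member <- lapply(groups, function(gr) which(glab == gr))
  if (length(unique(unlist(member))) != length(unlist(member)))
    stop("overlapping group membership")
  all_idx <- unlist(member)
  if (is.null(g_genes)) {
    sets <- member
    if (include_total) sets <- c(sets, list(all_idx))
    g_genes <- min(vapply(sets, function(idx) {
      ngs <- vapply(.locus_counts(g, idx),
                    function(ct) if (is.null(ct)) Inf else sum(ct), numeric(1))
      min(ngs)
    }, numeric(1)))
    if (!is.finite(g_genes)) stop("a locus has no data in some group")
  }
  one_row <- function(gr, idx) {
    lab <- rep("x", n_samples(g)); lab[idx] <- "in"
    cnts <- .locus_counts(g, idx)
    A <- sum(vapply(cnts, function(ct) if (is.null(ct)) 0L else length(ct),
                    integer(1)))
    ho <- observed_heterozygosity(g, lab, "in")$mean
    hs <- gene_diversity(g, lab, "in")$mean
    data.frame(Group = gr, N = length(idx), A = A,
               RA_pct = rare_allele_pct(g, lab, "in", cutoff),
               Ar = allelic_richness(g, lab, "in", g_genes)$mean,
               Ho = ho, Hs = hs, Fis = inbreeding_coefficient(ho, hs),
               stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, lapply(seq_along(groups), function(i)
    one_row(groups[i], member[[i]])))
  if (include_total) rows <- rbind(rows, one_row("Total", all_idx))
  rownames(rows) <- NULL
  rows
}

#' Write a diversity table as CSV
#'
#' Column order mirrors the conventional report layout (Group, N, A, RA%,
#' Ar, Ho, Hs, Fis).
#'
#' @param tab data.frame from [diversity_table()].
#' @param path output path.
#' @param digits round numeric columns to this many decimals (default 3);
#'   `NULL` to write full precision.
#' @export
write_diversity_csv <- function(tab, path, digits = 3) {
  if (!is.null(digits)) {
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], round, digits = digits)
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
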