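#' Diploid microsatellite genotype matrix
#'
#' Container for co-dominant microsatellite (nSSR) genotypes: for each of N
#' individuals and L loci an unordered pair of allele states, stored as
#' integer repeat sizes. Allele states are kept as raw sizes (not recoded
#' indices) so that stepwise-mutation distances remain meaningful; consumers
#' that need dense indices recode internally. A call is missing as a whole
#' (both alleles `NA`) or present as a whole; half-missing genotypes are not
#' representable.
#'
#' @param a1,a2 integer matrices (N x L) of allele repeat sizes; `NA` marks a
#'   missing call and must occur in both matrices at the same cells.
#' @param samples character vector of unique sample IDs (length N).
#' @param loci character vector of locus IDs (length L).
#' @return An object of class `genotype_matrix` with fields `a1`, `a2`,
#'   `samples`, `loci`.
#' @examples
#' g <- genotype_matrix(matrix(10L, 2, 3), matrix(11L, 2, 3),
#'                      samples = c("s1", "s2"), loci = c("L1", "L2", "L3"))
#' n_samples(g)
#' @export
genotype_matrix <- function(a1, a2, samples = NULL, loci = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!all(dim(a1) == dim(a2))) stop("a1 and a2 must have identical dimensions")
  if (is.null(samples)) samples <- rownames(a1)
  if (is.null(samples)) samples <- paste0("ind", seq_len(nrow(a1)))
  if (is.null(loci)) loci <- colnames(a1)
  if (is.null(loci)) loci <- paste0("loc", seq_len(ncol(a1)))
  samples <- as.character(samples); loci <- as.character(loci)
  if (length(samples) != nrow(a1)) stop("length(samples) != nrow(a1)")
  if (length(loci) != ncol(a1)) stop("length(loci) != ncol(a1)")
  if (anyDuplicated(samples)) stop("sample IDs must be unique")
  if (!identical(unname(is.na(a1)), unname(is.na(a2))))
    stop("missing calls must be whole-call missing (NA in both alleles)")
  if (any(a1 <= 0L, na.rm = TRUE) || any(a2 <= 0L, na.rm = TRUE))
    stop("allele states must be positive integers")
  dimnames(a1) <- dimnames(a2) <- list(samples, loci)
  structure(list(a1 = a1, a2 = a2, samples = samples, loci = loci),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%d missing calls)\n",
              nrow(x$a1), ncol(x$a1), sum(is.na(x$a1))))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param g a `genotype_matrix`.
#' @export
n_samples <- function(g) nrow(g$a1)

#' @rdname genotype_matrix
#' @export
n_loci <- function(g) ncol(g$a1)

#' Subset a genotype matrix by sample
#'
#' @param x a `genotype_matrix`.
#' @param i sample index, logical mask, or character vector of sample IDs.
#' @param ... ignored.
#' @return a `genotype_matrix` restricted to the selected samples, loci
#'   untouched.
#' @export
`[.genotype_matrix` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$samples)
  genotype_matrix(x$a1[i, , drop = FALSE], x$a2[i, , drop = FALSE],
                  samples = x$samples[i], loci = x$loci)
}

#' Combine genotype matrices over samples
#'
#' All inputs must share the same loci in the same order.
#' @param ... `genotype_matrix` objects.
#' @return a `genotype_matrix` with the samples of all inputs, in order.
#' @export
rbind_genotypes <- function(...) {
  gs <- list(...)
  loci <- gs[[1]]$loci
  for (g in gs) if (!identical(g$loci, loci)) stop("loci differ between inputs")
  genotype_matrix(do.call(rbind, lapply(gs, `[[`, "a1")),
                  do.call(rbind, lapply(gs, `[[`, "a2")),
                  samples = unlist(lapply(gs, `[[`, "samples")), loci = loci)
}

# ---- sample metadata -------------------------------------------------------

.known_groups <- data.frame(
  group    = c("CT", "CCL", "CCC", "CCCM", "CIC", "CICM",
               "ACL", "ACLM", "ACC", "ACCM", "AIC", "AICM"),
  lineage  = c("Taliensis", "ChinaType", "ChinaType", "Mosaic", "ChinaType",
               "Mosaic", "ChineseAssam", "Mosaic", "ChineseAssam", "Mosaic",
               "IndianAssam", "Mosaic"),
  category = c("wild", "landrace", "cultivar", "cultivar", "cultivar",
               "cultivar", "landrace", "landrace", "cultivar", "cultivar",
               "cultivar", "cultivar"),
  stringsAsFactors = FALSE)

#' Build sample metadata from group labels
#'
#' Maps the study's 12 subgroup codes (CT, CCL, CCC, CCCM, CIC, CICM, ACL,
#' ACLM, ACC, ACCM, AIC, AICM) to lineage (ChinaType, ChineseAssam,
#' IndianAssam, Taliensis, Mosaic) and category (landrace, cultivar, wild).
#' The trailing "M" marks a Mosaic (admixed) group. Unknown labels are kept
#' as user-defined groups with lineage `NA` and a warning.
#'
#' @param sample_id character vector of sample IDs.
#' @param group character vector of group labels, recycled to match.
#' @param origin optional free-text origin.
#' @return data.frame with columns `sample_id`, `group`, `lineage`, `origin`,
#'   `category`.
#' @export
sample_metadata <- function(sample_id, group, origin = NA_character_) {
  group <- rep_len(as.character(group), length(sample_id))
  m <- match(group, .known_groups$group)
  if (anyNA(m[!is.na(group)]))
    warning("unknown group label(s) kept as user-defined: ",
            paste(unique(group[is.na(m)]), collapse = ", "))
  lineage <- .known_groups$lineage[m]
  category <- .known_groups$category[m]
  # unknown groups: the M-suffix convention still identifies mosaics
  unk <- is.na(m)
  lineage[unk] <- ifelse(grepl("M$", group[unk]), "Mosaic", NA_character_)
  data.frame(sample_id = as.character(sample_id), group = group,
             lineage = lineage, origin = rep_len(origin, length(sample_id)),
             category = category, stringsAsFactors = FALSE)
}

# ---- STRUCTURE text format -------------------------------------------------

#' Read genotypes in STRUCTURE text format
#'
#' Whitespace-delimited text, no header. In the default `"two-row"` dialect
#' each individual occupies two consecutive rows (one allele per locus per
#' row), first token the sample ID. In the `"one-row"` dialect each
#' individual occupies one row with two adjacent columns per locus.
#'
#' @param path file path.
#' @param dialect `"two-row"` (default) or `"one-row"`.
#' @param missing_code integer code for a missing allele (default -9).
#' @param loci optional locus names; defaults to `loc1..locL`.
#' @return a [genotype_matrix()].
#' @export
read_structure_genotypes <- function(path, dialect = c("two-row", "one-row"),
                                     missing_code = -9L, loci = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty STRUCTURE file: ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  parse_row <- function(tk, ln) {
    v <- suppressWarnings(as.integer(tk))
    if (anyNA(v)) stop(sprintf("non-integer allele token '%s' at line %d",
                               tk[which(is.na(v))[1]], ln))
    v
  }
  if (dialect == "two-row") {
    if (length(toks) %% 2L != 0L)
      stop("two-row dialect requires an even number of rows, got ",
           length(toks))
    ids <- vapply(toks[seq(1, length(toks), by = 2)], `[[`, "", 1)
    ids2 <- vapply(toks[seq(2, length(toks), by = 2)], `[[`, "", 1)
    if (!identical(ids, ids2))
      stop("two-row dialect: consecutive row pairs carry different sample IDs")
    L <- length(toks[[1]]) - 1L
    a1 <- t(vapply(seq_along(ids), function(i)
      parse_row(toks[[2 * i - 1]][-1], 2 * i - 1), integer(L)))
    a2 <- t(vapply(seq_along(ids), function(i)
      parse_row(toks[[2 * i]][-1], 2 * i), integer(L)))
  } else {
    ids <- vapply(toks, `[[`, "", 1)
    L <- (length(toks[[1]]) - 1L) %/% 2L
    both <- t(vapply(seq_along(ids), function(i)
      parse_row(toks[[i]][-1], i), integer(2L * L)))
    a1 <- both[, seq(1, 2 * L, by = 2), drop = FALSE]
    a2 <- both[, seq(2, 2 * L, by = 2), drop = FALSE]
  }
  miss <- a1 == missing_code | a2 == missing_code
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  genotype_matrix(a1, a2, samples = ids, loci = loci)
}

#' Write genotypes in STRUCTURE text format
#'
#' @inheritParams read_structure_genotypes
#' @param g a [genotype_matrix()].
#' @export
write_structure_genotypes <- function(g, path, dialect = c("two-row", "one-row"),
                                      missing_code = -9L) {
  dialect <- match.arg(dialect)
  a1 <- g$a1; a2 <- g$a2
  a1[is.na(a1)] <- missing_code; a2[is.na(a2)] <- missing_code
  con <- file(path, "w"); on.exit(close(con))
  if (dialect == "two-row") {
    for (i in seq_len(nrow(a1))) {
      writeLines(paste(c(g$samples[i], a1[i, ]), collapse = " "), con)
      writeLines(paste(c(g$samples[i], a2[i, ]), collapse = " "), con)
    }
  } else {
    for (i in seq_len(nrow(a1))) {
      inter <- as.vector(rbind(a1[i, ], a2[i, ]))
      writeLines(paste(c(g$samples[i], inter), collapse = " "), con)
    }
  }
  invisible(path)
}

# ---- GenAlEx-style CSV -----------------------------------------------------

#' Read a GenAlEx-style genotype CSV
#'
#' Layout: three header lines (counts line `L,N,npops,...`; title line with
#' population names; column header `Sample,Pop,loc1,,loc2,,...`), then one
#' row per individual with two adjacent columns per locus. Missing allele
#' code 0 for this dialect.
#'
#' @param path file path.
#' @return list with elements `genotypes` (a [genotype_matrix()]) and
#'   `metadata` (see [sample_metadata()], groups from the Pop column).
#' @export
read_genalex_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- utils::read.csv(path, header = FALSE, nrows = 3,
                         stringsAsFactors = FALSE)
  L <- as.integer(hdr[1, 1])
  locus_names <- as.character(unlist(hdr[3, seq(3, 3 + 2 * L - 1, by = 2)]))
  dat <- utils::read.csv(path, header = FALSE, skip = 3,
                         stringsAsFactors = FALSE)
  ids <- as.character(dat[[1]]); pops <- as.character(dat[[2]])
  al <- as.matrix(dat[, 3:(2 + 2 * L), drop = FALSE])
  storage.mode(al) <- "integer"
  a1 <- al[, seq(1, 2 * L, by = 2), drop = FALSE]
  a2 <- al[, seq(2, 2 * L, by = 2), drop = FALSE]
  miss <- a1 == 0L | a2 == 0L | is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  list(genotypes = genotype_matrix(a1, a2, samples = ids, loci = locus_names),
       metadata = sample_metadata(ids, pops))
}

#' Write a GenAlEx-style genotype CSV
#'
#' @param g a [genotype_matrix()].
#' @param groups character vector of group labels, one per sample.
#' @param path output path.
#' @param title dataset title written to the second header line.
#' @export
write_genalex_csv <- function(g, groups, path, title = "teapopgen export") {
  L <- n_loci(g); N <- n_samples(g)
  groups <- rep_len(as.character(groups), N)
  pops <- unique(groups)
  a1 <- g$a1; a2 <- g$a2
  a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
  ncol_total <- 2L + 2L * L
  pad <- function(x) paste(c(x, rep("", ncol_total - length(x))), collapse = ",")
  lines <- c(
    pad(c(L, N, length(pops), as.vector(table(factor(groups, levels = pops))))),
    pad(c(title, "", pops)),
    pad(c("Sample", "Pop", as.vector(rbind(g$loci, "")))))
  for (i in seq_len(N)) {
    inter <- as.vector(rbind(a1[i, ], a2[i, ]))
    lines <- c(lines, paste(c(g$samples[i], groups[i], inter), collapse = ","))
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- aligned cpDNA sequences ----------------------------------------------

#' Aligned sequence set (concatenated cpDNA regions)
#'
#' @param seqs character matrix (samples x sites) over `A,C,G,T,-,N`
#'   (uppercase), rownames = sample IDs.
#' @param regions optional data.frame with columns `name`, `start`, `end`
#'   giving the boundaries of the concatenated parts; they must partition
#'   `1..ncol(seqs)`. Default: one region spanning the whole alignment.
#' @return object of class `seq_alignment`.
#' @export
seq_alignment <- function(seqs, regions = NULL) {
  seqs <- as.matrix(seqs)
  if (is.null(rownames(seqs))) rownames(seqs) <- paste0("seq", seq_len(nrow(seqs)))
  seqs[] <- toupper(seqs)
  bad <- !(seqs %in% c("A", "C", "G", "T", "-", "N"))
  if (any(bad)) stop("invalid alignment symbol(s): ",
                     paste(unique(seqs[bad]), collapse = ","))
  if (is.null(regions))
    regions <- data.frame(name = "region1", start = 1L, end = ncol(seqs),
                          stringsAsFactors = FALSE)
  o <- order(regions$start)
  regions <- regions[o, , drop = FALSE]
  if (regions$start[1] != 1L || regions$end[nrow(regions)] != ncol(seqs) ||
      (nrow(regions) > 1 && any(regions$start[-1] != regions$end[-nrow(regions)] + 1L)))
    stop("region boundaries must partition the alignment")
  structure(list(seqs = seqs, regions = regions), class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("seq_alignment: %d sequences x %d sites (%d region%s)\n",
              nrow(x$seqs), ncol(x$seqs), nrow(x$regions),
              if (nrow(x$regions) == 1) "" else "s"))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' All records must have equal length; lowercase is normalized to uppercase.
#'
#' @param path FASTA file path.
#' @param regions optional region table, see [seq_alignment()].
#' @return a [seq_alignment()].
#' @export
read_fasta_alignment <- function(path, regions = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- suppressWarnings(ape::read.FASTA(path))
  if (!length(recs)) stop("empty FASTA file: ", path)
  lens <- lengths(recs)
  if (length(unique(lens)) != 1L)
    stop("alignment length mismatch: record '", names(recs)[which(lens != lens[1])[1]],
         "' has length ", lens[lens != lens[1]][1], " (expected ", lens[1], ")")
  m <- toupper(do.call(rbind, as.character(recs)))
  m[!(m %in% c("A", "C", "G", "T", "-", "N"))] <- "N"
  rownames(m) <- names(recs)
  seq_alignment(m, regions = regions)
}

#' Write an alignment as FASTA
#'
#' @param aln a [seq_alignment()].
#' @param path output path.
#' @export
write_fasta_alignment <- function(aln, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(aln$seqs))) {
    writeLines(paste0(">", rownames(aln$seqs)[i]), con)
    writeLines(paste(aln$seqs[i, ], collapse = ""), con)
  }
  invisible(path)
}
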