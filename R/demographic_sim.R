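#' Three-population demographic model for tea domestication scenarios
#'
#' The three demes are the domesticated lineages ChinaType, ChineseAssam and
#' IndianAssam. All topologies share an old split at `T1` generations between
#' ChinaType and the Assam stock; they differ in the younger event at `T2`:
#'
#' * topology `"A"`: IndianAssam is founded at `T2` by admixture, receiving a
#'   fraction `alpha` of its ancestry from ChinaType and `1 - alpha` from
#'   ChineseAssam;
#' * topology `"B"`: IndianAssam splits from ChinaType at `T2`;
#' * topology `"C"`: IndianAssam splits from ChineseAssam at `T2`.
#'
#' @param topology `"A"`, `"B"` or `"C"`.
#' @param ne named numeric vector of diploid effective sizes for
#'   `ChinaType`, `ChineseAssam`, `IndianAssam`.
#' @param ne_anc ancestral diploid effective size after the `T1` merge;
#'   defaults to the size of the deme the lineages merge into (ChinaType).
#' @param t1 older split time, generations (`T1 > T2`).
#' @param t2 younger event time, generations.
#' @param alpha admixture proportion, required (and only allowed) for
#'   topology `"A"`.
#' @return object of class `demographic_model`.
#' @export
demographic_model <- function(topology = c("A", "B", "C"),
                              ne = c(ChinaType = 1e4, ChineseAssam = 1e4,
                                     IndianAssam = 1e4),
                              ne_anc = NULL, t1, t2, alpha = NULL) {
  topology <- match.arg(topology)
  ne <- unname(ne[c("ChinaType", "ChineseAssam", "IndianAssam")])
  if (anyNA(ne) || any(ne <= 0)) stop("all effective sizes must be positive")
  if (!(t1 > t2) || t2 <= 0) stop("require T1 > T2 > 0")
  if (topology == "A") {
    if (is.null(alpha)) stop("topology A requires an admixture proportion alpha")
    if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  } else if (!is.null(alpha)) {
    stop("alpha is only meaningful for topology A")
  }
  if (is.null(ne_anc)) ne_anc <- ne[1]
  structure(list(topology = topology, ne = ne, ne_anc = ne_anc,
                 t1 = t1, t2 = t2,
                 alpha = if (topology == "A") alpha else 0),
            class = "demographic_model")
}

.topo_code <- function(topology) match(topology, c("A", "B", "C")) - 1L

#' Simulate one microsatellite locus under the coalescent with stepwise
#' mutation
#'
#' Standard Kingman coalescent within demes (pairwise coalescence rate
#' `1/(2*Ne)` per generation, continuous time), instantaneous lineage
#' movement at `T2` and `T1` according to the model topology, and mutations
#' dropped as Poisson(`mu` x branch length), each changing the allele by
#' +-1 repeat unit with equal probability (strict SMM) from the ancestral
#' size.
#'
#' @param model a [demographic_model()].
#' @param sample_sizes integer vector of sampled gene copies (not diploids)
#'   per deme, in the order ChinaType, ChineseAssam, IndianAssam; total >= 2.
#' @param mu per-generation mutation rate of the locus.
#' @param anc_size ancestral allele size in repeat units (default 20; only
#'   size differences matter for any statistic computed downstream).
#' @return list with `sizes` (allele size per sampled gene), `deme` (1..3)
#'   and `tmrca` (generations).
#' @export
simulate_locus <- function(model, sample_sizes, mu, anc_size = 20L) {
  stopifnot(inherits(model, "demographic_model"))
  if (mu < 0) stop("mu must be non-negative")
  sample_sizes <- as.integer(sample_sizes)
  if (length(sample_sizes) != 3 || any(sample_sizes < 0) ||
      sum(sample_sizes) < 2)
    stop("sample_sizes must give >= 0 genes per deme, total >= 2")
  sim_locus_cpp(.topo_code(model$topology), model$ne, model$ne_anc,
                model$t1, model$t2, model$alpha, sample_sizes, mu,
                as.integer(anc_size))
}

#' Prior specification for demographic parameters
#'
#' Defaults (the source study states no priors, so these are declared
#' package defaults, all configurable): log-uniform diploid `Ne` on
#' \[1e2, 1e5\] for each deme and the ancestor; uniform `T1` on \[10, 1e5\]
#' generations; `T2` uniform on \[10, T1\] (conditionally on the drawn `T1`);
#' uniform `alpha` on \[0, 1\] (topology A only); per-locus mutation rate
#' log-uniform on \[1e-5, 1e-3\].
#'
#' @param ne_bounds,t1_bounds,mu_bounds length-2 numeric bounds.
#' @param t2_bounds either `NULL` (the default: `T2 | T1 ~ U(10, T1)`) or
#'   fixed bounds, in which case draws violating `T1 > T2` are rejected.
#' @param alpha_bounds bounds for the admixture proportion.
#' @param generation_time_years years per generation (default 12, the
#'   seed-to-seed replacement time assumed for pre-cultivation tea).
#' @param per_locus_mu if `TRUE` (default) each locus draws its own mutation
#'   rate; otherwise one rate is shared genome-wide.
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(ne_bounds = c(1e2, 1e5), t1_bounds = c(10, 1e5),
                       t2_bounds = NULL, alpha_bounds = c(0, 1),
                       mu_bounds = c(1e-5, 1e-3),
                       generation_time_years = 12, per_locus_mu = TRUE) {
  chk <- function(b, nm) {
    if (length(b) != 2 || !all(is.finite(b)) || b[1] >= b[2])
      stop(nm, " bounds must be finite with lower < upper")
  }
  chk(ne_bounds, "ne"); chk(t1_bounds, "t1"); chk(alpha_bounds, "alpha")
  chk(mu_bounds, "mu")
  if (!is.null(t2_bounds)) chk(t2_bounds, "t2")
  structure(list(ne_bounds = ne_bounds, t1_bounds = t1_bounds,
                 t2_bounds = t2_bounds, alpha_bounds = alpha_bounds,
                 mu_bounds = mu_bounds,
                 generation_time_years = generation_time_years,
                 per_locus_mu = per_locus_mu),
            class = "prior_spec")
}

.runif_log <- function(n, b) exp(stats::runif(n, log(b[1]), log(b[2])))

#' Draw one parameter set from the priors
#'
#' @param priors a [prior_spec()].
#' @param topology model topology, `"A"`, `"B"` or `"C"`.
#' @param n_loci number of loci (for per-locus mutation rates).
#' @param max_attempts rejection cap when fixed `t2_bounds` violate
#'   `T1 > T2`.
#' @return list of drawn parameters (`ne`, `ne_anc`, `t1`, `t2`, `alpha`,
#'   `mus`).
#' @export
draw_parameters <- function(priors, topology, n_loci = 23L,
                            max_attempts = 1e4L) {
  for (att in seq_len(max_attempts)) {
    t1 <- stats::runif(1, priors$t1_bounds[1], priors$t1_bounds[2])
    t2 <- if (is.null(priors$t2_bounds))
      stats::runif(1, min(10, t1 / 2), t1)
    else stats::runif(1, priors$t2_bounds[1], priors$t2_bounds[2])
    if (t1 > t2) {
      ne <- .runif_log(3, priors$ne_bounds)
      ne_anc <- .runif_log(1, priors$ne_bounds)
      alpha <- if (topology == "A")
        stats::runif(1, priors$alpha_bounds[1], priors$alpha_bounds[2]) else 0
      mus <- if (priors$per_locus_mu) .runif_log(n_loci, priors$mu_bounds)
             else rep(.runif_log(1, priors$mu_bounds), n_loci)
      return(list(ne = ne, ne_anc = ne_anc, t1 = t1, t2 = t2, alpha = alpha,
                  mus = mus))
    }
  }
  stop("could not draw parameters with T1 > T2 after ", max_attempts,
       " attempts; check t2_bounds")
}

#' Simulate one replicate dataset under a drawn or fixed parameter set
#'
#' Simulates all loci independently and pairs gene copies into diploids
#' (gene copies within a deme are exchangeable, so consecutive pairing is a
#' random pairing).
#'
#' @param topology `"A"`, `"B"` or `"C"`.
#' @param priors a [prior_spec()]; ignored when `params` is supplied.
#' @param design list with `n_dip` (diploid sample counts per deme, order
#'   ChinaType, ChineseAssam, IndianAssam) and `n_loci`.
#' @param params optional fixed parameter list as returned by
#'   [draw_parameters()].
#' @param anc_size ancestral allele size, repeat units.
#' @return list with `params`, `genotypes` (a [genotype_matrix()]) and
#'   `deme` (1..3 per individual).
#' @export
simulate_replicate <- function(topology, priors = prior_spec(),
                               design = list(n_dip = c(131L, 96L, 46L),
                                             n_loci = 23L),
                               params = NULL, anc_size = 20L) {
  if (is.null(params))
    params <- draw_parameters(priors, topology, design$n_loci)
  g <- sim_replicate_geno_cpp(.topo_code(topology), params$ne, params$ne_anc,
                              params$t1, params$t2, params$alpha,
                              as.integer(design$n_dip), params$mus,
                              as.integer(anc_size))
  # deep genealogies can walk the repeat count below 1; every downstream
  # statistic is shift-invariant, so slide each locus into positive range
  for (l in seq_len(ncol(g$a1))) {
    lo <- min(g$a1[, l], g$a2[, l])
    if (lo < 1L) {
      g$a1[, l] <- g$a1[, l] + (1L - lo)
      g$a2[, l] <- g$a2[, l] + (1L - lo)
    }
  }
  gm <- genotype_matrix(g$a1, g$a2)
  list(params = params, genotypes = gm, deme = g$deme)
}

#' Simulate a table of parameter draws and summary statistics
#'
#' The ABC training substrate: each row holds one prior draw (Ne values,
#' split times, admixture proportion, mean mutation rate) and the 11 summary
#' statistics of the simulated dataset (see [summarize_stats()]).
#'
#' @inheritParams simulate_replicate
#' @param n_reps number of replicates.
#' @param progress print a dot every 1000 replicates.
#' @return data.frame with columns `topology`, parameters
#'   (`ne1`, `ne2`, `ne3`, `ne_anc`, `t1`, `t2`, `alpha`, `mu_mean`) and
#'   statistics `S1..S11`.
#' @export
simulate_table <- function(topology, n_reps, priors = prior_spec(),
                           design = list(n_dip = c(131L, 96L, 46L),
                                         n_loci = 23L),
                           anc_size = 20L, progress = FALSE) {
  topo <- .topo_code(topology)
  n_dip <- as.integer(design$n_dip)
  par_mat <- matrix(NA_real_, n_reps, 8)
  stat_mat <- matrix(NA_real_, n_reps, 11)
  for (r in seq_len(n_reps)) {
    p <- draw_parameters(priors, topology, design$n_loci)
    par_mat[r, ] <- c(p$ne, p$ne_anc, p$t1, p$t2, p$alpha, mean(p$mus))
    stat_mat[r, ] <- sim_replicate_stats_cpp(topo, p$ne, p$ne_anc, p$t1,
                                             p$t2, p$alpha, n_dip, p$mus,
                                             as.integer(anc_size))
    if (progress && r %% 1000 == 0) cat(".")
  }
  if (progress) cat("\n")
  out <- data.frame(topology = topology, par_mat, stat_mat)
  names(out) <- c("topology", "ne1", "ne2", "ne3", "ne_anc", "t1", "t2",
                  "alpha", "mu_mean", paste0("S", 1:11))
  out
}

#' Write / read a simulation table (tab-delimited with header)
#'
#' @param tab data.frame from [simulate_table()].
#' @param path file path.
#' @export
write_simulation_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_simulation_table
#' @export
read_simulation_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Convert divergence times from generations to years
#'
#' @param generations non-negative number of generations.
#' @param generation_time years per generation (default 12 for tea).
#' @param signif_digits round to this many significant figures (default 3);
#'   `NULL` for no rounding.
#' @return years before present.
#' @examples
#' divergence_time_years(231)   # 2770 years at 3 significant figures
#' @export
divergence_time_years <- function(generations, generation_time = 12,
                                  signif_digits = 3) {
  if (any(generations < 0) || generation_time < 0)
    stop("negative input to divergence_time_years")
  y <- generations * generation_time
  if (!is.null(signif_digits)) y <- signif(y, signif_digits)
  y
}
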