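#' @name pipeline
#' @title End-to-end analysis pipeline
#'
#' @description
#' Orchestrates the stages — synthetic-data generation (or file input),
#' diversity table, admixture clustering with Evanno delta-K, hybrid-class
#' assignment, ABC model choice with divergence-time posteriors, and cpDNA
#' haplotype/tree/network analysis — under a single seeded configuration
#' with provenance written alongside every output.
NULL

#' Default pipeline configuration
#'
#' Every stage can be toggled and configured; seeds for all stages derive
#' from the single `seed`. The default runs on a bundled synthetic dataset
#' specification scaled for a quick complete run.
#'
#' @param seed master RNG seed.
#' @param outdir output directory.
#' @param synthetic list of [synth_spec()] arguments (set `NULL` and supply
#'   `inputs` to read files instead).
#' @param inputs optional list with `genalex_csv` or (`structure`,
#'   `metadata_csv`) and `fasta` paths.
#' @param stages character vector of stages to run, a subset of
#'   `c("diversity", "admixture", "newhybrids", "abc", "cpdna")`.
#' @param admixture,newhybrids,abc per-stage option lists (K range and
#'   starts; parent lineages, sweeps, burn-in, threshold; models, number of
#'   simulations, tolerance, PLS components).
#' @param force overwrite outputs of an identical earlier run.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, outdir = "teapopgen_out",
                            synthetic = list(), inputs = NULL,
                            stages = c("diversity", "admixture",
                                       "newhybrids", "abc", "cpdna"),
                            admixture = list(k_range = 1:4, n_starts = 5L),
                            newhybrids = list(p1 = "ChineseAssam",
                                              p2 = "ChinaType",
                                              sweeps = 2000L, burnin = 500L,
                                              threshold = 0.5),
                            abc = list(models = c("A", "B", "C"),
                                       n_sims = 2000L, tolerance = 0.02,
                                       pls_components = 6L,
                                       design = list(n_dip = c(30L, 30L, 30L),
                                                     n_loci = 23L)),
                            force = FALSE) {
  structure(list(seed = as.integer(seed), outdir = outdir,
                 synthetic = synthetic, inputs = inputs, stages = stages,
                 admixture = admixture, newhybrids = newhybrids, abc = abc,
                 force = force),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

#' Tabulate hybrid classes per mosaic category
#'
#' Counts per genealogical class (P1, P2, F1, F2, BC1, BC2, complex) for
#' each mosaic category and overall, with percentages of all listed
#' samples (so the complex samples stay in the denominator, and the
#' percentage row sums to 100 up to rounding).
#'
#' @param classes character vector of class labels.
#' @param categories mosaic category per sample (recycled; default one
#'   category `"all"`).
#' @param digits rounding for the percentage row (default 1).
#' @return list with `counts` (data.frame, one row per category plus
#'   `Total`) and `percent` (percentages for the `Total` row).
#' @export
summarize_hybrid_table <- function(classes, categories = "all", digits = 1) {
  lev <- c("P1", "P2", "F1", "F2", "BC1", "BC2", "complex")
  if (!length(classes))
    return(list(counts = data.frame(), percent = numeric(0)))
  categories <- rep_len(categories, length(classes))
  tab <- table(factor(categories), factor(classes, levels = lev))
  counts <- as.data.frame.matrix(tab)
  counts <- cbind(category = rownames(counts), counts,
                  total = rowSums(counts))
  total_row <- c(list(category = "Total"),
                 as.list(colSums(counts[, -1, drop = FALSE])))
  counts <- rbind(counts, as.data.frame(total_row, stringsAsFactors = FALSE))
  rownames(counts) <- NULL
  tot <- counts$total[counts$category == "Total"]
  percent <- round(100 * unlist(counts[counts$category == "Total", lev]) / tot,
                   digits)
  list(counts = counts, percent = percent)
}

.stage_log <- function(log, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  c(log, line)
}

#' Run the full pipeline
#'
#' Executes the configured stages in order and writes a report bundle:
#' diversity table CSV, delta-K table and Q-matrix CSVs, hybrid-class
#' posterior and summary CSVs, an ABC report (Bayes-factor table and
#' posterior summaries with divergence times in generations and years,
#' JSON) with posterior-draw CSV, haplotype table CSV, Newick tree, network
#' edge-list TSV and GML, a run log, and the configuration (with its hash)
#' for provenance. A stage failure aborts with the stage name; outputs of
#' completed stages persist. Re-running with an unchanged configuration
#' into the same directory requires `force`.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @return invisibly, a list of stage results (`data`, `diversity`,
#'   `admixture`, `newhybrids`, `abc`, `cpdna`, `outdir`, `hash`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  hash <- .config_hash(config)
  hash_file <- file.path(config$outdir, "config.md5")
  if (dir.exists(config$outdir) && file.exists(hash_file) &&
      identical(readLines(hash_file, warn = FALSE)[1], unname(hash)) &&
      !isTRUE(config$force))
    stop("outputs for this exact configuration already exist in ",
         config$outdir, "; set force = TRUE to overwrite")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  out <- list(outdir = config$outdir, hash = hash)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  set.seed(config$seed)
  # ---- data ----------------------------------------------------------------
  out$data <- run_stage("data", {
    if (!is.null(config$inputs)) {
      inp <- config$inputs
      if (!is.null(inp$genalex_csv)) {
        ga <- read_genalex_csv(inp$genalex_csv)
        dat <- list(genotypes = ga$genotypes, metadata = ga$metadata)
      } else {
        dat <- list(genotypes = read_structure_genotypes(inp$structure),
                    metadata = utils::read.csv(inp$metadata_csv,
                                               stringsAsFactors = FALSE))
      }
      if (!is.null(inp$fasta))
        dat$cpdna <- list(alignment = read_fasta_alignment(inp$fasta))
      dat
    } else {
      spec <- do.call(synth_spec, c(config$synthetic,
                                    if (is.null(config$synthetic$rng_seed))
                                      list(rng_seed = config$seed)))
      generate_synthetic_dataset(spec)
    }
  })
  log <- .stage_log(log, "data", sprintf("%d samples x %d loci",
                                         n_samples(out$data$genotypes),
                                         n_loci(out$data$genotypes)))
  g <- out$data$genotypes
  meta <- out$data$metadata

  # ---- diversity -----------------------------------------------------------
  if ("diversity" %in% config$stages) {
    out$diversity <- run_stage("diversity", {
      tab <- diversity_table(g, meta)
      write_diversity_csv(tab, file.path(config$outdir, "diversity.csv"))
      tab
    })
    log <- .stage_log(log, "diversity", sprintf("%d group rows",
                                                nrow(out$diversity) - 1))
  }

  # ---- admixture + delta K -------------------------------------------------
  if ("admixture" %in% config$stages) {
    out$admixture <- run_stage("admixture", {
      set.seed(config$seed + 1L)
      sc <- admixture_scan(g, k_range = config$admixture$k_range,
                           n_starts = config$admixture$n_starts)
      dk <- evanno_delta_k(sc$loglik, k_values = sc$k_range)
      utils::write.csv(dk, file.path(config$outdir, "delta_k.csv"),
                       row.names = FALSE)
      best_k <- if (all(is.na(dk$delta_k))) sc$k_range[1]
                else dk$K[which.max(dk$delta_k)]
      Q <- sc$fits[[paste0("K", best_k)]]$Q
      utils::write.csv(data.frame(sample_id = rownames(Q), Q),
                       file.path(config$outdir, "q_matrix.csv"),
                       row.names = FALSE)
      list(scan = sc, delta_k = dk, best_k = best_k, Q = Q,
           mosaic = mosaic_from_q(Q))
    })
    log <- .stage_log(log, "admixture",
                      sprintf("best K by delta-K = %d", out$admixture$best_k))
  }

  # ---- hybrid classes ------------------------------------------------------
  if ("newhybrids" %in% config$stages) {
    out$newhybrids <- run_stage("newhybrids", {
      set.seed(config$seed + 2L)
      nh <- config$newhybrids
      p1_idx <- which(meta$lineage == nh$p1)
      p2_idx <- which(meta$lineage == nh$p2)
      cand_idx <- which(meta$lineage == "Mosaic")
      if (!length(cand_idx)) cand_idx <- setdiff(seq_len(n_samples(g)),
                                                 c(p1_idx, p2_idx))
      post <- gibbs_newhybrids(g, candidates = cand_idx,
                               reference_p1 = p1_idx, reference_p2 = p2_idx,
                               sweeps = nh$sweeps, burnin = nh$burnin)
      cls <- classify_mosaics(post, threshold = nh$threshold)
      utils::write.csv(post, file.path(config$outdir,
                                       "hybrid_posteriors.csv"),
                       row.names = FALSE)
      summ <- summarize_hybrid_table(
        cls$class, meta$group[match(cls$sample_id, meta$sample_id)])
      utils::write.csv(summ$counts,
                       file.path(config$outdir, "hybrid_classes.csv"),
                       row.names = FALSE)
      list(posteriors = post, classes = cls, summary = summ)
    })
    log <- .stage_log(log, "newhybrids",
                      sprintf("%d candidates classified",
                              nrow(out$newhybrids$classes)))
  }

  # ---- ABC -----------------------------------------------------------------
  if ("abc" %in% config$stages) {
    out$abc <- run_stage("abc", {
      set.seed(config$seed + 3L)
      ab <- config$abc
      lin <- meta$lineage[match(g$samples, meta$sample_id)]
      keep <- lin %in% c("ChinaType", "ChineseAssam", "IndianAssam")
      gsub_ <- g[which(keep)]
      deme <- match(lin[keep], c("ChinaType", "ChineseAssam", "IndianAssam"))
      obs <- summarize_stats(gsub_, deme)
      design <- ab$design
      design$n_dip <- as.integer(table(factor(deme, levels = 1:3)))
      design$n_loci <- n_loci(g)
      sims <- lapply(ab$models, function(m)
        simulate_table(m, ab$n_sims, design = design))
      names(sims) <- ab$models
      pooled <- do.call(rbind, sims)
      pcols <- c("ne1", "ne2", "ne3", "ne_anc", "t1", "t2", "mu_mean")
      tr <- fit_pls(pooled[, .stat_cols(pooled)], pooled[, pcols],
                    n_components = ab$pls_components)
      ref <- if ("B" %in% ab$models) "B" else ab$models[1]
      # model choice in the standardized full-statistic space; the PLS
      # space serves parameter estimation within the chosen model
      scaler <- fit_stat_scaler(pooled[, .stat_cols(pooled)])
      bf <- bayes_factors(obs, sims, scaler, tolerance_frac = ab$tolerance,
                          reference_model = ref)
      best <- bf$model[which.max(bf$bayes_factor)]
      rej <- abc_reject(obs, sims[[best]], tr, tolerance_frac = ab$tolerance)
      adj <- regression_adjust(rej, param_cols = pcols)
      utils::write.csv(adj, file.path(config$outdir, "abc_posterior.csv"),
                       row.names = FALSE)
      summ <- lapply(c(t1 = "t1", t2 = "t2"), function(p)
        posterior_summary(adj[[p]], generation_time = 12))
      report <- list(bayes_factors = bf, best_model = best,
                     posterior = lapply(summ, function(s)
                       list(mode_generations = s$mode,
                            hpdi_generations = s$hpdi,
                            mode_years = s$mode_years,
                            hpdi_years = s$hpdi_years)))
      jsonlite::write_json(report, file.path(config$outdir,
                                             "abc_report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      c(report, list(adjusted = adj, observed = obs))
    })
    log <- .stage_log(log, "abc", sprintf("best model %s", out$abc$best_model))
  }

  # ---- cpDNA ---------------------------------------------------------------
  if ("cpdna" %in% config$stages && !is.null(out$data$cpdna)) {
    out$cpdna <- run_stage("cpdna", {
      aln <- out$data$cpdna$alignment
      hs <- collapse_haplotypes(aln)
      utils::write.csv(haplotype_table(hs),
                       file.path(config$outdir, "haplotypes.csv"),
                       row.names = FALSE)
      tree <- NULL
      if (length(hs$ids) >= 3) {
        tree <- nj_tree(k2p_matrix(hs))
        ape::write.tree(tree, file.path(config$outdir, "nj_haplotypes.nwk"))
      }
      net <- median_joining(hs)
      write_mj_network(net,
                       tsv_path = file.path(config$outdir, "mj_edges.tsv"),
                       gml_path = file.path(config$outdir, "mj_network.gml"))
      list(haplotypes = hs, tree = tree, network = net)
    })
    log <- .stage_log(log, "cpdna",
                      sprintf("%d haplotypes", length(out$cpdna$haplotypes$ids)))
  }

  writeLines(yaml::as.yaml(unclass(config)),
             file.path(config$outdir, "config.yaml"))
  writeLines(hash, hash_file)
  writeLines(log, file.path(config$outdir, "run_log.txt"))
  invisible(out)
}
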