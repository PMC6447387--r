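#' Pipeline configuration
#'
#' Assembles the settings for a full [run_pipeline()] analysis.  Defaults
#' mirror the standard workflow: 1.06 ratio cutoff, stripping from 10% to
#' 90% in 10% increments, dataset-specific 4-state recoding, a 60-class
#' profile mixture, and selection of the 40 most homogeneous genes when
#' per-gene inputs are available.
#'
#' @param input path to an alignment file, or an [aa_alignment], or `NULL`
#'   to simulate one from `sim` at run time.
#' @param sim a [regime_config()] used when `input` is `NULL`.
#' @param rates optional path to a site-rate file (enables rate stripping).
#' @param tree optional tree (path / newick / `phylo`) for the homogeneity
#'   test; defaults to the simulated tree when `input` is `NULL`.
#' @param partition optional partition file path or data frame; enables
#'   per-gene homogeneity testing and gene selection.
#' @param cutoff GARP:FIMNKY ratio cutoff.
#' @param strip_fractions removal schedule, ascending.
#' @param recode_bins integer vector of bin counts to search (4 and/or 6).
#' @param restarts recoding-search restarts.
#' @param K mixture classes.
#' @param replicates homogeneity-test bootstrap replicates.
#' @param select_n genes to keep in the homogeneous subset.
#' @param seed master seed; stage seeds are derived from it.
#' @param outdir output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, sim = regime_config(),
                            rates = NULL, tree = NULL, partition = NULL,
                            cutoff = 1.06,
                            strip_fractions = seq(0.1, 0.9, by = 0.1),
                            recode_bins = c(4L, 6L), restarts = 20L,
                            K = 60L, replicates = 99L, select_n = 40L,
                            seed = 1L, outdir = tempfile("compbias_run")) {
  stopifnot(all(diff(strip_fractions) > 0),
            all(strip_fractions >= 0 & strip_fractions < 1),
            all(recode_bins >= 2 & recode_bins <= 19))
  structure(as.list(environment()), class = "pipeline_config")
}

stage_seed <- function(cfg, offset) (cfg$seed * 1000L + offset) %% .Machine$integer.max

#' Run the full compositional-heterogeneity pipeline
#'
#' Stages, in dependency order: load or simulate the alignment; per-taxon
#' composition profile and UPGMA dendrogram; ratio-cutoff taxon partition;
#' per-site zeta scores; progressive stripping (and rate-based stripping if
#' rates are supplied); minmax chi-square recoding search and application
#' for each requested bin count; profile-mixture estimation, export, and
#' collapse under the 4-state scheme; per-gene homogeneity tests and gene
#' selection when a partition and tree are available.  Every artifact is
#' written under `cfg$outdir` and recorded in a JSON manifest with MD5
#' checksums, so a re-run with the same config and seed is byte-identical.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return the manifest (list), invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$outdir, "pipeline.log")
  logf <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    stage, msg)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    if (!quiet) message(line)
  }
  outputs <- character(0)
  emit <- function(path) { outputs <<- c(outputs, path); path }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      logf(stage, paste("ERROR:", conditionMessage(e)))
      manifest <- list(failed_stage = stage, error = conditionMessage(e),
                       outputs = outputs)
      jsonlite::write_json(manifest,
                           file.path(cfg$outdir, "manifest.partial.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      stop(sprintf("pipeline aborted at stage '%s': %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  ## -- input ---------------------------------------------------------------
  tree <- NULL
  a <- run_stage("input", {
    if (is.null(cfg$input)) {
      logf("input", "simulating two-regime alignment")
      sim_cfg <- cfg$sim
      sim_cfg$seed <- stage_seed(cfg, 1L)
      sim <- make_regime_alignment(sim_cfg)
      write_alignment(sim$alignment,
                      emit(file.path(cfg$outdir, "input.fasta")))
      ape::write.tree(sim$tree, emit(file.path(cfg$outdir, "input.nwk")))
      utils::write.table(sim$truth$taxon_regime,
                         emit(file.path(cfg$outdir, "truth_taxa.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      tree <- sim$tree
      sim$alignment
    } else if (inherits(cfg$input, "aa_alignment")) cfg$input
    else read_alignment(cfg$input)
  })
  if (is.null(tree) && !is.null(cfg$tree)) tree <- as_phylo(cfg$tree)
  logf("input", sprintf(
    "%d taxa x %d sites, %.2f%% missing (%.2f%% not counting X)",
    length(a$taxa), a$n_sites, 100 * missing_fraction(a),
    100 * missing_fraction(a, count_x = FALSE)))

  ## -- composition profile -------------------------------------------------
  comps <- run_stage("profile", taxon_compositions(a))
  utils::write.table(comps, emit(file.path(cfg$outdir, "compositions.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dendro <- run_stage("cluster", upgma_compositions(comps))
  ape::write.tree(dendro, emit(file.path(cfg$outdir, "composition_upgma.nwk")))

  ## -- partition -----------------------------------------------------------
  part <- run_stage("partition", {
    p <- partition_taxa(comps, cfg$cutoff)
    if (p$flagged)
      stop("partition is one-sided at cutoff ", cfg$cutoff,
           "; choose a cutoff inside the observed ratio range ",
           sprintf("[%.3f, %.3f]", min(comps$garp_fimnky),
                   max(comps$garp_fimnky)))
    p
  })
  logf("partition", sprintf("%d AT-rich / %d GC-rich at cutoff %g",
                            length(part$at_rich), length(part$gc_rich),
                            cfg$cutoff))

  ## -- zeta + stripping ----------------------------------------------------
  ztab <- run_stage("zeta", zeta_scores(a, part))
  write_zeta_table(ztab, emit(file.path(cfg$outdir, "zeta.tsv")))
  if (any(ztab$flagged))
    logf("zeta", sprintf("WARN: %d sites with an all-missing group",
                         sum(ztab$flagged)))
  run_stage("strip", {
    sched <- strip_schedule(a, ztab$zeta, cfg$strip_fractions)
    for (nm in names(sched)) {
      write_alignment(sched[[nm]]$alignment,
                      emit(file.path(cfg$outdir,
                                     sprintf("aln_strip%s.fasta", nm))))
      writeLines(as.character(sched[[nm]]$removed),
                 emit(file.path(cfg$outdir,
                                sprintf("removed_strip%s.txt", nm))))
    }
  })
  if (!is.null(cfg$rates)) run_stage("strip_rate", {
    rates <- read_site_rates(cfg$rates, a$n_sites)
    sched <- strip_schedule(a, rates, cfg$strip_fractions)
    for (nm in names(sched))
      write_alignment(sched[[nm]]$alignment,
                      emit(file.path(cfg$outdir,
                                     sprintf("aln_ratestrip%s.fasta", nm))))
  })

  ## -- recoding ------------------------------------------------------------
  schemes <- list()
  for (nb in cfg$recode_bins) {
    sr <- run_stage(sprintf("recode%d", nb),
                    search_scheme(a, nb, cfg$restarts,
                                  seed = stage_seed(cfg, 10L + nb)))
    logf(sprintf("recode%d", nb),
         sprintf("best scheme '%s' with max_t = %.6g",
                 format(sr$scheme), sr$max_t))
    write_scheme(sr$scheme,
                 emit(file.path(cfg$outdir, sprintf("scheme_S%d.txt", nb))))
    write_alignment(apply_scheme(a, sr$scheme),
                    emit(file.path(cfg$outdir,
                                   sprintf("aln_recoded_S%d.fasta", nb))))
    schemes[[as.character(nb)]] <- sr
  }

  ## -- mixture -------------------------------------------------------------
  mix <- run_stage("mixture", fit_mixture(a, cfg$K,
                                          seed = stage_seed(cfg, 30L)))
  export_mixture(mix, sprintf("ES%d", cfg$K),
                 emit(file.path(cfg$outdir,
                                sprintf("mixture_ES%d.nex", cfg$K))))
  write_mixture_tsv(mix, emit(file.path(cfg$outdir,
                                        sprintf("mixture_ES%d.tsv", cfg$K))))
  if ("4" %in% names(schemes)) {
    coll <- collapse_profiles(mix, schemes[["4"]]$scheme)
    export_mixture(coll, sprintf("ES%dS4", cfg$K),
                   emit(file.path(cfg$outdir,
                                  sprintf("mixture_ES%dS4.nex", cfg$K))))
  }

  ## -- homogeneity ---------------------------------------------------------
  selected <- NULL
  if (!is.null(tree)) run_stage("homogeneity", {
    partmap <- if (is.null(cfg$partition)) {
      data.frame(gene = "all", start = 1L, end = a$n_sites)
    } else if (is.character(cfg$partition)) read_partition(cfg$partition)
    else cfg$partition
    model <- substitution_model(freqs = chisquare_report(a)$pooled_freqs,
                                gamma_shape = 1)
    results <- lapply(seq_len(nrow(partmap)), function(i) {
      g <- site_subset(a, partmap$start[i]:partmap$end[i])
      test_gene(g, tree, model, N = cfg$replicates,
                seed = stage_seed(cfg, 100L + i), gene = partmap$gene[i])
    })
    tab <- data.frame(gene = vapply(results, `[[`, "", "gene"),
                      x2 = vapply(results, `[[`, 0, "observed_stat"),
                      p_value = vapply(results, `[[`, 0, "p_value"))
    utils::write.table(tab, emit(file.path(cfg$outdir, "homogeneity.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(partmap) > 1L) {
      selected <- select_homogeneous(results,
                                     min(cfg$select_n, nrow(partmap)))
      writeLines(selected, emit(file.path(cfg$outdir, "selected_genes.txt")))
    }
  })

  ## -- manifest ------------------------------------------------------------
  manifest <- list(
    config = c(cfg[c("cutoff", "strip_fractions", "recode_bins", "restarts",
                     "K", "replicates", "select_n", "seed", "outdir")],
               list(input = if (is.character(cfg$input)) cfg$input
                    else if (is.null(cfg$input)) "simulated",
                    sim = if (is.null(cfg$input)) unclass(cfg$sim))),
    n_taxa = length(a$taxa), n_sites = a$n_sites,
    missing_fraction = missing_fraction(a),
    at_rich = part$at_rich,
    schemes = lapply(schemes, function(s)
      list(scheme = format(s$scheme), max_t = s$max_t)),
    mixture = list(K = mix$K, loglik = mix$loglik, n_iter = mix$n_iter),
    selected_genes = selected,
    outputs = stats::setNames(as.list(unname(tools::md5sum(outputs))),
                              basename(outputs)))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logf("done", sprintf("%d artifacts in %s", length(outputs), cfg$outdir))
  invisible(manifest)
}
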