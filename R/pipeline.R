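# End-to-end orchestration: a single YAML-configurable entry point that runs
# the stages in dependency order (simulate -> score -> regulators ->
# gsea/ssgsea -> variants -> tssprofile), records input/output counts at
# every filter, and writes a manifest with an md5 checksum of every output
# so reruns can be verified byte-for-byte.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    outdir = "mraxis_out",
    stages = list(simulate = TRUE, score = TRUE, regulators = TRUE,
                  gsea = TRUE, ssgsea = TRUE, variants = TRUE,
                  tssprofile = TRUE),
    thresholds = list(fc_threshold = 1, q_threshold = 0.05,
                      min_coverage = 10L, min_tumour_vaf = 0.05,
                      max_normal_vaf = 0.01, pathway_min_vaf = 0.2,
                      pathway_min_coverage = 20L),
    simulate = list(n_tfs = 50L, n_target_genes = 1000L,
                    tf_dna_out_degree_mean = 20, ppi_degree_mean = 4,
                    planted_tf = "TF001", effect_mean = 2, noise_sd = 1,
                    depth_decay = 0.5, n_samples_per_group = 4L,
                    expression_shift = 2,
                    n_true_somatic = 20L, n_fp_per_caller = 30L,
                    n_strain_variants = 10L, n_normals = 2L,
                    vaf_true = 0.4, coverage_mean = 60,
                    n_profile_genes = 30L, depletion_factor = 0.2),
    gsea = list(n_perm = 1000L, weight = 1, alpha = 0.25),
    tssprofile = list(flank = 15000L, bin_size = 300L)
  )
}

merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]))
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]])
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Load a pipeline configuration
#'
#' Reads a YAML document (or takes a list) and merges it over the shipped
#' defaults, which mirror the package's standard thresholds: |log2FC| > 1
#' and q < 0.05 for DE calling, depth > 10 / tumour VAF >= 0.05 / normal
#' VAF <= 0.01 for somatic filtering, VAF > 0.2 and depth > 20 for pathway
#' classification, and +/- 15 kb TSS windows.
#'
#' @param config path to a YAML file, or a named list, or `NULL` for pure
#'   defaults.
#' @return the merged configuration list.
#' @export
pipeline_config <- function(config = NULL) {
  user <- if (is.null(config)) list()
  else if (is.character(config)) yaml::read_yaml(config)
  else config
  merge_config(pipeline_defaults(), user)
}

#' Validate a pipeline configuration
#'
#' Report-only: returns errors (out-of-range values, missing referenced
#' paths) and warnings (unknown keys) without stopping.
#'
#' @param config configuration list or YAML path (see [pipeline_config()]).
#' @return list with character vectors `errors` and `warnings`; empty
#'   vectors mean a clean report.
#' @export
validate_config <- function(config = NULL) {
  user <- if (is.character(config)) yaml::read_yaml(config) else config %||% list()
  defaults <- pipeline_defaults()
  errors <- character(0)
  warnings <- character(0)
  flag_unknown <- function(u, d, prefix = "") {
    for (nm in names(u)) {
      if (!nm %in% names(d))
        warnings <<- c(warnings, sprintf("unknown key '%s%s'", prefix, nm))
      else if (is.list(u[[nm]]) && is.list(d[[nm]]))
        flag_unknown(u[[nm]], d[[nm]], paste0(prefix, nm, "."))
    }
  }
  flag_unknown(user, defaults)
  cfg <- merge_config(defaults, user)
  chk <- function(ok, msg) if (!isTRUE(ok)) errors <<- c(errors, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L, "seed must be a single integer")
  th <- cfg$thresholds
  chk(th$fc_threshold > 0, "thresholds.fc_threshold must be positive")
  chk(th$q_threshold > 0 && th$q_threshold <= 1,
      "thresholds.q_threshold must lie in (0, 1]")
  chk(th$min_coverage >= 0, "thresholds.min_coverage must be nonnegative")
  chk(th$min_tumour_vaf > th$max_normal_vaf,
      "thresholds.min_tumour_vaf must exceed max_normal_vaf")
  chk(cfg$tssprofile$flank > 0, "tssprofile.flank must be positive")
  chk(cfg$tssprofile$bin_size > 0 &&
        (2 * cfg$tssprofile$flank) %% cfg$tssprofile$bin_size == 0,
      "tssprofile.bin_size must divide the window width")
  chk(cfg$simulate$depletion_factor >= 0 && cfg$simulate$depletion_factor < 1,
      "simulate.depletion_factor must lie in [0, 1)")
  for (p in cfg$paths %||% list())
    if (!file.exists(p)) errors <- c(errors, sprintf("missing path: %s", p))
  list(errors = errors, warnings = warnings)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on synthetic inputs
#' generated from the configured seed, writing every intermediate as a
#' plain-text file under `outdir`. The returned manifest records, per
#' stage, the files written with their md5 checksums and the record counts
#' into and out of every filter, so identical config + seed reruns can be
#' verified checksum-for-checksum.
#'
#' @param config configuration list or YAML path (see [pipeline_config()]).
#' @return the manifest (list), invisibly; also written to
#'   `outdir/manifest.yaml`.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- pipeline_config(config)
  report <- validate_config(cfg)
  if (length(report$errors))
    stop("configuration invalid:\n  ", paste(report$errors, collapse = "\n  "),
         call. = FALSE)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, stages = list())
  outputs <- character(0)
  emit <- function(stage, files, counts = NULL) {
    manifest$stages[[stage]] <<- list(
      files = lapply(stats::setNames(files, basename(files)),
                     function(f) unname(tools::md5sum(f))),
      counts = counts)
    outputs <<- c(outputs, files)
  }
  path <- function(f) file.path(cfg$outdir, f)
  st <- cfg$stages
  sim <- cfg$simulate
  state <- new.env(parent = emptyenv())

  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e)
      stop(sprintf("[stage %s] %s (partial outputs under %s)", stage,
                   conditionMessage(e), cfg$outdir), call. = FALSE))
  }

  if (isTRUE(st$simulate)) run_stage("simulate", function() {
    ncfg <- network_sim_config(sim$n_tfs, sim$n_target_genes,
                               sim$tf_dna_out_degree_mean, sim$ppi_degree_mean,
                               seed = cfg$seed)
    state$edges <- simulate_network(ncfg)
    planted <- plant_regulator(state$edges,
                               plant_config(sim$planted_tf, sim$effect_mean,
                                            sim$noise_sd, sim$depth_decay,
                                            seed = cfg$seed))
    state$de <- planted$de
    state$truth <- planted$truth
    state$sets <- list(
      planted_subnetwork = planted$truth$members$gene_id,
      random_control = with_seed(substream_seed(cfg$seed, "control_set"),
                                 sample(planted$de$gene, 50L)))
    state$expr <- simulate_expression_matrix(sim$n_samples_per_group,
                                             state$sets, "planted_subnetwork",
                                             sim$expression_shift,
                                             seed = cfg$seed)
    state$varsim <- simulate_variant_calls(
      variant_sim_config(sim$n_true_somatic, sim$n_fp_per_caller,
                         sim$n_strain_variants, sim$n_normals,
                         sim$vaf_true, sim$coverage_mean, seed = cfg$seed))
    state$ann <- simulate_annotations(sim$n_profile_genes)
    state$depleted <- state$ann$gene_id[seq_len(sim$n_profile_genes %/% 2)]
    state$coverage <- simulate_coverage(state$ann, state$depleted,
                                        sim$depletion_factor,
                                        seed = cfg$seed)
    files <- c(write_edges(state$edges, path("network_edges.tsv")),
               write_de_table(state$de, path("de_table.tsv")),
               write_gmt(state$sets, path("gene_sets.gmt")),
               write_blacklist(state$varsim$blacklist, path("strain_blacklist.tsv")),
               write_bed_annotations(state$ann, path("genes.bed")),
               write_bedgraph(state$coverage, path("coverage.bedGraph")))
    expr_df <- data.frame(gene = rownames(state$expr), state$expr,
                          check.names = FALSE)
    utils::write.table(expr_df, path("expression_matrix.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, path("expression_matrix.tsv"))
    for (cl in names(state$varsim$calls))
      for (nm in names(state$varsim$calls[[cl]])) {
        f <- path(sprintf("calls_%s_%s.vcf", cl, nm))
        write_variant_vcf(state$varsim$calls[[cl]][[nm]], f)
        files <- c(files, f)
      }
    emit("simulate", files,
         counts = list(edges = nrow(state$edges), genes = nrow(state$de),
                       true_somatic = nrow(state$varsim$truth)))
  })

  if (isTRUE(st$score)) run_stage("score", function() {
    scored <- score_de_table(state$de)
    ranked <- rank_genes(scored$gene, scored$score)
    calls <- call_differential(scored, cfg$thresholds$fc_threshold,
                               cfg$thresholds$q_threshold)
    utils::write.table(ranked, path("ranked_genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    state$ranked <- ranked
    state$calls <- calls
    emit("score", path("ranked_genes.tsv"),
         counts = list(genes_in = nrow(scored), up = length(calls$up),
                       down = length(calls$down)))
  })

  if (isTRUE(st$regulators)) run_stage("regulators", function() {
    mr <- master_regulators(state$de, state$edges,
                            fc_threshold = cfg$thresholds$fc_threshold,
                            q_threshold = cfg$thresholds$q_threshold)
    utils::write.table(format(mr$ranking, digits = 10),
                       path("regulator_ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    state$mr <- mr
    emit("regulators", path("regulator_ranking.tsv"),
         counts = list(tfs = mr$n_tfs, de_genes = mr$n_de_genes))
  })

  if (isTRUE(st$gsea)) run_stage("gsea", function() {
    res <- preranked_gsea_collection(state$ranked, state$sets,
                                     n_perm = cfg$gsea$n_perm,
                                     weight = cfg$gsea$weight,
                                     seed = cfg$seed)
    utils::write.table(format(res, digits = 10), path("gsea_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("gsea", path("gsea_results.tsv"), counts = list(sets = nrow(res)))
  })

  if (isTRUE(st$ssgsea)) run_stage("ssgsea", function() {
    expr <- prep_expression(state$expr)
    res <- ssgsea(expr, state$sets, alpha = cfg$gsea$alpha)
    utils::write.table(format(res, digits = 10), path("ssgsea_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("ssgsea", path("ssgsea_results.tsv"),
         counts = list(genes_kept = nrow(expr), scores = nrow(res)))
  })

  if (isTRUE(st$variants)) run_stage("variants", function() {
    fc <- filter_config(cfg$thresholds$min_coverage,
                        cfg$thresholds$min_tumour_vaf,
                        cfg$thresholds$max_normal_vaf,
                        cfg$thresholds$pathway_min_vaf,
                        cfg$thresholds$pathway_min_coverage)
    n_in <- sum(vapply(unlist(state$varsim$calls, recursive = FALSE), nrow,
                       integer(1)))
    cons <- unmatched_consensus(state$varsim$calls, state$varsim$blacklist)
    kept <- somatic_filter(cons, fc)
    write_variant_vcf(kept, path("somatic_consensus.vcf"))
    emit("variants", path("somatic_consensus.vcf"),
         counts = list(calls_in = n_in, consensus = nrow(cons),
                       filtered = nrow(kept)))
  })

  if (isTRUE(st$tssprofile)) run_stage("tssprofile", function() {
    win <- tss_windows(state$ann, state$depleted, cfg$tssprofile$flank)
    prof <- profile_density(state$coverage, win, cfg$tssprofile$bin_size)
    write_tss_profile(prof, path("tss_profile.tsv"))
    emit("tssprofile", path("tss_profile.tsv"),
         counts = list(genes = prof$n_genes, bins = length(prof$offset_bp)))
  })

  manifest$n_outputs <- length(outputs)
  yaml::write_yaml(manifest, file.path(cfg$outdir, "manifest.yaml"))
  invisible(manifest)
}
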