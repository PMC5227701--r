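#' Build a pipeline configuration
#'
#' @param output_dir directory for all stage outputs.
#' @param preset threshold preset, `"mouse-bm"` (FDR < 0.10, |dPSI| > 0.01)
#'   or `"human-cd34"` (FDR < 0.05, |dPSI| > 0.10).
#' @param seed integer seed forwarded to the simulator.
#' @param simulation named list of overrides for [simulation_config()].
#' @param min_mean_total expressed-event filter threshold.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate","quantify","diff","factorial","bias","context",
#'   "expression","report")`.
#' @param counts_path,samples_path,fasta_path optional external inputs used
#'   instead of simulation when the `simulate` stage is disabled.
#' @return List of class `PipelineConfig`.
#' @export
pipeline_config <- function(output_dir, preset = "mouse-bm", seed = 1L,
                            simulation = list(), min_mean_total = 10,
                            stages = c("simulate", "quantify", "diff",
                                       "factorial", "bias", "context",
                                       "expression", "report"),
                            counts_path = NULL, samples_path = NULL,
                            fasta_path = NULL) {
  known <- c("simulate", "quantify", "diff", "factorial", "bias", "context",
             "expression", "report")
  if (!all(stages %in% known))
    .stopf("unknown stage(s): %s", paste(setdiff(stages, known), collapse = ", "))
  thr <- threshold_preset(preset)
  structure(list(output_dir = output_dir, preset = preset, seed = as.integer(seed),
                 simulation = simulation, min_mean_total = min_mean_total,
                 stages = stages, thresholds = thr,
                 counts_path = counts_path, samples_path = samples_path,
                 fasta_path = fasta_path),
            class = "PipelineConfig")
}

#' Run the factorial splicing pipeline end to end
#'
#' simulate (or load) -> quantify PSI -> five differential-splicing
#' comparisons -> factorial classification, concordance and interaction
#' screen -> direction-bias tests -> acceptor-context analysis -> gene
#' expression -> report. Every stage writes deterministic tab-separated
#' outputs under `config$output_dir`, and a JSON manifest records the
#' config, seed, package version and MD5 of every output.
#'
#' @param config a `PipelineConfig`.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest path.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  out <- list()
  pth <- function(f) file.path(config$output_dir, f)
  st <- function(s) s %in% config$stages

  # -- simulate / load ----------------------------------------------------
  if (st("simulate")) {
    sim_cfg <- do.call(simulation_config,
                       utils::modifyList(list(seed = config$seed),
                                         config$simulation))
    ds <- simulate_factorial_experiment(sim_cfg)
    write_junction_table(ds$junction_counts, pth("junction_counts.tsv"),
                         pth("samples.tsv"))
    .write_tsv(ds$truth_events, pth("truth_events.tsv"))
    .write_tsv(ds$truth_genes, pth("truth_genes.tsv"))
    .write_tsv(data.frame(gene_id = rownames(ds$gene_counts),
                          ds$gene_counts, check.names = FALSE),
               pth("gene_counts.tsv"))
    write_context_fasta(ds$acceptor_sequences, pth("acceptor_contexts.fa"))
    out$dataset <- ds
    tbl <- ds$junction_counts
    contexts <- ds$acceptor_sequences
    gene_counts <- ds$gene_counts
    samples <- ds$samples
    say("simulate: %d events, %d genes, %d samples", nrow(tbl$events),
        nrow(gene_counts), nrow(samples))
  } else {
    tbl <- read_junction_table(config$counts_path, config$samples_path)
    contexts <- if (!is.null(config$fasta_path))
      read_context_fasta(config$fasta_path) else NULL
    gene_counts <- NULL
    samples <- tbl$samples
  }
  viol <- validate_inputs(tbl$events, samples, tbl$inclusion, tbl$skipping)
  if (length(viol)) .stopf("input validation failed: %s",
                           paste(viol, collapse = "; "))

  # -- quantify -----------------------------------------------------------
  if (st("quantify")) {
    tbl <- filter_expressed(tbl, config$min_mean_total)
    psi <- psi_matrix(tbl)
    .write_tsv(data.frame(event_id = rownames(psi), psi, check.names = FALSE),
               pth("psi_matrix.tsv"))
    out$psi <- psi
    say("quantify: %d events pass the coverage filter", nrow(psi))
  }

  thr <- config$thresholds
  # -- diff + factorial ---------------------------------------------------
  if (st("diff") || st("factorial")) {
    five <- run_five_comparisons(tbl)
    for (nm in names(.five_comparisons()))
      .write_tsv(five[[nm]], pth(sprintf("comparison_%s.tsv", nm)))
    out$five <- five
    say("diff: five comparisons over %d events", nrow(five$cumulative))
  }
  if (st("factorial")) {
    inter <- interaction_screen(tbl)
    .write_tsv(inter, pth("interaction.tsv"))
    cls <- classify_events(five, thr$fdr_max, thr$min_abs_dpsi,
                           interactions = inter)
    .write_tsv(cls, pth("classification.tsv"))
    both <- cls$drug_concordant | cls$drug_discordant
    conc <- if (sum(both) >= 3)
      concordance_regression(cls$dpsi_drug_WT[both], cls$dpsi_drug_MT[both])
    else NULL
    if (!is.null(conc))
      .write_tsv(data.frame(slope = conc$slope, intercept = conc$intercept,
                            r_squared = conc$r_squared,
                            f_test_p = conc$f_test_p,
                            n_events = conc$n_events),
                 pth("concordance_splicing.tsv"))
    traj <- trajectory_table(five, cls$event_id[cls$trajectory_eligible])
    .write_tsv(traj, pth("trajectories.tsv"))
    out$classification <- cls; out$interaction <- inter
    out$concordance_splicing <- conc; out$trajectories <- traj
    say("factorial: %d concordant, %d trajectory-eligible, %d interaction-significant",
        sum(cls$drug_concordant), sum(cls$trajectory_eligible),
        sum(cls$interaction_significant))
  }

  # -- direction bias -----------------------------------------------------
  if (st("bias")) {
    calls <- call_dysregulated(five$drug_in_WT, thr$fdr_max, thr$min_abs_dpsi)
    bias <- direction_bias_test(calls, "drug_in_WT")
    .write_tsv(bias, pth("direction_bias.tsv"))
    out$bias <- bias
    say("bias: SE %d/%d toward skipping (p=%.3g)", bias$n_toward[1],
        bias$n_total[1], bias$p_value[1])
  }

  # -- acceptor context ---------------------------------------------------
  if (st("context") && !is.null(contexts)) {
    res_mut <- compare_conditions(tbl, "MT.Veh", "WT.Veh")
    sets <- select_context_sets(res_mut, thr$fdr_max, thr$min_abs_dpsi,
                                ctrl_fdr_min = 0.5, ctrl_max_abs_dpsi = 0.001)
    se_ids <- tbl$events$event_id[tbl$events$event_type == "SE"]
    dys <- contexts[intersect(sets$dysregulated, se_ids)]
    ctl <- contexts[intersect(sets$control, se_ids)]
    if (length(dys) >= 1 && length(ctl) >= 1) {
      enr <- position_enrichment_test(dys, ctl, position = -3L)
      pfm_d <- build_pfm(dys); pfm_c <- build_pfm(ctl)
      .write_tsv(data.frame(position = pfm_d$positions,
                            ic_dysregulated = pfm_d$info_content,
                            ic_control = pfm_c$info_content,
                            t(pfm_d$freq), check.names = FALSE),
                 pth("pfm_dysregulated.tsv"))
      .write_tsv(data.frame(position = -3L, base = "T",
                            odds_ratio = enr$odds_ratio,
                            p_value = enr$p_value,
                            n_dys = length(dys), n_ctrl = length(ctl)),
                 pth("context_enrichment.tsv"))
      out$context <- list(enrichment = enr, pfm_dys = pfm_d, pfm_ctrl = pfm_c)
      say("context: -3 T enrichment OR=%.2f p=%.3g (%d vs %d SE events)",
          enr$odds_ratio, enr$p_value, length(dys), length(ctl))
    } else say("context: too few events for enrichment; skipped")
  }

  # -- expression ---------------------------------------------------------
  if (st("expression") && !is.null(gene_counts)) {
    sf <- estimate_size_factors(gene_counts)
    de_wt <- de_contrast(gene_counts, samples, "WT.Drug", "WT.Veh", sf)
    de_mt <- de_contrast(gene_counts, samples, "MT.Drug", "MT.Veh", sf)
    .write_tsv(de_wt, pth("de_drug_in_WT.tsv"))
    .write_tsv(de_mt, pth("de_drug_in_MT.tsv"))
    both <- !is.na(de_wt$fdr) & !is.na(de_mt$fdr) &
      de_wt$fdr < thr$fdr_max & de_mt$fdr < thr$fdr_max
    expr_conc <- if (sum(both) >= 3)
      expression_concordance(de_wt$log2_fold_change[both],
                             de_mt$log2_fold_change[both]) else NULL
    if (!is.null(expr_conc))
      .write_tsv(data.frame(slope = expr_conc$slope,
                            r_squared = expr_conc$r_squared,
                            f_test_p = expr_conc$f_test_p,
                            n_genes = expr_conc$n_events),
                 pth("concordance_expression.tsv"))
    out$de <- list(drug_in_WT = de_wt, drug_in_MT = de_mt,
                   concordance = expr_conc, size_factors = sf)
    say("expression: %d / %d DE calls (drug in WT / MT)",
        nrow(call_de_genes(de_wt)), nrow(call_de_genes(de_mt)))
  }

  # -- report -------------------------------------------------------------
  if (st("report")) {
    files <- setdiff(list.files(config$output_dir, full.names = TRUE),
                     pth("manifest.json"))
    manifest <- list(
      package = "spliceFactorial",
      version = as.character(utils::packageVersion("spliceFactorial")),
      seed = config$seed, preset = config$preset,
      thresholds = config$thresholds,
      min_mean_total = config$min_mean_total,
      simulation = config$simulation,
      stages = config$stages,
      outputs = as.list(tools::md5sum(files)))
    jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    out$manifest <- pth("manifest.json")
  }
  invisible(out)
}
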