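## End-to-end pipeline: simulate -> identify (per stage) -> PNP core
## extraction (per stage) -> stage comparison (consecutive pairs) ->
## signature-reversal drug scoring.  Fully deterministic given the seed.

#' Pipeline configuration
#'
#' Unknown arguments are rejected before any computation (R's argument
#' matching), and every parameter is range-checked here.
#'
#' @param sim a [sim_config()] describing the synthetic study.
#' @param energy_threshold PNP energy fraction in (0, 1].
#' @param K_protein,K_tf core-selection sizes.  The genome-scale analysis
#'   uses 3000 proteins and 300 TFs; the synthetic default is scaled to the
#'   simulated network.
#' @param quantile adaptive basal-shift threshold level.
#' @param alpha ANOVA significance level.
#' @param weight_hk housekeeping penalty weight for drug scoring.
#' @param n_drugs,k_drugs,effect_cutoff drug-scoring parameters.
#' @param drug_stage later stage whose signature (vs normal) is reversed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            energy_threshold = 0.85,
                            K_protein = 6L, K_tf = 2L,
                            quantile = 0.9, alpha = 0.05,
                            weight_hk = 1, n_drugs = 30L, k_drugs = 3L,
                            effect_cutoff = 0.3,
                            drug_stage = "advanced") {
  stopifnot(inherits(sim, "sim_config"),
            energy_threshold > 0, energy_threshold <= 1,
            K_protein >= 0, K_tf >= 0,
            quantile > 0, quantile < 1,
            alpha > 0, alpha < 1,
            weight_hk >= 0, n_drugs >= 2L, k_drugs >= 1L,
            effect_cutoff >= 0)
  drug_stage <- match.arg(drug_stage, STAGES[-1L])
  structure(list(sim = sim, energy_threshold = energy_threshold,
                 K_protein = as.integer(K_protein), K_tf = as.integer(K_tf),
                 quantile = quantile, alpha = alpha, weight_hk = weight_hk,
                 n_drugs = as.integer(n_drugs), k_drugs = as.integer(k_drugs),
                 effect_cutoff = effect_cutoff, drug_stage = drug_stage),
            class = "pipeline_config")
}

.log_line <- function(con, level, msg) {
  if (is.null(con)) return(invisible())
  writeLines(sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                     level, msg), con)
}

#' Run the full synthetic GEN pipeline
#'
#' Executes all steps in order, writing per-step TSV outputs, a
#' machine-readable `manifest.json` (parameters, seed, per-step counts,
#' edge-recovery scores vs the planted truth) and a timestamped
#' `pipeline.log` under `out_dir`.  All outputs except the log are
#' byte-identical across reruns with the same config.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return (invisibly) a list with all in-memory results: `ground_truth`,
#'   `candidate`, `stages`, `identified`, `cores`, `deltas`, `drug`
#'   (ranking + combination), `manifest`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(out_dir, "pipeline.log"), "w")
  on.exit(close(logcon), add = TRUE)
  step <- function(msg) .log_line(logcon, "INFO", msg)
  step(sprintf("pipeline start, seed=%d", cfg$sim$seed))

  ## 1. simulate
  step("simulate: ground truth + 4 stages + candidate with decoys")
  gt <- generate_ground_truth(cfg$sim)
  cand <- make_candidate_with_decoys(gt)
  stages <- simulate_study(gt)
  write_network_table(gt$network$edges, file.path(out_dir, "true_network.tsv"))
  ce <- cand$edges
  ce$is_decoy <- .edge_key(ce) %in% .edge_key(attr(cand, "decoys"))
  write_network_table(ce, file.path(out_dir, "candidate_network.tsv"))
  .write_df(cand$nodes, file.path(out_dir, "node_kinds.tsv"))
  for (st in STAGES) {
    write_matrix_tsv(stages[[st]]$expr,
                     file.path(out_dir, paste0("expr_", st, ".tsv")))
    write_matrix_tsv(stages[[st]]$methyl,
                     file.path(out_dir, paste0("methyl_", st, ".tsv")))
  }

  ## 2. identify per stage
  identified <- list()
  recovery <- list()
  for (st in STAGES) {
    step(paste("identify:", st))
    idn <- identify_stage(cand, stages[[st]])
    identified[[st]] <- idn
    recovery[[st]] <- score_edge_recovery(idn, gt$network)
    ab <- do.call(rbind, lapply(idn$estimates, function(e)
      if (length(e$abilities))
        data.frame(target = e$target, regulator = names(e$abilities),
                   ability = unname(e$abilities), stringsAsFactors = FALSE)))
    write_network_table(idn$pruned$edges,
                        file.path(out_dir, paste0("pruned_", st, ".tsv")),
                        node_table = basal_table(idn))
    if (!is.null(ab))
      .write_df(ab, file.path(out_dir, paste0("abilities_", st, ".tsv")))
  }

  ## 3. PNP core extraction per stage
  cores <- list()
  for (st in STAGES) {
    step(paste("pnp:", st))
    H <- assemble_ability_matrix(identified[[st]])
    scores <- project_network(H, cfg$energy_threshold)
    cores[[st]] <- extract_core(identified[[st]], scores,
                                cfg$K_protein, cfg$K_tf)
    .write_df(scores, file.path(out_dir, paste0("scores_", st, ".tsv")))
    .write_df(cores[[st]]$nodes, file.path(out_dir, paste0("core_nodes_", st, ".tsv")))
    write_network_table(cores[[st]]$edges,
                        file.path(out_dir, paste0("core_edges_", st, ".tsv")))
  }

  ## 4. consecutive stage comparison
  deltas <- list()
  for (i in seq_len(length(STAGES) - 1L)) {
    pair <- paste0(STAGES[i], "_to_", STAGES[i + 1L])
    step(paste("compare:", pair))
    d <- compare_stages(cores[[i]], cores[[i + 1L]],
                        identified[[i]], identified[[i + 1L]],
                        stages[[i]], stages[[i + 1L]],
                        alpha = cfg$alpha, quantile = cfg$quantile)
    deltas[[pair]] <- d
    .write_df(d$edge_status, file.path(out_dir, paste0("edges_", pair, ".tsv")))
    .write_df(d$de_table, file.path(out_dir, paste0("de_", pair, ".tsv")))
    flags <- data.frame(
      symbol = c(d$basal$methyl_flags, d$basal$ptm_flags),
      flag = c(rep("methylation", length(d$basal$methyl_flags)),
               rep("ptm", length(d$basal$ptm_flags))),
      stringsAsFactors = FALSE)
    .write_df(flags, file.path(out_dir, paste0("flags_", pair, ".tsv")))
  }

  ## 5. signature-reversal drug scoring (normal vs drug_stage)
  step(paste("drugscore: normal vs", cfg$drug_stage))
  de <- anova_annotate(stages$normal, stages[[cfg$drug_stage]], cfg$alpha)
  genes <- gt$network$nodes$symbol[gt$network$nodes$kind == "gene"]
  de <- de[de$symbol %in% genes, , drop = FALSE]
  up <- de$symbol[de$direction == "lower_in_later"]    # activate
  dn <- de$symbol[de$direction == "higher_in_later"]   # repress
  hk <- de$symbol[de$direction == "ns"]
  drug <- NULL
  if (length(up) || length(dn)) {
    spec <- signature_spec(up, dn, hk, cfg$weight_hk)
    C <- simulate_correlations(genes, spec, cfg$n_drugs, cfg$sim$seed)
    ranking <- score_drugs(C, spec)
    combo <- select_combination(ranking, C, spec, cfg$k_drugs,
                                cfg$effect_cutoff)
    .write_df(ranking, file.path(out_dir, "drug_ranking.tsv"))
    drug <- list(ranking = ranking, combination = combo, spec = spec)
  } else step("drugscore skipped: no differential genes")

  manifest <- list(
    package_version = as.character(utils::packageVersion("gennet")),
    seed = cfg$sim$seed,
    parameters = list(
      nodes = c(protein = cfg$sim$n_protein, tf = cfg$sim$n_tf,
                gene = cfg$sim$n_gene, mirna = cfg$sim$n_mirna,
                lncrna = cfg$sim$n_lncrna),
      n_samples = cfg$sim$n_samples,
      noise_sd = as.list(cfg$sim$noise_sd),
      decoy_fraction = cfg$sim$decoy_fraction,
      energy_threshold = cfg$energy_threshold,
      K_protein = cfg$K_protein, K_tf = cfg$K_tf,
      quantile = cfg$quantile, alpha = cfg$alpha,
      weight_hk = cfg$weight_hk),
    counts = list(
      true_edges = nrow(gt$network$edges),
      candidate_edges = nrow(cand$edges),
      pruned_edges = lapply(identified, function(i) nrow(i$pruned$edges)),
      core_nodes = lapply(cores, function(cc) nrow(cc$nodes)),
      core_edges = lapply(cores, function(cc) nrow(cc$edges))),
    edge_recovery = recovery,
    drug_combination = if (!is.null(drug)) drug$combination else character(0))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  step("pipeline done")

  invisible(list(ground_truth = gt, candidate = cand, stages = stages,
                 identified = identified, cores = cores, deltas = deltas,
                 drug = drug, manifest = manifest))
}
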