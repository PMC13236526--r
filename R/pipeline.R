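#' Run the full pipeline on synthetic data
#'
#' Simulates a panel, cohort, atlas, and gene-set/regulon collections from
#' one master seed, runs discovery, robustness, cohort validation, the
#' survival suite, signature projection, the correlation landscape, GSEA,
#' and regulon scoring, and writes every result as TSV/JSON under
#' `out_dir`. Deterministic: the same seed yields byte-identical outputs.
#'
#' @param out_dir output directory (created).
#' @param seed master seed; sub-seeds are fixed offsets below 2^31.
#' @param n_lines,n_drugs,n_genes panel scale.
#' @param n_samples cohort scale.
#' @return invisible list of in-memory results.
#' @export
run_pipeline <- function(out_dir, seed = 1, n_lines = 15, n_drugs = 120,
                         n_genes = 300, n_samples = 400) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- panel: two planted co-dependencies at the discovery scale ---
  planted <- list(
    planted_interaction(1, 1, 2, beta_on = 0.96,
                        target_partial_rho = -0.8, noise_sd = 1),
    planted_interaction(2, 3, 4, beta_on = 0.96,
                        target_partial_rho = -0.75, noise_sd = 1)
  )
  panel <- simulate_panel(panel_spec(
    n_lines = n_lines, n_genes = n_genes, n_drugs = n_drugs,
    planted = planted, noise_sd = 1, seed = seed
  ))
  write_panel(panel, file.path(out_dir, "panel"))

  interactions <- run_discovery(panel)
  if (!nrow(interactions)) {
    # Nothing passed the stringent retention thresholds at this desk scale:
    # follow up the strongest candidates by delta_r2 instead (flagged).
    tested <- attr(interactions, "all_tested")
    interactions <- utils::head(tested[order(-tested$delta_r2,
                                             tested$drug_id,
                                             tested$co_target), ], 5)
    interactions$perm_p <- rep(NA_real_, nrow(interactions))
    interactions$lolo_fraction <- rep(NA_real_, nrow(interactions))
    interactions$specificity_p <- rep(NA_real_, nrow(interactions))
    interactions$retained <- FALSE
  } else {
    interactions$retained <- TRUE
  }
  interactions <- run_robustness(panel, interactions, seed = seed + 1000L)
  write_result_tsv(interactions, file.path(out_dir, "interactions.tsv"))
  jsonlite::write_json(attr(interactions, "metadata"),
                       file.path(out_dir, "discovery_metadata.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- cohort: planted expression-drug effects and survival signal ---
  cohort <- simulate_cohort(cohort_spec(
    n_samples = n_samples, n_genes = 150,
    expression_drug_effects = list(
      list(gene = "ACSL4", drug = "dasatinib", target_r = -0.25),
      list(gene = "ACSL4", drug = "venetoclax", target_r = 0.36)
    ),
    signature_genes = c("SRC", "ACSL4"), true_log_hr = log(1.27),
    censoring_rate = 0.3,
    mutation_genes = list(
      list(gene = "IDH1", prevalence = 0.08, lp_shift = -0.9),
      list(gene = "FLT3", prevalence = 0.25, lp_shift = 0)
    ),
    n_drugs = 6, seed = seed + 2000L
  ))
  write_cohort(cohort, file.path(out_dir, "cohort"))

  mapping <- stats::setNames("dasatinib", interactions$drug_id[1])
  # Validate the discovered interactions against the cohort, rewiring the
  # co-target to the cohort's planted gene pair for the mapped drug.
  val_input <- data.frame(drug_id = interactions$drug_id[1],
                          co_target = "ACSL4", on_target = "SRC",
                          stringsAsFactors = FALSE)
  validation <- run_validation(cohort, val_input, mapping)
  write_result_tsv(validation, file.path(out_dir, "validation.tsv"))

  # --- survival suite ---
  lp <- compute_lp(cohort$expression, c("SRC", "ACSL4"))
  grp <- median_split(lp)
  km <- km_estimate(cohort$clinical$os_days, cohort$clinical$os_event, grp)
  km_df <- do.call(rbind, lapply(km, function(cv) {
    data.frame(group = unname(cv$label), time = unname(cv$times),
               survival = unname(cv$survival), at_risk = unname(cv$at_risk),
               stringsAsFactors = FALSE)
  }))
  write_result_tsv(km_df, file.path(out_dir, "km_curves.tsv"))
  lr <- logrank_test(cohort$clinical$os_days, cohort$clinical$os_event, grp)
  suite <- multivariable_suite(cohort, lp)
  suite_df <- do.call(rbind, lapply(names(suite), function(nm) {
    cf <- suite[[nm]]$coefficients
    cbind(model = nm, n = suite[[nm]]$n, n_events = suite[[nm]]$n_events, cf)
  }))
  write_result_tsv(suite_df, file.path(out_dir, "cox_models.tsv"))
  auc_t <- timedep_auc(cohort$clinical$os_days, cohort$clinical$os_event,
                       lp$scores, horizons = c(1, 2, 3))
  write_result_tsv(auc_t, file.path(out_dir, "timedep_auc.tsv"))
  jsonlite::write_json(list(logrank_chi2 = lr$chi2, logrank_p = lr$p_value),
                       file.path(out_dir, "logrank.json"),
                       auto_unbox = TRUE, digits = NA)
  contrasts <- mutation_contrast(lp$scores, cohort$mutations)
  write_result_tsv(contrasts, file.path(out_dir, "mutation_contrasts.tsv"))

  # --- atlas projection ---
  atlas <- simulate_atlas(atlas_spec(
    cell_types = c(cd14_mono = 250, ery_prog = 250, hsc = 250, lymphoid = 250),
    enriched_type = "cd14_mono", enrichment_shift = 3, n_genes = 40,
    seed = seed + 3000L
  ))
  write_atlas(atlas, file.path(out_dir, "atlas"))
  proj <- project_signature(atlas, c("SRC", "ACSL4"))
  write_result_tsv(proj$type_means, file.path(out_dir, "atlas_projection.tsv"))

  # --- landscape, GSEA, regulons ---
  ls <- landscape(cohort$expression, lp)
  write_result_tsv(ls, file.path(out_dir, "landscape.tsv"))
  top_corr <- ls$gene[!ls$tautological][1:30]
  collections <- simulate_gene_sets(
    universe = rownames(cohort$expression), n_sets = 12, set_size = 15,
    n_true_enriched = 2, correlated_genes = top_corr,
    n_regulons = 8, regulon_size = 12, n_true_regulons = 2,
    seed = seed + 4000L
  )
  write_gmt(collections$gene_sets, file.path(out_dir, "gene_sets.gmt"))
  write_regulons(collections$regulons, file.path(out_dir, "regulons.tsv"))
  ranked <- rank_metric(cohort$expression, lp)
  gsea <- gsea_preranked(ranked, collections$gene_sets, n_perm = 200,
                         seed = seed + 5000L)
  write_result_tsv(gsea, file.path(out_dir, "gsea.tsv"))
  act <- regulon_activity(cohort$expression, collections$regulons)
  tf_table <- correlate_activity(act, lp)
  write_result_tsv(tf_table, file.path(out_dir, "regulon_correlations.tsv"))

  invisible(list(
    panel = panel, interactions = interactions, cohort = cohort,
    validation = validation, lp = lp, km = km, logrank = lr, suite = suite,
    timedep_auc = auc_t, mutation_contrasts = contrasts, projection = proj,
    landscape = ls, gsea = gsea, regulon_correlations = tf_table
  ))
}
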