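# Generators: determinism, planted-effect calibration, manifests.

test_that("panel generation is deterministic and carries a truth manifest", {
  p1 <- planted_panel(seed = 3)
  p2 <- planted_panel(seed = 3)
  expect_identical(p1$auc, p2$auc)
  expect_identical(p1$dependency, p2$dependency)
  truth <- attr(p1, "truth")
  expect_equal(truth$planted[[1]]$co_target, "G00002")
  expect_equal(truth$planted[[1]]$target_partial_rho, -0.8)
  # a different seed changes the data
  expect_false(identical(p1$auc, planted_panel(seed = 4)$auc))
})

test_that("panel spec validation rejects bad inputs", {
  expect_error(panel_spec(n_lines = 3), class = "validation_error")
  expect_error(planted_interaction(1, 2, 2, beta_co = 1),
               class = "validation_error")
  expect_error(
    panel_spec(n_drugs = 2, n_genes = 5,
               planted = list(planted_interaction(3, 1, 2, beta_co = 1))),
    class = "validation_error"
  )
})

test_that("noise-free planted panel gives combined R2 = 1 and the analytic share", {
  panel <- noise_free_panel(seed = 5)
  fit <- fit_combined_model(panel, "D0001", "G00002")
  expect_equal(fit$r2_combo, 1, tolerance = 1e-10)
  # delta equals the variance share left after the on-target-only oracle fit
  o <- oracle_ols(panel$auc["D0001", ], panel$dependency["G00001", ])
  expect_equal(fit$delta_r2, 1 - o$r2, tolerance = 1e-10)
})

test_that("beta_co_for_partial_rho inverts the population partial correlation", {
  # large-n check: the generated data's partial correlation approaches target
  rho <- -0.8
  panel <- simulate_panel(panel_spec(
    n_lines = 4000, n_genes = 3, n_drugs = 1,
    planted = list(planted_interaction(1, 1, 2, beta_on = 0.96,
                                       target_partial_rho = rho)),
    noise_sd = 1, seed = 8
  ))
  got <- fit_combined_model(panel, "D0001", "G00002",
                            method = "pearson")$partial_rho
  expect_equal(got, rho, tolerance = 0.03)
})

test_that("cohort expression-drug coupling hits its target correlation", {
  # planted r = -0.25 at n = 476: sample r within +/-0.08 across seeds
  rs <- vapply(1:100, function(s) {
    cohort <- simulate_cohort(cohort_spec(
      n_samples = 476, n_genes = 5,
      expression_drug_effects = list(
        list(gene = "ACSL4", drug = "dasatinib", target_r = -0.25)
      ),
      seed = s
    ))
    cor(cohort$expression["ACSL4", ], cohort$drug_auc["dasatinib", ])
  }, numeric(1))
  # sampling sd of r at n = 476 is ~0.043, so the (-0.33, -0.17) band is a
  # ~1.9-sigma interval: demand the bulk inside it and an unbiased center
  expect_gte(sum(rs > -0.33 & rs < -0.17), 85)
  expect_lt(abs(mean(rs) + 0.25), 0.02)
})

test_that("cohort censoring machinery honors the requested rate", {
  none <- simulate_cohort(cohort_spec(n_samples = 100, n_genes = 5,
                                      censoring_rate = 0, seed = 2))
  expect_true(all(none$clinical$os_event == 1))
  some <- simulate_cohort(cohort_spec(n_samples = 4000, n_genes = 5,
                                      censoring_rate = 0.4, seed = 2))
  expect_equal(mean(some$clinical$os_event == 0), 0.4, tolerance = 0.05)
})

test_that("null cohorts give null Cox estimates at the stated rate", {
  inside <- vapply(1:100, function(s) {
    cohort <- simulate_cohort(cohort_spec(n_samples = 500, n_genes = 4,
                                          true_log_hr = 0,
                                          censoring_rate = 0.2, seed = s))
    lp <- compute_lp(cohort$expression, c("SRC", "ACSL4"))
    cf <- cox_fit(cohort$clinical$os_days, cohort$clinical$os_event,
                  data.frame(lp = lp$scores))$coefficients
    abs(cf$beta) < 2 * cf$se
  }, logical(1))
  expect_gte(sum(inside), 90)
})

test_that("cohort mutations carry their planted LP shift and prevalence", {
  cohort <- simulate_cohort(cohort_spec(
    n_samples = 2000, n_genes = 6,
    mutation_genes = list(list(gene = "IDH1", prevalence = 0.08,
                               lp_shift = -0.9)),
    seed = 4
  ))
  calls <- cohort$mutations["IDH1", ]
  expect_lt(abs(mean(calls) - 0.08), 0.02)
  lp <- compute_lp(cohort$expression, c("SRC", "ACSL4"))
  shift <- median(lp$scores[calls == 1]) - median(lp$scores[calls == 0])
  expect_equal(shift, -0.9, tolerance = 0.25)
})

test_that("atlas generator plants the enrichment where asked, and nowhere else", {
  null_atlas <- simulate_atlas(atlas_spec(
    cell_types = c(a = 250, b = 250, c = 250), enriched_type = "a",
    enrichment_shift = 0, n_genes = 10, seed = 5
  ))
  proj <- project_signature(null_atlas, c("SRC", "ACSL4"))
  expect_true(all(abs(proj$type_means$mean_score) < 0.3))
  shifted <- simulate_atlas(atlas_spec(
    cell_types = c(a = 300, b = 300, c = 300), enriched_type = "b",
    enrichment_shift = 3, n_genes = 10, seed = 5
  ))
  proj2 <- project_signature(shifted, c("SRC", "ACSL4"))
  expect_equal(proj2$top_type, "b")
  # analytic mean: 2 genes, shift d, enriched fraction f, pooled sd
  f <- 1 / 3; d <- 3
  expected <- 2 * d * (1 - f) / sqrt(1 + f * (1 - f) * d^2)
  expect_equal(proj2$type_means$mean_score[1], expected, tolerance = 0.5)
  expect_identical(simulate_atlas(atlas_spec(seed = 9))$expression,
                   simulate_atlas(atlas_spec(seed = 9))$expression)
})

test_that("gene-set generator is deterministic and plants true sets", {
  universe <- sprintf("GENE%03d", 1:100)
  corr <- universe[1:25]
  c1 <- simulate_gene_sets(universe, n_sets = 8, set_size = 10,
                           n_true_enriched = 2, correlated_genes = corr,
                           seed = 3)
  c2 <- simulate_gene_sets(universe, n_sets = 8, set_size = 10,
                           n_true_enriched = 2, correlated_genes = corr,
                           seed = 3)
  expect_identical(c1, c2)
  expect_equal(c1$truth$true_sets, c("SET_001", "SET_002"))
  expect_true(all(c1$gene_sets$SET_001 %in% corr))
  expect_error(simulate_gene_sets(universe, set_size = 3),
               class = "validation_error")
})

test_that("panel/cohort/atlas round-trip through their TSV formats", {
  dir <- withr::local_tempdir()
  panel <- planted_panel(seed = 12, n_genes = 20, n_drugs = 5)
  write_panel(panel, file.path(dir, "panel"))
  expect_true(file.exists(file.path(dir, "panel", "truth.json")))
  back <- read_panel(file.path(dir, "panel"))
  expect_equal(back$auc, panel$auc, tolerance = 1e-12)
  expect_identical(back$annotations, panel$annotations)

  cohort <- toy_cohort(seed = 13, n = 30)
  write_cohort(cohort, file.path(dir, "cohort"))
  back_c <- read_cohort(file.path(dir, "cohort"))
  expect_equal(back_c$expression, cohort$expression, tolerance = 1e-12)
  expect_equal(back_c$clinical$os_days, cohort$clinical$os_days,
               tolerance = 1e-6)

  atlas <- simulate_atlas(atlas_spec(cell_types = c(x = 10, y = 10),
                                     enriched_type = "x", n_genes = 6,
                                     seed = 14))
  write_atlas(atlas, file.path(dir, "atlas"))
  back_a <- read_atlas(file.path(dir, "atlas"))
  expect_equal(back_a$expression, atlas$expression, tolerance = 1e-12)
  expect_identical(back_a$cell_type, atlas$cell_type)
})
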