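# Ex vivo validation in a primary-specimen cohort.

planted_validation_cohort <- function(seed, n = 476) {
  simulate_cohort(cohort_spec(
    n_samples = n, n_genes = 30,
    expression_drug_effects = list(
      list(gene = "ACSL4", drug = "dasatinib", target_r = -0.25),
      list(gene = "ACSL4", drug = "venetoclax", target_r = 0.36)
    ),
    n_drugs = 8, seed = seed
  ))
}

test_that("map_drug_analogs validates against the cohort drug panel", {
  cohort <- planted_validation_cohort(seed = 51, n = 50)
  m <- map_drug_analogs(data.frame(discovery = "AZM-475271",
                                   cohort = "dasatinib"), cohort)
  expect_identical(m, c(`AZM-475271` = "dasatinib"))
  expect_warning(m0 <- map_drug_analogs(data.frame(a = character(),
                                                   b = character()), cohort))
  expect_length(m0, 0)
  expect_error(
    map_drug_analogs(data.frame(a = "x", b = "no_such_drug"), cohort),
    class = "mapping_error"
  )
})

test_that("validate_interaction recovers a planted effect and rejects nulls", {
  hits <- 0L; null_safe <- 0L
  for (s in 1:100) {
    cohort <- planted_validation_cohort(seed = s)
    recs <- data.frame(
      drug_id = c("dasatinib", "drug001"),
      co_target = c("ACSL4", "GENE00003"),
      on_target = c("SRC", "GENE00004"),
      stringsAsFactors = FALSE
    )
    out <- run_validation(cohort, recs,
                          stats::setNames(recs$drug_id, recs$drug_id))
    planted <- out[out$drug_id == "dasatinib", ]
    nullrow <- out[out$drug_id == "drug001", ]
    if (planted$r_unadjusted > -0.33 && planted$r_unadjusted < -0.17 &&
        isTRUE(planted$significant)) hits <- hits + 1L
    if (!isTRUE(nullrow$significant)) null_safe <- null_safe + 1L
  }
  # per-seed P(r in the ~1.9-sigma band) is ~0.94 and P(null q >= 0.05) is
  # ~0.95 by construction, so the counts are held to bounds the stated world
  # can actually meet (the planted partial-p itself is ~1e-7, so the
  # significance half essentially never fails)
  expect_gte(hits, 85)
  expect_gte(null_safe, 88)
})

test_that("a duplicated co/on-target is flagged but retained", {
  cohort <- planted_validation_cohort(seed = 52, n = 60)
  cohort$expression["SRC", ] <- cohort$expression["ACSL4", ]
  out <- validate_interaction(cohort, "dasatinib", "ACSL4", "SRC")
  expect_equal(out$error_code, "degenerate_partial")
  expect_true(is.na(out$partial_estimate))
  expect_false(is.na(out$r_unadjusted))
  expect_error(validate_interaction(cohort, "dasatinib", "NOPE", "SRC"),
               class = "gene_not_found_error")
})

test_that("partial Pearson equals the joint-model implied partial correlation", {
  for (s in 1:100) {
    cohort <- planted_validation_cohort(seed = 400 + s, n = 40)
    out <- validate_interaction(cohort, "dasatinib", "ACSL4", "SRC")
    # re-derive from the joint model's t statistic: r = t / sqrt(t^2 + df)
    auc <- cohort$drug_auc["dasatinib", ]
    fit <- lm(auc ~ scale(cohort$expression["ACSL4", ]) +
                scale(cohort$expression["SRC", ]))
    tval <- summary(fit)$coefficients[2, "t value"]
    df <- fit$df.residual
    expect_equal(out$partial_pearson, tval / sqrt(tval^2 + df),
                 tolerance = 1e-8)
  }
})

test_that("coef_joint is invariant to affine rescaling of raw expression", {
  cohort <- planted_validation_cohort(seed = 53, n = 100)
  out1 <- validate_interaction(cohort, "dasatinib", "ACSL4", "SRC")
  cohort$expression["ACSL4", ] <- 100 * cohort$expression["ACSL4", ] - 7
  cohort$expression["SRC", ] <- 0.01 * cohort$expression["SRC", ] + 2
  out2 <- validate_interaction(cohort, "dasatinib", "ACSL4", "SRC")
  expect_equal(out1$coef_joint, out2$coef_joint, tolerance = 1e-10)
  expect_equal(out1$partial_pearson, out2$partial_pearson, tolerance = 1e-10)
})

test_that("quartile_contrast partitions samples and detects monotone effects", {
  cohort <- planted_validation_cohort(seed = 54, n = 200)
  # strictly decreasing AUC in expression
  cohort$drug_auc["drug002", ] <- 20 - 2 * cohort$expression["ACSL4", ]
  qc <- quartile_contrast(cohort, "ACSL4", "drug002")
  expect_lt(qc$q4_mean, qc$q1_mean)
  expect_lt(qc$p_value, 1e-6)
  expect_equal(sum(qc$n_per_quartile), 200)
  # n = 40 gives exactly 10 per quartile
  small <- planted_validation_cohort(seed = 55, n = 40)
  expect_equal(quartile_contrast(small, "ACSL4", "dasatinib")$n_per_quartile,
               rep(10L, 4))
  expect_error(quartile_contrast(small, "ACSL4", "dasatinib", test = "t"), NA)
  tiny <- planted_validation_cohort(seed = 56, n = 30)
  expect_error(quartile_contrast(tiny, "ACSL4", "dasatinib"),
               class = "insufficient_data_error")
})

test_that("quartile_contrast p-values are uniform under the null", {
  ps <- vapply(1:200, function(s) {
    cohort <- simulate_cohort(cohort_spec(n_samples = 100, n_genes = 4,
                                          n_drugs = 2, seed = 9000 + s))
    quartile_contrast(cohort, "SRC", "drug001")$p_value
  }, numeric(1))
  # rank-sum p-values are mildly discrete, so ties trigger a benign ks.test
  # warning
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("negative_control_panel flags the focal drug appropriately", {
  strongest <- vapply(1:100, function(s) {
    cohort <- planted_validation_cohort(seed = 600 + s)
    attr(negative_control_panel(cohort, "ACSL4", "dasatinib",
                                paste0("drug00", 1:5)), "focal_strongest")
  }, logical(1))
  expect_gte(sum(strongest), 95)

  # gene loaded on the controls more strongly than on the focal drug:
  # the focal association cannot be the strongest
  cohort <- planted_validation_cohort(seed = 57)
  set.seed(570)
  shared <- rnorm(ncol(cohort$drug_auc))
  cohort$expression["GENE00001", ] <- shared
  ctrl <- paste0("drug00", 1:5)
  cohort$drug_auc[ctrl, ] <- cohort$drug_auc[ctrl, ] +
    2 * rep(shared, each = length(ctrl))
  cohort$drug_auc["dasatinib", ] <- cohort$drug_auc["dasatinib", ] + 0.5 * shared
  out <- negative_control_panel(cohort, "GENE00001", "dasatinib", ctrl)
  expect_false(attr(out, "focal_strongest"))
  expect_error(negative_control_panel(cohort, "ACSL4", "dasatinib",
                                      character()),
               class = "config_error")
})

test_that("resistance_correlation is antisymmetric and finds the planted r", {
  rs <- vapply(1:50, function(s) {
    cohort <- planted_validation_cohort(seed = 800 + s)
    resistance_correlation(cohort, "ACSL4", "venetoclax")$estimate
  }, numeric(1))
  expect_true(all(rs > 0.26 & rs < 0.46))
  cohort <- planted_validation_cohort(seed = 58)
  r1 <- resistance_correlation(cohort, "ACSL4", "venetoclax")
  cohort$drug_auc["venetoclax", ] <- -cohort$drug_auc["venetoclax", ]
  r2 <- resistance_correlation(cohort, "ACSL4", "venetoclax")
  expect_equal(r1$estimate, -r2$estimate, tolerance = 1e-12)
  cohort$expression["GENE00002", ] <- 5
  expect_error(resistance_correlation(cohort, "GENE00002", "venetoclax"),
               class = "degenerate_input_error")
})
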