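# LP construction, KM/log-rank, Cox (vs the survival package as oracle),
# time-dependent AUC, mutation contrasts.

test_that("compute_lp matches hand-computed z-scores and is affine-invariant", {
  expr <- rbind(
    SRC = c(1, 2, 3, 4, 5),
    ACSL4 = c(10, 10, 20, 30, 30)
  )
  colnames(expr) <- paste0("s", 1:5)
  lp <- compute_lp(expr, c("SRC", "ACSL4"))
  z1 <- (expr["SRC", ] - 3) / sd(expr["SRC", ])
  z2 <- (expr["ACSL4", ] - 20) / sd(expr["ACSL4", ])
  expect_equal(lp$scores, z1 + z2, tolerance = 1e-12)
  expect_lt(abs(mean(lp$scores)), 1e-10)
  expr2 <- expr
  expr2["SRC", ] <- 12 * expr2["SRC", ] - 4
  expect_equal(compute_lp(expr2, c("SRC", "ACSL4"))$scores, lp$scores,
               tolerance = 1e-10)
  expect_error(compute_lp(expr, c("SRC", "MISSING")),
               class = "gene_not_found_error")
  expr["SRC", ] <- 2
  expect_error(compute_lp(expr, c("SRC", "ACSL4")),
               class = "degenerate_input_error")
})

test_that("median_split follows the tie-to-low rule", {
  s140 <- stats::setNames(seq_len(140) + 0.5, paste0("s", 1:140))
  g <- median_split(s140)
  expect_equal(as.vector(table(g)), c(70, 70))
  g5 <- median_split(c(a = 1, b = 2, c = 3, d = 4, e = 5))
  expect_equal(sum(g5 == "high"), 2)
  expect_equal(sum(g5 == "low"), 3)
  expect_warning(median_split(rep(1, 6)), class = "degenerate_split_warning")
})

test_that("km_estimate matches the hand product-limit oracle exactly", {
  times <- c(3, 5, 5, 8, 10, 12)
  events <- c(1, 1, 0, 1, 0, 1)
  km <- km_estimate(times, events)[[1]]
  o <- oracle_km(times, events)
  expect_identical(km$times, o$times)
  expect_equal(km$survival, o$survival, tolerance = 1e-15)
  # hand values: S(3)=5/6, S(5)=5/6*4/5=2/3, S(8)=2/3*2/3=4/9, S(12)=0
  expect_equal(km$survival, c(5 / 6, 2 / 3, 4 / 9, 0), tolerance = 1e-12)
  expect_true(all(diff(km$survival) <= 0))
  # no censoring: KM equals the empirical survival function
  set.seed(61)
  tt <- rexp(40)
  km2 <- km_estimate(tt, rep(1, 40))[[1]]
  emp <- vapply(km2$times, function(u) mean(tt > u), numeric(1))
  expect_equal(km2$survival, emp, tolerance = 1e-12)
})

test_that("logrank_test handles identical groups, relabeling, and no events", {
  times <- c(3, 5, 5, 8, 10, 12)
  events <- c(1, 1, 0, 1, 0, 1)
  dup <- logrank_test(rep(times, 2), rep(events, 2),
                      rep(c("a", "b"), each = 6))
  expect_equal(dup$chi2, 0, tolerance = 1e-12)
  expect_equal(dup$p_value, 1)
  set.seed(62)
  t2 <- rexp(60); e2 <- rbinom(60, 1, 0.8)
  grp <- rep(c("x", "y"), 30)
  a <- logrank_test(t2, e2, grp)
  b <- logrank_test(t2, e2, ifelse(grp == "x", "y", "x"))
  expect_equal(a$chi2, b$chi2, tolerance = 1e-12)
  expect_error(logrank_test(t2, rep(0, 60), grp), class = "no_events_error")
  expect_error(logrank_test(t2, e2, rep("x", 60)), class = "group_error")
})

test_that("logrank_test agrees with the survival package", {
  skip_if_not_installed("survival")
  set.seed(63)
  tt <- rexp(120); ee <- rbinom(120, 1, 0.7)
  gg <- sample(c("a", "b"), 120, replace = TRUE)
  got <- logrank_test(tt, ee, gg)
  want <- survival::survdiff(survival::Surv(tt, ee) ~ gg)
  expect_equal(got$chi2, want$chisq, tolerance = 1e-8)
})

test_that("cox_fit matches the survival package on a tied two-covariate set", {
  skip_if_not_installed("survival")
  set.seed(64)
  n <- 150
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
  tt <- ceiling(rexp(n, exp(0.5 * x1 - 0.7 * x2)) * 20)  # heavy ties
  ee <- rbinom(n, 1, 0.75)
  got <- cox_fit(tt, ee, data.frame(x1 = x1, x2 = x2))
  want <- survival::coxph(survival::Surv(tt, ee) ~ x1 + x2, ties = "efron")
  expect_equal(got$coefficients$beta, unname(coef(want)), tolerance = 1e-6)
  expect_equal(got$coefficients$se,
               unname(sqrt(diag(want$var))), tolerance = 1e-6)
  expect_true(all(got$coefficients$ci_low <= got$coefficients$hazard_ratio))
  expect_true(all(got$coefficients$ci_high >= got$coefficients$hazard_ratio))
})

test_that("cox_fit raises typed errors on separation and tiny event counts", {
  set.seed(65)
  n <- 40
  x <- c(rep(0, 20), rep(1, 20))
  tt <- c(rexp(20, 10), rexp(20, 0.01) + 10)  # complete separation
  expect_error(cox_fit(tt, rep(1, n), data.frame(x = x)),
               class = "separation_error")
  expect_error(cox_fit(rexp(6), c(1, 1, 1, 0, 0, 0),
                       data.frame(x = rnorm(6))),
               class = "insufficient_data_error")
})

test_that("multivariable_suite fits the adjusted ladder with per-model n", {
  cohort <- simulate_cohort(cohort_spec(
    n_samples = 250, n_genes = 10, true_log_hr = log(1.27),
    censoring_rate = 0.25,
    mutation_genes = list(
      list(gene = "FLT3", prevalence = 0.25, lp_shift = 0),
      list(gene = "NPM1", prevalence = 0.3, lp_shift = 0),
      list(gene = "TP53", prevalence = 0.1, lp_shift = 0),
      list(gene = "IDH1", prevalence = 0.08, lp_shift = 0),
      list(gene = "IDH2", prevalence = 0.1, lp_shift = 0)
    ),
    seed = 66
  ))
  lp <- compute_lp(cohort$expression, c("SRC", "ACSL4"))
  suite <- multivariable_suite(cohort, lp)
  expect_named(suite, c("lp_only", "lp_age", "lp_age_cyto", "lp_age_mut3",
                        "lp_age_mut5"))
  ns <- vapply(suite, `[[`, 0L, "n")
  expect_true(all(diff(ns) <= 0))      # n never grows down the ladder
  expect_equal(unname(ns[1]), 250)     # zero-missingness keeps full n
  # independent covariates leave the LP HR within 1 SE across the ladder
  lp_rows <- lapply(suite, function(f) f$coefficients[f$coefficients$term == "lp", ])
  betas <- vapply(lp_rows, `[[`, 0, "beta")
  ses <- vapply(lp_rows, `[[`, 0, "se")
  expect_true(all(abs(betas - betas[1]) <= ses[1] + ses))
  # a mutation with no variance after subsetting is dropped with a warning
  # (raised once per ladder model that includes it)
  cohort$mutations["TP53", ] <- 0L
  w <- capture_warnings(multivariable_suite(cohort, lp))
  expect_true(any(grepl("constant covariate", w)))
})

test_that("timedep_auc is exact for perfect markers and null near 0.5", {
  set.seed(67)
  n <- 300
  tt <- rexp(n, 1 / 800)
  perfect <- timedep_auc(tt, rep(1, n), -tt, horizons = c(1, 2))
  expect_equal(perfect$auc, c(1, 1))
  cohort <- toy_cohort(seed = 68, n = 1000, log_hr = 0)
  null_auc <- timedep_auc(cohort$clinical$os_days, cohort$clinical$os_event,
                          rnorm(1000), horizons = c(1, 2))
  expect_true(all(null_auc$auc > 0.45 & null_auc$auc < 0.55))
  expect_error(timedep_auc(tt, rep(1, n), -tt, horizons = 50),
               class = "horizon_error")
})

test_that("timedep_auc is rank-invariant and additive markers help", {
  cohort <- toy_cohort(seed = 69, n = 500)
  lp <- compute_lp(cohort$expression, c("SRC", "ACSL4"))$scores
  a1 <- timedep_auc(cohort$clinical$os_days, cohort$clinical$os_event, lp,
                    horizons = c(1, 2, 3))
  a2 <- timedep_auc(cohort$clinical$os_days, cohort$clinical$os_event,
                    exp(lp / 2), horizons = c(1, 2, 3))
  expect_equal(a1$auc, a2$auc, tolerance = 1e-12)

  # marker + age when both carry signal: combined at least as good
  wins <- 0L
  for (s in 1:100) {
    n <- 400
    set.seed(7000 + s)
    m <- rnorm(n); age <- rnorm(n)
    risk <- 0.5 * m + 0.5 * age
    tt <- rexp(n, (1 / 800) * exp(risk))
    cens <- runif(n, 0, 2500)
    y <- pmin(tt, cens); e <- as.integer(tt <= cens)
    h <- c(1, 2)
    ok <- tryCatch({
      am <- timedep_auc(y, e, m, h)$auc
      aa <- timedep_auc(y, e, age, h)$auc
      ac <- timedep_auc(y, e, m + age, h)$auc
      all(ac >= am) && all(ac >= aa)
    }, error = function(err) NA)
    if (isTRUE(ok)) wins <- wins + 1L
  }
  expect_gte(wins, 90)
})

test_that("mutation_contrast finds planted shifts and controls the null", {
  hits <- 0L
  for (s in 1:100) {
    cohort <- simulate_cohort(cohort_spec(
      n_samples = 600, n_genes = 6,
      mutation_genes = list(list(gene = "IDH1", prevalence = 0.08,
                                 lp_shift = -0.9),
                            list(gene = "FLT3", prevalence = 0.25,
                                 lp_shift = 0)),
      seed = 7300 + s
    ))
    lp <- compute_lp(cohort$expression, c("SRC", "ACSL4"))
    out <- mutation_contrast(lp$scores, cohort$mutations)
    if (out$q[out$gene == "IDH1"] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 90)

  cohort <- simulate_cohort(cohort_spec(
    n_samples = 300, n_genes = 6,
    mutation_genes = list(list(gene = "TP53", prevalence = 0.01,
                               lp_shift = 0)),
    seed = 74
  ))
  lp <- compute_lp(cohort$expression, c("SRC", "ACSL4"))
  cohort$mutations["TP53", ] <- NA_integer_
  expect_warning(out <- mutation_contrast(lp$scores, cohort$mutations))
  expect_equal(nrow(out), 0)
  expect_match(attr(out, "skipped")[["TP53"]], "missing")
})
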