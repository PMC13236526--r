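# Robustness metrics for discovered interactions: an empirical permutation
# p (shuffling the drug's AUC labels), a leave-one-line-out stability
# fraction, and a random-drug specificity p for the co-target. Empirical
# p-values use the add-one estimator (1 + #extreme) / (1 + #null), so they
# are never zero.

# Complete-case design pieces shared by the permutation and LOLO refits.
interaction_case_set <- function(panel, record) {
  y_all <- panel$auc[record$drug_id, ]
  x1_all <- panel$dependency[record$on_target, ]
  x2_all <- panel$dependency[record$co_target, ]
  ok <- stats::complete.cases(y_all, x1_all, x2_all)
  list(y = y_all[ok], x1 = x1_all[ok], x2 = x2_all[ok],
       lines = panel$line_ids[ok])
}

#' Permutation test of an interaction's explained-variance gain
#'
#' Shuffles the drug's AUC vector across cell lines (the dependency matrix
#' stays fixed), recomputes `delta_r2` for each shuffle, and reports the
#' add-one empirical p `(1 + #\{perm >= observed\}) / (1 + n_perm)`.
#'
#' @param panel a [dependency_panel()].
#' @param record one interaction record (row of [run_discovery()] output, or
#'   any list with `drug_id`, `on_target`, `co_target`).
#' @param n_perm number of shuffles (>= 20; default 200).
#' @param seed RNG seed for this test's private stream.
#' @return `perm_p` in `[1/(n_perm+1), 1]`.
#' @export
permutation_test <- function(panel, record, n_perm = 200, seed = 1) {
  if (n_perm < 20) stop_config("n_perm must be >= 20")
  cs <- interaction_case_set(panel, record)
  n <- length(cs$y)
  if (n < 5) stop_insufficient("fewer than 5 complete lines")
  Xb <- cbind(1, cs$x1)
  Xc <- cbind(1, cs$x1, cs$x2)
  # delta_r2(y) = (SSE_base - SSE_combo) / SST, via fixed annihilator matrices.
  Qb <- diag(n) - Xb %*% solve(crossprod(Xb)) %*% t(Xb)
  Qc <- diag(n) - Xc %*% solve(crossprod(Xc)) %*% t(Xc)
  delta_of <- function(Y) {
    sst <- colSums((Y - rep(colMeans(Y), each = n))^2)
    (colSums((Qb %*% Y)^2) - colSums((Qc %*% Y)^2)) / sst
  }
  obs <- delta_of(matrix(cs$y, ncol = 1))
  perm <- with_seed(seed, {
    Y <- vapply(seq_len(n_perm), function(i) sample(cs$y), numeric(n))
    delta_of(Y)
  })
  (1 + sum(perm >= obs)) / (1 + n_perm)
}

#' Leave-one-line-out stability
#'
#' Refits the base and combined models with each cell line held out; an
#' iteration is "positive" iff its `delta_r2 > 0` and the sign of its
#' partial correlation matches the full-panel sign. Degenerate refits count
#' as not positive and are logged in the `failures` attribute.
#'
#' @inheritParams permutation_test
#' @param method partial-correlation method matching the discovery run.
#' @return `lolo_fraction` in `{0, 1/n, ..., 1}` with attributes
#'   `n_iterations` and `failures`.
#' @export
lolo <- function(panel, record, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  cs <- interaction_case_set(panel, record)
  n <- length(cs$y)
  if (n < 6) stop_insufficient("leave-one-line-out needs >= 6 complete lines")
  full <- fit_combined_model(panel, record$drug_id, record$co_target,
                             method = method)
  full_sign <- sign(full$partial_rho)
  positives <- 0L
  failures <- character()
  for (i in seq_len(n)) {
    res <- tryCatch({
      y <- cs$y[-i]; x1 <- cs$x1[-i]; x2 <- cs$x2[-i]
      base <- ols_fit(y, cbind(1, x1))
      combo <- ols_fit(y, cbind(1, x1, x2))
      pc <- partial_correlate(y, x2, x1, method = method)
      (combo$r2 - base$r2 > 0) && sign(pc$estimate) == full_sign
    }, codep_error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", cs$lines[i], conditionMessage(e)))
      FALSE
    })
    if (isTRUE(res)) positives <- positives + 1L
  }
  out <- positives / n
  attr(out, "n_iterations") <- n
  attr(out, "failures") <- failures
  out
}

#' Random-drug specificity test of a co-target
#'
#' Asks whether the co-target predicts unrelated drug sensitivities as well
#' as it predicts the focal drug's: samples `n_random_drugs` other drugs,
#' computes each one's |partial correlation| of AUC with the co-target
#' dependency (controlling that drug's own on-target; plain correlation if
#' unannotated), and reports the add-one fraction at least as large as the
#' observed |partial_rho|. Low values mean the association is specific.
#'
#' @inheritParams permutation_test
#' @param n_random_drugs size of the random-drug null (default 100).
#' @param method correlation method matching the discovery run.
#' @return `specificity_p` in `(0, 1]`.
#' @export
specificity_test <- function(panel, record, n_random_drugs = 100, seed = 1,
                             method = c("spearman", "pearson")) {
  method <- match.arg(method)
  others <- setdiff(panel$drug_ids, record$drug_id)
  if (length(others) < n_random_drugs) {
    stop_config(sprintf("panel has %d other drugs; need > n_random_drugs (%d)",
                        length(others), n_random_drugs))
  }
  obs <- abs(fit_combined_model(panel, record$drug_id, record$co_target,
                                method = method)$partial_rho)
  rand <- with_seed(seed, sample(others, n_random_drugs))
  null_rho <- vapply(rand, function(d) {
    tryCatch({
      on <- if (d %in% names(panel$annotations)) panel$annotations[[d]] else NA
      y <- panel$auc[d, ]
      x2 <- panel$dependency[record$co_target, ]
      if (!is.na(on) && on != record$co_target) {
        abs(partial_correlate(y, x2, panel$dependency[on, ],
                              method = method)$estimate)
      } else {
        abs(correlate(y, x2, method = method)$estimate)
      }
    }, codep_error = function(e) NA_real_)
  }, numeric(1))
  null_rho <- null_rho[!is.na(null_rho)]
  (1 + sum(null_rho >= obs)) / (1 + length(null_rho))
}

#' Attach all three robustness metrics to a set of interaction records
#'
#' Each record gets its own RNG stream seeded `seed + record index`, so the
#' per-record results do not depend on processing order.
#'
#' @param panel a [dependency_panel()].
#' @param records data.frame from [run_discovery()].
#' @param n_perm permutation count per record.
#' @param n_random_drugs specificity null size (skipped with NA when the
#'   panel has too few drugs).
#' @param seed master seed.
#' @param method correlation method matching the discovery run.
#' @return `records` with `perm_p`, `lolo_fraction`, `specificity_p` filled.
#' @export
run_robustness <- function(panel, records, n_perm = 200,
                           n_random_drugs = 100, seed = 1,
                           method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (!nrow(records)) return(records)
  can_spec <- length(panel$drug_ids) - 1 >= n_random_drugs
  for (i in seq_len(nrow(records))) {
    rec <- as.list(records[i, ])
    records$perm_p[i] <- permutation_test(panel, rec, n_perm = n_perm,
                                          seed = seed + i)
    records$lolo_fraction[i] <- as.numeric(lolo(panel, rec, method = method))
    records$specificity_p[i] <- if (can_spec) {
      specificity_test(panel, rec, n_random_drugs = n_random_drugs,
                       seed = seed + i, method = method)
    } else NA_real_
  }
  records
}
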