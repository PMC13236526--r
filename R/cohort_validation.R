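# Translational validation: does co-target expression predict ex vivo drug
# response in a primary-specimen cohort? Per-drug sample sets are pairwise
# complete (ex vivo panels are sparse), and both Pearson and Spearman
# partial correlations are carried.

#' Construct an expression cohort
#'
#' @param expression numeric matrix genes x samples (normalized log
#'   expression), with unique gene row names.
#' @param drug_auc numeric matrix drugs x samples (ex vivo AUC; NA allowed).
#' @param mutations integer matrix genes x samples in `{0, 1, NA}`.
#' @param clinical data.frame with columns `sample_id`, `os_days`,
#'   `os_event`, `age`, `cyto_risk`.
#' @return an `expression_cohort` list.
#' @export
expression_cohort <- function(expression, drug_auc = NULL, mutations = NULL,
                              clinical = NULL) {
  expression <- as.matrix(expression)
  if (is.null(rownames(expression)) || anyDuplicated(rownames(expression))) {
    stop_validation("expression needs unique gene row names")
  }
  samples <- colnames(expression)
  if (is.null(samples)) stop_validation("expression needs sample column names")
  check_axis <- function(m, what) {
    if (!is.null(m) && !identical(colnames(m), samples)) {
      stop_validation(sprintf("%s sample axis must match expression", what))
    }
  }
  check_axis(drug_auc, "drug_auc")
  check_axis(mutations, "mutations")
  if (!is.null(clinical) && !identical(clinical$sample_id, samples)) {
    stop_validation("clinical sample_id must match the expression sample axis")
  }
  structure(
    list(expression = expression, drug_auc = drug_auc, mutations = mutations,
         clinical = clinical, sample_ids = samples),
    class = "expression_cohort"
  )
}

#' Map discovery drugs to their cohort analogs
#'
#' @param mapping two-column data.frame (or path to a headerless two-column
#'   TSV): discovery drug id, cohort drug id.
#' @param cohort an [expression_cohort()] whose `drug_auc` rows the mapped
#'   cohort drugs must exist in.
#' @return named character vector discovery drug -> cohort drug; the
#'   `n_unmapped` attribute counts discovery drugs the caller asked about
#'   but did not map (set by [run_validation()]).
#' @export
map_drug_analogs <- function(mapping, cohort) {
  if (is.character(mapping) && length(mapping) == 1) {
    mapping <- utils::read.table(mapping, sep = "\t", header = FALSE,
                                 col.names = c("discovery", "cohort"),
                                 stringsAsFactors = FALSE)
  }
  if (!nrow(mapping)) {
    warning("empty drug-analog mapping")
    return(stats::setNames(character(), character()))
  }
  absent <- setdiff(mapping[[2]], rownames(cohort$drug_auc))
  if (length(absent)) {
    stop_mapping(sprintf("cohort drug(s) absent from drug_auc: %s",
                         paste(absent, collapse = ", ")))
  }
  stats::setNames(as.character(mapping[[2]]), as.character(mapping[[1]]))
}

#' Validate one interaction against ex vivo drug response
#'
#' Computes (i) the unadjusted Pearson correlation of co-target expression
#' with the drug's AUC, (ii) a joint OLS of AUC on the z-scored co-target
#' and on-target expression (`coef_joint` is the co-target coefficient, in
#' AUC units per z-unit), and (iii) partial correlations (both Pearson and
#' Spearman) of co-target expression with AUC controlling the on-target.
#' A degenerate partial (e.g. co-target duplicating the on-target) is
#' flagged via `error_code` and the record retained.
#'
#' @param cohort an [expression_cohort()].
#' @param drug_id cohort drug id.
#' @param co_target,on_target gene ids in the expression matrix.
#' @param method primary partial method for `partial_estimate`/`partial_p`.
#' @return one-row data.frame (a `ValidationResult`).
#' @export
validate_interaction <- function(cohort, drug_id, co_target, on_target,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  for (g in c(co_target, on_target)) {
    if (!g %in% rownames(cohort$expression)) {
      stop_gene_not_found(sprintf("gene %s absent from cohort expression", g))
    }
  }
  if (!drug_id %in% rownames(cohort$drug_auc)) {
    stop_mapping(sprintf("drug %s absent from cohort drug_auc", drug_id))
  }
  auc <- cohort$drug_auc[drug_id, ]
  e_co <- cohort$expression[co_target, ]
  e_on <- cohort$expression[on_target, ]
  ok <- stats::complete.cases(auc, e_co, e_on)
  if (sum(ok) < 10) {
    stop_insufficient(sprintf("drug %s: %d usable samples (need >= 10)",
                              drug_id, sum(ok)))
  }
  auc <- auc[ok]; e_co <- e_co[ok]; e_on <- e_on[ok]
  unadj <- correlate(e_co, auc, method = "pearson")
  error_code <- NA_character_
  coef_joint <- NA_real_
  partial <- list(pearson = NA_real_, spearman = NA_real_)
  partial_p <- list(pearson = NA_real_, spearman = NA_real_)
  joint <- tryCatch({
    ols_fit(auc, cbind(1, zscore(e_co), zscore(e_on)))
  }, codep_error = function(e) NULL)
  if (!is.null(joint)) coef_joint <- unname(joint$coef[2])
  for (m in c("pearson", "spearman")) {
    pc <- tryCatch(partial_correlate(auc, e_co, e_on, method = m),
                   codep_error = function(e) e)
    if (inherits(pc, "condition")) {
      error_code <- "degenerate_partial"
    } else {
      partial[[m]] <- pc$estimate
      partial_p[[m]] <- pc$p_value
    }
  }
  data.frame(
    drug_id = drug_id, co_target = co_target, on_target = on_target,
    r_unadjusted = unadj$estimate, p_unadjusted = unadj$p_value,
    coef_joint = coef_joint,
    partial_estimate = partial[[method]], partial_p = partial_p[[method]],
    partial_pearson = partial$pearson, partial_pearson_p = partial_p$pearson,
    partial_spearman = partial$spearman, partial_spearman_p = partial_p$spearman,
    n = sum(ok), error_code = error_code, stringsAsFactors = FALSE
  )
}

#' Validate a set of discovered interactions in a cohort
#'
#' Maps each discovery drug through the analog mapping, validates the
#' mapped pairs, and applies BH across the run. The p-value entering BH is
#' the adjusted (partial) p by default, switchable to the unadjusted p.
#'
#' @param cohort an [expression_cohort()].
#' @param interactions data.frame with `drug_id`, `co_target`, `on_target`.
#' @param mapping output of [map_drug_analogs()].
#' @param fdr_max significance threshold recorded in metadata (default 0.05).
#' @param method primary partial method.
#' @param bh_on `"partial"` (default) or `"unadjusted"`.
#' @return data.frame of validation results with `q_value` and `significant`
#'   columns; attribute `n_unmapped` counts untestable discovery drugs.
#' @export
run_validation <- function(cohort, interactions, mapping, fdr_max = 0.05,
                           method = c("pearson", "spearman"),
                           bh_on = c("partial", "unadjusted")) {
  method <- match.arg(method)
  bh_on <- match.arg(bh_on)
  testable <- interactions$drug_id %in% names(mapping)
  rows <- lapply(which(testable), function(i) {
    tryCatch(
      validate_interaction(cohort, mapping[[interactions$drug_id[i]]],
                           interactions$co_target[i],
                           interactions$on_target[i], method = method),
      codep_error = function(e) NULL
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame()
    attr(out, "n_unmapped") <- sum(!testable)
    return(out)
  }
  out <- do.call(rbind, rows)
  pv <- if (bh_on == "partial") out$partial_p else out$p_unadjusted
  out$q_value <- bh_adjust(pv)
  out$significant <- !is.na(out$q_value) & out$q_value < fdr_max
  attr(out, "n_unmapped") <- sum(!testable)
  attr(out, "metadata") <- list(fdr_max = fdr_max, method = method,
                                bh_on = bh_on)
  out
}

#' Expression-quartile contrast of drug response
#'
#' Splits samples into quartiles of the gene's expression (type-7 quantiles;
#' Q1 = lowest 25%, Q4 = highest) and rank-sum-tests the drug's AUC between
#' Q4 and Q1.
#'
#' @param cohort an [expression_cohort()].
#' @param gene,drug identifiers.
#' @param test `"ranksum"` (default; AUC distributions are typically skewed)
#'   or `"t"`.
#' @return list with `q1_mean`, `q4_mean`, `statistic`, `p_value`,
#'   `n_per_quartile`.
#' @export
quartile_contrast <- function(cohort, gene, drug,
                              test = c("ranksum", "t")) {
  test <- match.arg(test)
  if (!gene %in% rownames(cohort$expression)) {
    stop_gene_not_found(sprintf("gene %s absent", gene))
  }
  expr <- cohort$expression[gene, ]
  auc <- cohort$drug_auc[drug, ]
  ok <- stats::complete.cases(expr, auc)
  if (sum(ok) < 40) {
    stop_insufficient(sprintf("%d usable samples (need >= 40)", sum(ok)))
  }
  expr <- expr[ok]; auc <- auc[ok]
  br <- stats::quantile(expr, probs = c(0, 0.25, 0.5, 0.75, 1), type = 7)
  if (anyDuplicated(br)) stop_quantile("tied quartile breaks; quartiles ill-defined")
  quart <- cut(expr, breaks = br, include.lowest = TRUE, labels = FALSE)
  n_per <- tabulate(quart, nbins = 4)
  if (any(n_per == 0)) stop_quantile("empty quartile")
  a1 <- auc[quart == 1]; a4 <- auc[quart == 4]
  if (test == "ranksum") {
    ts <- rank_sum_test(a4, a1)
    stat <- ts$statistic; p <- ts$p_value
  } else {
    tt <- stats::t.test(a4, a1)
    stat <- unname(tt$statistic); p <- tt$p.value
  }
  list(q1_mean = mean(a1), q4_mean = mean(a4), statistic = stat,
       p_value = p, n_per_quartile = n_per)
}

#' Negative-control drug panel for one gene
#'
#' Correlates the gene's expression with the AUC of the focal drug and each
#' control drug; flags whether the focal association is the strongest in
#' absolute value.
#'
#' @param cohort an [expression_cohort()].
#' @param gene gene id.
#' @param focal_drug the drug of interest.
#' @param control_drugs non-empty character vector of control drug ids.
#' @return data.frame (drug, r, p, q, n, is_focal) with attribute
#'   `focal_strongest`.
#' @export
negative_control_panel <- function(cohort, gene, focal_drug, control_drugs) {
  if (!length(control_drugs)) stop_config("control_drugs must be non-empty")
  drugs <- c(focal_drug, control_drugs)
  absent <- setdiff(drugs, rownames(cohort$drug_auc))
  if (length(absent)) {
    stop_mapping(sprintf("drug(s) absent: %s", paste(absent, collapse = ", ")))
  }
  rows <- lapply(drugs, function(d) {
    r <- correlate(cohort$expression[gene, ], cohort$drug_auc[d, ],
                   method = "pearson")
    data.frame(drug = d, r = r$estimate, p = r$p_value, n = r$n,
               is_focal = d == focal_drug, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  strongest <- abs(out$r[out$is_focal]) > max(abs(out$r[!out$is_focal]))
  attr(out, "focal_strongest") <- strongest
  out
}

#' Resistance correlation of a gene with a drug's AUC
#'
#' Positive r means higher expression tracks higher AUC, i.e. ex vivo
#' resistance (lower AUC = greater sensitivity throughout).
#'
#' @param cohort an [expression_cohort()].
#' @param gene,drug identifiers.
#' @param method correlation method.
#' @return a `correlation_result`.
#' @export
resistance_correlation <- function(cohort, gene, drug,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!gene %in% rownames(cohort$expression)) {
    stop_gene_not_found(sprintf("gene %s absent", gene))
  }
  correlate(cohort$expression[gene, ], cohort$drug_auc[drug, ],
            method = method)
}
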