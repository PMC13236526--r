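# Drug-gene co-dependency discovery. For each annotated drug d with on-target
# g_on, a base model AUC_d = b0 + b1 * dep(g_on) + e is fitted; residuals are
# screened (Spearman by default) against every other gene's dependency
# profile to nominate co-target candidates; for each candidate a combined
# two-covariate model is fitted and the interaction is scored by the gain in
# explained variance (delta R2 = R2_combo - R2_base, on a common case set)
# and by the partial correlation of AUC with the co-target dependency
# controlling the on-target.

#' Construct a matched drug-sensitivity / dependency panel
#'
#' @param auc numeric matrix drugs x cell lines (dose-response AUC; lower =
#'   more sensitive), with row and column names.
#' @param dependency numeric matrix genes x cell lines (CRISPR dependency
#'   scores; more negative = more essential), same column order as `auc`.
#' @param annotations named character vector mapping drug id to its
#'   annotated on-target gene id.
#' @return a `dependency_panel` list with `auc`, `dependency`,
#'   `annotations`, `line_ids`, `drug_ids`, `gene_ids`.
#' @export
dependency_panel <- function(auc, dependency, annotations) {
  auc <- as.matrix(auc); dependency <- as.matrix(dependency)
  if (is.null(rownames(auc)) || is.null(rownames(dependency)) ||
      is.null(colnames(auc)) || is.null(colnames(dependency))) {
    stop_validation("auc and dependency must have row and column names")
  }
  if (!identical(colnames(auc), colnames(dependency))) {
    stop_validation("auc and dependency must share an identical ordered cell-line axis")
  }
  if (anyDuplicated(rownames(auc)) || anyDuplicated(rownames(dependency)) ||
      anyDuplicated(colnames(auc))) {
    stop_validation("duplicated drug, gene, or cell-line identifiers")
  }
  annotations <- annotations[!is.na(annotations)]
  bad <- setdiff(unname(annotations), rownames(dependency))
  if (length(bad)) {
    stop_validation(sprintf("annotated on-target(s) absent from gene_ids: %s",
                            paste(bad, collapse = ", ")))
  }
  structure(
    list(auc = auc, dependency = dependency, annotations = annotations,
         line_ids = colnames(auc), drug_ids = rownames(auc),
         gene_ids = rownames(dependency)),
    class = "dependency_panel"
  )
}

#' @export
print.dependency_panel <- function(x, ...) {
  cat(sprintf("<dependency_panel> %d drugs x %d genes x %d cell lines (%d annotated drugs)\n",
              length(x$drug_ids), length(x$gene_ids), length(x$line_ids),
              length(x$annotations)))
  invisible(x)
}

# Plain OLS on a design matrix; returns coef, residuals, r2.
ols_fit <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst <= 0) NA_real_ else 1 - sum(res^2) / sst
  list(coef = fit$coefficients, residuals = res, r2 = r2)
}

#' Fit the on-target base model for one drug
#'
#' OLS of the drug's AUC on its annotated on-target dependency (with
#' intercept), on pairwise-complete cell lines.
#'
#' @param panel a [dependency_panel()].
#' @param drug_id drug identifier.
#' @return a `base_model_fit`: `beta0`, `beta1`, `r2_base`, named
#'   `residuals`, `n`, plus `drug_id` and `on_target`.
#' @export
fit_base_model <- function(panel, drug_id) {
  if (!drug_id %in% names(panel$annotations)) {
    stop_annotation(sprintf("drug %s has no on-target annotation", drug_id))
  }
  on_target <- panel$annotations[[drug_id]]
  y_all <- panel$auc[drug_id, ]
  x_all <- panel$dependency[on_target, ]
  ok <- stats::complete.cases(y_all, x_all)
  if (sum(ok) < 5) {
    stop_insufficient(sprintf("drug %s: %d complete lines (need >= 5)",
                              drug_id, sum(ok)))
  }
  y <- y_all[ok]; x <- x_all[ok]
  if (length(unique(y)) < 2) stop_degenerate(sprintf("drug %s: constant AUC", drug_id))
  if (length(unique(x)) < 2) {
    stop_degenerate(sprintf("drug %s: constant on-target dependency", drug_id))
  }
  fit <- ols_fit(y, cbind(1, x))
  structure(
    list(drug_id = drug_id, on_target = on_target,
         beta0 = unname(fit$coef[1]), beta1 = unname(fit$coef[2]),
         r2_base = fit$r2,
         residuals = stats::setNames(fit$residuals, names(y)),
         n = length(y)),
    class = "base_model_fit"
  )
}

# Midranks of each matrix row (pairwise NA-free fast path assumed by caller).
row_ranks <- function(m) {
  t(apply(m, 1, rank))
}

#' Screen base-model residuals against all gene dependencies
#'
#' Correlates the base-model residuals with every gene's dependency profile
#' (the drug's on-target and any `exclude` genes are skipped). Genes that
#' fail the correlation preconditions (constant, too few complete pairs) are
#' skipped and counted in the `skipped` attribute.
#'
#' @param fit a [fit_base_model()] result.
#' @param panel the panel the fit came from.
#' @param exclude additional gene ids to skip.
#' @param method screen correlation, `"spearman"` (default) or `"pearson"`.
#' @return data.frame `(gene, screen_rho, p)` sorted by decreasing
#'   `|screen_rho|`, ties broken by gene id.
#' @export
screen_residuals <- function(fit, panel, exclude = character(),
                             method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (fit$n < 5) stop_insufficient("base fit has fewer than 5 residuals")
  lines <- names(fit$residuals)
  genes <- setdiff(panel$gene_ids, c(fit$on_target, exclude))
  empty <- data.frame(gene = character(), screen_rho = numeric(),
                      p = numeric(), stringsAsFactors = FALSE)
  if (!length(genes)) {
    attr(empty, "skipped") <- 0L
    return(empty)
  }
  res <- fit$residuals
  dep <- panel$dependency[genes, lines, drop = FALSE]
  skipped <- 0L
  auc_scale <- stats::sd(panel$auc[fit$drug_id, lines])
  if (stats::sd(res) <= 1e-10 * max(auc_scale, 1e-300)) {
    # Residuals identically zero: every correlation is degenerate.
    attr(empty, "skipped") <- length(genes)
    return(empty)
  }
  if (!anyNA(dep)) {
    # Vectorized fast path: (ranked) rows against the (ranked) residual.
    rv <- if (method == "spearman") rank(res) else res
    dm <- if (method == "spearman") row_ranks(dep) else dep
    sds <- apply(dm, 1, stats::sd)
    keep <- sds > 0
    skipped <- sum(!keep)
    dm <- dm[keep, , drop = FALSE]
    n <- length(rv)
    dmc <- dm - rowMeans(dm)
    rvc <- rv - mean(rv)
    rho <- as.vector(dmc %*% rvc) /
      (sqrt(rowSums(dmc^2)) * sqrt(sum(rvc^2)))
    rho <- pmax(-1, pmin(1, rho))
    p <- ifelse(abs(rho) >= 1 - 1e-15, 0,
                2 * stats::pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), n - 2))
    out <- data.frame(gene = genes[keep], screen_rho = rho, p = p,
                      stringsAsFactors = FALSE)
  } else {
    rows <- lapply(genes, function(g) {
      r <- tryCatch(correlate(res, dep[g, ], method = method),
                    codep_error = function(e) NULL)
      if (is.null(r)) return(NULL)
      data.frame(gene = g, screen_rho = r$estimate, p = r$p_value,
                 stringsAsFactors = FALSE)
    })
    skipped <- sum(vapply(rows, is.null, logical(1)))
    rows <- rows[!vapply(rows, is.null, logical(1))]
    out <- if (length(rows)) do.call(rbind, rows) else empty
  }
  out <- out[order(-abs(out$screen_rho), out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Fit the combined on-target + co-target model
#'
#' OLS of AUC on both dependencies with intercept; `delta_r2` is computed
#' against a base model refitted on the same complete-case line set, so
#' nesting guarantees `delta_r2 >= 0`. The partial correlation of AUC with
#' the co-target dependency controls the on-target dependency.
#'
#' @param panel a [dependency_panel()].
#' @param drug_id drug identifier (must be annotated).
#' @param co_target candidate co-target gene id.
#' @param method partial-correlation method (default `"spearman"`).
#' @return list with `r2_base`, `r2_combo`, `delta_r2`, `partial_rho`,
#'   `p_value`, `n`, `on_target`.
#' @export
fit_combined_model <- function(panel, drug_id, co_target,
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (!drug_id %in% names(panel$annotations)) {
    stop_annotation(sprintf("drug %s has no on-target annotation", drug_id))
  }
  on_target <- panel$annotations[[drug_id]]
  if (identical(co_target, on_target)) {
    stop_validation("co_target must differ from the on-target")
  }
  if (!co_target %in% panel$gene_ids) {
    stop_gene_not_found(sprintf("gene %s absent from panel", co_target))
  }
  y_all <- panel$auc[drug_id, ]
  x1_all <- panel$dependency[on_target, ]
  x2_all <- panel$dependency[co_target, ]
  ok <- stats::complete.cases(y_all, x1_all, x2_all)
  if (sum(ok) < 5) {
    stop_insufficient(sprintf("drug %s / %s: %d complete lines (need >= 5)",
                              drug_id, co_target, sum(ok)))
  }
  y <- y_all[ok]; x1 <- x1_all[ok]; x2 <- x2_all[ok]
  if (length(unique(y)) < 2) stop_degenerate("constant AUC")
  if (length(unique(x1)) < 2 || length(unique(x2)) < 2) {
    stop_degenerate("constant dependency covariate")
  }
  if (abs(stats::cor(x1, x2)) > 0.999) {
    stop_collinear(sprintf("dependencies of %s and %s are collinear",
                           on_target, co_target),
                   genes = c(on_target, co_target))
  }
  base <- ols_fit(y, cbind(1, x1))
  combo <- ols_fit(y, cbind(1, x1, x2))
  pc <- partial_correlate(y, x2, x1, method = method)
  delta <- combo$r2 - base$r2
  if (delta < -1e-10) {
    stop_validation(sprintf("negative delta_r2 (%.3g) on nested fits", delta))
  }
  list(
    drug_id = drug_id, on_target = on_target, co_target = co_target,
    r2_base = base$r2, r2_combo = combo$r2, delta_r2 = max(delta, 0),
    partial_rho = pc$estimate, p_value = pc$p_value, n = length(y)
  )
}

#' Run the full co-dependency discovery screen
#'
#' For each annotated drug: base fit, residual screen, combined fits for the
#' top `top_k` candidates by absolute screen correlation. BH adjustment is
#' applied across all fitted drug/co-target pairs in the run (one family;
#' recorded in metadata). Records passing `delta_r2 > delta_r2_min` and
#' `q < fdr_max` are retained, sorted by decreasing `delta_r2`.
#'
#' @param panel a [dependency_panel()].
#' @param delta_r2_min retention threshold on the explained-variance gain.
#' @param fdr_max retention threshold on the BH q-value.
#' @param top_k candidates fitted per drug (`Inf` for all genes).
#' @param screen_method correlation used for the residual screen and the
#'   partial correlation (`"spearman"` default).
#' @param screen_p_max optional screen-p filter applied before combined fits.
#' @param bh_family `"global"` (default; one family across all fitted pairs
#'   in the run) or `"per_drug"`.
#' @return data.frame of interaction records (one row per retained pair)
#'   with columns drug_id, on_target, co_target, r2_base, r2_combo,
#'   delta_r2, screen_rho, partial_rho, p_value, q_value and NA placeholders
#'   for the robustness metrics; attributes `metadata` (config, skip log,
#'   n_tested) and `all_tested` (every fitted pair, pre-filter).
#' @export
run_discovery <- function(panel, delta_r2_min = 0.02, fdr_max = 0.01,
                          top_k = 50, screen_method = c("spearman", "pearson"),
                          screen_p_max = NULL,
                          bh_family = c("global", "per_drug")) {
  screen_method <- match.arg(screen_method)
  bh_family <- match.arg(bh_family)
  drugs <- intersect(panel$drug_ids, names(panel$annotations))
  if (!length(drugs)) stop_empty_screen("no annotated drugs in panel")
  skip_log <- list()
  rows <- vector("list", length(drugs))
  for (i in seq_along(drugs)) {
    d <- drugs[i]
    fit <- tryCatch(fit_base_model(panel, d), codep_error = function(e) e)
    if (inherits(fit, "condition")) {
      skip_log[[d]] <- conditionMessage(fit)
      next
    }
    cand <- screen_residuals(fit, panel, method = screen_method)
    if (!is.null(screen_p_max)) cand <- cand[cand$p <= screen_p_max, , drop = FALSE]
    if (!nrow(cand)) {
      skip_log[[d]] <- "no screenable candidate genes"
      next
    }
    cand <- utils::head(cand, n = if (is.finite(top_k)) top_k else nrow(cand))
    fits <- lapply(cand$gene, function(g) {
      out <- tryCatch(fit_combined_model(panel, d, g, method = screen_method),
                      codep_error = function(e) NULL)
      out
    })
    keep <- !vapply(fits, is.null, logical(1))
    if (!any(keep)) {
      skip_log[[d]] <- "all combined fits degenerate"
      next
    }
    fits <- fits[keep]
    rows[[i]] <- data.frame(
      drug_id = d,
      on_target = vapply(fits, `[[`, "", "on_target"),
      co_target = vapply(fits, `[[`, "", "co_target"),
      r2_base = vapply(fits, `[[`, 0, "r2_base"),
      r2_combo = vapply(fits, `[[`, 0, "r2_combo"),
      delta_r2 = vapply(fits, `[[`, 0, "delta_r2"),
      screen_rho = cand$screen_rho[keep],
      partial_rho = vapply(fits, `[[`, 0, "partial_rho"),
      p_value = vapply(fits, `[[`, 0, "p_value"),
      n = vapply(fits, `[[`, 0L, "n"),
      stringsAsFactors = FALSE
    )
  }
  tested <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tested) || !nrow(tested)) {
    stop_empty_screen("every drug was skipped", skip_log = skip_log)
  }
  tested$q_value <- if (bh_family == "global") {
    bh_adjust(tested$p_value)
  } else {
    stats::ave(tested$p_value, tested$drug_id, FUN = bh_adjust)
  }
  retained <- tested[tested$delta_r2 > delta_r2_min & tested$q_value < fdr_max, ,
                     drop = FALSE]
  retained <- retained[order(-retained$delta_r2, retained$drug_id,
                             retained$co_target), , drop = FALSE]
  retained$perm_p <- rep(NA_real_, nrow(retained))
  retained$lolo_fraction <- rep(NA_real_, nrow(retained))
  retained$specificity_p <- rep(NA_real_, nrow(retained))
  rownames(retained) <- NULL
  attr(retained, "metadata") <- list(
    delta_r2_min = delta_r2_min, fdr_max = fdr_max, top_k = top_k,
    screen_method = screen_method, screen_p_max = screen_p_max,
    bh_family = bh_family, n_tested = nrow(tested),
    skip_log = skip_log
  )
  attr(retained, "all_tested") <- tested
  retained
}
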