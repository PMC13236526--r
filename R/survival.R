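# Composite-signature survival analysis. The linear predictor (LP) is the
# weighted sum of per-gene z-scores; downstream: median-split Kaplan-Meier
# with a log-rank test, Cox proportional-hazards regression (Newton-Raphson
# on the Efron partial likelihood), a progressively adjusted model ladder,
# IPCW cumulative/dynamic time-dependent AUC, and mutation-subgroup
# rank-sum contrasts. All estimators are implemented here; the `survival`
# package is used only as an independent oracle in the test suite.

#' Composite linear predictor from gene expression
#'
#' Each gene is z-scored across samples (sample SD) and the weighted sum is
#' taken per sample.
#'
#' @param expression genes x samples matrix.
#' @param genes signature gene ids (all must be present and non-constant).
#' @param weights per-gene weights (default all 1).
#' @return a `linear_predictor`: list with `genes`, `weights`, and named
#'   per-sample `scores`.
#' @export
compute_lp <- function(expression, genes, weights = rep(1, length(genes))) {
  if (length(weights) != length(genes)) {
    stop_validation("weights and genes must have equal length")
  }
  missing <- setdiff(genes, rownames(expression))
  if (length(missing)) {
    stop_gene_not_found(sprintf("gene(s) absent: %s",
                                paste(missing, collapse = ", ")),
                        genes = missing)
  }
  z <- vapply(genes, function(g) zscore(expression[g, ]),
              numeric(ncol(expression)))
  scores <- as.vector(z %*% weights)
  names(scores) <- colnames(expression)
  structure(list(genes = genes, weights = weights, scores = scores),
            class = "linear_predictor")
}

#' Median split of a linear predictor
#'
#' `high` = score strictly above the median; scores equal to the median go
#' to `low` (deterministic tie rule).
#'
#' @param lp a [compute_lp()] result (or a numeric score vector).
#' @return factor with levels `low`, `high`, named by sample.
#' @export
median_split <- function(lp) {
  scores <- if (inherits(lp, "linear_predictor")) lp$scores else lp
  if (length(scores) < 4) stop_insufficient("median split needs >= 4 samples")
  med <- stats::median(scores)
  g <- ifelse(scores > med, "high", "low")
  if (all(g == "low")) {
    warning(structure(
      class = c("degenerate_split_warning", "warning", "condition"),
      list(message = "all scores at or below the median; single group",
           call = sys.call())
    ))
  }
  factor(g, levels = c("low", "high"))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times follow-up times (> 0).
#' @param events event indicators in `{0, 1}`.
#' @param groups optional group labels; one curve per group.
#' @return list of `km_curve` objects (`times` = sorted distinct event
#'   times, `survival`, `at_risk`, `n_events`, `label`), one per group.
#' @export
km_estimate <- function(times, events, groups = NULL) {
  if (any(times <= 0)) stop_validation("times must be positive")
  if (!all(events %in% c(0, 1))) stop_validation("events must be 0/1")
  if (is.null(groups)) groups <- rep("all", length(times))
  out <- lapply(split(seq_along(times), groups), function(idx) {
    if (!length(idx)) stop_group("group with 0 subjects")
    tt <- times[idx]; ee <- events[idx]
    et <- sort(unique(tt[ee == 1]))
    surv <- numeric(length(et)); at_risk <- integer(length(et))
    d <- integer(length(et))
    s <- 1
    for (k in seq_along(et)) {
      at_risk[k] <- sum(tt >= et[k])
      d[k] <- sum(tt == et[k] & ee == 1)
      s <- s * (1 - d[k] / at_risk[k])
      surv[k] <- s
    }
    structure(list(times = et, survival = surv, at_risk = at_risk,
                   n_events = d, n = length(idx),
                   label = groups[idx[1]]),
              class = "km_curve")
  })
  out
}

# Evaluate a KM step function at arbitrary times; left = TRUE gives the
# left-continuous value S(t-).
km_eval <- function(curve, at, left = FALSE) {
  if (!length(curve$times)) return(rep(1, length(at)))
  idx <- if (left) findInterval(at, curve$times, left.open = TRUE)
         else findInterval(at, curve$times)
  c(1, curve$survival)[idx + 1]
}

#' Log-rank test
#'
#' Observed-minus-expected statistic with the hypergeometric variance;
#' chi-squared with `k - 1` degrees of freedom for `k` groups.
#'
#' @inheritParams km_estimate
#' @param groups group labels (>= 2 non-empty groups).
#' @return list with `chi2`, `df`, `p_value`.
#' @export
logrank_test <- function(times, events, groups) {
  if (any(times <= 0)) stop_validation("times must be positive")
  if (!all(events %in% c(0, 1))) stop_validation("events must be 0/1")
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop_group("log-rank needs >= 2 groups")
  if (any(table(groups) == 0)) stop_group("group with 0 subjects")
  if (sum(events) == 0) stop_no_events("no events; log-rank undefined")
  k <- nlevels(groups)
  et <- sort(unique(times[events == 1]))
  O <- numeric(k); E <- numeric(k)
  V <- matrix(0, k, k)
  for (tt in et) {
    at_risk <- times >= tt
    n <- sum(at_risk)
    d <- sum(times == tt & events == 1)
    nj <- vapply(levels(groups), function(g) sum(at_risk & groups == g), 0)
    dj <- vapply(levels(groups), function(g) {
      sum(times == tt & events == 1 & groups == g)
    }, 0)
    O <- O + dj
    E <- E + d * nj / n
    if (n > 1) {
      frac <- nj / n
      V <- V + d * (n - d) / (n - 1) * (diag(frac) - outer(frac, frac))
    }
  }
  u <- (O - E)[-k]
  Vm <- V[-k, -k, drop = FALSE]
  chi2 <- tryCatch(as.numeric(t(u) %*% solve(Vm, u)),
                   error = function(e) 0)
  if (!is.finite(chi2) || chi2 < 0) chi2 <- 0
  list(chi2 = chi2, df = k - 1, p_value = stats::pchisq(chi2, k - 1,
                                                        lower.tail = FALSE))
}

# Efron partial log-likelihood, gradient, and information at beta.
cox_loglik <- function(beta, times, events, X) {
  ord <- order(times)
  times <- times[ord]; events <- events[ord]
  X <- X[ord, , drop = FALSE]
  eta <- as.vector(X %*% beta)
  w <- exp(eta)
  p <- ncol(X)
  ll <- 0
  grad <- numeric(p)
  info <- matrix(0, p, p)
  et <- unique(times[events == 1])
  for (tt in et) {
    risk <- times >= tt
    dead <- times == tt & events == 1
    d <- sum(dead)
    S0 <- sum(w[risk])
    S1 <- colSums(X[risk, , drop = FALSE] * w[risk])
    S2 <- crossprod(X[risk, , drop = FALSE] * sqrt(w[risk]))
    D0 <- sum(w[dead])
    D1 <- colSums(X[dead, , drop = FALSE] * w[dead])
    D2 <- crossprod(X[dead, , drop = FALSE] * sqrt(w[dead]))
    ll <- ll + sum(eta[dead])
    grad <- grad + colSums(X[dead, , drop = FALSE])
    for (l in seq_len(d) - 1) {
      f <- l / d
      z0 <- S0 - f * D0
      z1 <- S1 - f * D1
      z2 <- S2 - f * D2
      ll <- ll - log(z0)
      grad <- grad - z1 / z0
      info <- info + z2 / z0 - tcrossprod(z1) / z0^2
    }
  }
  list(loglik = ll, grad = grad, info = info)
}

#' Cox proportional-hazards regression
#'
#' Maximizes the Efron-tie-corrected partial likelihood by Newton-Raphson
#' (convergence: gradient max-norm below `tol`). Hazard ratios are
#' `exp(beta)` with Wald 95% CIs and p-values.
#'
#' @param times,events follow-up and event indicator.
#' @param covariates named numeric matrix or data.frame (n x p).
#' @param ties only `"efron"` is implemented.
#' @param max_iter,tol Newton controls.
#' @return a `survival_fit`: data.frame `coefficients` (term, beta, se,
#'   hazard_ratio, ci_low, ci_high, wald_p) plus `n`, `n_events`,
#'   `ties_method`, `loglik`.
#' @export
cox_fit <- function(times, events, covariates, ties = "efron",
                    max_iter = 50, tol = 1e-8) {
  if (!identical(ties, "efron")) stop_config("only efron ties implemented")
  X <- as.matrix(as.data.frame(covariates))
  storage.mode(X) <- "double"
  ok <- stats::complete.cases(times, events, X)
  times <- times[ok]; events <- events[ok]; X <- X[ok, , drop = FALSE]
  n_events <- sum(events)
  if (n_events < 5 * ncol(X)) {
    stop_insufficient(sprintf("%d events for %d covariates (need >= 5 each)",
                              n_events, ncol(X)))
  }
  if (n_events < 10 * ncol(X)) {
    warning(sprintf("only %d events for %d covariates", n_events, ncol(X)))
  }
  # Center covariates for numerical stability (beta is unaffected).
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  beta <- numeric(ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    pieces <- cox_loglik(beta, times, events, Xc)
    if (max(abs(pieces$grad)) < tol) {
      converged <- TRUE
      break
    }
    step <- tryCatch(solve(pieces$info, pieces$grad), error = function(e) NULL)
    if (is.null(step)) stop_separation("singular information matrix")
    beta <- beta + step
    if (any(abs(beta) > 30)) {
      stop_separation("monotone likelihood (complete separation)")
    }
  }
  if (!converged) stop_convergence(sprintf("no convergence in %d iterations",
                                           max_iter))
  if (any(abs(beta) > 15)) {
    # a per-unit |log HR| this size only arises from monotone likelihoods
    stop_separation("monotone likelihood (complete separation)")
  }
  se <- sqrt(diag(solve(pieces$info)))
  z <- beta / se
  structure(
    list(
      coefficients = data.frame(
        term = colnames(X), beta = beta, se = se,
        hazard_ratio = exp(beta),
        ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
        wald_p = 2 * stats::pnorm(-abs(z)),
        stringsAsFactors = FALSE
      ),
      n = length(times), n_events = n_events, ties_method = "efron",
      loglik = pieces$loglik, iterations = it
    ),
    class = "survival_fit"
  )
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("<cox fit> n = %d, events = %d (%s ties)\n",
              x$n, x$n_events, x$ties_method))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

# Assemble the modelling frame for the adjusted-model ladder.
survival_frame <- function(cohort, lp) {
  cl <- cohort$clinical
  df <- data.frame(
    lp = lp$scores[cl$sample_id], age = cl$age,
    os_days = cl$os_days, os_event = cl$os_event,
    stringsAsFactors = FALSE
  )
  cyto <- cl$cyto_risk
  cyto[cyto == "missing"] <- NA
  df$cyto_intermediate <- as.numeric(cyto == "intermediate")
  df$cyto_poor <- as.numeric(cyto == "poor")
  if (!is.null(cohort$mutations)) {
    for (g in rownames(cohort$mutations)) {
      if (g == "NONE") next
      df[[paste0("mut_", g)]] <- as.numeric(cohort$mutations[g, cl$sample_id])
    }
  }
  df
}

#' Progressively adjusted Cox model ladder
#'
#' Fits the standard ladder: LP alone; + age; + age + cytogenetic risk (two
#' indicators against favorable); + age + FLT3/NPM1/TP53; + IDH1/IDH2.
#' Each model is complete-case with its own n; a mutation covariate with no
#' variance after the complete-case restriction is dropped with a warning.
#'
#' @param cohort an [expression_cohort()] with clinical and mutation data.
#' @param lp a [compute_lp()] result.
#' @param model_specs optional list of character vectors of frame column
#'   names (besides `lp`) to override the default ladder.
#' @return named list of `survival_fit` objects.
#' @export
multivariable_suite <- function(cohort, lp, model_specs = NULL) {
  df <- survival_frame(cohort, lp)
  if (is.null(model_specs)) {
    cyto <- c("cyto_intermediate", "cyto_poor")
    mut3 <- intersect(c("mut_FLT3", "mut_NPM1", "mut_TP53"), names(df))
    mut5 <- intersect(c("mut_FLT3", "mut_NPM1", "mut_TP53",
                        "mut_IDH1", "mut_IDH2"), names(df))
    model_specs <- list(
      lp_only = character(),
      lp_age = "age",
      lp_age_cyto = c("age", cyto),
      lp_age_mut3 = c("age", mut3),
      lp_age_mut5 = c("age", mut5)
    )
  }
  lapply(model_specs, function(extra) {
    cols <- c("lp", extra)
    sub <- df[stats::complete.cases(df[c("os_days", "os_event", cols)]), ,
              drop = FALSE]
    keep <- cols[vapply(cols, function(cc) stats::var(sub[[cc]]) > 0, TRUE)]
    if (length(keep) < length(cols)) {
      warning(sprintf("dropping constant covariate(s): %s",
                      paste(setdiff(cols, keep), collapse = ", ")))
    }
    cox_fit(sub$os_days, sub$os_event, sub[keep])
  })
}

#' IPCW time-dependent cumulative/dynamic AUC
#'
#' At horizon t: cases are subjects with an event by t, controls are
#' event-free at t; the censoring distribution is estimated by
#' Kaplan-Meier on the flipped indicator, cases weighted by `1/G(T_i-)` and
#' controls by `1/G(t)`. Higher marker = higher risk.
#'
#' @param times,events follow-up and event indicator.
#' @param marker numeric risk marker.
#' @param horizons evaluation times, in years by default.
#' @param time_unit `"days"` (horizons converted with 365.25) or `"same"`
#'   (horizons already on the time scale).
#' @return data.frame (horizon, auc, n_cases, n_controls).
#' @export
timedep_auc <- function(times, events, marker, horizons,
                        time_unit = c("days", "same")) {
  time_unit <- match.arg(time_unit)
  ok <- stats::complete.cases(times, events, marker)
  times <- times[ok]; events <- events[ok]; marker <- marker[ok]
  t_eval <- if (time_unit == "days") horizons * 365.25 else horizons
  if (any(t_eval >= max(times))) {
    stop_horizon("horizon at or beyond maximum follow-up")
  }
  cens_km <- km_estimate(times, 1 - events)[[1]]
  out <- lapply(seq_along(horizons), function(h) {
    tt <- t_eval[h]
    case <- times <= tt & events == 1
    ctrl <- times > tt
    n_case <- sum(case); n_ctrl <- sum(ctrl)
    if (n_case < 10) {
      warning(sprintf("only %d events before horizon %g", n_case, horizons[h]))
    }
    if (n_case == 0 || n_ctrl == 0) {
      return(data.frame(horizon = horizons[h], auc = NA_real_,
                        n_cases = n_case, n_controls = n_ctrl))
    }
    g_case <- km_eval(cens_km, times[case], left = TRUE)
    g_ctrl <- rep(km_eval(cens_km, tt), n_ctrl)
    w_case <- ifelse(g_case > 0, 1 / g_case, 0)
    w_ctrl <- ifelse(g_ctrl > 0, 1 / g_ctrl, 0)
    m_case <- marker[case]; m_ctrl <- marker[ctrl]
    cmp <- outer(m_case, m_ctrl, function(a, b) (a > b) + 0.5 * (a == b))
    num <- as.numeric(t(w_case) %*% cmp %*% w_ctrl)
    den <- sum(w_case) * sum(w_ctrl)
    data.frame(horizon = horizons[h], auc = num / den,
               n_cases = n_case, n_controls = n_ctrl)
  })
  do.call(rbind, out)
}

#' Mutation-subgroup score contrasts
#'
#' Rank-sum-tests a per-sample score (e.g. the LP) between mutated and
#' wild-type samples for each gene, with BH across the gene list. Genes
#' with fewer than 5 mutants (after dropping missing calls) are skipped
#' with a reason.
#'
#' @param scores named per-sample numeric vector.
#' @param mutations genes x samples 0/1/NA matrix.
#' @param gene_list genes to test (default: all mutation rows).
#' @return data.frame (gene, median_mut, median_wt, n_mut, n_wt, p, q);
#'   attribute `skipped` is a named character vector of reasons.
#' @export
mutation_contrast <- function(scores, mutations, gene_list = rownames(mutations)) {
  skipped <- character()
  rows <- lapply(gene_list, function(g) {
    if (!g %in% rownames(mutations)) {
      skipped[[g]] <<- "not in mutation matrix"
      return(NULL)
    }
    calls <- mutations[g, names(scores)]
    ok <- !is.na(calls) & !is.na(scores)
    if (!any(ok)) {
      skipped[[g]] <<- "all calls missing"
      return(NULL)
    }
    mut <- scores[ok & calls == 1]; wt <- scores[ok & calls == 0]
    if (length(mut) < 5) {
      skipped[[g]] <<- sprintf("only %d mutants (need >= 5)", length(mut))
      return(NULL)
    }
    ts <- rank_sum_test(mut, wt)
    data.frame(gene = g, median_mut = stats::median(mut),
               median_wt = stats::median(wt), n_mut = length(mut),
               n_wt = length(wt), p = ts$p_value, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    warning("no testable mutation genes")
    out <- data.frame()
    attr(out, "skipped") <- skipped
    return(out)
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  attr(out, "skipped") <- skipped
  out
}
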