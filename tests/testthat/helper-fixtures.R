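# Shared fixtures and independent oracles used across the suite. Oracles are
# deliberately written from first principles (sums, counts, closed forms) so
# they never share code with the implementation they check.

# A tiny deterministic panel with one exact (noise-free) planted interaction.
noise_free_panel <- function(seed = 42, n_lines = 15, n_genes = 30,
                             n_drugs = 5, beta_on = 0.96, beta_co = -4 / 3) {
  simulate_panel(panel_spec(
    n_lines = n_lines, n_genes = n_genes, n_drugs = n_drugs,
    planted = list(planted_interaction(1, 1, 2, beta_on = beta_on,
                                       beta_co = beta_co)),
    noise_sd = 0, seed = seed
  ))
}

planted_panel <- function(seed, n_lines = 15, n_genes = 200, n_drugs = 20,
                          rho = -0.8, noise_sd = 1) {
  simulate_panel(panel_spec(
    n_lines = n_lines, n_genes = n_genes, n_drugs = n_drugs,
    planted = list(planted_interaction(
      1, 1, 2, beta_on = 0.96, target_partial_rho = rho, noise_sd = noise_sd
    )),
    noise_sd = noise_sd, seed = seed
  ))
}

null_panel <- function(seed, n_lines = 15, n_genes = 500, n_drugs = 50) {
  simulate_panel(panel_spec(n_lines = n_lines, n_genes = n_genes,
                            n_drugs = n_drugs, noise_sd = 1, seed = seed))
}

# Independent OLS oracle via the normal equations: returns coefficients and
# R-squared for response y on design-with-intercept X.
oracle_ols <- function(y, X) {
  X <- cbind(1, X)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- X %*% beta
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  list(beta = as.vector(beta), r2 = 1 - sse / sst,
       residuals = as.vector(y - fitted))
}

# Midranks computed from scratch (sorting + tie averaging), independent of
# base::rank.
oracle_midrank <- function(v) {
  n <- length(v)
  ord <- order(v)
  r <- numeric(n)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && v[ord[j + 1]] == v[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

# Product-moment correlation from raw sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# Recursive closed-form partial correlation.
oracle_partial <- function(x, y, z) {
  rxy <- oracle_pearson(x, y)
  rxz <- oracle_pearson(x, z)
  ryz <- oracle_pearson(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# Direct m * p_(i) / i cummin BH oracle.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  pmin(1, q)[order(o)]
}

# Pairwise-count Mann-Whitney U for group a (wins over b + half ties).
oracle_u <- function(a, b) {
  u <- 0
  for (ai in a) for (bj in b) {
    u <- u + (ai > bj) + 0.5 * (ai == bj)
  }
  u
}

# Literal running-sum GSEA enrichment score (full O(n) walk).
oracle_es <- function(scores_desc, in_set, weight_p = 1) {
  n <- length(scores_desc)
  hit_w <- abs(scores_desc)^weight_p * in_set
  hit_w <- hit_w / sum(hit_w)
  miss_w <- (!in_set) / sum(!in_set)
  running <- cumsum(hit_w - miss_w)
  running[which.max(abs(running))]
}

# Hand product-limit KM on a flat table; returns survival at each distinct
# event time.
oracle_km <- function(times, events) {
  et <- sort(unique(times[events == 1]))
  s <- 1
  out <- numeric(length(et))
  for (k in seq_along(et)) {
    d <- sum(times == et[k] & events == 1)
    r <- sum(times >= et[k])
    s <- s * (1 - d / r)
    out[k] <- s
  }
  list(times = et, survival = out)
}

# Small survival cohort used in several survival tests.
toy_cohort <- function(seed = 11, n = 300, log_hr = log(1.27),
                       censoring = 0.3) {
  simulate_cohort(cohort_spec(
    n_samples = n, n_genes = 20, true_log_hr = log_hr,
    censoring_rate = censoring, seed = seed
  ))
}
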