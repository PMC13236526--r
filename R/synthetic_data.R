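# Seeded generators for every input the pipeline consumes: a cell-line
# dependency panel with planted drug-gene co-dependencies, a primary-specimen
# expression/drug-response/survival cohort, a labelled single-cell atlas, and
# gene-set / regulon collections. Each generator is fully deterministic given
# its spec's seed and carries a ground-truth manifest for recovery tests.

#' Specify a synthetic dependency panel
#'
#' @param n_lines number of cell lines (>= 5; default 15, the size of a
#'   typical adult AML PRISM/DepMap intersection).
#' @param n_genes,n_drugs panel dimensions.
#' @param planted list of [planted_interaction()] objects.
#' @param noise_sd residual SD of the AUC model, in AUC units.
#' @param auc_baseline intercept of every drug's AUC model.
#' @param essential_shift optional negative location shift applied to a
#'   random 10% "essential" subset of genes (cosmetic realism; the
#'   correlation-based screen is location invariant).
#' @param seed integer RNG seed.
#' @return a `panel_spec` object.
#' @export
panel_spec <- function(n_lines = 15, n_genes = 100, n_drugs = 20,
                       planted = list(), noise_sd = 1, auc_baseline = 10,
                       essential_shift = 0, seed = 1) {
  if (n_lines < 5) stop_validation("n_lines must be >= 5")
  if (n_genes < 2 || n_drugs < 1) stop_validation("panel too small")
  if (noise_sd < 0) stop_validation("noise_sd must be non-negative")
  for (pl in planted) {
    if (!inherits(pl, "planted_interaction")) {
      stop_validation("planted must be a list of planted_interaction objects")
    }
    if (pl$drug > n_drugs || pl$on_target > n_genes || pl$co_target > n_genes) {
      stop_validation("planted drug/gene index out of range")
    }
  }
  structure(
    list(n_lines = as.integer(n_lines), n_genes = as.integer(n_genes),
         n_drugs = as.integer(n_drugs), planted = planted,
         noise_sd = noise_sd, auc_baseline = auc_baseline,
         essential_shift = essential_shift, seed = as.integer(seed)),
    class = "panel_spec"
  )
}

#' One planted drug-gene co-dependency
#'
#' The AUC of the planted drug is generated as
#' `baseline + beta_on * dep(on_target) + beta_co * dep(co_target) + noise`.
#' `target_partial_rho` documents the intended partial correlation; when
#' `beta_co` is omitted it is derived from that target via
#' [beta_co_for_partial_rho()].
#'
#' @param drug,on_target,co_target integer indices into the panel.
#' @param beta_on,beta_co effect sizes in AUC units per dependency unit.
#' @param target_partial_rho intended partial correlation in (-1, 1).
#' @param noise_sd noise SD used when deriving `beta_co` from the target.
#' @export
planted_interaction <- function(drug, on_target, co_target,
                                beta_on = 1, beta_co = NULL,
                                target_partial_rho = NULL, noise_sd = 1) {
  if (on_target == co_target) stop_validation("on_target must differ from co_target")
  if (is.null(beta_co)) {
    if (is.null(target_partial_rho)) {
      stop_validation("supply beta_co or target_partial_rho")
    }
    beta_co <- beta_co_for_partial_rho(target_partial_rho, noise_sd)
  }
  structure(
    list(drug = as.integer(drug), on_target = as.integer(on_target),
         co_target = as.integer(co_target), beta_on = beta_on,
         beta_co = beta_co, target_partial_rho = target_partial_rho),
    class = "planted_interaction"
  )
}

#' Co-target effect size for a target partial correlation
#'
#' With independent standard-normal dependency scores and residual SD
#' `noise_sd`, the population partial correlation between AUC and the
#' co-target dependency (controlling the on-target) is
#' `beta_co / sqrt(beta_co^2 + noise_sd^2)`; inverting gives
#' `beta_co = rho * noise_sd / sqrt(1 - rho^2)`.
#'
#' @param rho target partial correlation in (-1, 1).
#' @param noise_sd residual SD.
#' @export
beta_co_for_partial_rho <- function(rho, noise_sd = 1) {
  if (abs(rho) >= 1) stop_validation("|rho| must be < 1")
  rho * noise_sd / sqrt(1 - rho^2)
}

#' Simulate a matched drug-sensitivity / CRISPR-dependency panel
#'
#' Dependency scores are standard normal per gene; each drug's AUC is the
#' baseline plus noise, plus on- and co-target dependency effects for
#' planted drugs. Every drug is annotated with an on-target gene (planted
#' drugs with their planted one, others with a random gene) so the discovery
#' base model is always estimable. Lower AUC means greater sensitivity.
#'
#' @param spec a [panel_spec()].
#' @return a `dependency_panel` whose `truth` attribute is the ground-truth
#'   manifest (planted parameters, seed, noise).
#' @export
simulate_panel <- function(spec) {
  if (!inherits(spec, "panel_spec")) stop_validation("spec must be a panel_spec")
  with_seed(spec$seed, {
    line_ids <- sprintf("CL%02d", seq_len(spec$n_lines))
    gene_ids <- sprintf("G%05d", seq_len(spec$n_genes))
    drug_ids <- sprintf("D%04d", seq_len(spec$n_drugs))
    dep <- matrix(stats::rnorm(spec$n_genes * spec$n_lines),
                  nrow = spec$n_genes, dimnames = list(gene_ids, line_ids))
    if (spec$essential_shift != 0) {
      ess <- sample(spec$n_genes, max(1, round(0.1 * spec$n_genes)))
      dep[ess, ] <- dep[ess, ] - abs(spec$essential_shift)
    }
    on_targets <- sample(spec$n_genes, spec$n_drugs, replace = TRUE)
    auc <- spec$auc_baseline +
      matrix(stats::rnorm(spec$n_drugs * spec$n_lines, sd = spec$noise_sd),
             nrow = spec$n_drugs, dimnames = list(drug_ids, line_ids))
    for (pl in spec$planted) {
      on_targets[pl$drug] <- pl$on_target
      auc[pl$drug, ] <- spec$auc_baseline +
        pl$beta_on * dep[pl$on_target, ] + pl$beta_co * dep[pl$co_target, ] +
        stats::rnorm(spec$n_lines, sd = spec$noise_sd)
    }
    annotations <- stats::setNames(gene_ids[on_targets], drug_ids)
    panel <- dependency_panel(auc, dep, annotations)
    attr(panel, "truth") <- list(
      seed = spec$seed, noise_sd = spec$noise_sd,
      planted = lapply(spec$planted, function(pl) {
        list(drug_id = drug_ids[pl$drug], on_target = gene_ids[pl$on_target],
             co_target = gene_ids[pl$co_target], beta_on = pl$beta_on,
             beta_co = pl$beta_co, target_partial_rho = pl$target_partial_rho)
      })
    )
    panel
  })
}

#' Specify a synthetic expression cohort
#'
#' Emulates a primary-specimen cohort with normalized expression, per-sample
#' ex vivo drug AUC, binary mutation calls, and overall-survival clinical
#' covariates.
#'
#' @param n_samples,n_genes cohort dimensions.
#' @param expression_drug_effects list of `list(gene=, drug=, target_r=)`
#'   entries; each drug's AUC is generated with the stated Pearson
#'   correlation to that gene's expression.
#' @param signature_genes two-gene signature driving survival (default
#'   `c("SRC", "ACSL4")`).
#' @param true_log_hr log hazard ratio per unit of the composite linear
#'   predictor (sum of the signature z-scores).
#' @param censoring_rate expected fraction censored, in `[0, 1)`.
#' @param mutation_genes list of `list(gene=, prevalence=, lp_shift=)`;
#'   mutant samples get `lp_shift / n_signature_genes` added to each raw
#'   signature-gene expression value.
#' @param n_drugs total drugs in the AUC matrix (effect-free drugs are pure
#'   noise); drug names for effect entries are taken from the effect list.
#' @param auc_missing_rate per-drug fraction of samples with missing AUC
#'   (ex vivo panels are sparse).
#' @param baseline_hazard events per day at LP = 0 (default gives a median
#'   survival near two years).
#' @param seed integer seed.
#' @export
cohort_spec <- function(n_samples = 476, n_genes = 200,
                        expression_drug_effects = list(),
                        signature_genes = c("SRC", "ACSL4"),
                        true_log_hr = log(1.27), censoring_rate = 0.3,
                        mutation_genes = list(), n_drugs = NULL,
                        auc_missing_rate = 0, baseline_hazard = log(2) / 730,
                        seed = 1) {
  if (n_samples < 10) stop_validation("n_samples must be >= 10")
  if (censoring_rate < 0 || censoring_rate >= 1) {
    stop_validation("censoring_rate must be in [0, 1)")
  }
  for (eff in expression_drug_effects) {
    if (abs(eff$target_r) >= 1) stop_validation("|target_r| must be < 1")
  }
  for (mg in mutation_genes) {
    if (mg$prevalence <= 0 || mg$prevalence >= 1) {
      stop_validation("mutation prevalence must be in (0, 1)")
    }
  }
  structure(
    list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
         expression_drug_effects = expression_drug_effects,
         signature_genes = signature_genes, true_log_hr = true_log_hr,
         censoring_rate = censoring_rate, mutation_genes = mutation_genes,
         n_drugs = n_drugs, auc_missing_rate = auc_missing_rate,
         baseline_hazard = baseline_hazard, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Simulate an expression / drug-response / survival cohort
#'
#' Expression is standard normal per gene. Drug AUC for an effect entry
#' `(gene, drug, target_r)` is `10 + r * z(expr) + sqrt(1 - r^2) * noise`,
#' so the population Pearson correlation equals `target_r` (lower AUC =
#' greater sensitivity). Survival times are exponential with hazard
#' `h0 * exp(log_hr * LP)`; censoring is uniform on `(0, c)` with `c` solved
#' numerically so the expected censored fraction matches `censoring_rate`.
#'
#' @param spec a [cohort_spec()].
#' @return an `expression_cohort` with a `truth` attribute.
#' @export
simulate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop_validation("spec must be a cohort_spec")
  with_seed(spec$seed, {
    sample_ids <- sprintf("S%04d", seq_len(spec$n_samples))
    eff_genes <- vapply(spec$expression_drug_effects, `[[`, "", "gene")
    mut_genes <- vapply(spec$mutation_genes, `[[`, "", "gene")
    named <- unique(c(spec$signature_genes, eff_genes))
    n_anon <- max(0, spec$n_genes - length(named))
    gene_ids <- c(named, sprintf("GENE%05d", seq_len(n_anon)))
    expr <- matrix(stats::rnorm(length(gene_ids) * spec$n_samples),
                   nrow = length(gene_ids),
                   dimnames = list(gene_ids, sample_ids))

    # Mutations, and their planted shift on the raw signature-gene expression.
    mut <- matrix(NA_integer_, nrow = max(1, length(mut_genes)),
                  ncol = spec$n_samples,
                  dimnames = list(if (length(mut_genes)) mut_genes else "NONE",
                                  sample_ids))
    for (mg in spec$mutation_genes) {
      calls <- stats::rbinom(spec$n_samples, 1, mg$prevalence)
      mut[mg$gene, ] <- calls
      if (!is.null(mg$lp_shift) && mg$lp_shift != 0) {
        per_gene <- mg$lp_shift / length(spec$signature_genes)
        expr[spec$signature_genes, calls == 1] <-
          expr[spec$signature_genes, calls == 1] + per_gene
      }
    }

    # Drug AUC matrix.
    eff_drugs <- vapply(spec$expression_drug_effects, `[[`, "", "drug")
    n_drugs <- if (is.null(spec$n_drugs)) max(1, length(eff_drugs)) else spec$n_drugs
    extra <- max(0, n_drugs - length(eff_drugs))
    drug_ids <- c(eff_drugs, sprintf("drug%03d", seq_len(extra)))
    auc <- matrix(10 + stats::rnorm(length(drug_ids) * spec$n_samples),
                  nrow = length(drug_ids),
                  dimnames = list(drug_ids, sample_ids))
    for (eff in spec$expression_drug_effects) {
      r <- eff$target_r
      g <- zscore(expr[eff$gene, ])
      auc[eff$drug, ] <- 10 + r * g +
        sqrt(1 - r^2) * stats::rnorm(spec$n_samples)
    }
    if (spec$auc_missing_rate > 0) {
      drop <- matrix(stats::runif(length(auc)) < spec$auc_missing_rate,
                     nrow = nrow(auc))
      auc[drop] <- NA_real_
    }

    # Survival driven by the signature linear predictor.
    lp <- colSums(t(apply(expr[spec$signature_genes, , drop = FALSE], 1, zscore)))
    haz <- spec$baseline_hazard * exp(spec$true_log_hr * lp)
    t_event <- stats::rexp(spec$n_samples, rate = haz)
    if (spec$censoring_rate == 0) {
      os_days <- t_event
      os_event <- rep(1L, spec$n_samples)
    } else {
      cmax <- solve_censoring_bound(t_event, spec$censoring_rate)
      cens <- stats::runif(spec$n_samples, 0, cmax)
      os_days <- pmin(t_event, cens)
      os_event <- as.integer(t_event <= cens)
    }
    age <- round(pmin(90, pmax(18, stats::rnorm(spec$n_samples, 58, 12))))
    cyto <- sample(c("favorable", "intermediate", "poor"), spec$n_samples,
                   replace = TRUE, prob = c(0.2, 0.55, 0.25))
    clinical <- data.frame(
      sample_id = sample_ids, os_days = os_days, os_event = os_event,
      age = age, cyto_risk = cyto, stringsAsFactors = FALSE
    )
    cohort <- expression_cohort(expr, auc, mut, clinical)
    attr(cohort, "truth") <- list(
      seed = spec$seed, signature_genes = spec$signature_genes,
      true_log_hr = spec$true_log_hr, censoring_rate = spec$censoring_rate,
      expression_drug_effects = spec$expression_drug_effects,
      mutation_genes = spec$mutation_genes
    )
    cohort
  })
}

# Uniform(0, c) censoring: P(censored) = E[min(T, c)] / c, decreasing in c.
# Solve for the c matching the requested rate on the realized event times.
solve_censoring_bound <- function(t_event, rate) {
  f <- function(cc) mean(pmin(t_event, cc)) / cc - rate
  lo <- min(t_event) * 1e-3
  hi <- max(t_event) * 2
  while (f(hi) > 0) hi <- hi * 2   # rate very small: extend right bracket
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

#' Specify a synthetic labelled cell atlas
#'
#' @param cell_types named integer vector: cells per annotated type (>= 2
#'   types for fold reporting).
#' @param enriched_type label receiving the signature shift.
#' @param enrichment_shift amount added to each signature gene's expression
#'   in the enriched type (expression-SD units).
#' @param n_genes total genes; signature genes are included.
#' @param signature_genes genes carrying the shift.
#' @param seed integer seed.
#' @export
atlas_spec <- function(cell_types = c(mono = 300, hsc = 300, lymph = 300),
                       enriched_type = "mono", enrichment_shift = 0,
                       n_genes = 50, signature_genes = c("SRC", "ACSL4"),
                       seed = 1) {
  if (!enriched_type %in% names(cell_types)) {
    stop_validation("enriched_type must appear in cell_types")
  }
  if (any(cell_types < 1)) stop_validation("each cell type needs >= 1 cell")
  structure(
    list(cell_types = cell_types, enriched_type = enriched_type,
         enrichment_shift = enrichment_shift, n_genes = as.integer(n_genes),
         signature_genes = signature_genes, seed = as.integer(seed)),
    class = "atlas_spec"
  )
}

#' Simulate a cell-type-labelled expression atlas
#'
#' Per-cell expression is standard normal; the enrichment shift is added to
#' the signature genes in the enriched type only.
#'
#' @param spec an [atlas_spec()].
#' @return a `cell_atlas` (cells x genes matrix plus labels) with a `truth`
#'   attribute.
#' @export
simulate_atlas <- function(spec) {
  if (!inherits(spec, "atlas_spec")) stop_validation("spec must be an atlas_spec")
  with_seed(spec$seed, {
    labels <- rep(names(spec$cell_types), times = spec$cell_types)
    n_cells <- length(labels)
    named <- unique(spec$signature_genes)
    n_anon <- max(0, spec$n_genes - length(named))
    gene_ids <- c(named, sprintf("GENE%05d", seq_len(n_anon)))
    expr <- matrix(stats::rnorm(n_cells * length(gene_ids)),
                   nrow = n_cells,
                   dimnames = list(sprintf("cell%05d", seq_len(n_cells)),
                                   gene_ids))
    if (spec$enrichment_shift != 0) {
      sel <- labels == spec$enriched_type
      expr[sel, spec$signature_genes] <-
        expr[sel, spec$signature_genes] + spec$enrichment_shift
    }
    atlas <- cell_atlas(expr, labels)
    attr(atlas, "truth") <- list(
      seed = spec$seed, enriched_type = spec$enriched_type,
      enrichment_shift = spec$enrichment_shift,
      signature_genes = spec$signature_genes
    )
    atlas
  })
}

#' Simulate gene-set and regulon collections
#'
#' Random member draws over a gene universe; "true" sets/regulons are built
#' from the genes most correlated with a reference score (typically the
#' cohort linear predictor), so enrichment methods have a planted positive.
#'
#' @param universe character vector of gene ids.
#' @param n_sets number of gene sets.
#' @param set_size members per set (>= 5).
#' @param n_true_enriched how many sets are drawn from `correlated_genes`.
#' @param correlated_genes genes known to track the reference score (needed
#'   when `n_true_enriched > 0`).
#' @param n_regulons,regulon_size regulon collection dimensions.
#' @param n_true_regulons regulons drawn from `correlated_genes` with mode +1.
#' @param seed integer seed.
#' @return list with `gene_sets` (name -> members), `regulons`
#'   (data.frame tf/target/mode), and a `truth` element naming the planted
#'   sets/regulons.
#' @export
simulate_gene_sets <- function(universe, n_sets = 20, set_size = 20,
                               n_true_enriched = 0, correlated_genes = NULL,
                               n_regulons = 10, regulon_size = 15,
                               n_true_regulons = 0, seed = 1) {
  if (set_size < 5) stop_validation("set_size must be >= 5")
  if ((n_true_enriched > 0 || n_true_regulons > 0) && is.null(correlated_genes)) {
    stop_validation("correlated_genes required when planting true sets")
  }
  with_seed(seed, {
    sets <- list()
    true_sets <- character()
    for (i in seq_len(n_sets)) {
      nm <- sprintf("SET_%03d", i)
      if (i <= n_true_enriched) {
        pool <- correlated_genes
        sets[[nm]] <- sample(pool, min(set_size, length(pool)))
        true_sets <- c(true_sets, nm)
      } else {
        sets[[nm]] <- sample(universe, set_size)
      }
    }
    regs <- list()
    true_regs <- character()
    for (i in seq_len(n_regulons)) {
      tf <- sprintf("TF_%03d", i)
      if (i <= n_true_regulons) {
        targets <- sample(correlated_genes, min(regulon_size, length(correlated_genes)))
        mode <- rep(1, length(targets))
        true_regs <- c(true_regs, tf)
      } else {
        targets <- sample(universe, regulon_size)
        mode <- sample(c(-1, 1), length(targets), replace = TRUE)
      }
      regs[[tf]] <- data.frame(tf = tf, target = targets, mode = mode,
                               stringsAsFactors = FALSE)
    }
    list(
      gene_sets = sets,
      regulons = do.call(rbind, c(regs, list(make.row.names = FALSE))),
      truth = list(seed = seed, true_sets = true_sets, true_regulons = true_regs)
    )
  })
}
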