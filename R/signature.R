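# Signature projection onto a labelled single-cell atlas, and the
# genome-wide correlation landscape of a cohort against the LP.

#' Construct a labelled cell atlas
#'
#' @param expression cells x genes numeric matrix (normalized), unique gene
#'   column names.
#' @param cell_type label per cell (length = rows of `expression`, no NA).
#' @export
cell_atlas <- function(expression, cell_type) {
  expression <- as.matrix(expression)
  if (is.null(colnames(expression)) || anyDuplicated(colnames(expression))) {
    stop_validation("expression needs unique gene column names")
  }
  if (length(cell_type) != nrow(expression) || anyNA(cell_type)) {
    stop_validation("every cell needs a label")
  }
  structure(list(expression = expression, cell_type = as.character(cell_type)),
            class = "cell_atlas")
}

#' Project a gene signature onto a cell atlas
#'
#' Per-cell score = weighted sum of per-gene z-scores, with z computed
#' across ALL cells pooled (per-type standardization would erase the
#' enrichment being measured). The fold of the top type over the second is
#' reported when both means are positive, otherwise their difference.
#'
#' @param atlas a [cell_atlas()].
#' @param genes signature genes (must be present).
#' @param weights per-gene weights (default 1).
#' @return list with `cell_scores`, `type_means` (data.frame sorted by
#'   decreasing mean), `top_type`, `fold` and `fold_type`
#'   (`"ratio"`/`"difference"`/NA).
#' @export
project_signature <- function(atlas, genes, weights = rep(1, length(genes))) {
  missing <- setdiff(genes, colnames(atlas$expression))
  if (length(missing)) {
    stop_gene_not_found(sprintf("gene(s) absent from atlas: %s",
                                paste(missing, collapse = ", ")),
                        genes = missing)
  }
  z <- vapply(genes, function(g) zscore(atlas$expression[, g]),
              numeric(nrow(atlas$expression)))
  scores <- as.vector(z %*% weights)
  means <- tapply(scores, atlas$cell_type, mean)
  tm <- data.frame(cell_type = names(means), mean_score = as.numeric(means),
                   n_cells = as.integer(table(atlas$cell_type)[names(means)]),
                   stringsAsFactors = FALSE)
  tm <- tm[order(-tm$mean_score), , drop = FALSE]
  rownames(tm) <- NULL
  fold <- NA_real_; fold_type <- NA_character_
  if (nrow(tm) >= 2) {
    top <- tm$mean_score[1]; second <- tm$mean_score[2]
    if (top > 0 && second > 0) {
      fold <- top / second; fold_type <- "ratio"
    } else {
      fold <- top - second; fold_type <- "difference"
    }
  } else {
    warning("single cell type: fold undefined")
  }
  list(cell_scores = scores, type_means = tm, top_type = tm$cell_type[1],
       fold = fold, fold_type = fold_type)
}

#' Genome-wide correlation landscape against a score
#'
#' Spearman correlation of every gene's expression with the per-sample
#' score; rank 1 = most positively correlated, ties broken by gene id.
#' Genes belonging to the score's own signature are flagged tautological.
#'
#' @param expression genes x samples matrix.
#' @param lp a [compute_lp()] result or a named per-sample numeric vector.
#' @return `ranked_landscape` data.frame (gene, rho, p, rank, tautological)
#'   sorted by rank; constant genes are skipped and listed in the `skipped`
#'   attribute; `n_genes_total` attribute gives the ranked universe size.
#' @export
landscape <- function(expression, lp) {
  sig_genes <- character()
  if (inherits(lp, "linear_predictor")) {
    sig_genes <- lp$genes
    lp <- lp$scores
  }
  if (!identical(colnames(expression), names(lp))) {
    expression <- expression[, names(lp), drop = FALSE]
  }
  n <- ncol(expression)
  if (n < 20) stop_insufficient("landscape needs >= 20 samples")
  sds <- apply(expression, 1, stats::sd)
  skipped <- rownames(expression)[sds == 0]
  keep <- sds > 0
  m <- expression[keep, , drop = FALSE]
  rm_ranks <- row_ranks(m)
  rv <- rank(lp)
  dmc <- rm_ranks - rowMeans(rm_ranks)
  rvc <- rv - mean(rv)
  rho <- as.vector(dmc %*% rvc) / (sqrt(rowSums(dmc^2)) * sqrt(sum(rvc^2)))
  rho <- pmax(-1, pmin(1, rho))
  p <- ifelse(abs(rho) >= 1 - 1e-15, 0,
              2 * stats::pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), n - 2))
  out <- data.frame(gene = rownames(m), rho = rho, p = p,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$rho, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$tautological <- out$gene %in% sig_genes
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "n_genes_total") <- nrow(out)
  class(out) <- c("ranked_landscape", class(out))
  out
}

#' Extract a functional gene panel from a landscape
#'
#' Reports the landscape rho and rank for named groups of genes (e.g.
#' ferroptosis execution, iron metabolism, canonical defense, alternative
#' defense, cystine import), preserving the configured group and gene
#' order. No new statistics are computed; absent genes get NA and a flag.
#'
#' @param landscape a [landscape()] result.
#' @param groups named list: group label -> character vector of genes.
#' @return data.frame (gene, group, rho, rank, missing).
#' @export
panel_report <- function(landscape, groups) {
  rows <- lapply(names(groups), function(grp) {
    genes <- groups[[grp]]
    idx <- match(genes, landscape$gene)
    data.frame(gene = genes, group = grp,
               rho = landscape$rho[idx], rank = landscape$rank[idx],
               missing = is.na(idx), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
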