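# Plain-text readers and writers. Matrices travel as TSV with row ids in
# the first column; ground-truth manifests and run metadata as JSON.

write_matrix_tsv <- function(m, path, id_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a dependency panel to a directory
#'
#' Emits `auc.tsv` (drugs x lines), `dependency.tsv` (genes x lines),
#' `annotations.tsv` (drug, on_target), and — when the panel was simulated —
#' `truth.json` with the planted ground truth.
#'
#' @param panel a [dependency_panel()].
#' @param dir output directory (created if needed).
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(panel$auc, file.path(dir, "auc.tsv"), "drug_id")
  write_matrix_tsv(panel$dependency, file.path(dir, "dependency.tsv"), "gene_id")
  utils::write.table(
    data.frame(drug_id = names(panel$annotations),
               on_target = unname(panel$annotations)),
    file.path(dir, "annotations.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  truth <- attr(panel, "truth")
  if (!is.null(truth)) {
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a dependency panel from a directory
#' @param dir directory written by [write_panel()] (or equivalent TSVs).
#' @export
read_panel <- function(dir) {
  ann <- utils::read.table(file.path(dir, "annotations.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  dependency_panel(
    read_matrix_tsv(file.path(dir, "auc.tsv")),
    read_matrix_tsv(file.path(dir, "dependency.tsv")),
    stats::setNames(ann$on_target, ann$drug_id)
  )
}

#' Write an expression cohort to a directory
#'
#' Emits `expression.tsv`, `drug_auc.tsv`, `mutations.tsv`, `clinical.tsv`
#' and, for simulated cohorts, `truth.json`.
#'
#' @param cohort an [expression_cohort()].
#' @param dir output directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(cohort$expression, file.path(dir, "expression.tsv"), "gene_id")
  if (!is.null(cohort$drug_auc)) {
    write_matrix_tsv(cohort$drug_auc, file.path(dir, "drug_auc.tsv"), "drug_id")
  }
  if (!is.null(cohort$mutations)) {
    write_matrix_tsv(cohort$mutations, file.path(dir, "mutations.tsv"), "gene_id")
  }
  if (!is.null(cohort$clinical)) {
    utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  truth <- attr(cohort, "truth")
  if (!is.null(truth)) {
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read an expression cohort from a directory
#' @param dir directory written by [write_cohort()].
#' @export
read_cohort <- function(dir) {
  path <- function(f) file.path(dir, f)
  expression_cohort(
    read_matrix_tsv(path("expression.tsv")),
    if (file.exists(path("drug_auc.tsv"))) read_matrix_tsv(path("drug_auc.tsv")),
    if (file.exists(path("mutations.tsv"))) read_matrix_tsv(path("mutations.tsv")),
    if (file.exists(path("clinical.tsv"))) {
      utils::read.table(path("clinical.tsv"), sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
    }
  )
}

#' Write a cell atlas to a directory (`expression.tsv` cells x genes,
#' `labels.tsv`)
#' @param atlas a [cell_atlas()].
#' @param dir output directory.
#' @export
write_atlas <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(atlas$expression, file.path(dir, "expression.tsv"), "cell_id")
  utils::write.table(
    data.frame(cell_id = rownames(atlas$expression),
               cell_type = atlas$cell_type),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}

#' Read a cell atlas from a directory
#' @param dir directory written by [write_atlas()].
#' @export
read_atlas <- function(dir) {
  expr <- read_matrix_tsv(file.path(dir, "expression.tsv"))
  labels <- utils::read.table(file.path(dir, "labels.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
  cell_atlas(expr, labels$cell_type[match(rownames(expr), labels$cell_id)])
}

# Deterministic TSV writer for result tables (fixed significant digits so a
# rerun under the same seed is byte-identical).
write_result_tsv <- function(df, path, digits = 10) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
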