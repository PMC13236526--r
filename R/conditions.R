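# Classed conditions used across the package. Every validation failure is a
# typed condition so callers (and tests) can discriminate with tryCatch().

codep_error <- function(class, message, ...) {
  structure(
    class = c(class, "codep_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
}

stop_degenerate <- function(message, ...) {
  stop(codep_error("degenerate_input_error", message, ...))
}

stop_insufficient <- function(message, ...) {
  stop(codep_error("insufficient_data_error", message, ...))
}

stop_validation <- function(message, ...) {
  stop(codep_error("validation_error", message, ...))
}

stop_config <- function(message, ...) {
  stop(codep_error("config_error", message, ...))
}

stop_annotation <- function(message, ...) {
  stop(codep_error("annotation_error", message, ...))
}

stop_collinear <- function(message, genes = NULL) {
  stop(codep_error("collinearity_error", message, genes = genes))
}

stop_mapping <- function(message, ...) {
  stop(codep_error("mapping_error", message, ...))
}

stop_gene_not_found <- function(message, genes = NULL) {
  stop(codep_error("gene_not_found_error", message, genes = genes))
}

stop_quantile <- function(message, ...) {
  stop(codep_error("quantile_error", message, ...))
}

stop_group <- function(message, ...) {
  stop(codep_error("group_error", message, ...))
}

stop_no_events <- function(message, ...) {
  stop(codep_error("no_events_error", message, ...))
}

stop_convergence <- function(message, ...) {
  stop(codep_error("convergence_error", message, ...))
}

stop_separation <- function(message, ...) {
  stop(codep_error("separation_error", message, ...))
}

stop_horizon <- function(message, ...) {
  stop(codep_error("horizon_error", message, ...))
}

stop_empty_screen <- function(message, skip_log = NULL) {
  stop(codep_error("empty_screen_error", message, skip_log = skip_log))
}

# Run `expr` with a private RNG stream seeded at `seed`; the caller's
# .Random.seed is restored afterwards so seeded helpers do not perturb
# surrounding simulations.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}
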