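# Preranked gene-set enrichment against the LP-correlation ranking, and a
# simplified signed-mean regulon-activity score. The enrichment statistic is
# the weighted Kolmogorov-Smirnov running-sum ES with a gene-label
# permutation null, sign-matched NES normalization, and the standard
# sign-pooled NES FDR.

#' Read a GMT gene-set file
#'
#' @param path tab-delimited file: set name, description, members.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, "")
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
}

#' Read a regulon TSV (tf, target, mode)
#' @param path three-column TSV with header.
#' @export
read_regulons <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("tf", "target", "mode") %in% names(df))) {
    stop_validation("regulon file needs tf, target, mode columns")
  }
  if (!all(df$mode %in% c(-1, 1))) stop_validation("mode must be +1 or -1")
  df
}

#' Write a regulon TSV
#' @param regulons data.frame with tf, target, mode.
#' @param path output path.
#' @export
write_regulons <- function(regulons, path) {
  utils::write.table(regulons, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Ranking metric for preranked enrichment
#'
#' Genes sorted by Spearman correlation with the score, descending
#' (delegates to [landscape()]).
#'
#' @inheritParams landscape
#' @return data.frame (gene, score) sorted by decreasing score.
#' @export
rank_metric <- function(expression, lp) {
  ls <- landscape(expression, lp)
  data.frame(gene = ls$gene, score = ls$rho, stringsAsFactors = FALSE)
}

# Enrichment score for hit positions in a ranked score vector (descending).
# Returns the signed max-deviation running-sum ES. O(k log k) given the
# precomputed |score|^p vector and its total ordering.
es_at_positions <- function(abs_wt, n, pos, weight_p) {
  k <- length(pos)
  pos <- sort(pos)
  w <- if (weight_p == 0) rep(1, k) else abs_wt[pos]
  wsum <- sum(w)
  if (wsum == 0) w <- rep(1, k); wsum <- sum(w)
  hit_cum <- cumsum(w) / wsum
  miss_step <- 1 / (n - k)
  # Running sum just after each hit, and just before each hit.
  after <- hit_cum - (pos - seq_len(k)) * miss_step
  before <- c(0, hit_cum[-k]) - (pos - seq_len(k)) * miss_step
  cand <- c(after, before)
  cand[which.max(abs(cand))]
}

#' Enrichment score of one gene set (exposed for oracle testing)
#'
#' Weighted KS running-sum statistic: hit increments proportional to
#' `|score|^weight_p` (normalized within the set), miss decrements uniform
#' `1/(n - k)`; ES is the running sum at its maximum absolute deviation.
#'
#' @param scores ranking scores sorted in decreasing order.
#' @param hits logical or index vector marking set members in that order.
#' @param weight_p score weighting exponent (1 canonical, 0 unweighted).
#' @export
gsea_es <- function(scores, hits, weight_p = 1) {
  n <- length(scores)
  pos <- if (is.logical(hits)) which(hits) else as.integer(hits)
  k <- length(pos)
  if (k == 0 || k >= n) stop_validation("set must be a proper non-empty subset")
  es_at_positions(abs(scores)^weight_p, n, pos, weight_p)
}

#' Preranked gene-set enrichment analysis
#'
#' ES per set as in [gsea_es()]; null distribution by gene-label
#' permutation (random positions, `n_perm` per set); NES = ES divided by
#' the mean |null ES| of matching sign; nominal p from the matching-sign
#' null (add-one); FDR by the standard sign-pooled NES procedure.
#'
#' @param ranked data.frame (gene, score) sorted by decreasing score, e.g.
#'   from [rank_metric()].
#' @param sets named list of character vectors.
#' @param weight_p score weighting exponent (default 1).
#' @param n_perm permutations per set (default 1000).
#' @param seed RNG seed.
#' @param min_size,max_size set-size bounds after intersection with the
#'   ranked universe.
#' @param min_universe warn (not error) below this many ranked genes.
#' @return data.frame (set, es, nes, p, fdr, size); skipped sets (outside
#'   the size bounds) listed in the `skipped` attribute.
#' @export
gsea_preranked <- function(ranked, sets, weight_p = 1, n_perm = 1000,
                           seed = 1, min_size = 5, max_size = 500,
                           min_universe = 100) {
  stopifnot(is.data.frame(ranked), all(c("gene", "score") %in% names(ranked)))
  n <- nrow(ranked)
  if (n < min_universe) {
    warning(sprintf("ranked universe has %d genes (< %d)", n, min_universe))
  }
  abs_wt <- abs(ranked$score)^weight_p
  skipped <- character()
  rows <- vector("list", length(sets))
  with_seed(seed, {
    for (i in seq_along(sets)) {
      nm <- names(sets)[i]
      pos <- which(ranked$gene %in% sets[[i]])
      k <- length(pos)
      if (k < min_size || k > max_size || k >= n) {
        skipped[[nm]] <- sprintf("size %d outside [%d, %d]", k, min_size,
                                 min(max_size, n - 1))
        next
      }
      es <- es_at_positions(abs_wt, n, pos, weight_p)
      null_es <- vapply(seq_len(n_perm), function(j) {
        es_at_positions(abs_wt, n, sample.int(n, k), weight_p)
      }, numeric(1))
      same <- null_es[sign(null_es) == sign(es)]
      nes <- if (length(same)) es / mean(abs(same)) else NA_real_
      p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
      rows[[i]] <- data.frame(set = nm, es = es, nes = nes, p = p, size = k,
                              stringsAsFactors = FALSE)
      attr(rows[[i]], "null_nes") <- if (length(same)) {
        null_es / mean(abs(same))
      } else numeric()
    }
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) {
    out <- data.frame()
    attr(out, "skipped") <- skipped
    return(out)
  }
  null_nes_all <- unlist(lapply(rows[keep], attr, "null_nes"))
  out <- do.call(rbind, rows[keep])
  # Sign-pooled NES FDR: fraction of pooled null NES at least as extreme
  # (same sign) over fraction of observed NES at least as extreme.
  out$fdr <- vapply(seq_len(nrow(out)), function(i) {
    nes <- out$nes[i]
    if (is.na(nes)) return(NA_real_)
    sgn <- sign(nes)
    null_same <- null_nes_all[sign(null_nes_all) == sgn]
    obs_same <- out$nes[!is.na(out$nes) & sign(out$nes) == sgn]
    num <- if (length(null_same)) mean(abs(null_same) >= abs(nes)) else 0
    den <- mean(abs(obs_same) >= abs(nes))
    min(1, num / den)
  }, numeric(1))
  out <- out[order(-abs(out$nes)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Simplified regulon activity (signed mean z)
#'
#' Activity(tf, sample) = mean over the regulon's targets of
#' `mode * z(target expression)`. A deliberately simplified VIPER-style
#' score; undersized regulons (after intersecting targets with the
#' expression matrix) are skipped.
#'
#' @param expression genes x samples matrix.
#' @param regulons data.frame (tf, target, mode).
#' @param min_size minimum targets present (default 10).
#' @return TF x sample activity matrix; `skipped` attribute names
#'   undersized regulons.
#' @export
regulon_activity <- function(expression, regulons, min_size = 10) {
  z <- t(apply(expression, 1, function(v) {
    if (length(unique(v[!is.na(v)])) < 2) rep(NA_real_, length(v)) else zscore(v)
  }))
  colnames(z) <- colnames(expression)
  tfs <- unique(regulons$tf)
  skipped <- character()
  rows <- list()
  for (tf in tfs) {
    sub <- regulons[regulons$tf == tf & regulons$target %in% rownames(z), ,
                    drop = FALSE]
    sub <- sub[!is.na(z[sub$target, 1]), , drop = FALSE]
    if (nrow(sub) < min_size) {
      skipped[[tf]] <- sprintf("%d usable targets (< %d)", nrow(sub), min_size)
      next
    }
    rows[[tf]] <- colMeans(sub$mode * z[sub$target, , drop = FALSE])
  }
  if (!length(rows)) {
    out <- matrix(numeric(), 0, ncol(expression))
    attr(out, "skipped") <- skipped
    return(out)
  }
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  out
}

#' Correlate regulon activity with a score
#'
#' Spearman rho of each TF's activity with the per-sample score, BH across
#' TFs, sorted by decreasing |rho|.
#'
#' @param activity TF x sample matrix from [regulon_activity()].
#' @param lp a [compute_lp()] result or named numeric vector.
#' @param top optionally keep only the top-|rho| TFs.
#' @return data.frame (tf, rho, p, q).
#' @export
correlate_activity <- function(activity, lp, top = NULL) {
  scores <- if (inherits(lp, "linear_predictor")) lp$scores else lp
  rows <- lapply(rownames(activity), function(tf) {
    r <- correlate(activity[tf, ], scores[colnames(activity)],
                   method = "spearman")
    data.frame(tf = tf, rho = r$estimate, p = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(-abs(out$rho), out$tf), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top)) out <- utils::head(out, top)
  out
}
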