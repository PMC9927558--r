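## Per-complex ranking metrics: ROC-AUC, PR-AUC, hit rate, success rate, and
## distribution summaries across complexes. All metrics are computed per
## complex and only then aggregated; scores are never pooled across
## complexes.

#' Rank the docking models of one complex
#'
#' Descending by score; ties broken lexicographically by model id so the
#' ranking is deterministic.
#'
#' @param records data frame with columns complex_id, model_id, score (and
#'   optionally is_positive).
#' @param complex_id the complex to rank.
#' @return the records of that complex in rank order.
#' @export
rank_models <- function(records, complex_id) {
  r <- records[records$complex_id == complex_id, , drop = FALSE]
  if (!nrow(r))
    grank_stop(sprintf("no predictions for complex '%s'", complex_id),
               "grank_unknown_complex_error")
  r <- r[order(-r$score, r$model_id), , drop = FALSE]
  rownames(r) <- NULL
  r
}

#' Hit rate among the top-k ranked models
#'
#' `N_hits(k) / N_pos`: the number of positive (near-native) models among the
#' top k ranked models of a complex, divided by the complex's total number of
#' positives. Undefined when the complex has no positives (such complexes are
#' left out of assessment).
#'
#' @param ranked_positives logical vector, positives flags in rank order.
#' @param k prefix size, `0 <= k <= length(ranked_positives)`.
#' @return fraction in `[0, 1]`.
#' @export
hit_rate <- function(ranked_positives, k) {
  npos <- sum(ranked_positives)
  if (npos == 0L)
    grank_stop("hit rate undefined for a complex with no positive models",
               "grank_no_positives_error")
  if (k < 0L || k > length(ranked_positives))
    grank_stop("k out of range", "grank_range_error")
  if (k == 0L) return(0)
  sum(ranked_positives[seq_len(k)]) / npos
}

#' Success rate at top-k across complexes
#'
#' Fraction of complexes with at least one positive model among their top-k
#' ranked models.
#'
#' @param per_complex_ranked named list: per complex, positives flags in rank
#'   order.
#' @param k prefix size (capped at each complex's model count).
#' @return fraction in `[0, 1]`.
#' @export
success_rate <- function(per_complex_ranked, k) {
  stopifnot(length(per_complex_ranked) >= 1L, k >= 0L)
  if (k == 0L) return(0)
  hits <- vapply(per_complex_ranked, function(v) {
    any(v[seq_len(min(k, length(v)))])
  }, logical(1L))
  mean(hits)
}

#' ROC-AUC by pairwise concordance
#'
#' Equals the probability that a random positive outscores a random negative,
#' counting ties as 1/2 — computed exactly through midranks, so it is
#' independent of any tie-breaking order and invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores numeric scores; `labels` logical (TRUE = positive).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0L || nneg == 0L)
    grank_stop("ROC-AUC needs both classes present", "grank_single_class_error")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' PR-AUC with step-wise interpolation
#'
#' Area under the precision-recall curve traced by sweeping a threshold over
#' the distinct score values (highest first): `sum over thresholds of
#' (R_t - R_{t-1}) * P_t`, precision held constant between recall points.
#' Models tied on score enter together, so the result does not depend on
#' tie-breaking.
#'
#' @inheritParams roc_auc
#' @return area in `(0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  npos <- sum(labels)
  if (npos == 0L)
    grank_stop("PR-AUC needs at least one positive", "grank_no_positives_error")
  thr <- sort(unique(scores), decreasing = TRUE)
  ## cumulative counts at thresholds: all models with score >= t
  o <- order(-scores)
  s_sorted <- scores[o]; l_sorted <- labels[o]
  cum_tp <- cumsum(l_sorted)
  cum_n <- seq_along(s_sorted)
  last_of_group <- !duplicated(s_sorted, fromLast = TRUE)
  tp <- cum_tp[last_of_group]
  nn <- cum_n[last_of_group]
  recall <- tp / npos
  precision <- tp / nn
  sum(diff(c(0, recall)) * precision)
}

#' Per-complex ranking metrics
#'
#' Computes ROC-AUC, PR-AUC and the full hit-rate curve (k = 0..N) for each
#' complex of a prediction table. Complexes lacking either class for a metric
#' are skipped with a count in the result.
#'
#' @param records data frame with complex_id, model_id, score, is_positive.
#' @return a `grank_metrics` list: `per_complex` data frame (complex_id,
#'   roc_auc, pr_auc, n_pos, n_neg), `hit_rate_curves` (named list of numeric
#'   vectors indexed by k = 0..N), `n_skipped_no_positives`.
#' @export
evaluate_predictions <- function(records) {
  stopifnot(all(c("complex_id", "model_id", "score", "is_positive") %in%
                  names(records)))
  ids <- unique(records$complex_id)
  rows <- list(); curves <- list(); skipped <- 0L
  for (id in ids) {
    r <- rank_models(records, id)
    pos <- as.logical(r$is_positive)
    npos <- sum(pos); nneg <- sum(!pos)
    if (npos == 0L) {           # assessment leaves out all-negative complexes
      skipped <- skipped + 1L
      next
    }
    roc <- if (nneg > 0L) roc_auc(r$score, pos) else NA_real_
    pr <- pr_auc(r$score, pos)
    curves[[id]] <- vapply(0:length(pos), function(k) hit_rate(pos, k),
                           numeric(1L))
    rows[[id]] <- data.frame(complex_id = id, roc_auc = roc, pr_auc = pr,
                             n_pos = npos, n_neg = nneg,
                             stringsAsFactors = FALSE)
  }
  if (!length(rows))
    grank_stop("no complex with positive models to assess",
               "grank_no_positives_error")
  structure(list(per_complex = do.call(rbind, unname(rows)),
                 hit_rate_curves = curves,
                 n_skipped_no_positives = skipped),
            class = "grank_metrics")
}

#' @export
print.grank_metrics <- function(x, ...) {
  s <- summarize_metrics(x)
  cat(sprintf("ranking metrics over %d complexes (%d skipped, no positives)\n",
              nrow(x$per_complex), x$n_skipped_no_positives))
  print(s$summary, row.names = FALSE)
  invisible(x)
}

#' Distribution summary of per-complex metrics
#'
#' Median and 25/75% quantiles (linear interpolation between order
#' statistics) of the per-complex ROC-AUC and PR-AUC, plus quantile curves of
#' the hit rate as a function of k.
#'
#' @param metrics a `grank_metrics` object from [evaluate_predictions()].
#' @param k_max largest k for the hit-rate summary (default: largest complex).
#' @return list with `summary` (metric, q25, median, q75) and
#'   `hit_rate_summary` (k, q25, median, q75); hit-rate curves shorter than
#'   `k_max` hold their final value, i.e. 1.
#' @export
summarize_metrics <- function(metrics, k_max = NULL) {
  pc <- metrics$per_complex
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE,
                                    names = FALSE)
  sm <- rbind(
    data.frame(metric = "roc_auc", t(qs(pc$roc_auc))),
    data.frame(metric = "pr_auc", t(qs(pc$pr_auc)))
  )
  names(sm) <- c("metric", "q25", "median", "q75")
  if (is.null(k_max))
    k_max <- max(vapply(metrics$hit_rate_curves, length, integer(1L))) - 1L
  hr <- t(vapply(0:k_max, function(k) {
    vals <- vapply(metrics$hit_rate_curves, function(cv) {
      cv[min(k, length(cv) - 1L) + 1L]
    }, numeric(1L))
    qs(vals)
  }, numeric(3L)))
  hit_rate_summary <- data.frame(k = 0:k_max, q25 = hr[, 1L],
                                 median = hr[, 2L], q75 = hr[, 3L])
  list(summary = sm, hit_rate_summary = hit_rate_summary)
}

#' Success-rate table at chosen k values
#'
#' @param records prediction table as in [evaluate_predictions()].
#' @param ks integer vector of prefix sizes.
#' @return data frame (k, success_rate). Complexes without positives are
#'   excluded, as in per-complex assessment.
#' @export
success_rate_table <- function(records, ks = c(1L, 10L, 25L, 50L, 100L)) {
  ids <- unique(records$complex_id)
  ranked <- list()
  for (id in ids) {
    pos <- as.logical(rank_models(records, id)$is_positive)
    if (any(pos)) ranked[[id]] <- pos
  }
  data.frame(k = ks,
             success_rate = vapply(ks, function(k) success_rate(ranked, k),
                                   numeric(1L)))
}
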