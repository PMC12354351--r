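# Ranking evaluation: AUC, Hits@k, mean rank, mean reciprocal rank, and the
# positional unit hit rate with its first-three-position average.
#
# Conventions (documented, configurable where noted):
#  * AUC ties count 1/2 (Mann-Whitney), computed exactly via average ranks.
#  * Mean rank / MRR evaluate one unit per (sample, true label); a
#    best-rank-per-sample alternative is available via `unit = "best"`.
#  * A label absent from a ranking gets rank length(ranking) + 1, flagged.

#' Construct a ranked prediction for one sample
#'
#' @param sample_id identifier.
#' @param ranked_elements element ids ordered best-first (rank 1 first); no
#'   duplicates.
#' @param scores numeric scores aligned with `ranked_elements` (optional).
#' @param label_set true element ids (nonempty for evaluation).
#' @return a `ranked_prediction`.
#' @export
ranked_prediction <- function(sample_id, ranked_elements, scores = NULL, label_set) {
  if (anyDuplicated(ranked_elements))
    stop("ranked_elements contains duplicates for sample ", sample_id)
  if (!is.null(scores) && length(scores) != length(ranked_elements))
    stop("scores and ranked_elements lengths differ for sample ", sample_id)
  structure(list(sample_id = sample_id,
                 ranked_elements = as.integer(ranked_elements),
                 scores = scores,
                 label_set = as.integer(unique(label_set))),
            class = "ranked_prediction")
}

#' Area under the ROC curve over scored samples
#'
#' Fraction of (positive, negative) pairs ranked correctly by score, ties
#' counted 1/2; computed exactly through the average-rank (Mann-Whitney)
#' identity.
#'
#' @param scores numeric prediction scores.
#' @param is_positive logical vector aligned with `scores`.
#' @return value in \[0, 1\].
#' @export
auc_score <- function(scores, is_positive) {
  stopifnot(length(scores) == length(is_positive), all(is.finite(scores)))
  np <- sum(is_positive); nn <- sum(!is_positive)
  if (np == 0L || nn == 0L)
    stop("AUC undefined: need at least one positive and one negative sample")
  r <- rank(scores, ties.method = "average")
  (sum(r[is_positive]) - np * (np + 1) / 2) / (np * nn)
}

#' Hits@k of one ranked prediction
#'
#' Per-sample label recall within the top k: `|label_set ∩ top-k| /
#' |label_set|`.
#'
#' @param pred a `ranked_prediction`.
#' @param k cut-off rank (>= 1).
#' @return value in \[0, 1\].
#' @export
hits_at_k <- function(pred, k = 10L) {
  stopifnot(k >= 1L)
  if (length(pred$label_set) == 0L) {
    warning("sample ", pred$sample_id, " has an empty label set; skipped")
    return(NA_real_)
  }
  topk <- utils::head(pred$ranked_elements, k)
  length(intersect(pred$label_set, topk)) / length(pred$label_set)
}

#' Mean Hits@k over predictions
#' @param preds list of `ranked_prediction`.
#' @param k cut-off rank.
#' @export
hits_at_k_mean <- function(preds, k = 10L) {
  v <- vapply(preds, hits_at_k, numeric(1), k = k)
  mean(v, na.rm = TRUE)
}

# Ranks of the true labels within a prediction's ranking; labels absent
# from the ranking get length(ranking) + 1 and are flagged with a warning.
label_ranks <- function(pred, unit = c("per_label", "best")) {
  unit <- match.arg(unit)
  r <- match(pred$label_set, pred$ranked_elements)
  if (anyNA(r)) {
    warning("sample ", pred$sample_id, ": ", sum(is.na(r)),
            " label(s) absent from the ranking; assigned rank ",
            length(pred$ranked_elements) + 1L)
    r[is.na(r)] <- length(pred$ranked_elements) + 1L
  }
  if (unit == "best") min(r) else r
}

#' Mean rank of the true labels
#'
#' Mean, over evaluation units, of the rank at which each true element
#' appears. Multi-label samples expand to one unit per (sample, label) by
#' default; `unit = "best"` scores each sample by its best-ranked label.
#'
#' @param preds list of `ranked_prediction`.
#' @param unit `"per_label"` (default) or `"best"`.
#' @return value >= 1.
#' @export
mean_rank <- function(preds, unit = c("per_label", "best")) {
  unit <- match.arg(unit)
  mean(unlist(lapply(preds, label_ranks, unit = unit)))
}

#' Mean reciprocal rank of the true labels
#'
#' Mean of 1/rank over the same evaluation units as [mean_rank()].
#'
#' @inheritParams mean_rank
#' @return value in (0, 1\].
#' @export
mrr <- function(preds, unit = c("per_label", "best")) {
  unit <- match.arg(unit)
  mean(1 / unlist(lapply(preds, label_ranks, unit = unit)))
}

#' Unit hit rate per rank position
#'
#' For each position k in 1..k_max, the fraction of samples whose k-th
#' ranked prediction is a true element. Rankings shorter than `k_max` count
#' the missing positions as misses (flagged). The mean of the first three
#' positions is attached as `attr(, "hits_avg")`.
#'
#' @param preds list of `ranked_prediction`.
#' @param k_max number of positions (default 10).
#' @return numeric vector of length `k_max`; names `pos1..posk`.
#' @export
unit_hit_rate <- function(preds, k_max = 10L) {
  stopifnot(k_max >= 1L, length(preds) >= 1L)
  if (any(vapply(preds, function(p) length(p$ranked_elements), integer(1)) < k_max))
    warning("some rankings are shorter than k_max = ", k_max,
            "; missing positions count as misses")
  v <- vapply(seq_len(k_max), function(k) {
    mean(vapply(preds, function(p) {
      if (length(p$ranked_elements) < k) return(0)
      as.numeric(p$ranked_elements[[k]] %in% p$label_set)
    }, numeric(1)))
  }, numeric(1))
  names(v) <- paste0("pos", seq_len(k_max))
  attr(v, "hits_avg") <- mean(v[seq_len(min(3L, k_max))])
  v
}

#' Rank all elements for a batch of cases with a model
#'
#' Scores every case with [model_forward()] and builds one
#' `ranked_prediction` per case from the global score vector (per-task
#' softmax scores concatenated over the category partition), ties broken by
#' element id.
#'
#' @param model a `tcm_model`.
#' @param cases list of case records with nonempty element lists.
#' @return list of `ranked_prediction`.
#' @export
predict_ranking <- function(model, cases) {
  out <- model_forward(model, cases)
  gs <- out$global_scores
  lapply(seq_along(cases), function(i) {
    sc <- gs[i, ]
    ord <- order(-sc, seq_along(sc), method = "radix")
    labs <- token_ids(model$vocabs$element_vocab, cases[[i]]$elements)
    ranked_prediction(cases[[i]]$case_id, ord, sc[ord], labs[labs > 0L])
  })
}

#' Full metric report for a set of ranked predictions
#'
#' @param preds list of `ranked_prediction`.
#' @param scores optional pooled score vector for AUC.
#' @param is_positive logical vector aligned with `scores`.
#' @param task_of_element optional integer map element id -> task (1..5) for
#'   per-task Hits@10 breakdowns.
#' @return a `metric_report` list: `auc`, `hits_at_10`, `mean_rank`, `mrr`,
#'   `unit_hit_rate` (length 10), `hits_avg`, `per_task_hits10`, `n_samples`.
#' @export
metric_report <- function(preds, scores = NULL, is_positive = NULL,
                          task_of_element = NULL) {
  uhr <- unit_hit_rate(preds, k_max = 10L)
  per_task <- NULL
  if (!is.null(task_of_element)) {
    per_task <- vapply(1:5, function(t) {
      sub <- lapply(preds, function(p) {
        labs <- p$label_set[task_of_element[p$label_set] == t]
        if (!length(labs)) return(NULL)
        keep <- task_of_element[p$ranked_elements] == t
        ranked_prediction(p$sample_id, p$ranked_elements[keep],
                          label_set = labs)
      })
      sub <- Filter(Negate(is.null), sub)
      if (!length(sub)) NA_real_ else hits_at_k_mean(sub, 10L)
    }, numeric(1))
    names(per_task) <- TASK_CODES
  }
  structure(list(
    auc = if (is.null(scores)) NA_real_ else auc_score(scores, is_positive),
    hits_at_10 = hits_at_k_mean(preds, 10L),
    mean_rank = mean_rank(preds),
    mrr = mrr(preds),
    unit_hit_rate = uhr,
    hits_avg = attr(uhr, "hits_avg"),
    per_task_hits10 = per_task,
    n_samples = length(preds)
  ), class = "metric_report")
}

#' Evaluate a model on a corpus
#'
#' Scores every case, builds the global rankings, and computes all metrics:
#' AUC over the pooled (case, element) scores with the true elements as
#' positives, Hits@10, mean rank, MRR, the unit hit rate for positions
#' 1..10 and its first-three average, and per-task Hits@10 breakdowns.
#'
#' @param model a `tcm_model`.
#' @param cases list of case records (nonempty element lists).
#' @return a `metric_report`.
#' @export
evaluate_ranking <- function(model, cases) {
  out <- model_forward(model, cases)
  gs <- out$global_scores
  preds <- lapply(seq_along(cases), function(i) {
    sc <- gs[i, ]
    ord <- order(-sc, seq_along(sc), method = "radix")
    labs <- token_ids(model$vocabs$element_vocab, cases[[i]]$elements)
    ranked_prediction(cases[[i]]$case_id, ord, sc[ord], labs[labs > 0L])
  })
  pos <- matrix(FALSE, length(cases), model$dims$Ve)
  for (i in seq_along(cases)) {
    labs <- token_ids(model$vocabs$element_vocab, cases[[i]]$elements)
    pos[i, labs[labs > 0L]] <- TRUE
  }
  metric_report(preds, scores = as.vector(gs), is_positive = as.vector(pos),
                task_of_element = model$partition$task_of_element)
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> n =", x$n_samples, "\n")
  cat(sprintf("  AUC      %.5f\n  Hits@10  %.5f\n  MeanRank %.5f\n  MRR      %.5f\n",
              x$auc, x$hits_at_10, x$mean_rank, x$mrr))
  cat(sprintf("  unit hit rate 1..3: %s (hits_avg %.5f)\n",
              paste(sprintf("%.4f", x$unit_hit_rate[1:3]), collapse = " "),
              x$hits_avg))
  invisible(x)
}

#' Paired bootstrap test for a per-sample metric difference
#'
#' Generic utility: given per-sample metric values for two systems on the
#' same samples, bootstrap the mean difference and report a two-sided
#' p-value for the null of zero difference.
#'
#' @param a,b numeric per-sample metric values, same length and order.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @return list with `mean_diff`, `p_value`, `ci` (2.5/97.5 percentiles).
#' @export
paired_bootstrap <- function(a, b, n_boot = 2000L, seed = 1L) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) mean(d[sample.int(length(d), replace = TRUE)]),
           numeric(1))
  })
  p <- 2 * min(mean(boots <= 0), mean(boots >= 0))
  list(mean_diff = mean(d), p_value = min(1, p),
       ci = stats::quantile(boots, c(0.025, 0.975), names = FALSE))
}
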