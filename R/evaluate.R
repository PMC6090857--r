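#' Confusion counts
#'
#' @param tp,fp,fn,tn non-negative integer counts.
#' @return named integer vector of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  structure(as.integer(counts), names = names(counts),
            class = "confusion_counts")
}

#' Metrics from confusion counts
#'
#' Precision tp/(tp+fp), recall tp/(tp+fn), F1 as their harmonic mean,
#' and the Matthews correlation coefficient
#' (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn)).
#' Degenerate denominators yield 0 by convention — needed for
#' per-transcript evaluation, where a transcript can receive zero
#' predicted positives.
#'
#' @param counts a [confusion_counts()] vector (or anything with named
#'   elements tp, fp, fn, tn).
#' @return named numeric vector `(precision, recall, f1, mcc)`.
#' @export
metrics_from_counts <- function(counts) {
  tp <- as.numeric(counts[["tp"]]); fp <- as.numeric(counts[["fp"]])
  fn <- as.numeric(counts[["fn"]]); tn <- as.numeric(counts[["tn"]])
  if (any(c(tp, fp, fn, tn) < 0)) stop("confusion counts must be non-negative")
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  c(precision = precision, recall = recall, f1 = f1, mcc = mcc)
}

#' Tally predictions against labels
#'
#' @param labels true labels ("positive"/"negative" or 0/1).
#' @param predicted predicted labels, same encoding and length.
#' @return list with `counts` ([confusion_counts()]) and `metrics`
#'   ([metrics_from_counts()]).
#' @export
evaluate_predictions <- function(labels, predicted) {
  if (length(labels) != length(predicted)) {
    stop("labels and predictions differ in length")
  }
  y <- as_binary_labels(labels)
  yhat <- as_binary_labels(predicted)
  counts <- confusion_counts(tp = sum(y == 1L & yhat == 1L),
                             fp = sum(y == 0L & yhat == 1L),
                             fn = sum(y == 1L & yhat == 0L),
                             tn = sum(y == 0L & yhat == 0L))
  list(counts = counts, metrics = metrics_from_counts(counts))
}

#' Per-transcript average metrics
#'
#' Computes the metric set separately for each transcript's candidate
#' sites (degenerate denominators giving 0) and returns the unweighted
#' mean across transcripts — the evaluation mode matching practical use,
#' where predictions are made one transcript at a time.
#'
#' @param samples sample table carrying `transcript_id` and `label`.
#' @param predicted predicted labels aligned with `samples` rows.
#' @return list with `per_transcript` (data.frame) and `mean` (named
#'   numeric vector).
#' @export
per_transcript_average <- function(samples, predicted) {
  if (nrow(samples) != length(predicted)) {
    stop("predictions do not align with the sample table")
  }
  ids <- unique(samples$transcript_id)
  rows <- lapply(ids, function(tx) {
    sel <- samples$transcript_id == tx
    m <- evaluate_predictions(samples$label[sel], predicted[sel])$metrics
    data.frame(transcript_id = tx, t(m), stringsAsFactors = FALSE)
  })
  per_tx <- do.call(rbind, rows)
  list(per_transcript = per_tx,
       mean = colMeans(per_tx[, c("precision", "recall", "f1", "mcc")]))
}

#' Build test subsets at fixed imbalance ratios
#'
#' For each ratio k, keeps every positive sample and draws `k` times as
#' many negatives uniformly without replacement (seeded).
#'
#' @param samples labelled sample table.
#' @param ratios integer negative:positive ratios (default 1:9).
#' @param seed integer seed.
#' @return named list of sample tables, one per ratio.
#' @export
build_imbalance_subsets <- function(samples, ratios = 1:9, seed = 1L) {
  validate_sample_table(samples)
  pos_idx <- which(samples$label == "positive")
  neg_idx <- which(samples$label == "negative")
  need <- max(ratios) * length(pos_idx)
  if (length(neg_idx) < need) {
    stop(sprintf(
      "only %d negatives for %d positives; maximum feasible ratio is %d",
      length(neg_idx), length(pos_idx),
      length(neg_idx) %/% max(1L, length(pos_idx))))
  }
  set.seed(seed)
  out <- lapply(ratios, function(k) {
    draw <- sample(neg_idx, k * length(pos_idx))
    sub <- samples[sort(c(pos_idx, draw)), , drop = FALSE]
    rownames(sub) <- NULL
    sub
  })
  names(out) <- as.character(ratios)
  out
}

#' Robustness of a model across imbalance ratios
#'
#' Scores a fitted model on each subset from
#' [build_imbalance_subsets()]; real predictors degrade as the
#' negative:positive ratio k grows, and the flatness of this curve is
#' the robustness of interest.
#'
#' @param model fitted `m6acs` model.
#' @param subsets named list of sample tables keyed by ratio.
#' @param snp SNP table if the model uses SNP features.
#' @return data.frame with one row per ratio: ratio, precision, recall,
#'   f1, mcc.
#' @export
robustness_curve <- function(model, subsets, snp = NULL) {
  rows <- lapply(names(subsets), function(k) {
    sub <- subsets[[k]]
    pred <- predict(model, sub, snp, type = "class")
    m <- evaluate_predictions(sub$label, pred)$metrics
    data.frame(ratio = as.integer(k), t(m))
  })
  do.call(rbind, rows)
}
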