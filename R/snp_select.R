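# SNP-specificity position selection: rank the 2*flank+1 window offsets
# by (a) two-sided Fisher's exact test on the 2x2 variant-by-class table
# and (b) greedy MRMR order (MID criterion, plug-in mutual information
# over binary variables), then fuse by average rank and keep the top k.

#' Per-position Fisher's exact test of SNP-state class difference
#'
#' For each window offset, tests the 2x2 contingency table
#' (variant / no-variant) x (positive / negative) with a two-sided
#' Fisher's exact test.
#'
#' @param states 0/1 matrix, samples x window offsets (see
#'   [snp_state_matrix()]).
#' @param labels 0/1 or "positive"/"negative" vector, one per sample.
#' @return numeric p-value per column of `states`.
#' @export
fisher_position_test <- function(states, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L) {
    stop("need both positive and negative samples for Fisher's test")
  }
  apply(states, 2L, function(x) {
    a <- sum(x == 1L & y == 1L)  # variant, positive
    b <- sum(x == 1L & y == 0L)  # variant, negative
    c_ <- sum(x == 0L & y == 1L)
    d <- sum(x == 0L & y == 0L)
    fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE))$p.value
  })
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    bad <- !labels %in% c("positive", "negative")
    if (any(bad)) stop("labels must be 'positive'/'negative' or 0/1")
    as.integer(labels == "positive")
  } else {
    labels <- as.integer(labels)
    if (!all(labels %in% c(0L, 1L))) stop("numeric labels must be 0/1")
    labels
  }
}

# plug-in mutual information in bits between two 0/1 vectors
mutual_information <- function(x, y) {
  n <- length(x)
  mi <- 0
  for (xv in 0:1) for (yv in 0:1) {
    pxy <- sum(x == xv & y == yv) / n
    if (pxy > 0) {
      px <- sum(x == xv) / n
      py <- sum(y == yv) / n
      mi <- mi + pxy * log2(pxy / (px * py))
    }
  }
  mi
}

#' Greedy MRMR ordering of window positions
#'
#' Orders positions by the minimum-redundancy maximum-relevance criterion
#' (MID): the first pick maximises the mutual information I(x; class);
#' each subsequent pick maximises
#' `I(x; class) - mean over selected s of I(x; s)`.
#' Constant (zero-entropy) positions are appended last, in offset order.
#' Ties break toward the smaller absolute window offset, negative offset
#' first.
#'
#' @inheritParams fisher_position_test
#' @param offsets integer window offsets naming the columns of `states`;
#'   inferred from `snp_<offset>` column names when NULL.
#' @return integer vector of column indices in selection order.
#' @export
mrmr_order <- function(states, labels, offsets = NULL) {
  y <- as_binary_labels(labels)
  p <- ncol(states)
  if (is.null(offsets)) offsets <- infer_offsets(states)
  constant <- apply(states, 2L, function(x) length(unique(x)) == 1L)
  relevance <- vapply(seq_len(p), function(j) {
    if (constant[j]) -Inf else mutual_information(states[, j], y)
  }, 0)
  # deterministic tie-break: |offset| ascending, negative before positive
  tie_order <- order(abs(offsets), offsets)
  tie_rank <- integer(p)
  tie_rank[tie_order] <- seq_len(p)

  active <- which(!constant)
  selected <- integer(0)
  redundancy_sum <- numeric(p)
  while (length(active) > 0L) {
    if (length(selected) == 0L) {
      score <- relevance[active]
    } else {
      score <- relevance[active] - redundancy_sum[active] / length(selected)
    }
    best <- active[order(-score, tie_rank[active])[1L]]
    selected <- c(selected, best)
    active <- setdiff(active, best)
    for (j in active) {
      redundancy_sum[j] <- redundancy_sum[j] +
        mutual_information(states[, j], states[, best])
    }
  }
  const_idx <- which(constant)
  unname(c(selected, const_idx[order(offsets[const_idx])]))
}

infer_offsets <- function(states) {
  nm <- colnames(states)
  if (!is.null(nm) && all(grepl("^snp_-?\\d+$", nm))) {
    as.integer(sub("^snp_", "", nm))
  } else {
    seq_len(ncol(states))
  }
}

#' Fuse Fisher and MRMR rankings into a position selection
#'
#' The fused score of each position is the mean of its two ranks; the k
#' positions with the smallest average rank are selected.  Ties break by
#' smaller Fisher rank, then smaller absolute offset, then negative
#' offset before positive.
#'
#' @param offsets integer window offsets.
#' @param fisher_p per-offset Fisher p-values.
#' @param fisher_rank per-offset rank of the Fisher p-value (1 = most
#'   significant).
#' @param mrmr_rank per-offset MRMR selection order (1 = first picked).
#' @param k number of positions to select (default 12).
#' @return a `position_ranking` data.frame with columns `offset`,
#'   `fisher_p`, `fisher_rank`, `mrmr_rank`, `average_rank`, `selected`,
#'   ordered by fused rank.
#' @export
fuse_rankings <- function(offsets, fisher_p, fisher_rank, mrmr_rank, k = 12L) {
  p <- length(offsets)
  if (k > p) stop(sprintf("k = %d exceeds the %d positions", k, p))
  stopifnot(length(fisher_rank) == p, length(mrmr_rank) == p)
  avg <- (fisher_rank + mrmr_rank) / 2
  ord <- order(avg, fisher_rank, abs(offsets), offsets)
  out <- data.frame(
    offset = offsets[ord],
    fisher_p = fisher_p[ord],
    fisher_rank = fisher_rank[ord],
    mrmr_rank = mrmr_rank[ord],
    average_rank = avg[ord],
    selected = seq_len(p) <= k,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("position_ranking", "data.frame")
  out
}

#' Identify the top-k SNP-specific window positions
#'
#' End-to-end selection: build per-sample SNP state vectors, compute
#' per-position Fisher's exact p-values and the MRMR selection order,
#' then fuse the two rankings by average rank and keep the top k.  The
#' returned ranking is stored with a fitted model so that test-time
#' feature assembly reuses the training-time positions.
#'
#' @param samples a sample table containing both classes.
#' @param snp SNP table.
#' @param k number of positions to select (default 12).
#' @param config run configuration ([m6acs_config()]); supplies the
#'   window half-width.
#' @return a `position_ranking` data.frame (see [fuse_rankings()]).
#' @export
select_snp_positions <- function(samples, snp, k = 12L,
                                 config = m6acs_config()) {
  validate_sample_table(samples)
  states <- snp_state_matrix(samples, snp, config$flank)
  if (all(states == 0L)) {
    stop("no SNP variant falls in any sample window; ranking is degenerate")
  }
  offsets <- infer_offsets(states)
  y <- as_binary_labels(samples$label)
  p_values <- fisher_position_test(states, y)
  fisher_rank <- integer(length(offsets))
  fisher_rank[order(p_values, abs(offsets), offsets)] <- seq_along(offsets)
  sel_order <- mrmr_order(states, y, offsets)
  mrmr_rank <- integer(length(offsets))
  mrmr_rank[sel_order] <- seq_along(offsets)
  fuse_rankings(offsets, p_values, fisher_rank, mrmr_rank, k)
}
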