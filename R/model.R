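#' Run and model configuration
#'
#' Bundles the window geometry, the feature-space options and the
#' gradient-boosted-tree hyperparameters.  The boosting defaults are the
#' published cost-sensitive setting: L2 regularisation (lambda) 700,
#' maximum tree depth 6, learning rate (eta) 0.1, 400 boosting rounds,
#' binary logistic objective evaluated by AUC, and a positive-class
#' weight (scale_pos_weight) of 6 so the minority m6A class dominates
#' the loss despite a ~10:1 negative:positive training ratio.
#'
#' @param flank window half-width in nucleotides (default 25; 51-nt
#'   windows).
#' @param kmer_sizes k-mer lengths for the composition block (default
#'   c(2, 3), 80 dimensions).
#' @param snp_top_k number of SNP-specific positions kept as features
#'   (default 12).
#' @param lambda L2 regularisation on leaf weights.
#' @param max_depth maximum tree depth.
#' @param eta learning rate.
#' @param nrounds boosting rounds.
#' @param scale_pos_weight multiplicative weight on positive-class loss;
#'   1 disables cost-sensitivity.
#' @param threshold probability cut-off for [classify_probs()] and
#'   `predict(type = "class")`.
#' @param seed integer seed for booster reproducibility.
#' @return a list of class `m6acs_config`.
#' @export
m6acs_config <- function(flank = 25L, kmer_sizes = c(2L, 3L), snp_top_k = 12L,
                         lambda = 700, max_depth = 6L, eta = 0.1,
                         nrounds = 400L, scale_pos_weight = 6,
                         threshold = 0.5, seed = 1L) {
  stopifnot(flank >= 2L, snp_top_k <= 2L * flank + 1L, all(kmer_sizes >= 1L),
            lambda >= 0, max_depth >= 1L, eta > 0, nrounds >= 1L,
            scale_pos_weight >= 0, threshold > 0, threshold < 1)
  structure(list(flank = as.integer(flank),
                 kmer_sizes = as.integer(kmer_sizes),
                 snp_top_k = as.integer(snp_top_k),
                 lambda = lambda, max_depth = as.integer(max_depth),
                 eta = eta, nrounds = as.integer(nrounds),
                 scale_pos_weight = scale_pos_weight,
                 threshold = threshold, seed = as.integer(seed)),
            class = "m6acs_config")
}

xgb_params <- function(config) {
  list(objective = "binary:logistic", booster = "gbtree",
       lambda = config$lambda, max_depth = config$max_depth,
       eta = config$eta, scale_pos_weight = config$scale_pos_weight,
       eval_metric = "auc", nthread = 1L, seed = config$seed)
}

#' Train the cost-sensitive boosted-tree classifier
#'
#' Trains on the entire (imbalanced) feature matrix — no subsampling of
#' the negative class; the imbalance is handled by the positive-class
#' weight in the objective.
#'
#' @param features numeric matrix, samples x features, with column
#'   names.
#' @param labels 0/1 or "positive"/"negative", one per row.
#' @param config an [m6acs_config()].
#' @return an `xgb.Booster`.
#' @export
train_booster <- function(features, labels, config = m6acs_config()) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  if (anyNA(features)) stop("feature matrix contains missing values")
  dtrain <- xgboost::xgb.DMatrix(features, label = y)
  xgboost::xgb.train(params = xgb_params(config), data = dtrain,
                     nrounds = config$nrounds, verbose = 0)
}

#' Fit an m6A site predictor
#'
#' The one-stop fitting interface: given a labelled sample table (and
#' optionally a SNP variant table), selects the top SNP-specific window
#' positions on the training data, assembles the full feature space
#' (509 dimensions at the defaults) and trains the cost-sensitive
#' gradient-boosted-tree classifier on all samples.
#'
#' @param samples labelled sample table (see [sample_table()] /
#'   [read_sample_table()]).
#' @param snp SNP table, or NULL to fit without the SNP feature block.
#' @param config an [m6acs_config()].
#' @param ranking optionally a precomputed `position_ranking`; when NULL
#'   and `snp` is given, [select_snp_positions()] is run on `samples`.
#' @return an object of class `m6acs` with components `booster`,
#'   `config`, `ranking`, `feature_names`, `n_train`, `class_counts`.
#' @examples
#' sim <- simulate_corpus(sim_config(n_transcripts = 30, seed = 7))
#' fit <- m6acs(sim$samples, sim$snp,
#'              config = m6acs_config(nrounds = 20, seed = 7))
#' print(fit)
#' head(predict(fit, sim$samples, sim$snp))
#' @export
m6acs <- function(samples, snp = NULL, config = m6acs_config(),
                  ranking = NULL) {
  validate_sample_table(samples)
  if (!is.null(snp) && is.null(ranking)) {
    ranking <- select_snp_positions(samples, snp, k = config$snp_top_k,
                                    config = config)
  }
  sel <- if (is.null(ranking)) NULL else ranking$offset[ranking$selected]
  x <- feature_matrix(samples, snp, sel, config)
  booster <- train_booster(x, samples$label, config)
  y <- as_binary_labels(samples$label)
  out <- list(booster = booster, config = config, ranking = ranking,
              feature_names = colnames(x), n_train = nrow(x),
              class_counts = c(positive = sum(y == 1L),
                               negative = sum(y == 0L)))
  class(out) <- "m6acs"
  out
}

#' Predict m6A site probabilities or labels
#'
#' @param object a fitted `m6acs` model.
#' @param samples sample table of candidate sites, or a ready-made
#'   feature matrix whose columns match the training layout.
#' @param snp SNP table; required when the model was fitted with SNP
#'   features and `samples` is a sample table.
#' @param type `"prob"` for probabilities, `"class"` for
#'   "positive"/"negative" labels at the configured threshold.
#' @param threshold overrides the stored classification threshold.
#' @param ... unused.
#' @return numeric probabilities in [0,1], or a character label vector.
#' @export
predict.m6acs <- function(object, samples, snp = NULL,
                          type = c("prob", "class"), threshold = NULL, ...) {
  type <- match.arg(type)
  if (is.matrix(samples)) {
    x <- samples
  } else {
    sel <- if (is.null(object$ranking)) NULL else
      object$ranking$offset[object$ranking$selected]
    if (!is.null(sel) && is.null(snp)) {
      stop("model uses SNP features; supply the SNP table")
    }
    x <- feature_matrix(samples, snp, sel, object$config)
  }
  if (!identical(colnames(x), object$feature_names)) {
    stop("feature layout does not match the fitted model")
  }
  p <- predict(object$booster, xgboost::xgb.DMatrix(x))
  if (type == "prob") return(p)
  thr <- if (is.null(threshold)) object$config$threshold else threshold
  classify_probs(p, thr)
}

#' Threshold probabilities into class labels
#'
#' A sample is called positive iff its probability is >= the threshold
#' (the boundary value is positive).
#'
#' @param probabilities numeric vector in [0,1].
#' @param threshold cut-off in (0,1), default 0.5.
#' @return character vector of "positive"/"negative".
#' @export
classify_probs <- function(probabilities, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  ifelse(probabilities >= threshold, "positive", "negative")
}

#' Split-count feature importance
#'
#' Importance of a feature is the number of tree splits that use it
#' across the whole ensemble (non-negative integers; features never used
#' score 0, and their sum is the ensemble's total split count).
#'
#' @param model a fitted `m6acs` model or an `xgb.Booster`.
#' @param type `"split"` (default) or `"gain"`.
#' @return named numeric vector over all features in layout order.
#' @export
feature_importance <- function(model, type = c("split", "gain")) {
  type <- match.arg(type)
  if (inherits(model, "m6acs")) {
    booster <- model$booster
    feats <- model$feature_names
  } else {
    booster <- model
    feats <- NULL
  }
  tree <- xgboost::xgb.model.dt.tree(model = booster)
  splits <- tree$Feature[tree$Feature != "Leaf"]
  if (is.null(feats)) feats <- sort(unique(splits))
  score <- setNames(numeric(length(feats)), feats)
  if (type == "split") {
    tab <- table(splits)
    score[names(tab)] <- as.numeric(tab)
  } else {
    gain <- tapply(tree$Gain[tree$Feature != "Leaf"], splits, sum)
    score[names(gain)] <- as.numeric(gain)
  }
  score
}

#' Stratified cross-validation of the full pipeline
#'
#' Splits the samples into stratified folds; within each training fold
#' the SNP position selection is re-run (no leakage into the held-out
#' fold), the model is retrained, and the held-out fold is scored.
#'
#' @param samples labelled sample table.
#' @param snp SNP table or NULL.
#' @param folds number of folds (default 10).
#' @param config an [m6acs_config()]; `config$seed` drives the fold
#'   assignment.
#' @return list with `per_fold` (data.frame of per-fold metrics) and
#'   `mean` (named numeric vector).
#' @export
cross_validate <- function(samples, snp = NULL, folds = 10L,
                           config = m6acs_config()) {
  validate_sample_table(samples)
  y <- as_binary_labels(samples$label)
  if (sum(y == 1L) < folds || sum(y == 0L) < folds) {
    stop(sprintf("need at least %d samples of each class for %d folds",
                 folds, folds))
  }
  set.seed(config$seed)
  fold_id <- integer(length(y))
  for (cls in 0:1) {
    idx <- which(y == cls)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  per_fold <- lapply(seq_len(folds), function(f) {
    train <- samples[fold_id != f, , drop = FALSE]
    test <- samples[fold_id == f, , drop = FALSE]
    fit <- m6acs(train, snp, config)
    pred <- predict(fit, test, snp, type = "class")
    res <- evaluate_predictions(test$label, pred)
    c(fold = f, unlist(res$metrics))
  })
  per_fold <- as.data.frame(do.call(rbind, per_fold))
  list(per_fold = per_fold,
       mean = colMeans(per_fold[, c("precision", "recall", "f1", "mcc")]))
}

#' @export
print.m6acs <- function(x, ...) {
  cat("m6A site predictor (cost-sensitive gradient-boosted trees)\n")
  cat(sprintf("  trained on %d samples (%d positive, %d negative)\n",
              x$n_train, x$class_counts["positive"],
              x$class_counts["negative"]))
  cat(sprintf("  features: %d (%s SNP block)\n", length(x$feature_names),
              if (is.null(x$ranking)) "no" else "with"))
  cat(sprintf(
    "  boosting: %d rounds, eta %g, depth %d, lambda %g, pos-weight %g\n",
    x$config$nrounds, x$config$eta, x$config$max_depth, x$config$lambda,
    x$config$scale_pos_weight))
  invisible(x)
}

#' @export
summary.m6acs <- function(object, ...) {
  print(object)
  imp <- feature_importance(object)
  top <- sort(imp, decreasing = TRUE)
  top <- top[top > 0]
  cat(sprintf("  splits in ensemble: %d; features used: %d of %d\n",
              as.integer(sum(imp)), length(top), length(imp)))
  cat("  top features by split count:\n")
  show <- utils::head(top, 10L)
  for (i in seq_along(show)) {
    cat(sprintf("    %-18s %d\n", names(show)[i], as.integer(show[i])))
  }
  if (!is.null(object$ranking)) {
    sel <- object$ranking$offset[object$ranking$selected]
    cat("  selected SNP offsets:", paste(sel, collapse = ", "), "\n")
  }
  invisible(list(importance = imp, ranking = object$ranking))
}

#' Plot feature importance of a fitted model
#'
#' Barplot of the top-n features by split-count importance.
#'
#' @param x a fitted `m6acs` model.
#' @param n number of features shown (default 20).
#' @param ... passed to [graphics::barplot()].
#' @return the plotted scores, invisibly.
#' @export
plot.m6acs <- function(x, n = 20L, ...) {
  imp <- sort(feature_importance(x), decreasing = TRUE)
  shown <- utils::head(imp[imp > 0], n)
  graphics::barplot(rev(shown), horiz = TRUE, las = 1,
                    xlab = "split count", cex.names = 0.7, ...)
  invisible(shown)
}
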