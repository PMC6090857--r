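# small configs keep unit-test training fast; the published defaults are
# exercised in the acceptance tests
fast_config <- function(...) m6acs_config(nrounds = 30L, lambda = 1, ...)

make_toy <- function(n = 200L, seed = 51L) {
  set.seed(seed)
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- as.integer(x[, 1] > 0)
  list(x = x, y = y)
}

test_that("a linearly separable toy problem is fit perfectly", {
  toy <- make_toy()
  booster <- train_booster(toy$x, toy$y, fast_config())
  p <- predict(booster, xgboost::xgb.DMatrix(toy$x))
  expect_true(all(p[toy$y == 1] >= 0.5))
  expect_true(all(p[toy$y == 0] < 0.5))
  # training AUC 1: every positive scores above every negative
  expect_gt(min(p[toy$y == 1]), max(p[toy$y == 0]))
})

test_that("training rejects degenerate inputs", {
  toy <- make_toy()
  expect_error(train_booster(toy$x, rep(1L, nrow(toy$x)), fast_config()),
               "single class")
  xna <- toy$x; xna[1, 1] <- NA
  expect_error(train_booster(xna, toy$y, fast_config()), "missing")
})

test_that("prediction is deterministic and layout-checked", {
  toy <- make_toy()
  cfg <- fast_config()
  fit <- list(booster = train_booster(toy$x, toy$y, cfg), config = cfg,
              ranking = NULL, feature_names = colnames(toy$x),
              n_train = nrow(toy$x),
              class_counts = c(positive = sum(toy$y),
                               negative = sum(1 - toy$y)))
  class(fit) <- "m6acs"
  p1 <- predict(fit, toy$x)
  p2 <- predict(fit, toy$x)
  expect_identical(p1, p2)
  # identical rows give identical probabilities
  dup <- toy$x[c(1, 1, 2, 2), ]
  pd <- predict(fit, dup)
  expect_identical(pd[1], pd[2])
  expect_identical(pd[3], pd[4])
  wrong <- toy$x
  colnames(wrong) <- paste0("g", 1:5)
  expect_error(predict(fit, wrong), "layout")
})

test_that("classification threshold behaves as a boundary-inclusive cutoff", {
  p <- c(0.2, 0.5, 0.8)
  expect_equal(classify_probs(p, 0.5),
               c("negative", "positive", "positive"))
  expect_true(all(classify_probs(rep(0.4, 5), 0.5) == "negative"))
  # monotone: raising the threshold never adds positives
  set.seed(52)
  probs <- runif(200)
  prev <- sum(classify_probs(probs, 0.05) == "positive")
  for (thr in seq(0.1, 0.95, by = 0.05)) {
    now <- sum(classify_probs(probs, thr) == "positive")
    expect_lte(now, prev)
    prev <- now
  }
})

test_that("split-count importance matches a tree-walk oracle", {
  toy <- make_toy()
  booster <- train_booster(toy$x, toy$y, fast_config())
  imp <- feature_importance(booster)
  tree <- xgboost::xgb.model.dt.tree(model = booster)
  total_splits <- sum(tree$Feature != "Leaf")
  expect_equal(sum(imp), total_splits)
  expect_true(all(imp >= 0))
  expect_true(all(imp == round(imp)))
  # a feature absent from every split scores 0 in the full layout
  fit <- list(booster = booster, config = fast_config(), ranking = NULL,
              feature_names = c(colnames(toy$x), "never_used"),
              n_train = nrow(toy$x),
              class_counts = c(positive = sum(toy$y),
                               negative = sum(1 - toy$y)))
  class(fit) <- "m6acs"
  expect_equal(unname(feature_importance(fit)["never_used"]), 0)
})

test_that("constant motif-forced features receive zero importance", {
  sim <- simulate_corpus(sim_config(n_transcripts = 25, seed = 53))
  fit <- m6acs(sim$samples, sim$snp, m6acs_config(nrounds = 40L, seed = 53L))
  imp <- feature_importance(fit)
  expect_equal(unname(imp["binary_0_A"]), 0)
  expect_equal(unname(imp["binary_1_C"]), 0)
  expect_equal(unname(imp["cpd_0_ring"]), 0)
})

test_that("fitted models round-trip through disk with bitwise-equal output", {
  sim <- simulate_corpus(sim_config(n_transcripts = 15, seed = 54))
  fit <- m6acs(sim$samples, sim$snp, m6acs_config(nrounds = 25L, seed = 54L))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fit, path)
  back <- load_model(path)
  expect_identical(predict(back, sim$samples, sim$snp),
                   predict(fit, sim$samples, sim$snp))
  expect_equal(back$ranking, fit$ranking)
})

test_that("permuted labels yield chance-level held-out performance", {
  set.seed(55)
  sim <- simulate_corpus(sim_config(n_transcripts = 50, seed = 55))
  samples <- sim$samples
  samples$label <- sample(samples$label)        # break all signal
  tx <- unique(samples$transcript_id)
  test_tx <- sample(tx, 20)
  train <- samples[!samples$transcript_id %in% test_tx, ]
  test <- samples[samples$transcript_id %in% test_tx, ]
  fit <- m6acs(train, config = m6acs_config(nrounds = 60L, seed = 55L))
  p <- predict(fit, test)
  y <- as.integer(test$label == "positive")
  # held-out AUC ~ 0.5 for a null model
  auc <- mean(outer(p[y == 1], p[y == 0], ">") +
                0.5 * outer(p[y == 1], p[y == 0], "=="))
  expect_gt(auc, 0.40)
  expect_lt(auc, 0.60)
})

test_that("stratified cross-validation is seed-deterministic and sane", {
  sim <- simulate_corpus(sim_config(n_transcripts = 20, seed = 56))
  cfg <- m6acs_config(nrounds = 20L, seed = 56L)
  cv1 <- cross_validate(sim$samples, sim$snp, folds = 3L, config = cfg)
  cv2 <- cross_validate(sim$samples, sim$snp, folds = 3L, config = cfg)
  expect_equal(cv1, cv2)
  expect_equal(nrow(cv1$per_fold), 3L)
  expect_true(all(cv1$per_fold$f1 >= 0 & cv1$per_fold$f1 <= 1))
  expect_error(cross_validate(sim$samples[1:20, ], sim$snp, folds = 10L,
                              config = cfg), "at least")
})

test_that("the full feature space outperforms binary-only features", {
  sim <- simulate_corpus(sim_config(n_transcripts = 50, seed = 57))
  set.seed(57)
  tx <- unique(sim$samples$transcript_id)
  test_tx <- sample(tx, 20)
  train <- sim$samples[!sim$samples$transcript_id %in% test_tx, ]
  test <- sim$samples[sim$samples$transcript_id %in% test_tx, ]
  cfg <- m6acs_config(nrounds = 100L, seed = 57L)

  fit_full <- m6acs(train, sim$snp, cfg)
  f1_full <- evaluate_predictions(
    test$label, predict(fit_full, test, sim$snp, type = "class")
  )$metrics[["f1"]]

  x_bin_train <- feature_matrix(train)[, 1:204]
  x_bin_test <- feature_matrix(test)[, 1:204]
  fit_bin <- list(booster = train_booster(x_bin_train, train$label, cfg),
                  config = cfg, ranking = NULL,
                  feature_names = colnames(x_bin_train),
                  n_train = nrow(x_bin_train),
                  class_counts = c(positive = sum(train$label == "positive"),
                                   negative = sum(train$label == "negative")))
  class(fit_bin) <- "m6acs"
  f1_bin <- evaluate_predictions(
    test$label, predict(fit_bin, x_bin_test, type = "class")
  )$metrics[["f1"]]
  expect_gt(f1_full, f1_bin)
})

test_that("print, summary and plot methods run cleanly", {
  sim <- simulate_corpus(sim_config(n_transcripts = 15, seed = 58))
  fit <- m6acs(sim$samples, sim$snp, m6acs_config(nrounds = 15L, seed = 58L))
  expect_output(print(fit), "cost-sensitive")
  expect_output(s <- summary(fit), "split count")
  expect_named(s, c("importance", "ranking"))
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
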