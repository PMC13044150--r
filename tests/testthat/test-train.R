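test_that("label-smoothed cross-entropy matches its closed forms", {
  # eps = 0 recovers the standard cross-entropy
  expect_equal(smoothedCrossEntropy(c(0.8, 0.2), 0, eps = 0), -log(0.8))
  expect_equal(smoothedCrossEntropy(c(0.3, 0.7), 1, eps = 0), -log(0.7))
  # uniform prediction costs log 2 regardless of eps
  for (e in c(0, 0.05, 0.2, 0.49))
    expect_equal(smoothedCrossEntropy(c(0.5, 0.5), 1, eps = e), log(2))
  # hand-evaluated smoothed case
  expect_equal(smoothedCrossEntropy(c(0.8, 0.2), 0, eps = 0.1),
               -(0.9 * log(0.8) + 0.1 * log(0.2)))
  expect_error(smoothedCrossEntropy(c(0.8, 0.2), 0, eps = 0.5), "eps")
  expect_error(smoothedCrossEntropy(c(0.8, 0.3), 0), "simplex")
  expect_message(smoothedCrossEntropy(c(1, 0), 0, eps = 0.1), "clamped")
})

test_that("cosine schedule hits its endpoints and midpoint", {
  expect_equal(cosineLR(0, 100), 0.001)
  expect_equal(cosineLR(100, 100, min_lr = 1e-5), 1e-5)
  expect_equal(cosineLR(50, 100, base_lr = 0.001, min_lr = 0.0002),
               (0.001 + 0.0002) / 2)
  expect_error(cosineLR(1, 0), "parameter error")
  expect_error(cosineLR(11, 10), "step")
  # monotone non-increasing over the schedule
  lrs <- cosineLR(0:50, 50)
  expect_true(all(diff(lrs) <= 0))
})

test_that("fold metrics match closed-form confusion arithmetic", {
  # TP=3, TN=4, FP=1, FN=2
  labels <- c(rep(1, 5), rep(0, 5))
  preds <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1)
  scores <- preds
  m <- evaluateMetrics(scores, preds, labels)
  expect_equal(m$acc, 0.7)
  expect_equal(m$sen, 0.6)
  expect_equal(m$spe, 0.8)
  expect_identical(c(m$tp, m$tn, m$fp, m$fn), c(3L, 4L, 1L, 2L))
})

test_that("AUC equals exhaustive pair counting, including ties", {
  # perfectly separating scores
  expect_equal(evaluateMetrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0),
                               c(1, 1, 0, 0))$auc, 1)
  # 6 scores with a tie across classes
  s <- c(0.7, 0.5, 0.5, 0.4, 0.3, 0.2)
  l <- c(1, 1, 0, 0, 1, 0)
  expect_equal(evaluateMetrics(s, as.integer(s > 0.5), l)$auc,
               aucOracle(s, l))
  # random score vectors with coarse (tie-rich) grids
  set.seed(44)
  for (r in 1:25) {
    n <- sample(6:15, 1)
    l <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- sample(seq(0, 1, 0.25), n, replace = TRUE)
    expect_equal(evaluateMetrics(s, as.integer(s > 0.5), l)$auc,
                 aucOracle(s, l))
  }
  expect_warning(m1 <- evaluateMetrics(c(1, 2), c(1, 1), c(1, 1)),
                 "one-class")
  expect_true(is.na(m1$auc))
})

test_that("stratified folds partition the cohort and preserve class ratio", {
  set.seed(7)
  labels <- c(rep(0, 33), rep(1, 27))
  folds <- stratifiedFolds(labels, 5, seed = 3)
  expect_identical(sort(unique(folds)), 1:5)
  expect_length(folds, 60)
  for (f in 1:5) {
    n1 <- sum(labels[folds == f] == 1)
    n0 <- sum(labels[folds == f] == 0)
    expect_true(abs(n1 - 27 / 5) <= 1)
    expect_true(abs(n0 - 33 / 5) <= 1)
  }
  # folds are seed-reproducible
  expect_identical(stratifiedFolds(labels, 5, seed = 3), folds)
  expect_error(stratifiedFolds(c(0, 1), 3), "at least k")
})

test_that("training bookkeeping: steps, reproducibility, divergence guard", {
  cd <- tinyCohortData(n_per_group = 4, seed = 51, n_timepoints = 40)
  cfg <- satConfig(hidden_dim = 8, n_heads = 2, n_layers = 1)
  model <- initModel(c(tA = 8L, tB = 10L), cfg, fusion_dim = 4,
                     clf_hidden = 4, seed = 2)
  # 2 epochs on 8 subjects at batch size 8 -> exactly 2 optimisation steps
  tc <- trainConfig(epochs = 2, batch_size = 8, outer_folds = 2)
  m1 <- trainModel(model, cd$data, config = tc, seed = 13)
  expect_identical(m1@trainLog$steps, 2L)
  expect_length(m1@trainLog$epoch_loss, 2L)
  expect_true(m1@trained)
  # same seed, same data -> identical final parameters
  m2 <- trainModel(model, cd$data, config = tc, seed = 13)
  expect_identical(m1@params, m2@params)
  # different seed diverges (dropout + shuffling)
  m3 <- trainModel(model, cd$data, config = tc, seed = 14)
  expect_false(identical(m1@params, m3@params))
  expect_error(trainModel(model, cd$data, idx = integer(0), config = tc),
               "empty training split")
})

test_that("loss decreases monotonically on separable data for most seeds", {
  cd <- tinyCohortData(n_per_group = 6, seed = 61, n_timepoints = 80)
  cfg <- satConfig(hidden_dim = 8, n_heads = 2, n_layers = 1,
                   dropout_rate = 0)
  ok <- 0L
  for (s in 1:10) {
    model <- initModel(c(tA = 8L, tB = 10L), cfg, fusion_dim = 4,
                       clf_hidden = 4, seed = 700 + s)
    # full-batch steps keep the per-epoch loss readable as a trajectory
    tc <- trainConfig(epochs = 10, batch_size = 12L, outer_folds = 2,
                      label_smoothing_eps = 0.1)
    m <- trainModel(model, cd$data, config = tc, seed = 800 + s)
    if (all(diff(m@trainLog$epoch_loss) < 0)) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("nested CV partitions cleanly, guards leakage and aggregates", {
  cd <- tinyCohortData(n_per_group = 9, seed = 71, n_timepoints = 50)
  tc <- trainConfig(epochs = 2, outer_folds = 3, inner_folds = 2, seed = 5,
                    grid = list(hidden_dim = 8L))
  res <- nestedCV(data = cd$data, train_config = tc,
                  sat_config = satConfig(hidden_dim = 8, n_heads = 2,
                                         n_layers = 1))
  # outer folds partition the cohort
  expect_identical(sort(unique(res$folds)), 1:3)
  expect_length(res$folds, 18)
  # leakage guard: every fold's test set disjoint from its training set
  for (l in res$leakage) {
    expect_true(l$disjoint)
    expect_length(intersect(l$train, l$test), 0)
    expect_setequal(c(l$train, l$test), cd$data$subjectIDs)
  }
  # single-configuration grid -> that configuration chosen in every fold
  for (ch in res$chosen) expect_identical(ch$hidden_dim, 8L)
  # aggregate equals recomputation from stored per-fold values
  expect_equal(unname(res$aggregate$acc["mean"]), mean(res$perFold$acc))
  expect_equal(unname(res$aggregate$auc["sd"]), sd(res$perFold$auc))
  # per-fold fusion weights are a simplex
  expect_equal(unname(rowSums(res$atlasWeights)), rep(1, 3),
               tolerance = 1e-6)
  # unknown grid entries are a configuration error before any training
  expect_error(nestedCV(data = cd$data,
                        train_config = trainConfig(outer_folds = 3,
                                                   grid = list(bogus = 1:2))),
               "configuration error")
})

test_that("fold assignments and run log persist to disk for audit", {
  cd <- tinyCohortData(n_per_group = 6, seed = 81, n_timepoints = 40)
  td <- withr::local_tempdir()
  tc <- trainConfig(epochs = 1, outer_folds = 2, seed = 3)
  res <- nestedCV(data = cd$data, train_config = tc,
                  sat_config = satConfig(hidden_dim = 8, n_heads = 2,
                                         n_layers = 1),
                  out_dir = td)
  folds <- utils::read.csv(file.path(td, "folds.csv"))
  expect_identical(folds$fold, res$folds)
  log <- jsonlite::read_json(file.path(td, "run_log.json"))
  expect_identical(log$seed, 3L)
  expect_length(log$fold_subjects, 2L)
  expect_true(file.exists(file.path(td, "fold_metrics.csv")))
})
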