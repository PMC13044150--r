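# Nested cross-validation harness: stratified outer folds estimate
# generalisation; inner folds on each outer-training set pick the grid
# configuration by mean inner AUC; the winner is retrained on the full
# outer-training set. Outer-test subjects never touch selection or training.

.seedFor <- function(...) {
  v <- c(...)
  as.integer(sum(v * rev(seq_along(v)) * 9973) %% 2147483563L)
}

.applyGrid <- function(sat_cfg, train_cfg, fusion_dim, clf_hidden, row) {
  satFields <- c("k_hops", "n_layers", "hidden_dim", "n_heads",
                 "dropout_rate", "readout", "ffn_dim", "edge_mode")
  trainFields <- c("learning_rate", "min_lr", "batch_size", "epochs",
                   "label_smoothing_eps", "weight_decay")
  for (nm in names(row)) {
    val <- row[[nm]]
    if (nm %in% satFields) sat_cfg[[nm]] <- val
    else if (nm %in% trainFields) train_cfg[[nm]] <- val
    else if (nm == "fusion_dim") fusion_dim <- as.integer(val)
    else if (nm == "clf_hidden") clf_hidden <- as.integer(val)
    else stop("configuration error: unknown grid entry '", nm, "'")
  }
  if ("hidden_dim" %in% names(row) && !"ffn_dim" %in% names(row))
    sat_cfg$ffn_dim <- NULL              # rescale ffn with the new width
  # re-validate the touched configs before any training happens
  sat_cfg <- do.call(satConfig, unclass(sat_cfg)[!vapply(sat_cfg, is.null,
                                                         logical(1))])
  list(sat = sat_cfg, train = train_cfg, fusion_dim = fusion_dim,
       clf_hidden = clf_hidden)
}

.trainEval <- function(data, trainIdx, evalIdx, sat_cfg, train_cfg,
                       fusion_dim, clf_hidden, seed) {
  dims <- vapply(data$graphs, function(gl) ncol(gl[[1]]@nodeFeatures),
                 integer(1))
  model <- initModel(dims, sat_cfg, fusion_dim, clf_hidden,
                     seed = .seedFor(seed, 1L))
  model <- trainModel(model, data, trainIdx, train_cfg,
                      seed = .seedFor(seed, 2L))
  pred <- predictCohort(model, data, evalIdx)
  met <- evaluateMetrics(pred$prob_case, pred$prediction, pred$label)
  list(model = model, pred = pred, metrics = met)
}

#' Nested cross-validation of the multi-atlas classifier
#'
#' @param cohort a [MultiAtlasCohort-class], or precomputed [cohortGraphs()]
#'   output passed as `data`.
#' @param train_config a [trainConfig()]; its `grid` drives the inner-loop
#'   hyperparameter search (an empty or single-point grid skips inner
#'   training and uses the sole configuration directly).
#' @param sat_config base encoder configuration, overridden per grid point.
#' @param fusion_dim,clf_hidden fusion-space and classifier widths.
#' @param knn_k,knn_metric graph-construction parameters (see
#'   [knnSparsify()]).
#' @param data optional precomputed [cohortGraphs()] result (overrides
#'   `cohort`).
#' @param out_dir optional directory; fold assignments and a structured run
#'   log are persisted there for audit.
#' @param verbose print per-fold progress.
#' @return object of class `"nestedCVResult"`: `folds` (per-subject outer
#'   fold id), `perFold` (data.frame of per-fold ACC/SEN/SPE/AUC and chosen
#'   configuration), `aggregate` (mean and sd per metric), `models` (per-fold
#'   trained models), `atlasWeights` (per-fold mean fusion weight per atlas,
#'   computed on that fold's training subjects), `leakage` (per-fold train /
#'   test id sets and the disjointness check).
#' @export
nestedCV <- function(cohort = NULL, train_config = trainConfig(),
                     sat_config = satConfig(), fusion_dim = 16L,
                     clf_hidden = 16L, knn_k = 15L, knn_metric = "signed",
                     data = NULL, out_dir = NULL, verbose = FALSE) {
  if (is.null(data)) {
    if (is.null(cohort)) stop("supply 'cohort' or 'data'")
    data <- cohortGraphs(cohort, K = knn_k, metric = knn_metric)
  }
  labels <- data$labels
  n <- length(labels)
  cfg <- train_config
  if (any(table(labels) < cfg$outer_folds))
    stop("need at least outer_folds subjects per class")

  grid <- if (length(cfg$grid))
    expand.grid(cfg$grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  else data.frame(row.names = 1)
  # validate every grid point up front (configuration errors precede training)
  gridCfgs <- lapply(seq_len(nrow(grid)), function(ci)
    .applyGrid(sat_config, cfg, fusion_dim, clf_hidden,
               as.list(grid[ci, , drop = FALSE])))

  folds <- stratifiedFolds(labels, cfg$outer_folds, seed = cfg$seed)
  perFold <- list(); models <- list(); chosen <- list()
  atlasW <- list(); leakage <- list(); predAll <- list()

  for (f in seq_len(cfg$outer_folds)) {
    testIdx <- which(folds == f)
    trainIdx <- which(folds != f)
    stopifnot(length(intersect(testIdx, trainIdx)) == 0L)  # leakage guard

    if (nrow(grid) > 1L) {
      innerFolds <- stratifiedFolds(labels[trainIdx], cfg$inner_folds,
                                    seed = .seedFor(cfg$seed, f, 7L))
      score <- numeric(nrow(grid))
      for (ci in seq_len(nrow(grid))) {
        gc <- gridCfgs[[ci]]
        vals <- numeric(cfg$inner_folds)
        for (ii in seq_len(cfg$inner_folds)) {
          itr <- trainIdx[innerFolds != ii]
          iva <- trainIdx[innerFolds == ii]
          te <- .trainEval(data, itr, iva, gc$sat, gc$train,
                           gc$fusion_dim, gc$clf_hidden,
                           seed = .seedFor(cfg$seed, f, ii, ci))
          vals[ii] <- if (cfg$select_metric == "auc") te$metrics$auc
                      else te$metrics$acc
        }
        score[ci] <- mean(vals, na.rm = TRUE)
      }
      best <- which.max(score)           # ties: first grid row
    } else best <- 1L

    gc <- gridCfgs[[best]]
    te <- .trainEval(data, trainIdx, testIdx, gc$sat, gc$train,
                     gc$fusion_dim, gc$clf_hidden,
                     seed = .seedFor(cfg$seed, f, 999L))
    trainPred <- predictCohort(te$model, data, trainIdx)
    wcols <- grep("^weight_", names(trainPred), value = TRUE)
    aw <- colMeans(trainPred[, wcols, drop = FALSE])
    names(aw) <- sub("^weight_", "", names(aw))

    perFold[[f]] <- data.frame(fold = f, acc = te$metrics$acc,
                               sen = te$metrics$sen, spe = te$metrics$spe,
                               auc = te$metrics$auc,
                               config = if (nrow(grid) >= 1L && ncol(grid))
                                 paste(names(grid), grid[best, ],
                                       sep = "=", collapse = ";") else "default")
    models[[f]] <- te$model
    chosen[[f]] <- if (ncol(grid)) as.list(grid[best, , drop = FALSE]) else list()
    atlasW[[f]] <- aw
    predAll[[f]] <- te$pred
    leakage[[f]] <- list(
      train = data$subjectIDs[trainIdx], test = data$subjectIDs[testIdx],
      disjoint = length(intersect(trainIdx, testIdx)) == 0L)
    if (verbose)
      message(sprintf("fold %d: acc %.3f auc %.3f (%s)", f, te$metrics$acc,
                      te$metrics$auc, perFold[[f]]$config))
  }

  perFold <- do.call(rbind, perFold)
  agg <- lapply(c(acc = "acc", sen = "sen", spe = "spe", auc = "auc"),
                function(m) c(mean = mean(perFold[[m]], na.rm = TRUE),
                              sd = stats::sd(perFold[[m]], na.rm = TRUE)))
  res <- list(folds = folds, perFold = perFold, aggregate = agg,
              models = models, chosen = chosen,
              atlasWeights = do.call(rbind, atlasW),
              predictions = predAll, leakage = leakage,
              subjectIDs = data$subjectIDs, seed = cfg$seed)
  class(res) <- "nestedCVResult"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(data.frame(subject_id = data$subjectIDs, fold = folds),
                     file.path(out_dir, "folds.csv"), row.names = FALSE)
    log <- list(seed = cfg$seed, outer_folds = cfg$outer_folds,
                inner_folds = cfg$inner_folds,
                chosen = chosen,
                fold_subjects = lapply(leakage, function(l)
                  list(train = l$train, test = l$test)),
                aggregate = agg)
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(perFold, file.path(out_dir, "fold_metrics.csv"),
                     row.names = FALSE)
  }
  res
}

#' @export
print.nestedCVResult <- function(x, ...) {
  cat("Nested cross-validation:", nrow(x$perFold), "outer folds\n")
  for (m in names(x$aggregate))
    cat(sprintf("  %s: %.4f +/- %.4f\n", toupper(m),
                x$aggregate[[m]]["mean"], x$aggregate[[m]]["sd"]))
  invisible(x)
}

#' Per-atlas mean fusion weights of a trained model
#'
#' Averages each subject's input-dependent fusion weights over the requested
#' subjects, yielding the atlas-attention report (one row per atlas).
#'
#' @param model a trained [MsatModel-class].
#' @param data [cohortGraphs()] output.
#' @param idx subject indices to average over (default all).
#' @param task task name recorded in the output.
#' @return data.frame with columns `task`, `atlas`, `mean_weight`,
#'   `sd_weight`.
#' @export
reportAtlasAttention <- function(model, data, idx = NULL, task = "task") {
  if (is.null(idx)) idx <- seq_along(data$labels)
  pred <- predictCohort(model, data, idx)
  wcols <- grep("^weight_", names(pred), value = TRUE)
  data.frame(task = task, atlas = sub("^weight_", "", wcols),
             mean_weight = vapply(wcols, function(cn) mean(pred[[cn]]),
                                  numeric(1)),
             sd_weight = vapply(wcols, function(cn) stats::sd(pred[[cn]]),
                                numeric(1)),
             row.names = NULL)
}
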