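# End-to-end validation experiments on synthetic cohorts. These fix the
# study conditions (generator scenario + evaluation protocol) so the same
# computation backs the test suite, the acceptance script and the vignette.

#' Planted-effect recovery benchmark
#'
#' Runs the full pipeline on the default recovery scenario
#' ([recoverySimSpec()]): nested cross-validation of the multi-atlas
#' classifier, per-atlas planted-ROI recall within the top-10 attention
#' ranking (attention averaged over each fold's training subjects, then over
#' folds), and the per-fold fusion-weight winner. Ten training epochs at a
#' toy-atlas scale are sufficient for convergence here (the planted effect is
#' strong) and keep the whole benchmark at a few minutes on one CPU.
#'
#' @param seed integer seed driving the simulation, fold assignment and
#'   training.
#' @param epochs training epochs per fit (default 10).
#' @param grid inner-loop search grid (default `hidden_dim` in 8, 16).
#' @param outer_folds,inner_folds cross-validation fold counts (5 / 3).
#' @param verbose print per-fold progress.
#' @return list with `cv` (the `"nestedCVResult"`), `meanAcc`, `meanAuc`,
#'   `recalls` (named per-atlas recall), `strongestAtlas` (the atlas with the
#'   largest planted ROI fraction), `weightWinFraction` (fraction of outer
#'   folds in which that atlas received the largest mean fusion weight),
#'   `attention` (per-atlas fold-averaged ROI weights) and `spec`.
#' @export
runRecoveryBenchmark <- function(seed = 1L, epochs = 10L,
                                 grid = list(hidden_dim = c(8L, 16L)),
                                 outer_folds = 5L, inner_folds = 3L,
                                 verbose = FALSE) {
  spec <- recoverySimSpec(seed = seed)
  cohort <- generateCohort(spec)
  data <- cohortGraphs(cohort, K = 15L)
  tcfg <- trainConfig(epochs = epochs, outer_folds = outer_folds,
                      inner_folds = inner_folds, seed = seed, grid = grid)
  cv <- nestedCV(data = data, train_config = tcfg,
                 sat_config = satConfig(), verbose = verbose)

  planted <- groundTruth(cohort)$plantedROIs
  anames <- names(planted)
  attention <- setNames(vector("list", length(anames)), anames)
  recalls <- setNames(numeric(length(anames)), anames)
  for (an in anames) {
    acc <- NULL
    for (f in seq_along(cv$models)) {
      rep <- roiAttention(cv$models[[f]], data, an,
                          idx = which(cv$folds != f))
      acc <- if (is.null(acc)) rep$roi_weights else acc + rep$roi_weights
    }
    attention[[an]] <- acc / length(cv$models)
    top <- topROIs(attention[[an]], 10L)
    recalls[an] <- recallTopK(top$roi_index, planted[[an]])
  }
  frac <- vapply(planted, length, integer(1)) /
    vapply(spec$atlases, nRois, integer(1))
  strongest <- names(which.max(frac))
  wins <- apply(cv$atlasWeights, 1, function(w) names(which.max(w)))
  list(cv = cv,
       meanAcc = unname(cv$aggregate$acc["mean"]),
       meanAuc = unname(cv$aggregate$auc["mean"]),
       recalls = recalls, strongestAtlas = strongest,
       weightWinFraction = mean(wins == strongest),
       attention = attention, spec = spec)
}

#' Null-cohort calibration of the classifier
#'
#' Repeats nested cross-validation on null cohorts (no planted effect,
#' [nullSimSpec()]) across several seeds. With identical case and control
#' generative laws, mean outer accuracy should sit in the chance band. A
#' single small configuration (hidden width 8, 2 heads, 6 epochs) is used:
#' chance-level behaviour does not depend on model capacity or training
#' length, and this keeps the five-seed calibration within a few minutes.
#'
#' @param seed base seed; run `i` uses `seed + i - 1`.
#' @param n_seeds number of independent repetitions (default 5).
#' @param epochs training epochs per fit (default 6).
#' @param outer_folds outer folds (default 5).
#' @return list with `accPerSeed`, `meanAcc`, `aucPerSeed`.
#' @export
runNullCalibration <- function(seed = 1L, n_seeds = 5L, epochs = 6L,
                               outer_folds = 5L) {
  accs <- numeric(n_seeds); aucs <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    s <- seed + i - 1L
    cohort <- generateCohort(nullSimSpec(seed = s))
    data <- cohortGraphs(cohort, K = 15L)
    tcfg <- trainConfig(epochs = epochs, outer_folds = outer_folds,
                        seed = s)
    cv <- nestedCV(data = data, train_config = tcfg,
                   sat_config = satConfig(hidden_dim = 8L, n_heads = 2L))
    accs[i] <- unname(cv$aggregate$acc["mean"])
    aucs[i] <- unname(cv$aggregate$auc["mean"])
  }
  list(accPerSeed = accs, meanAcc = mean(accs), aucPerSeed = aucs)
}

#' False-discovery calibration of the edge statistics under the null
#'
#' Simulates repetitions of a two-group edge comparison with no true effect:
#' per repetition, each subject gets independent standard-normal edge values
#' on a 10-ROI subset (45 edges), and [discriminativeEdges()] is run at the
#' given alpha. Under Benjamini-Hochberg control the proportion of
#' repetitions with at least one significant edge is at most about alpha.
#'
#' @param n_reps repetitions (default 200).
#' @param n_rois ROI subset size (default 10, i.e. 45 edges).
#' @param n_per_group subjects per group (default 20).
#' @param alpha FDR threshold (default 0.05).
#' @param seed RNG seed.
#' @return list with `propAnySignificant`, `nSignificantPerRep`, `n_reps`,
#'   `alpha`.
#' @export
nullEdgeCalibration <- function(n_reps = 200L, n_rois = 10L,
                                n_per_group = 20L, alpha = 0.05, seed = 1L) {
  nsub <- 2L * n_per_group
  labels <- rep(c(0L, 1L), each = n_per_group)
  counts <- withSeed(seed, {
    vapply(seq_len(n_reps), function(r) {
      mats <- lapply(seq_len(nsub), function(s) {
        m <- diag(n_rois)
        m[upper.tri(m)] <- stats::rnorm(n_rois * (n_rois - 1) / 2)
        m[lower.tri(m)] <- t(m)[lower.tri(m)]
        m
      })
      es <- discriminativeEdges(mats, labels, seq_len(n_rois), alpha = alpha)
      sum(es$significant)
    }, integer(1))
  })
  list(propAnySignificant = mean(counts > 0L), nSignificantPerRep = counts,
       n_reps = n_reps, alpha = alpha)
}
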