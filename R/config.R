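#' Structure-aware transformer encoder configuration
#'
#' Architecture knobs of the per-atlas graph encoder. Defaults follow the
#' model's reference training setup: three stacked SAT layers and dropout 0.3;
#' the k-hop subgraph radius defaults to 2, balancing locality against cost on
#' 116-246-node graphs.
#'
#' @param k_hops nonnegative subgraph radius for the structural embeddings.
#'   With `k_hops = 0` the structural embedding degenerates to a per-node MLP
#'   of the node's own features and the encoder reduces to a plain
#'   (structure-free) transformer.
#' @param n_layers number of stacked SAT layers (default 3).
#' @param hidden_dim node state width; must be divisible by `n_heads`.
#' @param n_heads number of attention heads.
#' @param dropout_rate dropout probability in \[0, 1), applied to the attention
#'   output and the feed-forward block during training only (default 0.3).
#' @param readout graph-level pooling over node states: `"mean"`, `"sum"` or
#'   `"max"`.
#' @param ffn_dim feed-forward block width; default `2 * hidden_dim`.
#' @param edge_mode `"weighted"` (edge weights act as multiplicative message
#'   coefficients in the subgraph GNN) or `"binary"` (topology only, an
#'   ablation mode).
#' @return a validated list of class `"satConfig"`.
#' @export
satConfig <- function(k_hops = 2L, n_layers = 3L, hidden_dim = 16L,
                      n_heads = 4L, dropout_rate = 0.3,
                      readout = c("mean", "sum", "max"),
                      ffn_dim = NULL, edge_mode = c("weighted", "binary")) {
  readout <- match.arg(readout)
  edge_mode <- match.arg(edge_mode)
  if (is.null(ffn_dim)) ffn_dim <- 2L * as.integer(hidden_dim)
  cfg <- list(k_hops = as.integer(k_hops), n_layers = as.integer(n_layers),
              hidden_dim = as.integer(hidden_dim),
              n_heads = as.integer(n_heads),
              dropout_rate = as.numeric(dropout_rate), readout = readout,
              ffn_dim = as.integer(ffn_dim), edge_mode = edge_mode)
  stopifnot(cfg$k_hops >= 0L, cfg$n_layers >= 1L, cfg$hidden_dim >= 1L,
            cfg$n_heads >= 1L, cfg$ffn_dim >= 1L)
  if (cfg$hidden_dim %% cfg$n_heads != 0L)
    stop("hidden_dim must be divisible by n_heads")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)")
  class(cfg) <- "satConfig"
  cfg
}

#' Training configuration
#'
#' Defaults reproduce the reference optimisation recipe: AdamW at an initial
#' learning rate of 0.001 under cosine annealing, batch size 8, 200 epochs,
#' label-smoothed cross-entropy. `outer_folds` should be 10 for large cohorts
#' and 5 for small ones; `inner_folds` defaults to 3, the smallest informative
#' inner split for cohorts of around a hundred subjects.
#'
#' @param learning_rate initial learning rate (default 0.001).
#' @param min_lr final learning rate of the cosine schedule (default 0).
#' @param batch_size minibatch size (default 8).
#' @param epochs training epochs (default 200).
#' @param label_smoothing_eps smoothing mass in \[0, 0.5); 0 recovers standard
#'   cross-entropy (default 0.1).
#' @param weight_decay AdamW decoupled weight decay (default 0.01).
#' @param outer_folds,inner_folds nested cross-validation fold counts.
#' @param seed integer seed governing fold assignment, parameter
#'   initialisation, batch shuffling and dropout.
#' @param grid named list of candidate values for hyperparameter search, e.g.
#'   `list(hidden_dim = c(8, 16))`. Entries may target encoder fields
#'   (`hidden_dim`, `k_hops`, `n_heads`, `n_layers`, `dropout_rate`) or
#'   training fields (`learning_rate`, `label_smoothing_eps`, `epochs`,
#'   `batch_size`, `weight_decay`). An empty grid means a single default
#'   configuration.
#' @param select_metric inner-loop model-selection criterion; `"auc"`
#'   (default) or `"acc"`.
#' @return a validated list of class `"trainConfig"`.
#' @export
trainConfig <- function(learning_rate = 0.001, min_lr = 0, batch_size = 8L,
                        epochs = 200L, label_smoothing_eps = 0.1,
                        weight_decay = 0.01, outer_folds = 10L,
                        inner_folds = 3L, seed = 1L, grid = list(),
                        select_metric = c("auc", "acc")) {
  select_metric <- match.arg(select_metric)
  cfg <- list(learning_rate = as.numeric(learning_rate),
              min_lr = as.numeric(min_lr),
              batch_size = as.integer(batch_size),
              epochs = as.integer(epochs),
              label_smoothing_eps = as.numeric(label_smoothing_eps),
              weight_decay = as.numeric(weight_decay),
              outer_folds = as.integer(outer_folds),
              inner_folds = as.integer(inner_folds),
              seed = as.integer(seed), grid = grid,
              select_metric = select_metric)
  stopifnot(cfg$learning_rate > 0, cfg$min_lr >= 0, cfg$batch_size >= 1L,
            cfg$epochs >= 1L, cfg$weight_decay >= 0,
            cfg$outer_folds >= 2L, cfg$inner_folds >= 2L)
  if (cfg$label_smoothing_eps < 0 || cfg$label_smoothing_eps >= 0.5)
    stop("label_smoothing_eps must lie in [0, 0.5)")
  if (length(grid) && is.null(names(grid)))
    stop("grid must be a named list")
  class(cfg) <- "trainConfig"
  cfg
}
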