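#' Lightweight attentional fusion weights
#'
#' Scores each atlas embedding with one shared learned affine map to a scalar
#' and normalises the scores through a softmax, yielding nonnegative per-atlas
#' weights that sum to one. The cost is one scalar product per atlas — linear
#' in the number of atlases, in contrast to the quadratic cost of pairwise
#' query-key attention. Identical embeddings therefore receive uniform
#' weights, and a single atlas degenerates to weight 1.
#'
#' @param embeddings matrix with one row per atlas (fusion-space embeddings),
#'   or a list of equal-length numeric vectors.
#' @param params list with `w` (scoring vector) and `b` (scalar offset);
#'   defaults to the `laff` slot of `model`.
#' @param model optionally, an [MsatModel-class] supplying `params`.
#' @return numeric weight vector summing to 1, named by the rownames /
#'   list names of `embeddings`; attribute `"score_evals"` records the number
#'   of scorer evaluations performed (one per atlas).
#' @export
laffWeights <- function(embeddings, params = NULL, model = NULL) {
  zs <- if (is.list(embeddings)) do.call(rbind, embeddings)
        else as.matrix(embeddings)
  if (is.null(params)) {
    if (is.null(model)) stop("supply 'params' or 'model'")
    params <- model@params$laff
  }
  if (ncol(zs) != length(params$w))
    stop("shape error: embedding dim ", ncol(zs), " vs scorer dim ",
         length(params$w))
  s <- drop(zs %*% params$w) + params$b      # one affine score per atlas
  alpha <- softmaxVec(s)
  names(alpha) <- rownames(zs)
  attr(alpha, "score_evals") <- nrow(zs)
  alpha
}

#' Fuse per-atlas embeddings with given weights
#'
#' Weighted sum of the (projected, equal-dimension) atlas embeddings. Linear
#' in the embeddings for fixed weights; one-hot weights return that atlas's
#' embedding exactly.
#'
#' @param embeddings matrix with one row per atlas, or list of vectors.
#' @param weights nonnegative weight vector summing to 1 (within 1e-6), one
#'   entry per atlas.
#' @return fused numeric vector.
#' @export
fuseEmbeddings <- function(embeddings, weights) {
  zs <- if (is.list(embeddings)) do.call(rbind, embeddings)
        else as.matrix(embeddings)
  weights <- as.numeric(weights)
  if (length(weights) != nrow(zs))
    stop("shape error: ", length(weights), " weights for ", nrow(zs),
         " embeddings")
  if (any(weights < -1e-9) || abs(sum(weights) - 1) > 1e-6)
    stop("weights must be nonnegative and sum to 1")
  drop(crossprod(zs, weights))
}

#' Classify a fused representation
#'
#' One hidden layer with ReLU followed by a 2-unit linear head and softmax.
#' Returns the two class probabilities (control, case); they are nonnegative
#' and sum to 1. The decision rule is argmax with ties broken toward the
#' control class.
#'
#' @param rep fused numeric vector.
#' @param params list with `Wc1`, `bc1`, `Wc2`, `bc2`; defaults to the
#'   classifier slot of `model`.
#' @param model optionally, an [MsatModel-class] supplying `params`.
#' @return named numeric vector `c(control = ..., case = ...)`, with
#'   attribute `"decision"` (0 control / 1 case).
#' @export
classifyFused <- function(rep, params = NULL, model = NULL) {
  if (is.null(params)) {
    if (is.null(model)) stop("supply 'params' or 'model'")
    params <- model@params$clf
  }
  u <- relu(drop(rep %*% params$Wc1) + params$bc1)
  logits <- drop(u %*% params$Wc2) + params$bc2
  p <- softmaxVec(logits)
  names(p) <- c("control", "case")
  attr(p, "decision") <- if (p[2] > 0.5) 1L else 0L
  p
}
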