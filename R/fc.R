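#' Compute a subject's functional-connectivity matrix
#'
#' Pearson correlation between every pair of ROI time series. The result is
#' symmetric with unit diagonal; any ROI whose series has zero variance is a
#' degenerate signal and raises an error naming the offending ROI.
#'
#' @param ts numeric matrix, timepoints x n_rois (at least 2 timepoints).
#' @param subjectID subject identifier recorded in the result.
#' @param atlas optional [AtlasSpec-class]; if given, the column count is
#'   checked against the atlas and ROI labels are used in error messages.
#' @return an [FCMatrix-class].
#' @examples
#' set.seed(1)
#' fc <- computeFC(matrix(rnorm(50 * 4), 50, 4))
#' fcValues(fc)[1:2, 1:2]
#' @export
computeFC <- function(ts, subjectID = "subject", atlas = NULL) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 2L) stop("at least 2 timepoints are required")
  if (any(!is.finite(ts))) stop("load error: non-finite values in time series")
  if (!is.null(atlas) && ncol(ts) != nRois(atlas))
    stop("format error: ", ncol(ts), " columns vs ", nRois(atlas),
         " ROIs in atlas '", atlas@name, "'")
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    lab <- if (!is.null(atlas)) roiLabels(atlas)[bad] else paste0("column ", bad)
    stop("degenerate signal: zero-variance ROI(s): ",
         paste(lab, collapse = ", "))
  }
  v <- stats::cor(ts)
  v <- (v + t(v)) / 2
  diag(v) <- 1
  v[v > 1] <- 1
  v[v < -1] <- -1
  dimnames(v) <- NULL
  new("FCMatrix", subjectID = as.character(subjectID),
      atlasName = if (is.null(atlas)) "" else atlas@name, values = v)
}

#' KNN-sparsify a functional-connectivity matrix into a brain graph
#'
#' Each node keeps its K most similar neighbours (self excluded); the K
#' directed selections per node are symmetrised by union, so every node ends
#' with degree at least K. Similarity is the signed correlation by default —
#' keeping the strongest positive couplings — or its absolute value with
#' `metric = "absolute"`. Ties at the K-th rank are broken toward the lower
#' ROI index. Surviving edges carry the signed correlation as weight.
#'
#' @param fc an [FCMatrix-class] or a plain symmetric correlation matrix.
#' @param K number of neighbours per node; must be `<= n_rois - 1`. Default 15.
#' @param metric neighbour ranking: `"signed"` (default) or `"absolute"`.
#' @param features node feature matrix; default the FC row profiles (see
#'   [fcNodeFeatures()]).
#' @param label diagnosis label to attach (NA if unknown).
#' @return a [BrainGraph-class].
#' @export
knnSparsify <- function(fc, K = 15L, metric = c("signed", "absolute"),
                        features = NULL, label = NA_integer_) {
  metric <- match.arg(metric)
  if (is(fc, "FCMatrix")) {
    v <- fc@values; sid <- fc@subjectID; an <- fc@atlasName
  } else {
    v <- as.matrix(fc); sid <- "subject"; an <- ""
  }
  n <- nrow(v)
  K <- as.integer(K)
  if (K < 1L || K > n - 1L)
    stop("parameter error: K must lie in [1, n_rois - 1]; got K = ", K,
         " with n_rois = ", n)
  sim <- if (metric == "absolute") abs(v) else v
  sel <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    s <- sim[i, ]
    s[i] <- -Inf                       # never select self
    # order(): decreasing similarity, ties broken by lower ROI index
    nb <- order(s, decreasing = TRUE)[seq_len(K)]
    sel[i, nb] <- TRUE
  }
  keep <- sel | t(sel)                 # union symmetrisation
  A <- ifelse(keep, v, 0)
  diag(A) <- 0
  if (is.null(features)) features <- v
  new("BrainGraph", subjectID = sid, atlasName = an, adjacency = A,
      nodeFeatures = as.matrix(features), label = as.integer(label),
      K = K)
}

#' Node features from a functional-connectivity matrix
#'
#' The feature vector of node i is row i of the FC matrix (its whole-brain
#' connectivity profile), so the feature matrix equals the FC matrix itself
#' and the feature dimension equals the atlas ROI count.
#'
#' @param fc an [FCMatrix-class] or plain matrix.
#' @return numeric matrix n_rois x n_rois.
#' @export
fcNodeFeatures <- function(fc) {
  if (is(fc, "FCMatrix")) fc@values else as.matrix(fc)
}

#' Time series to brain graph, in one step
#'
#' @param ts numeric matrix timepoints x n_rois, or a cohort's stored series.
#' @param subjectID subject identifier.
#' @param atlas optional [AtlasSpec-class].
#' @param K,metric passed to [knnSparsify()].
#' @param label diagnosis label.
#' @return a [BrainGraph-class].
#' @export
buildBrainGraph <- function(ts, subjectID = "subject", atlas = NULL,
                            K = 15L, metric = "signed", label = NA_integer_) {
  fc <- computeFC(ts, subjectID = subjectID, atlas = atlas)
  knnSparsify(fc, K = K, metric = metric, label = label)
}

#' Build all brain graphs of a cohort
#'
#' Computes the FC matrix and KNN graph for every subject under every atlas.
#' Graph construction is per-subject and deterministic, so it can be done once
#' up front and reused across cross-validation folds without leakage.
#'
#' @param cohort a [MultiAtlasCohort-class].
#' @param K,metric passed to [knnSparsify()].
#' @return list with elements `graphs` (per-atlas list of per-subject
#'   [BrainGraph-class]), `fc` (per-atlas list of [FCMatrix-class]), `labels`
#'   (integer vector) and `atlasNames`.
#' @export
cohortGraphs <- function(cohort, K = 15L, metric = "signed") {
  atl <- cohortAtlases(cohort)
  labs <- diagnosisLabels(cohort)
  sids <- subjectIDs(cohort)
  fc <- lapply(names(atl), function(an) {
    out <- lapply(seq_along(sids), function(i)
      computeFC(cohort@series[[an]][[i]], subjectID = sids[i],
                atlas = atl[[an]]))
    names(out) <- sids
    out
  })
  names(fc) <- names(atl)
  graphs <- lapply(names(atl), function(an) {
    out <- lapply(seq_along(sids), function(i)
      knnSparsify(fc[[an]][[i]], K = K, metric = metric, label = labs[i]))
    names(out) <- sids
    out
  })
  names(graphs) <- names(atl)
  list(graphs = graphs, fc = fc, labels = labs, atlasNames = names(atl),
       subjectIDs = sids)
}
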