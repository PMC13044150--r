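#' @import methods
#' @importFrom stats cor rnorm runif sd pt var setNames p.adjust
#' @importFrom utils read.csv read.delim write.csv head
NULL

#' Atlas specification
#'
#' An `AtlasSpec` describes one brain parcellation: its name, its ROI labels
#' (one per parcel) and, optionally, ROI centroid coordinates in a common
#' reference space and per-ROI anatomical lobe tags. The number of ROIs is
#' implied by the label vector; classical whole-brain atlases in this setting
#' have 116 (AAL), 200 (Craddock CC200) or 246 (Brainnetome) regions, but any
#' positive count is accepted.
#'
#' @slot name short atlas identifier, e.g. `"AAL116"`.
#' @slot roiLabels character vector of unique ROI labels; its length defines
#'   the number of ROIs.
#' @slot centroids numeric matrix with one row per ROI and 3 columns (x, y, z),
#'   or a 0-row matrix when centroids are unknown.
#' @slot lobeTags character vector of per-ROI lobe labels, or `character(0)`.
#'
#' @seealso [atlasSpec()], [toyAtlases()], [readAtlasSpec()]
#' @export
setClass("AtlasSpec",
  representation(
    name = "character",
    roiLabels = "character",
    centroids = "matrix",
    lobeTags = "character"
  )
)

setValidity("AtlasSpec", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  n <- length(object@roiLabels)
  if (n < 1L) msg <- c(msg, "atlas must have at least one ROI label")
  if (anyDuplicated(object@roiLabels))
    msg <- c(msg, "ROI labels must be unique within an atlas")
  if (nrow(object@centroids) > 0L) {
    if (nrow(object@centroids) != n)
      msg <- c(msg, "centroids must have one row per ROI")
    if (ncol(object@centroids) != 3L)
      msg <- c(msg, "centroids must have 3 columns (x, y, z)")
  }
  if (length(object@lobeTags) > 0L && length(object@lobeTags) != n)
    msg <- c(msg, "lobeTags must have one entry per ROI")
  if (length(msg)) msg else TRUE
})

#' Functional-connectivity matrix
#'
#' Symmetric ROI-by-ROI Pearson correlation matrix for one subject under one
#' atlas — the subject-level connectome. Entries lie in \[-1, 1\] and the
#' diagonal is exactly 1.
#'
#' @slot subjectID subject identifier.
#' @slot atlasName name of the atlas the matrix was computed under.
#' @slot values symmetric numeric matrix, unit diagonal, entries in \[-1, 1\].
#'
#' @seealso [computeFC()]
#' @export
setClass("FCMatrix",
  representation(
    subjectID = "character",
    atlasName = "character",
    values = "matrix"
  )
)

setValidity("FCMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (nrow(v) != ncol(v)) msg <- c(msg, "'values' must be square")
  if (any(!is.finite(v))) msg <- c(msg, "'values' must be finite")
  else {
    if (max(abs(v - t(v))) > 1e-8) msg <- c(msg, "'values' must be symmetric")
    if (max(abs(diag(v) - 1)) > 1e-8) msg <- c(msg, "diagonal must equal 1")
    if (max(abs(v)) > 1 + 1e-8) msg <- c(msg, "entries must lie in [-1, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' KNN-sparsified brain graph
#'
#' The unit consumed by the graph encoder: an undirected weighted graph over
#' the ROIs of one atlas, obtained by keeping each node's K most similar
#' neighbours in the FC matrix and symmetrising by union, together with the
#' node feature matrix (FC row profiles by default) and the diagnosis label.
#'
#' @slot subjectID subject identifier.
#' @slot atlasName atlas the graph was built under.
#' @slot adjacency symmetric weighted adjacency matrix, zero diagonal; a
#'   nonzero entry means the edge survived KNN sparsification and carries the
#'   signed correlation as weight.
#' @slot nodeFeatures numeric matrix, one row per ROI.
#' @slot label integer diagnosis label, 0 control / 1 case (NA if unknown).
#' @slot K the K used for sparsification.
#'
#' @seealso [knnSparsify()], [buildBrainGraph()]
#' @export
setClass("BrainGraph",
  representation(
    subjectID = "character",
    atlasName = "character",
    adjacency = "matrix",
    nodeFeatures = "matrix",
    label = "integer",
    K = "integer"
  )
)

setValidity("BrainGraph", function(object) {
  A <- object@adjacency
  msg <- character(0)
  if (nrow(A) != ncol(A)) msg <- c(msg, "adjacency must be square")
  else {
    if (any(diag(A) != 0)) msg <- c(msg, "self-loops are not allowed")
    if (max(abs(A - t(A))) > 1e-10)
      msg <- c(msg, "adjacency must be symmetric (undirected graph)")
  }
  if (nrow(object@nodeFeatures) != nrow(A))
    msg <- c(msg, "nodeFeatures must have one row per node")
  if (length(msg)) msg else TRUE
})

#' Multi-atlas cohort of subject time series
#'
#' Container aligning, across atlases, the per-subject ROI time-series
#' matrices of a two-group study. Every subject present has one
#' timepoints-by-ROI matrix per atlas; subjects missing any atlas are dropped
#' (with a warning) at load time.
#'
#' @slot atlases named list of [AtlasSpec-class] objects.
#' @slot series named list (one element per atlas) of named lists of numeric
#'   matrices (timepoints x n_rois), subject order identical across atlases.
#' @slot phenotype data.frame with columns `subject_id` and `label` (0/1),
#'   rows in the same subject order as `series`.
#'
#' @seealso [loadCohort()], [generateCohort()]
#' @export
setClass("MultiAtlasCohort",
  representation(
    atlases = "list",
    series = "list",
    phenotype = "data.frame"
  )
)

setValidity("MultiAtlasCohort", function(object) {
  msg <- character(0)
  if (!all(vapply(object@atlases, is, logical(1), "AtlasSpec")))
    msg <- c(msg, "'atlases' must be a list of AtlasSpec")
  anames <- unname(vapply(object@atlases, function(a) a@name, character(1)))
  if (!identical(sort(unname(names(object@series))), sort(anames)))
    msg <- c(msg, "'series' must have one element per atlas, named by atlas")
  ph <- object@phenotype
  if (!all(c("subject_id", "label") %in% names(ph)))
    msg <- c(msg, "phenotype needs columns 'subject_id' and 'label'")
  else {
    if (!all(ph$label %in% c(0L, 1L)))
      msg <- c(msg, "labels must be 0 (control) or 1 (case)")
    for (an in names(object@series)) {
      sl <- object@series[[an]]
      if (!identical(names(sl), as.character(ph$subject_id))) {
        msg <- c(msg, sprintf(
          "series for atlas '%s' must be named by, and ordered as, phenotype subjects", an))
        next
      }
      a <- object@atlases[[match(an, anames)]]
      ncols <- vapply(sl, ncol, integer(1))
      if (any(ncols != length(a@roiLabels)))
        msg <- c(msg, sprintf("atlas '%s': column count must equal its ROI count", an))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic multi-atlas cohort with known ground truth
#'
#' A [MultiAtlasCohort-class] produced by the latent-source simulator, carrying
#' the full simulation specification and the exact planted ROI sets per atlas,
#' so that classification accuracy, fusion weights and attention rankings can
#' be scored against a known answer.
#'
#' @slot groundTruth list with elements `spec` (the [simSpec()] used) and
#'   `plantedROIs` (named list of per-atlas integer ROI index vectors).
#'
#' @seealso [generateCohort()], [plantedROISets()]
#' @export
setClass("SyntheticCohort",
  contains = "MultiAtlasCohort",
  representation(groundTruth = "list")
)

#' Fitted multi-atlas graph-transformer model
#'
#' Holds the architecture configuration and all learned parameters of the
#' multi-atlas classifier: one structure-aware transformer encoder per atlas,
#' the per-atlas projections to the shared fusion space, the attentional
#' fusion scorer, and the classification head.
#'
#' @slot atlasNames atlas names, fixing the order of the per-atlas encoders.
#' @slot atlasDims named integer vector of input feature dimensions
#'   (= n_rois per atlas).
#' @slot satConfig encoder configuration from [satConfig()].
#' @slot fusionDim dimension of the shared fusion space.
#' @slot clfHidden width of the classifier hidden layer.
#' @slot params nested list of numeric parameter arrays.
#' @slot trained logical: has the model been through [trainModel()]?
#' @slot trainLog list with per-epoch losses and bookkeeping from training.
#'
#' @seealso [initModel()], [trainModel()], [predictCohort()]
#' @export
setClass("MsatModel",
  representation(
    atlasNames = "character",
    atlasDims = "integer",
    satConfig = "list",
    fusionDim = "integer",
    clfHidden = "integer",
    params = "list",
    trained = "logical",
    trainLog = "list"
  )
)

## ---- show methods -----------------------------------------------------

setMethod("show", "AtlasSpec", function(object) {
  cat("AtlasSpec '", object@name, "': ", length(object@roiLabels), " ROIs",
      if (nrow(object@centroids) > 0L) ", with centroids" else "",
      if (length(object@lobeTags) > 0L) ", with lobe tags" else "",
      "\n", sep = "")
})

setMethod("show", "FCMatrix", function(object) {
  cat("FCMatrix: subject '", object@subjectID, "', atlas '", object@atlasName,
      "', ", nrow(object@values), " x ", ncol(object@values), "\n", sep = "")
})

setMethod("show", "BrainGraph", function(object) {
  ne <- sum(object@adjacency != 0) / 2
  cat("BrainGraph: subject '", object@subjectID, "', atlas '",
      object@atlasName, "', ", nrow(object@adjacency), " nodes, ",
      ne, " undirected edges (K = ", object@K, ")\n", sep = "")
})

setMethod("show", "MultiAtlasCohort", function(object) {
  ph <- object@phenotype
  cat(class(object), ": ", nrow(ph), " subjects (",
      sum(ph$label == 1L), " cases / ", sum(ph$label == 0L), " controls), ",
      length(object@atlases), " atlases: ",
      paste(vapply(object@atlases, function(a)
        sprintf("%s[%d]", a@name, length(a@roiLabels)), character(1)),
        collapse = ", "),
      "\n", sep = "")
})

setMethod("show", "MsatModel", function(object) {
  cat("MsatModel (", if (object@trained) "trained" else "untrained", ")\n",
      "  atlases: ", paste(sprintf("%s[%d]", object@atlasNames,
                                   object@atlasDims), collapse = ", "), "\n",
      "  encoder: ", object@satConfig$n_layers, " SAT layers, hidden ",
      object@satConfig$hidden_dim, ", ", object@satConfig$n_heads,
      " heads, k_hops ", object@satConfig$k_hops, "\n",
      "  fusion dim ", object@fusionDim, ", classifier hidden ",
      object@clfHidden, "\n", sep = "")
})
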