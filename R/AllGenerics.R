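#' Number of ROIs of an atlas or atlas-shaped object
#' @param x an [AtlasSpec-class], [FCMatrix-class] or [BrainGraph-class].
#' @return integer ROI count.
#' @export
setGeneric("nRois", function(x) standardGeneric("nRois"))

#' @rdname nRois
#' @export
setMethod("nRois", "AtlasSpec", function(x) length(x@roiLabels))
#' @rdname nRois
#' @export
setMethod("nRois", "FCMatrix", function(x) nrow(x@values))
#' @rdname nRois
#' @export
setMethod("nRois", "BrainGraph", function(x) nrow(x@adjacency))

#' Atlas name of an object
#' @param x an object tied to an atlas.
#' @return character atlas name.
#' @export
setGeneric("atlasName", function(x) standardGeneric("atlasName"))
#' @rdname atlasName
#' @export
setMethod("atlasName", "AtlasSpec", function(x) x@name)
#' @rdname atlasName
#' @export
setMethod("atlasName", "FCMatrix", function(x) x@atlasName)
#' @rdname atlasName
#' @export
setMethod("atlasName", "BrainGraph", function(x) x@atlasName)

#' ROI labels of an atlas
#' @param x an [AtlasSpec-class].
#' @return character vector of ROI labels.
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))
#' @rdname roiLabels
#' @export
setMethod("roiLabels", "AtlasSpec", function(x) x@roiLabels)

#' Subject identifiers of a cohort
#' @param x a [MultiAtlasCohort-class].
#' @return character vector of subject IDs, in cohort order.
#' @export
setGeneric("subjectIDs", function(x) standardGeneric("subjectIDs"))
#' @rdname subjectIDs
#' @export
setMethod("subjectIDs", "MultiAtlasCohort",
          function(x) as.character(x@phenotype$subject_id))

#' Diagnosis labels of a cohort
#' @param x a [MultiAtlasCohort-class].
#' @return integer vector of 0/1 labels, in cohort order.
#' @export
setGeneric("diagnosisLabels", function(x) standardGeneric("diagnosisLabels"))
#' @rdname diagnosisLabels
#' @export
setMethod("diagnosisLabels", "MultiAtlasCohort",
          function(x) as.integer(x@phenotype$label))

#' Atlas specifications of a cohort
#' @param x a [MultiAtlasCohort-class].
#' @return named list of [AtlasSpec-class] objects.
#' @export
setGeneric("cohortAtlases", function(x) standardGeneric("cohortAtlases"))
#' @rdname cohortAtlases
#' @export
setMethod("cohortAtlases", "MultiAtlasCohort", function(x) {
  nm <- vapply(x@atlases, function(a) a@name, character(1))
  setNames(x@atlases, nm)
})

#' Extract one subject's time-series matrix
#' @param x a [MultiAtlasCohort-class].
#' @param atlas atlas name.
#' @param subject subject ID.
#' @return numeric matrix, timepoints x n_rois.
#' @export
setGeneric("getSeries", function(x, atlas, subject) standardGeneric("getSeries"))
#' @rdname getSeries
#' @export
setMethod("getSeries", "MultiAtlasCohort", function(x, atlas, subject) {
  if (!atlas %in% names(x@series))
    stop("unknown atlas '", atlas, "'")
  m <- x@series[[atlas]][[as.character(subject)]]
  if (is.null(m)) stop("unknown subject '", subject, "'")
  m
})

#' Ground truth of a synthetic cohort
#' @param x a [SyntheticCohort-class].
#' @return list with elements `spec` and `plantedROIs`.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname groundTruth
#' @export
setMethod("groundTruth", "SyntheticCohort", function(x) x@groundTruth)

#' FC values matrix
#' @param x an [FCMatrix-class].
#' @return the symmetric numeric correlation matrix.
#' @export
setGeneric("fcValues", function(x) standardGeneric("fcValues"))
#' @rdname fcValues
#' @export
setMethod("fcValues", "FCMatrix", function(x) x@values)

#' Weighted adjacency matrix of a brain graph
#' @param x a [BrainGraph-class].
#' @return symmetric numeric matrix with zero diagonal.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @rdname adjacency
#' @export
setMethod("adjacency", "BrainGraph", function(x) x@adjacency)

#' Node feature matrix of a brain graph
#' @param x a [BrainGraph-class].
#' @return numeric matrix, one row per node.
#' @export
setGeneric("nodeFeatures", function(x) standardGeneric("nodeFeatures"))
#' @rdname nodeFeatures
#' @export
setMethod("nodeFeatures", "BrainGraph", function(x) x@nodeFeatures)

#' Undirected edge list of a brain graph
#' @param x a [BrainGraph-class].
#' @return data.frame with columns `i`, `j` (i < j) and `weight`.
#' @export
setGeneric("edgeList", function(x) standardGeneric("edgeList"))
#' @rdname edgeList
#' @export
setMethod("edgeList", "BrainGraph", function(x) {
  A <- x@adjacency
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2], weight = A[idx])
})
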