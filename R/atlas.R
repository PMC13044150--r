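#' Construct an atlas specification
#'
#' @param name short atlas identifier.
#' @param roiLabels character vector of unique ROI labels.
#' @param centroids optional numeric matrix (n_rois x 3) of ROI centroids in a
#'   common reference space (e.g. MNI millimetres).
#' @param lobeTags optional character vector of per-ROI lobe labels.
#' @return an [AtlasSpec-class].
#' @examples
#' atlasSpec("demo", paste0("R", 1:5))
#' @export
atlasSpec <- function(name, roiLabels, centroids = NULL, lobeTags = NULL) {
  if (is.null(centroids))
    centroids <- matrix(numeric(0), nrow = 0, ncol = 3)
  new("AtlasSpec",
      name = as.character(name),
      roiLabels = as.character(roiLabels),
      centroids = as.matrix(centroids),
      lobeTags = if (is.null(lobeTags)) character(0) else as.character(lobeTags))
}

#' Read an atlas descriptor file
#'
#' Reads the CSV layout used for atlas descriptors: columns `roi_index`
#' (1-based), `roi_label`, optional `x`, `y`, `z` centroid columns and an
#' optional `lobe` column. Rows are sorted by `roi_index`.
#'
#' @param path path to the CSV file.
#' @param name atlas name; defaults to the file name without extension.
#' @return an [AtlasSpec-class].
#' @export
readAtlasSpec <- function(path, name = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi_index", "roi_label")
  if (!all(need %in% names(df)))
    stop("atlas descriptor needs columns: ", paste(need, collapse = ", "))
  df <- df[order(df$roi_index), , drop = FALSE]
  if (!identical(as.integer(df$roi_index), seq_len(nrow(df))))
    stop("roi_index must run 1..n without gaps")
  cent <- NULL
  if (all(c("x", "y", "z") %in% names(df)))
    cent <- as.matrix(df[, c("x", "y", "z")])
  lobe <- if ("lobe" %in% names(df)) df$lobe else NULL
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  atlasSpec(name, df$roi_label, centroids = cent, lobeTags = lobe)
}

#' Toy atlas triplet for desk-scale experiments
#'
#' Three small parcellations (20, 34 and 42 ROIs) standing in for the usual
#' coarse-to-fine whole-brain triplet (AAL 116 / CC200 / Brainnetome 246) so
#' that the complete nested cross-validation pipeline runs in minutes on one
#' CPU. ROI labels are `<atlas>_R<nn>`.
#'
#' @return named list of three [AtlasSpec-class] objects.
#' @export
toyAtlases <- function() {
  mk <- function(name, n)
    atlasSpec(name, sprintf("%s_R%02d", name, seq_len(n)))
  list(toy20 = mk("toy20", 20L),
       toy34 = mk("toy34", 34L),
       toy42 = mk("toy42", 42L))
}

#' Paper-scale atlas triplet
#'
#' Generic atlas descriptors at the standard whole-brain sizes (116, 200 and
#' 246 regions) for slower full-scale runs. Labels are placeholders
#' (`<atlas>_R<nnn>`); substitute [readAtlasSpec()] descriptors to attach real
#' anatomical labels and centroids.
#'
#' @return named list of three [AtlasSpec-class] objects.
#' @export
standardAtlases <- function() {
  mk <- function(name, n)
    atlasSpec(name, sprintf("%s_R%03d", name, seq_len(n)))
  list(AAL116 = mk("AAL116", 116L),
       CC200 = mk("CC200", 200L),
       BN246 = mk("BN246", 246L))
}
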