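#' Save a model checkpoint
#'
#' Serialises the model parameters together with the encoder configuration,
#' atlas names and a versioned header, so a checkpoint can be validated
#' before use.
#'
#' @param model an [MsatModel-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "MsatModel"))
  obj <- list(format = "atlasfuse-checkpoint", version = 1L,
              atlasNames = model@atlasNames, atlasDims = model@atlasDims,
              satConfig = model@satConfig, fusionDim = model@fusionDim,
              clfHidden = model@clfHidden, params = model@params,
              trained = model@trained, trainLog = model@trainLog)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [saveModel()].
#' @return an [MsatModel-class].
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "atlasfuse-checkpoint"))
    stop("not an atlasfuse checkpoint: ", path)
  if (obj$version > 1L)
    stop("checkpoint version ", obj$version, " is newer than this package")
  new("MsatModel", atlasNames = obj$atlasNames, atlasDims = obj$atlasDims,
      satConfig = obj$satConfig, fusionDim = obj$fusionDim,
      clfHidden = obj$clfHidden, params = obj$params,
      trained = obj$trained, trainLog = obj$trainLog)
}

#' Write brain-network-viewer node and edge files
#'
#' Emits the plain-text layout standard 3-D network viewers read: a node
#' file with one row per ROI (`x y z weight label`, whitespace-separated)
#' and a square edge matrix. Centroids are required for meaningful node
#' coordinates; without them the origin is written and a message emitted.
#'
#' @param report an `"attentionReport"` from [roiAttention()].
#' @param atlas_spec the matching [AtlasSpec-class].
#' @param node_file output path for the node table.
#' @param edge_file output path for the edge matrix.
#' @param edges optional [discriminativeEdges()] result; the edge matrix
#'   then carries the t statistic of significant edges (0 elsewhere). If
#'   omitted, an all-zero matrix is written.
#' @return invisibly, the two paths.
#' @export
writeBrainNetFiles <- function(report, atlas_spec, node_file, edge_file,
                               edges = NULL) {
  n <- length(report$roi_weights)
  cents <- atlas_spec@centroids
  if (nrow(cents) == 0L) {
    message("atlas '", atlas_spec@name, "' has no centroids; writing origin")
    cents <- matrix(0, n, 3)
  }
  nodes <- data.frame(cents[, 1], cents[, 2], cents[, 3],
                      report$roi_weights, roiLabels(atlas_spec))
  utils::write.table(nodes, node_file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  M <- matrix(0, n, n)
  if (!is.null(edges)) {
    sig <- edges[edges$significant, , drop = FALSE]
    for (r in seq_len(nrow(sig))) {
      M[sig$roi_i[r], sig$roi_j[r]] <- sig$t[r]
      M[sig$roi_j[r], sig$roi_i[r]] <- sig$t[r]
    }
  }
  utils::write.table(M, edge_file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(node_file, edge_file))
}
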