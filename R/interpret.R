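#' Aggregate attention matrices into per-ROI received mass
#'
#' The per-ROI attention weight is the column mass of the attention matrices —
#' the attention each node receives, averaged over query nodes — averaged
#' across the supplied matrices (typically heads and layers). Each attention
#' matrix has rows on the simplex, so the resulting ROI weights are
#' nonnegative and sum to one. This definition is isolated here so it can be
#' swapped (e.g. for emitted mass) without touching the rest of the pipeline.
#'
#' @param attn_matrices list of row-stochastic attention matrices (n x n).
#' @return numeric vector of per-ROI weights, summing to 1.
#' @export
attentionMass <- function(attn_matrices) {
  if (!length(attn_matrices)) stop("no attention matrices supplied")
  w <- Reduce(`+`, lapply(attn_matrices, colMeans)) / length(attn_matrices)
  w
}

#' Per-ROI attention report for one atlas
#'
#' For each subject, extracts the head-averaged attention matrix of every SAT
#' layer in evaluation mode (deterministic), reduces them to per-ROI received
#' attention mass via [attentionMass()], and averages across subjects.
#'
#' @param model a trained [MsatModel-class]; an untrained model is refused.
#' @param data [cohortGraphs()] output.
#' @param atlas atlas name.
#' @param idx subject indices (typically the training subjects).
#' @return list of class `"attentionReport"` with `atlas`, `roi_weights`
#'   (length n_rois, nonnegative, sums to 1) and `n_subjects`.
#' @export
roiAttention <- function(model, data, atlas, idx = NULL) {
  if (!model@trained)
    stop("refused: model is untrained; attention weights are only meaningful ",
         "for a trained model")
  if (!atlas %in% model@atlasNames) stop("unknown atlas '", atlas, "'")
  if (is.null(idx)) idx <- seq_along(data$labels)
  acc <- NULL
  for (i in idx) {
    glist <- lapply(data$graphs, `[[`, i)
    fo <- .forwardSubject(model, glist, collect = TRUE)
    w <- attentionMass(fo$attn[[atlas]])
    acc <- if (is.null(acc)) w else acc + w
  }
  structure(list(atlas = atlas, roi_weights = acc / length(idx),
                 n_subjects = length(idx)),
            class = "attentionReport")
}

#' Top-k ROIs by attention weight
#'
#' Deterministic ranking by weight, descending; ties broken toward the lower
#' ROI index.
#'
#' @param report an `"attentionReport"` from [roiAttention()], or a plain
#'   numeric weight vector.
#' @param k number of ROIs to return (default 10).
#' @param labels optional ROI labels.
#' @return data.frame with `rank`, `roi_index`, `roi_label`, `weight`.
#' @export
topROIs <- function(report, k = 10L, labels = NULL) {
  w <- if (inherits(report, "attentionReport")) report$roi_weights
       else as.numeric(report)
  k <- as.integer(k)
  if (k > length(w)) stop("k exceeds the number of ROIs")
  ord <- order(-w, seq_along(w))[seq_len(k)]
  data.frame(rank = seq_len(k), roi_index = ord,
             roi_label = if (is.null(labels)) as.character(ord)
                         else labels[ord],
             weight = w[ord])
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, clipped to \[0, 1\] and monotone
#' in p-value rank. A single p-value is returned unchanged; an empty input
#' gives an empty output.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return vector of q-values, same length and order.
#' @export
bhFDR <- function(p_values) {
  p <- as.numeric(p_values)
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# vectorised Welch two-sample t-test over the columns of two matrices
# (subjects x variables); returns t, df and two-sided p per column
.welchT <- function(X1, X0) {
  n1 <- nrow(X1); n0 <- nrow(X0)
  m1 <- colMeans(X1); m0 <- colMeans(X0)
  v1 <- apply(X1, 2, stats::var); v0 <- apply(X0, 2, stats::var)
  se2 <- v1 / n1 + v0 / n0
  t <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- se2 == 0
  t[degenerate] <- 0
  p[degenerate] <- 1                     # flat edge in both groups
  list(t = t, df = df, p = p, degenerate = degenerate)
}

#' Discriminative edges among a ROI subset
#'
#' For every unordered ROI pair within `roi_subset`, the FC edge values are
#' compared between cases and controls with a Welch (unequal-variance)
#' two-sample t-test; Benjamini-Hochberg correction is applied jointly over
#' all tested pairs and significance is called at `q < alpha`. An edge with
#' zero variance in both groups is recorded with p = 1 and flagged.
#'
#' @param fc_matrices list of [FCMatrix-class] (or plain matrices), one per
#'   subject.
#' @param labels 0/1 labels, one per subject (>= 2 per group).
#' @param roi_subset ROI indices to test among (e.g. from [topROIs()]).
#' @param alpha FDR threshold (default 0.05).
#' @param roi_labels optional label vector for reporting.
#' @return data.frame with one row per pair: `roi_i`, `roi_j` (i < j),
#'   `label_i`, `label_j`, `t`, `p`, `q`, `significant`, `degenerate`.
#' @export
discriminativeEdges <- function(fc_matrices, labels, roi_subset,
                                alpha = 0.05, roi_labels = NULL) {
  labels <- as.integer(labels)
  if (sum(labels == 1L) < 2L || sum(labels == 0L) < 2L)
    stop("need at least 2 subjects per group")
  roi_subset <- sort(unique(as.integer(roi_subset)))
  pairs <- t(utils::combn(roi_subset, 2L))
  vals <- vapply(fc_matrices, function(fc) {
    v <- if (is(fc, "FCMatrix")) fc@values else as.matrix(fc)
    v[pairs]
  }, numeric(nrow(pairs)))
  E <- t(vals)                          # subjects x pairs
  wt <- .welchT(E[labels == 1L, , drop = FALSE],
                E[labels == 0L, , drop = FALSE])
  q <- bhFDR(wt$p)
  lab <- function(i) if (is.null(roi_labels)) as.character(i)
                     else roi_labels[i]
  data.frame(roi_i = pairs[, 1], roi_j = pairs[, 2],
             label_i = lab(pairs[, 1]), label_j = lab(pairs[, 2]),
             t = wt$t, p = wt$p, q = q,
             significant = q < alpha, degenerate = wt$degenerate)
}

#' Cross-atlas overlap of top-ROI lists
#'
#' Groups the per-atlas top-k ROI labels into regions via a region map and
#' buckets each region by the number of atlases whose list contains it.
#' Labels absent from the map land in an `unmatched` bucket; they are never
#' silently dropped.
#'
#' @param top_lists named list (per atlas) of character ROI label vectors.
#' @param region_map data.frame with columns `atlas`, `roi_label`, `region`.
#' @return list with `table` (data.frame `region`, `n_atlases`, `atlases`),
#'   `buckets` (list: regions by atlas count, names `"1"`, `"2"`, ...) and
#'   `unmatched` (data.frame `atlas`, `roi_label`).
#' @export
crossAtlasOverlap <- function(top_lists, region_map) {
  need <- c("atlas", "roi_label", "region")
  if (!all(need %in% names(region_map)))
    stop("region_map needs columns: ", paste(need, collapse = ", "))
  hits <- list(); unmatched <- list()
  for (an in names(top_lists)) {
    for (lb in top_lists[[an]]) {
      r <- region_map$region[region_map$atlas == an &
                               region_map$roi_label == lb]
      if (length(r) == 0L)
        unmatched[[length(unmatched) + 1L]] <-
          data.frame(atlas = an, roi_label = lb)
      else
        hits[[length(hits) + 1L]] <- data.frame(atlas = an, region = r[1])
    }
  }
  hits <- if (length(hits)) unique(do.call(rbind, hits))
          else data.frame(atlas = character(0), region = character(0))
  tab <- if (nrow(hits)) {
    sp <- split(hits$atlas, hits$region)
    data.frame(region = names(sp),
               n_atlases = vapply(sp, length, integer(1)),
               atlases = vapply(sp, paste, character(1), collapse = ","),
               row.names = NULL)
  } else data.frame(region = character(0), n_atlases = integer(0),
                    atlases = character(0))
  buckets <- split(tab$region, tab$n_atlases)
  list(table = tab, buckets = buckets,
       unmatched = if (length(unmatched)) do.call(rbind, unmatched)
                   else data.frame(atlas = character(0),
                                   roi_label = character(0)))
}

#' Region map from atlas centroids
#'
#' Relates ROIs across atlases by spatial proximity: ROIs (from any atlas)
#' whose centroids lie within `max_dist` of each other are merged into one
#' region by single-linkage grouping. Atlases without centroids are skipped
#' with a message.
#'
#' @param atlases list of [AtlasSpec-class] with centroids.
#' @param max_dist merge radius in the centroid units (default 10).
#' @return data.frame with columns `atlas`, `roi_label`, `region`.
#' @export
regionMapFromCentroids <- function(atlases, max_dist = 10) {
  rows <- list()
  for (a in atlases) {
    if (nrow(a@centroids) == 0L) {
      message("atlas '", a@name, "' has no centroids; skipped")
      next
    }
    rows[[length(rows) + 1L]] <-
      data.frame(atlas = a@name, roi_label = roiLabels(a), a@centroids)
  }
  if (!length(rows)) stop("no atlas has centroids")
  df <- do.call(rbind, rows)
  colnames(df)[3:5] <- c("x", "y", "z")
  d <- stats::dist(df[, c("x", "y", "z")])
  cl <- stats::cutree(stats::hclust(d, method = "single"), h = max_dist)
  data.frame(atlas = df$atlas, roi_label = df$roi_label,
             region = paste0("region_", cl))
}

#' Write interpretability reports as CSV
#'
#' Writes the per-ROI attention report (`atlas, roi_index, roi_label,
#' mean_weight, rank`) and, if supplied, the edge statistics (`atlas, roi_i,
#' roi_j, t, p, q, significant`) in viewer-friendly plain text.
#'
#' @param report an `"attentionReport"`.
#' @param atlas_spec the matching [AtlasSpec-class] (for labels).
#' @param file output CSV path.
#' @param edges optional [discriminativeEdges()] data.frame.
#' @param edges_file output path for the edge table.
#' @return invisibly, the attention data.frame written.
#' @export
writeAttentionReport <- function(report, atlas_spec, file, edges = NULL,
                                 edges_file = NULL) {
  w <- report$roi_weights
  df <- data.frame(atlas = report$atlas, roi_index = seq_along(w),
                   roi_label = roiLabels(atlas_spec), mean_weight = w,
                   rank = rank(-w, ties.method = "first"))
  utils::write.csv(df, file, row.names = FALSE)
  if (!is.null(edges) && !is.null(edges_file)) {
    edges$atlas <- report$atlas
    utils::write.csv(edges, edges_file, row.names = FALSE)
  }
  invisible(df)
}
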