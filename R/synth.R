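#' Simulation specification for synthetic multi-atlas cohorts
#'
#' The generator emulates a two-group resting-state cohort observed under
#' several parcellations of one shared latent signal: `n_latent` zero-mean
#' unit-variance Gaussian sources with a group-dependent correlation
#' structure, and each ROI's time series equal to its assigned source plus
#' independent Gaussian noise. Cases differ from controls only in the
#' coupling of the designated `effect_edges` (shifted by `effect_delta`), so
#' group differences in expected FC appear exactly on ROI pairs mapped to
#' those source pairs — the planted ground truth.
#'
#' @param atlases list of [AtlasSpec-class].
#' @param loading_map named list (per atlas) of integer vectors, length
#'   n_rois, assigning every ROI to exactly one latent source.
#' @param n_cases,n_controls group sizes.
#' @param n_timepoints time-series length (default 195, a typical
#'   post-scrubbing resting-state run length).
#' @param n_latent number of latent sources.
#' @param baseline_rho baseline inter-source correlation (default 0.2).
#' @param effect_base control-group coupling on the effect edges (default
#'   0.5), so hypo-connectivity effects have room to act.
#' @param effect_edges list of length-2 integer vectors of source pairs whose
#'   coupling differs between groups.
#' @param effect_delta coupling change in cases (negative = hypo-connectivity).
#' @param noise_sd ROI-level noise standard deviation (> 0).
#' @param seed integer seed; the single source of randomness.
#' @return validated list of class `"simSpec"`.
#' @export
simSpec <- function(atlases, loading_map, n_cases = 60L, n_controls = 60L,
                    n_timepoints = 195L, n_latent = 12L, baseline_rho = 0.2,
                    effect_base = 0.5, effect_edges = list(c(1L, 2L)),
                    effect_delta = -0.4, noise_sd = 0.5, seed = 1L) {
  anames <- unname(vapply(atlases, atlasName, character(1)))
  names(atlases) <- anames
  if (!identical(sort(names(loading_map)), sort(anames)))
    stop("loading_map must have one entry per atlas, named by atlas")
  for (an in anames) {
    lm <- loading_map[[an]]
    if (length(lm) != nRois(atlases[[an]]))
      stop("loading_map for '", an, "' must assign every ROI")
    if (any(lm < 1L | lm > n_latent))
      stop("loading_map for '", an, "' references sources outside 1..n_latent")
  }
  for (e in effect_edges) {
    if (length(e) != 2L || e[1] == e[2] ||
        any(e < 1L | e > n_latent))
      stop("effect_edges must be distinct source pairs within 1..n_latent")
  }
  if (n_timepoints < 2L) stop("n_timepoints must be >= 2")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  spec <- list(atlases = atlases, loading_map = loading_map,
               n_cases = as.integer(n_cases),
               n_controls = as.integer(n_controls),
               n_timepoints = as.integer(n_timepoints),
               n_latent = as.integer(n_latent),
               baseline_rho = baseline_rho, effect_base = effect_base,
               effect_edges = effect_edges, effect_delta = effect_delta,
               noise_sd = noise_sd, seed = as.integer(seed))
  class(spec) <- "simSpec"
  spec
}

# group-level latent correlation matrix; repaired to the nearest valid
# correlation matrix (Higham alternating projections via Matrix::nearPD)
# when the planted shift breaks positive semidefiniteness
sourceCorrelation <- function(spec, group = c("control", "case")) {
  group <- match.arg(group)
  nl <- spec$n_latent
  R <- matrix(spec$baseline_rho, nl, nl)
  diag(R) <- 1
  for (e in spec$effect_edges) {
    v <- spec$effect_base + if (group == "case") spec$effect_delta else 0
    R[e[1], e[2]] <- v
    R[e[2], e[1]] <- v
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    Rrep <- as.matrix(Matrix::nearPD(R, corr = TRUE, conv.tol = 1e-8,
                                     maxit = 200)$mat)
    if (max(abs(Rrep - R)) > 0.1)
      stop("parameter error: planted couplings are not repairable to a ",
           "valid correlation matrix; reduce |effect_delta|")
    R <- Rrep
  }
  R
}

#' Generate a synthetic multi-atlas cohort
#'
#' Draws, for each subject, latent source time series from the group's
#' correlation structure and maps them to per-atlas ROI series with
#' independent Gaussian noise (`noise_sd`). All randomness comes from
#' `spec$seed`: two calls with the same spec are bit-identical. Because each
#' ROI series is its unit-variance source plus noise of variance
#' `noise_sd^2`, the expected FC between ROIs of different sources is the
#' latent coupling attenuated by `1 / (1 + noise_sd^2)`.
#'
#' @param spec a [simSpec()].
#' @return a [SyntheticCohort-class]; subjects are `sub001..` with controls
#'   first, and `groundTruth()` carries the spec and planted ROI sets.
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "simSpec"))
  Rc <- sourceCorrelation(spec, "control")
  Ra <- sourceCorrelation(spec, "case")
  Lc <- chol(Rc); La <- chol(Ra)
  n <- spec$n_controls + spec$n_cases
  labels <- c(rep(0L, spec$n_controls), rep(1L, spec$n_cases))
  sids <- sprintf("sub%03d", seq_len(n))
  tp <- spec$n_timepoints
  anames <- names(spec$atlases)
  series <- lapply(anames, function(an)
    setNames(vector("list", n), sids))
  names(series) <- anames
  withSeed(spec$seed, {
    for (i in seq_len(n)) {
      L <- if (labels[i] == 0L) Lc else La
      Z <- matrix(stats::rnorm(tp * spec$n_latent), tp) %*% L
      for (an in anames) {
        map <- spec$loading_map[[an]]
        Y <- Z[, map, drop = FALSE] +
          spec$noise_sd * matrix(stats::rnorm(tp * length(map)), tp)
        series[[an]][[i]] <- Y
      }
    }
  })
  new("SyntheticCohort",
      atlases = unname(spec$atlases), series = series,
      phenotype = data.frame(subject_id = sids, label = labels,
                             stringsAsFactors = FALSE),
      groundTruth = list(spec = spec, plantedROIs = plantedROISets(spec)))
}

#' Planted ROI sets per atlas
#'
#' The ROIs whose latent source participates in any effect edge — the ground
#' truth against which attention rankings are scored. Empty sets when there
#' are no effect edges or `effect_delta` is zero.
#'
#' @param spec a [simSpec()].
#' @return named list of integer ROI index vectors, one per atlas.
#' @export
plantedROISets <- function(spec) {
  stopifnot(inherits(spec, "simSpec"))
  if (!length(spec$effect_edges) || spec$effect_delta == 0)
    return(setNames(lapply(names(spec$atlases), function(an) integer(0)),
                    names(spec$atlases)))
  src <- sort(unique(unlist(spec$effect_edges)))
  setNames(lapply(names(spec$atlases), function(an)
    which(spec$loading_map[[an]] %in% src)), names(spec$atlases))
}

#' Recall of a planted ROI set within a top-k ranking
#'
#' `|topk intersect planted| / min(k, |planted|)`.
#'
#' @param top_idx ROI indices of the top-k ranking.
#' @param planted_idx planted ROI indices.
#' @return recall in \[0, 1\] (`NA` when the planted set is empty).
#' @export
recallTopK <- function(top_idx, planted_idx) {
  if (!length(planted_idx)) return(NA_real_)
  length(intersect(top_idx, planted_idx)) /
    min(length(top_idx), length(planted_idx))
}

#' Write a cohort to delimited-text files
#'
#' Produces exactly the layout [loadCohort()] reads:
#' `<out_dir>/<atlas>/<subject>.tsv` with a header row of ROI labels, plus
#' `<out_dir>/phenotype.csv`. For synthetic cohorts the ground truth is
#' written alongside as `ground_truth.json`.
#'
#' @param cohort a [MultiAtlasCohort-class].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
writeCohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  atl <- cohortAtlases(cohort)
  for (an in names(atl)) {
    d <- file.path(out_dir, an)
    dir.create(d, showWarnings = FALSE)
    labs <- roiLabels(atl[[an]])
    for (sid in subjectIDs(cohort)) {
      f <- file.path(d, paste0(sid, ".tsv"))
      m <- cohort@series[[an]][[sid]]
      colnames(m) <- labs
      utils::write.table(m, f, sep = "\t", row.names = FALSE,
                         col.names = TRUE, quote = FALSE)
      files <- c(files, f)
    }
  }
  pf <- file.path(out_dir, "phenotype.csv")
  utils::write.csv(cohort@phenotype, pf, row.names = FALSE)
  files <- c(files, pf)
  if (is(cohort, "SyntheticCohort")) {
    gt <- cohort@groundTruth
    spec <- gt$spec
    gtOut <- list(
      n_cases = spec$n_cases, n_controls = spec$n_controls,
      n_timepoints = spec$n_timepoints, n_latent = spec$n_latent,
      baseline_rho = spec$baseline_rho, effect_base = spec$effect_base,
      effect_edges = spec$effect_edges, effect_delta = spec$effect_delta,
      noise_sd = spec$noise_sd, seed = spec$seed,
      loading_map = spec$loading_map, planted_rois = gt$plantedROIs)
    gf <- file.path(out_dir, "ground_truth.json")
    jsonlite::write_json(gtOut, gf, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, gf)
  }
  invisible(files)
}

# loading map concentrating `conc[s]` ROIs on each effect source s and
# spreading the rest round-robin over the remaining sources
.makeLoadingMap <- function(n_rois, conc, n_latent) {
  lead <- rep(seq_along(conc), times = conc)
  rest <- setdiff(seq_len(n_latent), seq_along(conc))
  c(lead, rep(rest, length.out = n_rois - length(lead)))
}

#' Default planted-effect recovery scenario
#'
#' Three toy atlases (20/34/42 ROIs) over 12 latent sources, 60 cases vs 60
#' controls, 195 timepoints, baseline coupling 0.2, control coupling 0.5 on
#' the single effect edge (sources 1-2), case shift `effect_delta = -0.4`
#' (hypo-connectivity) and `noise_sd = 0.5`. The affected sources load 2+2
#' ROIs in `toy20`, 3+3 in `toy34` and 8+8 in `toy42`, so the finest atlas is
#' engineered to carry the strongest planted signal and should attract the
#' largest fusion weight.
#'
#' @param seed simulation seed.
#' @param effect_delta case coupling shift (default -0.4; set 0 for a null
#'   cohort via [nullSimSpec()]).
#' @return a [simSpec()].
#' @export
recoverySimSpec <- function(seed = 1L, effect_delta = -0.4) {
  atl <- toyAtlases()
  lm <- list(toy20 = .makeLoadingMap(20L, c(2L, 2L), 12L),
             toy34 = .makeLoadingMap(34L, c(3L, 3L), 12L),
             toy42 = .makeLoadingMap(42L, c(8L, 8L), 12L))
  simSpec(atlases = atl, loading_map = lm, n_cases = 60L, n_controls = 60L,
          n_timepoints = 195L, n_latent = 12L, baseline_rho = 0.2,
          effect_base = 0.5, effect_edges = list(c(1L, 2L)),
          effect_delta = effect_delta, noise_sd = 0.5, seed = seed)
}

#' Null scenario (no planted effect)
#'
#' The recovery scenario with `effect_delta = 0`: case and control FC
#' expectations are identical, so downstream classification accuracy should
#' sit in the chance band.
#'
#' @param seed simulation seed.
#' @return a [simSpec()].
#' @export
nullSimSpec <- function(seed = 1L) recoverySimSpec(seed, effect_delta = 0)

#' Paper-scale simulation scenario
#'
#' The same generative model at full atlas resolution (116/200/246 ROIs),
#' for slower optional runs.
#'
#' @param seed simulation seed.
#' @param effect_delta case coupling shift.
#' @return a [simSpec()].
#' @export
standardSimSpec <- function(seed = 1L, effect_delta = -0.4) {
  atl <- standardAtlases()
  lm <- list(AAL116 = .makeLoadingMap(116L, c(10L, 10L), 12L),
             CC200 = .makeLoadingMap(200L, c(17L, 17L), 12L),
             BN246 = .makeLoadingMap(246L, c(40L, 40L), 12L))
  simSpec(atlases = atl, loading_map = lm, n_cases = 60L, n_controls = 60L,
          n_timepoints = 195L, n_latent = 12L, baseline_rho = 0.2,
          effect_base = 0.5, effect_edges = list(c(1L, 2L)),
          effect_delta = effect_delta, noise_sd = 0.5, seed = seed)
}

#' Region map induced by a simulation's loading map
#'
#' Maps every ROI label of every atlas to its latent source (`S<k>`), giving
#' the exact cross-atlas correspondence for [crossAtlasOverlap()] on
#' synthetic data.
#'
#' @param spec a [simSpec()].
#' @return data.frame with columns `atlas`, `roi_label`, `region`.
#' @export
regionMapFromSpec <- function(spec) {
  stopifnot(inherits(spec, "simSpec"))
  do.call(rbind, lapply(names(spec$atlases), function(an)
    data.frame(atlas = an,
               roi_label = roiLabels(spec$atlases[[an]]),
               region = sprintf("S%02d", spec$loading_map[[an]]))))
}
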