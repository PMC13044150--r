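#' Assemble a multi-atlas cohort from in-memory matrices
#'
#' Lower-level constructor used by [loadCohort()] and the synthetic generator.
#'
#' @param atlases list of [AtlasSpec-class].
#' @param series named list (per atlas) of named lists of timepoints x n_rois
#'   matrices; subject names and order must match `phenotype$subject_id`.
#' @param phenotype data.frame with `subject_id` and `label` columns.
#' @return a [MultiAtlasCohort-class].
#' @export
multiAtlasCohort <- function(atlases, series, phenotype) {
  phenotype$subject_id <- as.character(phenotype$subject_id)
  phenotype$label <- as.integer(phenotype$label)
  rownames(phenotype) <- NULL
  new("MultiAtlasCohort", atlases = atlases, series = series,
      phenotype = phenotype)
}

#' Load a multi-atlas cohort from delimited-text files
#'
#' Reads one time-series file per subject per atlas from
#' `<timeseries_dir>/<atlas>/<subject_id>.tsv` (or `.csv`), plus a phenotype
#' CSV with columns `subject_id` and `label` (0 = control, 1 = case). Files
#' are delimited text with rows = timepoints and columns = ROIs; an optional
#' header row carries ROI labels. Subjects missing any requested atlas are
#' dropped with a warning; non-finite values or a column count differing from
#' the atlas ROI count are errors.
#'
#' @param timeseries_dir directory holding one subdirectory per atlas.
#' @param phenotype path to the phenotype CSV, or a data.frame.
#' @param atlases list of [AtlasSpec-class] to load.
#' @return a [MultiAtlasCohort-class].
#' @seealso [writeCohort()] for the inverse operation.
#' @export
loadCohort <- function(timeseries_dir, phenotype, atlases) {
  ph <- if (is.character(phenotype))
    utils::read.csv(phenotype, stringsAsFactors = FALSE) else phenotype
  if (!all(c("subject_id", "label") %in% names(ph)))
    stop("phenotype needs columns 'subject_id' and 'label'")
  if (!all(ph$label %in% c(0, 1)))
    stop("schema error: labels must be 0 or 1, got: ",
         paste(unique(ph$label[!ph$label %in% c(0, 1)]), collapse = ", "))
  ph$subject_id <- as.character(ph$subject_id)

  anames <- vapply(atlases, function(a) a@name, character(1))
  names(atlases) <- anames

  findFile <- function(an, sid) {
    for (ext in c("tsv", "csv")) {
      p <- file.path(timeseries_dir, an, paste0(sid, ".", ext))
      if (file.exists(p)) return(p)
    }
    NA_character_
  }

  paths <- sapply(anames, function(an)
    vapply(ph$subject_id, function(sid) findFile(an, sid), character(1)))
  paths <- matrix(paths, nrow = nrow(ph),
                  dimnames = list(ph$subject_id, anames))
  complete <- apply(!is.na(paths), 1, all)
  if (any(!complete)) {
    warning(sum(!complete), " subject(s) missing at least one atlas file, ",
            "dropped: ", paste(ph$subject_id[!complete], collapse = ", "))
    ph <- ph[complete, , drop = FALSE]
    paths <- paths[complete, , drop = FALSE]
  }
  if (nrow(ph) == 0L) stop("no subject has a complete set of atlas files")

  readTS <- function(path, atlas, sid) {
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    first <- readLines(path, n = 1L)
    hasHeader <- any(is.na(suppressWarnings(
      as.numeric(strsplit(first, sep, fixed = TRUE)[[1]]))))
    m <- as.matrix(utils::read.delim(path, sep = sep, header = hasHeader))
    storage.mode(m) <- "double"
    if (ncol(m) != nRois(atlas))
      stop("format error: '", basename(path), "' has ", ncol(m),
           " columns but atlas '", atlas@name, "' has ", nRois(atlas), " ROIs")
    if (nrow(m) < 2L)
      stop("subject '", sid, "': at least 2 timepoints required")
    if (any(!is.finite(m)))
      stop("load error: non-finite values in '", basename(path), "'")
    dimnames(m) <- NULL
    m
  }

  series <- lapply(anames, function(an) {
    sl <- lapply(seq_len(nrow(ph)), function(i)
      readTS(paths[i, an], atlases[[an]], ph$subject_id[i]))
    names(sl) <- ph$subject_id
    sl
  })
  names(series) <- anames
  multiAtlasCohort(atlases, series, ph[, c("subject_id", "label"), drop = FALSE])
}

#' Subset a cohort by subject
#'
#' @param cohort a [MultiAtlasCohort-class].
#' @param idx integer or logical index into the cohort's subject order.
#' @return a [MultiAtlasCohort-class] with the selected subjects.
#' @export
subsetCohort <- function(cohort, idx) {
  ph <- cohort@phenotype[idx, , drop = FALSE]
  series <- lapply(cohort@series, function(sl) sl[idx])
  multiAtlasCohort(cohort@atlases, series, ph)
}
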