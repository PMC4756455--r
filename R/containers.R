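#' Sample-by-clade relative abundance table
#'
#' Thin S3 wrapper around a numeric matrix with samples in rows and clades in
#' columns. Clade names follow the MetaPhlAn pipe-delimited, rank-prefixed
#' lineage convention (\code{k__...|p__...|...|s__...}) or, for species-level
#' tables, bare species names. Values are proportions in [0, 1].
#'
#' @param x numeric matrix, rows = samples, columns = clades; both dimensions
#'   must be named.
#' @param rank taxonomic rank the rows were filtered to (e.g. "species").
#' @return an object of class \code{abundance_table} (a matrix).
#' @export
abundance_table <- function(x, rank = "species") {
  x <- validate_profile_matrix(x, "abundance")
  if (any(rowSums(x) > 1 + 1e-6))
    stop("abundance: per-sample proportions at a single rank must sum to <= 1",
         call. = FALSE)
  structure(x, rank = rank, class = c("abundance_table", "matrix", "array"))
}

#' Sample-by-module functional relative abundance table
#'
#' @param x numeric matrix, rows = samples, columns = KEGG-style module ids
#'   (e.g. \code{M00319}); values are proportions.
#' @return an object of class \code{function_table}.
#' @export
function_table <- function(x) {
  x <- validate_profile_matrix(x, "functions")
  structure(x, class = c("function_table", "matrix", "array"))
}

validate_profile_matrix <- function(x, what) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(sprintf("%s: matrix must have sample rownames and feature colnames", what),
         call. = FALSE)
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x)))
    stop(sprintf("%s: duplicate sample or feature identifiers", what), call. = FALSE)
  if (anyNA(x) || any(x < 0))
    stop(sprintf("%s: values must be non-negative and non-missing", what),
         call. = FALSE)
  x
}

#' Per-species marker-gene abundance profiles (RPK)
#'
#' A named list mapping each species to a samples-by-markers matrix of marker
#' gene abundance in reads per kilobase (RPK). All species matrices must share
#' an identical sample set.
#'
#' @param profiles named list of numeric matrices (rows = samples,
#'   columns = markers, values = RPK >= 0).
#' @return an object of class \code{marker_profile_set}.
#' @export
marker_profile_set <- function(profiles) {
  if (!is.list(profiles) || is.null(names(profiles)) || any(names(profiles) == ""))
    stop("markers: must be a named list of species matrices", call. = FALSE)
  if (anyDuplicated(names(profiles)))
    stop("markers: duplicate species names", call. = FALSE)
  ref <- NULL
  profiles <- lapply(profiles, function(m) {
    m <- as.matrix(m); storage.mode(m) <- "double"; m
  })
  for (sp in names(profiles)) {
    m <- profiles[[sp]]
    if (is.null(rownames(m)) || is.null(colnames(m)))
      stop(sprintf("markers[%s]: needs sample rownames and marker colnames", sp),
           call. = FALSE)
    if (anyDuplicated(colnames(m)))
      stop(sprintf("markers[%s]: duplicate marker ids", sp), call. = FALSE)
    if (anyNA(m) || any(m < 0))
      stop(sprintf("markers[%s]: RPK must be non-negative", sp), call. = FALSE)
    if (is.null(ref)) ref <- sort(rownames(m))
    else if (!identical(sort(rownames(m)), ref))
      stop(sprintf("markers[%s]: sample set differs from other species", sp),
           call. = FALSE)
  }
  structure(profiles, class = "marker_profile_set")
}

#' Species-by-module genome carriage matrix
#'
#' Entry (s, m) is the fraction of reference genomes of species s that carry
#' module m completely, in [0, 1]. Used both to classify taxon-function
#' correlations as genomically encoded and to generate synthetic module
#' abundances from species abundances.
#'
#' @param x numeric matrix, rows = species, columns = modules, values in [0,1].
#' @return an object of class \code{carriage_matrix}.
#' @export
carriage_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("carriage: matrix must have species rownames and module colnames",
         call. = FALSE)
  if (anyNA(x) || any(x < 0) || any(x > 1))
    stop("carriage: values must lie in [0, 1]", call. = FALSE)
  structure(x, class = c("carriage_matrix", "matrix", "array"))
}

#' Per-sample metadata table
#'
#' A data frame with one row per sample carrying the identifiers
#' (\code{sample_id}, \code{subject_id}, \code{pair_id}, \code{timepoint})
#' plus clinical variables. Twins share \code{pair_id}; \code{timepoint} is
#' 1 or 2. Missing clinical values are permitted (\code{NA}) and handled
#' per-model downstream.
#'
#' @param df data frame with at least the four mandatory identifier columns.
#' @return an object of class \code{metadata_table} (a data frame).
#' @export
metadata_table <- function(df) {
  mandatory <- c("sample_id", "subject_id", "pair_id", "timepoint")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols))
    stop("metadata: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("metadata: duplicate sample_id", call. = FALSE)
  if (anyNA(df$timepoint) || !all(df$timepoint %in% c(1, 2)))
    stop("metadata: timepoint must be 1 or 2", call. = FALSE)
  tp_per_subject <- tapply(df$timepoint, df$subject_id,
                           function(v) length(unique(v)))
  if (any(tapply(df$sample_id, df$subject_id, length) > 2))
    stop("metadata: a subject has more than 2 samples", call. = FALSE)
  if (any(tp_per_subject < tapply(df$sample_id, df$subject_id, length)))
    stop("metadata: a subject has duplicated time points", call. = FALSE)
  for (col in c("sex", "smoking"))
    if (col %in% names(df)) df[[col]] <- factor(df[[col]])
  df$timepoint <- as.integer(df$timepoint)
  class(df) <- c("metadata_table", "data.frame")
  df
}

#' Names of clinical variables recognised in metadata tables
#'
#' @return character vector of clinical column names used as candidate
#'   predictors by the association stage.
#' @export
clinical_variables <- function() {
  c("bmi", "fbs", "fbi", "homa", "systolic_bp", "diastolic_bp",
    "triglycerides", "hscrp")
}

sample_ids <- function(x) UseMethod("sample_ids")
#' @export
sample_ids.abundance_table <- function(x) rownames(x)
#' @export
sample_ids.function_table <- function(x) rownames(x)
#' @export
sample_ids.marker_profile_set <- function(x) rownames(x[[1]])
#' @export
sample_ids.metadata_table <- function(x) x$sample_id
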