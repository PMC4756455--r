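# Tab-delimited readers/writers for the standard profile formats consumed by
# the pipeline: MetaPhlAn-style clade tables (percent units, pipe-delimited
# rank-prefixed lineages), HUMAnN-style module tables, per-species marker RPK
# tables, per-sample metadata, and the species-by-module carriage matrix.
# All files are UTF-8, tab-delimited with a header row; "NA" marks missing.

RANK_PREFIXES <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
                   family = "f", genus = "g", species = "s", strain = "t")

read_tsv_matrix <- function(path, what) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "NA",
                          colClasses = NA)
  if (nrow(df) == 0L)
    stop(sprintf("%s: no %s rows in '%s'", what, what, path), call. = FALSE)
  ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      if (length(bad))
        stop(sprintf("%s: non-numeric cell at row '%s', column '%s'",
                     what, ids[bad[1]], names(vals)[j]), call. = FALSE)
      vals[[j]] <- as.numeric(v)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

#' Read a MetaPhlAn-style taxonomic profile
#'
#' Parses a tab-delimited clade relative-abundance table: first column the
#' pipe-delimited, rank-prefixed clade lineage
#' (\code{k__...|p__...|...|s__...}), remaining columns one per sample, with
#' values as percentages (0-100, the MetaPhlAn output convention). Rows are
#' filtered to the requested rank and percentages are converted to
#' proportions at the boundary; all internal arithmetic in this package uses
#' proportions.
#'
#' @param path path to the tab-delimited profile.
#' @param rank rank to keep: one of kingdom, phylum, class, order, family,
#'   genus, species, strain. A row belongs to a rank when its deepest lineage
#'   field carries that rank's prefix.
#' @return an \code{\link{abundance_table}} (samples x clades, proportions).
#' @export
read_taxonomic_profile <- function(path, rank = "species") {
  rank <- match.arg(rank, names(RANK_PREFIXES))
  m <- read_tsv_matrix(path, "clade")
  lineages <- rownames(m)
  if (anyDuplicated(lineages))
    stop("clade: duplicate lineage '",
         lineages[duplicated(lineages)][1], "'", call. = FALSE)
  deepest <- character(length(lineages))
  for (i in seq_along(lineages)) {
    fields <- strsplit(lineages[i], "|", fixed = TRUE)[[1]]
    pref <- sub("__.*$", "", fields)
    if (!all(pref %in% RANK_PREFIXES) || any(!grepl("^[a-z]__", fields)))
      stop(sprintf("clade: malformed lineage at line %d: '%s'",
                   i + 1L, lineages[i]), call. = FALSE)
    deepest[i] <- pref[length(pref)]
  }
  if (anyNA(m) || any(m < 0))
    stop("clade: negative or missing abundance value", call. = FALSE)
  keep <- deepest == RANK_PREFIXES[[rank]]
  m <- m[keep, , drop = FALSE]
  abundance_table(t(m) / 100, rank = rank)
}

#' Read a HUMAnN-style functional module profile
#'
#' First column the module identifier (KEGG module style, e.g.
#' \code{M00319}), remaining columns one per sample; values are relative
#' abundance proportions.
#'
#' @param path path to the tab-delimited module table.
#' @return a \code{\link{function_table}} (samples x modules).
#' @export
read_module_profile <- function(path) {
  m <- read_tsv_matrix(path, "module")
  if (anyDuplicated(rownames(m)))
    stop("module: duplicate module id", call. = FALSE)
  if (anyNA(m) || any(m < 0))
    stop("module: negative or missing value", call. = FALSE)
  function_table(t(m))
}

#' Read per-species marker-gene RPK profiles from a directory
#'
#' Expects one tab-delimited file per species (\code{<species>.tsv}), rows =
#' marker genes, columns = samples, values = reads per kilobase. The species
#' name is taken from the filename. All files must share the same sample set.
#'
#' @param dir directory of per-species marker tables.
#' @return a \code{\link{marker_profile_set}}.
#' @export
read_marker_profiles <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (!length(files))
    stop("markers: no .tsv files in '", dir, "'", call. = FALSE)
  profiles <- lapply(files, function(f) {
    m <- read_tsv_matrix(f, "marker")
    if (anyNA(m) || any(m < 0))
      stop("markers: negative or missing RPK in '", f, "'", call. = FALSE)
    t(m)
  })
  names(profiles) <- sub("\\.tsv$", "", basename(files))
  marker_profile_set(profiles)
}

#' Read a sample metadata table
#'
#' Tab-delimited with mandatory columns \code{sample_id}, \code{subject_id},
#' \code{pair_id}, \code{timepoint} plus clinical variables. \code{sex} and
#' \code{smoking} are coded as categories; missing clinical values ("NA") are
#' kept as missing and handled per-model downstream, never dropped globally.
#'
#' @param path path to the metadata table.
#' @return a \code{\link{metadata_table}}.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  for (col in intersect(clinical_variables(), names(df)))
    df[[col]] <- as.numeric(df[[col]])
  if ("age" %in% names(df)) df$age <- as.numeric(df$age)
  metadata_table(df)
}

#' Read a species-by-module genome carriage matrix
#'
#' @param path tab-delimited table, first column species, remaining columns
#'   modules, values = fraction of reference genomes carrying the module.
#' @return a \code{\link{carriage_matrix}}.
#' @export
read_carriage <- function(path) {
  carriage_matrix(read_tsv_matrix(path, "carriage"))
}

#' Write a pipeline table to tab-delimited text
#'
#' The inverse of the corresponding reader: reading a written file
#' reconstructs the object (abundance tables are serialized in the MetaPhlAn
#' percent convention; marker profile sets are written as one file per
#' species into a directory).
#'
#' @param x table object.
#' @param path output file (or directory for \code{marker_profile_set}).
#' @return invisibly, \code{path}.
#' @export
write_table <- function(x, path) UseMethod("write_table")

write_id_matrix <- function(m, id_col, path) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
write_table.abundance_table <- function(x, path) {
  write_id_matrix(t(unclass(x) * 100), "clade_name", path)
}

#' @export
write_table.function_table <- function(x, path) {
  write_id_matrix(t(unclass(x)), "module", path)
}

#' @export
write_table.carriage_matrix <- function(x, path) {
  write_id_matrix(unclass(x), "species", path)
}

#' @export
write_table.metadata_table <- function(x, path) {
  df <- as.data.frame(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
write_table.marker_profile_set <- function(x, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  for (sp in names(x))
    write_id_matrix(t(x[[sp]]), "marker", file.path(path, paste0(sp, ".tsv")))
  invisible(path)
}

#' Extract the bare species name from a clade lineage string
#'
#' Strips the lineage path and the \code{s__} rank prefix so that species
#' names in marker profile sets can be matched against species-level clade
#' names from taxonomic tables. Upstream naming drift between tools is
#' common, so mismatches downstream warn rather than fail.
#'
#' @param lineage character vector of lineage strings or bare names.
#' @return character vector of species names.
#' @export
clade_species_name <- function(lineage) {
  leaf <- vapply(strsplit(lineage, "|", fixed = TRUE),
                 function(f) f[length(f)], character(1))
  sub("^[a-z]__", "", leaf)
}
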