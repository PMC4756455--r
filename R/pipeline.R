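# End-to-end orchestration: simulate (or load + validate) -> community ->
# associate -> strains -> taxfun, with one global seed expanded into
# per-stage seeds, stage logging, and a machine-readable run manifest with
# content digests so identical config + seed reproduces identical outputs.

missing_input_error <- function(msg) {
  stop(structure(class = c("twinmeta_missing_input", "error", "condition"),
                 list(message = msg, call = NULL)))
}

invalid_input_error <- function(msg) {
  stop(structure(class = c("twinmeta_invalid_input", "error", "condition"),
                 list(message = msg, call = NULL)))
}

log_stage <- function(...) message(format(Sys.time(), "%H:%M:%S "), ...)

#' Load and validate a directory of input tables
#'
#' Reads \code{abundance.tsv}, \code{modules.tsv}, \code{markers/},
#' \code{metadata.tsv} and \code{carriage.tsv}, running every container
#' invariant check. Sample identifiers must agree across tables.
#'
#' @param dir input directory.
#' @return list with abundance, functions, markers, metadata, carriage.
#' @export
load_inputs <- function(dir) {
  paths <- list(abundance = file.path(dir, "abundance.tsv"),
                modules = file.path(dir, "modules.tsv"),
                markers = file.path(dir, "markers"),
                metadata = file.path(dir, "metadata.tsv"),
                carriage = file.path(dir, "carriage.tsv"))
  for (nm in names(paths))
    if (!file.exists(paths[[nm]]))
      missing_input_error(paste0("missing input: ", paths[[nm]]))
  out <- tryCatch(list(
    abundance = read_taxonomic_profile(paths$abundance),
    functions = read_module_profile(paths$modules),
    markers = read_marker_profiles(paths$markers),
    metadata = read_metadata(paths$metadata),
    carriage = read_carriage(paths$carriage)
  ), error = function(e) invalid_input_error(conditionMessage(e)))
  ids <- sort(sample_ids(out$abundance))
  for (nm in c("functions", "markers", "metadata"))
    if (!identical(sort(sample_ids(out[[nm]])), ids))
      invalid_input_error(paste0("sample ids of ", nm,
                                 " differ from abundance table"))
  sp_ab <- clade_species_name(colnames(out$abundance))
  sp_mk <- clade_species_name(names(out$markers))
  if (length(setdiff(sp_mk, sp_ab)))
    warning("marker species not in abundance table: ",
            paste(setdiff(sp_mk, sp_ab), collapse = ", "))
  out
}

#' Run the full pipeline from a config
#'
#' The config (YAML file or list) contains a global \code{seed}, either a
#' \code{simulate} block (arguments for \code{\link{cohort_config}}) or an
#' \code{inputs} directory, and optional per-stage blocks
#' (\code{association}, \code{strain}, \code{taxfun}). The global seed is
#' expanded deterministically into per-stage seeds. Outputs are written to
#' \code{out_dir} and a \code{manifest.json} with content digests is written
#' last.
#'
#' @param config path to a YAML config or an equivalent list.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config))
      missing_input_error(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- Sys.time()
    log_stage("stage ", stage, " started")
    res <- force(expr)
    timings[[stage]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
    res
  }

  data <- clock("input", {
    if (!is.null(config$simulate)) {
      cfg <- do.call(cohort_config,
                     c(config$simulate, list(seed = derive_seed(seed, "simulate"))))
      cohort <- generate_cohort(cfg)
      write_cohort(cohort, file.path(out_dir, "simulated"))
      cohort
    } else if (!is.null(config$inputs)) {
      load_inputs(config$inputs)
    } else {
      missing_input_error("config needs a 'simulate' or 'inputs' block")
    }
  })
  log_stage("loaded ", nrow(data$abundance), " samples, ",
            ncol(data$abundance), " species, ",
            ncol(data$functions), " modules")

  community <- clock("community", {
    dm <- distance_matrix(data$abundance)
    ord <- ordinate(dm, k = 2)
    prs <- enumerate_pairs(data$metadata)
    cmp <- compare_groups(pair_values(prs, dm = dm))
    utils::write.table(dm$matrix, file.path(out_dir, "distance_matrix.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(ord$coordinates, file.path(out_dir, "ordination.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(cmp, file.path(out_dir, "community_contrasts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(contrasts = cmp, pairs = prs)
  })

  assoc <- clock("associate", {
    acfg <- do.call(association_config, config$association %||% list())
    res <- run_association(data$abundance, data$metadata, acfg)
    utils::write.table(res, file.path(out_dir, "associations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(results = res, q_threshold = acfg$q_threshold)
  })

  strains <- clock("strains", {
    scfg <- config$strain %||% list()
    cmp <- strain_comparisons(
      data$markers,
      eligible_comparisons(data$markers, community$pairs,
                           min_median_rpk = scfg$min_median_rpk %||% 5))
    utils::write.table(cmp, file.path(out_dir, "strain_comparisons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tests <- if (nrow(cmp) &&
                 all(table(factor(cmp$pair_type,
                                  c("unrelated", "twin", "self"))) >= 2))
      compare_strain_groups(cmp) else NULL
    jsonlite::write_json(tests, file.path(out_dir, "strain_tests.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    div <- species_mean_divergence(cmp)
    utils::write.table(div, file.path(out_dir, "strain_divergence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(comparisons = cmp, tests = tests)
  })

  taxfun <- clock("taxfun", {
    tcfg <- config$taxfun %||% list()
    recs <- correlation_matrix(data$abundance, data$functions)
    net <- cooccurrence_network(data$abundance,
                                q_threshold = tcfg$q_threshold %||% 0.2)
    recs <- classify_correlations(
      recs, data$carriage, net,
      encoded_threshold = tcfg$encoded_threshold %||% 0.5)
    utils::write.table(recs, file.path(out_dir, "taxon_function.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(net$edges, file.path(out_dir, "cooccurrence_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    recs
  })

  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  digests <- as.list(tools::md5sum(sort(outputs)))
  names(digests) <- substring(names(digests),
                              nchar(sub("/+$", "", out_dir)) + 2)
  manifest <- list(
    package_version = as.character(utils::packageVersion("twinmeta")),
    seed = seed,
    config = config,
    timings_sec = timings,
    digests = digests
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("pipeline complete: ", out_dir)
  invisible(manifest)
}

#' Summarize a completed pipeline run
#'
#' @param dir a pipeline output directory.
#' @param q_threshold q cutoff used when counting significant associations.
#' @return list of class \code{pipeline_report} with per-stage summaries;
#'   printing it gives a plain-text report. A \code{report.json} is written
#'   alongside the inputs.
#' @export
pipeline_report <- function(dir, q_threshold = 0.2) {
  need <- c("manifest.json", "associations.tsv", "strain_tests.json",
            "taxon_function.tsv", "community_contrasts.tsv")
  absent <- need[!file.exists(file.path(dir, need))]
  if (length(absent))
    stop("incomplete run directory; missing: ",
         paste(absent, collapse = ", "), call. = FALSE)
  assoc <- utils::read.delim(file.path(dir, "associations.tsv"))
  recs <- utils::read.delim(file.path(dir, "taxon_function.tsv"))
  tests <- jsonlite::read_json(file.path(dir, "strain_tests.json"),
                               simplifyVector = TRUE)
  contrasts <- utils::read.delim(file.path(dir, "community_contrasts.tsv"))
  rep <- list(
    n_associations_tested = nrow(assoc),
    n_associations_significant = sum(assoc$q < q_threshold),
    community_contrasts = contrasts,
    strain_tests = tests,
    taxfun_class_counts = as.list(table(recs$class))
  )
  class(rep) <- "pipeline_report"
  jsonlite::write_json(unclass(rep), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  rep
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== twinmeta run report ==\n")
  cat(sprintf("associations: %d tested, %d significant\n",
              x$n_associations_tested, x$n_associations_significant))
  if (x$n_associations_significant == 0)
    cat("  none significant\n")
  cat("community contrasts (Welch t):\n")
  print(x$community_contrasts)
  cat("strain group tests:\n")
  if (is.null(x$strain_tests) || !length(x$strain_tests))
    cat("  not computed (too few eligible comparisons)\n")
  else print(x$strain_tests)
  cat("taxon-function classes:\n")
  for (nm in names(x$taxfun_class_counts))
    cat(sprintf("  %s: %d\n", nm, x$taxfun_class_counts[[nm]]))
  invisible(x)
}
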