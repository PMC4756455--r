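# Synthetic twin-cohort generator.
#
# Emulates a monozygotic-twin shotgun-metagenomics study: n_pairs twin pairs
# sampled at up to two time points (with optional dropout), species
# relative-abundance profiles with twin-correlated subject latents and guild
# co-occurrence structure, per-species marker-gene barcodes with tunable
# twin/self divergence, functional-module abundances derived from species
# abundances through a genome-carriage matrix, and clinical metadata with
# optional planted microbe-phenotype effects. Every downstream analysis
# stage is testable against the generator's ground truth.

#' Configuration for a synthetic twin cohort
#'
#' Defaults emulate a 10-pair, two-time-point design with 4 samples lost to
#' follow-up (36 samples in total) and a moderately twin-correlated gut
#' community.
#'
#' @param n_pairs number of monozygotic twin pairs (>= 2).
#' @param n_timepoints samples per subject, 1 or 2.
#' @param n_dropped_samples samples removed to emulate incomplete sampling
#'   (taken from time point 2 first, so the baseline visit stays complete).
#' @param n_species,n_modules,n_markers_per_species table dimensions.
#' @param twin_species_correlation in [0,1]; weight of the shared pair-level
#'   latent in each subject's log-abundance profile. 0 = unrelated twins,
#'   1 = identical subject profiles up to sampling noise.
#' @param strain_twin_divergence expected fraction of barcode markers
#'   differing between co-twins, in [0,1].
#' @param strain_self_divergence same, within a subject across time points.
#' @param planted_effects list of planted microbe-phenotype effects, each a
#'   list with elements \code{variable} (a clinical column), \code{feature}
#'   (a species or module name), \code{sign} (+1/-1) and \code{size}
#'   (shift on the arcsin-sqrt scale per SD of the clinical variable).
#' @param noise_sd lognormal SD of per-sample abundance noise.
#' @param species_log_sd SD of species base log-abundances (heavy tail).
#' @param subject_log_sd SD of subject-level log-abundance deviations.
#' @param n_guilds number of co-occurrence guilds the species are split
#'   into; guild-mates share a subject-level abundance factor.
#' @param guild_sd SD of the shared guild factor.
#' @param marker_presence_prob probability a founder strain carries a marker.
#' @param depth_mean,depth_sd sequencing-depth factor converting relative
#'   abundance to marker RPK: per-sample depth = depth_mean * lognormal(depth_sd).
#' @param marker_noise_sd lognormal SD of per-marker RPK noise.
#' @param module_noise_sd lognormal SD used when deriving module abundances.
#' @param carriers_per_module species carrying each module in the generated
#'   carriage matrix.
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   cohorts.
#' @return a validated list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_pairs = 10, n_timepoints = 2,
                          n_dropped_samples = 4,
                          n_species = 50, n_modules = 30,
                          n_markers_per_species = 100,
                          twin_species_correlation = 0.5,
                          strain_twin_divergence = 0.3,
                          strain_self_divergence = 0.02,
                          planted_effects = list(),
                          noise_sd = 0.3,
                          species_log_sd = 1.5,
                          subject_log_sd = 1.0,
                          n_guilds = 5,
                          guild_sd = 0.8,
                          marker_presence_prob = 0.8,
                          depth_mean = 2000,
                          depth_sd = 0.5,
                          marker_noise_sd = 0.7,
                          module_noise_sd = 0.1,
                          carriers_per_module = 3,
                          seed = 1L) {
  assert_number(n_pairs, "n_pairs", lower = 2, integer = TRUE)
  assert_number(n_timepoints, "n_timepoints", lower = 1, upper = 2,
                integer = TRUE)
  assert_number(n_dropped_samples, "n_dropped_samples", lower = 0,
                upper = 2 * n_pairs * n_timepoints - 3 - 1e-9, integer = TRUE)
  assert_number(n_species, "n_species", lower = 2, integer = TRUE)
  assert_number(n_modules, "n_modules", lower = 1, integer = TRUE)
  assert_number(n_markers_per_species, "n_markers_per_species", lower = 1,
                integer = TRUE)
  assert_number(twin_species_correlation, "twin_species_correlation", 0, 1)
  assert_number(strain_twin_divergence, "strain_twin_divergence", 0, 1)
  assert_number(strain_self_divergence, "strain_self_divergence", 0, 1)
  assert_number(noise_sd, "noise_sd", lower = 0)
  assert_number(species_log_sd, "species_log_sd", lower = 0)
  assert_number(subject_log_sd, "subject_log_sd", lower = 0)
  assert_number(n_guilds, "n_guilds", lower = 1, integer = TRUE)
  assert_number(guild_sd, "guild_sd", lower = 0)
  assert_number(marker_presence_prob, "marker_presence_prob", 0, 1)
  assert_number(depth_mean, "depth_mean", lower = 0)
  assert_number(depth_sd, "depth_sd", lower = 0)
  assert_number(marker_noise_sd, "marker_noise_sd", lower = 0)
  assert_number(module_noise_sd, "module_noise_sd", lower = 0)
  assert_number(carriers_per_module, "carriers_per_module", lower = 1,
                upper = n_species, integer = TRUE)
  assert_number(seed, "seed", integer = TRUE)
  if (!is.list(planted_effects))
    stop_field("planted_effects", "must be a list of effect specifications")
  planted <- normalize_planted_effects(planted_effects)
  cfg <- list(n_pairs = as.integer(n_pairs),
              n_timepoints = as.integer(n_timepoints),
              n_dropped_samples = as.integer(n_dropped_samples),
              n_species = as.integer(n_species),
              n_modules = as.integer(n_modules),
              n_markers_per_species = as.integer(n_markers_per_species),
              twin_species_correlation = twin_species_correlation,
              strain_twin_divergence = strain_twin_divergence,
              strain_self_divergence = strain_self_divergence,
              planted_effects = planted,
              noise_sd = noise_sd,
              species_log_sd = species_log_sd,
              subject_log_sd = subject_log_sd,
              n_guilds = as.integer(n_guilds),
              guild_sd = guild_sd,
              marker_presence_prob = marker_presence_prob,
              depth_mean = depth_mean,
              depth_sd = depth_sd,
              marker_noise_sd = marker_noise_sd,
              module_noise_sd = module_noise_sd,
              carriers_per_module = as.integer(carriers_per_module),
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

normalize_planted_effects <- function(effects) {
  if (!length(effects))
    return(data.frame(variable = character(), feature = character(),
                      sign = numeric(), size = numeric(),
                      stringsAsFactors = FALSE))
  rows <- lapply(effects, function(e) {
    if (is.null(e$variable) || is.null(e$feature) || is.null(e$sign) ||
        is.null(e$size))
      stop_field("planted_effects",
                 "each effect needs variable, feature, sign, size")
    if (!e$variable %in% c(clinical_variables(), "age"))
      stop_field("planted_effects",
                 sprintf("unknown clinical variable '%s'", e$variable))
    if (!e$sign %in% c(-1, 1))
      stop_field("planted_effects", "sign must be +1 or -1")
    assert_number(e$size, "planted_effects$size", lower = 0)
    data.frame(variable = e$variable, feature = e$feature,
               sign = as.numeric(e$sign), size = as.numeric(e$size),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' HOMA insulin-resistance index
#'
#' Homeostasis model assessment from fasting blood insulin and fasting blood
#' sugar: \code{fbi * fbs / 405}, with insulin in uU/mL and glucose in mg/dL.
#'
#' @param fbi fasting blood insulin (uU/mL), >= 0.
#' @param fbs fasting blood sugar (mg/dL), >= 0.
#' @return the (vectorized) HOMA index.
#' @examples
#' compute_homa(10, 81)  # 2
#' @export
compute_homa <- function(fbi, fbs) {
  if (any(is.na(fbi)) || any(is.na(fbs)))
    return(ifelse(is.na(fbi) | is.na(fbs), NA_real_,
                  compute_homa(ifelse(is.na(fbi), 0, fbi),
                               ifelse(is.na(fbs), 0, fbs))))
  if (any(fbi < 0)) stop_field("fbi", "must be >= 0")
  if (any(fbs < 0)) stop_field("fbs", "must be >= 0")
  fbi * fbs / 405
}

#' Generate a strain barcode pair with a given divergence
#'
#' Draws barcode A with independent marker presence probability
#' \code{presence_prob}, then derives barcode B by flipping each marker
#' independently with probability \code{divergence}; the expected Hamming
#' distance is \code{divergence * n_markers}.
#'
#' @param n_markers number of markers (>= 1).
#' @param divergence per-marker flip probability, in [0,1].
#' @param seed optional RNG seed.
#' @param presence_prob marker presence probability for barcode A.
#' @return list with integer 0/1 vectors \code{a} and \code{b}.
#' @export
generate_strain_barcodes <- function(n_markers, divergence, seed = NULL,
                                     presence_prob = 0.5) {
  assert_number(n_markers, "n_markers", lower = 1, integer = TRUE)
  assert_number(divergence, "divergence", 0, 1)
  assert_number(presence_prob, "presence_prob", 0, 1)
  if (!is.null(seed)) set.seed(seed)
  a <- stats::rbinom(n_markers, 1L, presence_prob)
  list(a = a, b = flip_barcode(a, divergence))
}

flip_barcode <- function(barcode, divergence) {
  flips <- stats::rbinom(length(barcode), 1L, divergence)
  as.integer(xor(barcode, flips))
}

# Marginal-preserving barcode divergence: resample each marker from the
# founder presence distribution with probability divergence / (2q(1-q)),
# so the expected fraction of differing markers equals `divergence` while
# every subject keeps presence probability q. At divergence = 2q(1-q) the
# derived barcode is independent of the source, i.e. exactly
# unrelated-level; larger requested divergences saturate there.
resample_barcode <- function(barcode, divergence, presence_prob) {
  base <- 2 * presence_prob * (1 - presence_prob)
  if (base == 0 || divergence == 0) return(barcode)
  p_res <- min(1, divergence / base)
  pick <- stats::rbinom(length(barcode), 1L, p_res) == 1L
  fresh <- stats::rbinom(length(barcode), 1L, presence_prob)
  ifelse(pick, fresh, barcode)
}

#' Expected barcode divergence between unrelated strains
#'
#' Two independent founder barcodes with marker presence probability q differ
#' at a marker with probability 2q(1-q); setting
#' \code{strain_twin_divergence} to this value makes co-twins no more
#' similar at strain level than unrelated subjects.
#'
#' @param presence_prob founder marker presence probability q.
#' @return expected fraction of differing markers.
#' @export
unrelated_strain_divergence <- function(presence_prob) {
  2 * presence_prob * (1 - presence_prob)
}

#' Derive functional-module abundances from species abundances
#'
#' The pre-noise mass of module m in a sample is the carriage-weighted sum of
#' species abundances, \code{sum_s a(s) * carriage(s, m)}; multiplicative
#' lognormal noise is applied and rows are renormalized to sum to 1.
#'
#' @param species an \code{\link{abundance_table}} (samples x species).
#' @param carriage a \code{\link{carriage_matrix}} whose rows match the
#'   species columns.
#' @param noise_sd lognormal noise SD (0 = deterministic).
#' @param seed optional RNG seed.
#' @return a \code{\link{function_table}}.
#' @export
derive_module_abundances <- function(species, carriage, noise_sd = 0.1,
                                     seed = NULL) {
  if (!identical(colnames(species), rownames(carriage)))
    stop("species columns must match carriage rows", call. = FALSE)
  assert_number(noise_sd, "noise_sd", lower = 0)
  if (all(carriage == 0))
    stop("carriage matrix is all zero: no function mass to normalize",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  mass <- unclass(species) %*% unclass(carriage)
  if (noise_sd > 0)
    mass <- mass * exp(matrix(stats::rnorm(length(mass), 0, noise_sd),
                              nrow(mass)))
  rs <- rowSums(mass)
  if (any(rs <= 0))
    stop("some samples carry zero module mass; cannot renormalize",
         call. = FALSE)
  function_table(mass / rs)
}

#' Generate a complete synthetic twin cohort
#'
#' Produces species abundances, marker RPK profiles, module abundances,
#' clinical metadata and ground truth under one seed. Species log-abundances
#' combine a species baseline, a subject latent mixing a shared pair
#' component (weight \code{twin_species_correlation}) with an individual
#' component, a guild co-occurrence factor, and per-sample lognormal noise;
#' per sample the profile is renormalized to sum to 1. Strain barcodes
#' descend from a per-pair founder by marginal-preserving resampling: an
#' expected \code{strain_twin_divergence} fraction of the co-twin's markers
#' (and \code{strain_self_divergence} of the second visit's) differ from the
#' source barcode, while every subject keeps the founder marker presence
#' probability, so divergence at the unrelated level
#' (\code{\link{unrelated_strain_divergence}}) makes co-twin strains
#' statistically indistinguishable from unrelated ones. Marker RPK is the species'
#' relative abundance times a per-sample sequencing-depth factor, gated by
#' barcode presence, with per-marker lognormal noise. Planted clinical
#' effects shift the target feature on the arcsin-sqrt scale by
#' \code{sign * size} per standard deviation of the clinical variable.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return a list of class \code{synthetic_cohort} with elements
#'   \code{abundance}, \code{functions}, \code{markers}, \code{metadata},
#'   \code{carriage} and \code{truth} (planted effects, per-subject
#'   per-time-point barcodes, pair assignments). All tables share identical
#'   sample identifiers.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    config <- do.call(cohort_config, config)
  cfg <- config
  set.seed(cfg$seed)

  species <- sprintf("s__Species_%03d", seq_len(cfg$n_species))
  modules <- sprintf("M%05d", seq_len(cfg$n_modules))
  pairs <- sprintf("P%02d", seq_len(cfg$n_pairs))
  subjects <- as.vector(t(outer(pairs, c("A", "B"), paste0)))
  subj_pair <- rep(pairs, each = 2)
  names(subj_pair) <- subjects

  grid <- expand.grid(subject = subjects, timepoint = seq_len(cfg$n_timepoints),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$timepoint, match(grid$subject, subjects)), ]
  grid$sample_id <- sprintf("%s_T%d", grid$subject, grid$timepoint)
  # drop later visits first so the baseline time point stays complete
  if (cfg$n_dropped_samples > 0) {
    ord <- order(-grid$timepoint, stats::runif(nrow(grid)))
    drop_idx <- ord[seq_len(cfg$n_dropped_samples)]
    grid <- grid[-drop_idx, ]
  }
  n_samples <- nrow(grid)

  ## --- species abundances -------------------------------------------------
  mu <- stats::rnorm(cfg$n_species, 0, cfg$species_log_sd)
  guild <- rep_len(seq_len(cfg$n_guilds), cfg$n_species)
  rho <- cfg$twin_species_correlation
  pair_latent <- matrix(stats::rnorm(cfg$n_species * cfg$n_pairs),
                        cfg$n_species, dimnames = list(species, pairs))
  subj_latent <- matrix(stats::rnorm(cfg$n_species * length(subjects)),
                        cfg$n_species, dimnames = list(species, subjects))
  guild_factor <- matrix(stats::rnorm(cfg$n_guilds * length(subjects),
                                      0, cfg$guild_sd),
                         cfg$n_guilds, dimnames = list(NULL, subjects))
  loga <- matrix(0, n_samples, cfg$n_species,
                 dimnames = list(grid$sample_id, species))
  for (i in seq_len(n_samples)) {
    sj <- grid$subject[i]
    lat <- sqrt(rho) * pair_latent[, subj_pair[sj]] +
      sqrt(1 - rho) * subj_latent[, sj]
    loga[i, ] <- mu + cfg$subject_log_sd * lat + guild_factor[guild, sj] +
      stats::rnorm(cfg$n_species, 0, cfg$noise_sd)
  }
  abund <- exp(loga)
  abund <- abund / rowSums(abund)

  ## --- clinical metadata --------------------------------------------------
  meta <- make_clinical_metadata(grid, subj_pair)

  ## --- planted effects on species ----------------------------------------
  planted <- cfg$planted_effects
  sp_effects <- planted[planted$feature %in% species, , drop = FALSE]
  if (nrow(sp_effects))
    abund <- apply_planted_effects(abund, sp_effects, meta)
  abundance <- abundance_table(abund)

  ## --- carriage + module abundances ---------------------------------------
  carriage <- make_carriage(species, modules, cfg$carriers_per_module)
  functions <- derive_module_abundances(abundance, carriage,
                                        noise_sd = cfg$module_noise_sd)
  mod_effects <- planted[planted$feature %in% modules, , drop = FALSE]
  if (nrow(mod_effects))
    functions <- function_table(
      apply_planted_effects(unclass(functions), mod_effects, meta))
  unknown <- setdiff(planted$feature, c(species, modules))
  if (length(unknown))
    stop_field("planted_effects",
               sprintf("unknown feature '%s'", unknown[1]))

  ## --- strain barcodes and marker RPK -------------------------------------
  nm <- cfg$n_markers_per_species
  barcodes <- vector("list", cfg$n_species)
  names(barcodes) <- species
  for (sp in species) {
    bc <- array(0L, dim = c(length(subjects), nm, cfg$n_timepoints),
                dimnames = list(subjects, sprintf("%s_m%03d", sp, seq_len(nm)),
                                paste0("T", seq_len(cfg$n_timepoints))))
    for (p in pairs) {
      founder <- stats::rbinom(nm, 1L, cfg$marker_presence_prob)
      twinA <- founder
      twinB <- resample_barcode(founder, cfg$strain_twin_divergence,
                                cfg$marker_presence_prob)
      bc[paste0(p, "A"), , 1] <- twinA
      bc[paste0(p, "B"), , 1] <- twinB
      if (cfg$n_timepoints == 2) {
        bc[paste0(p, "A"), , 2] <- resample_barcode(
          twinA, cfg$strain_self_divergence, cfg$marker_presence_prob)
        bc[paste0(p, "B"), , 2] <- resample_barcode(
          twinB, cfg$strain_self_divergence, cfg$marker_presence_prob)
      }
    }
    barcodes[[sp]] <- bc
  }
  depth <- cfg$depth_mean * exp(stats::rnorm(n_samples, 0, cfg$depth_sd))
  names(depth) <- grid$sample_id
  markers <- lapply(species, function(sp) {
    m <- matrix(0, n_samples, nm,
                dimnames = list(grid$sample_id, dimnames(barcodes[[sp]])[[2]]))
    for (i in seq_len(n_samples)) {
      pres <- barcodes[[sp]][grid$subject[i], , grid$timepoint[i]]
      noise <- exp(stats::rnorm(nm, 0, cfg$marker_noise_sd))
      m[i, ] <- pres * abundance[grid$sample_id[i], sp] * depth[i] * noise
    }
    m
  })
  names(markers) <- species

  truth <- list(planted_effects = planted, barcodes = barcodes,
                pairs = subj_pair, depth = depth,
                guilds = stats::setNames(guild, species))
  structure(list(abundance = abundance, functions = functions,
                 markers = marker_profile_set(markers),
                 metadata = meta, carriage = carriage, truth = truth,
                 config = cfg),
            class = "synthetic_cohort")
}

make_clinical_metadata <- function(grid, subj_pair) {
  pairs <- unique(unname(subj_pair))
  subjects <- names(subj_pair)
  pair_age <- round(stats::runif(length(pairs), 30, 48))
  pair_sex <- sample(c("F", "M"), length(pairs), replace = TRUE)
  pair_smoking <- sample(c("never", "former", "current"), length(pairs),
                         replace = TRUE, prob = c(0.6, 0.2, 0.2))
  names(pair_age) <- names(pair_sex) <- names(pair_smoking) <- pairs
  # subject-level baselines within plausible healthy-to-subclinical ranges,
  # with small visit-to-visit drift
  base <- list(
    bmi = pmin(pmax(stats::rnorm(length(subjects), 23, 2.5), 18), 28),
    fbs = pmax(stats::rnorm(length(subjects), 92, 9), 65),
    fbi = pmax(stats::rnorm(length(subjects), 8, 3), 1),
    systolic_bp = pmax(stats::rnorm(length(subjects), 115, 11), 90),
    diastolic_bp = pmax(stats::rnorm(length(subjects), 74, 8), 55),
    triglycerides = pmax(stats::rnorm(length(subjects), 110, 45), 35),
    hscrp = stats::rlnorm(length(subjects), log(0.8), 0.8)
  )
  base <- lapply(base, function(v) { names(v) <- subjects; v })
  drift <- function(b, sd) pmax(b + stats::rnorm(length(b), 0, sd), 0.1)
  df <- data.frame(
    sample_id = grid$sample_id,
    subject_id = grid$subject,
    pair_id = unname(subj_pair[grid$subject]),
    timepoint = grid$timepoint,
    age = unname(pair_age[subj_pair[grid$subject]]),
    sex = unname(pair_sex[subj_pair[grid$subject]]),
    smoking = unname(pair_smoking[subj_pair[grid$subject]]),
    bmi = drift(base$bmi[grid$subject], 0.5),
    fbs = drift(base$fbs[grid$subject], 3),
    fbi = drift(base$fbi[grid$subject], 1),
    systolic_bp = drift(base$systolic_bp[grid$subject], 4),
    diastolic_bp = drift(base$diastolic_bp[grid$subject], 3),
    triglycerides = drift(base$triglycerides[grid$subject], 12),
    hscrp = pmax(base$hscrp[grid$subject] *
                   exp(stats::rnorm(nrow(grid), 0, 0.2)), 0.01),
    stringsAsFactors = FALSE
  )
  df$homa <- compute_homa(df$fbi, df$fbs)
  metadata_table(df)
}

make_carriage <- function(species, modules, carriers_per_module) {
  m <- matrix(0, length(species), length(modules),
              dimnames = list(species, modules))
  for (j in seq_along(modules)) {
    carriers <- sample(length(species), carriers_per_module)
    m[carriers, j] <- stats::runif(carriers_per_module, 0.6, 1)
  }
  carriage_matrix(m)
}

apply_planted_effects <- function(mat, effects, meta) {
  for (k in seq_len(nrow(effects))) {
    var <- meta[[effects$variable[k]]]
    z <- (var - mean(var, na.rm = TRUE)) / stats::sd(var, na.rm = TRUE)
    z[is.na(z)] <- 0
    y <- asin(sqrt(pmin(mat[, effects$feature[k]], 1)))
    y <- pmin(pmax(y + effects$sign[k] * effects$size[k] * z, 0), pi / 2)
    mat[, effects$feature[k]] <- sin(y)^2
  }
  mat / rowSums(mat)
}

#' Write a synthetic cohort to a directory of standard tables
#'
#' Writes \code{abundance.tsv}, \code{modules.tsv},
#' \code{markers/<species>.tsv}, \code{metadata.tsv}, \code{carriage.tsv}
#' and \code{truth.json} in the tab-delimited formats the readers consume.
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param dir output directory (created if absent).
#' @return invisibly, \code{dir}.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_table(cohort$abundance, file.path(dir, "abundance.tsv"))
  write_table(cohort$functions, file.path(dir, "modules.tsv"))
  write_table(cohort$markers, file.path(dir, "markers"))
  write_table(cohort$metadata, file.path(dir, "metadata.tsv"))
  write_table(cohort$carriage, file.path(dir, "carriage.tsv"))
  truth <- list(
    planted_effects = cohort$truth$planted_effects,
    pairs = as.list(cohort$truth$pairs),
    barcodes_t1 = lapply(cohort$truth$barcodes, function(b)
      apply(b[, , 1, drop = FALSE], 1, paste0, collapse = ""))
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
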