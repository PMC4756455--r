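test_that("cohort has the configured sample count and consistent identifiers", {
  co <- generate_cohort(cohort_config(n_pairs = 10, n_timepoints = 2,
                                      n_dropped_samples = 4, seed = 7))
  expect_equal(nrow(co$abundance), 36)
  ids <- sort(rownames(co$abundance))
  expect_identical(sort(rownames(co$functions)), ids)
  expect_identical(sort(co$metadata$sample_id), ids)
  expect_identical(sort(rownames(co$markers[[1]])), ids)
  expect_equal(length(unique(co$metadata$subject_id)), 20)
})

test_that("species relative abundances sum to one for varied configs", {
  for (s in 1:5) {
    co <- generate_cohort(tiny_config(seed = s, noise_sd = runif(1, 0, 1),
                                      twin_species_correlation = runif(1)))
    expect_true(all(abs(rowSums(co$abundance) - 1) < 1e-6))
    expect_true(all(co$abundance >= 0))
  }
})

test_that("generation is deterministic given the seed", {
  cfg <- tiny_config(seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$abundance, b$abundance)
  expect_identical(a$markers, b$markers)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth$barcodes, b$truth$barcodes)
  c2 <- generate_cohort(tiny_config(seed = 12))
  expect_false(identical(a$abundance, c2$abundance))
})

test_that("invalid config fields are rejected with the field named", {
  expect_error(cohort_config(n_pairs = 1), "n_pairs")
  expect_error(cohort_config(n_timepoints = 3), "n_timepoints")
  expect_error(cohort_config(strain_twin_divergence = 1.2),
               "strain_twin_divergence")
  expect_error(cohort_config(twin_species_correlation = -0.1),
               "twin_species_correlation")
  # dropped-sample bound: must leave at least 4 samples
  expect_error(cohort_config(n_pairs = 2, n_timepoints = 1,
                             n_dropped_samples = 1), "n_dropped_samples")
  expect_error(
    generate_cohort(tiny_config(planted_effects = list(
      list(variable = "nonesuch", feature = "s__Species_001",
           sign = 1, size = 0.5)))),
    "planted_effects")
})

test_that("empty planted effects give an empty ground-truth effect list", {
  co <- generate_cohort(tiny_config(seed = 2))
  expect_equal(nrow(co$truth$planted_effects), 0)
})

test_that("twin log-abundance correlation increases with the mixing weight", {
  mean_twin_cor <- function(rho, seed) {
    co <- generate_cohort(cohort_config(
      n_pairs = 10, n_timepoints = 1, n_dropped_samples = 0, n_species = 40,
      twin_species_correlation = rho, guild_sd = 0, noise_sd = 0.2,
      seed = seed))
    md <- co$metadata
    cors <- sapply(unique(md$pair_id), function(p) {
      ids <- md$sample_id[md$pair_id == p]
      cor(log(co$abundance[ids[1], ] + 1e-9), log(co$abundance[ids[2], ] + 1e-9))
    })
    mean(cors)
  }
  lo <- sapply(1:5, function(s) mean_twin_cor(0.1, s))
  hi <- sapply(1:5, function(s) mean_twin_cor(0.9, s))
  expect_true(all(hi > lo))
})

test_that("twin pairs are compositionally closer than unrelated pairs when correlated", {
  # rank-sum direction over many seeds
  direction <- sapply(1:50, function(s) {
    co <- generate_cohort(tiny_config(seed = s, twin_species_correlation = 0.6,
                                      n_pairs = 8, n_species = 30))
    dm <- distance_matrix(co$abundance)
    pv <- pair_values(enumerate_pairs(co$metadata), dm = dm)
    w <- wilcox.test(pv$value[pv$pair_type == "twin"],
                     pv$value[pv$pair_type == "unrelated"],
                     alternative = "less", exact = FALSE)
    w$statistic / (sum(pv$pair_type == "twin") *
                     sum(pv$pair_type == "unrelated")) < 0.5
  })
  expect_gte(mean(direction), 0.9)
})

test_that("marker RPK is zero exactly where the subject's barcode is absent", {
  co <- generate_cohort(tiny_config(seed = 3))
  md <- co$metadata
  for (sp in names(co$markers)[1:3]) {
    m <- co$markers[[sp]]
    for (i in seq_len(nrow(md))) {
      bc <- co$truth$barcodes[[sp]][md$subject_id[i], , md$timepoint[i]]
      expect_identical(unname(m[md$sample_id[i], ] == 0), unname(bc == 0L))
    }
  }
})

test_that("zero self-divergence keeps within-subject presence patterns identical", {
  co <- generate_cohort(tiny_config(seed = 4, strain_self_divergence = 0))
  md <- co$metadata
  both <- names(which(table(md$subject_id) == 2))
  for (sp in names(co$markers)[1:3]) {
    m <- co$markers[[sp]]
    for (sj in both) {
      ids <- md$sample_id[md$subject_id == sj]
      expect_identical(m[ids[1], ] > 0, m[ids[2], ] > 0)
    }
  }
})

test_that("barcode pair generation matches its flip model", {
  bc <- generate_strain_barcodes(100, 0, seed = 1)
  expect_identical(bc$a, bc$b)
  bc <- generate_strain_barcodes(100, 1, seed = 1)
  expect_equal(sum(bc$a != bc$b), 100)
  # Monte-Carlo mean Hamming distance vs Binomial(1000, 0.2)
  d <- sapply(1:100, function(s)
    with(generate_strain_barcodes(1000, 0.2, seed = s), sum(a != b)))
  se <- sqrt(1000 * 0.2 * 0.8)
  expect_lt(abs(mean(d) - 200), 3 * se / sqrt(100))
  expect_error(generate_strain_barcodes(100, 1.5), "divergence")
})

test_that("module abundances follow the carriage-weighted sum before noise", {
  ab <- abundance_table(matrix(c(0.5, 0.5), 1, 2,
                               dimnames = list("s1", c("s__A", "s__B"))))
  # module M1 carried only by the first species, M2 by both
  carr <- carriage_matrix(matrix(c(1, 0, 1, 1), 2, 2,
                                 dimnames = list(c("s__A", "s__B"),
                                                 c("M1", "M2"))))
  ft <- derive_module_abundances(ab, carr, noise_sd = 0)
  # un-normalized masses 0.5 and 1.0 -> proportions 1/3, 2/3
  expect_equal(unname(ft["s1", ]), c(0.5, 1.0) / 1.5)
  # single species carrying a single module fully
  ab1 <- abundance_table(matrix(1, 1, 1, dimnames = list("s1", "s__A")))
  c1 <- carriage_matrix(matrix(1, 1, 1, dimnames = list("s__A", "M1")))
  expect_equal(unname(derive_module_abundances(ab1, c1, noise_sd = 0)[1, 1]), 1)
  # determinism with a seed, and the all-zero carriage error
  f1 <- derive_module_abundances(ab, carr, noise_sd = 0.2, seed = 9)
  f2 <- derive_module_abundances(ab, carr, noise_sd = 0.2, seed = 9)
  expect_identical(f1, f2)
  c0 <- carriage_matrix(matrix(0, 2, 2, dimnames = dimnames(carr)))
  expect_error(derive_module_abundances(ab, c0), "all zero")
})

test_that("HOMA follows the insulin*glucose/405 formula", {
  expect_equal(compute_homa(10, 81), 2)
  expect_equal(compute_homa(0, 123), 0)
  expect_error(compute_homa(-1, 90), "fbi")
  expect_equal(compute_homa(c(10, NA), c(81, 90)), c(2, NA))
})

test_that("metadata respects twin sharing and plausible clinical ranges", {
  co <- generate_cohort(cohort_config(seed = 5))
  md <- co$metadata
  for (p in unique(md$pair_id)) {
    sub <- md[md$pair_id == p, ]
    expect_equal(length(unique(sub$age)), 1)
    expect_equal(length(unique(as.character(sub$sex))), 1)
  }
  num_cols <- intersect(clinical_variables(), names(md))
  for (cl in num_cols) expect_true(all(md[[cl]] > 0))
  expect_true(all(md$age >= 30 & md$age <= 48))
  expect_equal(md$homa, compute_homa(md$fbi, md$fbs))
})
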