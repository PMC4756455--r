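test_that("RPK and coverage conversions follow their formulas", {
  expect_equal(marker_rpk(50, 2000), 25)
  expect_equal(marker_rpk(0, 500), 0)
  expect_error(marker_rpk(10, 0), "marker_length")
  expect_error(marker_rpk(-1, 100), "read_count")
  expect_equal(rpk_to_coverage(10, 100), 1)
  expect_equal(rpk_to_coverage(0, 100), 0)
  expect_equal(rpk_to_coverage(20, 100), 2)
  expect_error(rpk_to_coverage(5, 0), "read_length")
  # composition simplifies to reads * read_length / marker_length
  set.seed(6)
  for (i in 1:20) {
    reads <- rpois(1, 100); len <- sample(200:3000, 1); rl <- sample(50:300, 1)
    expect_equal(rpk_to_coverage(marker_rpk(reads, len), rl),
                 reads * rl / len)
  }
})

make_mps <- function(mats) marker_profile_set(mats)

test_that("median-RPK eligibility is strict and monotone", {
  m <- rbind(S1 = c(6, 6, 6), S2 = c(6, 6, 6), S3 = c(5, 5, 5),
             S4 = c(0, 0, 0))
  colnames(m) <- paste0("m", 1:3)
  mps <- make_mps(list(s__X = m))
  prs <- data.frame(sample_a = c("S1", "S1", "S1"),
                    sample_b = c("S2", "S3", "S4"),
                    pair_type = c("twin", "twin", "self"),
                    stringsAsFactors = FALSE)
  class(prs) <- c("pair_set", "data.frame")
  el <- eligible_comparisons(mps, prs, min_median_rpk = 5)
  # only the (6,6) pair passes: median 5 and all-zero samples are excluded
  expect_equal(nrow(el), 1)
  expect_equal(el$sample_b, "S2")
  # raising the threshold never adds comparisons
  for (thr in c(0, 2, 5, 6, 10)) {
    lo <- nrow(eligible_comparisons(mps, prs, min_median_rpk = thr))
    hi <- nrow(eligible_comparisons(mps, prs, min_median_rpk = thr + 1))
    expect_lte(hi, lo)
  }
  # median over ALL markers including zeros
  mz <- rbind(S1 = c(100, 100, 0, 0), S2 = c(100, 100, 100, 100))
  colnames(mz) <- paste0("m", 1:4)
  mps2 <- make_mps(list(s__Y = mz))
  prs2 <- prs[1, ]; prs2$sample_b <- "S2"
  # S1 median = 50 > 5 so still eligible; but with threshold 60 it is not
  expect_equal(nrow(eligible_comparisons(mps2, prs2, 60)), 0)
})

test_that("strain distances follow Bray-Curtis on relative marker profiles", {
  m <- rbind(S1 = c(10, 0, 5), S2 = c(0, 10, 5), S3 = c(10, 0, 5),
             S4 = c(0, 20, 0))
  colnames(m) <- paste0("m", 1:3)
  mps <- make_mps(list(s__X = m))
  expect_equal(strain_distance(mps, "s__X", "S1", "S2"), 2 / 3)
  expect_equal(strain_distance(mps, "s__X", "S1", "S3"), 0)
  expect_equal(strain_distance(mps, "s__X", "S1", "S4"), 1)  # disjoint
  expect_equal(strain_distance(mps, "s__X", "S1", "S2"),
               strain_distance(mps, "s__X", "S2", "S1"))
  expect_error(strain_distance(mps, "s__Z", "S1", "S2"), "unknown species")
  set.seed(11)
  for (i in 1:50) {
    a <- runif(6) * rbinom(6, 1, 0.8); b <- runif(6) * rbinom(6, 1, 0.8)
    if (sum(a) == 0 || sum(b) == 0) next
    mm <- rbind(A = a, B = b); colnames(mm) <- paste0("m", 1:6)
    d <- strain_distance(make_mps(list(s__R = mm)), "s__R", "A", "B")
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, bc_oracle(a / sum(a), b / sum(b)), tolerance = 1e-12)
  }
})

test_that("barcodes bin abundance into four levels with strict presence", {
  rpk <- c(m1 = 0, m2 = 0.5, m3 = 1, m4 = 5, m5 = 10, m6 = 50)
  bc <- make_barcode(rpk)
  expect_identical(as.character(bc$level),
                   c("absent", "low", "low", "mid", "mid", "high"))
  expect_identical(bc$present, bc$level != "absent")
  expect_error(make_barcode(rpk, level_bounds = c(10, 1)), "level_bounds")
})

test_that("barcode differences mark one-sided presence", {
  a <- make_barcode(c(m1 = 5, m2 = 0, m3 = 2))
  b <- make_barcode(c(m1 = 5, m2 = 3, m3 = 0))
  d <- barcode_diff(a, b)
  expect_identical(d$discordant, c(FALSE, TRUE, TRUE))
  expect_identical(barcode_diff(a, a)$discordant, rep(FALSE, 3))
  comp <- make_barcode(c(m1 = 0, m2 = 4, m3 = 0))
  expect_equal(sum(barcode_diff(a, comp)$discordant), 3)
  b2 <- make_barcode(c(x1 = 5, x2 = 3, x3 = 0))
  expect_error(barcode_diff(a, b2), "different marker sets")
})

test_that("pooled strain group tests separate twin from self when they differ", {
  ps <- sapply(1:10, function(s) {
    co <- generate_cohort(tiny_config(seed = s, strain_twin_divergence = 0.3,
                                      strain_self_divergence = 0,
                                      n_pairs = 6, n_dropped_samples = 0))
    prs <- enumerate_pairs(co$metadata)
    sc <- strain_comparisons(co$markers,
                             eligible_comparisons(co$markers, prs))
    compare_strain_groups(sc)$p[2]
  })
  expect_gte(mean(ps < 0.01), 0.9)
})

test_that("per-species divergence summaries match a brute-force grouping", {
  cmp <- data.frame(
    species = c("s__A", "s__A", "s__A", "s__B"),
    sample_a = "x", sample_b = "y",
    pair_type = c("twin", "twin", "self", "twin"),
    distance = c(0.2, 0.4, 0.1, 0.5), stringsAsFactors = FALSE)
  sm <- species_mean_divergence(cmp)
  expect_equal(sm$mean_distance[sm$species == "s__A" &
                                  sm$pair_type == "twin"], 0.3)
  expect_equal(sm$n_comparisons[sm$species == "s__A" &
                                  sm$pair_type == "twin"], 2L)
  expect_equal(sm$mean_distance[sm$species == "s__B"], 0.5)
  set.seed(13)
  big <- data.frame(
    species = sample(c("s__A", "s__B", "s__C"), 60, TRUE),
    sample_a = "x", sample_b = "y",
    pair_type = sample(c("twin", "self", "unrelated"), 60, TRUE),
    distance = runif(60), stringsAsFactors = FALSE)
  sm2 <- species_mean_divergence(big)
  for (i in seq_len(nrow(sm2))) {
    sel <- big$species == sm2$species[i] & big$pair_type == sm2$pair_type[i]
    expect_equal(sm2$mean_distance[i], mean(big$distance[sel]))
    expect_equal(sm2$n_comparisons[i], sum(sel))
  }
})

test_that("self strain distances sit below twin distances when divergence says so", {
  direction <- sapply(1:50, function(s) {
    co <- generate_cohort(tiny_config(seed = s, strain_twin_divergence = 0.3,
                                      strain_self_divergence = 0.02))
    prs <- enumerate_pairs(co$metadata)
    sc <- strain_comparisons(co$markers,
                             eligible_comparisons(co$markers, prs))
    if (!all(c("twin", "self") %in% sc$pair_type)) return(NA)
    w <- suppressWarnings(wilcox.test(sc$distance[sc$pair_type == "self"],
                                      sc$distance[sc$pair_type == "twin"],
                                      alternative = "less", exact = FALSE))
    w$p.value < 0.5
  })
  expect_gte(mean(direction, na.rm = TRUE), 0.9)
})
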