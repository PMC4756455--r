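test_that("tie-corrected Spearman matches the rank-then-Pearson oracle", {
  sp <- spearman_cor(c(1, 2, 2, 4), c(1, 3, 2, 4))
  or <- spearman_oracle(c(1, 2, 2, 4), c(1, 3, 2, 4))
  expect_equal(sp$rho, or$rho, tolerance = 1e-14)
  expect_equal(sp$p, or$p, tolerance = 1e-12)
  x <- 1:8
  expect_equal(spearman_cor(x, exp(x))$rho, 1)
  expect_equal(spearman_cor(x, -x^3)$rho, -1)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:3, 1:3), "n >= 4")
  set.seed(17)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    x <- sample(1:10, n, TRUE); y <- sample(1:10, n, TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    sp <- spearman_cor(x, y); or <- spearman_oracle(x, y)
    expect_equal(sp$rho, or$rho, tolerance = 1e-13)
    expect_equal(sp$p, or$p, tolerance = 1e-12)
  }
})

test_that("the correlation matrix covers every taxon-module cell", {
  set.seed(23)
  n <- 20
  taxa <- matrix(runif(n * 5, 0, 0.1), n, 5,
                 dimnames = list(paste0("S", 1:n), paste0("s__t", 1:5)))
  mods <- matrix(runif(n * 4, 0, 0.1), n, 4,
                 dimnames = list(paste0("S", 1:n), paste0("M0000", 1:4)))
  recs <- correlation_matrix(abundance_table(taxa), function_table(mods))
  expect_equal(nrow(recs), 20)
  # each cell matches the scalar operation
  for (i in seq_len(nrow(recs))) {
    sp <- spearman_cor(taxa[, recs$taxon[i]], mods[, recs$module[i]])
    expect_equal(recs$rho[i], sp$rho, tolerance = 1e-12)
    expect_equal(recs$p[i], sp$p, tolerance = 1e-12)
  }
  expect_equal(recs$q[!is.na(recs$p)], fdr_bh(recs$p[!is.na(recs$p)]))
  # self-correlation layout: diagonal cells have rho 1
  self <- correlation_matrix(abundance_table(taxa),
                             function_table(taxa))
  diag_recs <- self[self$taxon == self$module, ]
  expect_true(all(abs(diag_recs$rho - 1) < 1e-12))
  # invariant to sample order
  perm <- sample(n)
  recs2 <- correlation_matrix(abundance_table(taxa[perm, ]),
                              function_table(mods))
  expect_equal(recs$rho, recs2$rho, tolerance = 1e-12)
})

test_that("co-occurrence networks find planted covariation and bound false edges", {
  set.seed(29)
  n <- 100
  base <- runif(n, 0, 0.05)
  taxa <- cbind(s__a = base + rnorm(n, 0, 0.001),
                s__b = base * 1.2 + rnorm(n, 0, 0.001),
                matrix(runif(n * 6, 0, 0.05), n,
                       dimnames = list(NULL, paste0("s__n", 1:6))))
  taxa <- pmax(taxa, 0)
  rownames(taxa) <- paste0("S", 1:n)
  net <- cooccurrence_network(abundance_table(taxa))
  has_edge <- any((net$edges$taxon_a == "s__a" & net$edges$taxon_b == "s__b") |
                    (net$edges$taxon_a == "s__b" & net$edges$taxon_b == "s__a"))
  expect_true(has_edge)
  expect_true(all(net$edges$taxon_a != net$edges$taxon_b))
  expect_equal(unname(diag(net$rho)), rep(1, 8))
  expect_error(cooccurrence_network(abundance_table(taxa[, 1:2])), ">= 3")
  # false-edge rate among independent taxa stays near the q threshold
  frac <- sapply(1:50, function(s) {
    set.seed(s + 1000)
    tx <- matrix(runif(100 * 8, 0, 0.05), 100,
                 dimnames = list(paste0("S", 1:100), paste0("s__i", 1:8)))
    nrow(cooccurrence_network(abundance_table(tx))$edges) / choose(8, 2)
  })
  expect_lte(mean(frac), 0.2 + 0.1)
})

test_that("classification follows the encoded/associated/unexplained rules", {
  recs <- data.frame(
    taxon = c("s__carrier", "s__friend", "s__loner", "s__neg", "s__weak"),
    module = "M1",
    rho = c(0.9, 0.8, 0.7, -0.8, 0.1),
    p = c(1e-6, 1e-5, 1e-4, 1e-5, 0.5),
    q = c(1e-5, 1e-4, 1e-3, 1e-4, 0.6),
    tier = c("fdr", "fdr", "fdr", "fdr", "none"),
    stringsAsFactors = FALSE)
  carr <- carriage_matrix(matrix(c(1, 0, 0, 0, 0), 5, 1,
                                 dimnames = list(recs$taxon, "M1")))
  net <- structure(list(
    rho = matrix(0.9, 5, 5, dimnames = list(recs$taxon, recs$taxon)),
    edges = data.frame(taxon_a = "s__carrier", taxon_b = "s__friend",
                       rho = 0.9, q = 1e-4, stringsAsFactors = FALSE)),
    class = "cooccurrence_network")
  out <- classify_correlations(recs, carr, net)
  cls <- setNames(out$class, out$taxon)
  expect_equal(unname(cls["s__carrier"]), "encoded")
  expect_equal(unname(cls["s__friend"]), "associated")
  expect_equal(unname(cls["s__loner"]), "unexplained")
  expect_equal(unname(cls["s__neg"]), "not-classified")
  expect_equal(unname(cls["s__weak"]), "not-classified")
  # classes are exhaustive and mutually exclusive over significant positives
  sigpos <- out$tier != "none" & out$rho > 0
  expect_true(all(out$class[sigpos] %in%
                    c("encoded", "associated", "unexplained")))
  expect_true(all(out$class[!sigpos] == "not-classified"))
  # raising the threshold never increases the encoded count
  n_enc <- sapply(c(0, 0.25, 0.5, 0.75, 1), function(th)
    sum(classify_correlations(recs, carr, net,
                              encoded_threshold = th)$class == "encoded"))
  expect_true(all(diff(n_enc) <= 0))
})

test_that("missing carriage cells are treated as zero with a warning", {
  recs <- data.frame(taxon = "s__x", module = "M9", rho = 0.9, p = 1e-5,
                     q = 1e-4, tier = "fdr", stringsAsFactors = FALSE)
  carr <- carriage_matrix(matrix(1, 1, 1, dimnames = list("s__y", "M1")))
  net <- structure(list(rho = matrix(1, 1, 1,
                                     dimnames = list("s__x", "s__x")),
                        edges = data.frame(taxon_a = character(),
                                           taxon_b = character())),
                   class = "cooccurrence_network")
  expect_warning(out <- classify_correlations(recs, carr, net), "missing")
  expect_equal(out$carriage, 0)
  expect_equal(out$class, "unexplained")
})

test_that("cross-cohort overlap intersects by identifiers and sign", {
  r1 <- data.frame(taxon = c("s__a", "s__b", "s__c"),
                   module = c("M1", "M2", "M3"),
                   rho = c(0.8, 0.7, -0.6), p = 1e-5, q = 1e-4,
                   tier = "fdr", stringsAsFactors = FALSE)
  full <- cross_cohort_overlap(r1, r1, tier = "fdr")
  expect_equal(nrow(full), 3)
  r2 <- r1; r2$rho[1] <- -0.5  # sign flip excluded
  expect_equal(nrow(cross_cohort_overlap(r1, r2, tier = "fdr")), 2)
  r3 <- r1; r3$taxon <- paste0(r3$taxon, "_other")
  expect_equal(nrow(cross_cohort_overlap(r1, r3, tier = "fdr")), 0)
  r4 <- r1; r4$tier <- c("nominal", "none", "fdr")
  expect_equal(nrow(cross_cohort_overlap(r1, r4, tier = "fdr")), 1)
  expect_equal(nrow(cross_cohort_overlap(r1, r4, tier = "nominal")), 2)
})
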