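# Taxon-function correlation analysis: tie-corrected Spearman correlation of
# every species profile against every functional-module profile, BH FDR over
# the whole matrix, significance tiers (nominal p < 0.01, FDR q < 0.2), a
# taxon co-occurrence network, and classification of significant positive
# correlations as genomically 'encoded', co-occurrence 'associated', or
# 'unexplained' against a genome-carriage matrix.

#' Tie-corrected Spearman correlation with t-approximation p-value
#'
#' Average-rank Spearman rho (Pearson correlation of mid-ranks) with the
#' two-sided p-value from the t approximation
#' \code{t = rho * sqrt((n - 2) / (1 - rho^2))} on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length n >= 4, neither constant.
#' @return list with \code{rho} and \code{p}.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y))
    stop("vectors must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 4) stop("need n >= 4 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: Spearman correlation undefined", call. = FALSE)
  rho <- stats::cor(rank(x), rank(y), method = "pearson")
  if (abs(rho) >= 1) return(list(rho = sign(rho), p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Taxon-by-module Spearman correlation records
#'
#' Correlates every taxon profile against every module profile over the
#' shared samples, applies BH FDR across the full taxon-by-module matrix as
#' one family, and assigns significance tiers: \code{fdr} when q < 0.2,
#' otherwise \code{nominal} when p < 0.01, otherwise \code{none}. Constant
#' profiles yield NA correlations (flagged, never significant).
#'
#' @param taxa an \code{\link{abundance_table}}.
#' @param modules a \code{\link{function_table}}.
#' @param p_nominal,q_fdr tier thresholds (defaults 0.01 and 0.2).
#' @return data frame with columns \code{taxon}, \code{module}, \code{rho},
#'   \code{p}, \code{q}, \code{tier}; one row per taxon-module cell.
#' @export
correlation_matrix <- function(taxa, modules, p_nominal = 0.01, q_fdr = 0.2) {
  shared <- intersect(rownames(taxa), rownames(modules))
  if (length(shared) < 4)
    stop("need >= 4 shared samples", call. = FALSE)
  tx <- as.matrix(taxa)[shared, , drop = FALSE]
  md <- as.matrix(modules)[shared, , drop = FALSE]
  # rank once per profile; constant profiles flagged NA
  grid <- expand.grid(taxon = colnames(tx), module = colnames(md),
                      stringsAsFactors = FALSE)
  rho <- p <- rep(NA_real_, nrow(grid))
  const_t <- apply(tx, 2, stats::sd) == 0
  const_m <- apply(md, 2, stats::sd) == 0
  rtx <- apply(tx, 2, rank)
  rmd <- apply(md, 2, rank)
  cmat <- suppressWarnings(stats::cor(rtx, rmd))
  n <- length(shared)
  for (i in seq_len(nrow(grid))) {
    if (const_t[grid$taxon[i]] || const_m[grid$module[i]]) next
    r <- cmat[grid$taxon[i], grid$module[i]]
    rho[i] <- r
    p[i] <- if (abs(r) >= 1) 0 else
      2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2)
  }
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- fdr_bh(p[!is.na(p)])
  tier <- rep("none", nrow(grid))
  tier[!is.na(p) & p < p_nominal] <- "nominal"
  tier[!is.na(q) & q < q_fdr] <- "fdr"
  data.frame(grid, rho = rho, p = p, q = q, tier = tier,
             stringsAsFactors = FALSE)
}

#' Taxon co-occurrence network by Spearman correlation
#'
#' Correlates all taxon pairs, BH-adjusts over the distinct off-diagonal
#' pairs (a separate family from the taxon-module matrix), and keeps
#' significant positive edges (rho > 0, q < \code{q_threshold}).
#'
#' @param taxa an \code{\link{abundance_table}} with >= 3 taxa.
#' @param q_threshold edge significance cutoff (default 0.2).
#' @return list of class \code{cooccurrence_network} with the symmetric
#'   \code{rho}, \code{p}, \code{q} matrices and the \code{edges} data frame
#'   of significant positive pairs.
#' @export
cooccurrence_network <- function(taxa, q_threshold = 0.2) {
  tx <- as.matrix(taxa)
  if (ncol(tx) < 3) stop("need >= 3 taxa", call. = FALSE)
  nt <- ncol(tx)
  n <- nrow(tx)
  rtx <- apply(tx, 2, rank)
  rho <- suppressWarnings(stats::cor(rtx))
  diag(rho) <- 1
  p <- matrix(NA_real_, nt, nt, dimnames = dimnames(rho))
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    r <- rho[idx[k, 1], idx[k, 2]]
    if (is.na(r)) next
    p[idx[k, 1], idx[k, 2]] <- if (abs(r) >= 1) 0 else
      2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2)
  }
  pv <- p[upper.tri(p)]
  qv <- rep(NA_real_, length(pv))
  qv[!is.na(pv)] <- fdr_bh(pv[!is.na(pv)])
  q <- matrix(NA_real_, nt, nt, dimnames = dimnames(rho))
  q[upper.tri(q)] <- qv
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  sig <- which(upper.tri(rho) & rho > 0 & !is.na(q) & q < q_threshold,
               arr.ind = TRUE)
  edges <- data.frame(taxon_a = colnames(tx)[sig[, 1]],
                      taxon_b = colnames(tx)[sig[, 2]],
                      rho = rho[sig], q = q[sig],
                      stringsAsFactors = FALSE)
  structure(list(rho = rho, p = p, q = q, edges = edges,
                 q_threshold = q_threshold),
            class = "cooccurrence_network")
}

network_neighbors <- function(network, taxon) {
  e <- network$edges
  c(e$taxon_b[e$taxon_a == taxon], e$taxon_a[e$taxon_b == taxon])
}

#' Classify significant positive taxon-module correlations
#'
#' A significant positive correlation (tier nominal or fdr, rho > 0) is
#' \emph{encoded} when the taxon's reference genomes carry the module at a
#' fraction >= \code{encoded_threshold}; otherwise \emph{associated} when
#' the taxon has a significant-positive co-occurrence edge to at least one
#' taxon whose own record for that module is encoded; otherwise
#' \emph{unexplained}. Negative or non-significant records are
#' \code{not-classified}; for significant negative records the
#' anti-correlated carriers are listed as an annotation rather than a class.
#' Taxon-module cells missing from the carriage matrix are treated as
#' carriage 0 with a warning.
#'
#' @param records data frame from \code{\link{correlation_matrix}}.
#' @param carriage a \code{\link{carriage_matrix}}.
#' @param network a \code{\link{cooccurrence_network}} over the same taxa.
#' @param encoded_threshold carriage fraction required to call a
#'   correlation encoded (default 0.5).
#' @return the records with added columns \code{carriage}, \code{class}.
#' @export
classify_correlations <- function(records, carriage, network,
                                  encoded_threshold = 0.5) {
  assert_number(encoded_threshold, "encoded_threshold", 0, 1)
  cm <- as.matrix(carriage)
  get_carriage <- function(taxon, module) {
    if (taxon %in% rownames(cm) && module %in% colnames(cm))
      cm[taxon, module] else NA_real_
  }
  records$carriage <- mapply(get_carriage, records$taxon, records$module)
  if (anyNA(records$carriage)) {
    warning("carriage matrix missing ", sum(is.na(records$carriage)),
            " taxon-module cell(s); treated as 0")
    records$carriage[is.na(records$carriage)] <- 0
  }
  sig <- records$tier != "none" & !is.na(records$rho)
  pos <- sig & records$rho > 0
  encoded <- pos & records$carriage >= encoded_threshold
  # encoded carriers per module, for the 'associated' and annotation rules
  carriers_by_module <- split(records$taxon[encoded], records$module[encoded])
  cls <- rep("not-classified", nrow(records))
  annotation <- rep("", nrow(records))
  cls[encoded] <- "encoded"
  todo <- which(pos & !encoded)
  for (i in todo) {
    nb <- network_neighbors(network, records$taxon[i])
    enc <- carriers_by_module[[records$module[i]]] %||% character()
    cls[i] <- if (length(intersect(nb, enc))) "associated" else "unexplained"
  }
  neg <- sig & records$rho < 0
  for (i in which(neg)) {
    enc <- carriers_by_module[[records$module[i]]] %||% character()
    anti <- enc[network$rho[records$taxon[i], enc] < 0]
    if (length(anti))
      annotation[i] <- paste("anti-correlated carriers:",
                             paste(anti, collapse = ","))
  }
  records$class <- cls
  records$annotation <- annotation
  records
}

#' Overlap of significant correlations between two cohorts
#'
#' Intersects the significant (taxon, module) records of two analyses at a
#' chosen tier, requiring matching identifiers and the same sign of rho.
#'
#' @param records_a,records_b record data frames (classified or not).
#' @param tier "nominal" accepts both tiers (p < 0.01); "fdr" requires
#'   q < 0.2 in both cohorts.
#' @return data frame of shared records with both rho values.
#' @export
cross_cohort_overlap <- function(records_a, records_b, tier = c("fdr", "nominal")) {
  tier <- match.arg(tier)
  pick <- function(r) {
    keep <- if (tier == "fdr") r$tier == "fdr"
            else r$tier %in% c("nominal", "fdr")
    r[keep & !is.na(r$rho), c("taxon", "module", "rho")]
  }
  a <- pick(records_a); b <- pick(records_b)
  m <- merge(a, b, by = c("taxon", "module"), suffixes = c("_a", "_b"))
  m <- m[sign(m$rho_a) == sign(m$rho_b), ]
  rownames(m) <- NULL
  m
}
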