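# Community-level ecology: Bray-Curtis dissimilarity, principal-coordinates
# ordination, unrelated/twin/self pair enumeration and Welch t contrasts, and
# two-cohort prevalence/conditional-abundance comparison.

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' \code{sum(|a_i - b_i|) / sum(a_i + b_i)}: 0 for identical profiles, 1 for
#' disjoint supports. A semimetric (triangle inequality not guaranteed).
#'
#' @param a,b non-negative numeric vectors of equal length, not both all-zero.
#' @return dissimilarity in [0, 1].
#' @examples
#' bray_curtis(c(2, 1, 0), c(1, 1, 1))  # 1/3
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b))
    stop("vectors must have equal length", call. = FALSE)
  if (any(a < 0) || any(b < 0))
    stop("abundances must be non-negative", call. = FALSE)
  tot <- sum(a) + sum(b)
  if (tot == 0)
    stop("Bray-Curtis undefined for two all-zero vectors", call. = FALSE)
  sum(abs(a - b)) / tot
}

#' All-pairs Bray-Curtis distance matrix
#'
#' Computes the symmetric sample-by-sample Bray-Curtis matrix for an
#' abundance, function or marker matrix (samples in rows).
#'
#' @param table matrix-like with samples in rows (e.g. an
#'   \code{\link{abundance_table}} or a per-species marker matrix).
#' @return a \code{dist_matrix}: list with \code{sample_ids}, the symmetric
#'   \code{matrix}, and \code{metric = "bray-curtis"}.
#' @export
distance_matrix <- function(table) {
  m <- as.matrix(table)
  zero_rows <- rownames(m)[rowSums(m) == 0]
  if (length(zero_rows))
    stop("all-zero sample row(s): ", paste(zero_rows, collapse = ", "),
         call. = FALSE)
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  dimnames(d) <- list(rownames(m), rownames(m))
  structure(list(sample_ids = rownames(m), matrix = d,
                 metric = "bray-curtis"),
            class = "dist_matrix")
}

#' Principal-coordinates (classical metric MDS) ordination
#'
#' Gower double-centering eigendecomposition of the squared distance matrix.
#' Axes with eigenvalue below 1e-10 (including all negative axes) are
#' dropped; retained axes are ordered by decreasing eigenvalue and oriented
#' so that each axis' largest-magnitude coordinate is positive, giving a
#' reproducible embedding.
#'
#' @param dm a \code{dist_matrix} from \code{\link{distance_matrix}}.
#' @param k number of requested dimensions, 1 <= k <= n - 1.
#' @return list with \code{coordinates} (samples x retained axes, at most k)
#'   and \code{eigenvalues} for the retained axes.
#' @export
ordinate <- function(dm, k = 2) {
  n <- length(dm$sample_ids)
  assert_number(k, "k", lower = 1, integer = TRUE)
  if (k > n - 1)
    stop_field("k", sprintf("must be <= n - 1 = %d", n - 1))
  fit <- stats::cmdscale(stats::as.dist(dm$matrix), k = n - 1, eig = TRUE)
  eig <- fit$eig[seq_len(n - 1)]
  keep <- which(eig > 1e-10)
  keep <- keep[seq_len(min(length(keep), k))]
  if (!length(keep)) {
    coords <- matrix(0, n, k, dimnames = list(dm$sample_ids, NULL))
    return(list(coordinates = coords, eigenvalues = rep(0, k)))
  }
  coords <- fit$points[, keep, drop = FALSE]
  for (j in seq_len(ncol(coords))) {
    i_max <- which.max(abs(coords[, j]))
    if (coords[i_max, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- dm$sample_ids
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = eig[keep])
}

#' Enumerate unrelated / twin / self sample pairs
#'
#' Follows the twin-study comparison design: \emph{self} pairs are the two
#' visits of one subject; \emph{twin} pairs are co-twins at the baseline
#' time point; \emph{unrelated} pairs are members of different twin pairs,
#' also restricted to the baseline time point.
#'
#' @param metadata a \code{\link{metadata_table}}.
#' @return data frame of class \code{pair_set} with columns
#'   \code{sample_a}, \code{sample_b}, \code{pair_type}.
#' @export
enumerate_pairs <- function(metadata) {
  md <- as.data.frame(metadata)
  self <- do.call(rbind, lapply(split(md, md$subject_id), function(g) {
    if (nrow(g) < 2) return(NULL)
    g <- g[order(g$timepoint), ]
    data.frame(sample_a = g$sample_id[1], sample_b = g$sample_id[2],
               pair_type = "self", stringsAsFactors = FALSE)
  }))
  if (is.null(self)) {
    warning("no subjects with two time points: self group is empty")
    self <- data.frame(sample_a = character(), sample_b = character(),
                       pair_type = character(), stringsAsFactors = FALSE)
  }
  t1 <- md[md$timepoint == 1, ]
  t1 <- t1[order(t1$sample_id), ]
  cross <- NULL
  if (nrow(t1) >= 2) {
    idx <- utils::combn(nrow(t1), 2)
    cross <- data.frame(
      sample_a = t1$sample_id[idx[1, ]],
      sample_b = t1$sample_id[idx[2, ]],
      pair_type = ifelse(t1$pair_id[idx[1, ]] == t1$pair_id[idx[2, ]],
                         "twin", "unrelated"),
      stringsAsFactors = FALSE)
  }
  out <- rbind(self, cross)
  rownames(out) <- NULL
  class(out) <- c("pair_set", "data.frame")
  out
}

#' Attach a per-pair scalar to a pair set
#'
#' Convenience for group contrasts: evaluates either a pairwise distance
#' (from a \code{dist_matrix}) or the absolute difference of a per-sample
#' value (e.g. |delta BMI|) for every enumerated pair.
#'
#' @param pairs a \code{pair_set}.
#' @param dm optional \code{dist_matrix}; value = distance between members.
#' @param values optional named per-sample numeric vector;
#'   value = |values[a] - values[b]|.
#' @return the pair set with a \code{value} column.
#' @export
pair_values <- function(pairs, dm = NULL, values = NULL) {
  if (is.null(dm) == is.null(values))
    stop("supply exactly one of dm or values", call. = FALSE)
  if (!is.null(dm)) {
    pairs$value <- dm$matrix[cbind(pairs$sample_a, pairs$sample_b)]
  } else {
    pairs$value <- abs(values[pairs$sample_a] - values[pairs$sample_b])
  }
  pairs
}

#' Welch t contrasts between pair-type groups
#'
#' Applies a Welch (unequal-variance) two-sample t-test to each requested
#' contrast of per-pair scalar values, e.g. Bray-Curtis distance or |delta
#' BMI| by unrelated/twin/self.
#'
#' @param pairs a \code{pair_set} with a \code{value} column (see
#'   \code{\link{pair_values}}).
#' @param contrasts list of 2-element character vectors of pair types;
#'   default the twin-study contrasts (unrelated vs twin, twin vs self).
#' @return data frame with group names, sizes, means, Welch t and two-sided
#'   p per contrast.
#' @export
compare_groups <- function(pairs,
                           contrasts = list(c("unrelated", "twin"),
                                            c("twin", "self"))) {
  if (is.null(pairs$value))
    stop("pairs must carry a value column", call. = FALSE)
  rows <- lapply(contrasts, function(ct) {
    va <- pairs$value[pairs$pair_type == ct[1]]
    vb <- pairs$value[pairs$pair_type == ct[2]]
    for (g in seq_along(ct))
      if (length(list(va, vb)[[g]]) < 2)
        stop(sprintf("group '%s' has fewer than 2 values", ct[g]),
             call. = FALSE)
    tt <- welch_t(va, vb)
    data.frame(group_a = ct[1], group_b = ct[2],
               n_a = length(va), n_b = length(vb),
               mean_a = mean(va), mean_b = mean(vb),
               t = tt$statistic, p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Welch test that degrades gracefully when both groups are constant
welch_t <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(statistic = 0, p.value = 1))
    return(list(statistic = sign(mean(a) - mean(b)) * Inf, p.value = 0))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p.value = tt$p.value)
}

#' Per-clade prevalence and conditional mean abundance
#'
#' Prevalence is the percent of samples in which a clade's relative
#' abundance strictly exceeds \code{threshold}; the conditional mean is the
#' average abundance over only those passing samples (NA when no sample
#' passes).
#'
#' @param table an \code{\link{abundance_table}}.
#' @param threshold strict relative-abundance cutoff (default 0.001).
#' @return data frame of class \code{cohort_summary} with columns
#'   \code{clade}, \code{prevalence} (percent), \code{conditional_mean};
#'   the threshold is kept as an attribute.
#' @export
summarize_cohort <- function(table, threshold = 0.001) {
  assert_number(threshold, "threshold", lower = 0)
  m <- as.matrix(table)
  pass <- m > threshold
  prevalence <- 100 * colMeans(pass)
  cond_mean <- vapply(seq_len(ncol(m)), function(j) {
    if (!any(pass[, j])) return(NA_real_)
    mean(m[pass[, j], j])
  }, numeric(1))
  out <- data.frame(clade = colnames(m), prevalence = prevalence,
                    conditional_mean = cond_mean,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' Compare two cohort summaries by Pearson correlation
#'
#' Correlates per-clade prevalence (and, separately, conditional mean
#' abundance) across the clades shared by two cohorts.
#'
#' @param a,b \code{cohort_summary} objects.
#' @return list with \code{n_shared} and, for \code{prevalence} and
#'   \code{conditional_mean}, Pearson r and two-sided p.
#' @export
compare_cohorts <- function(a, b) {
  shared <- intersect(a$clade, b$clade)
  one_metric <- function(col) {
    va <- a[[col]][match(shared, a$clade)]
    vb <- b[[col]][match(shared, b$clade)]
    ok <- !is.na(va) & !is.na(vb)
    va <- va[ok]; vb <- vb[ok]
    if (length(va) < 3)
      stop("need >= 3 shared clades with defined values", call. = FALSE)
    if (stats::sd(va) == 0 || stats::sd(vb) == 0)
      stop("constant ", col, " vector: correlation undefined", call. = FALSE)
    ct <- stats::cor.test(va, vb, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, n = length(va))
  }
  list(n_shared = length(shared),
       prevalence = one_metric("prevalence"),
       conditional_mean = one_metric("conditional_mean"))
}
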