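# Strain-level comparison via clade-specific marker-gene abundance barcodes:
# RPK/coverage conversions, median-RPK eligibility, Bray-Curtis strain
# distances between unrelated/twin/self sample pairs, pooled group tests,
# per-species divergence summaries, and presence/absence barcode reports.

#' Reads per kilobase of a marker gene
#'
#' @param read_count reads mapped to the marker, >= 0.
#' @param marker_length marker gene length in nucleotides, > 0.
#' @return \code{read_count / (marker_length / 1000)} (vectorized).
#' @examples
#' marker_rpk(50, 2000)  # 25
#' @export
marker_rpk <- function(read_count, marker_length) {
  if (any(marker_length <= 0))
    stop_field("marker_length", "must be > 0")
  if (any(read_count < 0))
    stop_field("read_count", "must be >= 0")
  read_count / (marker_length / 1000)
}

#' Convert marker RPK to approximate fold coverage
#'
#' \code{rpk * read_length / 1000}: with 100-nt reads, 10 RPK corresponds to
#' about x1 coverage of the marker.
#'
#' @param rpk reads per kilobase, >= 0.
#' @param read_length sequencing read length in nucleotides, > 0.
#' @return fold coverage (vectorized).
#' @examples
#' rpk_to_coverage(10, 100)  # 1
#' @export
rpk_to_coverage <- function(rpk, read_length) {
  if (any(read_length <= 0))
    stop_field("read_length", "must be > 0")
  if (any(rpk < 0))
    stop_field("rpk", "must be >= 0")
  rpk * read_length / 1000
}

#' Enumerate strain comparisons eligible by median marker abundance
#'
#' A (species, sample) combination is eligible when the median RPK over ALL
#' of the species' markers — zero-RPK markers included — is strictly greater
#' than \code{min_median_rpk}; a pair comparison requires both samples to be
#' eligible. This restricts strain fingerprinting to samples where the
#' species is well covered.
#'
#' @param markers a \code{\link{marker_profile_set}}.
#' @param pairs a \code{pair_set} from \code{\link{enumerate_pairs}}.
#' @param min_median_rpk strict median-RPK cutoff (default 5).
#' @return data frame with columns \code{species}, \code{sample_a},
#'   \code{sample_b}, \code{pair_type} (possibly zero rows).
#' @export
eligible_comparisons <- function(markers, pairs, min_median_rpk = 5) {
  assert_number(min_median_rpk, "min_median_rpk", lower = 0)
  rows <- lapply(names(markers), function(sp) {
    med <- apply(markers[[sp]], 1, stats::median)
    ok <- names(med)[med > min_median_rpk]
    keep <- pairs$sample_a %in% ok & pairs$sample_b %in% ok
    if (!any(keep)) return(NULL)
    data.frame(species = sp, pairs[keep, c("sample_a", "sample_b",
                                           "pair_type")],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(species = character(), sample_a = character(),
                      sample_b = character(), pair_type = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Bray-Curtis distance between two samples' marker profiles of one species
#'
#' Computed over the full marker vectors of the species (absent markers as
#' zero), with each sample's vector first normalized to its within-species
#' relative marker abundance. The normalization makes the strain distance a
#' function of the marker composition — the presence/absence barcode and the
#' relative marker levels — rather than of sequencing depth or of the
#' species' overall abundance, which differ between samples for reasons
#' unrelated to strain identity. When both profiles have equal totals
#' (e.g. raw vectors (10, 0, 5) and (0, 10, 5), giving 2/3) the value
#' coincides with the raw-RPK Bray-Curtis.
#'
#' @param markers a \code{\link{marker_profile_set}}.
#' @param species species name (a key of \code{markers}).
#' @param sample_a,sample_b sample identifiers.
#' @return Bray-Curtis distance in [0, 1].
#' @export
strain_distance <- function(markers, species, sample_a, sample_b) {
  if (!species %in% names(markers))
    stop("unknown species '", species, "'", call. = FALSE)
  m <- markers[[species]]
  a <- m[sample_a, ]; b <- m[sample_b, ]
  if (sum(a) == 0 || sum(b) == 0)
    stop("species has an all-zero marker profile in a compared sample",
         call. = FALSE)
  bray_curtis(a / sum(a), b / sum(b))
}

#' Compute strain distances for a set of eligible comparisons
#'
#' @param markers a \code{\link{marker_profile_set}}.
#' @param comparisons data frame from \code{\link{eligible_comparisons}}.
#' @return the comparisons with a \code{distance} column.
#' @export
strain_comparisons <- function(markers, comparisons) {
  comparisons$distance <- vapply(seq_len(nrow(comparisons)), function(i)
    strain_distance(markers, comparisons$species[i],
                    comparisons$sample_a[i], comparisons$sample_b[i]),
    numeric(1))
  comparisons
}

#' Discretize a marker profile into a presence barcode with four levels
#'
#' A marker is present when its RPK strictly exceeds
#' \code{presence_min_rpk}; present markers are binned into low / mid / high
#' at the two \code{level_bounds}. The default bounds (1 and 10 RPK) put the
#' high bin at roughly >= x1 coverage for 100-nt reads. Bins are for
#' reporting and display only; strain distances never use them.
#'
#' @param rpk named numeric vector of marker RPK for one (species, sample).
#' @param presence_min_rpk strict presence threshold (default 0).
#' @param level_bounds increasing pair of bin boundaries (default c(1, 10)).
#' @return data frame with columns \code{marker}, \code{present},
#'   \code{level} (absent/low/mid/high).
#' @export
make_barcode <- function(rpk, presence_min_rpk = 0, level_bounds = c(1, 10)) {
  if (length(level_bounds) != 2 || diff(level_bounds) <= 0)
    stop_field("level_bounds", "must be two increasing values")
  present <- rpk > presence_min_rpk
  level <- ifelse(!present, "absent",
                  ifelse(rpk <= level_bounds[1], "low",
                         ifelse(rpk <= level_bounds[2], "mid", "high")))
  data.frame(marker = names(rpk), present = unname(present),
             level = factor(unname(level),
                            levels = c("absent", "low", "mid", "high")),
             stringsAsFactors = FALSE)
}

#' Per-marker discordance between two barcodes
#'
#' Marks markers present in exactly one of the two samples — the
#' black-marker display convention for co-twin comparisons, or gray-dot
#' differences between visits of the same subject.
#'
#' @param a,b barcodes from \code{\link{make_barcode}} over the same marker
#'   set.
#' @return data frame with \code{marker}, \code{present_a}, \code{present_b},
#'   \code{discordant}.
#' @export
barcode_diff <- function(a, b) {
  if (!identical(a$marker, b$marker))
    stop("barcodes cover different marker sets", call. = FALSE)
  data.frame(marker = a$marker, present_a = a$present, present_b = b$present,
             discordant = xor(a$present, b$present),
             stringsAsFactors = FALSE)
}

#' Pooled Welch t contrasts of strain distances by pair type
#'
#' Pools the Bray-Curtis strain distances of all eligible species-sample-pair
#' comparisons and tests unrelated vs twin and twin vs self by Welch t-test.
#'
#' @param comparisons data frame from \code{\link{strain_comparisons}}.
#' @return data frame with group names, sizes, means, t and two-sided p per
#'   contrast.
#' @export
compare_strain_groups <- function(comparisons) {
  ps <- comparisons[, c("sample_a", "sample_b", "pair_type")]
  ps$value <- comparisons$distance
  class(ps) <- c("pair_set", "data.frame")
  compare_groups(ps)
}

#' Per-species mean strain divergence by pair type
#'
#' @param comparisons data frame from \code{\link{strain_comparisons}}.
#' @return data frame with \code{species}, \code{pair_type},
#'   \code{mean_distance}, \code{n_comparisons}.
#' @export
species_mean_divergence <- function(comparisons) {
  if (!nrow(comparisons))
    return(data.frame(species = character(), pair_type = character(),
                      mean_distance = numeric(), n_comparisons = integer(),
                      stringsAsFactors = FALSE))
  agg <- stats::aggregate(distance ~ species + pair_type, data = comparisons,
                          FUN = mean)
  cnt <- stats::aggregate(distance ~ species + pair_type, data = comparisons,
                          FUN = length)
  out <- merge(agg, cnt, by = c("species", "pair_type"),
               suffixes = c("", "_n"))
  names(out) <- c("species", "pair_type", "mean_distance", "n_comparisons")
  out$n_comparisons <- as.integer(out$n_comparisons)
  out[order(out$species, out$pair_type), ]
}
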