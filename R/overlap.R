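#' Common peaks between two peak sets
#'
#' Two peaks are common when they share at least one base pair (half-open
#' intervals: touching ends share none). The relation is symmetric but the
#' counts are reported per side -- one a-peak spanning two b-peaks counts
#' once on the a side and twice on the b side.
#'
#' @param a,b Peak data.frames (`chrom`, `start`, `end`), same genome
#'   build.
#' @return list with `a_common` and `b_common`: each side's subset of
#'   peaks overlapping the other set.
#' @export
common_peaks <- function(a, b) {
  ga <- peaks_to_granges(a)
  gb <- peaks_to_granges(b)
  # disjoint seqlevel sets are expected across studies, not a warning
  list(a_common = a[suppressWarnings(
         GenomicRanges::countOverlaps(ga, gb)) > 0, , drop = FALSE],
       b_common = b[suppressWarnings(
         GenomicRanges::countOverlaps(gb, ga)) > 0, , drop = FALSE])
}

#' Anchor-set peaks common to every other set
#'
#' @param sets List of at least two peak data.frames; the first is the
#'   anchor.
#' @return The subset of anchor peaks overlapping (>= 1 bp) at least one
#'   peak in each other set.
#' @export
multiway_common <- function(sets) {
  if (length(sets) < 2) stop("multiway_common needs at least two peak sets")
  anchor <- sets[[1]]
  keep <- rep(TRUE, nrow(anchor))
  ga <- peaks_to_granges(anchor)
  for (other in sets[-1])
    keep <- keep & suppressWarnings(GenomicRanges::countOverlaps(
      ga, peaks_to_granges(other))) > 0
  anchor[keep, , drop = FALSE]
}

#' Percentage of query peaks overlapping a reference set
#'
#' @param query Non-empty peak data.frame.
#' @param reference Peak data.frame.
#' @param digits Decimals reported (default 1).
#' @return `100 * n_common / n_query`, rounded to `digits`.
#' @export
overlap_percent <- function(query, reference, digits = 1) {
  if (!nrow(query)) stop("query peak set is empty")
  n_common <- nrow(common_peaks(query, reference)$a_common)
  round(100 * n_common / nrow(query), digits)
}

#' Cooperativity composition of a peak subset
#'
#' @param subset Peak data.frame (e.g. an overlap subset), with `peak_id`.
#' @param calls data.frame mapping `peak_id` to `group` (`LOW`/`HIGH`);
#'   every subset peak must be called.
#' @return list with `LOW` and `HIGH` fractions (summing to 1), or `NULL`
#'   for an empty subset.
#' @export
overlap_composition <- function(subset, calls) {
  if (!nrow(subset)) return(NULL)
  grp <- calls$group[match(subset$peak_id, calls$peak_id)]
  if (anyNA(grp))
    stop("no cooperativity call for peak(s): ",
         paste(utils::head(subset$peak_id[is.na(grp)], 3), collapse = ", "))
  list(LOW = mean(grp == "LOW"), HIGH = mean(grp == "HIGH"))
}
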