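#' Cap read-start counts
#'
#' As a compromise between removing PCR-induced duplicate artifacts and
#' preserving library complexity at high depth, read-start positions with
#' more than `cap` reads are limited to exactly `cap` reads. Capping is
#' strand-aware: each (chromosome, strand, position) triple is capped
#' independently.
#'
#' @param track data.frame with columns `chrom`, `strand`, `pos`, `count`.
#' @param cap Positive integer cap (default 28).
#' @return The track with `count = min(count, cap)`; positions untouched.
#' @export
cap_read_starts <- function(track, cap = 28) {
  if (!is.numeric(cap) || length(cap) != 1 || cap <= 0)
    stop("cap must be a single positive integer")
  stopifnot(all(c("chrom", "strand", "pos", "count") %in% names(track)))
  if (any(track$count < 0)) stop("read-start counts must be non-negative")
  track$count <- pmin(track$count, cap)
  track
}

#' Normalize peak counts to reads per million mapped
#'
#' Adds one `norm_<sample>` column per sample:
#' `norm = raw * 1e6 / library_size`. Raw counts are preserved.
#'
#' @param peaks Peak data.frame with raw count columns named by sample.
#' @param library_sizes Named vector of mapped-read totals (> 0), one per
#'   sample column present in `peaks`.
#' @param samples Sample columns to normalize.
#' @return `peaks` with added `norm_*` columns.
#' @export
normalize_counts <- function(peaks, library_sizes,
                             samples = intersect(coop_samples(),
                                                 names(peaks))) {
  miss <- setdiff(samples, names(library_sizes))
  if (length(miss))
    stop("missing library size for sample(s): ", paste(miss, collapse = ", "))
  if (any(library_sizes[samples] <= 0))
    stop("library sizes must be positive")
  for (s in samples)
    peaks[[paste0("norm_", s)]] <- peaks[[s]] * 1e6 / library_sizes[[s]]
  peaks
}

# fold condition against a control that may be zero: a zero control is
# exceeded by any positive signal (the "2-fold change versus" limit)
fold_ok <- function(x, ctrl, fold) ifelse(ctrl == 0, x > 0, x >= fold * ctrl)

#' Filter peaks by minimum reads and fold change over controls
#'
#' A peak qualifies for a genotype when the genotype's combined raw count is
#' at least `min_reads` and its normalized count is at least
#' `fold_threshold`-fold above both the GFP control and the input. Peaks
#' with no qualifying genotype are dropped; the per-genotype qualifying
#' mask is retained in `qual_*` columns. The minimum-read condition is
#' applied to raw combined counts; the fold conditions compare normalized
#' counts.
#'
#' @param peaks Normalized peak data.frame (see [normalize_counts()]); GFP
#'   and INPUT columns must be present.
#' @param min_reads Minimum raw read count (default 50).
#' @param fold_threshold Fold-enrichment threshold (default 2).
#' @return The qualifying subset of `peaks` with added logical `qual_EE`,
#'   `qual_RR`, `qual_WT`, `qual_EERR` columns.
#' @export
filter_peaks <- function(peaks, min_reads = 50, fold_threshold = 2) {
  if (min_reads <= 0 || fold_threshold <= 0)
    stop("min_reads and fold_threshold must be positive")
  need <- c(paste0("norm_", coop_samples()))
  if (!all(need %in% names(peaks)))
    stop("peaks must carry normalized counts for all six samples; ",
         "run normalize_counts() first")
  for (g in coop_genotypes()) {
    peaks[[paste0("qual_", g)]] <-
      peaks[[g]] >= min_reads &
      fold_ok(peaks[[paste0("norm_", g)]], peaks$norm_GFP, fold_threshold) &
      fold_ok(peaks[[paste0("norm_", g)]], peaks$norm_INPUT, fold_threshold)
  }
  keep <- Reduce(`|`, lapply(paste0("qual_", coop_genotypes()),
                             function(cn) peaks[[cn]]))
  out <- peaks[keep, , drop = FALSE]
  coop_log(sprintf("filter_peaks: %d of %d peaks retained (min_reads=%g, fold=%g)",
                   nrow(out), nrow(peaks), min_reads, fold_threshold))
  rownames(out) <- NULL
  out
}

peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(peaks$start + 1L, peaks$end))
}

#' Interval union of peaks across samples
#'
#' Merges peak intervals from several peak sets into maximal union
#' intervals: intervals sharing at least one bp are combined (adjacent
#' half-open intervals are not). Per-sample counts of constituent peaks are
#' summed over each union interval, forming combined tag counts per region.
#'
#' @param peak_sets A list of peak data.frames (or a single data.frame).
#' @param samples Count columns to aggregate (those present are used).
#' @return A peak data.frame of pairwise non-overlapping, sorted union
#'   intervals with summed counts and fresh `peak_id`s.
#' @export
union_peaks <- function(peak_sets, samples = coop_samples()) {
  if (is.data.frame(peak_sets)) peak_sets <- list(peak_sets)
  all_pk <- do.call(rbind, lapply(peak_sets, function(p)
    p[c("chrom", "start", "end",
        intersect(samples, names(p)))]))
  validate_intervals(all_pk, "peak")
  gr <- peaks_to_granges(all_pk)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  red <- red[order(as.character(GenomicRanges::seqnames(red)),
                   GenomicRanges::start(red))]
  hit <- GenomicRanges::findOverlaps(gr, red)
  out <- data.frame(
    peak_id = sprintf("union_%05d", seq_along(red)),
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    stringsAsFactors = FALSE)
  for (s in intersect(samples, names(all_pk))) {
    agg <- tapply(all_pk[[s]][S4Vectors::queryHits(hit)],
                  S4Vectors::subjectHits(hit), sum)
    v <- numeric(length(red))
    v[as.integer(names(agg))] <- agg
    out[[s]] <- v
  }
  coop_log(sprintf("union_peaks: %d input peaks merged into %d union intervals",
                   nrow(all_pk), nrow(out)))
  out
}
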