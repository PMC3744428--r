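# fixed descending-cooperativity order used to break ranking ties; with
# equal counts the tie order cannot create a spurious gap (ratio is 1)
.tie_order <- c("EERR", "WT", "RR", "EE")

#' Rank-gap genotype presence calling
#'
#' Genotype presence at a peak is called independently of peak calling by
#' ranking the four genotypes by their normalized read count and scanning
#' the three adjacent ranked pairs for the first at-least-`fold_threshold`
#' difference. The genotypes above that first gap are designated as
#' binding; if no gap is found, all four genotypes are considered present.
#' A positive count above a zero count counts as a gap; two zero counts do
#' not. The controls (GFP/input) never participate.
#'
#' @param norm_counts Named non-negative numeric vector over
#'   `EE`, `RR`, `WT`, `EERR` (normalized counts).
#' @param fold_threshold Gap ratio; "at least" is inclusive, so a ratio of
#'   exactly `fold_threshold` triggers the gap. Must be >= 1.
#' @return A list with `bound` (character vector of binding genotypes, in
#'   rank order) and `gap_rank` (the rank after which the gap occurred, or
#'   `NA` when all four are bound).
#' @export
call_presence <- function(norm_counts, fold_threshold = 2) {
  g <- coop_genotypes()
  if (!all(g %in% names(norm_counts)))
    stop("norm_counts must be named over EE/RR/WT/EERR")
  x <- as.numeric(norm_counts[g])
  if (any(is.na(x)) || any(x < 0))
    stop("normalized counts must be non-negative and non-missing")
  if (fold_threshold < 1) stop("fold_threshold must be >= 1")
  ord <- order(-x, match(g, .tie_order))
  xs <- x[ord]
  gap <- NA_integer_
  for (k in 1:3) {
    a <- xs[k]; b <- xs[k + 1]
    if ((b == 0 && a > 0) || (b > 0 && a >= fold_threshold * b)) {
      gap <- k
      break
    }
  }
  bound <- if (is.na(gap)) g[ord] else g[ord][seq_len(gap)]
  list(bound = bound, gap_rank = gap)
}

#' Assign a cooperativity class from a presence call
#'
#' Classes encode the nested structure of the cistrome: sites bound even by
#' the weakest-cooperativity mutant are the highest-affinity sites.
#' Precedence is EE > RR > WT > EERR: a peak bound by EE is `EE_CLASS`,
#' otherwise bound by RR is `RR_CLASS`, otherwise bound by wild type is
#' `WT_CLASS`, otherwise `EERR_ONLY`. The EE and RR classes form the LOW
#' cooperativity group (high-affinity sites); WT and EERR-only form HIGH.
#'
#' @param bound Non-empty character vector of binding genotypes.
#' @return A list with `class` and `group`.
#' @export
assign_class <- function(bound) {
  if (length(bound) == 0) stop("bound set must be non-empty")
  if (!all(bound %in% coop_genotypes()))
    stop("unknown genotype in bound set")
  cls <- if ("EE" %in% bound) "EE_CLASS"
    else if ("RR" %in% bound) "RR_CLASS"
    else if ("WT" %in% bound) "WT_CLASS"
    else "EERR_ONLY"
  list(class = cls,
       group = if (cls %in% c("EE_CLASS", "RR_CLASS")) "LOW" else "HIGH")
}

#' Classify all peaks by cooperativity
#'
#' Applies [call_presence()] and [assign_class()] to every row of a
#' normalized peak table.
#'
#' @param peaks Peak data.frame carrying `norm_EE` .. `norm_EERR` columns.
#' @param fold_threshold Gap ratio, see [call_presence()].
#' @return `peaks` with added columns `bound_set` (comma-separated),
#'   `gap_rank`, `class`, `group`.
#' @export
classify_peaks <- function(peaks, fold_threshold = 2) {
  cols <- paste0("norm_", coop_genotypes())
  if (!all(cols %in% names(peaks)))
    stop("peaks must carry norm_EE/norm_RR/norm_WT/norm_EERR columns")
  n <- nrow(peaks)
  bound_set <- character(n); gap_rank <- integer(n)
  cls <- character(n); grp <- character(n)
  for (i in seq_len(n)) {
    nc <- stats::setNames(as.numeric(peaks[i, cols]), coop_genotypes())
    pc <- call_presence(nc, fold_threshold)
    ac <- assign_class(pc$bound)
    bound_set[i] <- paste(sort(pc$bound), collapse = ",")
    gap_rank[i] <- if (is.na(pc$gap_rank)) NA_integer_ else pc$gap_rank
    cls[i] <- ac$class; grp[i] <- ac$group
  }
  peaks$bound_set <- bound_set
  peaks$gap_rank <- gap_rank
  peaks$class <- cls
  peaks$group <- grp
  peaks
}

#' Aggregate cooperativity labels to genes
#'
#' A gene supported by any LOW cooperativity peak is a LOW cooperativity
#' gene, even when it also has HIGH peaks; genes supported only by HIGH
#' peaks are HIGH. Genes without linked peaks are absent from the output.
#'
#' @param peak_calls data.frame with columns `peak_id`, `group` and
#'   `gene_id` (each peak mapped to at most one gene; rows with `NA`
#'   gene_id are ignored).
#' @return data.frame with `gene_id`, `label`, `peak_ids`
#'   (comma-separated), `n_peaks`.
#' @export
label_genes <- function(peak_calls) {
  stopifnot(all(c("peak_id", "group", "gene_id") %in% names(peak_calls)))
  pc <- peak_calls[!is.na(peak_calls$gene_id), , drop = FALSE]
  if (nrow(pc) == 0)
    return(data.frame(gene_id = character(), label = character(),
                      peak_ids = character(), n_peaks = integer()))
  out <- do.call(rbind, lapply(split(pc, pc$gene_id), function(d)
    data.frame(gene_id = d$gene_id[1],
               label = if (any(d$group == "LOW")) "LOW" else "HIGH",
               peak_ids = paste(d$peak_id, collapse = ","),
               n_peaks = nrow(d), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Cooperativity class composition
#'
#' @param classes Character vector of class labels
#'   (`EE_CLASS`/`RR_CLASS`/`WT_CLASS`/`EERR_ONLY`).
#' @return Named list with per-class counts, `LOW`, `HIGH` and `total`;
#'   the four class counts partition the input and LOW + HIGH = total.
#' @export
class_composition <- function(classes) {
  lv <- c("EE_CLASS", "RR_CLASS", "WT_CLASS", "EERR_ONLY")
  if (!all(classes %in% lv)) stop("unknown class label")
  tab <- table(factor(classes, levels = lv))
  out <- as.list(as.integer(tab))
  names(out) <- lv
  out$LOW <- out$EE_CLASS + out$RR_CLASS
  out$HIGH <- out$WT_CLASS + out$EERR_ONLY
  out$total <- length(classes)
  out
}
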