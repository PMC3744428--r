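peak_midpoint <- function(peaks) (peaks$start + peaks$end) %/% 2L

#' Nearest-gene annotation by distance to the most-5' TSS
#'
#' Each peak is annotated with the gene whose most-5' transcription start
#' site is closest to the peak midpoint, on the peak's chromosome. Ties are
#' broken by the lexicographically smaller gene id. The signed distance is
#' given in gene orientation: negative upstream of the TSS, positive
#' downstream. Peaks on chromosomes without genes are returned unannotated
#' (`NA` gene), not as an error.
#'
#' @param peaks Peak data.frame (`chrom`, `start`, `end`).
#' @param genes Gene models from [read_gene_models()].
#' @return data.frame with `peak_id`, `gene_id`, `distance`.
#' @export
nearest_gene <- function(peaks, genes) {
  if (nrow(genes) == 0) stop("gene model list is empty")
  mid <- peak_midpoint(peaks)
  gene_id <- rep(NA_character_, nrow(peaks))
  distance <- rep(NA_integer_, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    gi <- which(genes$chrom == ch)
    if (!length(gi)) next
    pi <- which(peaks$chrom == ch)
    tss <- genes$tss[gi]
    for (j in pi) {
      d <- abs(tss - mid[j])
      cand <- gi[d == min(d)]
      pick <- cand[order(genes$gene_id[cand])][1]
      gene_id[j] <- genes$gene_id[pick]
      distance[j] <- if (genes$strand[pick] == "+")
        mid[j] - genes$tss[pick] else genes$tss[pick] - mid[j]
    }
  }
  data.frame(peak_id = if ("peak_id" %in% names(peaks)) peaks$peak_id else
               seq_len(nrow(peaks)),
             gene_id = gene_id, distance = distance,
             stringsAsFactors = FALSE)
}

#' Classify peaks into genomic regions
#'
#' The genome is divided into promoter, gene body, distal and intergenic
#' regions. A peak (anchored at its midpoint) is PROMOTER when the midpoint
#' lies within `promoter_up` bp upstream to `promoter_down` bp downstream
#' of any gene's TSS (orientation-aware); otherwise GENE_BODY when inside
#' any gene span; otherwise DISTAL when within `distal_max_bp` of any gene
#' span; otherwise INTERGENIC. Precedence PROMOTER > GENE_BODY > DISTAL >
#' INTERGENIC resolves overlaps.
#'
#' @param peaks Peak data.frame.
#' @param genes Gene models.
#' @param cfg A [coop_config()] providing the windows.
#' @return Character vector of region classes, one per peak.
#' @export
classify_region <- function(peaks, genes, cfg = coop_config()) {
  mid <- peak_midpoint(peaks)
  midr <- GenomicRanges::GRanges(peaks$chrom,
                                 IRanges::IRanges(mid + 1L, mid + 1L))
  up <- ifelse(genes$strand == "+", genes$tss - cfg$promoter_up,
               genes$tss - cfg$promoter_down)
  dn <- ifelse(genes$strand == "+", genes$tss + cfg$promoter_down,
               genes$tss + cfg$promoter_up)
  prom <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(pmax(up, 0L) + 1L, dn + 1L))
  body <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1L,
                                                  genes$end))
  dist <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(genes$start - cfg$distal_max_bp, 0L) + 1L,
                     genes$end + cfg$distal_max_bp))
  in_prom <- GenomicRanges::countOverlaps(midr, prom) > 0
  in_body <- GenomicRanges::countOverlaps(midr, body) > 0
  in_dist <- GenomicRanges::countOverlaps(midr, dist) > 0
  ifelse(in_prom, "PROMOTER",
         ifelse(in_body, "GENE_BODY",
                ifelse(in_dist, "DISTAL", "INTERGENIC")))
}

#' Region composition per cooperativity group
#'
#' @param region Character vector of region classes.
#' @param group Parallel vector of cooperativity groups (`LOW`/`HIGH`).
#' @return data.frame with `group`, `region`, `fraction`; fractions sum to
#'   1 within each non-empty group. Empty groups are absent.
#' @export
region_composition <- function(region, group) {
  stopifnot(length(region) == length(group))
  if (!length(region))
    return(data.frame(group = character(), region = character(),
                      fraction = numeric()))
  lv <- c("PROMOTER", "GENE_BODY", "DISTAL", "INTERGENIC")
  out <- do.call(rbind, lapply(split(region, group), function(r) {
    tab <- table(factor(r, levels = lv)) / length(r)
    data.frame(region = lv, fraction = as.numeric(tab))
  }))
  out$group <- sub("\\.\\d+$", "", rownames(out))
  rownames(out) <- NULL
  out[c("group", "region", "fraction")]
}
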