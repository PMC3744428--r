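#' Sample identifiers used throughout the pipeline
#'
#' The pipeline follows six ChIP-seq samples: four p53 genotypes that differ
#' in DNA binding cooperativity -- `EE` (p53 R181E, strongly reduced
#' cooperativity), `RR` (p53 E180R, reduced), `WT` (wild type) and `EERR`
#' (co-expressed EE+RR heterotetramers, cooperativity above wild type) --
#' plus two controls, a `GFP`-infected sample and sequencing `INPUT`.
#'
#' @return `coop_samples()` returns all six sample labels;
#'   `coop_genotypes()` the four genotype labels only.
#' @export
coop_samples <- function() c("EE", "RR", "WT", "EERR", "GFP", "INPUT")

#' @rdname coop_samples
#' @export
coop_genotypes <- function() c("EE", "RR", "WT", "EERR")

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with the study defaults:
#' peaks qualify at >= 50 combined reads and >= 2-fold enrichment over both
#' controls, read starts are capped at 28 reads, full-site motif spacers run
#' from 0 to 13 bp, and the Monte-Carlo signature null uses 10,000 random
#' gene sets.
#'
#' @param promoter_up,promoter_down Promoter window around the TSS, in bp
#'   upstream/downstream in gene orientation.
#' @param distal_max_bp Maximum distance from a gene span still called DISTAL.
#' @param max_spacer Maximum spacer length (bp) between motif half-sites.
#' @param fold_threshold Fold-change threshold shared by the peak filter and
#'   the rank-gap presence caller.
#' @param min_reads Minimum combined raw read count for a genotype to qualify.
#' @param read_start_cap Per-position read-start cap (PCR artifact control).
#' @param mc_iterations Number of random signatures in the Monte-Carlo null.
#' @param rng_seed Seed recorded with stochastic results.
#' @param walking_window Window (odd) of the walking-average smoother.
#' @param score_threshold Normalized motif score in \[0, 1\] above which a
#'   full-site hit is reported.
#' @param genome_build Declared build tag; all interval inputs must share it.
#' @return A named list of class `coop_config`.
#' @export
coop_config <- function(promoter_up = 5000, promoter_down = 1000,
                        distal_max_bp = 50000, max_spacer = 13,
                        fold_threshold = 2, min_reads = 50,
                        read_start_cap = 28, mc_iterations = 10000,
                        rng_seed = 1, walking_window = 25,
                        score_threshold = 0.8, genome_build = "hg19") {
  cfg <- list(promoter_up = promoter_up, promoter_down = promoter_down,
              distal_max_bp = distal_max_bp, max_spacer = max_spacer,
              fold_threshold = fold_threshold, min_reads = min_reads,
              read_start_cap = read_start_cap, mc_iterations = mc_iterations,
              rng_seed = rng_seed, walking_window = walking_window,
              score_threshold = score_threshold, genome_build = genome_build)
  num <- cfg[setdiff(names(cfg), "genome_build")]
  if (!all(vapply(num, is.numeric, logical(1))) ||
      any(unlist(num[c("promoter_up", "promoter_down", "distal_max_bp",
                       "fold_threshold", "min_reads", "read_start_cap",
                       "mc_iterations", "walking_window")]) <= 0))
    stop("all coop_config thresholds must be positive numbers")
  if (max_spacer < 0) stop("max_spacer must be >= 0")
  class(cfg) <- "coop_config"
  cfg
}

# internal logging helper: every filtering step reports before/after counts
coop_log <- function(...) message("[coopcis] ", ...)

#' Convert between 0-based half-open and 1-based inclusive coordinates
#'
#' All internal interval arithmetic uses 0-based half-open coordinates
#' (the BED convention). These converters are bijective on valid intervals.
#'
#' @param start,end 0-based half-open interval.
#' @param first,last 1-based inclusive interval.
#' @return A two-column data.frame in the other convention.
#' @export
to_one_based <- function(start, end) {
  stopifnot(all(end > start), all(start >= 0))
  data.frame(first = start + 1L, last = end)
}

#' @rdname to_one_based
#' @export
to_zero_based <- function(first, last) {
  stopifnot(all(last >= first), all(first >= 1))
  data.frame(start = first - 1L, end = last)
}

validate_intervals <- function(df, what = "interval") {
  bad <- which(is.na(df$chrom) | df$chrom == "" | is.na(df$start) |
               is.na(df$end) | df$start < 0 | df$end <= df$start)
  if (length(bad))
    stop(sprintf("invalid %s at line %d: chrom='%s' start=%s end=%s",
                 what, bad[1], df$chrom[bad[1]],
                 format(df$start[bad[1]]), format(df$end[bad[1]])))
  invisible(df)
}

#' Read a peak table
#'
#' Peaks are stored as BED3 coordinates (0-based half-open) plus one named
#' raw-count column per sample. Sample columns are identified by the header
#' (never by position alone).
#'
#' @param path Tab-delimited file with header
#'   `chrom start end EE RR WT EERR GFP INPUT` (count columns may be a
#'   subset but must be named).
#' @param samples Sample columns required to be present.
#' @return A data.frame with columns `peak_id`, `chrom`, `start`, `end` and
#'   one integer count column per sample.
#' @export
read_peaks <- function(path, samples = coop_samples()) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  if (file.size(path) == 0) {
    warning("empty peak file: ", path)
    out <- data.frame(peak_id = character(), chrom = character(),
                      start = integer(), end = integer())
    for (s in samples) out[[s]] <- integer()
    return(out)
  }
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop("peak file must carry columns chrom/start/end")
  miss <- setdiff(samples, names(df))
  if (length(miss))
    stop("peak file is missing sample column(s): ",
         paste(miss, collapse = ", "))
  validate_intervals(df, "peak")
  cnt <- as.matrix(df[samples])
  if (any(is.na(cnt)) || any(cnt < 0))
    stop(sprintf("negative or missing count at line %d",
                 which(rowSums(is.na(cnt) | cnt < 0) > 0)[1]))
  out <- data.frame(peak_id = if ("peak_id" %in% names(df)) df$peak_id else
                      sprintf("peak_%05d", seq_len(nrow(df))),
                    chrom = df$chrom,
                    start = as.integer(df$start), end = as.integer(df$end),
                    stringsAsFactors = FALSE)
  for (s in samples) out[[s]] <- as.numeric(df[[s]])
  out
}

#' Write a peak table
#'
#' @param peaks A peak data.frame as returned by [read_peaks()].
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# parse the gene_id attribute out of a GTF/GFF attribute string
gtf_gene_id <- function(attr) {
  m <- regmatches(attr, regexpr('gene_id[ =]+"?[^";]+"?', attr))
  id <- rep(NA_character_, length(attr))
  ok <- lengths(regmatches(attr, gregexpr("gene_id", attr))) > 0 &
    nchar(m) > 0
  id[ok] <- gsub('gene_id[ =]+"?([^";]+)"?.*', "\\1", m[ok])
  id
}

#' Read gene models
#'
#' Accepts either a GTF/GFF-style 9-column file (1-based inclusive
#' coordinates; the `gene_id` attribute is used) or a minimal 6-column TSV
#' with header `gene_id chrom start end strand name` in 0-based half-open
#' coordinates. One gene model per gene id is returned; records sharing a
#' gene id are merged to their union span and the most-5' TSS is re-derived
#' from the strand (`start` on `+`, `end - 1` on `-`). Records without a
#' strand are rejected with a warning.
#'
#' @param path Input file.
#' @return A data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, `name` (0-based half-open).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("gene model file not found: ", path)
  first <- readLines(path, n = 1)
  is_gtf <- length(strsplit(first, "\t")[[1]]) == 9 &&
    !grepl("gene_id\tchrom", first)
  if (is_gtf) {
    df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
    genes <- data.frame(gene_id = gtf_gene_id(df$V9), chrom = df$V1,
                        start = df$V4 - 1L, end = df$V5, strand = df$V7,
                        name = NA_character_, stringsAsFactors = FALSE)
  } else {
    genes <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end", "strand")
    if (!all(need %in% names(genes)))
      stop("minimal gene table must carry columns ",
           paste(need, collapse = "/"))
    if (is.null(genes$name)) genes$name <- genes$gene_id
  }
  bad_strand <- !(genes$strand %in% c("+", "-"))
  if (any(bad_strand)) {
    warning(sum(bad_strand), " gene record(s) without strand rejected")
    genes <- genes[!bad_strand, , drop = FALSE]
  }
  genes <- genes[!is.na(genes$gene_id), , drop = FALSE]
  validate_intervals(genes, "gene")
  # merge duplicate gene ids to the union span
  merged <- do.call(rbind, lapply(split(genes, genes$gene_id), function(g) {
    if (length(unique(g$chrom)) > 1 || length(unique(g$strand)) > 1)
      stop("gene ", g$gene_id[1], " spans multiple chromosomes or strands")
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               start = min(g$start), end = max(g$end), strand = g$strand[1],
               name = g$name[1], stringsAsFactors = FALSE)
  }))
  merged$tss <- ifelse(merged$strand == "+", merged$start, merged$end - 1L)
  rownames(merged) <- NULL
  merged[order(merged$chrom, merged$start), ]
}

#' Write (and re-read) a pipeline result table
#'
#' Every tabular pipeline output is serialized both as TSV and as JSON so
#' that `read_report(write_report(x))` round-trips the values.
#'
#' @param results A data.frame (may have zero rows, never zero columns).
#' @param path_base Output path without extension; `.tsv` and `.json` are
#'   appended.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_report <- function(results, path_base) {
  if (!is.data.frame(results) || ncol(results) == 0)
    stop("results must be a data.frame with at least one column")
  tsv <- paste0(path_base, ".tsv")
  json <- paste0(path_base, ".json")
  utils::write.table(results, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(results, json, digits = NA, na = "null")
  invisible(c(tsv = tsv, json = json))
}

#' @rdname write_report
#' @param path A `.tsv` or `.json` path produced by [write_report()].
#' @export
read_report <- function(path) {
  if (grepl("\\.json$", path)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  }
}
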