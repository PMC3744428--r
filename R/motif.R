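# degenerate base classes of the p53 half-site consensus RRRCWWGYYY
# (R = A/G, W = A/T, Y = C/T)
.halfsite_classes <- list(
  c("A", "G"), c("A", "G"), c("A", "G"), "C", c("A", "T"), c("A", "T"),
  "G", c("C", "T"), c("C", "T"), c("C", "T"))

.base_levels <- c("A", "C", "G", "T")

#' Build a half-site scoring matrix
#'
#' With no training sites, the degenerate consensus RRRCWWGYYY is encoded
#' directly: every base inside its positional class scores 1, every base
#' outside scores 0. With aligned training 10-mers, a pseudocounted
#' log-odds matrix against a uniform background is built instead. Either
#' way the full-site (two half-sites) scored by the consensus matrix is
#' symmetric under reverse complement, because RRRCWWGYYY doubled is its
#' own reverse complement as a degenerate pattern.
#'
#' @param training_sites Optional character vector of aligned 10-mers.
#' @param pseudocount Pseudocount per base (default 0.5).
#' @return A 4 x 10 numeric matrix (rows A/C/G/T, columns positions).
#' @export
build_matrix <- function(training_sites = NULL, pseudocount = 0.5) {
  if (is.null(training_sites)) {
    m <- matrix(0, 4, 10, dimnames = list(.base_levels, NULL))
    for (p in 1:10) m[.halfsite_classes[[p]], p] <- 1
    return(m)
  }
  if (any(nchar(training_sites) != 10))
    stop("training sites must all be length 10")
  chars <- do.call(rbind, strsplit(toupper(training_sites), ""))
  if (!all(chars %in% .base_levels)) stop("training sites must be ACGT only")
  n <- nrow(chars)
  m <- matrix(NA_real_, 4, 10, dimnames = list(.base_levels, NULL))
  for (p in 1:10) {
    cnt <- table(factor(chars[, p], levels = .base_levels))
    f <- (as.numeric(cnt) + pseudocount) / (n + 4 * pseudocount)
    m[, p] <- log2(f / 0.25)
  }
  m
}

# encode a DNA string as integer indices into a 5-row score matrix whose
# fifth row (N and anything non-ACGT) scores 0 at every position
encode_dna <- function(seq) {
  idx <- match(strsplit(toupper(seq), "")[[1]], .base_levels)
  idx[is.na(idx)] <- 5L
  idx
}

revcomp <- function(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))

# sliding half-site scores: hs[i] = score of the 10-mer starting at i
halfsite_scores <- function(code, matrix5) {
  L <- length(code)
  if (L < 10) return(numeric(0))
  n <- L - 9L
  hs <- numeric(n)
  for (p in 1:10) hs <- hs + matrix5[cbind(code[p:(n + p - 1L)], p)]
  hs
}

is_consensus_halfsite <- function(half) {
  ch <- strsplit(toupper(half), "")[[1]]
  length(ch) == 10 &&
    all(vapply(1:10, function(p) ch[p] %in% .halfsite_classes[[p]],
               logical(1)))
}

#' Scan a sequence for spacer-tolerant p53 full-sites
#'
#' Evaluates every placement of two half-sites separated by a spacer of 0
#' to `max_spacer` bases, on both strands, against a half-site scoring
#' matrix. The total score is the sum of the two half-site scores (no
#' spacer penalty by default; `spacer_penalty` subtracts that many score
#' units per spacer base). Scores are also reported normalized to the
#' maximum achievable full-site score, so group comparisons do not depend
#' on the matrix. `N` bases score 0 at any position. Ties for the top hit
#' are broken deterministically: smallest forward-strand offset, then
#' smallest spacer, then the + strand.
#'
#' When the best full-site falls below `threshold` (normalized scale), the
#' best single half-site is additionally reported in `half_best` and
#' flagged `half_site_only`, supporting peaks whose element resembles a
#' half-site rather than a full-site; [scan_peaks()] reports that row for
#' such peaks.
#'
#' @param seq A DNA string (A/C/G/T/N). Sequences shorter than 20 bp give
#'   an empty result.
#' @param matrix Half-site matrix from [build_matrix()].
#' @param max_spacer Maximum spacer length (default 13).
#' @param threshold Normalized score threshold for reported hits
#'   (default 0.8).
#' @param spacer_penalty Score units subtracted per spacer base (default 0).
#' @return A list with `top` (the arg-max full-site, one-row data.frame,
#'   or NULL for short sequences), `hits` (all full-site placements with
#'   normalized score >= `threshold`) and `half_best` (the best single
#'   half-site, only when the top full-site is below `threshold`, else
#'   NULL). Columns: `offset` (0-based, forward strand, leftmost
#'   base of the site), `strand`, `spacer`, `half1`, `half2` (scores),
#'   `total`, `score` (normalized), `half1_seq`, `half2_seq`, `core1`,
#'   `core2`, `w1_1`, `w1_2`, `perfect`, `half_site_only`.
#' @export
scan_fullsites <- function(seq, matrix = build_matrix(), max_spacer = 13,
                           threshold = 0.8, spacer_penalty = 0) {
  L <- nchar(seq)
  empty <- hit_frame(0)
  if (L < 20) return(list(top = NULL, hits = empty))
  m5 <- rbind(matrix, N = 0)
  max_half <- sum(apply(matrix, 2, max))
  strands <- list(`+` = seq, `-` = revcomp(seq))
  halves <- list()
  acc <- list(offset = list(), strand = list(), spacer = list(),
              half1 = list(), half2 = list(), total = list(), i = list())
  for (st in names(strands)) {
    sq <- strands[[st]]
    hs <- halfsite_scores(encode_dna(sq), m5)
    halves[[st]] <- hs
    for (s in 0:max_spacer) {
      n_i <- L - 19L - s
      if (n_i < 1) next
      i <- seq_len(n_i)
      j <- length(acc$offset) + 1L
      acc$offset[[j]] <- if (st == "+") i - 1L else L - i + 1L - 20L - s
      acc$strand[[j]] <- rep(st, n_i)
      acc$spacer[[j]] <- rep(s, n_i)
      acc$half1[[j]] <- hs[i]
      acc$half2[[j]] <- hs[i + 10L + s]
      acc$total[[j]] <- hs[i] + hs[i + 10L + s] - spacer_penalty * s
      acc$i[[j]] <- i
    }
  }
  all_hits <- data.frame(lapply(acc, function(v) unlist(v, use.names = FALSE)),
                         stringsAsFactors = FALSE)
  all_hits$score <- all_hits$total / (2 * max_half)
  ord <- order(-all_hits$total, all_hits$offset, all_hits$spacer,
               all_hits$strand == "-")
  all_hits <- all_hits[ord, , drop = FALSE]
  decorate <- function(h) {
    sq <- strands[[h$strand]]
    h$half1_seq <- substr(sq, h$i, h$i + 9L)
    h$half2_seq <- substr(sq, h$i + 10L + h$spacer, h$i + 19L + h$spacer)
    h$core1 <- substr(h$half1_seq, 4, 7)
    h$core2 <- substr(h$half2_seq, 4, 7)
    h$w1_1 <- substr(h$half1_seq, 5, 5)
    h$w1_2 <- substr(h$half2_seq, 5, 5)
    h$perfect <- h$spacer == 0 && is_consensus_halfsite(h$half1_seq) &&
      is_consensus_halfsite(h$half2_seq)
    h$half_site_only <- FALSE
    h$i <- NULL
    h
  }
  top <- decorate(all_hits[1, , drop = FALSE])
  keep <- all_hits[all_hits$score >= threshold, , drop = FALSE]
  hits <- if (nrow(keep)) do.call(rbind, lapply(seq_len(nrow(keep)),
    function(r) decorate(keep[r, , drop = FALSE]))) else empty
  half_best <- NULL
  if (top$score < threshold) {
    # additionally report the best single half-site, flagged
    best <- NULL
    for (st in names(strands)) {
      hs <- halves[[st]]
      if (!length(hs)) next
      i <- which.max(hs)
      off0 <- if (st == "+") i - 1L else L - i + 1L - 10L
      cand <- list(st = st, i = i, off0 = off0, sc = hs[i])
      if (is.null(best) || cand$sc > best$sc ||
          (cand$sc == best$sc && cand$off0 < best$off0)) best <- cand
    }
    sq <- strands[[best$st]]
    hseq <- substr(sq, best$i, best$i + 9L)
    half_best <- data.frame(offset = best$off0, strand = best$st,
                      spacer = NA_integer_, half1 = best$sc,
                      half2 = NA_real_, total = best$sc,
                      score = best$sc / (2 * max_half),
                      half1_seq = hseq, half2_seq = NA_character_,
                      core1 = substr(hseq, 4, 7), core2 = NA_character_,
                      w1_1 = substr(hseq, 5, 5), w1_2 = NA_character_,
                      perfect = FALSE, half_site_only = TRUE,
                      stringsAsFactors = FALSE)
  }
  rownames(top) <- rownames(hits) <- NULL
  list(top = top, hits = hits, half_best = half_best)
}

hit_frame <- function(n) {
  data.frame(offset = integer(n), strand = character(n),
             spacer = integer(n), half1 = numeric(n), half2 = numeric(n),
             total = numeric(n), score = numeric(n),
             half1_seq = character(n), half2_seq = character(n),
             core1 = character(n), core2 = character(n),
             w1_1 = character(n), w1_2 = character(n),
             perfect = logical(n), half_site_only = logical(n),
             stringsAsFactors = FALSE)
}

#' Top hit per sequence
#'
#' Reports each sequence's arg-max full-site, or -- when no full-site
#' reaches the score threshold -- its best single half-site, flagged
#' `half_site_only`.
#'
#' @param seqs Named character vector or `Biostrings::DNAStringSet`.
#' @param ... Passed to [scan_fullsites()].
#' @return data.frame of top hits with a leading `seq_id` column; sequences
#'   shorter than 20 bp are absent.
#' @export
scan_peaks <- function(seqs, ...) {
  if (methods::is(seqs, "DNAStringSet")) {
    nm <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- nm
  }
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq_%05d",
                                                   seq_along(seqs))
  rows <- lapply(names(seqs), function(id) {
    res <- scan_fullsites(seqs[[id]], ...)
    top <- if (!is.null(res$half_best)) res$half_best else res$top
    if (is.null(top)) return(NULL)
    cbind(seq_id = id, top, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- cbind(seq_id = character(0), hit_frame(0))
  rownames(out) <- NULL
  out
}

#' Core tetramer and central W bases of a hit
#'
#' The CWWG core is the central tetramer (positions 4-7) of each
#' half-site; the `w1` bases are position 5 of each half-site, i.e.
#' positions 5 and 15 of the spacer-free 20-mer consensus. CATG is the
#' torsionally most flexible core and marks high-affinity elements.
#'
#' @param hit A one-row hit data.frame from [scan_fullsites()].
#' @return list with `core1`, `core2`, `w1_bases` (length-2 character).
#' @export
classify_core <- function(hit) {
  list(core1 = hit$core1, core2 = hit$core2,
       w1_bases = c(hit$w1_1, hit$w1_2))
}

#' Is a hit a perfect response element?
#'
#' A hit is perfect when its two half-sites are directly adjacent
#' (spacer 0) and all 20 bases lie within their degenerate consensus class;
#' anything else (mismatches, spacers, half-sites) is non-canonical.
#'
#' @param hit A one-row hit data.frame.
#' @return logical.
#' @export
call_perfect <- function(hit) {
  isTRUE(!is.na(hit$spacer) && hit$spacer == 0 &&
           is_consensus_halfsite(hit$half1_seq) &&
           is_consensus_halfsite(hit$half2_seq))
}

#' Summarize top motif hits per cooperativity group
#'
#' @param tops data.frame of per-peak top hits (from [scan_peaks()]).
#' @param group Parallel vector of cooperativity groups.
#' @param max_spacer Spacer support of the distribution.
#' @return data.frame with one row per group: `mean_score`,
#'   `perfect_frac`, `spacer0_frac`, `halfsite_frac`, `catg_frac`,
#'   `cawg_frac`, plus `spacer_<s>` columns giving the spacer-length
#'   distribution over full-site hits (each row's distribution sums to 1).
#'   Empty groups are skipped with a warning.
#' @export
summarize_motifs <- function(tops, group, max_spacer = 13) {
  stopifnot(nrow(tops) == length(group))
  out <- list()
  for (g in unique(group)) {
    d <- tops[group == g, , drop = FALSE]
    if (!nrow(d)) {
      warning("empty group skipped: ", g)
      next
    }
    full <- d[!d$half_site_only, , drop = FALSE]
    sp <- table(factor(full$spacer, levels = 0:max_spacer))
    sp <- if (nrow(full)) as.numeric(sp) / nrow(full) else
      rep(NA_real_, max_spacer + 1)
    cores <- c(d$core1, d$core2)
    cores <- cores[!is.na(cores)]
    row <- data.frame(group = g, n = nrow(d),
                      mean_score = mean(d$score),
                      perfect_frac = mean(d$perfect),
                      spacer0_frac = mean(!is.na(d$spacer) & d$spacer == 0),
                      halfsite_frac = mean(d$half_site_only),
                      catg_frac = mean(cores == "CATG"),
                      cawg_frac = mean(grepl("^CA[AT]G$", cores)),
                      stringsAsFactors = FALSE)
    for (s in 0:max_spacer) row[[paste0("spacer_", s)]] <- sp[s + 1]
    out[[g]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
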