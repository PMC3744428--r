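# -- fixture builders ---------------------------------------------------

make_peaks <- function(chrom, start, end, ...) {
  df <- data.frame(peak_id = sprintf("p%03d", seq_along(start)),
                   chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  cnt <- list(...)
  for (s in names(cnt)) df[[s]] <- cnt[[s]]
  df
}

# peak table with all six raw count columns and norms for given libraries
make_counted_peaks <- function(counts, library_sizes = NULL) {
  n <- nrow(counts)
  df <- make_peaks("chr1", seq_len(n) * 1000, seq_len(n) * 1000 + 400)
  for (s in coop_samples()) df[[s]] <- counts[[s]]
  if (!is.null(library_sizes)) df <- normalize_counts(df, library_sizes)
  df
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

make_genes <- function(gene_id, chrom, start, end, strand) {
  g <- data.frame(gene_id = gene_id, chrom = chrom, start = start,
                  end = end, strand = strand, name = gene_id,
                  stringsAsFactors = FALSE)
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  g
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T"))
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

# -- independent oracles ------------------------------------------------

# brute-force motif oracle: scores every 10-mer by per-character lookup
# and enumerates every (offset, spacer, strand) placement explicitly,
# applying the same deterministic tie-break as the scanner contract
oracle_half_scores <- function(sq, mat) {
  ch <- strsplit(toupper(sq), "")[[1]]
  L <- length(ch)
  if (L < 10) return(numeric(0))
  vapply(seq_len(L - 9), function(i) {
    idx <- match(ch[i:(i + 9)], rownames(mat))
    sum(ifelse(is.na(idx), 0, mat[cbind(idx, 1:10)]), na.rm = TRUE)
  }, numeric(1))
}

oracle_top_fullsite <- function(seq, mat, max_spacer) {
  L <- nchar(seq)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq)))
  best <- NULL
  for (st in c("+", "-")) {
    sq <- if (st == "+") seq else rc
    oh <- oracle_half_scores(sq, mat)
    for (s in 0:max_spacer) {
      for (i in seq_len(max(0, L - 19 - s))) {
        tot <- oh[i] + oh[i + 10 + s]
        off <- if (st == "+") i - 1 else L - i + 1 - 20 - s
        cand <- list(total = tot, offset = off, spacer = s, strand = st)
        if (is.null(best) || tot > best$total ||
            (tot == best$total &&
             (off < best$offset ||
              (off == best$offset &&
               (s < best$spacer ||
                (s == best$spacer && st == "+" &&
                 best$strand == "-")))))) best <- cand
      }
    }
  }
  best
}

# all-pairs interval overlap oracle (>= 1 shared bp, half-open)
oracle_common <- function(a, b) {
  hit <- rep(FALSE, nrow(a))
  for (i in seq_len(nrow(a)))
    hit[i] <- any(b$chrom == a$chrom[i] &
                    pmax(b$start, a$start[i]) < pmin(b$end, a$end[i]))
  hit
}

# pairwise merge to fixpoint: brute-force interval union
oracle_union <- function(iv) {
  repeat {
    merged <- FALSE
    i <- 1
    while (i < nrow(iv)) {
      j <- i + 1
      while (j <= nrow(iv)) {
        if (iv$chrom[i] == iv$chrom[j] &&
            max(iv$start[i], iv$start[j]) < min(iv$end[i], iv$end[j])) {
          iv$start[i] <- min(iv$start[i], iv$start[j])
          iv$end[i] <- max(iv$end[i], iv$end[j])
          iv <- iv[-j, , drop = FALSE]
          merged <- TRUE
        } else j <- j + 1
      }
      i <- i + 1
    }
    if (!merged) break
  }
  iv[order(iv$chrom, iv$start), c("chrom", "start", "end")]
}
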