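#' Call regulated genes from log2 fold-changes
#'
#' Per genotype, a gene is UP when its log2 fold-change versus the GFP
#' control exceeds `log2(threshold)` and DOWN when below
#' `-log2(threshold)`; "more than `threshold`-fold" is strict, so a change
#' of exactly the threshold is NONE. The overall direction is UP/DOWN if
#' any genotype passes; genes passing in both directions across genotypes
#' are flagged DISCORDANT rather than dropped.
#'
#' @param fc data.frame with `gene_id` and log2 fold-change columns
#'   `EE`, `RR`, `WT`, `EERR`.
#' @param threshold Fold threshold (> 1, default 2).
#' @return `fc` with added `dir_<genotype>` columns and `direction`
#'   (`UP`/`DOWN`/`NONE`/`DISCORDANT`).
#' @export
call_regulated <- function(fc, threshold = 2) {
  if (threshold <= 1) stop("threshold must be > 1")
  g <- coop_genotypes()
  miss <- setdiff(c("gene_id", g), names(fc))
  if (length(miss))
    stop("fold-change table is missing column(s): ",
         paste(miss, collapse = ", "))
  cut <- log2(threshold)
  any_up <- rep(FALSE, nrow(fc)); any_dn <- rep(FALSE, nrow(fc))
  for (s in g) {
    d <- ifelse(fc[[s]] > cut, "UP", ifelse(fc[[s]] < -cut, "DOWN", "NONE"))
    fc[[paste0("dir_", s)]] <- d
    any_up <- any_up | d == "UP"
    any_dn <- any_dn | d == "DOWN"
  }
  fc$direction <- ifelse(any_up & any_dn, "DISCORDANT",
                         ifelse(any_up, "UP",
                                ifelse(any_dn, "DOWN", "NONE")))
  fc
}

#' Join regulated genes with their binding peaks
#'
#' Produces the bound-and-regulated table: one row per (peak, gene) pair
#' where the gene is differentially regulated (direction not NONE) and has
#' at least one linked peak. Distinct gene and distinct peak counts are
#' reported alongside.
#'
#' @param regulated Output of [call_regulated()].
#' @param peak_gene data.frame with `peak_id`, `gene_id` and optionally
#'   peak-level columns (e.g. `group`, normalized counts) carried through.
#' @return list with `table` (the join), `n_genes`, `n_peaks`.
#' @export
bound_and_regulated <- function(regulated, peak_gene) {
  reg <- regulated[regulated$direction != "NONE", , drop = FALSE]
  joined <- merge(peak_gene, reg, by = "gene_id")
  list(table = joined,
       n_genes = length(unique(joined$gene_id)),
       n_peaks = length(unique(joined$peak_id)))
}

#' Centered walking average
#'
#' A centered moving mean over a series already ordered by a ranking key
#' (e.g. decreasing EE/RR binding strength); edge windows are truncated so
#' the output has the input's length. A window of 1 is the identity; a
#' window larger than the series returns the global mean everywhere.
#'
#' @param values Numeric series.
#' @param window Odd positive window width (default 25).
#' @return Numeric vector, same length as `values`.
#' @export
walking_average <- function(values, window = 25) {
  if (window < 1 || window %% 2 == 0)
    stop("window must be a positive odd integer")
  n <- length(values)
  if (n == 0) return(numeric(0))
  if (window > n) return(rep(mean(values), n))
  h <- (window - 1) / 2
  cs <- cumsum(c(0, values))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Fraction of regulated genes carrying a binding peak
#'
#' @param regulated Output of [call_regulated()] (DISCORDANT genes count
#'   in both directions).
#' @param has_peak Logical vector parallel to `regulated`: does the gene
#'   have at least one linked peak?
#' @return list with `DOWN` and `UP`, each a list `n_with_peak`, `n`,
#'   `fraction` (fraction is `NA` when the direction has no genes).
#' @export
repressed_peak_fraction <- function(regulated, has_peak) {
  stopifnot(nrow(regulated) == length(has_peak))
  one <- function(dir) {
    sel <- regulated$direction == dir | regulated$direction == "DISCORDANT"
    n <- sum(sel)
    nw <- sum(has_peak & sel)
    list(n_with_peak = nw, n = n,
         fraction = if (n > 0) nw / n else NA_real_)
  }
  list(DOWN = one("DOWN"), UP = one("UP"))
}

#' Regulation and binding strength by cooperativity group
#'
#' Summarizes the bound-and-regulated table per gene cooperativity group:
#' mean absolute log2 fold-change per genotype, and the distribution
#' (mean, median, 10th/90th percentile) of wild-type normalized binding
#' strength when a `norm_WT` column is present.
#'
#' @param joined The `table` element of [bound_and_regulated()], carrying a
#'   `label` or `group` column.
#' @return data.frame, one row per group. Empty input gives zero rows.
#' @export
regulation_by_group <- function(joined) {
  grp_col <- if ("label" %in% names(joined)) "label" else "group"
  if (!grp_col %in% names(joined))
    stop("joined table must carry a 'label' or 'group' column")
  if (!nrow(joined)) return(data.frame())
  out <- do.call(rbind, lapply(split(joined, joined[[grp_col]]), function(d) {
    row <- data.frame(group = d[[grp_col]][1], n = nrow(d))
    for (g in coop_genotypes())
      row[[paste0("mean_abs_fc_", g)]] <- mean(abs(d[[g]]))
    if ("norm_WT" %in% names(d)) {
      q <- stats::quantile(d$norm_WT, c(0.1, 0.5, 0.9))
      row$wt_mean <- mean(d$norm_WT)
      row$wt_median <- q[[2]]
      row$wt_q10 <- q[[1]]
      row$wt_q90 <- q[[3]]
    }
    row
  }))
  rownames(out) <- NULL
  out
}
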