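#' Simulation parameters
#'
#' Defaults emulate the statistical structure of the study the pipeline
#' analyzes: the cooperativity-class mix follows the observed cistrome
#' composition (88 : 1579 : 3145 : 375), library sizes equal the stated
#' mapped-read totals per sample, bound sites carry about 5 reads per
#' million against a 0.1 rpm background with negative-binomial
#' overdispersion, low-cooperativity sites embed mostly perfect CATG-core
#' spacer-free response elements while high-cooperativity sites embed
#' degraded and spacer-containing ones, expression effects scale with
#' genotype cooperativity, and cohort survival depends on the activity of
#' the high-cooperativity gene set only.
#'
#' @param n_peaks,n_genes Problem sizes.
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param class_mix Target proportions of the four truth classes.
#' @param coop_levels Cooperativity level per genotype, strictly increasing
#'   EE < RR < WT < EERR; a genotype binds a site iff its level reaches the
#'   site's required threshold.
#' @param library_sizes Mapped reads per sample.
#' @param depth_rpm Occupancy of a bound site, reads per million.
#' @param background_rpm Background occupancy (unbound/GFP/input).
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 means deterministic counts (the
#'   noiseless limit).
#' @param strength_sdlog Log-sd of per-site strength variation.
#' @param p_promoter Probability a peak is placed at a gene promoter (and
#'   thereby linked to that gene as its truth target).
#' @param peak_width Range of simulated peak widths (bp).
#' @param seq_length Length of simulated peak sequences (bp).
#' @param perfect_prob Probability of embedding a perfect element, per
#'   group (`LOW`, `HIGH`).
#' @param catg_prob Probability the embedded cores are CATG, per group.
#' @param spacer_prob Probability a degraded element carries a spacer > 0.
#' @param mismatch_low,mismatch_high Mismatch-count range of degraded
#'   elements per group.
#' @param max_spacer Maximum embedded spacer length.
#' @param delta_up,delta_down Expression effect sizes (log2 units) of
#'   activation at bound genes and of indirect repression.
#' @param fc_noise_sd Log2 fold-change noise sd.
#' @param n_repressed Number of peak-free repressed genes.
#' @param n_patients Cohort size.
#' @param cohort_effect Expression shift per unit of gene-set activity.
#' @param hazard_rate Baseline exponential hazard.
#' @param hazard_beta Log-hazard reduction per unit of high-cooperativity
#'   set activity (0 gives the null cohort).
#' @param censor_rate Probability a patient is censored.
#' @param seed RNG seed; every generator is deterministic given it.
#' @return Named list of class `sim_params`.
#' @export
sim_params <- function(n_peaks = 2000, n_genes = 600,
                       chrom_sizes = c(chr1 = 6e7, chr2 = 4.5e7,
                                       chr3 = 3e7),
                       class_mix = c(EE_CLASS = 88, RR_CLASS = 1579,
                                     WT_CLASS = 3145, EERR_ONLY = 375) /
                         5187,
                       coop_levels = c(EE = 0.25, RR = 0.5, WT = 0.75,
                                       EERR = 1),
                       library_sizes = c(EE = 31.2e6, RR = 84.1e6,
                                         WT = 88.6e6, EERR = 100.4e6,
                                         GFP = 37.6e6, INPUT = 34.3e6),
                       depth_rpm = 5, background_rpm = 0.1,
                       dispersion = 0.05, strength_sdlog = 0.25,
                       p_promoter = 0.6, peak_width = c(200, 600),
                       seq_length = 200,
                       perfect_prob = c(LOW = 0.5, HIGH = 0.15),
                       catg_prob = c(LOW = 0.8, HIGH = 0.3),
                       spacer_prob = 0.85,
                       mismatch_low = 1:2, mismatch_high = 2:3,
                       max_spacer = 13,
                       delta_up = 2.5, delta_down = 2, fc_noise_sd = 0.4,
                       n_repressed = 60, n_patients = 200,
                       cohort_effect = 1, hazard_rate = 0.1,
                       hazard_beta = 0.8, censor_rate = 0.3, seed = 1) {
  p <- as.list(environment())
  if (abs(sum(p$class_mix) - 1) > 1e-8)
    stop("class_mix proportions must sum to 1")
  if (is.unsorted(p$coop_levels[coop_genotypes()], strictly = TRUE))
    stop("coop_levels must be strictly increasing EE < RR < WT < EERR")
  if (p$depth_rpm <= 0 || p$dispersion < 0)
    stop("depth must be positive and dispersion non-negative")
  if (any(c(p$censor_rate, p$spacer_prob, p$perfect_prob, p$catg_prob) < 0) ||
      any(c(p$censor_rate, p$spacer_prob, p$perfect_prob, p$catg_prob) > 1))
    stop("rates must lie in [0, 1]")
  class(p) <- "sim_params"
  p
}

# NB draw that degrades gracefully: dispersion 0 means deterministic counts
sim_counts <- function(mu, dispersion) {
  if (dispersion == 0) return(round(mu))
  stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

#' Simulate gene models
#'
#' @param params A [sim_params()] object.
#' @return Gene-model data.frame in the [read_gene_models()] schema.
#' @export
simulate_genes <- function(params = sim_params()) {
  set.seed(params$seed)
  n <- params$n_genes
  chrom <- sample(names(params$chrom_sizes), n, replace = TRUE,
                  prob = params$chrom_sizes)
  len <- round(stats::runif(n, 2000, 50000))
  start <- vapply(seq_len(n), function(i)
    round(stats::runif(1, 1e5, params$chrom_sizes[[chrom[i]]] - len[i] -
                         1e5)), numeric(1))
  g <- data.frame(gene_id = sprintf("GENE%04d", seq_len(n)), chrom = chrom,
                  start = as.integer(start),
                  end = as.integer(start + len),
                  strand = sample(c("+", "-"), n, replace = TRUE),
                  name = sprintf("GENE%04d", seq_len(n)),
                  stringsAsFactors = FALSE)
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  g
}

#' Simulate a peak table with per-sample counts and truth labels
#'
#' Each site draws a truth class from the class mix; the class fixes the
#' site's required cooperativity threshold, and a genotype binds iff its
#' cooperativity level reaches it -- so binding is nested by construction
#' (a site bound by EE is bound by all four genotypes). Bound samples draw
#' negative-binomial counts around `depth_rpm x strength` scaled to the
#' sample's library size (so normalized counts are comparable across
#' genotypes); unbound samples and the controls draw background counts.
#' Site strength decreases with the required threshold: high-affinity
#' (low-cooperativity) sites are the most strongly bound.
#'
#' @param params A [sim_params()] object.
#' @param genes Optional gene models; when given, a `p_promoter` fraction
#'   of peaks is placed at gene promoters and linked to those genes as
#'   truth targets.
#' @return list with `peaks` (a raw-count peak table) and `truth`
#'   (`peak_id`, `true_class`, `true_group`, `threshold`, `strength`,
#'   `target_gene`).
#' @export
simulate_peaks <- function(params = sim_params(), genes = NULL) {
  set.seed(params$seed)
  n <- params$n_peaks
  cls <- sample(names(params$class_mix), n, replace = TRUE,
                prob = params$class_mix)
  weakest <- c(EE_CLASS = "EE", RR_CLASS = "RR", WT_CLASS = "WT",
               EERR_ONLY = "EERR")
  r <- unname(params$coop_levels[weakest[cls]])
  strength <- stats::rlnorm(n, 0, params$strength_sdlog) * (1.5 - r)
  width <- round(stats::runif(n, params$peak_width[1], params$peak_width[2]))
  target <- rep(NA_character_, n)
  chrom <- character(n); start <- numeric(n)
  at_prom <- !is.null(genes) &
    stats::runif(n) < params$p_promoter
  gi <- sample(seq_len(if (is.null(genes)) 1 else nrow(genes)), n,
               replace = TRUE)
  for (i in seq_len(n)) {
    if (at_prom[i]) {
      g <- genes[gi[i], ]
      off <- round(stats::runif(1, -2000, 500))
      mid <- g$tss + if (g$strand == "+") off else -off
      chrom[i] <- g$chrom
      start[i] <- max(0, mid - width[i] %/% 2)
      target[i] <- g$gene_id
    } else {
      chrom[i] <- sample(names(params$chrom_sizes), 1,
                         prob = params$chrom_sizes)
      start[i] <- round(stats::runif(1, 0,
                                     params$chrom_sizes[[chrom[i]]] -
                                       width[i]))
    }
  }
  peaks <- data.frame(peak_id = sprintf("peak_%05d", seq_len(n)),
                      chrom = chrom, start = as.integer(start),
                      end = as.integer(start + width),
                      stringsAsFactors = FALSE)
  occupancy <- params$depth_rpm * strength
  for (s in coop_samples()) {
    bound <- if (s %in% coop_genotypes())
      params$coop_levels[[s]] >= r else rep(FALSE, n)
    mu <- ifelse(bound, occupancy, params$background_rpm) *
      params$library_sizes[[s]] / 1e6
    peaks[[s]] <- sim_counts(mu, params$dispersion)
  }
  truth <- data.frame(peak_id = peaks$peak_id, true_class = cls,
                      true_group = ifelse(cls %in% c("EE_CLASS",
                                                     "RR_CLASS"),
                                          "LOW", "HIGH"),
                      threshold = r, strength = strength,
                      target_gene = target, stringsAsFactors = FALSE)
  list(peaks = peaks, truth = truth)
}

sample_class_base <- function(p) p[sample(length(p), 1)]

# draw one embedded full-site for a peak of the given truth group
sim_element <- function(group, params) {
  draw_half <- function(catg) {
    h <- vapply(.halfsite_classes, sample_class_base, character(1))
    if (catg) h[4:7] <- c("C", "A", "T", "G")
    h
  }
  catg <- stats::runif(1) < params$catg_prob[[group]]
  perfect <- stats::runif(1) < params$perfect_prob[[group]]
  h1 <- draw_half(catg); h2 <- draw_half(catg)
  spacer <- 0L
  n_mm <- 0L
  if (!perfect) {
    if (stats::runif(1) < params$spacer_prob)
      spacer <- sample(seq_len(params$max_spacer), 1,
                       prob = 0.7 ^ seq_len(params$max_spacer))
    mm_range <- if (group == "LOW") params$mismatch_low else
      params$mismatch_high
    n_mm <- if (length(mm_range) == 1) mm_range else
      sample(mm_range, 1)
    site <- c(h1, h2)
    pos <- sample(20, n_mm)
    for (p in pos) {
      cl <- .halfsite_classes[[(p - 1) %% 10 + 1]]
      site[p] <- sample(setdiff(.base_levels, cl), 1)
    }
    h1 <- site[1:10]; h2 <- site[11:20]
  }
  list(half1 = paste(h1, collapse = ""), half2 = paste(h2, collapse = ""),
       spacer = spacer, n_mismatch = n_mm, perfect = perfect)
}

#' Simulate peak sequences with embedded response elements
#'
#' Each peak receives a uniform-random flanking sequence with one embedded
#' full-site whose fidelity follows the truth group: LOW (high-affinity)
#' sites are mostly perfect, CATG-core and spacer-free; HIGH sites mostly
#' carry mismatches, non-CATG cores and spacers. Elements are embedded on
#' a random strand and their placement is recorded.
#'
#' @param truth Truth table from [simulate_peaks()].
#' @param params A [sim_params()] object.
#' @return list with `seqs` (named character vector, one per peak) and
#'   `info` (`peak_id`, `offset` 0-based forward-strand, `strand`,
#'   `spacer`, `n_mismatch`, `perfect`).
#' @export
simulate_sequences <- function(truth, params = sim_params()) {
  set.seed(params$seed + 1L)
  n <- nrow(truth)
  L <- params$seq_length
  seqs <- character(n)
  info <- data.frame(peak_id = truth$peak_id, offset = integer(n),
                     strand = character(n), spacer = integer(n),
                     n_mismatch = integer(n), perfect = logical(n),
                     stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    el <- sim_element(truth$true_group[i], params)
    site <- paste0(el$half1,
                   paste(sample(.base_levels, el$spacer, replace = TRUE),
                         collapse = ""),
                   el$half2)
    strand <- sample(c("+", "-"), 1)
    if (strand == "-") site <- revcomp(site)
    w <- nchar(site)
    off <- sample(0:(L - w), 1)
    flank <- sample(.base_levels, L - w, replace = TRUE)
    seqs[i] <- paste0(paste(flank[seq_len(off)], collapse = ""), site,
                      paste(flank[seq_len(L - w - off) + off],
                            collapse = ""))
    info$offset[i] <- off
    info$strand[i] <- strand
    info$spacer[i] <- el$spacer
    info$n_mismatch[i] <- el$n_mismatch
    info$perfect[i] <- el$perfect
  }
  names(seqs) <- truth$peak_id
  list(seqs = seqs, info = info)
}

#' Simulate per-genotype expression log2 fold-changes
#'
#' Bound genes (truth targets of simulated peaks) are activated in
#' proportion to each genotype's cooperativity, but only by genotypes that
#' actually bind the gene's site. A designated set of repressed genes
#' carries no peaks, yet is downregulated through a mediator whose
#' induction rises with cooperativity -- emulating indirect,
#' cooperativity-dependent repression. All other genes are noise.
#'
#' @param genes Gene models (from [simulate_genes()]).
#' @param truth Truth table from [simulate_peaks()].
#' @param params A [sim_params()] object.
#' @return list with `fc` (gene_id x genotype log2 fold-change table) and
#'   `roles` (`gene_id`, `role` in BOUND/REPRESSED/NULL).
#' @export
simulate_expression <- function(genes, truth, params = sim_params()) {
  set.seed(params$seed + 2L)
  ids <- genes$gene_id
  n <- length(ids)
  cl <- params$coop_levels
  rel <- cl / cl[["EERR"]]
  fc <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
  for (g in coop_genotypes())
    fc[[g]] <- stats::rnorm(n, 0, params$fc_noise_sd)
  # strongest (lowest-threshold) site per bound gene drives activation
  linked <- truth[!is.na(truth$target_gene), , drop = FALSE]
  gene_thr <- tapply(linked$threshold, linked$target_gene, min)
  bound_idx <- match(names(gene_thr), ids)
  for (g in coop_genotypes()) {
    binds <- cl[[g]] >= gene_thr
    fc[[g]][bound_idx] <- fc[[g]][bound_idx] +
      params$delta_up * as.numeric(binds) * rel[[g]]
  }
  role <- rep("NULL", n)
  role[bound_idx] <- "BOUND"
  free <- which(role == "NULL")
  rep_idx <- sample(free, min(params$n_repressed, length(free)))
  for (g in coop_genotypes())
    fc[[g]][rep_idx] <- fc[[g]][rep_idx] - params$delta_down * rel[[g]]^2
  role[rep_idx] <- "REPRESSED"
  list(fc = fc, roles = data.frame(gene_id = ids, role = role,
                                   stringsAsFactors = FALSE))
}

#' Simulate a patient cohort with gene-set-linked survival
#'
#' Every patient draws an independent activity score per gene set; set
#' genes' expression is shifted by activity times `cohort_effect` on top
#' of unit Gaussian noise. Survival times are exponential with hazard
#' `hazard_rate * exp(-hazard_beta * activity)` of the *high*-cooperativity
#' set only, so high-set-UP patients live longer when `hazard_beta > 0`
#' and the design is null when it is 0. Censoring occurs with probability
#' `censor_rate`, uniformly before the event.
#'
#' @param gene_sets Named list of gene-id vectors; the element named
#'   `"high"` drives the hazard.
#' @param universe Character vector of all gene ids (must contain the
#'   sets).
#' @param params A [sim_params()] object.
#' @return list with `expr` (genes x patients log-scale matrix),
#'   `clinical` (`patient_id`, `time`, `event`) and `activity` (patients x
#'   sets).
#' @export
simulate_cohort <- function(gene_sets, universe,
                            params = sim_params()) {
  set.seed(params$seed + 3L)
  if (!all(unlist(gene_sets) %in% universe))
    stop("gene sets must lie within the simulated gene universe")
  P <- params$n_patients
  N <- length(universe)
  expr <- matrix(stats::rnorm(N * P), N, P,
                 dimnames = list(universe,
                                 sprintf("patient_%03d", seq_len(P))))
  activity <- sapply(gene_sets, function(s) stats::rnorm(P))
  rownames(activity) <- colnames(expr)
  for (s in names(gene_sets)) {
    sel <- universe %in% gene_sets[[s]]
    expr[sel, ] <- expr[sel, ] +
      matrix(activity[, s] * params$cohort_effect, sum(sel), P,
             byrow = TRUE)
  }
  z <- if ("high" %in% names(gene_sets)) activity[, "high"] else
    rep(0, P)
  t_event <- stats::rexp(P, params$hazard_rate *
                           exp(-params$hazard_beta * z))
  censored <- stats::runif(P) < params$censor_rate
  time <- ifelse(censored, stats::runif(P) * t_event, t_event)
  clinical <- data.frame(patient_id = colnames(expr), time = time,
                         event = as.integer(!censored),
                         stringsAsFactors = FALSE)
  list(expr = expr, clinical = clinical, activity = activity)
}

#' Simulate a complete study
#'
#' Runs all four generators coherently: gene models, peaks with truth
#' labels, peak sequences, expression fold-changes, and a patient cohort
#' whose gene sets are the truth-labelled LOW and HIGH cooperativity bound
#' genes. Optionally writes every table to `outdir` as plain text
#' (TSV/FASTA), in the formats the io readers accept.
#'
#' @param params A [sim_params()] object.
#' @param outdir Optional output directory.
#' @return list with `genes`, `peaks`, `truth`, `seqs`, `seq_info`, `fc`,
#'   `roles`, `gene_sets`, `cohort`.
#' @export
simulate_study <- function(params = sim_params(), outdir = NULL) {
  genes <- simulate_genes(params)
  pk <- simulate_peaks(params, genes)
  sq <- simulate_sequences(pk$truth, params)
  ex <- simulate_expression(genes, pk$truth, params)
  linked <- pk$truth[!is.na(pk$truth$target_gene), , drop = FALSE]
  gl <- label_genes(data.frame(peak_id = linked$peak_id,
                               group = linked$true_group,
                               gene_id = linked$target_gene,
                               stringsAsFactors = FALSE))
  gene_sets <- list(low = gl$gene_id[gl$label == "LOW"],
                    high = gl$gene_id[gl$label == "HIGH"])
  cohort <- simulate_cohort(gene_sets, genes$gene_id, params)
  out <- list(genes = genes, peaks = pk$peaks, truth = pk$truth,
              seqs = sq$seqs, seq_info = sq$info, fc = ex$fc,
              roles = ex$roles, gene_sets = gene_sets, cohort = cohort)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(f) file.path(outdir, f)
    write_peaks(out$peaks, fp("peaks.tsv"))
    utils::write.table(genes[c("gene_id", "chrom", "start", "end",
                               "strand", "name")],
                       fp("genes.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(out$seqs),
                                fp("peaks.fa"))
    utils::write.table(out$fc, fp("expression_log2fc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(gene_id = rownames(cohort$expr),
                                  cohort$expr, check.names = FALSE),
                       fp("cohort_expression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(cohort$clinical, fp("cohort_clinical.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$truth, fp("truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}

#' Synthetic stand-ins for the study's supplementary tables
#'
#' The study's supplementary tables are not redistributable, so these
#' generators build synthetic tables with the same published structure and
#' marginal composition: a bound-and-regulated table of 489 (peak, gene)
#' rows over 351 distinct genes, and a repressed-gene table of 221 genes
#' of which exactly 13 carry a binding peak. All identifiers and values
#' are synthetic; only the printed totals are reproduced so that counting
#' code paths can be exercised.
#'
#' @param seed RNG seed.
#' @param n_genes,n_sites Bound-and-regulated totals (defaults 351/489).
#' @param n_repressed,n_repressed_with_peak Repressed-gene totals
#'   (defaults 221/13).
#' @return list with `s1` (peak-gene rows: `gene_id`, `peak_id`, `chrom`,
#'   `start`, `end`, `group`, log2 fold-changes) and `s2` (`gene_id`,
#'   fold-changes, `has_peak`).
#' @export
synthetic_supplementary_tables <- function(seed = 1, n_genes = 351,
                                           n_sites = 489,
                                           n_repressed = 221,
                                           n_repressed_with_peak = 13) {
  set.seed(seed)
  stopifnot(n_sites >= n_genes, n_repressed >= n_repressed_with_peak)
  gene <- sprintf("SGENE%04d", seq_len(n_genes))
  owner <- c(gene, sample(gene, n_sites - n_genes, replace = TRUE))
  start <- sort(round(stats::runif(n_sites, 1e5, 5e7)))
  s1 <- data.frame(gene_id = owner,
                   peak_id = sprintf("speak_%04d", seq_len(n_sites)),
                   chrom = "chr1", start = start, end = start + 400,
                   group = sample(c("LOW", "HIGH"), n_sites, TRUE),
                   stringsAsFactors = FALSE)
  for (g in coop_genotypes())
    s1[[g]] <- stats::rnorm(n_sites, 1.6, 0.5)
  # listed genes are >2-fold regulated by definition of the table
  s1$EERR <- pmax(s1$EERR, 1.1)
  rep_gene <- sprintf("RGENE%04d", seq_len(n_repressed))
  s2 <- data.frame(gene_id = rep_gene, stringsAsFactors = FALSE)
  for (g in coop_genotypes())
    s2[[g]] <- stats::rnorm(n_repressed, -1.6, 0.5)
  s2$EERR <- pmin(s2$EERR, -1.1)
  s2$has_peak <- seq_len(n_repressed) %in%
    sample(n_repressed, n_repressed_with_peak)
  list(s1 = s1, s2 = s2)
}
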