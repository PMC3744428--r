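#' Mean-center an expression matrix across samples
#'
#' Each gene (row) is centered to mean zero across patients, in log scale,
#' so that a patient's within-profile ranking reflects expression relative
#' to the cohort mean.
#'
#' @param expr Numeric matrix, genes x patients (>= 2 patients), log scale.
#' @return The centered matrix.
#' @export
mean_center <- function(expr) {
  if (!is.matrix(expr) || ncol(expr) < 2)
    stop("expr must be a genes x patients matrix with >= 2 patients")
  sweep(expr, 1, rowMeans(expr))
}

# per-patient gene ranking: decreasing centered expression, ties broken by
# gene id so runs are deterministic
rank_genes <- function(centered) {
  ids <- rownames(centered)
  if (is.null(ids)) stop("expression matrix must have gene rownames")
  apply(centered, 2, function(x) order(-x, ids))
}

#' Unweighted single-sample enrichment score
#'
#' Classic KS-style running sum over a patient's ranked gene list: the sum
#' steps up by `1/|S|` at gene-set members and down by `1/(N-|S|)` at
#' non-members; the enrichment score is the signed extreme deviation, in
#' \[-1, 1\]. Positive scores mean the set concentrates among the
#' patient's most up-regulated genes. The score depends only on ranks, so
#' it is invariant under monotone transforms of the centered values.
#'
#' @param ranked_ids Character vector: the patient's genes, best-ranked
#'   first.
#' @param gene_set Character vector of gene ids; must be a non-empty
#'   proper subset of the universe.
#' @return The enrichment score (numeric scalar).
#' @export
enrichment_score <- function(ranked_ids, gene_set) {
  N <- length(ranked_ids)
  member <- ranked_ids %in% gene_set
  k <- sum(member)
  if (k == 0 || k == N)
    stop("gene_set must be a non-empty proper subset of the gene universe")
  rs <- cumsum(ifelse(member, 1 / k, -1 / (N - k)))
  rs[which.max(abs(rs))]
}

#' Per-patient enrichment scores for a cohort
#'
#' @param centered Mean-centered genes x patients matrix (gene rownames).
#' @param gene_set Character vector of gene ids.
#' @return Named numeric vector of enrichment scores, one per patient.
#' @export
cohort_enrichment <- function(centered, gene_set) {
  ord <- rank_genes(centered)
  ids <- rownames(centered)
  member <- ids %in% gene_set
  k <- sum(member)
  N <- length(ids)
  if (k == 0 || k == N)
    stop("gene_set must be a non-empty proper subset of the gene universe")
  steps <- matrix(ifelse(member[ord], 1 / k, -1 / (N - k)), nrow = N)
  rs <- apply(steps, 2, cumsum)
  es <- apply(rs, 2, function(v) v[which.max(abs(v))])
  stats::setNames(es, colnames(centered))
}

#' Stratify patients by enrichment-score sign
#'
#' Patients with a positive enrichment score form the UP group; zero or
#' negative scores go DOWN (zero means no enrichment).
#'
#' @param es Named numeric vector of enrichment scores.
#' @return Character vector of group labels (`UP`/`DOWN`), same names.
#' @export
stratify <- function(es) {
  grp <- ifelse(es > 0, "UP", "DOWN")
  if (length(unique(grp)) < 2)
    coop_log("stratify: one group is empty; downstream tests not testable")
  grp
}

#' Kaplan-Meier survival estimates per group
#'
#' Product-limit estimator under right-censoring (via
#' [survival::survfit()]); curves start at S(0) = 1 and events at tied
#' times are processed before censorings. Empty groups have no curve.
#'
#' @param time Positive survival times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param group Group labels.
#' @param at_times Optional times at which numbers at risk are reported.
#' @return list with `curves` (data.frame: `group`, `time`, `n_risk`,
#'   `n_event`, `surv`) and, when `at_times` is given, `at_risk`
#'   (data.frame: `group`, `time`, `n_risk`).
#' @export
kaplan_meier <- function(time, event, group, at_times = NULL) {
  stopifnot(all(time > 0), all(event %in% c(0, 1)))
  d <- data.frame(time = time, event = event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  st <- summary(fit)
  grp <- if (is.null(st$strata)) rep(unique(d$group)[1], length(st$time))
    else sub("^group=", "", as.character(st$strata))
  curves <- data.frame(group = grp, time = st$time, n_risk = st$n.risk,
                       n_event = st$n.event, surv = st$surv,
                       stringsAsFactors = FALSE)
  out <- list(curves = curves)
  if (!is.null(at_times)) {
    sa <- summary(fit, times = at_times, extend = TRUE)
    ga <- if (is.null(sa$strata)) rep(unique(d$group)[1], length(sa$time))
      else sub("^group=", "", as.character(sa$strata))
    out$at_risk <- data.frame(group = ga, time = sa$time,
                              n_risk = sa$n.risk, stringsAsFactors = FALSE)
  }
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank test with hypergeometric variance at tied event times
#' (via [survival::survdiff()]), one degree of freedom. A cohort with an
#' empty group or no events is reported as not testable rather than an
#' error.
#'
#' @param time Positive survival times.
#' @param event Event indicator (1/0).
#' @param group Two-level group labels.
#' @return list with `testable`, `chisq`, `df` (= 1), `p`.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(all(time > 0))
  if (length(unique(group)) < 2 || sum(event) == 0)
    return(list(testable = FALSE, chisq = NA_real_, df = 1L, p = NA_real_))
  d <- data.frame(time = time, event = event, group = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  list(testable = TRUE, chisq = unname(sd$chisq), df = 1L,
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Monte-Carlo signature null for a survival association
#'
#' Calibrates the observed gene-set survival association against random
#' gene signatures of equal size: each iteration draws a uniform random
#' gene set, computes per-patient enrichment scores, stratifies by score
#' sign and records the log-rank chi-square (0 when the iteration is not
#' testable). The empirical p-value uses the add-one formula
#' `p = (1 + #\{null >= observed\}) / (1 + n_iter)`, so p is never zero.
#'
#' @param centered Mean-centered genes x patients matrix.
#' @param gene_set Observed gene set.
#' @param time,event Survival outcome, parallel to patients.
#' @param n_iter Number of random signatures (default 10000).
#' @param seed RNG seed recorded in the result.
#' @return list with `observed` (chi-square), `null` (numeric vector),
#'   `p`, `n_iter`, `seed`.
#' @export
monte_carlo_p <- function(centered, gene_set, time, event,
                          n_iter = 10000, seed = 1) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  ids <- rownames(centered)
  k <- sum(ids %in% gene_set)
  if (k == 0 || k >= length(ids))
    stop("gene_set must be a non-empty proper subset of the gene universe")
  set.seed(seed)
  ord <- rank_genes(centered)          # ranking is set-independent
  N <- length(ids)
  stat_of <- function(set) {
    member <- ids %in% set
    ks <- sum(member)
    steps <- matrix(ifelse(member[ord], 1 / ks, -1 / (N - ks)), nrow = N)
    rs <- apply(steps, 2, cumsum)
    es <- apply(rs, 2, function(v) v[which.max(abs(v))])
    grp <- ifelse(es > 0, "UP", "DOWN")
    if (length(unique(grp)) < 2 || sum(event) == 0) return(0)
    lr <- logrank_test(time, event, grp)
    if (lr$testable) lr$chisq else 0
  }
  observed <- stat_of(gene_set)
  null <- vapply(seq_len(n_iter),
                 function(i) stat_of(sample(ids, k)), numeric(1))
  list(observed = observed, null = null,
       p = (1 + sum(null >= observed)) / (1 + n_iter),
       n_iter = n_iter, seed = seed)
}
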