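consensus <- build_matrix()

test_that("consensus matrix encodes the degenerate half-site classes", {
  expect_equal(dim(consensus), c(4, 10))
  expect_equal(consensus[, 4], c(A = 0, C = 1, G = 0, T = 0))
  expect_equal(consensus[, 1], c(A = 1, C = 0, G = 1, T = 0))
  expect_equal(consensus[, 5], c(A = 1, C = 0, G = 0, T = 1))
  expect_equal(consensus[, 8], c(A = 0, C = 1, G = 0, T = 1))
})

test_that("trained matrices rank training bases above absent bases", {
  m <- build_matrix(rep("GGGCATGTCC", 50))
  best <- apply(m, 2, function(col) names(which.max(col)))
  expect_equal(paste(best, collapse = ""), "GGGCATGTCC")

  # two sites differing at position 1: both observed bases beat the others
  m2 <- build_matrix(c("AGGCATGTCC", "GGGCATGTCC"))
  expect_true(all(m2[c("A", "G"), 1] > m2[c("C", "T"), 1]))
  expect_error(build_matrix("ACGT"), "length 10")
})

test_that("full-site scanning finds exact and spacered consensus instances", {
  hit <- scan_fullsites("GGGCATGTCCGGGCATGTCC", consensus)$top
  expect_equal(hit$offset, 0)
  expect_equal(hit$spacer, 0)
  expect_equal(hit$total, 20)
  expect_equal(hit$score, 1)
  expect_true(hit$perfect)

  sp <- scan_fullsites(paste0("GGGCATGTCC", "TTT", "GGGCATGTCC"),
                       consensus)$top
  expect_equal(sp$spacer, 3)
  expect_equal(sp$half1, 10)
  expect_equal(sp$half2, 10)
  expect_false(sp$perfect)

  expect_null(scan_fullsites("GGGCATGTC", consensus)$top)  # < 20 bp
})

test_that("consensus scanning is strand-symmetric and flank-invariant", {
  set.seed(5)
  for (i in 1:10) {
    s <- random_dna(60)
    fwd <- scan_fullsites(s, consensus)$top
    rev <- scan_fullsites(coopcis:::revcomp(s), consensus)$top
    expect_equal(fwd$total, rev$total)
    # score-neutral flanks shift the top hit's offset, never its score
    flank <- scan_fullsites(paste0(strrep("N", 17), s, strrep("N", 23)),
                            consensus)$top
    expect_equal(flank$total, fwd$total)
    if (flank$strand == "+" && fwd$strand == "+")
      expect_equal(flank$offset, fwd$offset + 17)
  }
})

test_that("mutating a top-hit base out of its class never raises the score", {
  set.seed(6)
  seqs <- paste0("AA", "GGGCATGTCC", "GA", "AGGCTTGCTT", "ACGT")
  base <- scan_fullsites(seqs, consensus)$top$total
  ch <- strsplit(seqs, "")[[1]]
  for (p in 3:12) {     # the embedded first half-site
    mut <- ch
    mut[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    expect_lte(scan_fullsites(paste(mut, collapse = ""),
                              consensus)$top$total, base)
  }
})

test_that("core typing extracts the CWWG tetramer and the central W base", {
  hit <- scan_fullsites("GGGCATGTCCGGGCTTGTCC", consensus)$top
  core <- classify_core(hit)
  expect_equal(core$core1, "CATG")
  expect_equal(core$core2, "CTTG")
  expect_equal(core$w1_bases, c("A", "T"))
})

test_that("perfect calls require spacer zero and all bases in class", {
  expect_true(call_perfect(
    scan_fullsites("GGGCATGTCCGGGCATGTCC", consensus)$top))
  # one mismatch at a Y position
  expect_false(call_perfect(
    scan_fullsites("GGGCATGTCCGGGCATGTCA", consensus)$top))
  # perfect halves separated by a 2-bp spacer are non-canonical
  expect_false(call_perfect(
    scan_fullsites("GGGCATGTCCAAGGGCATGTCC", consensus)$top))
})

test_that("N bases score zero, never negative", {
  withN <- scan_fullsites("GGGCNTGTCCGGGCATGTCC", consensus)$top
  expect_equal(withN$total, 19)
  allN <- scan_fullsites(strrep("N", 40), consensus)
  expect_equal(allN$top$total, 0)
})

test_that("a weak full-site is reported as its best half-site, flagged", {
  # one strong half-site in otherwise class-free sequence
  s <- paste0(strrep("C", 15), "GGGCATGTCC", strrep("G", 15))
  res <- scan_fullsites(s, consensus, threshold = 0.8)
  expect_false(res$top$half_site_only)     # the arg-max full-site itself
  expect_true(res$half_best$half_site_only)
  expect_equal(res$half_best$half1_seq, "GGGCATGTCC")
  expect_equal(res$half_best$total, 10)
  expect_equal(nrow(res$hits), 0)
  # the per-peak report carries the flagged half-site row
  rep <- scan_peaks(c(weak = s), consensus, threshold = 0.8)
  expect_true(rep$half_site_only)
  # a strong full-site is never replaced
  strong <- scan_peaks(c(ok = "GGGCATGTCCGGGCATGTCC"), consensus)
  expect_false(strong$half_site_only)
})

test_that("scanner equals the brute-force placement oracle on random DNA", {
  set.seed(7)
  for (i in 1:25) {
    s <- random_dna(sample(40:120, 1), c("A", "C", "G", "T", "N"))
    got <- scan_fullsites(s, consensus, max_spacer = 5,
                          threshold = 1.1)$top
    want <- oracle_top_fullsite(s, consensus, max_spacer = 5)
    expect_equal(got$total, want$total)
    expect_equal(got$offset, want$offset)
    expect_equal(got$spacer, want$spacer)
    expect_equal(got$strand, want$strand)
  }
})

test_that("motif summaries separate groups as designed by the generator", {
  p <- sim_params(n_peaks = 300, seed = 21)
  tr <- simulate_peaks(p)$truth
  sq <- simulate_sequences(tr, p)
  tops <- scan_peaks(sq$seqs)
  sm <- summarize_motifs(tops[match(tr$peak_id, tops$seq_id), ],
                         tr$true_group)
  low <- sm[sm$group == "LOW", ]
  high <- sm[sm$group == "HIGH", ]
  expect_gt(low$mean_score, high$mean_score)
  expect_gt(low$spacer0_frac, high$spacer0_frac)
  expect_gt(low$perfect_frac, high$perfect_frac)
  expect_gt(low$catg_frac, high$catg_frac)
  # spacer distribution is a distribution
  spcols <- grep("^spacer_", names(sm))
  expect_equal(rowSums(sm[, spcols]), c(1, 1), ignore_attr = TRUE)
})
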