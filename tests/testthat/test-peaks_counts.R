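test_that("read-start capping saturates at the cap and is idempotent", {
  tr <- data.frame(chrom = "chr1", strand = c("+", "+", "-"),
                   pos = c(10, 20, 10), count = c(30, 10, 28))
  expect_equal(cap_read_starts(tr, 28)$count, c(28, 10, 28))
  expect_equal(cap_read_starts(tr, 1)$count, c(1, 1, 1))
  low <- data.frame(chrom = "chr1", strand = "+", pos = 1:3,
                    count = c(5, 0, 2))
  expect_equal(cap_read_starts(low, 28), low)       # identity under cap
  once <- cap_read_starts(tr, 28)
  expect_equal(cap_read_starts(once, 28), once)     # idempotence
  expect_error(cap_read_starts(tr, 0), "positive")
})

test_that("per-million normalization scales by library size", {
  pk <- make_counted_peaks(data.frame(EE = 50, RR = 0, WT = 100, EERR = 10,
                                      GFP = 5, INPUT = 5))
  libs <- c(EE = 25e6, RR = 10e6, WT = 50e6, EERR = 10e6, GFP = 10e6,
            INPUT = 10e6)
  norm <- normalize_counts(pk, libs)
  expect_equal(norm$norm_EE, 2)
  expect_equal(norm$norm_RR, 0)
  expect_equal(norm$norm_WT, 2)
  expect_equal(norm$EE, 50)  # raw preserved
  # doubling all library sizes halves every normalized count
  half <- normalize_counts(pk, libs * 2)
  for (s in coop_samples())
    expect_equal(half[[paste0("norm_", s)]],
                 norm[[paste0("norm_", s)]] / 2)
  expect_error(normalize_counts(pk, libs[-1]), "missing library size")
})

test_that("peak filter applies min-read and two-fold-over-control rules", {
  libs <- setNames(rep(1e6, 6), coop_samples())  # norm == raw
  counts <- data.frame(
    EE = c(49, 100, 100, 0), RR = c(49, 100, 0, 0),
    WT = c(49, 100, 0, 0), EERR = c(49, 100, 0, 0),
    GFP = c(1, 60, 10, 0), INPUT = c(1, 10, 20, 0))
  pk <- make_counted_peaks(counts, libs)
  suppressMessages(out <- filter_peaks(pk, min_reads = 50,
                                       fold_threshold = 2))
  # row 1: 49 reads everywhere -> below the 50-read minimum, dropped
  expect_false("p001" %in% out$peak_id)
  # row 2: 100 vs GFP 60 is 1.67-fold < 2 -> every genotype fails, dropped
  expect_false("p002" %in% out$peak_id)
  # row 3: 100 raw, 2-fold over GFP 10 and INPUT 20 -> kept for EE
  expect_true(out$qual_EE[out$peak_id == "p003"])
  # row 4: all-zero genotypes -> dropped entirely
  expect_false("p004" %in% out$peak_id)
  # output is a subset and re-filtering is idempotent
  expect_true(all(out$peak_id %in% pk$peak_id))
  suppressMessages(again <- filter_peaks(out, 50, 2))
  expect_equal(again, out)
})

test_that("zero-control fold condition is satisfied by any positive signal", {
  libs <- setNames(rep(1e6, 6), coop_samples())
  pk <- make_counted_peaks(data.frame(EE = 60, RR = 60, WT = 60, EERR = 60,
                                      GFP = 0, INPUT = 0), libs)
  suppressMessages(out <- filter_peaks(pk))
  expect_equal(nrow(out), 1)
  expect_true(all(unlist(out[paste0("qual_", coop_genotypes())])))
})

test_that("interval union merges on >= 1 shared bp and sums counts", {
  a <- make_peaks("chr1", 100, 200, WT = 10)
  b <- make_peaks("chr1", 150, 250, WT = 5)
  suppressMessages(u <- union_peaks(list(a, b)))
  expect_equal(c(u$start, u$end), c(100, 250))
  expect_equal(u$WT, 15)

  # half-open adjacency shares zero bp: two peaks remain
  suppressMessages(u2 <- union_peaks(list(make_peaks("chr1", 100, 200),
                                          make_peaks("chr1", 200, 300))))
  expect_equal(nrow(u2), 2)

  # chained overlaps collapse to the single brute-force fixpoint interval
  chain <- make_peaks("chr1", c(100, 180, 260), c(200, 280, 360))
  suppressMessages(u3 <- union_peaks(chain))
  expect_equal(u3[c("chrom", "start", "end")],
               oracle_union(chain), ignore_attr = TRUE)
  expect_equal(nrow(u3), 1)
})

test_that("union output matches the pairwise-merge oracle and is sorted", {
  set.seed(11)
  for (rep in 1:5) {
    start <- sample(0:5000, 60)
    iv <- make_peaks(sample(c("chr1", "chr2"), 60, TRUE), start,
                     start + sample(50:400, 60, TRUE))
    suppressMessages(u <- union_peaks(iv))
    expect_equal(u[c("chrom", "start", "end")], oracle_union(iv),
                 ignore_attr = TRUE)
    # pairwise non-overlapping, sorted, coverage >= input coverage of one set
    by_chr <- split(u, u$chrom)
    for (d in by_chr) {
      expect_true(all(diff(d$start) > 0))
      expect_true(all(utils::head(d$end, -1) <= utils::tail(d$start, -1)))
    }
  }
})
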