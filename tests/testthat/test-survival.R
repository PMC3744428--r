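test_that("mean centering zeroes each gene across patients", {
  m <- matrix(c(1, 2, 3, 5, 5, 5), 2, 3, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("p1", "p2", "p3")))
  cen <- mean_center(m)
  expect_equal(cen["g1", ], c(p1 = -1, p2 = 0, p3 = 1))
  expect_equal(cen["g2", ], c(p1 = 0, p2 = 0, p3 = 0))  # constant row ok
  expect_equal(mean_center(cen), cen)                   # idempotent
  expect_error(mean_center(m[, 1, drop = FALSE]), ">= 2 patients")
})

test_that("enrichment scores hit the extreme-concentration closed forms", {
  genes <- sprintf("g%02d", 1:10)
  expect_equal(enrichment_score(genes, genes[1:2]), 1)
  expect_equal(enrichment_score(genes, genes[9:10]), -1)
  # hand-computed running sum: N=4, members at ranks 1 and 3 ->
  # +0.5, 0, +0.5, 0 -> extreme +0.5
  expect_equal(enrichment_score(c("a", "b", "c", "d"), c("a", "c")), 0.5)
  expect_error(enrichment_score(genes, character(0)), "proper subset")
  expect_error(enrichment_score(genes, genes), "proper subset")
})

test_that("enrichment depends on ranks only and stays within [-1, 1]", {
  set.seed(13)
  genes <- sprintf("g%02d", 1:40)
  for (i in 1:20) {
    expr <- matrix(rnorm(80), 40, 2, dimnames = list(genes, c("a", "b")))
    cen <- mean_center(expr)
    set <- sample(genes, 8)
    es <- cohort_enrichment(cen, set)
    expect_true(all(es >= -1 & es <= 1))
    # strictly monotone transform of centered values preserves the score
    mono <- sign(cen) * log1p(abs(cen)) * 3
    expect_equal(cohort_enrichment(mono, set), es)
  }
})

test_that("stratification splits on the sign of the score, zero goes DOWN", {
  es <- c(p1 = 0.3, p2 = -0.2, p3 = 0)
  grp <- stratify(es)
  expect_equal(unname(grp), c("UP", "DOWN", "DOWN"))
  expect_equal(sum(grp == "UP") + sum(grp == "DOWN"), 3)
  expect_message(stratify(c(a = 1, b = 2)), "empty")
})

test_that("Kaplan-Meier estimates match closed forms and tie conventions", {
  # all events, one group: the empirical survival function
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1), rep("A", 3))
  expect_equal(km$curves$surv, c(2 / 3, 1 / 3, 0))
  # all censored: S stays at 1 (no event rows in the summary)
  kc <- kaplan_meier(c(1, 2, 3), c(0, 0, 0), rep("A", 3))
  expect_true(all(kc$curves$n_event == 0))
  # event and censor tied at t = 2: the event is processed first, so
  # hand-computed S = 3/4 (t=1), 3/4 * 2/3 = 1/2 (t=2), then the censored
  # patient leaves and the last event drops S to 0
  kt <- kaplan_meier(c(1, 2, 2, 3), c(1, 1, 0, 1), rep("A", 4))
  expect_equal(kt$curves$surv, c(3 / 4, 1 / 2, 0))
  # numbers at risk at requested times
  ar <- kaplan_meier(c(1, 2, 3, 4), c(1, 1, 1, 1),
                     rep("A", 4), at_times = c(0, 2.5))$at_risk
  expect_equal(ar$n_risk, c(4, 2))
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(14)
  t <- round(rexp(40, 0.2), 3)
  km <- kaplan_meier(t, rep(1, 40), rep("A", 40))
  emp <- vapply(km$curves$time, function(x) mean(t > x), numeric(1))
  expect_equal(km$curves$surv, emp)
})

test_that("log-rank statistic matches the hand-computed O-E/V value", {
  # 5 vs 5, all group-A events at t=1, all group-B events at t=10:
  # only t=1 contributes, O_A = 5, E_A = 2.5, V = 5*(1/2)*(1/2)*(5/9),
  # chi-square = 2.5^2 / (25/36) = 9
  time <- c(rep(1, 5), rep(10, 5))
  event <- rep(1, 10)
  group <- rep(c("A", "B"), each = 5)
  lr <- logrank_test(time, event, group)
  expect_true(lr$testable)
  expect_equal(lr$chisq, 9, tolerance = 1e-10)
  expect_equal(lr$p, pchisq(9, 1, lower.tail = FALSE))
  # label symmetry
  lr2 <- logrank_test(time, event, rev(group))
  expect_equal(lr2$chisq, lr$chisq)
  # identical groups: statistic 0, p 1
  same <- logrank_test(c(1, 2, 3, 1, 2, 3), rep(1, 6),
                       rep(c("A", "B"), each = 3))
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)
  # degenerate cohorts are flagged, not errors
  expect_false(logrank_test(1:4, rep(0, 4),
                            rep(c("A", "B"), 2))$testable)
  expect_false(logrank_test(1:4, rep(1, 4), rep("A", 4))$testable)
})

test_that("the Monte-Carlo null is reproducible and uses the add-one formula", {
  set.seed(15)
  genes <- sprintf("g%02d", 1:30)
  expr <- matrix(rnorm(30 * 20), 30, 20,
                 dimnames = list(genes, sprintf("p%02d", 1:20)))
  cen <- mean_center(expr)
  time <- rexp(20, 0.1)
  event <- rbinom(20, 1, 0.8)
  mc1 <- monte_carlo_p(cen, genes[1:5], time, event, n_iter = 50,
                       seed = 99)
  mc2 <- monte_carlo_p(cen, genes[1:5], time, event, n_iter = 50,
                       seed = 99)
  expect_identical(mc1, mc2)
  expect_equal(length(mc1$null), 50)
  expect_equal(mc1$p,
               (1 + sum(mc1$null >= mc1$observed)) / 51)
  expect_gt(mc1$p, 0)   # the add-one formula never yields p = 0
  expect_error(monte_carlo_p(cen, genes, time, event, 10, 1),
               "proper subset")
})
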