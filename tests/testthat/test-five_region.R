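test_that("boundary p-values reproduce the published 0.02 and 0.03", {
  t <- overall_table()
  expect_equal(round_report(boundary_pvalue(t, 1.5, "greater")), 0.02)
  expect_equal(round_report(boundary_pvalue(t, 0.5, "less")), 0.03)
  # the strict recognizable-ability boundary: normal-tail oracle
  l <- log((106 * 29) / (33 * 110))
  se <- sqrt(1 / 106 + 1 / 33 + 1 / 110 + 1 / 29)
  expect_equal(boundary_pvalue(t, 2, "greater"), pnorm((l - log(2)) / se))
  expect_equal(round(boundary_pvalue(t, 2, "greater"), 4), 0.0015)
})

test_that("p = 0.5 when the point estimate sits on the boundary", {
  t <- table2x2(20, 10, 20, 10)  # OR = (20*10)/(10*20) = 1
  expect_equal(boundary_pvalue(t, 1, "greater"), 0.5)
  expect_equal(boundary_pvalue(t, 1, "less"), 0.5)
})

test_that("composite p-values nest monotonically in the boundary", {
  set.seed(103)
  for (i in 1:50) {
    t <- random_positive_table()
    if (estimate_discrimination(t)$odds_ratio >= 1.5) next
    expect_lte(boundary_pvalue(t, 2, "greater"),
               boundary_pvalue(t, 1.5, "greater"))
  }
})

test_that("five-region CI reproduces the published (0.5, 1.49) by lower truncation", {
  ci <- five_region_ci(overall_table())
  expect_equal(round_report(as.numeric(ci)), c(0.5, 1.49))
  expect_true(attr(ci, "truncated_lower"))
  expect_false(attr(ci, "truncated_upper"))
  # untruncated Wald lower bound is below the 0.5 boundary
  expect_lt(attr(ci, "wald")[["lower"]], 0.5)
})

test_that("five-region CI equals the Wald CI when no truncation applies", {
  # balanced n=100: both outer regions rejected but Wald CI already inside
  t <- table2x2(50, 50, 50, 50)
  ci <- five_region_ci(t)
  wald <- wald_ci_or(t)
  expect_equal(as.numeric(ci), as.numeric(wald))
  expect_equal(round(as.numeric(ci), 3), c(0.574, 1.741))
  expect_lt(boundary_pvalue(t, 2, "greater"), 0.05)
  expect_lt(boundary_pvalue(t, 0.5, "less"), 0.05)
  # a Wald CI strictly inside [0.5, 2] is never altered
  set.seed(104)
  for (i in 1:50) {
    t <- random_positive_table()
    wald <- wald_ci_or(t)
    if (wald[["lower"]] <= 0.5 || wald[["upper"]] >= 2) next
    expect_equal(as.numeric(five_region_ci(t)), as.numeric(wald))
  }
})

test_that("overall five-region test concludes equivalence within [0.5, 2]", {
  fr <- five_region_test(overall_table(), lenient_upper = TRUE)
  expect_identical(unname(fr$region_verdicts[c(1, 5)]),
                   c("rejected", "rejected"))
  expect_identical(unname(fr$region_verdicts[2:4]), rep("retained", 3))
  expect_equal(round_report(as.numeric(fr$ci)), c(0.5, 1.49))
  expect_match(fr$conclusion, "equivalent within \\[0.5, 2\\]")
  # lenient upper region OR > 1.5 is also rejected (p = 0.02 < 0.05)
  expect_lt(fr$p_upper[["OR>=1.5"]], 0.05)
  expect_length(fr$p_upper, 2L)
})

test_that("tiny table is inconclusive with a CI spanning all five regions", {
  fr <- five_region_test(table2x2(2, 2, 2, 2))
  expect_true(all(fr$region_verdicts == "retained"))
  expect_lt(fr$ci[["lower"]], 0.5)
  expect_gt(fr$ci[["upper"]], 2)
  expect_identical(fr$conclusion, "inconclusive")
})

test_that("a rejected outer region never intersects the returned CI", {
  set.seed(105)
  for (i in 1:200) {
    t <- random_positive_table()
    fr <- five_region_test(t)
    if (fr$p_upper[[1]] < fr$alpha) expect_lte(fr$ci[["upper"]], 2)
    if (fr$p_lower < fr$alpha) expect_gte(fr$ci[["lower"]], 0.5)
    # CI is contained in the closure of the retained regions
    if (fr$region_verdicts[[1]] == "rejected" &&
        fr$region_verdicts[[5]] == "rejected") {
      expect_gte(fr$ci[["lower"]], 0.5)
      expect_lte(fr$ci[["upper"]], 2)
    }
  }
})

test_that("equivalence rejection rate under true OR = 1 matches the joint analytic power", {
  # with Se = Sp = 0.5 at n = 278, both boundary tests reject with
  # probability ~ 2 Phi(ln2/SE - z_0.95) - 1, SE = 4/sqrt(278)
  spec <- power_spec()
  reps <- 4000
  set.seed(106)
  cfg_seed <- sample.int(1e6, reps)
  both <- logical(reps)
  n1 <- rep(139L, reps)
  set.seed(107)
  a <- rbinom(reps, 139, 0.5); d <- rbinom(reps, 139, 0.5)
  for (i in seq_len(reps)) {
    t <- table2x2(a[i], 139 - a[i], 139 - d[i], d[i])
    both[i] <- boundary_pvalue(t, 2, "greater") < 0.05 &&
      boundary_pvalue(t, 0.5, "less") < 0.05
  }
  analytic <- 2 * pnorm(log(2) / (4 / sqrt(278)) - qnorm(0.95)) - 1
  mc_se <- sqrt(analytic * (1 - analytic) / reps)
  # 3 MC-SEs plus a small allowance for the estimated (not true) SE
  expect_lt(abs(mean(both) - analytic), 3 * mc_se + 0.01)
})

test_that("region partition validates its boundaries", {
  expect_error(region_partition(lower = 1.2), "boundaries")
  expect_error(region_partition(upper = 0.8), "boundaries")
  p <- region_partition(lower = 0.5, upper = 1.5)
  fr <- five_region_test(overall_table(), partition = p)
  expect_match(names(fr$p_upper)[1], "1.5", fixed = TRUE)
})
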