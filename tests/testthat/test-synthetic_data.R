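test_that("identical configurations give identical datasets", {
  cfg <- simulation_config(seed = 11)
  d1 <- simulate_study(cfg)
  d2 <- simulate_study(simulation_config(seed = 11))
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  d3 <- simulate_study(simulation_config(seed = 12))
  expect_false(identical(as.data.frame(d1), as.data.frame(d3)))
})

test_that("default generator emulates the study's response structure", {
  # across seeds: mean OR near 0.85, marginal 'tap' reply rate near 77.7%
  reps <- 60
  or <- tap_frac <- numeric(reps)
  for (i in seq_len(reps)) {
    ds <- simulate_study(simulation_config(seed = 200 + i))
    t <- aggregate_tables(ds)$all
    or[i] <- estimate_discrimination(t)$odds_ratio
    tap_frac[i] <- (t$a + t$c) / t$n
  }
  # log-OR is approx normal with SE ~ 0.289 per study
  expect_lt(abs(mean(log(or)) - log(0.8468)), 3 * 0.289 / sqrt(reps))
  expect_lt(abs(mean(tap_frac) - 0.777), 3 * sqrt(0.777 * 0.223 / (278 * reps)))
})

test_that("null configuration gives OR ~ 1 and AUC ~ 0.5", {
  ds <- simulate_study(simulation_config(n_total = 20000, true_se = 0.5,
                                         true_sp = 0.5, seed = 31))
  est <- estimate_discrimination(aggregate_tables(ds)$all)
  expect_lt(abs(est$auc - 0.5), 0.015)
  expect_lt(abs(log(est$odds_ratio)), 0.12)
})

test_that("bernoulli allocation gives a binomial tap-arm fraction", {
  ds <- simulate_study(simulation_config(n_total = 10000, seed = 41))
  n_tap <- sum(ds$arm == "tap")
  expect_lt(abs(n_tap / 10000 - 0.5), 3 * sqrt(0.25 / 10000))
  dsf <- simulate_study(simulation_config(n_total = 278, seed = 42,
                                          allocation = "fixed_equal"))
  expect_identical(sum(dsf$arm == "tap"), 139L)
})

test_that("large-n estimates recover the true (Se, Sp) within 0.01", {
  cfg <- simulation_config(n_total = 27800, seed = 51)
  est <- estimate_discrimination(aggregate_tables(simulate_study(cfg))$all)
  expect_lt(abs(est$se - 106 / 139), 0.01)
  expect_lt(abs(est$sp - 29 / 139), 0.01)
})

test_that("simulated covariates track the configured margins", {
  ds <- simulate_study(simulation_config(n_total = 20000, seed = 61))
  expect_lt(abs(mean(ds$gender == "male") - 118 / 278), 0.02)
  expect_lt(abs(mean(ds$position == "faculty") - 31 / 278), 0.02)
  expect_lt(abs(mean(ds$dispenser_last_month == "yes") - 189 / 278), 0.02)
  expect_lt(abs(mean(ds$fountain_before == "yes") - 26 / 278), 0.02)
})

test_that("embedded study counts are internally consistent", {
  cnt <- taipei_counts()
  t <- cnt$tables$all
  expect_identical(c(t$a, t$b, t$c, t$d), c(106L, 33L, 110L, 29L))
  expect_identical(unname(cnt$arm_sizes$gender["male", ]), c(52, 66))
  expect_identical(unname(cnt$arm_sizes$gender["female", ]), c(87, 73))
  # subgroup arm sizes sum to (139, 139) for every covariate
  for (m in cnt$arm_sizes)
    expect_identical(unname(colSums(m)), c(139, 139))
  # reported subgroup n equals the arm-size sums
  rep <- cnt$reported
  expect_identical(rep$n[rep$stratum == "all"], 278L)
  expect_identical(rep$n[rep$stratum == "faculty"],
                   as.integer(sum(cnt$arm_sizes$position["faculty", ])))
})

test_that("back-solver recovers the dispenser-no subgroup table", {
  cand <- reconstruct_subgroup_table(46, 43, 0.52, 0.42)
  expect_gt(length(cand), 0)
  hit <- vapply(cand, function(t)
    t$a == 25 && t$b == 21 && t$c == 30 && t$d == 13, logical(1))
  expect_true(any(hit))
  # independent exhaustive-enumeration oracle over all 47 x 44 cell pairs
  oracle <- 0L
  for (a in 0:46) for (d in 0:43) {
    b <- 46 - a; cc <- 43 - d
    if (b == 0 || cc == 0) next
    or <- a * d / (b * cc); auc <- (a / 46 + d / 43) / 2
    r2 <- function(x) sign(x) * floor(abs(x) * 100 + 0.5) / 100
    if (r2(or) == 0.52 && r2(auc) == 0.42) oracle <- oracle + 1L
  }
  expect_identical(length(cand), as.integer(oracle))
})

test_that("back-solver handles trivial and inconsistent targets", {
  cand <- reconstruct_subgroup_table(2, 2, 1.00, 0.50)
  expect_true(any(vapply(cand, function(t)
    all(c(t$a, t$b, t$c, t$d) == 1L), logical(1))))
  # OR < 1 with AUC > 0.5 violates the side-of-null invariant: empty set
  expect_length(reconstruct_subgroup_table(10, 10, 0.10, 0.90), 0)
  # deterministic ordering: a ascending, then d ascending
  cand2 <- reconstruct_subgroup_table(20, 20, 1.00, 0.50)
  aa <- vapply(cand2, `[[`, integer(1), "a")
  dd <- vapply(cand2, `[[`, integer(1), "d")
  expect_true(all(diff(order(aa, dd)) == 1))
})

test_that("every back-solved table satisfies the OR/AUC side-of-null invariant", {
  for (cand in list(reconstruct_subgroup_table(46, 43, 0.52, 0.42),
                    reconstruct_subgroup_table(16, 10, 0.71, 0.46),
                    reconstruct_subgroup_table(15, 16, 1.50, 0.55))) {
    expect_gt(length(cand), 0)
    for (t in cand) {
      est <- estimate_discrimination(t)
      if (est$correction_applied) next
      expect_identical(est$odds_ratio > 1, est$auc > 0.5)
    }
  }
})
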