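test_that("normality check rejects tiny samples and flags non-normal data", {
  expect_error(ks_normality(c(1, 2)), "at least 3")
  set.seed(61)
  expect_gt(ks_normality(rnorm(200)), 0.05)
  expect_lt(ks_normality(runif(1000)), 0.05)
  # tiny-sample Monte-Carlo path returns a valid p-value
  set.seed(62)
  p <- ks_normality(rnorm(4))
  expect_true(p >= 0 && p <= 1)
})

test_that("normality check is calibrated and powerful at n = 1000", {
  set.seed(63)
  p_null <- replicate(200, ks_normality(rnorm(1000)))
  rej <- mean(p_null < 0.05)
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.08)
  p_unif <- replicate(200, ks_normality(runif(1000)))
  expect_gte(mean(p_unif < 0.05), 0.95)
})

test_that("signed-rank p-values match exact enumeration", {
  # n = 5, all differences positive: p = 2 / 2^5
  x <- c(2.1, 3.0, 1.4, 2.2, 2.8); y <- x - c(1, 2, 3, 4, 5) / 10
  got <- wilcoxon_signed_rank(x, y)
  expect_equal(got$p.value, 0.0625)
  expect_equal(got$p.value, enum_signed_rank_p(x - y))

  set.seed(64)
  for (i in 1:5) {
    d <- round(rnorm(7), 2)
    d <- d[d != 0]
    if (length(d) < 5 || anyDuplicated(abs(d))) next
    got <- wilcoxon_signed_rank(d, rep(0, length(d)))
    expect_equal(got$p.value, enum_signed_rank_p(d), tolerance = 1e-12)
  }
  expect_error(wilcoxon_signed_rank(x, x), "degenerate")
})

test_that("Mann-Whitney U matches exact enumeration", {
  a <- c(1, 2, 3); b <- c(10, 11, 12)  # complete separation
  got <- mann_whitney_u(a, b)
  expect_equal(got$statistic, 0)
  expect_equal(got$p.value, 0.1)  # 2 / choose(6, 3) * ... enumerated
  expect_equal(got$p.value, enum_mann_whitney_p(a, b))

  # identical multisets: U = n m / 2 by symmetry
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$statistic, 4.5)
  expect_error(mann_whitney_u(numeric(0), b), "empty")

  set.seed(65)
  for (i in 1:5) {
    a <- round(rnorm(4), 2); b <- round(rnorm(4) + 0.5, 2)
    if (anyDuplicated(c(a, b))) next
    expect_equal(mann_whitney_u(a, b)$p.value, enum_mann_whitney_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("paired and unpaired tests hold their nominal size", {
  # 1000 replicates: the rate estimator's binomial sd is ~0.007, so the
  # band is several sd wide around the exact achievable levels (0.048 for
  # the signed-rank at n = 20, 0.049 for the U test at n = 25)
  set.seed(66)
  rej_w <- mean(replicate(1000, {
    d <- rnorm(20)
    wilcoxon_signed_rank(d, rep(0, 20))$p.value < 0.05
  }))
  expect_gte(rej_w, 0.03); expect_lte(rej_w, 0.08)

  rej_u <- mean(replicate(1000, {
    mann_whitney_u(rnorm(25), rnorm(25))$p.value < 0.05
  }))
  expect_gte(rej_u, 0.03); expect_lte(rej_u, 0.08)
})

test_that("Bonferroni thresholds follow alpha / m with 1-sf display", {
  bf <- bonferroni_alpha(0.05, 67)
  expect_equal(bf$threshold, 0.05 / 67)
  expect_equal(bf$display, 0.0007)
  expect_equal(bonferroni_alpha(0.05, 1)$threshold, 0.05)
  expect_equal(bonferroni_alpha(0.05, 5)$threshold, 0.01)
  thr <- vapply(1:20, function(m) bonferroni_alpha(0.05, m)$threshold,
                numeric(1))
  expect_true(all(diff(thr) < 0))
  expect_error(bonferroni_alpha(0.05, 0), "m must")
})

test_that("TOST equivalence reacts to margins as designed", {
  set.seed(67)
  a <- rnorm(30); b <- rnorm(30)
  expect_true(tost_equivalence(a, b, margin = 2)$equivalent)
  expect_false(tost_equivalence(a, b + 10, margin = 1)$equivalent)
  expect_error(tost_equivalence(a, b, margin = 0), "margin")

  # power grows with n when the true difference is zero
  eq_rate <- function(n) mean(replicate(100,
    tost_equivalence(rnorm(n), rnorm(n), margin = 1)$equivalent))
  set.seed(68)
  r_small <- eq_rate(8); r_big <- eq_rate(40)
  expect_gt(r_big, r_small)
  expect_gt(r_big, 0.5)
})

test_that("the group battery produces one test per cell per comparison", {
  set.seed(69)
  grid <- expand.grid(participant = paste0("P", 1:4), session = 1:2,
                      muscle = paste0("M", 1:3),
                      movement = c("A", "B"),
                      condition = c("stim", "no_stim", "control"),
                      stringsAsFactors = FALSE)
  grid$hfd <- 1.5 + rnorm(nrow(grid), 0, 0.1)
  grid$hfd[grid$condition == "no_stim"] <- grid$hfd[grid$condition ==
                                                      "no_stim"] + 1
  rep_ <- run_group_analysis(grid)
  # 3 muscles x 2 movements x 2 comparisons
  expect_equal(nrow(rep_$tests), 12L)
  expect_equal(rep_$bonferroni$m, 12L)
  expect_true(all(rep_$tests$p.value >= 0 & rep_$tests$p.value <= 1))
  # the planted stim < no-stim effect is overwhelming (8 pairs, +1 shift)
  paired <- rep_$tests[rep_$tests$comparison == "stim_vs_nostim", ]
  expect_true(all(paired$p.value < 0.05))

  # missing cells are skipped with a reason, not imputed
  grid2 <- grid[!(grid$condition == "no_stim" & grid$muscle == "M1"), ]
  rep2 <- run_group_analysis(grid2)
  expect_true(any(rep2$skipped$muscle == "M1"))
  expect_equal(nrow(rep2$tests), 10L)
})
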