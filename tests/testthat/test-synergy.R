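test_that("exact planted factorizations are recovered", {
  pl <- planted_envelope(m = 10, n = 400, k = 3, seed = 2)
  f <- nnmf(pl$E, 3, n_restarts = 30, seed = 1)
  expect_true(all(f$W >= 0) && all(f$A >= 0))
  expect_lt(f$residual / sqrt(sum(pl$E^2)), 1e-3)
  expect_equal(apply(f$W, 2, max), rep(1, 3))  # unit-max column scaling

  # full rank k = m reconstructs (essentially) everything
  r2 <- vaf_curve(pl$E + 0.01, k_range = 10, n_restarts = 10, seed = 1)
  expect_gte(r2[["10"]], 0.999)
})

test_that("the multiplicative-update objective never increases", {
  pl <- planted_envelope(m = 8, n = 200, k = 3, seed = 5, noise_sd = 0.3)
  f <- nnmf(pl$E, 3, n_restarts = 3, seed = 2, trace = TRUE)
  expect_true(all(diff(f$trace) <= 1e-9 * max(f$trace)))
})

test_that("input validation catches bad envelopes and ranks", {
  E <- matrix(runif(40), 4, 10)
  expect_error(nnmf(E - 1, 2), "non-negative")
  expect_error(nnmf(E, 0), "k must")
  expect_error(nnmf(E, 5), "k must")
})

test_that("the VAF curve saturates at the planted rank", {
  # rank-1 data: every channel proportional to one burst
  a <- generate_activations(1, 300, seed = 3)
  E1 <- matrix(runif(8, 0.2, 1), 8, 1) %*% a
  r2 <- vaf_curve(E1, 1:3, n_restarts = 10, seed = 1)
  expect_gte(r2[["1"]], 0.999)

  # exact rank-3 data with distinct bursts: R2_3 ~ 1, R2_2 clearly below
  pl <- planted_envelope(m = 10, n = 400, k = 3, seed = 7)
  r2 <- vaf_curve(pl$E, 1:4, n_restarts = 20, seed = 1)
  expect_gte(r2[["3"]], 0.999)
  expect_lt(r2[["2"]], 0.999)

  # non-decreasing within restart-noise tolerance on random envelopes
  set.seed(19)
  for (i in 1:5) {
    E <- matrix(runif(10 * 120), 10, 120)
    r2 <- vaf_curve(E, 1:6, n_restarts = 10, seed = i)
    expect_true(all(diff(r2) >= -1e-3))
  }
})

test_that("order selection follows the threshold-crossing rule", {
  expect_equal(as.integer(select_order(c(`1` = 0.5, `2` = 0.86,
                                         `3` = 0.9))), 2L)
  expect_equal(as.integer(select_order(c(`1` = 0.9, `2` = 0.95))), 1L)
  s <- select_order(c(`1` = 0.3, `2` = 0.5, `3` = 0.7))
  expect_equal(as.integer(s), 3L)
  expect_false(attr(s, "threshold_met"))
  expect_error(select_order(numeric(0)), "empty")
})

test_that("synergy_fit recovers planted structure end to end", {
  pl <- planted_envelope(m = 10, n = 500, k = 4, seed = 23,
                         noise_sd = 0.02)
  fit <- synergy_fit(pl$E, k_range = 1:6, n_restarts = 50, seed = 1)
  expect_s3_class(fit, "synergy_fit")
  expect_equal(fit$k, 4L)
  m <- match_and_reorder(fit, pl$W)
  expect_true(all(m$similarities >= 0.95))

  # channels of mutually independent bursts -> one synergy per channel
  k <- 4
  A <- generate_activations(k, 600,
                            list(centers = (1:k) * 600 / (k + 1),
                                 widths = rep(110, k),
                                 amplitudes = rep(1, k)))
  E <- diag(k) %*% A + 1e-6
  fit2 <- synergy_fit(E, k_range = 1:4, n_restarts = 20, seed = 2)
  expect_equal(fit2$k, k)

  # all-equal channels -> a single synergy
  E3 <- matrix(rep(A[1, ] + 0.01, 5), 5, byrow = TRUE)
  fit3 <- synergy_fit(E3, k_range = 1:3, n_restarts = 10, seed = 3)
  expect_equal(fit3$k, 1L)
})

test_that("synergy_fit behaves like a classed model object", {
  pl <- planted_envelope(m = 6, n = 200, k = 2, seed = 3, noise_sd = 0.05)
  rownames(pl$E) <- paste0("M", 1:6)
  fit <- synergy_fit(pl$E, k = 2, n_restarts = 10, seed = 1)
  expect_equal(dim(coef(fit)), c(6L, 2L))
  expect_equal(fitted(fit) + residuals(fit), pl$E, tolerance = 1e-12)
  expect_output(print(fit), "k = 2")
  expect_output(print(summary(fit)), "loadings")

  # predicting the training data reproduces the activations closely
  A_hat <- predict(fit)
  expect_equal(dim(A_hat), dim(fit$A))
  expect_lt(sqrt(sum((fit$W %*% A_hat - fitted(fit))^2)) /
              sqrt(sum(fitted(fit)^2)), 0.05)
  expect_error(predict(fit, newdata = -pl$E), "non-negative")
})
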