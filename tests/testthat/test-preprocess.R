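test_that("band-pass response matches the design at key frequencies", {
  fs <- 600
  t <- seq(0, 5, by = 1 / fs)
  # DC lies deep in the stopband
  dc <- bandpass_filter(rep(1, length(t)), fs, 10, 300, 6)
  expect_lt(max(abs(dc)), 0.01)
  # 50 Hz is mid-passband: unit sinusoid passes within 2%
  y50 <- bandpass_filter(sin(2 * pi * 50 * t), fs, 10, 300, 6)
  expect_equal(max(abs(y50[1000:2000])), 1, tolerance = 0.02)
  # 2 Hz is below the low edge: attenuated to < 10%
  y2 <- bandpass_filter(sin(2 * pi * 2 * t), fs, 10, 300, 6)
  expect_lt(max(abs(y2)), 0.10)
  expect_error(bandpass_filter(t, -1, 10, 300), "fs")
  expect_error(bandpass_filter(t, fs, 300, 10), "low < high")
})

test_that("filtering is linear", {
  fs <- 600
  set.seed(4)
  x <- rnorm(3000); y <- rnorm(3000)
  f <- function(s) bandpass_filter(s, fs, 10, 300, 6)
  expect_equal(f(2 * x - 3 * y), 2 * f(x) - 3 * f(y), tolerance = 1e-9)
})

test_that("median filter removes isolated spikes and keeps structure", {
  expect_equal(median_filter_artifact(c(1, 1, 9, 1, 1), 5), rep(1, 5))
  expect_equal(median_filter_artifact(rep(3.5, 20), 5), rep(3.5, 20))
  expect_error(median_filter_artifact(1:10, 4), "odd")

  # periodic 1-sample pulses on a sinusoid: envelope error halves
  fs <- 600
  t <- seq(0, 2, by = 1 / fs)
  clean <- sin(2 * pi * 30 * t)
  x <- clean
  x[seq(5, length(x), by = 20)] <- x[seq(5, length(x), by = 20)] + 10
  e_clean <- rms_envelope(clean, fs, 100)
  err <- function(sig) sqrt(mean((rms_envelope(sig, fs, 100) - e_clean)^2))
  expect_lt(err(median_filter_artifact(x, 5)), 0.5 * err(x))
})

test_that("RMS envelope has floor-window semantics and exact values", {
  fs <- 600
  expect_length(rms_envelope(rnorm(600), fs, 100), 10)  # 1 s -> 10 windows
  expect_equal(rms_envelope(rep(2, 600), fs, 100), rep(2, 10))
  # unit sinusoid with integer cycles per window: RMS = 1/sqrt(2)
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  ev <- rms_envelope(sin(2 * pi * 30 * t), fs, 100)
  expect_equal(ev, rep(1 / sqrt(2), 10), tolerance = 0.01)
  expect_error(rms_envelope(rnorm(10), fs, 100), "shorter")
})

test_that("segmentation yields exactly n_points columns and preserves shape", {
  env <- matrix(rep(seq(0, 1, length.out = 120), each = 2), nrow = 2)
  rownames(env) <- c("A", "B")
  ev <- data.frame(movement = "M1", trial = 1L, condition = "control",
                   start = 600L, end = 6000L)  # raw samples at fs=600
  tr <- segment_and_time_normalize(env, ev, fs = 600, window_ms = 100,
                                   n_points = 7000)
  expect_length(tr, 1)
  expect_equal(ncol(tr[[1]]), 7000L)

  # constant envelope stays constant
  envc <- matrix(5, 1, 120, dimnames = list("A", NULL))
  trc <- segment_and_time_normalize(envc, ev, 600, 100, 7000)
  expect_equal(unname(trc[[1]][1, ]), rep(5, 7000))

  # linear ramp stays linear (affine signals are fixed points of linear
  # interpolation)
  ramp <- matrix(seq(0, 1, length.out = 120), 1,
                 dimnames = list("A", NULL))
  trr <- segment_and_time_normalize(ramp, ev, 600, 100, 7000)
  y <- trr[[1]][1, ]
  fit <- lm(y ~ seq_along(y))
  expect_lt(max(abs(residuals(fit))), 1e-9)

  ev_bad <- ev; ev_bad$end <- 600 * 500L
  expect_error(segment_and_time_normalize(env, ev_bad, 600, 100, 7000),
               "outside envelope range")
})

test_that("amplitude normalization obeys its scope contracts", {
  m <- matrix(c(0, 2, 4, 1, 1, 2), 2, 3, byrow = TRUE,
              dimnames = list(c("A", "B"), NULL))
  attr(m, "condition") <- "control"; attr(m, "trial") <- 1L
  out <- amplitude_normalize(list(m), scope = "per_trial")[[1]]
  expect_equal(unname(out["A", ]), c(0, 0.5, 1))  # min-max formula

  # scale invariance: c * E normalizes identically
  m10 <- m * 10; attributes(m10) <- attributes(m)
  out10 <- amplitude_normalize(list(m10), scope = "per_trial")[[1]]
  expect_equal(out, out10)

  # per-muscle-session: the session max of each muscle is 1
  tr1 <- matrix(runif(20, 0, 2), 2, 10, dimnames = list(c("A", "B"), NULL))
  tr2 <- matrix(runif(20, 0, 5), 2, 10, dimnames = list(c("A", "B"), NULL))
  attr(tr1, "condition") <- "control"; attr(tr2, "condition") <- "control"
  nn <- amplitude_normalize(list(tr1, tr2), scope = "per_muscle_session")
  mx <- pmax(apply(nn[[1]], 1, max), apply(nn[[2]], 1, max))
  expect_equal(unname(mx), c(1, 1))
  expect_true(all(vapply(nn, max, numeric(1)) <= 1 + 1e-12))

  z <- matrix(0, 2, 5, dimnames = list(c("A", "B"), NULL))
  attr(z, "condition") <- "control"
  expect_error(amplitude_normalize(list(z), "per_muscle_session"),
               "all-zero")
})

test_that("ensemble averaging is the element-wise mean", {
  a <- matrix(1:6, 2, 3); b <- matrix(7:12, 2, 3)
  same <- ensemble_average(list(a, a, a))
  expect_equal(unclass(same)[1:2, 1:3], a)
  expect_equal(unclass(ensemble_average(list(matrix(0), matrix(3),
                                             matrix(6))))[1, 1], 3)
  # oracle: explicit element loop
  set.seed(8)
  trs <- replicate(3, matrix(runif(12), 3, 4), simplify = FALSE)
  got <- ensemble_average(trs)
  want <- matrix(0, 3, 4)
  for (i in 1:3) for (j in 1:4)
    want[i, j] <- mean(c(trs[[1]][i, j], trs[[2]][i, j], trs[[3]][i, j]))
  expect_equal(unclass(got)[1:3, 1:4], want)
  expect_error(ensemble_average(list(a, matrix(1, 3, 3))), "mismatch")
})

test_that("the preprocessing chain honors the protocol shape contract", {
  sim <- synthesize_session(generator_config(n_synergies = 2,
                                             trial_duration_s = 1.5,
                                             seed = 21), "control")
  pp <- preprocess_session(sim$session)
  expect_length(pp$trials, 18)
  expect_true(all(vapply(pp$trials, ncol, integer(1)) == 7000L))
  expect_true(all(vapply(pp$trials, min, numeric(1)) >= 0))
  expect_true(all(vapply(pp$trials, max, numeric(1)) <= 1 + 1e-12))
  expect_length(pp$ensembles, 6)
  expect_equal(dim(pp$ensembles[[1]]), c(10L, 7000L))
})
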