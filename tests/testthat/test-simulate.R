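test_that("planted synergy bases are unit-norm, separated and reproducible", {
  W1 <- generate_synergy_basis(10, 1, seed = 3)
  expect_equal(dim(W1), c(10L, 1L))
  expect_true(all(W1 >= 0))
  expect_equal(sum(W1^2), 1)

  W <- generate_synergy_basis(10, 4, seed = 7)
  expect_equal(sqrt(colSums(W^2)), rep(1, 4))
  cs <- crossprod(W)
  expect_true(all(cs[upper.tri(cs)] <= 0.8))  # exhaustive pair check

  expect_identical(W, generate_synergy_basis(10, 4, seed = 7))
  expect_error(generate_synergy_basis(10, 11, seed = 1), "k must")
  expect_error(generate_synergy_basis(10, 0, seed = 1), "k must")
})

test_that("raised-cosine activations are localized, non-negative bursts", {
  n <- 1200
  spec <- list(centers = n / 2, widths = 600, amplitudes = 1)
  A <- generate_activations(1, n, spec)
  expect_true(all(A >= 0))
  expect_lte(abs(which.max(A[1, ]) - 1 - n / 2), 1)  # argmax at center

  A0 <- generate_activations(1, n, list(centers = n / 2, widths = 600,
                                        amplitudes = 0))
  expect_equal(A0, matrix(0, 1, n))

  # discrete burst area vs analytic raised-cosine integral A*w/2
  for (w in c(301, 500, 799)) {
    Aw <- generate_activations(1, n, list(centers = n / 2, widths = w,
                                          amplitudes = 2))
    expect_equal(sum(Aw), 2 * w / 2, tolerance = 0.01)
  }

  expect_error(generate_activations(1, n, list(centers = 100, widths = 300,
                                               amplitudes = 1)),
               "outside")
})

test_that("synthetic sessions follow the BMCA protocol counts", {
  ctl <- synthesize_session(generator_config(n_synergies = 2,
                                             trial_duration_s = 1,
                                             seed = 5), "control")$session
  expect_equal(nrow(ctl$events), 18L)  # 1 condition x 3 trials x 6 movements
  expect_setequal(unique(ctl$events$condition), "control")

  sci <- synthesize_session(generator_config(n_synergies = 2,
                                             trial_duration_s = 1,
                                             seed = 5), "SCI")$session
  expect_equal(nrow(sci$events), 36L)  # 2 conditions x 3 trials x 6 movements
  expect_setequal(unique(sci$events$condition), c("stim", "no_stim"))
  expect_equal(sum(sci$events$condition == "stim"), 18L)
})

test_that("identical generator configs give identical sessions", {
  g <- generator_config(n_synergies = 3, noise_sd = 0.05,
                        trial_duration_s = 1, seed = 11)
  a <- synthesize_session(g, "SCI")
  b <- synthesize_session(g, "SCI")
  expect_identical(a$session$emg, b$session$emg)
  expect_identical(a$session$events, b$session$events)
  expect_identical(a$truth$W_true, b$truth$W_true)
})

test_that("noise-free sessions reproduce the planted mixture envelope", {
  g <- generator_config(n_synergies = 3, noise_sd = 0, seed = 2)
  sim <- synthesize_session(g, "control")
  pp <- preprocess_session(sim$session,
                           pipeline_config(normalization = "per_trial"))
  w <- 60  # 100 ms at 600 Hz
  for (key in names(pp$ensembles)[1:2]) {
    E <- pp$ensembles[[key]]
    mv <- attr(E, "movement")
    M <- sim$truth$W_true %*% sim$truth$A_true[[mv]]
    Menv <- t(apply(M, 1, function(r) {
      nb <- floor(length(r) / w)
      sqrt(colMeans(matrix(r[seq_len(nb * w)], w)^2))
    }))
    M7 <- t(apply(Menv, 1, function(r)
      approx(seq_along(r), r, n = ncol(E))$y))
    # channels with real planted activity (a silent channel's envelope is
    # sensor noise floor only and carries no signal to correlate)
    active <- apply(M7, 1, max) >= 0.1 * max(M7)
    cc <- vapply(which(active), function(i) cor(E[i, ], M7[i, ]),
                 numeric(1))
    expect_gte(sum(active), 5)
    expect_true(all(cc > 0.99))
  }
})

test_that("median filtering recovers artifact-hit channels", {
  art <- list(rate_hz = 31, width_ms = 2, amplitude = 8)
  g <- generator_config(n_synergies = 2, noise_sd = 0, artifact = art,
                        conditions = "stim", trial_duration_s = 2,
                        seed = 9)
  sim <- synthesize_session(g, "SCI")
  s <- sim$session
  ev <- s$events[1, ]
  idx <- (ev$start + 1):ev$end
  x <- s$emg["R-IL", idx]
  mv <- ev$movement
  clean_env <- (sim$truth$W_true %*% sim$truth$A_true[[mv]])[1, ]  # R-IL
  env_of <- function(sig) rms_envelope(sig, s$fs, 100)
  nb <- length(env_of(x))
  ref <- sqrt(colMeans(matrix(clean_env[seq_len(nb * 60)]^2, 60)))
  err_raw <- sqrt(mean((env_of(x) - ref)^2))
  err_med <- sqrt(mean((env_of(median_filter_artifact(x, 5)) - ref)^2))
  expect_lt(err_med, err_raw)  # filtering moves the envelope toward truth
})
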