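#' Configuration for the synthetic BMCA session generator
#'
#' The generator emulates the BMCA protocol: 6 voluntary movements x 3
#' trials per condition, 10-channel sEMG at 600 Hz. Muscle envelopes are
#' non-negative synergy mixtures `W A` (time-invariant synergies driven by
#' raised-cosine activation bursts) amplitude-modulating a band-limited
#' broadband carrier, plus envelope noise and optional periodic biphasic
#' stimulation-artifact pulses on flagged channels. The no-stim SCI
#' condition is simulated as noise-only envelopes (absent volitional EMG).
#'
#' @param n_synergies planted synergy count, 1..10.
#' @param noise_sd envelope noise scale as a fraction of the clean-envelope
#'   RMS (drawn per 100 ms block).
#' @param artifact `NULL`, or `list(rate_hz=, width_ms=, amplitude=)` with
#'   rate in 28-44 Hz; pulses are added on artifact channels under `stim`.
#' @param asymmetry left/right loading imbalance in `[0, 1]`; left-side
#'   rows of the planted basis are scaled by `1 - asymmetry`.
#' @param trial_duration_s trial length in seconds.
#' @param conditions optional condition subset; defaults per group.
#' @param fs sampling rate in Hz.
#' @param seed integer RNG seed; identical configs give identical sessions.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_synergies = 4L, noise_sd = 0.05,
                             artifact = NULL, asymmetry = 0,
                             trial_duration_s = 6, conditions = NULL,
                             fs = 600, seed = 1L) {
  if (n_synergies < 1L || n_synergies > 10L)
    stop("n_synergies must be in 1..10")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (trial_duration_s <= 0) stop("trial_duration_s must be > 0")
  if (asymmetry < 0 || asymmetry > 1) stop("asymmetry must be in [0, 1]")
  if (!is.null(artifact)) {
    if (!all(c("rate_hz", "width_ms", "amplitude") %in% names(artifact)))
      stop("artifact needs rate_hz, width_ms, amplitude")
    if (artifact$rate_hz < 28 || artifact$rate_hz > 44)
      stop("artifact rate_hz must be within 28-44 Hz")
  }
  if (!is.null(conditions)) {
    bad <- setdiff(conditions, c("stim", "no_stim", "control"))
    if (length(bad)) stop("unknown condition: ", paste(bad, collapse = ", "))
  }
  structure(list(n_synergies = as.integer(n_synergies), noise_sd = noise_sd,
                 artifact = artifact, asymmetry = asymmetry,
                 trial_duration_s = trial_duration_s,
                 conditions = conditions, fs = fs, seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a planted synergy basis
#'
#' Draws a non-negative muscles x k basis with unit-norm columns whose
#' pairwise cosine similarity does not exceed `max_cosine`. Each synergy is
#' given a distinct set of dominant muscles over a weak background, then
#' redrawn (deterministically) until the cosine constraint holds.
#'
#' @param n_muscles number of rows.
#' @param k number of synergies, `1 <= k <= n_muscles`.
#' @param seed integer seed; same arguments give the same matrix.
#' @param max_cosine pairwise column cosine bound.
#' @return non-negative `n_muscles` x `k` matrix, columns unit-norm.
#' @export
generate_synergy_basis <- function(n_muscles, k, seed = 1L,
                                   max_cosine = 0.8) {
  if (k < 1L || k > n_muscles)
    stop("k must satisfy 1 <= k <= n_muscles")
  set.seed(seed)
  for (attempt in 1:200) {
    W <- matrix(stats::runif(n_muscles * k, 0, 0.15), n_muscles, k)
    # distinct dominant muscles per synergy keep columns well separated
    dom <- sample(n_muscles)
    per <- max(1L, n_muscles %/% k)
    for (j in seq_len(k)) {
      lead <- dom[((j - 1L) * per + 1L):min(j * per, n_muscles)]
      W[lead, j] <- W[lead, j] + stats::runif(length(lead), 0.7, 1)
    }
    W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
    if (k == 1L) return(W)
    cs <- crossprod(W)
    if (max(abs(cs[upper.tri(cs)])) <= max_cosine) return(W)
  }
  stop("could not satisfy the pairwise cosine constraint")
}

#' Generate raised-cosine activation bursts
#'
#' Each synergy's activation is a smooth raised-cosine burst
#' `a(t) = A/2 (1 + cos(2 pi (t - c)/w))` on its support `|t - c| <= w/2`,
#' zero elsewhere. Defaults stagger the k bursts evenly across the trial.
#'
#' @param k number of rows (synergies).
#' @param n_samples trial length in samples.
#' @param burst_spec optional `list(centers=, widths=, amplitudes=)` in
#'   samples / amplitude units; every burst support must lie inside
#'   `[0, n_samples)`.
#' @param seed seed for the default +/-20% amplitude jitter.
#' @return non-negative `k` x `n_samples` matrix.
#' @export
generate_activations <- function(k, n_samples, burst_spec = NULL,
                                 seed = 1L) {
  if (n_samples <= 0) stop("n_samples must be > 0")
  if (is.null(burst_spec)) {
    set.seed(seed)
    # disjoint supports with rest gaps: planted activations stay
    # orthogonal and the envelope keeps a low mean, so every planted
    # component carries distinct centered variance and the planted order
    # is identifiable at the VAF threshold
    burst_spec <- list(centers = (seq_len(k)) * n_samples / (k + 1),
                       widths = rep(0.75 * n_samples / (k + 1), k),
                       amplitudes = stats::runif(k, 0.8, 1.2))
  }
  ctr <- burst_spec$centers; wid <- burst_spec$widths
  amp <- burst_spec$amplitudes
  if (length(ctr) != k || length(wid) != k || length(amp) != k)
    stop("burst_spec fields must have length k")
  if (any(ctr - wid / 2 < 0) || any(ctr + wid / 2 >= n_samples))
    stop("burst support outside [0, n_samples)")
  t <- seq_len(n_samples) - 1
  A <- matrix(0, k, n_samples)
  for (j in seq_len(k)) {
    on <- abs(t - ctr[j]) <= wid[j] / 2
    A[j, on] <- amp[j] / 2 * (1 + cos(2 * pi * (t[on] - ctr[j]) / wid[j]))
  }
  A
}

# band-limited (10-250 Hz) unit-carrier noise; each 100 ms window is
# rescaled to exactly unit RMS so amplitude modulation survives the RMS
# envelope stage undistorted
make_carrier <- function(n, fs, win = round(0.1 * fs)) {
  x <- bandpass_filter(stats::rnorm(n), fs, 10,
                       min(250, 0.99 * fs / 2), order = 4)
  nw <- floor(n / win)
  for (b in seq_len(nw)) {
    idx <- ((b - 1) * win + 1):(b * win)
    r <- sqrt(mean(x[idx]^2))
    if (r > 0) x[idx] <- x[idx] / r
  }
  if (nw * win < n) {
    idx <- (nw * win + 1):n
    r <- sqrt(mean(x[idx]^2))
    if (r > 0) x[idx] <- x[idx] / r
  }
  x
}

# block-constant noise field (one iid draw per 100 ms window) so the RMS
# envelope inherits it sample-for-sample
block_noise <- function(n_rows, n_samples, fs, sd, win = round(0.1 * fs)) {
  nb <- ceiling(n_samples / win)
  z <- matrix(stats::rnorm(n_rows * nb, 0, sd), n_rows, nb)
  z[, rep(seq_len(nb), each = win)[seq_len(n_samples)], drop = FALSE]
}

#' Synthesize a BMCA session with planted synergy structure
#'
#' Builds a full protocol session: 6 movements x 3 trials per condition
#' (control group: 18 trials; SCI group with stim/no-stim: 36 trials).
#' Under `stim`/`control` the clean muscle envelope of each trial is
#' `W_true A_true` (movement-specific burst gains); under `no_stim`
#' envelopes are noise-only. Raw signal = carrier noise amplitude-modulated
#' by the envelope, plus sensor noise and optional artifact pulses.
#'
#' @param config a [generator_config()].
#' @param group `"SCI"` or `"control"`.
#' @param layout a [channel_layout()].
#' @return `list(session = session_record, truth = planted_truth)`; the
#'   truth carries `W_true` (post-asymmetry, unit-norm columns), the
#'   per-movement activations `A_true`, and the seed.
#' @export
synthesize_session <- function(config = generator_config(),
                               group = c("SCI", "control"),
                               layout = channel_layout()) {
  group <- match.arg(group)
  stopifnot(inherits(config, "generator_config"))
  fs <- config$fs
  k <- config$n_synergies
  conds <- config$conditions
  if (is.null(conds))
    conds <- if (group == "SCI") c("stim", "no_stim") else "control"

  set.seed(config$seed)
  W <- generate_synergy_basis(10L, k, seed = config$seed)
  if (config$asymmetry > 0) {
    left <- grepl("^L-", layout$names)
    W[left, ] <- W[left, ] * (1 - config$asymmetry)
    W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  }

  n_t <- round(config$trial_duration_s * fs)
  gap <- round(0.5 * fs)
  movements <- bmca_movements()
  # movement-specific activations: same burst layout, mildly distinct
  # gains
  A_mov <- vector("list", 6L)
  for (v in 1:6) {
    A0 <- generate_activations(k, n_t, seed = config$seed + v)
    A_mov[[v]] <- A0 * stats::runif(k, 0.9, 1.1)
  }
  names(A_mov) <- movements
  # equalize each synergy's energy share in the normalized-envelope
  # domain (what the factorization analyzes): amplitude normalization
  # rescales muscle rows, so without this a planted component can end up
  # carrying an arbitrarily small share of the analyzed variance and the
  # planted order would not be identifiable — the structure would not
  # truly be "planted". Few fixed-point iterations suffice.
  if (k > 1L) {
    for (it in 1:4) {
      M_all <- do.call(cbind, lapply(A_mov, function(A) W %*% A))
      D <- apply(M_all, 1, max)
      D[D == 0] <- 1
      Weff <- W / D
      wn <- colSums(Weff^2)
      for (v in 1:6) {
        e <- wn * rowSums(A_mov[[v]]^2)
        A_mov[[v]] <- A_mov[[v]] * sqrt(mean(e) / e)
      }
    }
  }

  n_trials <- length(conds) * 6L * 3L
  total <- n_trials * (n_t + gap) + gap
  emg <- matrix(0, 10L, total, dimnames = list(layout$names, NULL))
  events <- vector("list", n_trials)
  art_rows <- match(layout$artifact_channels, layout$names)

  pos <- gap  # 0-based sample cursor
  e <- 0L
  for (cond in conds) for (v in 1:6) for (tr in 1:3) {
    if (cond == "no_stim") {
      env <- abs(block_noise(10L, n_t, fs, 0.05))
    } else {
      M <- W %*% A_mov[[v]]
      srms <- sqrt(mean(M^2))
      env <- pmax(M + block_noise(10L, n_t, fs, config$noise_sd * srms), 0)
    }
    raw <- env * t(vapply(1:10, function(i) make_carrier(n_t, fs),
                          numeric(n_t)))
    if (cond == "stim" && !is.null(config$artifact)) {
      a <- config$artifact
      wpulse <- max(1L, round(a$width_ms / 1000 * fs))
      period <- max(2L * wpulse, round(fs / a$rate_hz))
      starts <- seq(1L, n_t - 2L * wpulse, by = period)
      pulse <- rep(c(a$amplitude, -a$amplitude), each = wpulse)
      for (s0 in starts) {
        idx <- s0:(s0 + 2L * wpulse - 1L)
        raw[art_rows, idx] <- raw[art_rows, idx] +
          matrix(pulse, length(art_rows), length(idx), byrow = TRUE)
      }
    }
    emg[, (pos + 1):(pos + n_t)] <- raw
    e <- e + 1L
    events[[e]] <- data.frame(movement = movements[v], trial = tr,
                              condition = cond, start = pos,
                              end = pos + n_t, stringsAsFactors = FALSE)
    pos <- pos + n_t + gap
  }
  # low-level sensor noise everywhere so no channel is identically zero
  emg <- emg + matrix(stats::rnorm(length(emg), 0, 0.01), nrow(emg))

  session <- session_record(emg = emg, fs = fs,
                            events = do.call(rbind, events),
                            participant_id = sprintf("SYN-%d", config$seed),
                            session_index = 1L, group = group,
                            layout = layout)
  truth <- structure(list(W_true = W, A_true = A_mov, seed = config$seed,
                          config = config),
                     class = "planted_truth")
  list(session = session, truth = truth)
}

#' Planted basis in normalized-envelope units
#'
#' Amplitude normalization divides each muscle's envelope by its session
#' maximum, so the synergy basis expressed in the analyzed (normalized)
#' units is the planted basis with rows rescaled by those maxima. This
#' returns that effective basis — the correct reference when judging
#' recovery of the planted structure from preprocessed envelopes.
#'
#' @param truth a `planted_truth` from [synthesize_session()].
#' @return muscles x k non-negative matrix, columns unit-norm.
#' @export
truth_basis <- function(truth) {
  stopifnot(inherits(truth, "planted_truth"))
  W <- truth$W_true
  M <- do.call(cbind, lapply(truth$A_true, function(A) W %*% A))
  d <- apply(M, 1, max)
  d[d == 0] <- 1
  Weff <- W / d
  sweep(Weff, 2, sqrt(colSums(Weff^2)), "/")
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("planted synergy truth: k =", ncol(x$W_true), "seed", x$seed, "\n")
  invisible(x)
}
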