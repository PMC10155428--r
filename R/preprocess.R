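#' Zero-phase Butterworth band-pass filter
#'
#' Designs a Butterworth band-pass of total order `order` (design order
#' `order/2`, doubled by the band transformation) and applies it
#' forward-backward with odd-reflection padding (one second), giving zero
#' phase and negligible edge transients. An upper edge at or above Nyquist
#' is capped at 0.99 Nyquist: a digital band-pass to Nyquist is degenerate,
#' capping preserves the intended response.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz), > 0.
#' @param low,high band edges in Hz, `0 < low < high`.
#' @param order total filter order (even).
#' @param zero_phase apply forward-backward (default) or single-pass causal.
#' @return filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, low = 10, high = 300, order = 6,
                            zero_phase = TRUE) {
  if (fs <= 0) stop("fs must be > 0")
  if (low <= 0 || high <= low) stop("need 0 < low < high")
  if (fs <= 2 * low) stop("fs must exceed twice the low cutoff")
  if (order < 2 || order %% 2 != 0) stop("order must be an even integer >= 2")
  nyq <- fs / 2
  if (high >= nyq) high <- 0.99 * nyq
  bf <- signal::butter(order / 2, c(low, high) / nyq, type = "pass")
  if (!zero_phase)
    return(as.numeric(signal::filter(bf$b, bf$a, x)))
  filtfilt_reflect(bf$b, bf$a, x, pad = round(fs))
}

# forward-backward filtering with odd-reflection padding; pads are clipped
# to the signal length
filtfilt_reflect <- function(b, a, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad < 1L) stop("signal too short to filter")
  pre <- 2 * x[1L] - x[(pad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xx <- c(pre, x, post)
  y <- as.numeric(signal::filter(b, a, xx))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(pad + 1L):(pad + n)]
}

#' Median filter for stimulation artifacts
#'
#' Running median of odd kernel length with reflect-padded edges; removes
#' isolated spikes narrower than half the kernel while leaving smooth
#' structure intact. Applied to channels near the stimulation electrode.
#'
#' @param x numeric signal.
#' @param kernel odd integer >= 3.
#' @return filtered signal, same length as `x`.
#' @export
median_filter_artifact <- function(x, kernel = 5) {
  if (kernel %% 2 != 1 || kernel < 3) stop("kernel must be odd and >= 3")
  n <- length(x)
  h <- (kernel - 1L) %/% 2L
  if (n <= h) stop("signal shorter than the median kernel")
  xx <- c(x[(h + 1L):2L], x, x[(n - 1L):(n - h)])
  y <- stats::runmed(xx, kernel, endrule = "keep")
  as.numeric(y[(h + 1L):(h + n)])
}

#' RMS envelope over non-overlapping windows
#'
#' Root-mean-square amplitude per fixed window; the trailing incomplete
#' window is dropped (floor semantics), so the output has
#' `floor(n / window_samples)` values at an effective rate of
#' `1000 / window_ms` Hz.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param window_ms window length in milliseconds.
#' @return numeric envelope.
#' @export
rms_envelope <- function(x, fs, window_ms = 100) {
  w <- floor(fs * window_ms / 1000)
  if (w < 1) stop("window spans less than one sample")
  nwin <- floor(length(x) / w)
  if (nwin < 1) stop("signal shorter than one RMS window")
  m <- matrix(x[seq_len(nwin * w)], nrow = w)
  sqrt(colMeans(m^2))
}

#' Segment trial envelopes and time-normalize to a fixed grid
#'
#' Maps each raw-sample event window onto the envelope time base (only
#' fully contained RMS windows are used), then linearly interpolates each
#' channel onto a uniform grid of `n_points` samples including both
#' endpoints, so every trial is comparable regardless of its duration.
#'
#' @param envelope channels x envelope-samples matrix (output of
#'   [rms_envelope()] per channel).
#' @param events event table with 0-based half-open `start`/`end` raw
#'   sample indices.
#' @param fs raw sampling rate in Hz.
#' @param window_ms RMS window used to build `envelope`.
#' @param n_points output grid length (7000 by default).
#' @return list of channels x `n_points` matrices, one per event, each with
#'   attributes `movement`, `condition`, `trial`.
#' @export
segment_and_time_normalize <- function(envelope, events, fs,
                                       window_ms = 100, n_points = 7000) {
  w <- floor(fs * window_ms / 1000)
  n_env <- ncol(envelope)
  out <- vector("list", nrow(events))
  for (r in seq_len(nrow(events))) {
    i0 <- floor(events$start[r] / w) + 1L  # first fully covered window
    i1 <- floor(events$end[r] / w)        # last fully covered window
    if (i0 < 1L || i1 > n_env || i1 - i0 + 1L < 2L)
      stop(sprintf("event outside envelope range (movement %s trial %d)",
                   events$movement[r], events$trial[r]))
    seg <- envelope[, i0:i1, drop = FALSE]
    grid <- seq(1, ncol(seg), length.out = n_points)
    m <- t(apply(seg, 1, function(ch)
      stats::approx(seq_len(ncol(seg)), ch, xout = grid)$y))
    rownames(m) <- rownames(envelope)
    attr(m, "movement") <- events$movement[r]
    attr(m, "condition") <- events$condition[r]
    attr(m, "trial") <- events$trial[r]
    out[[r]] <- m
  }
  out
}

#' Amplitude-normalize segmented trials
#'
#' `per_muscle_session` (default): each muscle is divided by its maximum
#' over all trials of the same condition in the session, so the session
#' maximum of every muscle is 1. `per_trial`: min-max scaling of each
#' muscle within each trial (min -> 0, max -> 1). Both are invariant to
#' positive rescaling of the input.
#'
#' @param trials list of channels x n matrices from
#'   [segment_and_time_normalize()].
#' @param scope normalization scope.
#' @return list of normalized trials (attributes preserved).
#' @export
amplitude_normalize <- function(trials,
                                scope = c("per_muscle_session",
                                          "per_trial")) {
  scope <- match.arg(scope)
  if (scope == "per_trial") {
    return(lapply(trials, function(m) {
      out <- m
      for (i in seq_len(nrow(m))) {
        rng <- range(m[i, ])
        if (rng[2] == rng[1])
          stop("all-constant trial for muscle ", rownames(m)[i])
        out[i, ] <- (m[i, ] - rng[1]) / (rng[2] - rng[1])
      }
      attributes(out) <- attributes(m)
      out
    }))
  }
  conds <- vapply(trials, attr, "", "condition")
  out <- trials
  for (cond in unique(conds)) {
    idx <- which(conds == cond)
    mx <- Reduce(pmax, lapply(trials[idx], function(m) apply(m, 1, max)))
    if (any(mx <= 0))
      stop("all-zero session envelope for muscle ",
           paste(rownames(trials[[idx[1]]])[mx <= 0], collapse = ", "))
    for (r in idx) {
      m <- trials[[r]] / mx
      attributes(m) <- attributes(trials[[r]])
      out[[r]] <- m
    }
  }
  out
}

#' Ensemble-average repeated trials
#'
#' Element-wise mean of same-shaped trial matrices (the 3 repetitions of a
#' movement under one condition).
#'
#' @param trials list of channels x n matrices of identical shape.
#' @return the mean matrix, carrying `movement`/`condition` from the first
#'   trial and `trials` (the trial indices averaged) as attributes.
#' @export
ensemble_average <- function(trials) {
  if (!length(trials)) stop("no trials to average")
  d <- dim(trials[[1]])
  if (!all(vapply(trials, function(m) identical(dim(m), d), TRUE)))
    stop("trial shape mismatch")
  m <- Reduce(`+`, lapply(trials, unclass)) / length(trials)
  dimnames(m) <- dimnames(trials[[1]])
  attr(m, "movement") <- attr(trials[[1]], "movement")
  attr(m, "condition") <- attr(trials[[1]], "condition")
  attr(m, "trials") <- vapply(trials, function(x) {
    tr <- attr(x, "trial")
    if (is.null(tr)) NA_integer_ else as.integer(tr)
  }, integer(1))
  m
}

#' Run the full preprocessing chain on a session
#'
#' Band-pass filter each channel, median-filter the artifact-flagged
#' channels, compute RMS envelopes, segment and time-normalize every trial,
#' amplitude-normalize, and ensemble-average the trials of each
#' (movement, condition).
#'
#' @param record a [session_record()].
#' @param config a [pipeline_config()].
#' @return object of class `preprocessed_session`: `trials` (normalized
#'   per-trial matrices) and `ensembles` (one channels x n_timepoints
#'   matrix per movement/condition, named `"<movement>|<condition>"`).
#' @export
preprocess_session <- function(record, config = pipeline_config()) {
  stopifnot(inherits(record, "session_record"))
  emg <- record$emg
  filt <- t(apply(emg, 1, bandpass_filter, fs = record$fs,
                  low = config$filter_low, high = config$filter_high,
                  order = config$filter_order))
  for (ch in record$layout$artifact_channels)
    filt[ch, ] <- median_filter_artifact(filt[ch, ], config$median_kernel)
  env <- t(apply(filt, 1, rms_envelope, fs = record$fs,
                 window_ms = config$rms_window_ms))
  rownames(env) <- rownames(emg)
  trials <- segment_and_time_normalize(env, record$events, record$fs,
                                       config$rms_window_ms,
                                       config$n_timepoints)
  trials <- amplitude_normalize(trials, config$normalization)
  key <- paste(vapply(trials, attr, "", "movement"),
               vapply(trials, attr, "", "condition"), sep = "|")
  ensembles <- lapply(split(trials, key), ensemble_average)
  structure(list(trials = trials, ensembles = ensembles,
                 events = record$events, layout = record$layout,
                 participant_id = record$participant_id,
                 session_index = record$session_index,
                 group = record$group, config = config),
            class = "preprocessed_session")
}

#' @export
print.preprocessed_session <- function(x, ...) {
  cat("preprocessed BMCA session:", x$participant_id, "\n")
  cat(sprintf("  %d segmented trials, %d ensembles (%d timepoints)\n",
              length(x$trials), length(x$ensembles),
              ncol(x$ensembles[[1]])))
  invisible(x)
}
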