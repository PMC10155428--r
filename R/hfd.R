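#' Higuchi average curve lengths
#'
#' For a series `E(1..N)` and each lag `k`, builds the `k` subsampled
#' sequences starting at offsets `m = 1..k`, computes each sequence's
#' normalized length (sum of absolute increments scaled by
#' `(N-1)/(floor((N-m)/k) k)`, divided by `k`), and averages them. For
#' curves of fractal dimension `D`, `L_k` scales as `k^-D`.
#'
#' @param x numeric series of length `N >= 2 * k_max`.
#' @param k_max largest lag.
#' @return numeric vector `L[k]` for `k = 1..k_max`.
#' @export
curve_lengths <- function(x, k_max) {
  x <- as.numeric(x)
  if (k_max < 1) stop("k_max must be >= 1")
  if (length(x) < 2 * k_max)
    stop("series too short: need length >= 2 * k_max")
  as.numeric(.higuchi_lengths_cpp(x, as.integer(k_max)))
}

#' Higuchi fractal dimension of a time series
#'
#' Least-squares slope of `ln L_k` against `ln(1/k)` over `k = 2..k_max`
#' (lags with non-positive or non-finite `L_k` are excluded). Values near 1
#' indicate a smooth curve; white noise approaches 2.
#'
#' `k_max` defaults to 512: envelope trials are linearly interpolated to
#' 7000 points from ~60 RMS samples, so lags must span the interpolation
#' knot spacing (~117 samples) for roughness at the native envelope scale
#' to register in the slope.
#'
#' @param x numeric series.
#' @param k_max largest lag, `2 <= k_max < length(x) / 2`.
#' @param fit_range lags used in the slope fit (default `2:k_max`).
#' @return the fractal dimension (positive scalar).
#' @export
higuchi_fd <- function(x, k_max = 512, fit_range = NULL) {
  if (k_max < 2) stop("k_max must be >= 2")
  L <- curve_lengths(x, k_max)
  ks <- if (is.null(fit_range)) 2:k_max else fit_range
  ks <- ks[ks >= 1 & ks <= k_max]
  keep <- is.finite(L[ks]) & L[ks] > 0
  if (sum(keep) < 2)
    stop("degenerate series: fewer than 2 positive curve lengths")
  ks <- ks[keep]
  # slope of ln L_k on ln(1/k)
  lx <- log(1 / ks)
  ly <- log(L[ks])
  unname(stats::cov(lx, ly) / stats::var(lx))
}

#' Complexity table for a preprocessed session
#'
#' Higuchi fractal dimension of every muscle's time-normalized envelope,
#' computed per trial and averaged over the repetitions of each
#' (muscle, movement, condition). Degenerate trials yield `NA` (flagged in
#' `n_trials`), never an imputed value.
#'
#' @param pp a [preprocess_session()] result, or a list of trial matrices.
#' @param k_max largest Higuchi lag.
#' @return data.frame with columns `muscle`, `movement`, `condition`,
#'   `hfd`, `n_trials`; class `hfd_table`.
#' @export
complexity_table <- function(pp, k_max = 512) {
  trials <- if (inherits(pp, "preprocessed_session")) pp$trials else pp
  rows <- list()
  for (m in trials) {
    mv <- attr(m, "movement"); cd <- attr(m, "condition")
    for (i in seq_len(nrow(m))) {
      v <- tryCatch(higuchi_fd(m[i, ], k_max), error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <-
        data.frame(muscle = rownames(m)[i], movement = mv, condition = cd,
                   hfd = v, stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, rows)
  agg <- stats::aggregate(hfd ~ muscle + movement + condition, long,
                          function(v) mean(v, na.rm = TRUE),
                          na.action = stats::na.pass)
  ntr <- stats::aggregate(hfd ~ muscle + movement + condition, long,
                          function(v) sum(is.finite(v)),
                          na.action = stats::na.pass)
  agg$n_trials <- ntr$hfd
  agg$hfd[agg$n_trials == 0] <- NA_real_
  agg <- agg[order(agg$condition, agg$movement, agg$muscle), ]
  rownames(agg) <- NULL
  class(agg) <- c("hfd_table", "data.frame")
  agg
}
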