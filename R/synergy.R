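#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative envelope matrix `E` (muscles x time) as
#' `E ~ W A` with `W >= 0` (muscles x k synergy loadings) and `A >= 0`
#' (k x time activation coefficients), minimizing the Frobenius residual
#' with the classic multiplicative update rule. The objective is
#' non-increasing at every iteration; `n_restarts` random initializations
#' guard against local optima and the best (lowest-residual) factorization
#' is returned, ties broken by restart index. Columns of `W` are normalized
#' to unit maximum with the scale absorbed into `A`.
#'
#' @param E non-negative numeric matrix.
#' @param k factorization rank, `1 <= k <= nrow(E)`.
#' @param n_restarts random restarts (100 by default).
#' @param seed integer seed; results are deterministic given the seed.
#' @param tol relative residual-improvement convergence threshold.
#' @param max_iter iteration cap for the final refinement.
#' @param screen_tol,screen_iter coarse tolerance and iteration cap used to
#'   screen the restarts; only the best restart is refined to full
#'   tolerance (the usual replicated-NMF economy; screening does not
#'   change which basin wins, only how far losing restarts are run).
#' @param trace record the per-iteration residual (runs every restart at
#'   full tolerance so the trace is a faithful single-run objective).
#' @return list with `W`, `A`, `residual` (Frobenius), `iterations`, `k`,
#'   and `trace` when requested.
#' @export
nnmf <- function(E, k, n_restarts = 100, seed = 1L, tol = 1e-6,
                 max_iter = 1000, screen_tol = 1e-4, screen_iter = 100,
                 trace = FALSE) {
  E <- as.matrix(E)
  if (any(!is.finite(E))) stop("E must be finite")
  if (any(E < 0)) stop("E must be non-negative")
  m <- nrow(E); n <- ncol(E)
  if (k < 1 || k > m) stop("k must satisfy 1 <= k <= nrow(E)")
  # keep multiplicative updates well-defined on zero rows/columns
  if (any(rowSums(E) == 0) || any(colSums(E) == 0))
    E <- E + .Machine$double.eps
  scale <- mean(E)
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    W0 <- matrix(scale * stats::runif(m * k), m, k)
    A0 <- matrix(stats::runif(k * n), k, n)
    fit <- if (trace)
      .nnmf_mu_cpp(E, W0, A0, as.integer(max_iter), tol, TRUE)
    else
      .nnmf_mu_cpp(E, W0, A0, as.integer(screen_iter), screen_tol, FALSE)
    if (is.null(best) || fit$residual < best$residual) best <- fit
  }
  if (!trace) {
    # refine the winning restart to full tolerance
    it0 <- best$iterations
    best <- .nnmf_mu_cpp(E, best$W, best$A, as.integer(max_iter), tol,
                         FALSE)
    best$iterations <- best$iterations + it0
  }
  # unit-max columns of W, scale into A
  cmax <- apply(best$W, 2, max)
  cmax[cmax == 0] <- 1
  W <- sweep(best$W, 2, cmax, "/")
  A <- best$A * cmax
  rownames(W) <- rownames(E)
  out <- list(W = W, A = A, residual = best$residual,
              iterations = best$iterations, k = as.integer(k))
  if (trace) out$trace <- best$trace
  out
}

# variance accounted for by a reconstruction.
# "centered": 1 - SSE / SST with SST centered on the original data (the
# conventional definition). "literal": the printed variant that normalizes
# by the per-muscle-centered sum of squares of the reconstruction itself —
# kept for comparison; it can exceed 1 and need not be monotone in k.
r2_reconstruction <- function(E, R, method = c("centered", "literal")) {
  method <- match.arg(method)
  sse <- sum((E - R)^2)
  if (method == "centered") {
    sst <- sum((E - mean(E))^2)
  } else {
    sst <- sum((R - rowMeans(R))^2)
  }
  1 - sse / sst
}

#' Variance-accounted-for curve over candidate synergy counts
#'
#' Runs [nnmf()] at each rank in `k_range` and reports the explained
#' variance `R^2_k` of the rank-k reconstruction. With enough restarts the
#' curve is non-decreasing in k (up to restart noise ~1e-3).
#'
#' @param E non-negative muscles x time matrix.
#' @param k_range candidate ranks (default 1..10).
#' @param n_restarts,seed,tol,max_iter passed to [nnmf()]; each rank uses
#'   the deterministic sub-seed `seed + k`.
#' @param r2_method `"centered"` (default) or `"literal"`.
#' @return named numeric vector of `R^2_k`.
#' @export
vaf_curve <- function(E, k_range = 1:10, n_restarts = 100, seed = 1L,
                      tol = 1e-6, max_iter = 1000,
                      r2_method = c("centered", "literal")) {
  r2_method <- match.arg(r2_method)
  r2 <- vapply(k_range, function(k) {
    fit <- nnmf(E, k, n_restarts = n_restarts, seed = seed + k,
                tol = tol, max_iter = max_iter)
    r2_reconstruction(E, fit$W %*% fit$A, r2_method)
  }, numeric(1))
  names(r2) <- as.character(k_range)
  r2
}

#' Select the synergy count from a VAF curve
#'
#' Smallest k whose `R^2_k` reaches the threshold (85% by default). If no
#' k qualifies, the largest candidate is returned with attribute
#' `threshold_met = FALSE`.
#'
#' @param r2_curve named numeric vector from [vaf_curve()].
#' @param threshold VAF threshold in (0, 1).
#' @return selected k (integer) with attributes `threshold_met` and
#'   `threshold`.
#' @export
select_order <- function(r2_curve, threshold = 0.85) {
  if (!length(r2_curve)) stop("empty R^2 curve")
  ks <- as.integer(names(r2_curve))
  if (anyNA(ks)) ks <- seq_along(r2_curve)
  hit <- which(r2_curve >= threshold)
  if (length(hit)) {
    k <- ks[hit[1L]]; met <- TRUE
  } else {
    k <- max(ks); met <- FALSE
  }
  structure(as.integer(k), threshold_met = met, threshold = threshold)
}

#' Fit the muscle synergy model to an envelope matrix
#'
#' The central estimator: given a preprocessed, amplitude-normalized,
#' ensemble-averaged envelope matrix (muscles x time), computes the VAF
#' curve over `k_range`, selects the synergy count at the VAF threshold,
#' and refits [nnmf()] at the selected rank. Supplying `k` skips the
#' model-order scan.
#'
#' @param E non-negative muscles x time matrix.
#' @param k fixed synergy count, or `NULL` to select from the VAF curve.
#' @param k_range candidate ranks for the scan.
#' @param vaf_threshold VAF threshold for [select_order()].
#' @param n_restarts,seed,tol,max_iter NNMF settings (see [nnmf()]).
#' @param r2_method VAF definition (see [vaf_curve()]).
#' @return object of class `synergy_fit`: `W`, `A`, `k`, `r2_curve`,
#'   `r2`, `residual`, `threshold_met`, plus the data for method support.
#' @seealso [coef.synergy_fit()], [predict.synergy_fit()],
#'   [plot.synergy_fit()]
#' @export
synergy_fit <- function(E, k = NULL, k_range = 1:10, vaf_threshold = 0.85,
                        n_restarts = 100, seed = 1L, tol = 1e-6,
                        max_iter = 1000,
                        r2_method = c("centered", "literal")) {
  r2_method <- match.arg(r2_method)
  E <- as.matrix(E)
  curve <- NULL; met <- TRUE
  if (is.null(k)) {
    curve <- vaf_curve(E, k_range, n_restarts, seed, tol, max_iter,
                       r2_method)
    sel <- select_order(curve, vaf_threshold)
    k <- as.integer(sel)
    met <- attr(sel, "threshold_met")
  }
  fit <- nnmf(E, k, n_restarts = n_restarts, seed = seed + 1000L,
              tol = tol, max_iter = max_iter)
  R <- fit$W %*% fit$A
  structure(list(W = fit$W, A = fit$A, k = fit$k,
                 r2_curve = curve,
                 r2 = r2_reconstruction(E, R, r2_method),
                 residual = fit$residual, threshold = vaf_threshold,
                 threshold_met = met, r2_method = r2_method,
                 data = E, movement = attr(E, "movement"),
                 condition = attr(E, "condition"),
                 call = match.call()),
            class = "synergy_fit")
}

#' @export
print.synergy_fit <- function(x, ...) {
  cat("Muscle synergy model (NNMF)\n")
  if (!is.null(x$movement))
    cat("  movement:", x$movement, " condition:", x$condition, "\n")
  cat(sprintf("  %d muscles x %d timepoints, k = %d synergies%s\n",
              nrow(x$W), ncol(x$A), x$k,
              if (x$threshold_met) ""
              else " (VAF threshold unmet; max k reported)"))
  cat(sprintf("  R^2 = %.4f (threshold %.2f), Frobenius residual %.4g\n",
              x$r2, x$threshold, x$residual))
  invisible(x)
}

#' @export
summary.synergy_fit <- function(object, ...) {
  out <- list(k = object$k, r2 = object$r2, r2_curve = object$r2_curve,
              threshold = object$threshold,
              threshold_met = object$threshold_met,
              loadings = object$W, residual = object$residual)
  class(out) <- "summary.synergy_fit"
  out
}

#' @export
print.summary.synergy_fit <- function(x, ...) {
  cat("Muscle synergy model: k =", x$k, "\n")
  if (!is.null(x$r2_curve)) {
    cat("VAF curve:\n")
    print(round(x$r2_curve, 4))
  }
  cat(sprintf("Selected-model R^2 = %.4f (threshold %.2f, %s)\n", x$r2,
              x$threshold, if (x$threshold_met) "met" else "unmet"))
  cat("Synergy loadings W:\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' @export
coef.synergy_fit <- function(object, ...) object$W

#' @export
fitted.synergy_fit <- function(object, ...) object$W %*% object$A

#' @export
residuals.synergy_fit <- function(object, ...)
  object$data - fitted(object)

#' Project new envelope data onto fitted synergies
#'
#' Holds the fitted loadings `W` fixed and estimates non-negative
#' activation coefficients for `newdata` by multiplicative updates on `A`
#' alone.
#'
#' @param object a [synergy_fit()].
#' @param newdata non-negative muscles x time matrix (same muscles);
#'   defaults to the training data.
#' @param max_iter,tol update settings.
#' @param ... unused.
#' @return k x time activation matrix.
#' @export
predict.synergy_fit <- function(object, newdata = NULL, max_iter = 500,
                                tol = 1e-8, ...) {
  E <- if (is.null(newdata)) object$data else as.matrix(newdata)
  if (any(E < 0)) stop("newdata must be non-negative")
  if (nrow(E) != nrow(object$W)) stop("newdata muscle count mismatch")
  W <- object$W
  A <- matrix(mean(E), object$k, ncol(E))
  WtE <- crossprod(W, E); WtW <- crossprod(W)
  prev <- Inf
  for (i in seq_len(max_iter)) {
    A <- A * WtE / (WtW %*% A + 1e-12)
    res <- sqrt(sum((E - W %*% A)^2))
    if (prev - res < tol * max(prev, 1e-12)) break
    prev <- res
  }
  A
}

#' Plot a fitted synergy model
#'
#' Three panels: the VAF curve with the selection threshold, the synergy
#' loading vectors (barplots), and the activation coefficients over the
#' normalized task time.
#'
#' @param x a [synergy_fit()].
#' @param ... unused.
#' @export
plot.synergy_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1 + (!is.null(x$r2_curve)) + 1, 1),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  if (!is.null(x$r2_curve)) {
    graphics::plot(as.integer(names(x$r2_curve)), x$r2_curve, type = "b",
                   xlab = "number of synergies k", ylab = expression(R^2),
                   main = "variance accounted for", ylim = c(0, 1))
    graphics::abline(h = x$threshold, lty = 2)
    graphics::abline(v = x$k, col = 2, lty = 3)
  }
  graphics::barplot(t(x$W), beside = TRUE, names.arg = rownames(x$W),
                    las = 2, main = sprintf("synergy loadings (k = %d)",
                                            x$k),
                    legend.text = paste0("S", seq_len(x$k)),
                    args.legend = list(x = "topright", bty = "n"))
  graphics::matplot(seq(0, 100, length.out = ncol(x$A)), t(x$A),
                    type = "l", lty = 1, xlab = "task completion (%)",
                    ylab = "activation", main = "activation coefficients")
  invisible(x)
}
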