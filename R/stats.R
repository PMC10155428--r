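#' Composite normality check (Lilliefors)
#'
#' Kolmogorov-Smirnov style test of normality with mean and SD estimated
#' from the sample (Lilliefors correction, which keeps the type-I error at
#' its nominal level; the naive KS test against a fitted normal is badly
#' conservative). For n of 3-4, below the range of the analytic p-value
#' approximation, a Monte-Carlo null of the same statistic is used.
#'
#' @param x numeric sample, n >= 3.
#' @param mc_reps Monte-Carlo replicates for tiny samples.
#' @return p-value.
#' @export
ks_normality <- function(x, mc_reps = 2000) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (n >= 5) return(unname(nortest::lillie.test(x)$p.value))
  dstat <- function(v) {
    z <- sort((v - mean(v)) / stats::sd(v))
    p <- stats::pnorm(z)
    i <- seq_along(z)
    max(p - (i - 1) / length(z), i / length(z) - p)
  }
  d0 <- dstat(x)
  null <- vapply(seq_len(mc_reps),
                 function(i) dstat(stats::rnorm(n)), numeric(1))
  mean(null >= d0)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are discarded before ranking; the p-value is exact for
#' up to 25 nonzero pairs (normal approximation above, or in the presence
#' of ties), two-sided.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return list: `statistic` (V, the positive-rank sum), `p.value`, `n`
#'   (nonzero pairs).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  if (!length(d)) stop("degenerate: all paired differences are zero")
  n <- length(d)
  if (n < 5) stop("need at least 5 nonzero paired differences")
  ht <- suppressWarnings(
    stats::wilcox.test(d, exact = (n <= 25), correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value, n = n)
}

#' Mann-Whitney U test for two independent groups
#'
#' Exact two-sided p for small tie-free samples, tie-corrected normal
#' approximation otherwise. The statistic U counts pairs `(a_i, b_j)` with
#' `a_i > b_j` (plus half-ties).
#'
#' @param a,b numeric samples.
#' @return list: `statistic` (U), `p.value`, `n` (the two sample sizes).
#' @export
mann_whitney_u <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty group")
  ht <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       n = c(length(a), length(b)))
}

#' Bonferroni family-wise threshold
#'
#' Per-test significance threshold `alpha / m`, with a display value
#' rounded to one significant figure (the convention used when reporting a
#' corrected threshold, e.g. 0.05 over 67 tests -> 0.000746 displayed as
#' 0.0007).
#'
#' @param alpha family-wise level in (0, 1).
#' @param m number of tests, >= 1.
#' @return list: `threshold`, `display`, `alpha`, `m`.
#' @export
bonferroni_alpha <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  thr <- alpha / m
  list(threshold = thr, display = signif(thr, 1), alpha = alpha,
       m = as.integer(m))
}

#' Independent-groups equivalence test (TOST)
#'
#' Two one-sided Welch t-tests of the mean difference against the margins
#' `-margin` and `+margin`; the groups are declared equivalent when both
#' one-sided p-values fall below `alpha`.
#'
#' @param a,b numeric samples, n >= 3 each.
#' @param margin equivalence margin (> 0), in the units of the data.
#' @param alpha significance level per one-sided test.
#' @return list: `equivalent`, `p.value` (the larger one-sided p),
#'   `p_lower`, `p_upper`, `diff`, `df`.
#' @export
tost_equivalence <- function(a, b, margin, alpha = 0.05) {
  if (margin <= 0) stop("margin must be > 0")
  if (length(a) < 3 || length(b) < 3) stop("need n >= 3 per group")
  d <- mean(a) - mean(b)
  va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
  se <- sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p_lower <- stats::pt((d + margin) / se, df, lower.tail = FALSE)
  p_upper <- stats::pt((d - margin) / se, df, lower.tail = TRUE)
  p <- max(p_lower, p_upper)
  list(equivalent = (p < alpha), p.value = p, p_lower = p_lower,
       p_upper = p_upper, diff = d, df = df)
}

#' Group statistics battery over complexity tables
#'
#' Runs, per (muscle, movement) cell: a paired Wilcoxon signed-rank test
#' of stim vs no-stim (paired on participant and session) and/or an
#' unpaired Mann-Whitney U test of control vs stim, then attaches the
#' Bonferroni-corrected threshold over the family of tests actually run
#' (or a caller-specified family size). Optionally adds the TOST
#' equivalence test on end-of-study R-squared values.
#'
#' @param hfd data.frame with columns `participant`, `session`, `muscle`,
#'   `movement`, `condition`, `hfd` (one row per trial-averaged cell).
#' @param comparisons subset of `"stim_vs_nostim"`, `"control_vs_stim"`.
#' @param alpha family-wise level.
#' @param m family size for the Bonferroni threshold; default = number of
#'   comparisons successfully run.
#' @param r2_sci,r2_control optional R-squared samples for the equivalence
#'   test.
#' @param r2_margin equivalence margin on R-squared (absolute).
#' @return object of class `stats_report`: `tests` (one row per cell),
#'   `bonferroni`, `equivalence`, `skipped`.
#' @export
run_group_analysis <- function(hfd,
                               comparisons = c("stim_vs_nostim",
                                               "control_vs_stim"),
                               alpha = 0.05, m = NULL,
                               r2_sci = NULL, r2_control = NULL,
                               r2_margin = 0.05) {
  comparisons <- match.arg(comparisons, several.ok = TRUE)
  cells <- unique(hfd[, c("muscle", "movement")])
  rows <- list(); skipped <- list()
  add_skip <- function(cmp, mu, mv, why)
    skipped[[length(skipped) + 1L]] <<-
      data.frame(comparison = cmp, muscle = mu, movement = mv,
                 reason = why, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(cells))) {
    mu <- cells$muscle[r]; mv <- cells$movement[r]
    cell <- hfd[hfd$muscle == mu & hfd$movement == mv, ]
    if ("stim_vs_nostim" %in% comparisons) {
      st <- cell[cell$condition == "stim", ]
      ns <- cell[cell$condition == "no_stim", ]
      key <- c("participant", "session")
      mrg <- merge(st, ns, by = key, suffixes = c(".stim", ".nostim"))
      mrg <- mrg[is.finite(mrg$hfd.stim) & is.finite(mrg$hfd.nostim), ]
      if (nrow(mrg) < 5) {
        add_skip("stim_vs_nostim", mu, mv, "fewer than 5 complete pairs")
      } else {
        ht <- tryCatch(wilcoxon_signed_rank(mrg$hfd.stim, mrg$hfd.nostim),
                       error = function(e) NULL)
        if (is.null(ht)) add_skip("stim_vs_nostim", mu, mv,
                                  "degenerate pairs")
        else rows[[length(rows) + 1L]] <-
          data.frame(comparison = "stim_vs_nostim", muscle = mu,
                     movement = mv, test = "wilcoxon_signed_rank",
                     statistic = ht$statistic, p.value = ht$p.value,
                     n = ht$n, stringsAsFactors = FALSE)
      }
    }
    if ("control_vs_stim" %in% comparisons) {
      ctl <- cell$hfd[cell$condition == "control" & is.finite(cell$hfd)]
      st <- cell$hfd[cell$condition == "stim" & is.finite(cell$hfd)]
      if (!length(ctl) || !length(st)) {
        add_skip("control_vs_stim", mu, mv, "missing group")
      } else {
        ht <- mann_whitney_u(ctl, st)
        rows[[length(rows) + 1L]] <-
          data.frame(comparison = "control_vs_stim", muscle = mu,
                     movement = mv, test = "mann_whitney_u",
                     statistic = ht$statistic, p.value = ht$p.value,
                     n = sum(ht$n), stringsAsFactors = FALSE)
      }
    }
  }
  tests <- if (length(rows)) do.call(rbind, rows) else
    data.frame(comparison = character(), muscle = character(),
               movement = character(), test = character(),
               statistic = numeric(), p.value = numeric(), n = integer())
  if (is.null(m)) m <- max(1L, nrow(tests))
  bf <- bonferroni_alpha(alpha, m)
  tests$significant <- tests$p.value < bf$threshold
  eq <- NULL
  if (!is.null(r2_sci) && !is.null(r2_control))
    eq <- tost_equivalence(r2_sci, r2_control, margin = r2_margin,
                           alpha = alpha)
  structure(list(tests = tests, bonferroni = bf, equivalence = eq,
                 skipped = if (length(skipped)) do.call(rbind, skipped)
                           else NULL),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat("group statistics report\n")
  cat(sprintf("  %d tests, Bonferroni threshold %.3g (display %g) over m = %d\n",
              nrow(x$tests), x$bonferroni$threshold, x$bonferroni$display,
              x$bonferroni$m))
  if (nrow(x$tests)) {
    for (cmp in unique(x$tests$comparison)) {
      sub <- x$tests[x$tests$comparison == cmp, ]
      cat(sprintf("  %s: %d/%d cells significant\n", cmp,
                  sum(sub$significant), nrow(sub)))
    }
  }
  if (!is.null(x$equivalence))
    cat(sprintf("  R^2 equivalence: %s (p = %.4g)\n",
                if (x$equivalence$equivalent) "equivalent"
                else "not equivalent", x$equivalence$p.value))
  if (!is.null(x$skipped))
    cat("  skipped:", nrow(x$skipped), "cells\n")
  invisible(x)
}
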