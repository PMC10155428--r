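#' Cosine similarity between two loading vectors
#'
#' `R = <a, b> / (||a|| ||b||)`; for non-negative synergy loadings R lies
#' in `[0, 1]`, with 1 meaning identical direction and 0 independence.
#' Invariant to positive rescaling of either vector.
#'
#' @param a,b numeric vectors of equal length with positive norm.
#' @return the cosine similarity.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("undefined similarity: zero vector")
  sum(a * b) / (na * nb)
}

# all pairwise column cosines between two loading matrices
cosine_matrix <- function(Wa, Wb) {
  Wa <- sweep(Wa, 2, sqrt(colSums(Wa^2)), "/")
  Wb <- sweep(Wb, 2, sqrt(colSums(Wb^2)), "/")
  crossprod(Wa, Wb)
}

# extract the loading matrix from a synergy_fit or plain matrix
loadings_of <- function(x) {
  if (inherits(x, "synergy_fit")) x$W else as.matrix(x)
}

#' Match synergies to a template by optimal assignment
#'
#' Finds the one-to-one pairing of template synergies to `set` synergies
#' maximizing the total cosine similarity (exact search; synergy counts
#' are at most the 10 recorded muscles). The returned permutation `p`
#' means template synergy `i` matches set synergy `p[i]`.
#'
#' @param set,template [synergy_fit()] objects or loading matrices with
#'   equal synergy counts.
#' @return list: `permutation`, `similarities` (matched cosine per
#'   template synergy), `total`, and the reordered `W` (and `A` when `set`
#'   is a fit).
#' @export
match_and_reorder <- function(set, template) {
  Wt <- loadings_of(template); Ws <- loadings_of(set)
  if (ncol(Wt) != ncol(Ws))
    stop("synergy count mismatch between set and template")
  S <- cosine_matrix(Wt, Ws)
  res <- .best_assignment_cpp(S)
  perm <- as.integer(res$assignment)
  out <- list(permutation = perm,
              similarities = S[cbind(seq_along(perm), perm)],
              total = res$total,
              W = Ws[, perm, drop = FALSE])
  if (inherits(set, "synergy_fit"))
    out$A <- set$A[perm, , drop = FALSE]
  out
}

#' Choose the template participant
#'
#' Scores each candidate set by the summed optimal-assignment cosine
#' similarity to every other set and returns the index of the maximizer
#' (ties broken by the lowest index) — the participant whose synergies
#' correlate best with the rest of the cohort.
#'
#' @param sets list of >= 2 [synergy_fit()] objects or loading matrices,
#'   all with the same synergy count.
#' @return integer index into `sets`.
#' @export
choose_template <- function(sets) {
  if (length(sets) < 2L) stop("need at least 2 synergy sets")
  ks <- vapply(sets, function(s) ncol(loadings_of(s)), integer(1))
  if (length(unique(ks)) != 1L)
    stop("synergy sets differ in k; re-extract at a common k first")
  n <- length(sets)
  score <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    score[i] <- score[i] + match_and_reorder(sets[[j]], sets[[i]])$total
  }
  which.max(score)  # ties -> lowest index
}

#' Zero-lag cross-correlation of activation coefficients
#'
#' Mean-centered, norm-scaled correlation at lag zero (Pearson), so values
#' lie in `[-1, 1]`.
#'
#' @param a,b numeric activation rows of equal length, non-constant.
#' @return the correlation.
#' @export
activation_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("rows must have equal length")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: constant activation row")
  stats::cor(a, b)
}

#' Match synergies across a cohort
#'
#' Chooses the template participant, reorders every other participant's
#' synergies against it by optimal assignment, and reports matched cosine
#' similarities of the loadings and zero-lag correlations of the
#' activation coefficients.
#'
#' @param sets list of [synergy_fit()] objects with a common k.
#' @param template_id optional fixed template index (default: chosen by
#'   [choose_template()]).
#' @return object of class `synergy_match`: `template_id`, `permutations`,
#'   `similarities` (sets x k matched cosines), `activation_correlations`.
#' @export
compare_synergies <- function(sets, template_id = NULL) {
  if (is.null(template_id)) template_id <- choose_template(sets)
  template <- sets[[template_id]]
  k <- ncol(loadings_of(template))
  n <- length(sets)
  perms <- matrix(NA_integer_, n, k)
  sims <- matrix(NA_real_, n, k)
  acors <- matrix(NA_real_, n, k)
  for (i in seq_len(n)) {
    m <- match_and_reorder(sets[[i]], template)
    perms[i, ] <- m$permutation
    sims[i, ] <- m$similarities
    if (!is.null(m$A) && inherits(template, "synergy_fit"))
      acors[i, ] <- vapply(seq_len(k), function(j)
        activation_correlation(template$A[j, ], m$A[j, ]), numeric(1))
  }
  nm <- names(sets)
  if (is.null(nm)) nm <- paste0("set", seq_len(n))
  dimnames(sims) <- list(nm, paste0("S", seq_len(k)))
  dimnames(acors) <- dimnames(sims)
  structure(list(template_id = template_id, permutations = perms,
                 similarities = sims, activation_correlations = acors),
            class = "synergy_match")
}

#' @export
print.synergy_match <- function(x, ...) {
  cat("synergy matching: template =", rownames(x$similarities)[x$template_id],
      "\n")
  cat("matched cosine similarities:\n")
  print(round(x$similarities, 3))
  invisible(x)
}
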