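# Independent brute-force oracles used to validate the fast implementations.
# These deliberately mirror the defining formulas with plain loops and stay
# independent of the package's code paths.

# Higuchi average curve length, literal double loop over lag k and offset m
naive_curve_lengths <- function(x, k_max) {
  N <- length(x)
  L <- numeric(k_max)
  for (k in seq_len(k_max)) {
    acc <- 0
    for (m in seq_len(k)) {
      ni <- floor((N - m) / k)
      if (ni < 1) next
      s <- 0
      for (i in seq_len(ni))
        s <- s + abs(x[m + i * k] - x[m + (i - 1) * k])
      acc <- acc + (1 / k) * s * (N - 1) / (ni * k)
    }
    L[k] <- acc / k
  }
  L
}

# chart-weighted segment activity, literal double loop over segments/samples
naive_spinal_map <- function(E, K, n_j) {
  S <- matrix(0, ncol(K), ncol(E))
  for (j in seq_len(ncol(K))) {
    for (s in seq_len(ncol(E))) {
      acc <- 0
      for (i in seq_len(nrow(E))) acc <- acc + K[i, j] * E[i, s]
      S[j, s] <- acc / n_j[j]
    }
  }
  rownames(S) <- colnames(K)
  S
}

# exhaustive assignment over all permutations, maximizing total score
naive_best_assignment <- function(S) {
  k <- nrow(S)
  perms <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
  perms <- perms[apply(perms, 1, function(p) !anyDuplicated(p)), ,
                 drop = FALSE]
  tot <- apply(perms, 1, function(p) sum(S[cbind(seq_len(k), p)]))
  list(assignment = unname(perms[which.max(tot), ]), total = max(tot))
}

# exact two-sided signed-rank p-value by enumerating all sign patterns
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  p_low <- mean(v_all <= v_obs)
  p_high <- mean(v_all >= v_obs)
  min(1, 2 * min(p_low, p_high))
}

# exact two-sided Mann-Whitney p-value by enumerating group labelings
enum_mann_whitney_p <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  idx <- utils::combn(length(pool), na)
  u_of <- function(av, bv) sum(outer(av, bv, ">")) +
    0.5 * sum(outer(av, bv, "=="))
  u_obs <- u_of(a, b)
  mu <- na * length(b) / 2
  u_all <- apply(idx, 2, function(i) u_of(pool[i], pool[-i]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# small planted-structure envelope matrix for factorization tests
planted_envelope <- function(m = 10, n = 400, k = 3, seed = 1,
                             noise_sd = 0) {
  set.seed(seed)
  W <- generate_synergy_basis(m, k, seed = seed)
  A <- generate_activations(k, n, seed = seed)
  E <- W %*% A
  if (noise_sd > 0)
    E <- pmax(E + matrix(rnorm(m * n, 0, noise_sd * sd(E)), m, n), 0)
  list(E = E, W = W, A = A)
}
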