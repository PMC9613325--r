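# Independent brute-force oracles, kept deliberately separate from the
# package implementations they check.

# Benjamini-Hochberg step-up from the definition: sort, p_(i) * n / i,
# cumulative minimum from the largest rank down, clamp at 1.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  if (n > 1) for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# Tie-corrected Kruskal-Wallis H from the classic formula:
# H = [12 / (N(N+1)) * sum R_i^2 / n_i - 3(N+1)] / C with
# C = 1 - sum(t^3 - t) / (N^3 - N).
brute_kw_h <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  Rs <- tapply(r, groups, sum)
  ns <- tapply(r, groups, length)
  h <- 12 / (N * (N + 1)) * sum(Rs^2 / ns) - 3 * (N + 1)
  tt <- table(values)
  C <- 1 - sum(tt^3 - tt) / (N^3 - N)
  if (C == 0) return(0)
  h / C
}

# Dunn z for groups a vs b, explicit formula with tie correction.
brute_dunn_z <- function(values, groups, a, b) {
  r <- rank(values)
  N <- length(values)
  tt <- table(values)
  tie <- sum(tt^3 - tt) / (12 * (N - 1))
  ra <- mean(r[groups == a]); rb <- mean(r[groups == b])
  na <- sum(groups == a); nb <- sum(groups == b)
  (ra - rb) / sqrt((N * (N + 1) / 12 - tie) * (1 / na + 1 / nb))
}

# CLR scores by explicit loops over rows.
brute_clr <- function(r) {
  M <- abs(r)
  J <- nrow(M)
  z <- matrix(0, J, J)
  for (i in seq_len(J)) {
    row <- M[i, -i]
    mu <- mean(row)
    s <- stats::sd(row)
    for (j in seq_len(J)) {
      if (j == i || s == 0) next
      z[i, j] <- max(0, (M[i, j] - mu) / s)
    }
  }
  out <- sqrt(z^2 + t(z)^2)
  diag(out) <- 0
  out
}

# Upper hypergeometric tail by exhaustive enumeration of overlap outcomes.
brute_hyper_tail <- function(k, K, N, n) {
  xs <- k:min(K, n)
  xs <- xs[xs >= max(0, n - (N - K))]
  if (length(xs) == 0) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# COVSCA goodness of fit by direct Frobenius arithmetic.
brute_gof <- function(weights, loadings, S) {
  recon <- lapply(seq_along(S), function(k) {
    out <- matrix(0, nrow(S[[k]]), ncol(S[[k]]))
    for (l in seq_along(loadings)) {
      out <- out + weights[k, l] * tcrossprod(loadings[[l]])
    }
    out
  })
  resid <- sum(mapply(function(s, r) sum((s - r)^2), S, recon))
  100 * (1 - resid / sum(sapply(S, function(s) sum(s^2))))
}
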