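# Independent brute-force oracles and tiny fixture builders.  Everything
# here is deliberately naive (scalar loops, explicit formulas) so it checks
# the vectorized implementations rather than mirroring them.

random_binary_matrix <- function(nr, nc, p = 0.4,
                                 rn = sprintf("R%02d", seq_len(nr)),
                                 cn = sprintf("C%02d", seq_len(nc))) {
  matrix(as.numeric(runif(nr * nc) < p), nr, nc, dimnames = list(rn, cn))
}

# Scalar-loop cosine over rows of a profile matrix.
naive_cosine <- function(p) {
  n <- nrow(p)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ni <- sqrt(sum(p[i, ]^2)); nj <- sqrt(sum(p[j, ]^2))
    out[i, j] <- if (ni == 0 || nj == 0) 0 else sum(p[i, ] * p[j, ]) / (ni * nj)
  }
  out
}

# Scalar-loop Jaccard over supports.
naive_jaccard <- function(p) {
  n <- nrow(p)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    si <- which(p[i, ] != 0); sj <- which(p[j, ] != 0)
    u <- length(union(si, sj))
    out[i, j] <- if (u == 0) 0 else length(intersect(si, sj)) / u
  }
  out
}

naive_integrate <- function(cs, js) {
  out <- js
  nz <- cs != 0
  out[nz] <- (cs[nz] + js[nz]) / 2
  out
}

# Triple-loop evaluation of the projection/fusion equations.
naive_lp <- function(ils, psi) {
  m <- nrow(psi); e <- ncol(psi)
  out <- matrix(0, m, e)
  for (i in seq_len(m)) {
    nrm <- sqrt(sum(ils[i, ]^2))
    if (nrm == 0) next
    for (col in seq_len(e)) {
      out[i, col] <- sum(ils[i, ] * psi[, col]) / nrm
    }
  }
  out
}

naive_dp <- function(ids, psi) {
  m <- nrow(psi); e <- ncol(psi)
  out <- matrix(0, m, e)
  for (j in seq_len(e)) {
    nrm <- sqrt(sum(ids[, j]^2))
    if (nrm == 0) next
    for (row in seq_len(m)) {
      out[row, j] <- sum(ids[, j] * psi[row, ]) / nrm
    }
  }
  out
}

naive_fuse <- function(lp, dp, ils, ids, omega) {
  m <- nrow(lp); e <- ncol(lp)
  out <- matrix(0, m, e)
  for (i in seq_len(m)) for (j in seq_len(e)) {
    d <- sqrt(sum(ils[i, ]^2)) + sqrt(sum(ids[, j]^2))
    out[i, j] <- if (d == 0) 0 else (omega * lp[i, j] + (1 - omega) * dp[i, j]) / d
  }
  out
}

# Exhaustive pairwise-ordering AUC (Mann-Whitney by enumeration, ties = 1/2).
naive_auc <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# Scalar evaluation of the factorization loss used for finite differences.
naive_loss <- function(A, X, Y, lambda) {
  s <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    s <- s + (A[i, j] - sum(X[i, ] * Y[, j]))^2
  }
  s + lambda * (sum(X^2) + sum(Y^2))
}

# Small aligned triple wrapped the way align_on_mirna builds it.
make_triple <- function(a_lm, a_md) {
  align_on_mirna(bipartite_network(a_lm), bipartite_network(a_md),
                 mode = "intersection")
}

named <- function(m, rn = sprintf("L%d", seq_len(nrow(m))),
                  cn = sprintf("D%d", seq_len(ncol(m)))) {
  dimnames(m) <- list(rn, cn)
  m
}

# A modest planted-signal fixture reused across optimization tests.
fixture_sim <- function(seed = 42) {
  generate_network(synthetic_config(m = 20, n = 12, e = 15, g = 3,
                                    p_in = 0.6, p_out = 0.05, q = 0.5,
                                    seed = seed))
}
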