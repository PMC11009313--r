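# Independent maximum-entropy oracle: solves the constrained maxent problem
# by direct convex optimization of the exponential-family dual (BFGS on the
# Lagrange multipliers), entirely separate from the package's iterative
# proportional fitting path.

# re-derivation of the smoothed constraint targets from the stated rule:
# pseudocount 0.5 per cell of the highest-order tables, scaled by 4^(kmax-k)
# for lower-order subsets so the system is consistent
oracle_targets <- function(seqs, constraints, pseudocount = 0.5) {
  bases <- c("A", "C", "G", "T")
  m <- matrix(match(unlist(strsplit(toupper(seqs), "")), bases),
              ncol = nchar(seqs[1]), byrow = TRUE)
  kmax <- max(lengths(constraints))
  lapply(constraints, function(cs) {
    k <- length(cs)
    idx <- rep(1L, nrow(m))
    for (j in seq_along(cs)) idx <- idx + (m[, cs[j]] - 1L) * 4L^(j - 1L)
    cnt <- tabulate(idx, nbins = 4L^k) + pseudocount * 4^(kmax - k)
    cnt / sum(cnt)
  })
}

# feature (indicator) matrix: states x constraint cells, state ordering
# matching the package's cell index 1 + sum((b_j - 1) * 4^(j-1))
oracle_feature_matrix <- function(constraints, L) {
  states <- as.matrix(expand.grid(rep(list(0:3), L)))
  blocks <- lapply(constraints, function(cs) {
    idx <- rep(1L, nrow(states))
    for (j in seq_along(cs)) idx <- idx + states[, cs[j]] * 4L^(j - 1L)
    M <- matrix(0, nrow(states), 4L^length(cs))
    M[cbind(seq_len(nrow(states)), idx)] <- 1
    M
  })
  do.call(cbind, blocks)
}

oracle_maxent <- function(targets, constraints, L) {
  A <- oracle_feature_matrix(constraints, L)
  tvec <- unlist(targets)
  obj <- function(lam) {
    u <- as.vector(A %*% lam)
    mx <- max(u)
    (log(sum(exp(u - mx))) + mx) - sum(lam * tvec)
  }
  gr <- function(lam) {
    u <- as.vector(A %*% lam)
    p <- exp(u - max(u))
    p <- p / sum(p)
    as.vector(crossprod(A, p)) - tvec
  }
  fit <- stats::optim(rep(0, ncol(A)), obj, gr, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-16))
  u <- as.vector(A %*% fit$par)
  p <- exp(u - max(u))
  p / sum(p)
}

kl_div <- function(p, q) sum(p[p > 0] * log(p[p > 0] / q[p > 0]))

# marginal of a full distribution vector over a position subset
dist_marginal <- function(p, cs, L) {
  states <- as.matrix(expand.grid(rep(list(0:3), L)))
  idx <- rep(1L, length(p))
  for (j in seq_along(cs)) idx <- idx + states[, cs[j]] * 4L^(j - 1L)
  as.vector(rowsum(p, idx))
}
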