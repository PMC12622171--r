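# Independent brute-force / closed-form oracles shared by the module and
# acceptance suites. These never call the code paths they check.

# Fisher direction from the generalized eigenproblem S_B w = lambda S_W w,
# solved as the leading eigenvector of solve(S_W) S_B; returns the
# ASD-high-oriented projection scores
fda_eigen_oracle <- function(X, labels) {
  is_pos <- labels == "ASD"
  mu1 <- colMeans(X[is_pos, , drop = FALSE])
  mu0 <- colMeans(X[!is_pos, , drop = FALSE])
  c1 <- sweep(X[is_pos, , drop = FALSE], 2, mu1)
  c0 <- sweep(X[!is_pos, , drop = FALSE], 2, mu0)
  sw <- crossprod(c1) + crossprod(c0)
  sb <- tcrossprod(mu1 - mu0)
  ev <- eigen(solve(sw) %*% sb)
  w <- Re(ev$vectors[, which.max(Re(ev$values))])
  s <- drop(X %*% w)
  if (mean(s[is_pos]) < mean(s[!is_pos])) s <- -s
  s
}

# two Gaussian classes with a shared covariance, ASD first
make_gaussian_classes <- function(n1, n0, p, delta, seed, sigma = NULL) {
  set.seed(seed)
  if (is.null(sigma)) sigma <- diag(p)
  L <- chol(sigma)
  X <- rbind(
    matrix(rnorm(n1 * p), n1) %*% L + matrix(delta, n1, p, byrow = TRUE),
    matrix(rnorm(n0 * p), n0) %*% L)
  colnames(X) <- sprintf("f%d", seq_len(p))
  list(X = X, labels = rep(c("ASD", "TD"), c(n1, n0)))
}

# double-loop strict-exceedance indicators against the TD extremes
brute_force_indicators <- function(vals, groups, directions) {
  out <- matrix(0L, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  for (i in seq_len(nrow(vals))) {
    for (j in seq_len(ncol(vals))) {
      v <- vals[i, j]
      if (is.na(v)) next
      td <- vals[groups == "TD", j]
      hit <- if (directions[j] == "low") v < min(td, na.rm = TRUE)
             else v > max(td, na.rm = TRUE)
      out[i, j] <- as.integer(hit)
    }
  }
  out
}

# AUROC by exhaustive pair counting with half-credit ties
auroc_pairs_oracle <- function(x, y) {
  mean(outer(x, y, ">") + 0.5 * outer(x, y, "=="))
}
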