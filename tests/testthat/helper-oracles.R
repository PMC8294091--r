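# Independent oracles used across the test suite. Each deliberately takes a
# different computational path from the package implementation.

# --- recursive coefficient-of-kinship oracle (memoized) ---------------------
# f(i, j) with founders unrelated and non-inbred unless produced by the
# pedigree itself; numerator relationship = 2 * f off-diagonal,
# 1 + f(s, d) on the diagonal.
kinship_oracle <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- ifelse(is.na(ped$sire), NA_integer_, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), NA_integer_, idx[ped$dam])
  memo <- new.env(hash = TRUE)
  f <- function(i, j) {
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      if (is.na(si[i])) 0.5 else 0.5 * (1 + f(si[i], di[i]))
    } else {
      # j is never an ancestor of i when i < j (topological order)
      if (is.na(si[j])) 0 else 0.5 * (f(i, si[j]) + f(i, di[j]))
    }
    memo[[key]] <- val
    val
  }
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) K[i, j] <- K[j, i] <- f(i, j)
  2 * K  # additive relationship; diagonal = 2 f(i,i) = 1 + F_i
}

# direct elementwise evaluation of the dominance relationship formula from
# a (possibly oracle-derived) A matrix
dominance_oracle <- function(ped, A) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  D <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { D[i, j] <- 1; next }
    if (is.na(ped$sire[i]) || is.na(ped$sire[j])) next
    g <- idx[ped$sire[i]]; h <- idx[ped$dam[i]]
    k <- idx[ped$sire[j]]; l <- idx[ped$dam[j]]
    D[i, j] <- (A[g, k] * A[h, l] + A[g, l] * A[h, k]) / 4
  }
  D
}

# --- explicit restricted log-likelihood (solve/determinant path) ------------
restricted_logL_oracle <- function(y, kernel_list, theta, with_const = TRUE) {
  n <- length(y)
  X <- matrix(1, n, 1)
  V <- theta[length(theta)] * diag(n)
  for (k in seq_along(kernel_list)) V <- V + theta[k] * kernel_list[[k]]
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% crossprod(X, Vi)
  ll <- -0.5 * (determinant(V)$modulus[1] + determinant(XtViX)$modulus[1] +
                drop(crossprod(y, P %*% y)))
  if (with_const) ll <- ll - 0.5 * (n - 1) * log(2 * pi)
  ll
}

# grid maximizer of the restricted likelihood; returns the best grid point
reml_grid_oracle <- function(y, kernel_list, grids) {
  pts <- as.matrix(expand.grid(grids))
  ll <- apply(pts, 1, function(th) restricted_logL_oracle(y, kernel_list, th))
  pts[which.max(ll), ]
}

# --- Gaussian conditioning oracle for BLUP / PEV (known zero mean) ----------
# (u, y) jointly normal: u ~ N(0, s2u K), y = u + e, e ~ N(0, s2e I)
conditioning_oracle <- function(y, K, s2u, s2e) {
  n <- length(y)
  Cyy <- s2u * K + s2e * diag(n)
  Cuy <- s2u * K
  W <- Cuy %*% solve(Cyy)
  list(u_hat = drop(W %*% y),
       pev = diag(s2u * K - W %*% t(Cuy)))
}

# --- miscellaneous ----------------------------------------------------------
# rank-then-Pearson route to the Spearman correlation
spearman_oracle <- function(a, b) stats::cor(rank(a), rank(b))

# truncated-normal mean by numerical integration: E[X | X > z] / p
intensity_oracle <- function(p) {
  z <- stats::qnorm(1 - p)
  stats::integrate(function(x) x * stats::dnorm(x), z, Inf,
                   rel.tol = 1e-10)$value / p
}

# HWE genotype simulator (unrelated individuals, known frequencies)
hwe_genotypes <- function(n, p) {
  m <- length(p)
  calls <- vapply(p, function(pi) stats::rbinom(n, 2L, pi), integer(n))
  genotype_matrix(matrix(calls, n, m))
}
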