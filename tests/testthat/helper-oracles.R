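# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: the power-law fit is the standard ML estimator,
# the constrained-l1 oracle enumerates supports and solves each restricted
# problem by bisection over the lasso penalty with a coordinate-descent
# inner loop (a different algorithm family from the package's homotopy).

# Clauset-style continuous ML estimate of a power-law tail exponent.
# xmin = 2 excludes the Poisson-saturated degree-1 mass that any fixed-edge
# generator produces at low mean degree.
powerlaw_mle <- function(degrees, xmin = 2) {
  d <- degrees[degrees >= xmin]
  1 + length(d) / sum(log(d / (xmin - 0.5)))
}

# coordinate-descent lasso on a fixed support (independent of the homotopy)
cd_lasso_support <- function(A, b, lam, s0 = NULL, iters = 2000) {
  p <- ncol(A)
  G <- crossprod(A)
  Atb <- drop(crossprod(A, b))
  dg <- diag(G)
  s <- if (is.null(s0)) numeric(p) else s0
  for (it in seq_len(iters)) {
    delta <- 0
    for (j in seq_len(p)) {
      rho_j <- Atb[j] - sum(G[j, ] * s) + dg[j] * s[j]
      new <- sign(rho_j) * max(abs(rho_j) - lam, 0) / dg[j]
      delta <- max(delta, abs(new - s[j]))
      s[j] <- new
    }
    if (delta < 1e-12) break
  }
  s
}

# min ||s||_1 s.t. ||A[,T] s - b|| <= eps on one support, by bisection on the
# lasso penalty (residual norm is monotone in the penalty)
support_l1_min <- function(A_T, b, eps) {
  # feasibility on this support
  s_ls <- qr.coef(qr(A_T), b)
  s_ls[is.na(s_ls)] <- 0
  if (sqrt(sum((A_T %*% s_ls - b)^2)) > eps + 1e-9) return(NULL)
  lam_hi <- max(abs(crossprod(A_T, b)))
  lam_lo <- 0
  s <- numeric(ncol(A_T))
  for (it in 1:60) {
    lam <- (lam_hi + lam_lo) / 2
    s <- cd_lasso_support(A_T, b, lam, s)
    rn <- sqrt(sum((A_T %*% s - b)^2))
    if (rn > eps) lam_hi <- lam else lam_lo <- lam
  }
  s <- cd_lasso_support(A_T, b, lam_lo, s)
  sum(abs(s))
}

# brute-force oracle: minimal l1 norm over all supports of size <= kmax.
# The sphere constraint activates coordinates beyond the planted sparsity,
# so exhaustive checks enumerate every support (kmax = n).
brute_force_l1 <- function(A, b, eps, kmax = 3) {
  n <- ncol(A)
  if (sqrt(sum(b^2)) <= eps) return(0)
  best <- Inf
  for (k in seq_len(kmax)) {
    for (T in utils::combn(n, k, simplify = FALSE)) {
      v <- support_l1_min(A[, T, drop = FALSE], b, eps)
      if (!is.null(v) && v < best) best <- v
    }
  }
  best
}

# linear network dynamics dx/dt = (A - diag(p)) x, solved exactly by the
# matrix exponential (eigendecomposition), for variational-equation oracles
linear_traj <- function(M, x0, times) {
  out <- deSolve::ode(y = x0, times = times,
                      func = function(t, x, p) list(drop(M %*% x)),
                      rtol = 1e-10, atol = 1e-12)
  unname(out[, -1, drop = FALSE])
}

frob <- function(M) sqrt(sum(M^2))

# small random stable direct-influence matrix for round-trip tests
random_stable_S <- function(n, density = 0.1, seed = 1, sr = 0.7) {
  with_seed(seed, {
    S <- matrix(rnorm(n * n) * (runif(n * n) < density), n, n)
    diag(S) <- 0
    r <- max(Mod(eigen(S, only.values = TRUE)$values))
    if (r > 0) S * sr / r else S
  })
}
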