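# Lyapunov solvers via eigendecomposition with a Kronecker fallback.
# The eigen route is O(N^3) and handles the large neuron-level drift
# matrices; the Kronecker route is exact for small or defective systems.

# Solve A X + X A' + Q = 0 (continuous time); A must be Hurwitz.
lyap_continuous <- function(A, Q) {
  N <- nrow(A)
  eg <- eigen(A)
  if (max(Re(eg$values)) >= 0) stop("unstable system: Re(eigenvalue) >= 0")
  X <- tryCatch({
    V <- eg$vectors
    Vi <- solve(V)
    Qt <- Vi %*% Q %*% t(Vi)
    L <- outer(eg$values, eg$values, "+")
    if (min(Mod(L)) < 1e-12) stop("near-defective")
    Xt <- -Qt / L
    Re(V %*% Xt %*% t(V))
  }, error = function(e) {
    if (N > 120) stop("Lyapunov eigen solve failed on a large system: ",
                      conditionMessage(e))
    I <- diag(N)
    matrix(solve(kronecker(I, A) + kronecker(A, I), -as.vector(Q)), N, N)
  })
  (X + t(X)) / 2
}

# Solve X = A X A' + Q (discrete time); spectral radius of A must be < 1.
lyap_discrete <- function(A, Q) {
  N <- nrow(A)
  eg <- eigen(A)
  if (max(Mod(eg$values)) >= 1) stop("unstable system: spectral radius >= 1")
  X <- tryCatch({
    V <- eg$vectors
    Vi <- solve(V)
    Qt <- Vi %*% Q %*% t(Vi)
    L <- 1 - outer(eg$values, eg$values, "*")
    if (min(Mod(L)) < 1e-12) stop("near-defective")
    Xt <- Qt / L
    Re(V %*% Xt %*% t(V))
  }, error = function(e) {
    if (N > 120) stop("Lyapunov eigen solve failed on a large system: ",
                      conditionMessage(e))
    matrix(solve(diag(N * N) - kronecker(A, A), as.vector(Q)), N, N)
  })
  (X + t(X)) / 2
}

# Companion-form matrix of a VAR(p) coefficient list.
companion_matrix <- function(coeffs) {
  R <- nrow(coeffs[[1]])
  p <- length(coeffs)
  C <- matrix(0, p * R, p * R)
  C[seq_len(R), ] <- do.call(cbind, coeffs)
  if (p > 1) {
    C[(R + 1):(p * R), seq_len((p - 1) * R)] <- diag((p - 1) * R)
  }
  C
}

# Autocovariance sequence Gamma(0..K) of a stable VAR, Gamma(h) = E[x_t x_{t-h}'].
acov_var <- function(coeffs, Sigma, K) {
  R <- nrow(Sigma)
  p <- length(coeffs)
  C <- companion_matrix(coeffs)
  Q <- matrix(0, p * R, p * R)
  Q[seq_len(R), seq_len(R)] <- Sigma
  Gbig <- lyap_discrete(C, Q)
  # companion stationary covariance holds Gamma(i-j) blocks for lags 0..p-1
  G <- vector("list", K + 1)
  for (h in 0:min(K, p - 1)) {
    G[[h + 1]] <- Gbig[seq_len(R), (h * R + 1):((h + 1) * R), drop = FALSE]
  }
  if (K >= p) {
    for (h in p:K) {
      Gh <- matrix(0, R, R)
      for (k in seq_len(p)) {
        Gprev <- G[[h - k + 1]]
        Gh <- Gh + coeffs[[k]] %*% Gprev
      }
      G[[h + 1]] <- Gh
    }
  }
  G
}

# Innovation covariance of the best linear predictor of x_t from its past q
# values, given the autocovariance list G = Gamma(0..>=q).
innovation_cov <- function(G, q) {
  R <- nrow(G[[1]])
  if (q == 0) return(G[[1]])
  Gm <- matrix(0, q * R, q * R)
  for (i in seq_len(q)) {
    for (j in seq_len(q)) {
      h <- j - i
      blk <- if (h >= 0) G[[h + 1]] else t(G[[-h + 1]])
      Gm[((i - 1) * R + 1):(i * R), ((j - 1) * R + 1):(j * R)] <- blk
    }
  }
  Cm <- do.call(cbind, G[2:(q + 1)])          # Cov(x_t, [x_{t-1};...])
  S <- G[[1]] - Cm %*% solve(Gm, t(Cm))
  (S + t(S)) / 2
}
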