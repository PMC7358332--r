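# Shared fixtures, built in code.

# white-noise scan
noise_scan <- function(T = 200, R = 3, tr = 0.75, seed = 1) {
  set.seed(seed)
  regional_scan(matrix(rnorm(T * R), T, R), tr = tr)
}

# scan simulated from a known VAR model
var_scan <- function(model, T = 1000, seed = 1, tr = model$tr) {
  regional_scan(simulate(model, nsim = T, seed = seed), tr = tr)
}

# canonical lower-triangular test model: 1 drives 2
chain_var <- function() {
  var_model(rbind(c(0.5, 0), c(0.5, 0.5)))
}

# naive conditional GC oracle: explicit OLS loops, no shared code with the
# package's vectorized estimator
naive_conditional_gc <- function(x, i, j, p = 1) {
  x <- sweep(x, 2, colMeans(x))
  R <- ncol(x); T <- nrow(x)
  fit_resid_var <- function(cols, target) {
    idx <- (p + 1):T
    X <- NULL
    for (k in 1:p) X <- cbind(X, x[idx - k, cols, drop = FALSE])
    Y <- x[idx, target]
    b <- solve(t(X) %*% X, t(X) %*% Y)
    e <- Y - X %*% b
    sum(e^2) / length(idx)
  }
  fit_resid_cov2 <- function(t1, t2) {
    idx <- (p + 1):T
    X <- NULL
    for (k in 1:p) X <- cbind(X, x[idx - k, , drop = FALSE])
    E <- sapply(c(t1, t2), function(tg) {
      b <- solve(t(X) %*% X, t(X) %*% x[idx, tg])
      x[idx, tg] - X %*% b
    })
    crossprod(E) / length(idx)
  }
  all <- seq_len(R)
  v_j_full <- fit_resid_var(all, j)
  v_i_full <- fit_resid_var(all, i)
  v_j_red <- fit_resid_var(setdiff(all, i), j)
  v_i_red <- fit_resid_var(setdiff(all, j), i)
  S2 <- fit_resid_cov2(i, j)
  f_ij <- log(v_j_red / v_j_full)
  f_ji <- log(v_i_red / v_i_full)
  f_inst <- log(S2[1, 1] * S2[2, 2] / det(S2))
  c(f_ij = f_ij, f_ji = f_ji, f_inst = f_inst, f_full = f_ij + f_ji + f_inst)
}
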