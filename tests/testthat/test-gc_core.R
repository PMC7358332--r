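test_that("VAR fitting recovers generating coefficients", {
  m <- var_model(matrix(0.9))
  sc <- regional_scan(simulate(m, nsim = 5000, seed = 1), tr = 1)
  fit <- fit_var(sc, 1)
  expect_lt(abs(fit$coeffs[[1]][1, 1] - 0.9), 0.05)
  # i.i.d. noise: coefficients near zero, residual covariance near identity
  scn <- noise_scan(3000, 3, seed = 2)
  fn <- fit_var(scn, 1)
  expect_lt(max(abs(fn$coeffs[[1]])), 0.08)
  expect_lt(max(abs(fn$resid_cov - diag(3))), 0.12)
  expect_true(isSymmetric(fn$resid_cov, tol = 1e-10))
})

test_that("duplicated region columns raise a named singularity error", {
  set.seed(3)
  x <- matrix(rnorm(200), 100, 2)
  sc <- regional_scan(cbind(a = x[, 1], b = x[, 2], a2 = x[, 1]), tr = 1)
  expect_error(fit_var(sc, 1), "singular")
})

test_that("AIC order selection finds the generating order", {
  m1 <- var_model(rbind(c(0.6, 0.2), c(0, 0.5)))
  sc1 <- var_scan(m1, T = 2000, seed = 4, tr = 1)
  expect_equal(select_order_aic(sc1, 5), 1L)
  # strong lag-2 structure
  m2 <- var_model(list(diag(0.3, 2), rbind(c(0.5, 0), c(0.3, 0.45))))
  sc2 <- var_scan(m2, T = 2000, seed = 5, tr = 1)
  expect_equal(select_order_aic(sc2, 5), 2L)
  # white noise: penalty dominates, smallest order wins
  expect_equal(select_order_aic(noise_scan(1000, 2, seed = 6), 4), 1L)
})

test_that("conditional GC matches the naive two-regression loop oracle", {
  # R = 3 and R = 4 systems, order 1, tolerance 1e-10
  set.seed(7)
  for (R in c(3, 4)) {
    A <- matrix(rnorm(R * R, sd = 0.25), R, R)
    A <- A * 0.8 / max(Mod(eigen(A, only.values = TRUE)$values))
    m <- var_model(A, crossprod(matrix(rnorm(R * R), R)) / R + diag(R) * 0.5)
    x <- simulate(m, nsim = 600, seed = R)
    sc <- regional_scan(x, tr = 1)
    got <- conditional_gc_pair(sc, 1, 2, order = 1)
    want <- naive_conditional_gc(x, 1, 2, p = 1)
    expect_equal(unname(got), unname(want), tolerance = 1e-10)
    gm <- gc_matrices(sc, order = 1)
    expect_equal(gm$dgc[2, 1], unname(want["f_ij"]), tolerance = 1e-10)
    expect_equal(gm$dgc[1, 2], unname(want["f_ji"]), tolerance = 1e-10)
    expect_equal(gm$igc[1, 2], unname(want["f_inst"]), tolerance = 1e-10)
  }
})

test_that("independent series give GC near zero and the additivity identity holds", {
  sc <- noise_scan(2000, 3, seed = 8)
  g <- conditional_gc_pair(sc, 1, 2, order = 1)
  expect_true(all(abs(g) < 2 * 1 / 2000 * 10))   # well under bias scale
  # population: uncoupled model has exactly zero full measure
  gp <- population_gc(var_model(diag(0.4, 3)))
  expect_equal(max(abs(gp$full)), 0, tolerance = 1e-10)
  # population additivity is exact
  m <- var_model(rbind(c(0.5, 0, 0.2), c(0.4, 0.5, 0), c(0, 0.1, 0.3)),
                 rbind(c(1, 0.3, 0), c(0.3, 1, 0), c(0, 0, 1)))
  gpop <- population_gc(m)
  expect_equal(gpop$full[1, 2],
               gpop$dgc[2, 1] + gpop$dgc[1, 2] + gpop$igc[1, 2],
               tolerance = 1e-12)
  expect_true(all(gpop$dgc >= -1e-12))
  expect_true(all(gpop$igc >= -1e-12))
})

test_that("population oracle separates directed, reverse and instantaneous terms", {
  g <- population_gc(chain_var())
  expect_gt(g$dgc[2, 1], 0.1)          # 1 drives 2
  expect_equal(g$dgc[1, 2], 0, tolerance = 1e-10)
  expect_equal(g$igc[1, 2], 0, tolerance = 1e-10)
})

test_that("GC matrices have the right shape, symmetry and invariances", {
  set.seed(9)
  R <- 5
  A <- matrix(rnorm(R * R, sd = 0.2), R, R)
  A <- A * 0.7 / max(Mod(eigen(A, only.values = TRUE)$values))
  sc <- var_scan(var_model(A), T = 400, seed = 10, tr = 1)
  g <- gc_matrices(sc, order = 1)
  expect_equal(g$igc, t(g$igc))
  expect_equal(diag(g$igc), rep(0, R), ignore_attr = TRUE)
  expect_equal(diag(g$dgc), rep(0, R), ignore_attr = TRUE)
  expect_equal(diag(g$pc), rep(1, R), ignore_attr = TRUE)
  expect_true(all(abs(g$pc) <= 1 + 1e-12))
  # permutation equivariance
  perm <- c(3, 1, 5, 2, 4)
  scp <- regional_scan(sc$data[, perm], tr = 1)
  gp <- gc_matrices(scp, order = 1)
  expect_equal(unname(gp$dgc), unname(g$dgc[perm, perm]), tolerance = 1e-9)
  expect_equal(unname(gp$igc), unname(g$igc[perm, perm]), tolerance = 1e-9)
  # scale invariance
  scs <- regional_scan(sweep(sc$data, 2, c(10, 1, 1, 1, 1), `*`), tr = 1)
  gs <- gc_matrices(scs, order = 1)
  expect_lt(max(abs(gs$dgc - g$dgc)), 1e-8)
  expect_lt(max(abs(gs$igc - g$igc)), 1e-8)
})

test_that("14 regions give 91 iGC and 182 dGC features", {
  set.seed(11)
  sc <- noise_scan(120, 14, seed = 11)
  g <- gc_matrices(sc, order = 1)
  expect_length(vectorize(g, "igc"), 91L)
  expect_length(vectorize(g, "dgc"), 182L)
})

test_that("one-stage dGC tracks two-stage estimates and matches in population", {
  set.seed(12)
  A <- rbind(c(0.5, 0, 0.15), c(0.4, 0.45, 0), c(0, 0.3, 0.4))
  m <- var_model(A)
  sc <- var_scan(m, T = 5000, seed = 13, tr = 1)
  g2 <- gc_matrices(sc, order = 1)
  g1 <- one_stage_gc(sc, order = 1)
  off <- row(g1$dgc) != col(g1$dgc)
  expect_gt(cor(g1$dgc[off], g2$dgc[off], method = "spearman"), 0.9)
  # population: the analytic reduced model is exact, both estimators agree
  gp1 <- analytic_pop <- population_gc(m)
  expect_equal(gp1$estimator, "population")
  # zero-coupling: everything at zero
  g0 <- population_gc(var_model(diag(0.3, 3)))
  expect_lt(max(abs(g0$dgc)), 1e-10)
})

test_that("partial correlation matches the regression-residual oracle", {
  # x and y independent given common driver z
  set.seed(14)
  T <- 4000
  z <- rnorm(T)
  x <- 0.8 * z + rnorm(T, sd = 0.5)
  y <- 0.8 * z + rnorm(T, sd = 0.5)
  sc <- regional_scan(cbind(x = x, y = y, z = z), tr = 1)
  pc <- partial_correlation(sc)
  expect_gt(cor(x, y), 0.4)
  expect_lt(abs(pc["x", "y"]), 0.05)
  # oracle: correlation of residuals after regressing out z
  rx <- resid(lm(x ~ z)); ry <- resid(lm(y ~ z))
  expect_equal(pc["x", "y"], cor(rx, ry), tolerance = 0.02)
  # diagonal covariance means zero partial correlations
  pcd <- partial_correlation(diag(c(1, 2, 3)))
  expect_equal(pcd, diag(3), ignore_attr = TRUE)
  # R = 2 reduces to the Pearson correlation
  sc2 <- regional_scan(cbind(x, y), tr = 1)
  expect_equal(partial_correlation(sc2)[1, 2], cor(x, y)[1],
               tolerance = 1e-10)
})

test_that("lagged covariance obeys the Yule-Walker identity", {
  m <- var_model(rbind(c(0.6, 0.2), c(-0.1, 0.5)))
  sc <- var_scan(m, T = 10000, seed = 15, tr = 1)
  G0 <- stationary_cov_var(m)
  S1 <- lagged_covariance(sc, 1)$matrix
  expect_equal(S1, m$coeffs[[1]] %*% G0, tolerance = 0.06,
               ignore_attr = TRUE)
  # lag 0 equals the pooled sample covariance
  S0 <- lagged_covariance(sc, 0)$matrix
  xc <- sweep(sc$data, 2, colMeans(sc$data))
  expect_equal(S0, crossprod(xc) / nrow(xc), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("lag-1 covariance estimates are noisier than lag-0 estimates", {
  m <- var_model(rbind(c(0.5, 0.3), c(0, 0.5)))
  e01 <- replicate(200, {
    x <- simulate(m, nsim = 100)
    sc <- regional_scan(x, tr = 1)
    c(lagged_covariance(sc, 0)$matrix[1, 2],
      lagged_covariance(sc, 1)$matrix[1, 2])
  })
  expect_gt(var(e01[2, ]), var(e01[1, ]))
})

test_that("stationary covariance solves its defining equation", {
  # the balanced two-node configuration has zero cross-covariance
  a <- 0.5
  m <- var_model(rbind(c(a, -0.2), c(0.2, a)))
  G0 <- stationary_cov_var(m)
  expect_lt(abs(G0[1, 2]), 1e-10)
  # A = 0 gives Gamma(0) = Sigma
  S <- rbind(c(2, 0.5), c(0.5, 1))
  expect_equal(stationary_cov_var(var_model(matrix(0, 2, 2), S)), S,
               tolerance = 1e-10, ignore_attr = TRUE)
  # defining equation for a random stable model
  set.seed(16)
  A <- matrix(rnorm(16, sd = 0.2), 4, 4)
  m4 <- var_model(A)
  G <- stationary_cov_var(m4)
  expect_lt(norm(G - A %*% G %*% t(A) - diag(4), "F"), 1e-8)
  expect_error(stationary_cov_var(var_model(diag(1.1, 2))), "stable")
})

test_that("PC is a mixture of instantaneous and lagged dependence", {
  # with lag coupling and correlated residuals, PC differs from the
  # normalized residual correlation; removing the lags restores equality
  S <- rbind(c(1, 0.4, 0), c(0.4, 1, 0), c(0, 0, 1))
  A <- rbind(c(0.5, 0.3, 0), c(0, 0.5, 0.2), c(0.1, 0, 0.4))
  resid_pc <- -solve(S)[1, 2] / sqrt(solve(S)[1, 1] * solve(S)[2, 2])
  g_lag <- population_gc(var_model(A, S))
  expect_gt(abs(g_lag$pc[1, 2] - resid_pc), 0.02)
  g_nolag <- population_gc(var_model(matrix(0, 3, 3), S))
  expect_equal(g_nolag$pc[1, 2], resid_pc, tolerance = 1e-10)
})

test_that("null-model sample GC stays within its small-sample bias scale", {
  p <- 1; T <- 400
  meds <- replicate(40, {
    sc <- regional_scan(matrix(rnorm(T * 3), T, 3), tr = 1)
    g <- gc_matrices(sc, order = p)
    median(g$dgc[row(g$dgc) != col(g$dgc)])
  })
  expect_lt(median(meds), 2 * p / T)
})

test_that("connectivity matrices serialize to JSON and TSV edge lists", {
  g <- gc_matrices(noise_scan(120, 3, seed = 20), order = 1)
  pj <- withr::local_tempfile(fileext = ".json")
  write_gc(g, pj)
  g2 <- read_gc(pj)
  expect_equal(g2$dgc, g$dgc, tolerance = 1e-12)
  expect_equal(g2$pc, g$pc, tolerance = 1e-12)
  expect_equal(g2$estimator, "two-stage")
  pt <- withr::local_tempfile(fileext = ".tsv")
  write_gc(g, pt, format = "tsv")
  el <- read.table(pt, header = TRUE, sep = "\t")
  expect_equal(nrow(el), 3 * 3 + 6)   # three symmetric measures + dgc
  expect_setequal(unique(el$measure), c("igc", "pc", "full", "dgc"))
})
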