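test_that("exact discretization matches the scalar and Lyapunov checks", {
  # W = 0, tau = 1, delta = 1: coefficient exp(-1) I
  net <- continuous_network(matrix(0, 2, 2), tau = 1)
  dm <- discretize_ou(net, 1)
  expect_equal(unname(dm$coeffs[[1]]), exp(-1) * diag(2), tolerance = 1e-6)
  # delta -> 0: coefficient -> identity, innovation covariance -> 0
  dm0 <- discretize_ou(net, 1e-6)
  expect_equal(unname(dm0$coeffs[[1]]), diag(2), tolerance = 1e-5)
  expect_lt(max(abs(dm0$resid_cov)), 1e-5)
  # rate-scaled form approaches the continuous noise intensity
  expect_equal(unname(attr(dm0, "sigma_rate")), diag(2), tolerance = 1e-3)
  # stationary covariance of the discrete model equals the continuous one
  set.seed(1)
  W <- matrix(rnorm(25, sd = 0.15), 5, 5)
  net5 <- continuous_network(W, tau = 0.5)
  G0c <- solve_lyapunov_continuous(net5)
  for (delta in c(0.05, 0.75)) {
    dm5 <- discretize_ou(net5, delta)
    expect_lt(max(abs(stationary_cov_var(dm5) - G0c)), 1e-6)
  }
})

test_that("continuous Lyapunov solution satisfies its equation and Monte Carlo", {
  # scalar: A = -1, Sigma = 2 -> Gamma(0) = 1
  net1 <- continuous_network(matrix(0, 1, 1), tau = 1,
                             Sigma = matrix(2))
  expect_equal(solve_lyapunov_continuous(net1)[1, 1], 1, tolerance = 1e-10)
  set.seed(2)
  W <- matrix(rnorm(25, sd = 0.2), 5, 5)
  net <- continuous_network(W, tau = 0.3)
  G0 <- solve_lyapunov_continuous(net)
  expect_lt(max(abs(net$A %*% G0 + G0 %*% t(net$A) + net$Sigma)), 1e-8)
  # long simulated series reproduce it within 5 percent relative error
  x <- simulate(discretize_ou(net, 0.05), nsim = 60000, seed = 3)
  Cs <- cov(x)
  expect_lt(norm(Cs - G0, "F") / norm(G0, "F"), 0.05)
})

test_that("VAR simulation is seeded, stationary and Yule-Walker consistent", {
  m <- var_model(rbind(c(0.6, 0.2), c(0, 0.5)))
  x1 <- simulate(m, nsim = 500, seed = 4)
  x2 <- simulate(m, nsim = 500, seed = 4)
  expect_identical(x1, x2)
  # A = 0: sample covariance near identity
  x0 <- simulate(var_model(matrix(0, 3, 3)), nsim = 20000, seed = 5)
  expect_lt(max(abs(cov(x0) - diag(3))), 0.05)
  # sample lag-1 covariance ~ A Gamma(0)
  xl <- simulate(m, nsim = 10000, seed = 6)
  S1 <- t(xl[-1, ]) %*% xl[-nrow(xl), ] / (nrow(xl) - 1)
  target <- m$coeffs[[1]] %*% stationary_cov_var(m)
  expect_lt(norm(S1 - target, "F") / norm(target, "F"), 0.05)
  expect_error(simulate(var_model(diag(1.2, 2))), "unstable")
})

test_that("hemodynamic kernel has canonical shape and shifts with latency", {
  h <- hrf_kernel(0.01)
  t_peak <- (which.max(h) - 1) * 0.01
  expect_gt(t_peak, 4.5)
  expect_lt(t_peak, 6.5)
  expect_lt(min(h), 0)                       # undershoot
  expect_gt(max(h), abs(min(h)))             # peak dominates undershoot
  expect_gt(sum(h), 0)
  # latency 3 s delays the unnormalized kernel exactly
  h0 <- hrf_kernel(0.01, normalize = FALSE)
  h3 <- hrf_kernel(0.01, onset_latency = 3, normalize = FALSE)
  shift <- 300
  expect_equal(h3[(shift + 1):length(h3)], h0[1:(length(h0) - shift)],
               tolerance = 1e-12)
  expect_equal(h3[1:shift], rep(0, shift))
  expect_identical(hrf_kernel(0.01, onset_latency = 0), h)
})

test_that("neural-to-BOLD convolution is causal and latency-sensitive", {
  # impulse reproduces the kernel (after the discarded transient)
  dt <- 0.05
  h <- hrf_kernel(dt)
  n <- length(h)
  x <- matrix(0, 3 * n, 1)
  x[n + 10, 1] <- 1
  sc <- neural_to_bold(x, sim_dt = dt, tr_out = dt)
  got <- sc$data[(10):(10 + n - 1), 1]
  expect_equal(got, h, tolerance = 1e-8, ignore_attr = TRUE)
  # constant input: constant output equal to input times kernel sum
  xc <- matrix(2, 3 * n, 1)
  scc <- neural_to_bold(xc, sim_dt = dt, tr_out = dt, normalize = FALSE)
  hu <- hrf_kernel(dt, normalize = FALSE)
  expect_equal(scc$data[, 1], rep(2 * sum(hu), nrow(scc$data)),
               tolerance = 1e-6, ignore_attr = TRUE)
  # two nodes, same input, onsets 3 s and 4 s: cross-correlogram peak at 1 s
  set.seed(7)
  m <- var_model(matrix(0.9), tr = dt)
  xi <- simulate(m, nsim = 4000, seed = 7)
  two <- cbind(xi, xi)
  sc2 <- neural_to_bold(two, sim_dt = dt, tr_out = dt,
                        onset_latency = c(3, 4))
  cc <- ccf(sc2$data[, 2], sc2$data[, 1], lag.max = 40, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)] * dt, 1, tolerance = 0.2)
  expect_error(neural_to_bold(two, dt, dt, onset_latency = c(1, 2, 3)),
               "one onset latency per node")
  expect_error(neural_to_bold(two, 0.3, 0.75), "divide")
})

test_that("cluster networks have the advertised structure", {
  net <- build_cluster_network(9, 100, seed = 1)
  expect_equal(dim(net$W), c(900L, 900L))
  expect_equal(length(net$node_of_neuron), 900L)
  # no internode edges: block diagonal
  blocks <- outer(net$node_of_neuron, net$node_of_neuron, "==")
  expect_true(all(net$W[!blocks] == 0))
  # internode edges confined to the 5 percent port subsets
  edges <- data.frame(src = 1, dst = 2, sign = 1)
  net2 <- build_cluster_network(2, 100, inter_edges = edges, seed = 2)
  off <- net2$W[101:200, 1:100]
  nz <- which(off != 0, arr.ind = TRUE)
  expect_true(all(nz[, 1] <= 5))
  expect_true(all(nz[, 2] <= 5))
  expect_gt(length(nz), 0)
})

test_that("node averaging is a per-node mean and linear", {
  set.seed(8)
  x <- matrix(rnorm(50 * 6), 50, 6)
  map <- rep(1:2, each = 3)
  nd <- node_average(x, map)
  expect_equal(ncol(nd), 2L)
  expect_equal(nd[, 1], rowMeans(x[, 1:3]), ignore_attr = TRUE)
  expect_equal(node_average(3 * x, map), 3 * nd)
  # identical neurons: node series equals any member
  xid <- x[, c(1, 1, 1)]
  expect_equal(node_average(xid, rep(1, 3))[, 1], x[, 1],
               ignore_attr = TRUE)
})

test_that("emergent timescales behave as the eigenstructure dictates", {
  # isolated units: all timescales equal tau
  net0 <- continuous_network(matrix(0, 4, 4), tau = 0.05)
  expect_equal(eigen_timescales(net0), rep(0.05, 4))
  # purely feedforward chain: nilpotent W, slowest timescale = tau
  Wff <- matrix(0, 5, 5)
  Wff[cbind(2:5, 1:4)] <- 0.9
  netff <- continuous_network(Wff, tau = 0.05)
  expect_equal(max(eigen_timescales(netff)), 0.05, tolerance = 1e-10)
  # recurrent cluster: slowest mode at least 10x tau (default scaling)
  cl <- build_cluster_network(1, 100, seed = 3, tau = 0.05)
  expect_gte(max(eigen_timescales(cl)), 10 * 0.05)
  # scaling net excitation toward instability slows the slowest mode
  set.seed(9)
  W <- matrix(rnorm(100, sd = 0.1), 10, 10)
  lead <- max(Re(eigen(W, only.values = TRUE)$values))
  W <- W * (0.5 / lead)
  t1 <- max(eigen_timescales(continuous_network(W, tau = 0.05)))
  t2 <- max(eigen_timescales(continuous_network(W * 1.6, tau = 0.05)))
  expect_gt(t2, t1)
})

test_that("discretized population GC matches long-simulation estimates", {
  net <- two_node_network(1, 0.9)
  dm <- discretize_ou(net, 0.75)
  gp <- population_gc(dm)
  sc <- regional_scan(simulate(dm, nsim = 30000, seed = 10), tr = 0.75)
  gs <- gc_matrices(sc, order = 1)
  expect_lt(abs(gs$dgc[2, 1] - gp$dgc[2, 1]), 0.02)
  expect_lt(abs(gs$igc[1, 2] - gp$igc[1, 2]), 0.02)
  expect_lt(gs$dgc[1, 2], 0.01)
})

test_that("cohort generation is reproducible and round-trips through io", {
  nets <- dual_timescale_networks()
  spec <- cohort_spec(nets, n_subjects = 3, n_timepoints = 80, seed = 11)
  coh1 <- generate_cohort(spec)
  coh2 <- generate_cohort(spec)
  expect_identical(coh1$scans[[2]]$data, coh2$scans[[2]]$data)
  expect_length(coh1$scans, 6L)
  sc <- coh1$scans[[1]]
  expect_s3_class(sc, "regional_scan")
  expect_equal(nrow(sc$data), 80L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scan(sc, path)
  back <- read_scan(path, tr = sc$tr)
  expect_equal(back$data, sc$data, tolerance = 1e-6)
  # degenerate spec: no variability, no noise -> identical subjects
  spec0 <- cohort_spec(nets, n_subjects = 2, n_timepoints = 60,
                       between_subject_sd = 0, sigma_latency = 0,
                       noise_frac = 0,
                       behavior_loadings = matrix(1, 1, 36),
                       score_noise_sd = 0, seed = 12)
  coh0 <- generate_cohort(spec0)
  # all subjects share the unperturbed networks and latencies exactly
  expect_equal(coh0$truth$perturbations[[1]], matrix(0, 6, 6))
  expect_equal(coh0$truth$perturbations[[2]], matrix(0, 6, 6))
  expect_equal(coh0$truth$latencies[1, ], coh0$truth$latencies[2, ])
  expect_equal(unname(coh0$scores[, 1]), c(0, 0))
})

test_that("cohort spec validation catches inconsistencies", {
  nets <- dual_timescale_networks()
  expect_error(cohort_spec(unname(nets)), "named")
  expect_error(cohort_spec(nets, behavior_loadings = matrix(1, 2, 10)),
               "N\\^2")
  expect_error(cohort_spec(nets, tr = 0.75, sim_dt = 0.07), "divide")
})

test_that("symmetric balanced E-E feedback shows no dGC direction preference", {
  ee <- cluster_pair_experiment("ee", reps = 8, n_surr = 20, seed = 7)
  per_rep <- attr(ee, "reps")
  d <- per_rep[, "dgc_12"] - per_rep[, "dgc_21"]
  # paired comparison across repetitions: no systematic direction
  expect_gt(wilcox.test(d)$p.value, 0.01)
})

test_that("residual correlation drives iGC monotonically in a seven-node model", {
  set.seed(30)
  A <- matrix(rnorm(49, sd = 0.15), 7, 7)
  A <- A * 0.7 / max(Mod(eigen(A, only.values = TRUE)$values))
  igc12 <- sapply(seq(-0.9, 0.9, by = 0.3), function(rho) {
    S <- diag(7); S[1, 2] <- S[2, 1] <- rho
    population_gc(var_model(A, S))$igc[1, 2]
  })
  # zero at zero residual correlation, increasing in |rho|
  expect_lt(abs(igc12[4]), 1e-10)
  expect_true(all(diff(igc12[1:4]) < 0))   # decreasing toward rho = 0
  expect_true(all(diff(igc12[4:7]) > 0))   # increasing away from it
})
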