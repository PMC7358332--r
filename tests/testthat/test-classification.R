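test_that("vectorization has documented lengths, ordering and round-trip", {
  set.seed(1)
  M <- matrix(rnorm(16), 4, 4); diag(M) <- 0
  S <- M + t(M); diag(S) <- 0
  v_i <- vectorize(S, "igc")
  expect_length(v_i, 6L)
  expect_equal(unname(v_i[1:3]), S[1, 2:4])   # row-major upper triangle
  v_d <- vectorize(M, "dgc")
  expect_length(v_d, 12L)
  expect_equal(unvectorize(v_d, "dgc", 4), M)
  expect_equal(unvectorize(v_i, "igc", 4), S)
  # R = 2 edge case
  expect_length(vectorize(matrix(c(0, 1, 1, 0), 2), "igc"), 1L)
  expect_length(vectorize(matrix(c(0, 1, 2, 0), 2), "dgc"), 2L)
  # source -> destination naming: entry (i, j) is j -> i
  M2 <- matrix(0, 2, 2); M2[2, 1] <- 7
  expect_equal(unname(vectorize(M2, "dgc")["R1->R2"]), 7)
})

test_that("feature tables enforce aligned ordering across subjects", {
  g <- replicate(3, {
    m <- matrix(rnorm(9), 3, 3); diag(m) <- 0; m
  }, simplify = FALSE)
  tab <- feature_table(g, labels = c("a", "b", "a"), which = "dgc")
  expect_equal(dim(tab$x), c(3L, 6L))
  expect_identical(colnames(tab$x), tab$feature_ids)
  # hashing the ids is stable across construction
  tab2 <- feature_table(g, labels = c("a", "b", "a"), which = "dgc")
  expect_identical(tab$feature_ids, tab2$feature_ids)
})

test_that("run averaging is entrywise and validates estimators", {
  sc <- noise_scan(100, 3, seed = 2)
  g1 <- gc_matrices(sc, order = 1)
  g2 <- gc_matrices(noise_scan(100, 3, seed = 3), order = 1)
  avg <- average_runs(g1, g2)
  expect_equal(avg$dgc, (g1$dgc + g2$dgc) / 2)
  expect_equal(average_runs(g1, g1)$igc, g1$igc)
  g3 <- gc_matrices(noise_scan(100, 3, seed = 4), order = 1)
  chained <- average_runs(list(g1, g2, g3))
  expect_equal(chained$dgc, (g1$dgc + g2$dgc + g3$dgc) / 3)
  g1s <- g1; g1s$estimator <- "one-stage"
  expect_error(average_runs(g1, g1s), "estimator")
})

test_that("two-way classification separates separable features and stays at chance on noise", {
  set.seed(5)
  x <- rbind(matrix(rnorm(40 * 5, mean = 2), 40, 5),
             matrix(rnorm(40 * 5, mean = -2), 40, 5))
  tab <- feature_table_raw(x, labels = rep(c("a", "b"), each = 40))
  r <- two_way_classify(tab, scheme = "loo")
  expect_equal(r$accuracy, 1)
  expect_equal(r$ci_high, 1)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 1)
  # label-independent features: CI straddles 0.5
  xn <- matrix(rnorm(100 * 6), 100, 6)
  tn <- feature_table_raw(xn, labels = rep(c("a", "b"), 50))
  rn <- two_way_classify(tn, scheme = "kfold10", seed = 6)
  expect_gt(rn$ci_high, 0.5)
  expect_lt(rn$ci_low, 0.5)
  expect_error(two_way_classify(
    feature_table_raw(xn, labels = rep("a", 100))), "two classes")
})

test_that("hyperparameter tuning runs and returns a valid configuration", {
  set.seed(7)
  x <- rbind(matrix(rnorm(30 * 4, 1), 30, 4),
             matrix(rnorm(30 * 4, -1), 30, 4))
  tab <- feature_table_raw(x, labels = rep(c("a", "b"), each = 30))
  r <- two_way_classify(tab, scheme = "kfold10", hyperopt = TRUE, seed = 7)
  expect_true(r$provenance$learner %in% c("svm", "logistic"))
  expect_gt(r$accuracy, 0.8)
})

test_that("Clopper-Pearson bounds match the beta-quantile oracle", {
  for (kn in list(c(9, 10), c(973, 1000))) {
    k <- kn[1]; n <- kn[2]
    ci <- clopper_pearson(k, n)
    bt <- binom.test(k, n)$conf.int
    expect_equal(unname(ci), as.numeric(bt), tolerance = 1e-10)
    expect_equal(unname(ci["lower"]), qbeta(0.025, k, n - k + 1),
                 tolerance = 1e-12)
    expect_equal(unname(ci["upper"]), qbeta(0.975, k + 1, n - k),
                 tolerance = 1e-12)
  }
  expect_equal(unname(clopper_pearson(0, 10)["lower"]), 0)
  expect_equal(unname(clopper_pearson(10, 10)["upper"]), 1)
})

test_that("N-way one-versus-all classification behaves at both extremes", {
  set.seed(8)
  # seven balanced classes of pure noise: accuracy near 1/7
  xn <- matrix(rnorm(140 * 4), 140, 4)
  tn <- feature_table_raw(xn, labels = rep(letters[1:7], each = 20))
  rn <- nway_classify(tn, seed = 8)
  expect_lt(abs(rn$accuracy - 1 / 7), 0.12)
  # three well-separated blobs
  xs <- rbind(matrix(rnorm(30 * 3, 0), 30, 3),
              matrix(rnorm(30 * 3, 4), 30, 3),
              matrix(rnorm(30 * 3, -4), 30, 3))
  ts_ <- feature_table_raw(xs, labels = rep(c("a", "b", "c"), each = 30))
  rs <- nway_classify(ts_, seed = 9)
  expect_gt(rs$accuracy, 0.9)
  expect_error(nway_classify(
    feature_table_raw(xs, labels = rep(c("a", "b"), 45))), ">= 3")
})

test_that("accuracy is invariant to a consistent feature permutation", {
  set.seed(10)
  x <- rbind(matrix(rnorm(30 * 6, 1), 30, 6),
             matrix(rnorm(30 * 6, -1), 30, 6))
  labs <- rep(c("a", "b"), each = 30)
  r1 <- two_way_classify(feature_table_raw(x, labs), scheme = "kfold10",
                         seed = 11)
  perm <- sample(6)
  r2 <- two_way_classify(feature_table_raw(x[, perm], labs),
                         scheme = "kfold10", seed = 11)
  expect_equal(r1$accuracy, r2$accuracy)
})

test_that("permutation test calibrates on null features and detects signal", {
  set.seed(12)
  x <- rbind(matrix(rnorm(20 * 4, 1.5), 20, 4),
             matrix(rnorm(20 * 4, -1.5), 20, 4))
  labs <- rep(c("a", "b"), each = 20)
  subs <- rep(paste0("s", 1:20), 2)
  tab <- feature_table_raw(x, labs, subjects = subs)
  pt <- permutation_test(tab, n_perm = 99, seed = 12)
  expect_lte(pt$p, 0.05)
  expect_equal(pt$p, (sum(pt$null >= pt$observed) + 1) / 100)
  # null features: p should be non-small most of the time
  ps <- replicate(10, {
    xn <- matrix(rnorm(40 * 4), 40, 4)
    tn <- feature_table_raw(xn, labs, subjects = subs)
    permutation_test(tn, n_perm = 49, seed = sample.int(1e6, 1))$p
  })
  expect_gte(mean(ps > 0.05), 0.7)
})

test_that("observed accuracy below the null median gives p above one half", {
  set.seed(13)
  # degenerate: anti-informative labels via construction
  x <- matrix(rnorm(40 * 3), 40, 3)
  tab <- feature_table_raw(x, rep(c("a", "b"), 20))
  pt <- permutation_test(tab, n_perm = 99, seed = 13)
  if (pt$observed < median(pt$null)) expect_gt(pt$p, 0.5)
  expect_true(pt$p >= 0 && pt$p <= 1)
})

test_that("subject averaging improves or preserves accuracy in m", {
  set.seed(14)
  n_sub <- 40
  mu <- c(rep(0.6, 3), rep(-0.6, 3))
  x <- NULL; labs <- NULL; subs <- NULL
  for (s in 1:n_sub) {
    x <- rbind(x, rnorm(6, mu, 2), rnorm(6, -mu, 2))
    labs <- c(labs, "t", "r")
    subs <- c(subs, rep(paste0("s", s), 2))
  }
  tab <- feature_table_raw(x, labs, subjects = subs)
  res <- subject_average_classify(tab, m_values = c(1, 5, 10), seed = 15)
  expect_equal(res$m, c(1, 5, 10))
  expect_gte(res$accuracy[3] + 0.1, res$accuracy[1])
  expect_error(subject_average_classify(tab, m_values = 1000, seed = 1),
               "exceeds")
  # zero-noise features: accuracy identical (and perfect) for all m
  x0 <- x; x0[labs == "t", ] <- rep(mu, each = n_sub)
  x0[labs == "r", ] <- rep(-mu, each = n_sub)
  tab0 <- feature_table_raw(x0, labs, subjects = subs)
  res0 <- subject_average_classify(tab0, m_values = c(1, 2, 5), seed = 16)
  expect_equal(res0$accuracy, rep(1, 3))
})

test_that("baseline series features are per-region means then SDs", {
  set.seed(17)
  sc <- noise_scan(100, 14, seed = 17)
  f <- bold_baseline_features(sc)
  expect_length(f, 28L)
  expect_equal(unname(f[1:14]), unname(colMeans(sc$data)))
  # constant series: SD features zero
  scc <- regional_scan(matrix(rep(c(1, 2), each = 50), 50, 4), tr = 1)
  expect_equal(unname(bold_baseline_features(scc)[5:8]), rep(0, 4))
  # z-scored input: means 0, SDs 1
  z <- scale(sc$data)
  scz <- regional_scan(z, tr = 1)
  fz <- bold_baseline_features(scz)
  expect_equal(unname(fz), c(rep(0, 14), rep(1, 14)), tolerance = 1e-12)
})
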