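#' Two-level recursive feature elimination
#'
#' Outer loop: the observations are split into `n1` folds; each fold in
#' turn is held out to measure generalization accuracy while elimination
#' runs on the remaining folds.  Inner loop: the training data are split
#' into `n2` folds; the classifier is trained `n2` times leaving one fold
#' out, and the absolute discriminative weights are averaged across the
#' runs.  At each level the `drop_fraction` of features with the lowest
#' average weight is discarded (at least one) and the classifier is
#' retrained, until no features remain.  Per-level accuracies are averaged
#' over the outer folds; the reported retained sets and mean weights come
#' from the same elimination run on all observations, which makes the sets
#' nested by construction.  The whole procedure can be repeated with
#' different fold seeds and the accuracy curves averaged.
#'
#' @param table a `feature_table` with two labels.
#' @param n1 outer folds.
#' @param n2 inner folds.
#' @param drop_fraction fraction of current features dropped per level.
#' @param n_repeats fold-seed repetitions averaged into the curve.
#' @param seed RNG seed.
#' @param learner,cost learner configuration.
#' @return object of class `rfe_result`: `levels` data frame (level,
#'   n_features, accuracy), `retained` (list of feature-id sets per level),
#'   `weights` (list of mean absolute weights per level), `elbow`
#'   (see [fit_elbow()]), and the selected feature ids at the elbow.
#' @export
rfe_two_level <- function(table, n1 = 10, n2 = 5, drop_fraction = 0.10,
                          n_repeats = 1, seed = 1, learner = "svm",
                          cost = 1) {
  if (length(unique(table$labels)) != 2) {
    stop("two classes required; use rfe_nway for multiclass")
  }
  rfe_engine(table, n1, n2, drop_fraction, n_repeats, seed, learner, cost)
}

# sizes of the elimination path: each level retains the ceiling of
# (1 - drop_fraction) of the current features, always dropping at least one
rfe_sizes <- function(F, drop_fraction) {
  sizes <- integer(0)
  while (F > 0) {
    sizes <- c(sizes, F)
    F <- F - rfe_drop_count(F, drop_fraction)
  }
  sizes
}

rfe_drop_count <- function(F, drop_fraction) {
  max(1L, F - as.integer(ceiling((1 - drop_fraction) * F)))
}

# inner-fold averaged absolute weights for binary labels; the fold split
# is redrawn `reps` times and the averages pooled, which stabilises the
# elimination ranking
inner_weights <- function(x, labs, n2, learner, cost, reps = 3L) {
  w <- numeric(ncol(x))
  n_fits <- 0L
  for (r in seq_len(reps)) {
    fold <- make_folds(labs, n2)
    for (f in unique(fold)) {
      std <- train_standardizer(x[fold != f, , drop = FALSE])
      mdl <- train_linear(std$apply(x[fold != f, , drop = FALSE]),
                          labs[fold != f], learner, "ridge", cost)
      w <- w + abs(mdl$weights)
      n_fits <- n_fits + 1L
    }
  }
  w / n_fits
}

rfe_engine <- function(table, n1, n2, drop_fraction, n_repeats, seed,
                       learner, cost, drop_fraction_per_learner = 0.01) {
  set.seed(seed)
  x <- table$x
  labs <- table$labels
  ids <- table$feature_ids
  multi <- length(unique(labs)) > 2

  # mean absolute weights plus the column indices to drop at this level
  drop_step <- function(xc, labsc) {
    if (!multi) {
      w <- inner_weights(xc, labsc, n2, learner, cost)
      nd <- rfe_drop_count(ncol(xc), drop_fraction)
      list(weights = w, drop = order(w)[seq_len(nd)])
    } else {
      classes <- sort(unique(labsc))
      dropset <- integer(0)
      wsum <- numeric(ncol(xc))
      for (cl in classes) {
        yy <- ifelse(labsc == cl, "pos", "neg")
        w <- inner_weights(xc, yy, n2, learner, cost)
        wsum <- wsum + w
        nd <- max(1L, ceiling(drop_fraction_per_learner * ncol(xc)))
        dropset <- union(dropset, order(w)[seq_len(nd)])
      }
      list(weights = wsum / length(classes), drop = dropset)
    }
  }

  eval_acc <- function(xtr, ltr, xte, lte) {
    std <- train_standardizer(xtr)
    if (!multi) {
      mdl <- train_linear(std$apply(xtr), ltr, learner, "ridge", cost)
      mean(mdl$predict(std$apply(xte)) == lte)
    } else {
      classes <- sort(unique(ltr))
      sc <- vapply(classes, function(cl) {
        yy <- ifelse(ltr == cl, "pos", "neg")
        mdl <- train_linear(std$apply(xtr), yy, learner, "ridge", cost)
        d <- mdl$decision(std$apply(xte))
        if (mdl$levels[1] == "neg") -d else d
      }, numeric(nrow(xte)))
      sc <- matrix(sc, nrow = nrow(xte))
      mean(classes[max.col(sc, ties.method = "first")] == lte)
    }
  }

  # elimination path on a data subset; returns per-level feature index sets
  elimination_path <- function(xc, labsc) {
    cur <- seq_len(ncol(xc))
    path <- list()
    wts <- list()
    while (length(cur) > 0) {
      path[[length(path) + 1]] <- cur
      st <- drop_step(xc[, cur, drop = FALSE], labsc)
      wts[[length(wts) + 1]] <- setNames(st$weights, ids[cur])
      cur <- cur[-st$drop]
    }
    list(path = path, weights = wts)
  }

  # reported nested sets + weights come from the full-data elimination
  full <- elimination_path(x, labs)
  n_levels_ref <- length(full$path)
  acc_sum <- NULL
  for (r in seq_len(n_repeats)) {
    ofold <- make_folds(labs, n1, table$subjects)
    acc <- matrix(NA_real_, length(unique(ofold)), n_levels_ref)
    for (f in sort(unique(ofold))) {
      te <- ofold == f
      ep <- elimination_path(x[!te, , drop = FALSE], labs[!te])
      for (lv in seq_along(ep$path)) {
        if (lv > ncol(acc)) break
        keep <- ep$path[[lv]]
        acc[f, lv] <- eval_acc(x[!te, keep, drop = FALSE], labs[!te],
                               x[te, keep, drop = FALSE], labs[te])
      }
    }
    a <- colMeans(acc, na.rm = TRUE)
    acc_sum <- if (is.null(acc_sum)) a else acc_sum + a
  }
  accuracy <- acc_sum / n_repeats
  n_feats <- lengths(full$path)
  lv_df <- data.frame(level = seq_along(full$path), n_features = n_feats,
                      accuracy = accuracy[seq_along(full$path)])
  elbow <- tryCatch(fit_elbow(lv_df$accuracy), error = function(e) NULL)
  elbow_level <- if (is.null(elbow)) nrow(lv_df) else elbow$elbow
  structure(list(levels = lv_df,
                 retained = lapply(full$path, function(i) ids[i]),
                 weights = full$weights,
                 elbow = elbow,
                 elbow_level = elbow_level,
                 selected = ids[full$path[[elbow_level]]],
                 n1 = n1, n2 = n2, drop_fraction = drop_fraction,
                 seed = seed),
            class = "rfe_result")
}

#' N-way recursive feature elimination
#'
#' As [rfe_two_level()], but with one-versus-all binary learners: at each
#' level every learner's inner-fold-averaged absolute weights are computed,
#' and the union of each learner's bottom `drop_fraction_per_learner` of
#' features is discarded.
#'
#' @inheritParams rfe_two_level
#' @param drop_fraction_per_learner per-learner drop fraction (union over
#'   learners is removed each level).
#' @return an `rfe_result`.
#' @export
rfe_nway <- function(table, n1 = 10, n2 = 5,
                     drop_fraction_per_learner = 0.01, n_repeats = 1,
                     seed = 1, learner = "svm", cost = 1) {
  if (length(unique(table$labels)) < 3) {
    stop("multiclass RFE needs >= 3 classes; use rfe_two_level")
  }
  rfe_engine(table, n1, n2, drop_fraction = NA, n_repeats, seed, learner,
             cost, drop_fraction_per_learner = drop_fraction_per_learner)
}

#' @export
print.rfe_result <- function(x, ...) {
  cat("RFE over ", nrow(x$levels), " levels (",
      x$levels$n_features[1], " -> 1 features)\n", sep = "")
  cat(sprintf("  peak accuracy %.3f; elbow at level %d (%d features)\n",
              max(x$levels$accuracy, na.rm = TRUE), x$elbow_level,
              x$levels$n_features[x$elbow_level]))
  invisible(x)
}

#' @export
plot.rfe_result <- function(x, ...) {
  plot(x$levels$n_features, x$levels$accuracy, log = "x", type = "b",
       xlab = "retained features", ylab = "generalization accuracy", ...)
  abline(v = x$levels$n_features[x$elbow_level], lty = 2)
  invisible(x)
}

#' Elbow of an accuracy-versus-level curve
#'
#' Fits, for every candidate breakpoint, two least-squares lines over the
#' level index: one on the levels up to and including the breakpoint (the
#' plateau, excluding the very first level, i.e. the full feature set) and
#' one on the later levels (the decline), requiring the first line's slope
#' to exceed the second's.  Returns the breakpoint minimising the total
#' squared residual; if no breakpoint satisfies the slope constraint the
#' last level is returned with a warning.
#'
#' @param accuracy per-level accuracies, level 1 = all features; at least
#'   five levels are required so both lines have two or more points.
#' @return list with `elbow` (level index), `sse`, `slopes`, and
#'   `constrained` (FALSE when the warning path was taken).
#' @export
fit_elbow <- function(accuracy) {
  L <- length(accuracy)
  if (L < 5) stop("need at least 5 levels to locate an elbow")
  xs <- seq_len(L)
  fit_line <- function(ii) {
    xx <- xs[ii]; yy <- accuracy[ii]
    if (length(xx) < 2) return(list(slope = 0, sse = 0))
    b <- stats::coef(stats::lm.fit(cbind(1, xx), yy))
    list(slope = b[2], sse = sum((yy - b[1] - b[2] * xx)^2))
  }
  best <- NULL
  for (e in 3:(L - 2)) {
    f1 <- fit_line(2:e)                             # first point excluded
    f2 <- fit_line((e + 1):L)
    if (!(f1$slope > f2$slope + 1e-8)) next   # strict, within float noise
    sse <- f1$sse + f2$sse
    if (is.null(best) || sse < best$sse) {
      best <- list(elbow = e, sse = sse,
                   slopes = c(f1$slope, f2$slope), constrained = TRUE)
    }
  }
  if (is.null(best)) {
    warning("no breakpoint satisfies the slope constraint; ",
            "returning the last level")
    best <- list(elbow = L, sse = NA_real_, slopes = c(NA, NA),
                 constrained = FALSE)
  }
  best
}

#' Task-generic features by binomial tail test
#'
#' Treats a feature's presence in each of `n` selected sets as a Bernoulli
#' trial with success probability `p` equal to the mean selected-set size
#' divided by the number of candidate features, and returns the features
#' present in at least `k*` sets, where `k*` is the smallest count whose
#' binomial tail probability `P(X >= k)` falls below `alpha`.
#'
#' @param selected_sets list of character vectors (feature ids selected per
#'   task).
#' @param universe_size total number of candidate features.
#' @param alpha significance level.
#' @return list with `features` (character vector), `k_star`, `p_success`,
#'   and the per-feature counts.
#' @export
binomial_task_generic <- function(selected_sets, universe_size,
                                  alpha = 0.05) {
  n <- length(selected_sets)
  if (n < 2) stop("need at least two selected sets")
  p <- mean(lengths(selected_sets)) / universe_size
  counts <- table(unlist(lapply(selected_sets, unique)))
  tail_p <- function(k) pbinom(k - 1, n, p, lower.tail = FALSE)
  ks <- which(vapply(seq_len(n), tail_p, numeric(1)) < alpha)
  k_star <- if (length(ks) == 0) Inf else min(ks)
  feats <- names(counts)[counts >= k_star]
  list(features = feats, k_star = k_star, p_success = p,
       counts = counts)
}

#' Phase-scrambling surrogate of a time series
#'
#' Preserves the Fourier amplitude spectrum exactly while randomizing the
#' phases (with conjugate symmetry, so the output is real).  DC and, for
#' even lengths, the Nyquist component are untouched, so mean and variance
#' are preserved.  Applied independently per region this destroys all
#' cross-region dependence, which is what makes it a null for connectivity.
#'
#' @param x numeric vector, length >= 8.
#' @param seed optional RNG seed.
#' @return numeric surrogate vector of the same length.
#' @export
phase_scramble <- function(x, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  if (n < 8) stop("series too short to scramble")
  X <- fft(x)
  half <- seq(2L, floor((n - 1) / 2) + 1L)   # excludes DC and any Nyquist bin
  ph <- runif(length(half), 0, 2 * pi)
  X[half] <- Mod(X[half]) * exp(1i * ph)
  mirror <- n + 2L - half
  keep <- mirror > max(half)       # skip self-conjugate (Nyquist) bin
  X[mirror[keep]] <- Conj(X[half[keep]])
  Re(fft(X, inverse = TRUE)) / n
}

#' Significance of the overlap between two selected feature sets
#'
#' The observed statistic is the overlap size as a proportion of
#' `|set_b|`; the null permutes feature identities, drawing random sets of
#' the same sizes from the universe.
#'
#' @param set_a,set_b character vectors of feature ids.
#' @param universe character vector (or integer count) of all candidate
#'   features.
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return list with `p`, `observed` (proportion), `null`.
#' @export
overlap_significance <- function(set_a, set_b, universe, n_perm = 1000,
                                 seed = 1) {
  if (length(set_b) == 0) stop("set_b is empty; overlap proportion undefined")
  if (length(universe) == 1 && is.numeric(universe)) {
    universe <- as.character(seq_len(universe))
  }
  if (!all(c(set_a, set_b) %in% universe)) {
    stop("sets must be subsets of the universe")
  }
  set.seed(seed)
  obs <- length(intersect(set_a, set_b)) / length(set_b)
  null <- vapply(seq_len(n_perm), function(b) {
    a <- sample(universe, length(set_a))
    bb <- sample(universe, length(set_b))
    length(intersect(a, bb)) / length(bb)
  }, numeric(1))
  list(p = (sum(null >= obs) + 1) / (n_perm + 1), observed = obs,
       null = null)
}
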