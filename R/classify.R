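#' Vectorize a connectivity matrix into a feature vector
#'
#' Symmetric measures (`igc`, `pc`, `full`) use the upper triangle in
#' row-major order (`R(R-1)/2` features); directed measures (`dgc`,
#' `digraph`) use all off-diagonal entries in row-major order (`R^2 - R`
#' features).  The ordering and the feature names are deterministic, so
#' feature columns align across subjects.
#'
#' @param gc a `gc_matrices` object, or a plain matrix.
#' @param which one of `"igc"`, `"dgc"`, `"pc"`, `"full"`, `"digraph"`.
#' @return named numeric vector.
#' @export
vectorize <- function(gc, which = c("igc", "dgc", "pc", "full", "digraph")) {
  which <- match.arg(which)
  M <- if (is.matrix(gc)) gc else gc[[if (which == "digraph") "dgc" else which]]
  if (any(!is.finite(M))) stop("connectivity matrix has non-finite entries")
  R <- nrow(M)
  nm <- rownames(M)
  if (is.null(nm)) nm <- paste0("R", seq_len(R))
  if (which %in% c("igc", "pc", "full")) {
    idx <- which(upper.tri(M), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    v <- M[idx]
    names(v) <- paste0(nm[idx[, 1]], "~", nm[idx[, 2]])
  } else {
    idx <- which(row(M) != col(M), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    v <- M[idx]
    # entry (i, j) is the connection from source j to destination i
    names(v) <- paste0(nm[idx[, 2]], "->", nm[idx[, 1]])
  }
  v
}

#' Rebuild a matrix from a vectorized connectivity feature vector
#'
#' @param v named vector from [vectorize()].
#' @param which measure kind used at vectorization.
#' @param R number of regions.
#' @return R x R matrix (zero diagonal; symmetric kinds mirrored).
#' @export
unvectorize <- function(v, which = c("igc", "dgc", "pc", "full", "digraph"),
                        R) {
  which <- match.arg(which)
  M <- matrix(0, R, R)
  if (which %in% c("igc", "pc", "full")) {
    idx <- which(upper.tri(M), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    M[idx] <- v
    M <- M + t(M)
  } else {
    idx <- which(row(M) != col(M), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    M[idx] <- v
  }
  M
}

#' Assemble a feature table from per-scan connectivity
#'
#' @param gc_list list of `gc_matrices` (one per scan/subject-condition).
#' @param labels condition label per element.
#' @param which measure to vectorize.
#' @param subjects optional subject id per element (needed for
#'   within-subject permutation testing).
#' @return object of class `feature_table` with fields `x` (matrix rows =
#'   scans), `feature_ids`, `labels`, `subjects`, `provenance`.
#' @export
feature_table <- function(gc_list, labels, which = "igc", subjects = NULL) {
  vs <- lapply(gc_list, vectorize, which = which)
  ids <- names(vs[[1]])
  if (!all(vapply(vs, function(v) identical(names(v), ids), logical(1)))) {
    stop("feature ordering differs across scans")
  }
  x <- do.call(rbind, vs)
  if (length(labels) != nrow(x)) stop("one label per scan required")
  prov <- paste0(which, "/", if (inherits(gc_list[[1]], "gc_matrices")) {
    gc_list[[1]]$estimator
  } else "matrix")
  structure(list(x = x, feature_ids = ids, labels = as.character(labels),
                 subjects = if (is.null(subjects)) NULL
                            else as.character(subjects),
                 provenance = prov),
            class = "feature_table")
}

#' Feature table from raw matrices or vectors
#' @param x numeric matrix rows = observations.
#' @param labels label per row.
#' @param subjects optional subject id per row.
#' @param feature_ids optional column names.
#' @return a `feature_table`.
#' @export
feature_table_raw <- function(x, labels, subjects = NULL,
                              feature_ids = colnames(x)) {
  x <- as.matrix(x)
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(ncol(x)))
  colnames(x) <- feature_ids
  structure(list(x = x, feature_ids = feature_ids,
                 labels = as.character(labels),
                 subjects = if (is.null(subjects)) NULL
                            else as.character(subjects),
                 provenance = "raw"),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("Feature table: ", nrow(x$x), " observations x ", ncol(x$x),
      " features (", x$provenance, "); labels: ",
      paste(names(table(x$labels)), table(x$labels), sep = ":",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# ---- linear learner backend -------------------------------------------------

# standardize with training statistics; columns with negligible variation
# (constants, or numerical round-off residue) are left unscaled so that
# rescaling cannot amplify noise at machine precision into pseudo-signal
train_standardizer <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv < 1e-8] <- 1
  list(apply = function(z) sweep(sweep(z, 2, mu), 2, sdv, `/`))
}

train_linear <- function(x, y, learner = "svm", penalty = "ridge",
                         cost = 1) {
  y <- factor(y)
  if (learner == "svm") {
    fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
    w <- as.numeric(t(fit$coefs) %*% fit$SV)
    list(predict = function(z) as.character(predict(fit, z)),
         decision = function(z) {
           d <- attr(predict(fit, z, decision.values = TRUE),
                     "decision.values")
           as.numeric(d) * if (grepl(paste0("^", levels(y)[1], "/"),
                                     colnames(d)[1])) 1 else -1
         },
         weights = setNames(w, colnames(x)), levels = levels(y))
  } else {
    fit <- suppressWarnings(
      glmnet::glmnet(x, y, family = "binomial",
                     alpha = if (penalty == "lasso") 1 else 0,
                     lambda = 1 / cost, standardize = FALSE))
    w <- as.numeric(fit$beta)
    list(predict = function(z) {
           pr <- predict(fit, z, type = "class")
           as.character(pr)
         },
         decision = function(z) {
           -as.numeric(predict(fit, z, type = "link"))
         },
         weights = setNames(w, colnames(x)), levels = levels(y))
  }
}

# stratified fold assignment
make_folds <- function(labels, k, subjects = NULL) {
  n <- length(labels)
  fold <- integer(n)
  if (!is.null(subjects)) {
    # keep a subject's rows in one fold
    us <- unique(subjects)
    sf <- sample(rep_len(seq_len(k), length(us)))
    fold <- sf[match(subjects, us)]
  } else {
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  }
  fold
}

cv_accuracy <- function(x, labels, fold, learner = "svm",
                        penalty = "ridge", cost = 1) {
  pred <- character(length(labels))
  for (f in unique(fold)) {
    te <- fold == f
    std <- train_standardizer(x[!te, , drop = FALSE])
    mdl <- train_linear(std$apply(x[!te, , drop = FALSE]), labels[!te],
                        learner, penalty, cost)
    pred[te] <- mdl$predict(std$apply(x[te, , drop = FALSE]))
  }
  pred
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' @param k successes.
#' @param n trials.
#' @param conf confidence level.
#' @return numeric vector `c(lower, upper)`.
#' @export
clopper_pearson <- function(k, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- if (k == 0) 0 else qbeta(a, k, n - k + 1)
  hi <- if (k == n) 1 else qbeta(1 - a, k + 1, n - k)
  c(lower = lo, upper = hi)
}

#' Two-way classification with cross-validation
#'
#' Linear max-margin (or logistic) classification of a two-condition
#' feature table, with leave-one-out or 10-fold cross-validation, exact
#' binomial confidence bounds on the accuracy, and optional hyperparameter
#' tuning: the cohort is split into five tuning folds, each used in turn to
#' pick the best (learner, penalty, cost) by accuracy on the held-out
#' remainder, and the winning configuration is used for the final
#' cross-validation.
#'
#' @param table a `feature_table` with exactly two labels.
#' @param scheme `"loo"` or `"kfold10"`.
#' @param hyperopt logical; run the tuning protocol first.
#' @param seed RNG seed for fold assignment.
#' @param learner,penalty,cost default learner configuration.
#' @return object of class `cv_result` with accuracy, Clopper-Pearson CI,
#'   precision, recall, per-fold predictions, and provenance.
#' @export
two_way_classify <- function(table, scheme = c("loo", "kfold10"),
                             hyperopt = FALSE, seed = 1, learner = "svm",
                             penalty = "ridge", cost = 1) {
  scheme <- match.arg(scheme)
  labs <- table$labels
  if (length(unique(labs)) != 2) stop("need exactly two classes")
  set.seed(seed)
  if (hyperopt) {
    hp <- tune_linear(table$x, labs)
    learner <- hp$learner; penalty <- hp$penalty; cost <- hp$cost
  }
  n <- nrow(table$x)
  fold <- if (scheme == "loo") seq_len(n) else make_folds(labs, 10)
  pred <- cv_accuracy(table$x, labs, fold, learner, penalty, cost)
  cv_result(pred, labs, scheme,
            provenance = list(learner = learner, penalty = penalty,
                              cost = cost, seed = seed,
                              features = table$provenance))
}

tune_linear <- function(x, labs, n_tune_folds = 5,
                        costs = 10^seq(-4, 4, by = 2)) {
  fold <- make_folds(labs, n_tune_folds)
  grid <- expand.grid(learner = c("svm", "logistic"),
                      penalty = c("ridge", "lasso"), cost = costs,
                      stringsAsFactors = FALSE)
  grid <- grid[!(grid$learner == "svm" & grid$penalty == "lasso"), ]
  score <- numeric(nrow(grid))
  for (f in seq_len(n_tune_folds)) {
    tr <- fold == f          # small tuning set trains; the rest evaluates
    std <- train_standardizer(x[tr, , drop = FALSE])
    for (g in seq_len(nrow(grid))) {
      mdl <- tryCatch(
        train_linear(std$apply(x[tr, , drop = FALSE]), labs[tr],
                     grid$learner[g], grid$penalty[g], grid$cost[g]),
        error = function(e) NULL)
      if (is.null(mdl)) next
      acc <- mean(mdl$predict(std$apply(x[!tr, , drop = FALSE])) ==
                    labs[!tr])
      score[g] <- score[g] + acc
    }
  }
  best <- which.max(score)
  list(learner = grid$learner[best], penalty = grid$penalty[best],
       cost = grid$cost[best])
}

cv_result <- function(pred, labs, scheme, provenance = list(),
                      permutation_p = NULL) {
  lv <- sort(unique(labs))
  k <- sum(pred == labs)
  n <- length(labs)
  ci <- clopper_pearson(k, n)
  pos <- lv[1]
  tp <- sum(pred == pos & labs == pos)
  structure(list(accuracy = k / n, ci_low = ci[["lower"]],
                 ci_high = ci[["upper"]],
                 precision = if (sum(pred == pos) > 0)
                   tp / sum(pred == pos) else NA_real_,
                 recall = tp / sum(labs == pos),
                 predictions = pred, labels = labs, scheme = scheme,
                 permutation_p = permutation_p, provenance = provenance),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "CV accuracy (%s): %.3f  [95%% CI %.3f, %.3f]  n = %d\n",
    x$scheme, x$accuracy, x$ci_low, x$ci_high, length(x$labels)))
  if (!is.null(x$permutation_p)) {
    cat(sprintf("  permutation p = %.4g\n", x$permutation_p))
  }
  invisible(x)
}

#' N-way classification with one-versus-all linear learners
#'
#' Trains one binary learner per class (that class positive, the rest
#' negative) and assigns each held-out observation to the class with the
#' largest decision value; ties break by lowest class index.  Accuracy is
#' assessed with leave-one-out cross-validation.
#'
#' @param table a `feature_table` with three or more labels.
#' @param seed RNG seed.
#' @param learner,cost learner configuration.
#' @return a `cv_result`.
#' @export
nway_classify <- function(table, seed = 1, learner = "svm", cost = 1) {
  labs <- table$labels
  classes <- sort(unique(labs))
  if (length(classes) < 3) {
    stop("need >= 3 classes; use two_way_classify for binary problems")
  }
  if (any(table(labs) < 2)) stop("every class needs >= 2 members")
  set.seed(seed)
  x <- table$x
  n <- nrow(x)
  pred <- character(n)
  for (i in seq_len(n)) {
    std <- train_standardizer(x[-i, , drop = FALSE])
    xtr <- std$apply(x[-i, , drop = FALSE])
    xte <- std$apply(x[i, , drop = FALSE])
    scores <- vapply(classes, function(cl) {
      yy <- ifelse(labs[-i] == cl, "pos", "neg")
      mdl <- train_linear(xtr, yy, learner, "ridge", cost)
      d <- mdl$decision(xte)
      if (mdl$levels[1] == "neg") -d else d
    }, numeric(1))
    pred[i] <- classes[which.max(scores)]   # which.max: first (lowest) wins
  }
  cv_result(pred, labs, "loo",
            provenance = list(learner = learner, cost = cost, seed = seed))
}

#' Permutation test of classification accuracy
#'
#' The observed statistic is the 10-fold cross-validation accuracy; the
#' null distribution is built by permuting condition labels (within each
#' subject's own scans when subject ids are available, otherwise across
#' all rows) and recomputing the same accuracy.  Returns the add-one
#' smoothed p value `(b + 1) / (n_perm + 1)`.
#'
#' @param table a `feature_table`.
#' @param n_perm number of label permutations.
#' @param seed RNG seed.
#' @param learner,cost learner configuration.
#' @return list with `p`, `observed`, `null` (vector of null accuracies).
#' @export
permutation_test <- function(table, n_perm = 1000, seed = 1,
                             learner = "svm", cost = 1) {
  set.seed(seed)
  labs <- table$labels
  x <- table$x
  fold <- make_folds(labs, 10)
  obs <- mean(cv_accuracy(x, labs, fold, learner, cost = cost) == labs)
  null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    pl <- permute_labels(labs, table$subjects)
    pfold <- make_folds(pl, 10)
    null[b] <- mean(cv_accuracy(x, pl, pfold, learner, cost = cost) == pl)
  }
  p <- (sum(null >= obs) + 1) / (n_perm + 1)
  list(p = p, observed = obs, null = null)
}

permute_labels <- function(labs, subjects = NULL) {
  if (is.null(subjects)) return(sample(labs))
  out <- labs
  for (s in unique(subjects)) {
    idx <- which(subjects == s)
    out[idx] <- sample(labs[idx])
  }
  out
}

#' Classification of subject-averaged connectivity features
#'
#' Splits subjects into two halves, trains on one half, groups the held-out
#' subjects into folds of size `m`, averages their features within each
#' fold, and classifies the fold means; the roles of the halves are then
#' exchanged.  Averaging over subjects suppresses independent
#' between-subject feature noise, so accuracy typically grows with `m`.
#'
#' @param table a `feature_table` with two labels; rows must carry subject
#'   ids, with each subject observed under both conditions.
#' @param m_values fold sizes to evaluate.
#' @param seed RNG seed.
#' @param learner,cost learner configuration.
#' @return data frame with columns `m`, `accuracy`, `n_tested`.
#' @export
subject_average_classify <- function(table, m_values = c(1, 2, 4, 5, 10),
                                     seed = 1, learner = "svm", cost = 1) {
  if (is.null(table$subjects)) stop("subject ids required")
  set.seed(seed)
  subs <- unique(table$subjects)
  half <- sample(subs, floor(length(subs) / 2))
  halves <- list(train = half, test = setdiff(subs, half))
  out <- list()
  for (m in m_values) {
    if (m > min(lengths(halves))) stop("m = ", m, " exceeds half size")
    correct <- 0L; total <- 0L
    for (swap in 1:2) {
      tr_sub <- if (swap == 1) halves$train else halves$test
      te_sub <- setdiff(subs, tr_sub)
      tr <- table$subjects %in% tr_sub
      std <- train_standardizer(table$x[tr, , drop = FALSE])
      mdl <- train_linear(std$apply(table$x[tr, , drop = FALSE]),
                          table$labels[tr], learner, "ridge", cost)
      for (lv in unique(table$labels)) {
        rows <- which(!tr & table$labels == lv)
        rows <- rows[sample.int(length(rows))]
        grp <- split(rows, ceiling(seq_along(rows) / m))
        grp <- grp[lengths(grp) == m]
        for (g in grp) {
          xm <- colMeans(table$x[g, , drop = FALSE])
          correct <- correct +
            (mdl$predict(std$apply(matrix(xm, 1))) == lv)
          total <- total + 1L
        }
      }
    }
    out[[length(out) + 1]] <- data.frame(m = m, accuracy = correct / total,
                                         n_tested = total)
  }
  do.call(rbind, out)
}

#' Baseline features from the raw series
#'
#' Per-region mean followed by per-region SD (2R features), the signal-level
#' control against which connectivity-based decoding is compared.
#'
#' @param scan a [regional_scan()].
#' @return named numeric vector of length `2 R`.
#' @export
bold_baseline_features <- function(scan) {
  m <- colMeans(scan$data)
  s <- apply(scan$data, 2, sd)
  c(setNames(m, paste0("mean_", colnames(scan$data))),
    setNames(s, paste0("sd_", colnames(scan$data))))
}
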