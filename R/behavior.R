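#' Leave-one-out prediction of individual scores from connectivity
#'
#' For each score: a ridge-regularized linear regressor is fitted on all
#' subjects but one and predicts the left-out subject's score from that
#' subject's connectivity features; assembling the held-out predictions
#' gives a fully out-of-sample predicted vector, which is compared with
#' the observed scores by robust (percentage-bend) correlation.
#' Significance across scores is controlled with the Benjamini-Yekutieli
#' procedure, valid under arbitrary dependence between scores.
#'
#' @param features numeric matrix (subjects x features) or a
#'   `feature_table`.
#' @param scores numeric matrix (subjects x scores); NAs allowed and
#'   handled per score.
#' @param lambda ridge penalty.
#' @param bend percentage-bend constant.
#' @param alpha significance level for the BY correction.
#' @param min_subjects scores with fewer complete subjects are skipped.
#' @return object of class `prediction_result`: `summary` data frame
#'   (score, n, r, p, significant) and `details` (observed and predicted
#'   vectors per score).
#' @export
loo_predict <- function(features, scores, lambda = 1, bend = 0.2,
                        alpha = 0.05, min_subjects = 10) {
  x <- if (inherits(features, "feature_table")) features$x else
    as.matrix(features)
  scores <- as.matrix(scores)
  if (nrow(scores) != nrow(x)) stop("subjects misaligned")
  if (is.null(colnames(scores))) {
    colnames(scores) <- paste0("score", seq_len(ncol(scores)))
  }
  details <- list()
  rows <- list()
  for (j in seq_len(ncol(scores))) {
    ok <- which(!is.na(scores[, j]))
    if (length(ok) < min_subjects) {
      message("score ", colnames(scores)[j], " skipped: only ",
              length(ok), " complete subjects")
      next
    }
    pred <- loo_ridge(x[ok, , drop = FALSE], scores[ok, j], lambda)
    ct <- percentage_bend_corr(scores[ok, j], pred, bend = bend)
    details[[colnames(scores)[j]]] <-
      list(observed = scores[ok, j], predicted = pred, subjects = ok)
    rows[[length(rows) + 1]] <- data.frame(
      score = colnames(scores)[j], n = length(ok), r = ct[["r"]],
      p = ct[["p"]])
  }
  if (length(rows) == 0) stop("no score had enough complete subjects")
  sm <- do.call(rbind, rows)
  sm$significant <- by_correct(sm$p, alpha = alpha)
  structure(list(summary = sm, details = details, lambda = lambda,
                 bend = bend, alpha = alpha),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat("Leave-one-out score prediction (", nrow(x$summary), " scores, ",
      "ridge lambda = ", x$lambda, ")\n", sep = "")
  print(transform(x$summary, r = round(r, 3), p = signif(p, 3)),
        row.names = FALSE)
  invisible(x)
}

# leave-one-out ridge predictions; features are standardized with
# training-fold statistics so the penalty acts on a common scale, and the
# intercept is unpenalized
loo_ridge <- function(x, y, lambda) {
  n <- nrow(x)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    xt <- x[-i, , drop = FALSE]
    yt <- y[-i]
    mu <- colMeans(xt)
    sdv <- apply(xt, 2, sd)
    sdv[sdv < 1e-12] <- 1
    my <- mean(yt)
    xc <- sweep(sweep(xt, 2, mu), 2, sdv, `/`)
    b <- solve(crossprod(xc) + lambda * diag(ncol(x)),
               crossprod(xc, yt - my))
    pred[i] <- my + ((x[i, ] - mu) / sdv) %*% b
  }
  pred
}

#' Percentage-bend correlation
#'
#' Robust correlation that downweights marginal outliers: each variable is
#' centred at its percentage-bend measure of location, scaled by the
#' `(1 - bend)` quantile of absolute deviations from the median, clipped to
#' `[-1, 1]`, and the clipped scores are correlated.  The p value uses the
#' Student-t approximation on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (>= 4).
#' @param bend bending constant in (0, 0.5); 0.2 is the conventional
#'   default.
#' @return named vector `c(r, p)`.
#' @export
percentage_bend_corr <- function(x, y, bend = 0.2) {
  n <- length(x)
  if (length(y) != n || n < 4) stop("need equal-length vectors, n >= 4")
  a <- pb_scores(x, bend)
  b <- pb_scores(y, bend)
  r <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  c(r = r, p = p)
}

# clipped standardized scores around the percentage-bend location
pb_scores <- function(x, bend) {
  n <- length(x)
  omega <- sort(abs(x - median(x)))[floor((1 - bend) * n + 0.5)]
  if (omega <= 0) stop("zero robust scale: too many tied values")
  psi <- (x - median(x)) / omega
  i1 <- sum(psi < -1)
  i2 <- sum(psi > 1)
  sx <- ifelse(abs(psi) > 1, 0, x)
  loc <- (sum(sx) + omega * (i2 - i1)) / (n - i1 - i2)
  pmin(pmax((x - loc) / omega, -1), 1)
}

#' Benjamini-Yekutieli significance flags
#'
#' Step-up false-discovery-rate control with the harmonic-sum inflation
#' factor, valid under arbitrary dependence of the p values.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param alpha target FDR level.
#' @return logical vector of significance flags.
#' @export
by_correct <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BY") < alpha
}

#' Subject identification from composite score predictions
#'
#' Every score is z-scored across complete-case subjects and stacked into
#' a per-subject composite vector; each score is predicted out-of-sample
#' with [loo_predict()]'s regressor, and each subject's predicted composite
#' is correlated with every subject's observed composite.  If connectivity
#' carries individual-specific information, the diagonal (self) correlations
#' should be distributed above the off-diagonal ones, which is tested with
#' a two-sample Kolmogorov-Smirnov statistic.
#'
#' @param features matrix (subjects x features) or `feature_table`.
#' @param scores matrix (subjects x scores); only complete-case subjects
#'   are used.
#' @param lambda ridge penalty.
#' @return list with `corr` (subjects x subjects, rows = predicted),
#'   `ks_stat`, `p`, and the complete-case subject indices.
#' @export
composite_identify <- function(features, scores, lambda = 1) {
  x <- if (inherits(features, "feature_table")) features$x else
    as.matrix(features)
  scores <- as.matrix(scores)
  cc <- which(complete.cases(scores))
  if (length(cc) < 2) stop("need at least two complete-case subjects")
  x <- x[cc, , drop = FALSE]
  z <- scale(scores[cc, , drop = FALSE])
  pred <- vapply(seq_len(ncol(z)), function(j) {
    loo_ridge(x, z[, j], lambda)
  }, numeric(length(cc)))
  corr <- cor(t(pred), t(z))          # [predicted subject, observed subject]
  diag_r <- diag(corr)
  off_r <- corr[row(corr) != col(corr)]
  ks <- suppressWarnings(ks.test(diag_r, off_r, alternative = "less"))
  list(corr = corr, ks_stat = unname(ks$statistic), p = ks$p.value,
       subjects = cc)
}
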