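#' Fit a multivariate autoregressive model on a segmented scan
#'
#' Ordinary-least-squares fit of a VAR(p) model, pooling lagged
#' (predictor, response) pairs from every segment of the scan while never
#' forming a pair that crosses a segment junction.  Columns are demeaned per
#' segment before fitting (each segment may come from a different block of
#' the recording), and the residual covariance is normalised by the
#' effective regression sample count so that connectivity magnitudes remain
#' comparable across segmentations.
#'
#' @param scan a [regional_scan()].
#' @param order model order p (every segment must be longer than p).
#' @param demean `"segment"` (default) or `"none"`.
#' @return An object of class `slowgc_var` with components `order`, `coeffs`
#'   (list of p coefficient matrices A_1..A_p, rows = response region),
#'   `resid_cov`, `n_obs`, `region_names`, `residuals`, `tr`.
#' @examples
#' sc <- regional_scan(matrix(rnorm(600), 200, 3), tr = 0.75)
#' m <- fit_var(sc, order = 1)
#' coef(m)[[1]]
#' @export
fit_var <- function(scan, order = 1L, demean = c("segment", "none")) {
  demean <- match.arg(demean)
  p <- as.integer(order)
  if (p < 1) stop("order must be >= 1")
  R <- ncol(scan$data)
  xy <- lagged_design(scan, p, demean = demean == "segment")
  X <- xy$X
  Y <- xy$Y
  if (nrow(X) <= ncol(X)) stop("too few lagged pairs for order ", p)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- unique(((qrX$pivot[(qrX$rank + 1):ncol(X)] - 1) %% R) + 1)
    stop("singular regressor matrix; offending column(s): ",
         paste(colnames(scan$data)[bad], collapse = ", "))
  }
  B <- qr.coef(qrX, Y)                        # (pR) x R
  E <- Y - X %*% B
  Sigma <- crossprod(E) / nrow(X)
  Sigma <- (Sigma + t(Sigma)) / 2
  coeffs <- lapply(seq_len(p), function(k) {
    t(B[((k - 1) * R + 1):(k * R), , drop = FALSE])
  })
  nm <- colnames(scan$data)
  coeffs <- lapply(coeffs, function(A) {
    dimnames(A) <- list(nm, nm); A
  })
  dimnames(Sigma) <- list(nm, nm)
  structure(
    list(order = p, coeffs = coeffs, resid_cov = Sigma, n_obs = nrow(X),
         region_names = nm, residuals = E, tr = scan$tr,
         demean = demean),
    class = "slowgc_var")
}

# Stack the within-segment lagged design: Y rows are x_t, X rows are
# (x_{t-1}', ..., x_{t-p}').
lagged_design <- function(scan, p, demean = TRUE) {
  Xs <- list(); Ys <- list()
  for (rows in segment_rows(scan)) {
    if (length(rows) <= p) {
      stop("segment of length ", length(rows), " cannot support order ", p)
    }
    seg <- scan$data[rows, , drop = FALSE]
    if (demean) seg <- sweep(seg, 2, colMeans(seg))
    idx <- (p + 1):nrow(seg)
    Ys[[length(Ys) + 1]] <- seg[idx, , drop = FALSE]
    Xs[[length(Xs) + 1]] <- do.call(cbind, lapply(seq_len(p), function(k) {
      seg[idx - k, , drop = FALSE]
    }))
  }
  list(X = do.call(rbind, Xs), Y = do.call(rbind, Ys))
}

#' Construct a VAR model from known parameters
#'
#' Wraps ground-truth coefficient matrices and an innovation covariance in
#' the same object returned by [fit_var()], so population-level quantities
#' ([stationary_cov_var()], [population_gc()], [simulate.slowgc_var()]) can
#' be computed from a specification rather than a fit.
#'
#' @param coeffs a single R x R matrix or list of p such matrices (A_1..A_p).
#' @param resid_cov innovation covariance (default identity).
#' @param tr nominal sampling interval in seconds.
#' @return A `slowgc_var` object with `n_obs = Inf`.
#' @export
var_model <- function(coeffs, resid_cov = NULL, tr = 1) {
  if (is.matrix(coeffs)) coeffs <- list(coeffs)
  coeffs <- lapply(coeffs, as.matrix)
  R <- nrow(coeffs[[1]])
  if (is.null(resid_cov)) resid_cov <- diag(R)
  resid_cov <- (resid_cov + t(resid_cov)) / 2
  nm <- colnames(coeffs[[1]])
  if (is.null(nm)) nm <- paste0("R", seq_len(R))
  structure(
    list(order = length(coeffs), coeffs = coeffs, resid_cov = resid_cov,
         n_obs = Inf, region_names = nm, residuals = NULL, tr = tr,
         demean = "none"),
    class = "slowgc_var")
}

#' @export
coef.slowgc_var <- function(object, ...) object$coeffs

#' @export
residuals.slowgc_var <- function(object, ...) object$residuals

#' @export
print.slowgc_var <- function(x, ...) {
  cat("VAR(", x$order, ") model, ", length(x$region_names), " regions, ",
      if (is.finite(x$n_obs)) paste0(x$n_obs, " effective samples")
      else "population parameters", "\n", sep = "")
  cat("  spectral radius: ", format(spectral_radius(x), digits = 4),
      if (is_stable(x)) " (stable)" else " (UNSTABLE)", "\n", sep = "")
  invisible(x)
}

#' @export
summary.slowgc_var <- function(object, ...) {
  out <- list(order = object$order, n_obs = object$n_obs,
              spectral_radius = spectral_radius(object),
              stable = is_stable(object),
              resid_cov = object$resid_cov,
              coef_norms = vapply(object$coeffs, function(A) {
                norm(A, "F")
              }, numeric(1)))
  class(out) <- "summary.slowgc_var"
  out
}

#' @export
print.summary.slowgc_var <- function(x, ...) {
  cat("VAR(", x$order, ") fit: n_obs = ", x$n_obs,
      ", spectral radius = ", format(x$spectral_radius, digits = 4),
      " (", if (x$stable) "stable" else "unstable", ")\n", sep = "")
  cat("  Frobenius norm of A_k:",
      paste(format(x$coef_norms, digits = 3), collapse = ", "), "\n")
  cat("  residual covariance:\n")
  print(x$resid_cov, digits = 3)
  invisible(x)
}

#' One-step-ahead predictions from a fitted VAR
#'
#' @param object a `slowgc_var`.
#' @param newdata a [regional_scan()] (or numeric matrix, treated as a single
#'   segment); predictions use the model's per-segment demeaning convention.
#' @param ... unused.
#' @return matrix of one-step predictions aligned with the rows that have a
#'   full lag history within their segment.
#' @export
predict.slowgc_var <- function(object, newdata, ...) {
  if (is.matrix(newdata)) newdata <- regional_scan(newdata, tr = object$tr)
  xy <- lagged_design(newdata, object$order,
                      demean = object$demean == "segment")
  B <- do.call(rbind, lapply(object$coeffs, t))
  xy$X %*% B
}

#' Spectral radius of the companion matrix
#' @param model a `slowgc_var`.
#' @return largest eigenvalue modulus; the model is stable iff < 1.
#' @export
spectral_radius <- function(model) {
  max(Mod(eigen(companion_matrix(model$coeffs), only.values = TRUE)$values))
}

is_stable <- function(model) spectral_radius(model) < 1

#' Select VAR model order by AIC
#'
#' Fits orders 1..`p_max` and returns the order minimising
#' `log det(Sigma(p)) + 2 p R^2 / n`; ties resolve to the smallest order.
#'
#' @param scan a [regional_scan()].
#' @param p_max largest order to consider.
#' @return integer order.
#' @export
select_order_aic <- function(scan, p_max = 8L) {
  R <- ncol(scan$data)
  aic <- rep(NA_real_, p_max)
  for (p in seq_len(p_max)) {
    m <- tryCatch(fit_var(scan, p), error = function(e) NULL)
    if (is.null(m)) break
    aic[p] <- determinant(m$resid_cov)$modulus + 2 * p * R^2 / m$n_obs
  }
  if (all(is.na(aic))) stop("no order could be fitted")
  which.min(aic)                      # which.min takes the first minimum
}

#' Sample lagged covariance, segment-aware
#'
#' Averages outer products `x_t x_{t-lag}'` over all within-segment pairs,
#' after per-segment demeaning; pairs never span a junction.
#'
#' @param scan a [regional_scan()].
#' @param lag nonnegative integer lag.
#' @return list with `lag` and `matrix` (`Sigma_lag = E[x_t x_{t-lag}']`).
#' @export
lagged_covariance <- function(scan, lag = 1L) {
  lag <- as.integer(lag)
  if (lag < 0) stop("lag must be nonnegative")
  R <- ncol(scan$data)
  S <- matrix(0, R, R)
  n <- 0L
  for (rows in segment_rows(scan)) {
    if (length(rows) <= lag) next
    seg <- sweep(scan$data[rows, , drop = FALSE], 2,
                 colMeans(scan$data[rows, , drop = FALSE]))
    idx <- (lag + 1):nrow(seg)
    S <- S + t(seg[idx, , drop = FALSE]) %*% seg[idx - lag, , drop = FALSE]
    n <- n + length(idx)
  }
  if (n == 0) stop("no segment longer than the requested lag")
  M <- S / n
  if (lag == 0) M <- (M + t(M)) / 2
  list(lag = lag, matrix = M)
}

#' Stationary covariance of a stable VAR model
#'
#' Solves the discrete-time Lyapunov equation for the companion form and
#' returns the top-left R x R block, i.e. the zero-lag autocovariance
#' Gamma(0) of the stationary process.
#'
#' @param model a `slowgc_var` (must be stable).
#' @return symmetric positive-semidefinite matrix.
#' @export
stationary_cov_var <- function(model) {
  if (!is_stable(model)) stop("model is not stable")
  acov_var(model$coeffs, model$resid_cov, 0)[[1]]
}
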