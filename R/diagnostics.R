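#' Stationarity and model-adequacy diagnostics
#'
#' Runs four checks of whether a VAR fit is a valid, adequate description of
#' a scan: (1) stability, via the log spectral radius of the companion
#' matrix (pass if negative); (2) consistency, the percentage of the data's
#' correlation structure (lag-0 and lag-1 covariances) captured by the
#' model's one-step predictions (pass at 80% or above); (3) residual
#' whiteness, via the Durbin-Watson statistic per regional series (pass if
#' the statistic lies in (1, 3) for more than 90% of series); and (4)
#' stationarity, via the augmented Dickey-Fuller unit-root test per series
#' (pass if the test statistic is below its 5% critical value for more than
#' 90% of series).
#'
#' @param scan the [regional_scan()] the model was fitted on.
#' @param model the fitted `slowgc_var`.
#' @param consistency_threshold_pct,dw_fraction,adf_fraction pass thresholds.
#' @return An object of class `stationarity_report`.
#' @export
stationarity_tests <- function(scan, model,
                               consistency_threshold_pct = 80,
                               dw_fraction = 0.9, adf_fraction = 0.9) {
  lsr <- log(spectral_radius(model))
  cons <- consistency_pct(scan, model)
  dw <- apply(model$residuals, 2, durbin_watson)
  dwf <- mean(dw > 1 & dw < 3)
  adf <- apply(scan$data, 2, function(x) adf_test(x))
  adff <- mean(vapply(adf, function(a) a$stat < a$crit, logical(1)))
  passed <- c(stability = lsr < 0,
              consistency = cons >= consistency_threshold_pct,
              whiteness = dwf > dw_fraction,
              stationarity = adff > adf_fraction)
  structure(list(log_spectral_radius = lsr, consistency_pct = cons,
                 dw = dw, dw_pass_fraction = dwf,
                 adf_stats = vapply(adf, `[[`, numeric(1), "stat"),
                 adf_crit = adf[[1]]$crit, adf_pass_fraction = adff,
                 passed = passed),
            class = "stationarity_report")
}

#' @export
print.stationarity_report <- function(x, ...) {
  ok <- function(b) if (b) "pass" else "FAIL"
  cat("Stationarity / model-adequacy report\n")
  cat(sprintf("  stability:    log spectral radius = %.4f  [%s]\n",
              x$log_spectral_radius, ok(x$passed["stability"])))
  cat(sprintf("  consistency:  %.1f%%  [%s]\n", x$consistency_pct,
              ok(x$passed["consistency"])))
  cat(sprintf("  whiteness:    DW in (1,3) for %.0f%% of series  [%s]\n",
              100 * x$dw_pass_fraction, ok(x$passed["whiteness"])))
  cat(sprintf("  stationarity: ADF below critical for %.0f%% of series  [%s]\n",
              100 * x$adf_pass_fraction, ok(x$passed["stationarity"])))
  invisible(x)
}

# Fraction of the data correlation structure (lag-0 and lag-1 covariance
# entries) captured by the model's one-step predictions, as a percentage.
consistency_pct <- function(scan, model) {
  pred_rows <- list(); data_rows <- list()
  p <- model$order
  B <- do.call(rbind, lapply(model$coeffs, t))
  for (rows in segment_rows(scan)) {
    seg <- scan$data[rows, , drop = FALSE]
    if (model$demean == "segment") seg <- sweep(seg, 2, colMeans(seg))
    if (nrow(seg) <= p) next
    idx <- (p + 1):nrow(seg)
    X <- do.call(cbind, lapply(seq_len(p), function(k) {
      seg[idx - k, , drop = FALSE]
    }))
    pred_rows[[length(pred_rows) + 1]] <- X %*% B
    data_rows[[length(data_rows) + 1]] <- seg[idx, , drop = FALSE]
  }
  pred <- do.call(rbind, pred_rows)
  dat <- do.call(rbind, data_rows)
  cvec <- function(M) {
    n <- nrow(M)
    c(crossprod(M) / n, crossprod(M[-1, , drop = FALSE],
                                  M[-n, , drop = FALSE]) / (n - 1))
  }
  cd <- cvec(dat)
  100 * (1 - sqrt(sum((cvec(pred) - cd)^2)) / sqrt(sum(cd^2)))
}

durbin_watson <- function(e) sum(diff(e)^2) / sum(e^2)

# Augmented Dickey-Fuller regression with constant:
#   diff(y)_t = a + b*y_{t-1} + sum_k g_k diff(y)_{t-k} + e_t
# Statistic is the t ratio of b; critical value is the MacKinnon 5%
# response-surface value for the constant-only case.
adf_test <- function(y, lags = NULL) {
  n <- length(y)
  if (is.null(lags)) lags <- max(1L, floor(4 * (n / 100)^0.25))
  dy <- diff(y)
  T <- length(dy) - lags
  yl <- y[(lags + 1):(n - 1)]
  Dy <- dy[(lags + 1):length(dy)]
  X <- cbind(1, yl)
  for (k in seq_len(lags)) X <- cbind(X, dy[(lags + 1 - k):(length(dy) - k)])
  fit <- stats::lm.fit(X, Dy)
  s2 <- sum(fit$residuals^2) / (T - ncol(X))
  XtXinv <- chol2inv(chol(crossprod(X)))
  stat <- fit$coefficients[2] / sqrt(s2 * XtXinv[2, 2])
  crit <- -2.8621 - 2.738 / T - 8.36 / T^2 - 4.85 / T^3
  list(stat = unname(stat), crit = crit, lags = lags)
}
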